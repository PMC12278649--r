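# Task-level utilities: unit conversion, xenograft responses, data splits
# with leakage guarantees, evaluation metrics, and DDI negative sampling.

#' Convert FPKM to TPM
#'
#' `tpm[i, j] = fpkm[i, j] / sum_k fpkm[k, j] * 1e6`; every column of the
#' result sums to one million.  Idempotent on TPM input.
#'
#' @param m Nonnegative matrix (genes x contexts).
#' @return Matrix of the same shape with `unit` attribute `"TPM"`.
#' @export
fpkm_to_tpm <- function(m) {
  if (any(m < 0)) stop("negative expression values")
  cs <- colSums(m)
  if (any(cs == 0)) {
    bad <- colnames(m)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("all-zero expression column(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(m, 2, cs, "/") * 1e6
  attr(out, "unit") <- "TPM"
  out
}

#' Xenograft trajectory container
#'
#' @param model_id Xenograft model id.
#' @param drug_a,drug_b Drug ids (single-drug records use the same id
#'   twice).
#' @param t Strictly increasing integer days post transplantation.
#' @param dvol Relative tumor-volume change `(Vol_t - Vol_0)/Vol_0` at
#'   each `t`; if day 0 is present its change must be 0.
#' @param permissive If `TRUE`, unordered time points are sorted (with
#'   their volumes) instead of rejected; duplicates remain an error.
#' @return A `xeno_trajectory`.
#' @export
xeno_trajectory <- function(model_id, drug_a, drug_b, t, dvol,
                            permissive = FALSE) {
  stopifnot(length(t) == length(dvol), length(t) >= 1L)
  if (permissive) {
    ord <- order(t)
    t <- t[ord]
    dvol <- dvol[ord]
  }
  if (is.unsorted(t, strictly = TRUE))
    stop("time points must be strictly increasing")
  if (any(t == 0) && abs(dvol[t == 0]) > 1e-12)
    stop("relative volume change at day 0 must be 0")
  structure(list(model_id = model_id, drug_a = drug_a, drug_b = drug_b,
                 t = as.integer(t), dvol = dvol),
            class = "xeno_trajectory")
}

#' BestResponse of a xenograft trajectory
#'
#' The minimum relative tumor-volume change over all time points at or
#' after day 10.
#'
#' @param traj A `xeno_trajectory` (or list with `t` and `dvol`).
#' @param min_day Day cutoff (default 10).
#' @return Scalar minimum change.
#' @export
best_response <- function(traj, min_day = 10) {
  keep <- traj$t >= min_day
  if (!any(keep))
    stop("no time point at or after day ", min_day)
  min(traj$dvol[keep])
}

#' Split a triplet dataset
#'
#' Seeded train/validation/test partitions with verifiable leakage
#' constraints:
#' \describe{
#'   \item{vanilla}{uniform split of triplets.}
#'   \item{by_combination}{unordered drug pairs are split; no test pair
#'     occurs in train (in either order).}
#'   \item{by_cell_line}{contexts are split; no test context occurs in
#'     train.}
#'   \item{ddi_one_new_drug}{drugs are split into seen/unseen; test pairs
#'     have exactly one unseen drug, train pairs none.}
#'   \item{ddi_two_new_drugs}{test pairs have both drugs unseen.}
#' }
#' For the DDI modes the validation set is carved from the both-seen pool
#' and triplets that fit neither constraint are dropped.
#'
#' @param triplets Triplet `data.frame`.
#' @param mode One of the five modes above.
#' @param fractions Train/valid/test fractions summing to 1.
#' @param seed Integer seed.
#' @return List of integer row-index vectors `train`, `valid`, `test`.
#' @export
make_splits <- function(triplets, mode = c("vanilla", "by_combination",
                                           "by_cell_line",
                                           "ddi_one_new_drug",
                                           "ddi_two_new_drugs"),
                        fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(abs(sum(fractions) - 1) < 1e-8, nrow(triplets) >= 1L)
  set.seed(seed)
  n <- nrow(triplets)
  three_way <- function(units) {
    u <- sample(units)
    n1 <- max(1L, round(length(u) * fractions[1]))
    n2 <- max(1L, round(length(u) * fractions[2]))
    if (n1 + n2 >= length(u)) stop("dataset too small to split")
    list(train = u[seq_len(n1)],
         valid = u[n1 + seq_len(n2)],
         test = u[(n1 + n2 + 1L):length(u)])
  }
  if (mode == "vanilla") {
    return(three_way(seq_len(n)))
  }
  if (mode == "by_combination") {
    pair <- paste(pmin(triplets$drug_a, triplets$drug_b),
                  pmax(triplets$drug_a, triplets$drug_b), sep = "\r")
    sp <- three_way(unique(pair))
    return(list(train = which(pair %in% sp$train),
                valid = which(pair %in% sp$valid),
                test = which(pair %in% sp$test)))
  }
  if (mode == "by_cell_line") {
    sp <- three_way(unique(triplets$context))
    return(list(train = which(triplets$context %in% sp$train),
                valid = which(triplets$context %in% sp$valid),
                test = which(triplets$context %in% sp$test)))
  }
  # DDI new-drug modes
  drugs <- unique(c(triplets$drug_a, triplets$drug_b))
  if (length(drugs) < 3L) stop("dataset too small to split")
  min_unseen <- if (mode == "ddi_two_new_drugs") 2L else 1L
  unseen <- sample(drugs, max(min_unseen,
                              round(length(drugs) * fractions[3])))
  a_new <- triplets$drug_a %in% unseen
  b_new <- triplets$drug_b %in% unseen
  test <- if (mode == "ddi_one_new_drug") which(xor(a_new, b_new))
          else which(a_new & b_new)
  pool <- which(!a_new & !b_new)
  if (length(test) == 0L || length(pool) < 2L)
    stop("dataset too small for the '", mode, "' constraint")
  nv <- max(1L, round(length(pool) * fractions[2] /
                        (fractions[1] + fractions[2])))
  if (nv >= length(pool)) stop("dataset too small to split")
  vid <- sample(pool, nv)
  list(train = setdiff(pool, vid), valid = vid, test = test)
}

#' Classification and regression metrics
#'
#' Classification (threshold 0.5, scores at exactly 0.5 call positive):
#' balanced accuracy (mean of sensitivity and specificity), area under
#' the precision-recall curve by step-wise integration, F1 and Cohen's
#' kappa.  Regression: Spearman and Pearson correlations (average ranks
#' on ties).
#'
#' @param labels 0/1 vector (classification) or real vector (regression).
#' @param scores Predicted scores, same length.
#' @param mode `"classification"` or `"regression"`.
#' @return Named list of metric values.
#' @export
eval_metrics <- function(labels, scores,
                         mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  if (mode == "regression") {
    return(list(spearman = stats::cor(labels, scores, method = "spearman"),
                pearson = stats::cor(labels, scores, method = "pearson")))
  }
  if (length(unique(labels)) < 2L)
    stop("threshold metrics need both classes present")
  call <- as.integer(scores >= 0.5)
  tp <- sum(call == 1 & labels == 1); fp <- sum(call == 1 & labels == 0)
  tn <- sum(call == 0 & labels == 0); fn <- sum(call == 0 & labels == 1)
  tpr <- tp / (tp + fn); tnr <- tn / (tn + fp)
  bacc <- (tpr + tnr) / 2
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  n <- length(labels)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
  list(bacc = bacc, auprc = auprc(labels, scores), f1 = f1, kappa = kappa)
}

# Area under the precision-recall curve: step-wise (no linear
# interpolation), descending unique score thresholds; equals average
# precision.
auprc <- function(labels, scores) {
  ord <- order(-scores)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  npos <- sum(y)
  if (npos == 0) return(NA_real_)
  # evaluate at the last index of each tied score block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  prec <- tp[last] / (tp[last] + fp[last])
  rec <- tp[last] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Negative sampling for DDI training
#'
#' Draws uniformly from the space of (unordered drug pair, interaction
#' type) triplets that do not occur among the positives, without
#' duplicates, until the negative set matches the positive count.
#'
#' @param positives `data.frame` with `drug_a`, `drug_b`, `context`
#'   (interaction type).
#' @param drugs Character vector of candidate drug ids.
#' @param types Character vector of interaction types.
#' @param seed Integer seed.
#' @param preserve_type_marginal If `TRUE`, draw each negative's type from
#'   the positives' type distribution rather than uniformly.
#' @return `data.frame` of negatives (`label = 0`), same count as
#'   positives.
#' @export
negative_sample_ddi <- function(positives, drugs, types, seed = 1L,
                                preserve_type_marginal = FALSE) {
  set.seed(seed)
  key <- function(a, b, ty) paste(pmin(a, b), pmax(a, b), ty, sep = "\r")
  pos_keys <- key(positives$drug_a, positives$drug_b, positives$context)
  n_pairs <- length(drugs) * (length(drugs) - 1) / 2
  space <- n_pairs * length(types)
  need <- nrow(positives)
  if (space - length(unique(pos_keys)) < need)
    stop("negative space exhausted: ", space - length(unique(pos_keys)),
         " candidates for ", need, " negatives")
  seen <- new.env(parent = emptyenv())
  for (k in pos_keys) assign(k, TRUE, envir = seen)
  out_a <- character(need); out_b <- character(need)
  out_t <- character(need)
  got <- 0L
  guard <- 0L
  while (got < need) {
    guard <- guard + 1L
    if (guard > 1000L * need)
      stop("negative sampling failed to find enough candidates")
    pr <- sample(drugs, 2L)
    ty <- if (preserve_type_marginal) sample(positives$context, 1L)
          else sample(types, 1L)
    k <- key(pr[1], pr[2], ty)
    if (!is.null(seen[[k]])) next
    assign(k, TRUE, envir = seen)
    got <- got + 1L
    out_a[got] <- min(pr); out_b[got] <- max(pr); out_t[got] <- ty
  }
  data.frame(drug_a = out_a, drug_b = out_b, context = out_t,
             label = rep(0L, need), stringsAsFactors = FALSE)
}
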