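# Training objectives: supervised (aggregated + sampled-view auxiliary)
# plus two consistency terms that tie the augmented views of one triplet
# together — an InfoNCE loss in the view-embedding space and a soft-label
# mean-squared-error in the output space.
#
# Batch losses are reported as per-sample means so values are comparable
# across batch sizes; the relative weighting of the terms is carried
# entirely by the lambda hyperparameters.

#' Sample modality pairs for the auxiliary and consistency terms
#'
#' Draws `min(r, length(keys))` distinct view keys uniformly without
#' replacement.  Reproducible given the RNG state (seed the session or
#' pass `seed`).
#'
#' @param keys Vector of candidate view keys (canonical slots 1..64, or
#'   any nonempty subset).
#' @param r Number of pairs to draw (default 2).
#' @param seed Optional integer seed applied before drawing.
#' @return Vector of sampled keys.
#' @export
sample_modality_pairs <- function(keys, r = 2L, seed = NULL) {
  if (length(keys) == 0L) stop("no available view keys to sample from")
  if (!is.null(seed)) set.seed(seed)
  n <- min(r, length(keys))
  keys[sample.int(length(keys), n)]
}

bce <- function(y, p) -mean(y * log(p) + (1 - y) * log(1 - p))

#' Supervised loss
#'
#' Per-sample mean loss on the aggregated prediction plus `lambda_aux`
#' times the summed per-view losses over the sampled modality pairs.
#' Binary cross-entropy for classification; squared error for the
#' xenograft regression mode.
#'
#' @param labels Numeric vector (0/1 for classification, real for
#'   regression).
#' @param yhat_star Aggregated predictions, same length.
#' @param view_preds List over sampled modality pairs; each element a list
#'   with `pred` and `triplet` (indices into `labels`) for the views that
#'   exist.  May be empty.
#' @param lambda_aux Auxiliary weight.
#' @param mode `"classification"` or `"regression"`.
#' @return List: `total`, `main`, `aux`.
#' @export
supervised_loss <- function(labels, yhat_star, view_preds = list(),
                            lambda_aux = 0.01,
                            mode = c("classification", "regression")) {
  mode <- match.arg(mode)
  lossfn <- if (mode == "classification") bce
            else function(y, p) mean((y - p)^2)
  main <- lossfn(labels, yhat_star)
  aux <- 0
  for (vp in view_preds) {
    if (length(vp$pred) == 0L) next
    aux <- aux + lossfn(labels[vp$triplet], vp$pred)
  }
  list(total = main + lambda_aux * aux, main = main, aux = aux)
}

#' InfoNCE consistency between two sampled views
#'
#' Cross-entropy of matching each triplet's first-sampled-view embedding
#' to its own second-sampled-view embedding against all second-view
#' embeddings in the batch, under cosine similarity (temperature 1).
#' Mean over the batch: with all similarities equal the loss is `log(N)`.
#'
#' @param z1,z2 Matrices (N x d), rows aligned by triplet; `N >= 2`.
#' @return Scalar loss.
#' @export
consistency_infonce <- function(z1, z2) {
  z1 <- as.matrix(z1); z2 <- as.matrix(z2)
  if (nrow(z1) < 2L || nrow(z1) != nrow(z2))
    stop("need aligned batches with N >= 2")
  n1 <- sqrt(rowSums(z1^2)); n2 <- sqrt(rowSums(z2^2))
  if (any(n1 < 1e-12) || any(n2 < 1e-12))
    stop("zero-norm view embedding in the InfoNCE batch")
  S <- (z1 / n1) %*% t(z2 / n2)
  lse <- apply(S, 1, function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  })
  mean(lse - diag(S))
}

#' Soft-label output consistency
#'
#' Mean squared difference between each sampled view's prediction and the
#' aggregated prediction, with the aggregated prediction treated as a
#' fixed soft label (no gradient flows through it during training).
#'
#' @param yhat_star Aggregated predictions per triplet.
#' @param view_preds As in [supervised_loss()].
#' @return Scalar: mean over all contributing (triplet, pair) entries;
#'   0 if none contribute.
#' @export
consistency_mse <- function(yhat_star, view_preds) {
  num <- 0; cnt <- 0L
  for (vp in view_preds) {
    if (length(vp$pred) == 0L) next
    num <- num + sum((yhat_star[vp$triplet] - vp$pred)^2)
    cnt <- cnt + length(vp$pred)
  }
  if (cnt == 0L) 0 else num / cnt
}

#' Compose a loss breakdown
#'
#' @param main,aux,infonce,mse Component values.
#' @param lambda_aux,lambda_infonce,lambda_mse Weights.
#' @return List (`loss_breakdown`) with components, lambdas and `total =
#'   main + lambda_aux*aux + lambda_infonce*infonce + lambda_mse*mse`.
#' @export
loss_breakdown <- function(main, aux, infonce, mse, lambda_aux,
                           lambda_infonce, lambda_mse) {
  structure(list(
    total = main + lambda_aux * aux + lambda_infonce * infonce +
      lambda_mse * mse,
    supervised_main = main, supervised_aux = aux,
    infonce = infonce, mse = mse,
    lambda_aux = lambda_aux, lambda_infonce = lambda_infonce,
    lambda_mse = lambda_mse), class = "loss_breakdown")
}

# ---- tape-level batch objective -----------------------------------------

# Builds the full training loss for one batch on the tape.  Returns node
# ids for the total and each component plus the forward structures.
tape_training_loss <- function(model, params, batch, ctx_cache,
                               sampled_keys, train = TRUE,
                               labels = NULL, soft_labels = NULL) {
  cfg <- model$cfg
  fw <- forward_batch(model, params, batch, ctx_cache, train = train)
  tp <- fw$tp
  y <- if (is.null(labels)) batch$label else labels
  regression <- model$task == "xenograft"
  main <- if (regression) ad_mse_mean(tp, fw$yhat, y)
          else ad_bce_mean(tp, fw$yhat, y)

  zero <- function() ad_leaf(tp, matrix(0))
  aux <- NULL
  rows_all <- integer(0); tri_all <- integer(0)
  for (k in sampled_keys) {
    rows <- which(fw$plan$key == k)
    rows_all <- c(rows_all, rows)
    tri_all <- c(tri_all, fw$plan$triplet[rows])
    if (length(rows) == 0L) next
    vp <- ad_gather_rows(tp, fw$preds, rows)
    term <- if (regression) ad_mse_mean(tp, vp, y[fw$plan$triplet[rows]])
            else ad_bce_mean(tp, vp, y[fw$plan$triplet[rows]])
    aux <- if (is.null(aux)) term else ad_add(tp, aux, term)
  }
  if (is.null(aux)) aux <- zero()

  # InfoNCE over the first two sampled keys, on triplets that carry both
  info <- zero()
  if (length(sampled_keys) >= 2L) {
    k1 <- sampled_keys[1]; k2 <- sampled_keys[2]
    r1 <- which(fw$plan$key == k1); r2 <- which(fw$plan$key == k2)
    common <- intersect(fw$plan$triplet[r1], fw$plan$triplet[r2])
    if (length(common) >= 2L) {
      rows1 <- r1[match(common, fw$plan$triplet[r1])]
      rows2 <- r2[match(common, fw$plan$triplet[r2])]
      z1 <- ad_gather_rows(tp, fw$view_emb, rows1)
      z2 <- ad_gather_rows(tp, fw$view_emb, rows2)
      z1n <- ad_rowdiv(tp, z1, ad_rownorms(tp, z1))
      z2n <- ad_rowdiv(tp, z2, ad_rownorms(tp, z2))
      S <- ad_matmul(tp, z1n, ad_transpose(tp, z2n))
      info <- ad_mean(tp, ad_sub(tp, ad_logsumexp_rows(tp, S),
                                 ad_diag(tp, S)))
    }
  }

  # soft-label MSE: aggregated prediction detached (constant target)
  msec <- zero()
  if (length(rows_all)) {
    soft <- if (is.null(soft_labels)) as.numeric(ad_value(tp, fw$yhat))
            else soft_labels
    soft <- soft[tri_all]
    msec <- ad_mse_mean(tp, ad_gather_rows(tp, fw$preds, rows_all), soft)
  }

  total <- main
  if (cfg$lambda_aux > 0)
    total <- ad_add(tp, total, ad_scale(tp, aux, cfg$lambda_aux))
  if (cfg$lambda_infonce > 0)
    total <- ad_add(tp, total, ad_scale(tp, info, cfg$lambda_infonce))
  if (cfg$lambda_mse > 0)
    total <- ad_add(tp, total, ad_scale(tp, msec, cfg$lambda_mse))

  list(tp = tp, fw = fw, total = total, main = main, aux = aux,
       infonce = info, mse = msec)
}
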