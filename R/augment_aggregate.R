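# The augmentor (modality-pair view enumeration and view embeddings) and
# the aggregator (top-k noisy-label masking + affine + shortcut), plus the
# per-view prediction heads and the batched tape forward pass they share.

#' Enumerate modality-pair views for a drug pair
#'
#' The full Cartesian product of drug A's available modalities with drug
#' B's, in canonical modality order: two fully profiled drugs give the
#' maximal 64 views, 5 x 4 availability gives 20.
#'
#' @param avail_a,avail_b Nonempty character vectors of modality ids.
#' @param drug_a,drug_b Optional drug ids used in error messages.
#' @return `data.frame` with columns `ma`, `mb` and the canonical slot
#'   `key` (1..64).
#' @export
#' @examples
#' nrow(enumerate_views(modality_ids(), modality_ids()))  # 64
enumerate_views <- function(avail_a, avail_b, drug_a = "drug A",
                            drug_b = "drug B") {
  M <- modality_ids()
  avail_a <- intersect(M, avail_a)
  avail_b <- intersect(M, avail_b)
  if (length(avail_a) == 0L)
    stop("no available modalities for ", drug_a)
  if (length(avail_b) == 0L)
    stop("no available modalities for ", drug_b)
  grid <- expand.grid(mb = avail_b, ma = avail_a,
                      stringsAsFactors = FALSE)[, c("ma", "mb")]
  ia <- match(grid$ma, M); ib <- match(grid$mb, M)
  out <- data.frame(ma = grid$ma, mb = grid$mb,
                    key = (ia - 1L) * length(M) + ib,
                    stringsAsFactors = FALSE)
  out[order(out$key), , drop = FALSE]
}

view_key_label <- function(key) {
  M <- modality_ids()
  ia <- (key - 1L) %/% length(M) + 1L
  ib <- (key - 1L) %% length(M) + 1L
  paste0(M[ia], "|", M[ib])
}

#' Top-k masking of view predictions
#'
#' Keeps the `min(k, n)` largest entries and zeroes the rest, the noisy-
#' label step of the aggregator.  Ties are broken in favor of the earlier
#' (canonical) position so the retained set is reproducible.
#'
#' @param predictions Nonempty numeric vector.
#' @param k Number of entries to keep, `>= 1`.
#' @return List: `masked` (vector with non-top entries zeroed) and
#'   `retained` (indices kept, in canonical order).
#' @export
top_k_mask <- function(predictions, k) {
  if (length(predictions) == 0L) stop("empty prediction vector")
  stopifnot(k >= 1L)
  keep <- min(k, length(predictions))
  ord <- order(-predictions, seq_along(predictions))
  retained <- sort(ord[seq_len(keep)])
  masked <- numeric(length(predictions))
  masked[retained] <- predictions[retained]
  list(masked = masked, retained = retained)
}

#' Aggregate per-view predictions
#'
#' The refined prediction is an affine read-out of the top-k-masked
#' prediction vector plus a shortcut: `y* = w_nll' masked + sum(top-k)/k`.
#' With `w_nll = 0` this is exactly the mean of the retained top-k.  For
#' classification tasks the result is clamped into `(0, 1)` by
#' `eps = 1e-7`, because the affine term can leave the unit interval; for
#' regression it is returned unclamped.
#'
#' @param predictions Numeric vector of per-view predictions in canonical
#'   slot order (use `keys` when the vector covers a subset of the 64
#'   slots).
#' @param k Top-k size (effective k is `min(k, n)`).
#' @param w_nll Affine weight vector; either length 64 (canonical slots)
#'   or one weight per prediction.  Default all zeros.
#' @param keys Optional canonical slot (1..64) of each prediction.
#' @param task `"classification"` (clamped) or `"regression"`.
#' @param shortcut `"topk_mean"` (sum of retained top-k over effective k)
#'   or `"all_mean"` (sum of all predictions over k).
#' @return List (`aggregated_prediction`): `value`, `retained` (canonical
#'   keys of the retained views), `k_effective`.
#' @export
aggregate_views <- function(predictions, k, w_nll = NULL, keys = NULL,
                            task = c("classification", "regression"),
                            shortcut = c("topk_mean", "all_mean")) {
  task <- match.arg(task)
  shortcut <- match.arg(shortcut)
  n <- length(predictions)
  if (n == 0L) stop("empty prediction vector")
  if (is.null(keys)) keys <- seq_len(n)
  if (is.null(w_nll)) w_nll <- numeric(64L)
  w <- if (length(w_nll) == 64L) w_nll[keys] else w_nll
  mk <- top_k_mask(predictions, k)
  k_eff <- min(k, n)
  sc <- if (shortcut == "topk_mean") sum(mk$masked) / k_eff
        else sum(predictions) / k
  val <- sum(w * mk$masked) + sc
  if (task == "classification") val <- min(max(val, 1e-7), 1 - 1e-7)
  structure(list(value = val, retained = keys[mk$retained],
                 k_effective = k_eff),
            class = "aggregated_prediction")
}

#' Build one view embedding
#'
#' One-layer augmentor transformation of the concatenated drug-pair and
#' context embeddings: `ReLU(W' [z_a | z_b | c])`, from `3*dhid` to
#' `2*dhid` (evaluation mode; dropout off).
#'
#' @param z_ma,z_mb Drug modality embeddings, length `dhid`.
#' @param context Context vector, length `dhid`.
#' @param model A `pairviews_model` for the synergy/xenograft tasks.
#' @return Numeric vector of length `2*dhid`.
#' @export
build_view_embedding <- function(z_ma, z_mb, context, model) {
  dh <- model$cfg$dhid
  if (length(z_ma) != dh || length(z_mb) != dh || length(context) != dh)
    stop("z_ma, z_mb and context must all have length dhid = ", dh)
  x <- matrix(c(z_ma, z_mb, context), nrow = 1)
  as.numeric(pmax(x %*% model$params$aug_W +
                    matrix(model$params$aug_b, 1), 0))
}

#' Per-view synergy prediction head
#'
#' Two-layer read-out with a sigmoid: `sigmoid(w2' ReLU(W1' z))`, mapping
#' a `2*dhid` view embedding to a probability in (0, 1).
#'
#' @param view_emb Numeric vector of length `2*dhid`.
#' @param model A `pairviews_model`.
#' @return Probability.
#' @export
predict_view_synergy <- function(view_emb, model) {
  P <- model$params
  if (length(view_emb) != 2L * model$cfg$dhid)
    stop("view embedding must have length 2*dhid")
  h <- pmax(matrix(view_emb, 1) %*% P$head_W1 + matrix(P$head_b1, 1), 0)
  s <- as.numeric(h %*% P$head_w2 + P$head_b2)
  1 / (1 + exp(-s))
}

#' Per-view interaction (DDI) prediction head
#'
#' Bilinear scoring between the drug-pair view embedding and the
#' interaction-type context: `sigmoid(tanh(wz' z)' c_hat)` with
#' `c_hat = tanh(c + wc' [z | c])` (evaluation mode).
#'
#' @param view_emb Drug-pair view embedding, length `2*dhid` (the DDI
#'   augmentor concatenates the two drugs only; the context enters through
#'   `c_hat`).
#' @param context Interaction-type embedding, length `dhid`.
#' @param model A `pairviews_model` initialized for the DDI task.
#' @return Probability.
#' @export
predict_view_ddi <- function(view_emb, context, model) {
  P <- model$params
  dh <- model$cfg$dhid
  if (length(view_emb) != 2L * dh) stop("view embedding must be 2*dhid")
  if (length(context) != dh) stop("context must be dhid")
  z <- matrix(view_emb, 1); cc <- matrix(context, 1)
  chat <- tanh(cc + cbind(z, cc) %*% P$ddi_wc)
  tz <- tanh(z %*% P$ddi_wz)
  1 / (1 + exp(-sum(tz * chat)))
}

# ---- batched forward pass on the tape -----------------------------------

# Cached per-pair view enumeration (availability is static per model)
pair_views_cached <- function(model, a, b) {
  key <- paste(a, b, sep = "\r")
  v <- model$plan_cache[[key]]
  if (is.null(v)) {
    va <- enumerate_views(model_availability(model, a),
                          model_availability(model, b), a, b)
    v <- list(ka = paste(va$ma, a, sep = "\r"),
              kb = paste(va$mb, b, sep = "\r"), key = va$key)
    assign(key, v, envir = model$plan_cache)
  }
  v
}

# Build the per-triplet view inventory: which (ma, mb) views exist and
# which row of the stacked drug-embedding matrix each side uses.
plan_views <- function(model, triplets, emb_index) {
  n <- nrow(triplets)
  vs <- vector("list", n)
  for (i in seq_len(n))
    vs[[i]] <- pair_views_cached(model, triplets$drug_a[i],
                                 triplets$drug_b[i])
  nv <- vapply(vs, function(v) length(v$key), 1L)
  list(triplet = rep.int(seq_len(n), nv),
       key = unlist(lapply(vs, `[[`, "key"), use.names = FALSE),
       row_a = unname(emb_index[unlist(lapply(vs, `[[`, "ka"),
                                       use.names = FALSE)]),
       row_b = unname(emb_index[unlist(lapply(vs, `[[`, "kb"),
                                       use.names = FALSE)]))
}

# dropout helper: inverted-dropout mask as a constant (draws from the
# current RNG stream, so training remains seed-deterministic)
tape_dropout <- function(tp, x, p, train) {
  if (!train || p <= 0) return(x)
  v <- ad_value(tp, x)
  mask <- matrix(stats::rbinom(length(v), 1L, 1 - p), nrow(v)) / (1 - p)
  ad_mul_const(tp, x, mask)
}

# Full forward pass for a batch of triplets.  Returns tape node ids for the
# per-view embeddings/predictions and the aggregated prediction, plus the
# view plan (triplet, canonical key) needed by the objectives.
forward_batch <- function(model, params, triplets, ctx_cache,
                          train = FALSE, tp = NULL) {
  cfg <- model$cfg
  if (is.null(tp)) tp <- ad_tape(4096L)
  P <- push_params(tp, params)
  drug_ids <- unique(c(triplets$drug_a, triplets$drug_b))
  DE <- tape_drug_embeddings(tp, P, model, drug_ids)
  # stack modality blocks into one matrix; global row lookup (modality,drug)
  Mseq <- intersect(modality_ids(), names(DE))
  nodes <- lapply(Mseq, function(m) DE[[m]]$node)
  offs <- 0L
  emb_index <- integer(0)
  for (m in Mseq) {
    idx <- DE[[m]]$index
    emb_index[paste(m, names(idx), sep = "\r")] <- offs + idx
    offs <- offs + length(idx)
  }
  Zall <- if (length(nodes) == 1L) nodes[[1]] else ad_vconcat(tp, nodes)
  plan <- plan_views(model, triplets, emb_index)
  Za <- ad_gather_rows(tp, Zall, plan$row_a)
  Zb <- ad_gather_rows(tp, Zall, plan$row_b)
  nT <- nrow(triplets)

  if (model$task == "ddi") {
    type_idx <- match(triplets$context, model$type_ids)
    if (anyNA(type_idx))
      stop("unknown interaction type(s): ",
           paste(unique(triplets$context[is.na(type_idx)]), collapse = ", "))
    Zv <- ad_tanh(tp, tape_linear(tp, ad_hconcat(tp, list(Za, Zb)),
                                  P$aug_W, P$aug_b))
    Zv <- tape_dropout(tp, Zv, cfg$dropout, train)
    Cv <- ad_gather_rows(tp, P$type_emb, type_idx[plan$triplet])
    chat <- ad_tanh(tp, ad_add(tp, Cv,
                               ad_matmul(tp, ad_hconcat(tp, list(Zv, Cv)),
                                         P$ddi_wc)))
    chat <- tape_dropout(tp, chat, cfg$dropout, train)
    tz <- tape_dropout(tp, ad_tanh(tp, ad_matmul(tp, Zv, P$ddi_wz)),
                       cfg$dropout, train)
    preds <- ad_clamp(tp, ad_sigmoid(tp, ad_rowsums(tp, ad_mul(tp, tz,
                                                               chat))),
                      1e-7, 1 - 1e-7)
  } else {
    # context rows per unique context, then per view
    uc <- unique(triplets$context)
    crow <- lapply(uc, function(cid) {
      gidx <- ctx_cache[[cid]]
      if (is.null(gidx))
        stop("unknown context: '", cid, "'")
      if (length(gidx) == 0L) ad_leaf(tp, matrix(0, 1, cfg$dhid))
      else tape_encode_gene_set(tp, P, cfg, gidx, "context")
    })
    Cnode <- if (length(crow) == 1L) crow[[1]] else ad_rbind_rows(tp, crow)
    ctx_idx <- match(triplets$context, uc)
    Cv <- ad_gather_rows(tp, Cnode, ctx_idx[plan$triplet])
    if (model$task == "xenograft" && any(!is.na(triplets$time_days))) {
      tt <- triplets$time_days[plan$triplet]
      na <- is.na(tt)
      tt[na] <- 0
      Tm <- sinusoid_code(tt, cfg$dhid)
      Tm[na, ] <- 0
      Cv <- ad_add(tp, Cv, ad_leaf(tp, Tm))
    }
    Zv <- ad_relu(tp, tape_linear(tp, ad_hconcat(tp, list(Za, Zb, Cv)),
                                  P$aug_W, P$aug_b))
    Zv <- tape_dropout(tp, Zv, cfg$dropout, train)
    H <- ad_relu(tp, tape_linear(tp, Zv, P$head_W1, P$head_b1))
    H <- tape_dropout(tp, H, cfg$dropout, train)
    score <- tape_linear(tp, H, P$head_w2, P$head_b2)
    # clamp: saturated sigmoids would otherwise reach exactly 0/1 in
    # floating point and blow up the per-view cross-entropy terms
    preds <- if (model$task == "synergy")
      ad_clamp(tp, ad_sigmoid(tp, score), 1e-7, 1 - 1e-7)
    else score
  }

  agg <- tape_aggregate(tp, preds, plan, nT, P, cfg,
                        classification = model$task != "xenograft")
  list(tp = tp, P = P, preds = preds, view_emb = Zv, plan = plan,
       yhat = agg$yhat, retained = agg$retained, n_triplets = nT)
}

# Aggregator on the tape: scatter view predictions into the canonical
# 64-slot grid, mask to the top-k (ties to the earlier canonical slot),
# then affine + shortcut.
tape_aggregate <- function(tp, preds, plan, nT, P, cfg, classification) {
  G <- ad_scatter(tp, preds, plan$triplet, plan$key, nT, 64L)
  V <- ad_value(tp, G)
  mask <- matrix(0, nT, 64L)
  k_eff <- numeric(nT)
  retained <- vector("list", nT)
  has <- matrix(FALSE, nT, 64L)
  has[cbind(plan$triplet, plan$key)] <- TRUE
  for (i in seq_len(nT)) {
    slots <- which(has[i, ])
    mk <- top_k_mask(V[i, slots], cfg$top_k)
    keep <- slots[mk$retained]
    mask[i, keep] <- 1
    k_eff[i] <- length(keep)
    retained[[i]] <- keep
  }
  masked <- ad_mul_const(tp, G, mask)
  affine <- ad_matmul(tp, masked, P$w_nll)
  shortcut <- if (cfg$shortcut == "topk_mean")
    ad_mul_const(tp, ad_rowsums(tp, masked), matrix(1 / k_eff, ncol = 1))
  else
    ad_scale(tp, ad_rowsums(tp, G), 1 / cfg$top_k)
  yhat <- ad_add(tp, affine, shortcut)
  if (classification) yhat <- ad_clamp(tp, yhat, 1e-7, 1 - 1e-7)
  list(yhat = yhat, retained = retained)
}

#' Per-triplet view inventory
#'
#' Dataset audit: for every triplet, the number of available modality-pair
#' views and their keys.
#'
#' @param model A `pairviews_model`.
#' @param triplets Triplet `data.frame` (see [read_triplet_table()]).
#' @return `data.frame` with `drug_a`, `drug_b`, `context`, `n_views` and
#'   a comma-separated `views` label column.
#' @export
view_inventory <- function(model, triplets) {
  out <- triplets[, c("drug_a", "drug_b", "context")]
  out$n_views <- 0L
  out$views <- ""
  for (i in seq_len(nrow(triplets))) {
    va <- enumerate_views(model_availability(model, triplets$drug_a[i]),
                          model_availability(model, triplets$drug_b[i]),
                          triplets$drug_a[i], triplets$drug_b[i])
    out$n_views[i] <- nrow(va)
    out$views[i] <- paste(view_key_label(va$key), collapse = ",")
  }
  out
}
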