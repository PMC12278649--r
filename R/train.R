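# Training loop (Adam, linear warmup + polynomial decay), prediction, and
# the 2D-3D alignment pretrainer.

#' Precompute context gene sets
#'
#' For the cell-line and xenograft tasks: thresholds every context's
#' expression column at `expr_threshold`, expands by one-hop PPI
#' neighbors, and maps the genes into the model's embedding-table indices.
#' Contexts whose over-expressed set is empty get an empty index vector
#' (zero context vector downstream) with a warning.
#'
#' @param model A `pairviews_model`.
#' @param expr Expression matrix (genes x contexts), TPM.
#' @param ppi Optional `ppi_network`.
#' @return Named list: context id -> integer indices into the gene table.
#' @export
build_context_cache <- function(model, expr, ppi = NULL) {
  adj <- if (!is.null(ppi)) ppi_adjacency(ppi) else NULL
  out <- vector("list", ncol(expr))
  names(out) <- colnames(expr)
  for (cid in colnames(expr)) {
    v <- stats::setNames(expr[, cid], rownames(expr))
    genes <- overexpressed_genes(v, model$cfg$expr_threshold,
                                 if (is.null(adj)) NULL else adj)
    if (length(genes) == 0L)
      warning("context '", cid, "': no gene meets the over-expression ",
              "threshold; zero context vector")
    idx <- match(genes, model$gene_ids)
    out[[cid]] <- idx[!is.na(idx)]
  }
  out
}

lr_at_step <- function(step, cfg) {
  if (step <= cfg$warmup_steps)
    return(cfg$lr * step / max(cfg$warmup_steps, 1L))
  rem <- (cfg$steps - step) / max(cfg$steps - cfg$warmup_steps, 1L)
  cfg$lr * max(rem, 0)^cfg$poly_power
}

#' Train a drug-pair view model
#'
#' Minibatch Adam on the combined objective (supervised + InfoNCE and
#' soft-label consistency), with linear learning-rate warmup followed by
#' polynomial decay.  The modality-pair sample `M*` (size `r`) is redrawn
#' for every batch from the full 64-slot view grid and shared by the
#' auxiliary and both consistency terms.  Fully deterministic given the
#' configuration seed.
#'
#' @param model A `pairviews_model`.
#' @param triplets Triplet `data.frame` with 0/1 `label` (or real labels
#'   for the xenograft task).
#' @param ctx_cache From [build_context_cache()] (ignored for DDI).
#' @param valid Optional validation triplet `data.frame`; when given, the
#'   parameters with the best validation score (balanced accuracy for
#'   classification, mean squared error for regression) are kept instead
#'   of the final-step parameters.
#' @param eval_every Validation cadence in steps.
#' @param verbose Print a progress line every `verbose` steps (0 = quiet).
#' @return The model with trained parameters and a `history` data.frame
#'   (per-step loss breakdown; the recomposition identity
#'   `total = main + lambda*...` holds at every row).  With `valid` the
#'   model also records `best_step` and `best_valid`.
#' @export
train_model <- function(model, triplets, ctx_cache = NULL, valid = NULL,
                        eval_every = 50L, verbose = 0L) {
  cfg <- model$cfg
  stopifnot(nrow(triplets) >= 1L)
  set.seed(cfg$seed)
  params <- model$params
  m1 <- lapply(params, function(p) array(0, dim = dim(p)))
  m2 <- m1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  hist <- data.frame(step = seq_len(cfg$steps), total = NA_real_,
                     main = NA_real_, aux = NA_real_, infonce = NA_real_,
                     mse = NA_real_, lr = NA_real_)
  n <- nrow(triplets)
  best <- list(score = -Inf, params = NULL, step = NA_integer_)
  validate <- function(params, step) {
    mtmp <- model
    mtmp$params <- params
    pr <- predict_pairs(mtmp, valid, ctx_cache)
    score <- if (model$task == "xenograft")
      -mean((valid$label - pr$prediction)^2)
    else eval_metrics(valid$label, pr$prediction)$bacc
    if (score > best$score)
      best <<- list(score = score, params = params, step = step)
  }
  for (step in seq_len(cfg$steps)) {
    idx <- sample.int(n, min(cfg$batch_size, n))
    batch <- triplets[idx, , drop = FALSE]
    sampled <- sample_modality_pairs(seq_len(64L), cfg$r)
    tl <- tape_training_loss(model, params, batch, ctx_cache, sampled,
                             train = TRUE)
    tot <- as.numeric(ad_value(tl$tp, tl$total))
    if (!is.finite(tot)) {
      stop("non-finite loss at step ", step, "; batch triplets: ",
           paste(batch$drug_a, batch$drug_b, batch$context,
                 sep = "/", collapse = ", "))
    }
    hist$total[step] <- tot
    hist$main[step] <- as.numeric(ad_value(tl$tp, tl$main))
    hist$aux[step] <- as.numeric(ad_value(tl$tp, tl$aux))
    hist$infonce[step] <- as.numeric(ad_value(tl$tp, tl$infonce))
    hist$mse[step] <- as.numeric(ad_value(tl$tp, tl$mse))
    grads <- ad_backward(tl$tp, tl$total)
    lr <- lr_at_step(step, cfg)
    hist$lr[step] <- lr
    gscale <- 1
    if (cfg$clip_norm > 0) {
      gn2 <- 0
      for (nm in names(params)) {
        g <- grads[[tl$fw$P[[nm]]]]
        if (!is.null(g)) gn2 <- gn2 + sum(g^2)
      }
      if (!is.finite(gn2))
        stop("non-finite gradient at step ", step)
      if (sqrt(gn2) > cfg$clip_norm) gscale <- cfg$clip_norm / sqrt(gn2)
    }
    for (nm in names(params)) {
      g <- grads[[tl$fw$P[[nm]]]]
      if (is.null(g)) next
      g <- g * gscale
      m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * g
      m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * g^2
      mh <- m1[[nm]] / (1 - b1^step)
      vh <- m2[[nm]] / (1 - b2^step)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
    if (!is.null(valid) &&
        (step %% eval_every == 0L || step == cfg$steps)) {
      rng <- get(".Random.seed", envir = globalenv())
      validate(params, step)
      assign(".Random.seed", rng, envir = globalenv())
    }
    if (verbose > 0L && step %% verbose == 0L)
      message(sprintf("step %d/%d  loss %.4f  lr %.2e", step, cfg$steps,
                      tot, lr))
  }
  if (!is.null(valid) && !is.null(best$params)) {
    model$params <- best$params
    model$best_step <- best$step
    model$best_valid <- best$score
  } else {
    model$params <- params
  }
  model$history <- hist
  model
}

#' Predict for a table of triplets
#'
#' Evaluation-mode forward pass (dropout off, deterministic).  For
#' classification tasks returns the aggregated probability and the binary
#' call at threshold 0.5 (a probability of exactly 0.5 maps to the
#' positive class); for the xenograft task returns the real-valued
#' prediction.
#'
#' @param model A trained `pairviews_model`.
#' @param triplets Triplet `data.frame`.
#' @param ctx_cache From [build_context_cache()] (ignored for DDI).
#' @param chunk Triplets per forward chunk (memory control).
#' @param average_orders If `TRUE`, predict each triplet in both drug
#'   orders and average (the default reports the given anchor/library
#'   order as-is).
#' @return `data.frame`: the triplet columns plus `prediction` (and
#'   `call` for classification).
#' @export
predict_pairs <- function(model, triplets, ctx_cache = NULL, chunk = 64L,
                          average_orders = FALSE) {
  preds <- numeric(nrow(triplets))
  starts <- seq(1L, nrow(triplets), by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nrow(triplets))
    fw <- forward_batch(model, model$params,
                        triplets[s:e, , drop = FALSE], ctx_cache,
                        train = FALSE)
    preds[s:e] <- as.numeric(ad_value(fw$tp, fw$yhat))
  }
  if (average_orders) {
    swapped <- triplets
    swapped$drug_a <- triplets$drug_b
    swapped$drug_b <- triplets$drug_a
    preds <- (preds + predict_pairs(model, swapped, ctx_cache, chunk,
                                    average_orders = FALSE)$prediction) / 2
  }
  out <- triplets
  out$prediction <- preds
  if (model$task != "xenograft") out$call <- as.integer(preds >= 0.5)
  out
}

#' Predict synergy for one triplet
#'
#' @param drug_a,drug_b,context Ids resolvable in the model / context
#'   cache.
#' @param model A trained `pairviews_model`.
#' @param ctx_cache From [build_context_cache()].
#' @return List: `probability`, `call` (1 iff probability >= 0.5), and
#'   the retained top-k view keys.
#' @export
predict_synergy <- function(drug_a, drug_b, context, model, ctx_cache) {
  if (is.null(model$static[[drug_a]])) stop("unknown drug: '", drug_a, "'")
  if (is.null(model$static[[drug_b]])) stop("unknown drug: '", drug_b, "'")
  tri <- data.frame(drug_a = drug_a, drug_b = drug_b, context = context,
                    label = NA_real_, time_days = NA_integer_,
                    stringsAsFactors = FALSE)
  fw <- forward_batch(model, model$params, tri, ctx_cache, train = FALSE)
  p <- as.numeric(ad_value(fw$tp, fw$yhat))
  list(probability = p, call = as.integer(p >= 0.5),
       retained = fw$retained[[1]])
}

#' Predict synergy for a three-drug combination
#'
#' Decomposes the combination into its three drug pairs, predicts each
#' with the pair model, and averages the three probabilities.  Invariant
#' to the listing order of the drugs.
#'
#' @param drugs Character vector of three distinct drug ids.
#' @param context Context id.
#' @param model,ctx_cache As in [predict_synergy()].
#' @return List: `probability` (mean of the three pairwise predictions)
#'   and `pairwise` (named vector of the three pair probabilities).
#' @export
predict_three_drug <- function(drugs, context, model, ctx_cache) {
  if (length(drugs) != 3L || anyDuplicated(drugs))
    stop("need exactly three distinct drugs")
  drugs <- csort(drugs)
  pairs <- utils::combn(drugs, 2L)
  pw <- apply(pairs, 2, function(pr)
    predict_synergy(pr[1], pr[2], context, model, ctx_cache)$probability)
  names(pw) <- apply(pairs, 2, paste, collapse = "+")
  list(probability = mean(pw), pairwise = pw)
}

# ---- 2D-3D contrastive alignment ----------------------------------------

#' Align a tiny 2D graph encoder with 3D-view embeddings
#'
#' Trains a small message-passing encoder so that each molecule's 2D
#' embedding scores highest against its own 3D-view vector under the
#' symmetric InfoNCE objective.  The trained encoder can then be passed
#' to [pairviews_model()] as `phi2d` to supply the 3D-view modality for
#' drugs without precomputed 3D embeddings.
#'
#' @param graphs List of `mol_graph`s.
#' @param z3d Matrix (molecules x d3) of 3D-view embeddings, rows aligned
#'   with `graphs`.
#' @param width Hidden width of the encoder.
#' @param steps,lr Optimization schedule (plain Adam, constant rate).
#' @param seed Integer seed.
#' @return List (`phi2d`): encoder parameters, `element_vocab`,
#'   `out_dim`, and the per-step `history` of the alignment loss.
#' @export
align_2d3d <- function(graphs, z3d, width = 16L, steps = 100L, lr = 1e-2,
                       seed = 1L) {
  stopifnot(length(graphs) >= 2L, nrow(z3d) == length(graphs))
  set.seed(seed)
  elems <- csort(unique(unlist(lapply(graphs, function(g) g$atoms$element))))
  atom_dim <- length(elems) + 1L + 7L + 5L + 1L
  out_dim <- ncol(z3d)
  cfg2 <- list(graph_layers = 1L)
  params <- list(
    g_in_W = glorot(atom_dim, width), g_in_b = zeros(1, width),
    g_W1 = glorot(2L * width, width), g_b1 = zeros(1, width),
    g_pool_W = glorot(2L * width, out_dim), g_pool_b = zeros(1, out_dim))
  feats <- lapply(graphs, atom_features, element_vocab = elems)
  msgs <- lapply(graphs, message_operator)
  m1 <- lapply(params, function(p) array(0, dim = dim(p))); m2 <- m1
  hist <- numeric(steps)
  for (step in seq_len(steps)) {
    tp <- ad_tape(2048L)
    P <- push_params(tp, params)
    rows <- lapply(seq_along(graphs), function(i)
      tape_encode_graph(tp, P, cfg2, feats[[i]], msgs[[i]]))
    Z2 <- ad_rbind_rows(tp, rows)
    S <- ad_matmul(tp, Z2, ad_leaf(tp, t(z3d)))
    l12 <- ad_mean(tp, ad_sub(tp, ad_logsumexp_rows(tp, S), ad_diag(tp, S)))
    St <- ad_transpose(tp, S)
    l21 <- ad_mean(tp, ad_sub(tp, ad_logsumexp_rows(tp, St),
                              ad_diag(tp, St)))
    loss <- ad_scale(tp, ad_add(tp, l12, l21), 0.5)
    hist[step] <- as.numeric(ad_value(tp, loss))
    grads <- ad_backward(tp, loss)
    for (nm in names(params)) {
      g <- grads[[P[[nm]]]]
      if (is.null(g)) next
      m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * g
      m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * g^2
      params[[nm]] <- params[[nm]] -
        lr * (m1[[nm]] / (1 - 0.9^step)) /
          (sqrt(m2[[nm]] / (1 - 0.999^step)) + 1e-8)
    }
  }
  structure(list(params = params, element_vocab = elems,
                 out_dim = out_dim, width = width, history = hist),
            class = "phi2d")
}

# evaluation-mode encoding with an alignment-trained 2D encoder
phi2d_encode <- function(phi2d, graph, elems_unused = NULL) {
  tp <- ad_tape()
  P <- push_params(tp, phi2d$params)
  out <- tape_encode_graph(tp, P, list(graph_layers = 1L),
                           atom_features(graph, phi2d$element_vocab),
                           message_operator(graph))
  as.numeric(ad_value(tp, out))
}

# current alignment loss of a phi2d encoder on a set of molecules
phi2d_alignment_loss <- function(phi2d, graphs, z3d) {
  Z2 <- do.call(rbind, lapply(graphs, function(g) phi2d_encode(phi2d, g)))
  infonce_2d3d(Z2, z3d, score = "dot")
}

#' Reference desk-scale recovery configuration
#'
#' The configuration used by the package's planted-rule recovery studies:
#' width-16 encoders (one transformer / message-passing layer each),
#' batch 32, 1,200 Adam steps at rate 1e-2 with 20 warmup steps, no
#' dropout, and the standard aggregation (top-k = 8) and loss weights.
#' Small enough to run on one CPU, large enough to recover the planted
#' two-modality rule from the default synthetic fixture.
#'
#' @param seed Integer seed.
#' @param steps Optimization steps (default 1200).
#' @return A [run_config()].
#' @export
recovery_config <- function(seed, steps = 1200L) {
  run_config(dhid = 16L, smiles_dim = 16L, smiles_layers = 1L,
             graph_dim = 16L, graph_layers = 1L, gene_dim = 16L,
             text_dim = 16L, onto_dim = 8L, batch_size = 32L,
             steps = as.integer(steps), warmup_steps = 20L, lr = 1e-2,
             dropout = 0, top_k = 8L, seed = as.integer(seed))
}
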