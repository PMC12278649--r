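# The projector: eight modality-specific encoders mapping heterogeneous
# drug payloads into a shared dhid-dimensional space, plus the context
# encoders (cell-line gene sets, sinusoidal time, interaction types).
#
# Each encoder has a tape-level implementation (tape_encode_*) used by the
# training forward pass, and exported wrappers that evaluate it for a
# single input.  All randomness at initialization flows from the run
# configuration seed.

# linear layer on the tape: X %*% W + b
tape_linear <- function(tp, x, W, b) {
  force(x)
  ad_add_bias(tp, ad_matmul(tp, x, W), b)
}

# sinusoidal position/time code, 1-based positions
sinusoid_code <- function(positions, d) {
  stopifnot(d %% 2 == 0)
  i <- seq_len(d %/% 2) - 1L
  freq <- 1 / 10000^(2 * i / d)
  out <- matrix(0, length(positions), d)
  for (r in seq_along(positions)) {
    out[r, seq(1, d, by = 2)] <- sin(positions[r] * freq)
    out[r, seq(2, d, by = 2)] <- cos(positions[r] * freq)
  }
  out
}

#' Sinusoidal time embedding
#'
#' Interleaved sine/cosine code for a day count `t`:
#' `v[2i] = sin(t / 10000^(2i/d))`, `v[2i+1] = cos(t / 10000^(2i/d))`
#' (0-based indexing).  The squared norm is `d/2` for every `t`, so time
#' never changes the scale of the context vector it is added to.
#'
#' @param t Nonnegative integer day count.
#' @param dhid Even embedding size.
#' @return Numeric vector of length `dhid`.
#' @export
#' @examples
#' time_embedding(0, 8)   # c(0, 1, 0, 1, ...)
time_embedding <- function(t, dhid) {
  if (dhid %% 2 != 0) stop("dhid must be even for sin/cos pairing")
  if (t < 0) stop("t must be nonnegative")
  as.numeric(sinusoid_code(t, dhid))
}

# ---- SMILES transformer encoder -----------------------------------------

tape_encode_smiles <- function(tp, P, cfg, tok_ids, drop_mask = NULL) {
  L <- length(tok_ids)
  X <- ad_gather_rows(tp, P$tok_emb, tok_ids)
  pos <- ad_leaf(tp, sinusoid_code(seq_len(L), cfg$smiles_dim))
  X <- ad_add(tp, X, pos)
  scale <- 1 / sqrt(cfg$smiles_dim)
  for (l in seq_len(cfg$smiles_layers)) {
    Q <- tape_linear(tp, X, P[[paste0("sm_Wq", l)]], P[[paste0("sm_bq", l)]])
    K <- tape_linear(tp, X, P[[paste0("sm_Wk", l)]], P[[paste0("sm_bk", l)]])
    V <- tape_linear(tp, X, P[[paste0("sm_Wv", l)]], P[[paste0("sm_bv", l)]])
    S <- ad_scale(tp, ad_matmul(tp, Q, ad_transpose(tp, K)), scale)
    A <- ad_softmax_rows(tp, S)
    H <- tape_linear(tp, ad_matmul(tp, A, V),
                     P[[paste0("sm_Wo", l)]], P[[paste0("sm_bo", l)]])
    X <- ad_add(tp, X, H)
    Fh <- ad_relu(tp, tape_linear(tp, X, P[[paste0("sm_W1", l)]],
                                  P[[paste0("sm_b1", l)]]))
    Fo <- tape_linear(tp, Fh, P[[paste0("sm_W2", l)]],
                      P[[paste0("sm_b2", l)]])
    X <- ad_add(tp, X, Fo)
  }
  cls <- ad_gather_rows(tp, X, L)          # [CLS] is the final token
  tape_linear(tp, cls, P$smiles_out_W, P$smiles_out_b)
}

# ---- molecular-graph message-passing encoder ----------------------------

tape_encode_graph <- function(tp, P, cfg, feat, msg_op) {
  # feat: constant atom-feature matrix; msg_op: row-normalized adjacency
  H <- tape_linear(tp, ad_leaf(tp, feat), P$g_in_W, P$g_in_b)
  Mop <- ad_leaf(tp, msg_op)
  for (l in seq_len(cfg$graph_layers)) {
    Msg <- ad_matmul(tp, Mop, H)
    U <- ad_relu(tp, tape_linear(tp, ad_hconcat(tp, list(H, Msg)),
                                 P[[paste0("g_W", l)]],
                                 P[[paste0("g_b", l)]]))
    H <- ad_add(tp, H, U)                  # residual message passing
  }
  pooled <- ad_hconcat(tp, list(ad_colmeans(tp, H), ad_colmax(tp, H)))
  tape_linear(tp, pooled, P$g_pool_W, P$g_pool_b)
}

# ---- gene-set encoders ---------------------------------------------------

tape_pool_genes <- function(tp, P, cfg, gene_idx) {
  if (length(gene_idx) == 0L)
    return(ad_leaf(tp, matrix(0, 1, cfg$gene_dim)))
  E <- ad_gather_rows(tp, P$gene_table, gene_idx)
  if (cfg$gene_pool == "sum") ad_colmeans(tp, ad_scale(tp, E, length(gene_idx)))
  else ad_colmeans(tp, E)
}

tape_encode_gene_set <- function(tp, P, cfg, gene_idx, role = c("target",
                                                                "context")) {
  role <- match.arg(role)
  pooled <- tape_pool_genes(tp, P, cfg, gene_idx)
  if (role == "target") tape_linear(tp, pooled, P$target_W, P$target_b)
  else tape_linear(tp, pooled, P$cell_W, P$cell_b)
}

#' Expand a target gene set over a PPI network
#'
#' For each target gene, adds its `k_g` nearest PPI neighbors (highest edge
#' weight first, ties broken by lexicographic gene id).  Genes absent from
#' the network contribute only themselves.
#'
#' @param targets Nonempty character vector of gene ids.
#' @param ppi A `ppi_network` from [read_edge_list()] (or an adjacency
#'   environment from the internal cache).
#' @param k_g Number of neighbors per target, `>= 0`.
#' @return Sorted character vector: the union of targets and selected
#'   neighbors.
#' @export
expand_target_genes <- function(targets, ppi, k_g) {
  stopifnot(length(targets) > 0L, k_g >= 0)
  adj <- if (is.environment(ppi)) ppi else ppi_adjacency(ppi)
  out <- targets
  if (k_g > 0) {
    for (g in targets) {
      e <- adj[[g]]
      if (is.null(e)) next
      ord <- order(-e$w, e$nb, method = "radix")
      out <- c(out, e$nb[ord][seq_len(min(k_g, length(e$nb)))])
    }
  }
  csort(unique(out))
}

#' Encode a gene set
#'
#' Permutation-invariant pooling (mean by default) of the learnable gene
#' embeddings followed by one linear transformation to the shared space.
#' Unknown genes are dropped with a warning; if every gene is unknown the
#' pooled vector is zero.
#'
#' @param genes Character vector of gene ids.
#' @param model A fitted or initialized `pairviews_model`.
#' @param role `"target"` (drug-target transformation) or `"context"`
#'   (cell-line transformation); both share the gene-embedding table.
#' @return Numeric vector of length `dhid`.
#' @export
encode_gene_set <- function(genes, model, role = c("target", "context")) {
  role <- match.arg(role)
  idx <- match(genes, model$gene_ids)
  if (anyNA(idx)) {
    warning("encode_gene_set: dropping ", sum(is.na(idx)),
            " gene(s) not in the embedding table")
    idx <- idx[!is.na(idx)]
  }
  tp <- ad_tape()
  P <- push_params(tp, model$params)
  out <- tape_encode_gene_set(tp, P, model$cfg, idx, role)
  as.numeric(ad_value(tp, out))
}

# ---- fixed-vector / pluggable encoders ----------------------------------

tape_encode_fixed <- function(tp, P, v, W, b) {
  tape_linear(tp, ad_leaf(tp, matrix(v, nrow = 1)), W, b)
}

#' Encode a fixed-length payload vector
#'
#' One linear transformation to the shared space; used for the 27-length
#' side-effect indicator and the 60-length sensitivity profile.
#'
#' @param payload Numeric vector of length 27 (`"SIDE_EFFECTS"`) or 60
#'   (`"SENSITIVITY"`).
#' @param model A `pairviews_model`.
#' @param modality `"SIDE_EFFECTS"` or `"SENSITIVITY"`.
#' @return Numeric vector of length `dhid`.
#' @export
encode_fixed_vector <- function(payload, model,
                                modality = c("SIDE_EFFECTS", "SENSITIVITY")) {
  modality <- match.arg(modality)
  want <- if (modality == "SIDE_EFFECTS") SIDE_EFFECT_LEN else SENSITIVITY_LEN
  if (length(payload) != want)
    stop(modality, " payload must have length ", want, ", got ",
         length(payload))
  tp <- ad_tape()
  P <- push_params(tp, model$params)
  out <- if (modality == "SIDE_EFFECTS")
    tape_encode_fixed(tp, P, payload, P$sides_W, P$sides_b)
  else tape_encode_fixed(tp, P, payload, P$sens_W, P$sens_b)
  as.numeric(ad_value(tp, out))
}

#' Hashed bag-of-tokens text featurizer
#'
#' Deterministic fallback for drugs that ship a raw description string
#' instead of a precomputed text embedding: lowercased alphanumeric tokens
#' are hashed (FNV-1a) into `dim` buckets and counted.
#'
#' @param text Description string.
#' @param dim Number of hash buckets.
#' @return Numeric count vector of length `dim`.
#' @export
hash_text_features <- function(text, dim) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nzchar(toks)]
  v <- numeric(dim)
  for (tk in toks) {
    h <- string_hash32(tk)
    v[(h %% dim) + 1L] <- v[(h %% dim) + 1L] + 1
  }
  v
}

# ---- random walk with restart + SVD ontology embeddings -----------------

#' Random-walk-with-restart node profiles
#'
#' Iterates `t_j <- (1 - alpha) * t(T) %*% t_j + alpha * e_j` for every
#' seed node `j`, where `T` is the column-stochastic transition matrix of
#' the degree-normalized graph, until the l1 change falls below `tol`.
#' Every profile is a probability vector at every iteration.  Isolated
#' nodes restart onto themselves (their profile is their own basis vector).
#'
#' @param net A `ppi_network` (ontology graphs use the same container).
#' @param alpha Restart probability in (0, 1).
#' @param tol l1 convergence tolerance.
#' @param max_iter Iteration cap.
#' @return Matrix (nodes x nodes); row `j` is the stationary profile of
#'   seed `j`.  Dimnames are node ids.
#' @export
rwr_node_profiles <- function(net, alpha = 0.5, tol = 1e-6, max_iter = 100L) {
  stopifnot(alpha > 0, alpha < 1)
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, nodes)
    ti <- match(net$edges$to, nodes)
    A[cbind(fi, ti)] <- net$edges$weight
    A[cbind(ti, fi)] <- net$edges$weight
  }
  deg <- colSums(A)
  isolated <- deg == 0
  if (any(isolated)) {
    message("rwr_node_profiles: ", sum(isolated),
            " isolated node(s) restart onto themselves")
    diag(A)[isolated] <- 1
    deg <- colSums(A)
  }
  # walk matrix T is row-stochastic (T[i, j] = w_ij / deg_i); propagating
  # with its transpose (column-stochastic) keeps every profile a
  # probability vector at every iteration
  Tm <- sweep(A, 2, deg, "/")            # = t(row-stochastic T) for sym A
  P <- diag(n)                            # columns: profiles, start at seeds
  for (it in seq_len(max_iter)) {
    Pn <- (1 - alpha) * (Tm %*% P) + alpha * diag(n)
    delta <- max(colSums(abs(Pn - P)))
    P <- Pn
    if (delta < tol) break
  }
  out <- t(P)                             # row j = profile of seed j
  dimnames(out) <- list(nodes, nodes)
  out
}

#' Ontology node embeddings by RWR + SVD
#'
#' Stacks the per-seed stationary profiles into a matrix, factorizes it by
#' singular value decomposition, and represents each node by its top-`dim`
#' singular directions scaled by the singular values.  Signs are fixed by
#' making the largest-magnitude entry of each right singular vector
#' positive, so the embedding is deterministic.
#'
#' @param net Ontology graph as a `ppi_network`.
#' @param dim Embedding dimension, at most the node count.
#' @param alpha,tol,max_iter Passed to [rwr_node_profiles()].
#' @return List with `embeddings` (nodes x dim matrix, rownames = node
#'   ids), `alpha`, `dim` and the `singular_values`.
#' @export
ontology_embeddings <- function(net, dim, alpha = 0.5, tol = 1e-6,
                                max_iter = 100L) {
  n <- length(net$nodes)
  if (dim > n) stop("dim (", dim, ") exceeds the node count (", n, ")")
  R <- rwr_node_profiles(net, alpha, tol, max_iter)
  sv <- svd(R)
  V <- sv$v[, seq_len(dim), drop = FALSE]
  for (j in seq_len(dim)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  emb <- V %*% diag(sv$d[seq_len(dim)], nrow = dim)
  rownames(emb) <- net$nodes
  list(embeddings = emb, alpha = alpha, dim = dim,
       singular_values = sv$d)
}

# ---- cross-modal InfoNCE alignment --------------------------------------

#' Symmetric InfoNCE loss between paired 2D and 3D embeddings
#'
#' Both matching directions (2D to 3D and 3D to 2D) are averaged with
#' weight 1/2.  With all pairwise scores equal the loss is `log(N)`; it
#' approaches zero as matched scores dominate.
#'
#' @param z2d,z3d Matrices (N x d), row i of each being the two views of
#'   the same molecule; `N >= 2`.
#' @param score `"dot"` (default) or `"cosine"` similarity.
#' @return Scalar loss (mean over the batch).
#' @export
infonce_2d3d <- function(z2d, z3d, score = c("dot", "cosine")) {
  score <- match.arg(score)
  z2d <- as.matrix(z2d); z3d <- as.matrix(z3d)
  if (nrow(z2d) < 2L || nrow(z2d) != nrow(z3d))
    stop("need paired batches with N >= 2")
  if (score == "cosine") {
    z2d <- z2d / sqrt(rowSums(z2d^2) + 1e-12)
    z3d <- z3d / sqrt(rowSums(z3d^2) + 1e-12)
  }
  S <- z2d %*% t(z3d)
  lse <- function(x) {
    m <- max(x); m + log(sum(exp(x - m)))
  }
  n <- nrow(S)
  l_2to3 <- mean(vapply(seq_len(n), function(i) lse(S[i, ]) - S[i, i],
                        numeric(1)))
  l_3to2 <- mean(vapply(seq_len(n), function(i) lse(S[, i]) - S[i, i],
                        numeric(1)))
  (l_2to3 + l_3to2) / 2
}

# ---- context encoders ----------------------------------------------------

#' Over-expressed gene set of a context
#'
#' Genes whose expression is at or above the threshold (the comparison is
#' `>=`), optionally expanded by their one-hop PPI neighbors.
#'
#' @param expr Named numeric expression vector (TPM) over the gene
#'   vocabulary.
#' @param threshold Over-expression threshold; default 400 TPM.
#' @param ppi Optional `ppi_network` for the one-hop expansion.
#' @return Sorted character vector of gene ids (possibly empty).
#' @export
overexpressed_genes <- function(expr, threshold = 400, ppi = NULL) {
  g <- names(expr)[expr >= threshold]
  if (length(g) == 0L) return(character(0))
  if (!is.null(ppi)) {
    adj <- if (is.environment(ppi)) ppi else ppi_adjacency(ppi)
    nb <- unlist(lapply(g, function(x)
      if (is.null(adj[[x]])) character(0) else adj[[x]]$nb))
    g <- c(g, nb)
  }
  csort(unique(g))
}

#' Cell-line context features
#'
#' Thresholds the TPM vector at `expr_threshold` to get the over-expressed
#' set, expands it by one-hop PPI neighbors, and encodes the resulting
#' gene set with the shared gene-embedding table and the cell-line
#' transformation layer.  An empty over-expressed set yields a zero
#' context vector (warned loudly) rather than an error.
#'
#' @param expr Named TPM vector.
#' @param model A `pairviews_model`.
#' @param ppi Optional `ppi_network`.
#' @return List (`context_features`): `vector` (length `dhid`), `kind =
#'   "cell_line"`, and the `genes` used.
#' @export
cell_line_context <- function(expr, model, ppi = NULL) {
  genes <- overexpressed_genes(expr, model$cfg$expr_threshold, ppi)
  if (length(genes) == 0L)
    warning("cell_line_context: no gene meets the over-expression ",
            "threshold (", model$cfg$expr_threshold, "); zero context vector")
  v <- if (length(genes)) encode_gene_set(genes, model, "context")
       else numeric(model$cfg$dhid)
  list(vector = v, kind = "cell_line", genes = genes)
}

#' Interaction-type context features
#'
#' Looks up the learnable embedding row of a registered interaction type.
#'
#' @param type_id Interaction-type id.
#' @param model A `pairviews_model` initialized for the DDI task.
#' @return List (`context_features`): `vector`, `kind =
#'   "interaction_type"`.
#' @export
interaction_type_context <- function(type_id, model) {
  i <- match(type_id, model$type_ids)
  if (is.na(i)) stop("unknown interaction type: '", type_id, "'")
  list(vector = as.numeric(model$params$type_emb[i, ]),
       kind = "interaction_type")
}

# Batched variants: all drugs of a batch share one tape subgraph.  The
# SMILES transformer concatenates every sequence and restricts attention
# to within-sequence blocks via an additive mask (block-diagonal
# attention is exactly per-sequence attention); the graph encoder uses a
# block-diagonal message operator and per-block pooling.  Both are
# numerically identical to the per-drug encoders.

tape_encode_smiles_batch <- function(tp, P, cfg, tok_list) {
  Ls <- lengths(tok_list)
  n <- length(Ls)
  total <- sum(Ls)
  X <- ad_gather_rows(tp, P$tok_emb, unlist(tok_list, use.names = FALSE))
  pos <- do.call(rbind, lapply(Ls, function(L)
    sinusoid_code(seq_len(L), cfg$smiles_dim)))
  X <- ad_add_const(tp, X, pos)
  grp <- rep(seq_len(n), Ls)
  mask <- matrix(-1e30, total, total)
  mask[outer(grp, grp, "==")] <- 0
  scale <- 1 / sqrt(cfg$smiles_dim)
  for (l in seq_len(cfg$smiles_layers)) {
    Q <- tape_linear(tp, X, P[[paste0("sm_Wq", l)]], P[[paste0("sm_bq", l)]])
    K <- tape_linear(tp, X, P[[paste0("sm_Wk", l)]], P[[paste0("sm_bk", l)]])
    V <- tape_linear(tp, X, P[[paste0("sm_Wv", l)]], P[[paste0("sm_bv", l)]])
    S <- ad_add_const(tp, ad_scale(tp, ad_matmul(tp, Q,
                                                 ad_transpose(tp, K)),
                                   scale), mask)
    A <- ad_softmax_rows(tp, S)
    H <- tape_linear(tp, ad_matmul(tp, A, V),
                     P[[paste0("sm_Wo", l)]], P[[paste0("sm_bo", l)]])
    X <- ad_add(tp, X, H)
    Fh <- ad_relu(tp, tape_linear(tp, X, P[[paste0("sm_W1", l)]],
                                  P[[paste0("sm_b1", l)]]))
    X <- ad_add(tp, X, tape_linear(tp, Fh, P[[paste0("sm_W2", l)]],
                                   P[[paste0("sm_b2", l)]]))
  }
  cls <- ad_gather_rows(tp, X, cumsum(Ls))
  tape_linear(tp, cls, P$smiles_out_W, P$smiles_out_b)
}

tape_encode_graph_batch <- function(tp, P, cfg, feats, msgs) {
  ns <- vapply(feats, nrow, 1L)
  n <- length(ns)
  total <- sum(ns)
  Mop <- matrix(0, total, total)
  off <- 0L
  for (i in seq_len(n)) {
    idx <- off + seq_len(ns[i])
    Mop[idx, idx] <- msgs[[i]]
    off <- off + ns[i]
  }
  H <- tape_linear(tp, ad_leaf(tp, do.call(rbind, feats)),
                   P$g_in_W, P$g_in_b)
  Mn <- ad_leaf(tp, Mop)
  for (l in seq_len(cfg$graph_layers)) {
    Msg <- ad_matmul(tp, Mn, H)
    U <- ad_relu(tp, tape_linear(tp, ad_hconcat(tp, list(H, Msg)),
                                 P[[paste0("g_W", l)]],
                                 P[[paste0("g_b", l)]]))
    H <- ad_add(tp, H, U)
  }
  grp <- rep(seq_len(n), ns)
  Pool <- matrix(0, n, total)
  Pool[cbind(grp, seq_len(total))] <- 1 / ns[grp]
  mean_pool <- ad_matmul(tp, ad_leaf(tp, Pool), H)
  max_pool <- ad_blockmax(tp, H, grp, n)
  pooled <- ad_hconcat(tp, list(mean_pool, max_pool))
  tape_linear(tp, pooled, P$g_pool_W, P$g_pool_b)
}
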