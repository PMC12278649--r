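# Reverse-mode automatic differentiation on a flat tape.
#
# Nodes hold matrix values; every operation pushes one node whose `back`
# closure maps the incoming gradient to gradients for its parents.  The
# tape is an environment so ops can append without copying.  All model
# forward passes in this package are built from these primitives, and the
# engine is validated against central finite differences in the test suite.

ad_tape <- function(capacity = 512L) {
  # environment-backed node storage: assignment mutates in place, so
  # pushing is O(1) without copy-on-write churn on a growing list
  tp <- new.env(parent = emptyenv())
  tp$vals <- new.env(parent = emptyenv(), size = capacity)
  tp$parents <- new.env(parent = emptyenv(), size = capacity)
  tp$backs <- new.env(parent = emptyenv(), size = capacity)
  tp$n <- 0L
  tp
}

ad_push <- function(tp, value, parents = integer(0), back = NULL) {
  n <- tp$n + 1L
  k <- as.character(n)
  assign(k, value, envir = tp$vals)
  if (length(parents)) assign(k, parents, envir = tp$parents)
  if (!is.null(back)) assign(k, back, envir = tp$backs)
  tp$n <- n
  n
}

ad_value <- function(tp, id) {
  force(id)
  tp$vals[[as.character(id)]]
}

#' @noRd
ad_leaf <- function(tp, value) ad_push(tp, value)

ad_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  lv <- tp$vals[[as.character(loss_id)]]
  grads[[loss_id]] <- array(1, dim = dim(as.matrix(lv)))
  for (i in seq(loss_id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    ki <- as.character(i)
    bk <- tp$backs[[ki]]
    if (is.null(bk)) next
    pg <- bk(g)
    ps <- tp$parents[[ki]]
    for (j in seq_along(ps)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  grads
}

# ---- primitive operations ------------------------------------------------

ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[as.character(a)]]; B <- tp$vals[[as.character(b)]]
  ad_push(tp, A %*% B, c(a, b),
          function(g) list(g %*% t(B), t(A) %*% g))
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[as.character(a)]] + tp$vals[[as.character(b)]], c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[as.character(a)]] - tp$vals[[as.character(b)]], c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[as.character(a)]]; B <- tp$vals[[as.character(b)]]
  ad_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

# broadcast a 1 x d bias row over an n x d matrix
ad_add_bias <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[as.character(a)]]; bv <- tp$vals[[as.character(b)]]
  ad_push(tp, sweep(A, 2, as.numeric(bv), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), 1)))
}

ad_scale <- function(tp, a, k) {
  force(a)
  ad_push(tp, tp$vals[[as.character(a)]] * k, a, function(g) list(g * k))
}

# elementwise product with a constant (mask, dropout mask, label weights...)
ad_mul_const <- function(tp, a, m) {
  force(a)
  ad_push(tp, tp$vals[[as.character(a)]] * m, a, function(g) list(g * m))
}

ad_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  keep <- (A > 0)
  ad_push(tp, A * keep, a, function(g) list(g * keep))
}

ad_tanh <- function(tp, a) {
  force(a)
  Y <- tanh(tp$vals[[as.character(a)]])
  ad_push(tp, Y, a, function(g) list(g * (1 - Y^2)))
}

ad_sigmoid <- function(tp, a) {
  force(a)
  Y <- 1 / (1 + exp(-tp$vals[[as.character(a)]]))
  ad_push(tp, Y, a, function(g) list(g * Y * (1 - Y)))
}

ad_log <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, log(A), a, function(g) list(g / A))
}

ad_square <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, A^2, a, function(g) list(2 * g * A))
}

ad_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, matrix(sum(A)), a,
          function(g) list(array(as.numeric(g), dim = dim(A))))
}

ad_mean <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, matrix(mean(A)), a,
          function(g) list(array(as.numeric(g) / length(A), dim = dim(A))))
}

ad_rowsums <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, matrix(rowSums(A), ncol = 1), a,
          function(g) list(matrix(g, nrow(A), ncol(A))))
}

ad_colmeans <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, matrix(colMeans(A), 1), a,
          function(g) list(matrix(g, nrow(A), ncol(A), byrow = TRUE) / nrow(A)))
}

ad_colmax <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  idx <- max.col(t(A), ties.method = "first")  # row index of max per column
  ad_push(tp, matrix(A[cbind(idx, seq_len(ncol(A)))], 1), a,
          function(g) {
            G <- array(0, dim = dim(A))
            G[cbind(idx, seq_len(ncol(A)))] <- as.numeric(g)
            list(G)
          })
}

ad_gather_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  ad_push(tp, A[idx, , drop = FALSE], a,
          function(g) {
            G <- array(0, dim = dim(A))
            agg <- rowsum(g, idx)
            G[as.integer(rownames(agg)), ] <- agg
            list(G)
          })
}

ad_hconcat <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$vals[[as.character(i)]])
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_push(tp, do.call(cbind, vals), as.integer(ids),
          function(g) lapply(seq_along(widths), function(j)
            g[, starts[j]:ends[j], drop = FALSE]))
}

# stack single-row nodes into a matrix
ad_rbind_rows <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$vals[[as.character(i)]])
  ad_push(tp, do.call(rbind, vals), as.integer(ids),
          function(g) lapply(seq_along(ids), function(j)
            g[j, , drop = FALSE]))
}

# scatter a column vector of view values into a (n_rows x n_cols) canonical
# grid at positions (rows[i], cols[i]); used to place per-view predictions
# into the 64-slot canonical view layout.
ad_scatter <- function(tp, a, rows, cols, n_rows, n_cols) {
  force(a)
  v <- tp$vals[[as.character(a)]]
  M <- matrix(0, n_rows, n_cols)
  M[cbind(rows, cols)] <- as.numeric(v)
  ad_push(tp, M, a,
          function(g) list(matrix(g[cbind(rows, cols)], ncol = 1)))
}

ad_clamp <- function(tp, a, lo, hi) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  keep <- (A >= lo) & (A <= hi)
  ad_push(tp, pmin(pmax(A, lo), hi), a, function(g) list(g * keep))
}

ad_softmax_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  S <- exp(A - apply(A, 1, max))
  S <- S / rowSums(S)
  ad_push(tp, S, a,
          function(g) list((g - rowSums(g * S)) * S))
}

ad_logsumexp_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  m <- apply(A, 1, max)
  E <- exp(A - m)
  se <- rowSums(E)
  ad_push(tp, matrix(m + log(se), ncol = 1), a,
          function(g) list(as.numeric(g) * E / se))
}

ad_diag <- function(tp, a) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  n <- nrow(A)
  ad_push(tp, matrix(diag(A), ncol = 1), a,
          function(g) {
            G <- array(0, dim = dim(A))
            diag(G) <- as.numeric(g)
            list(G)
          })
}

# divide each row of A (n x d) by the matching entry of a positive n x 1 node
ad_rowdiv <- function(tp, a, s) {
  force(a); force(s)
  A <- tp$vals[[as.character(a)]]; sv <- as.numeric(tp$vals[[as.character(s)]])
  ad_push(tp, A / sv, c(a, s),
          function(g) list(g / sv,
                           matrix(-rowSums(g * A) / sv^2, ncol = 1)))
}

ad_sqrt <- function(tp, a) {
  force(a)
  Y <- sqrt(tp$vals[[as.character(a)]])
  ad_push(tp, Y, a, function(g) list(g / (2 * Y)))
}

ad_transpose <- function(tp, a) {
  force(a)
  ad_push(tp, t(tp$vals[[as.character(a)]]), a, function(g) list(t(g)))
}

# mean binary cross-entropy of predictions p (n x 1, in (0,1)) against
# constant labels y; fused for tape economy.
ad_bce_mean <- function(tp, a, y) {
  force(a)
  p <- as.numeric(tp$vals[[as.character(a)]])
  n <- length(p)
  ad_push(tp, matrix(-mean(y * log(p) + (1 - y) * log(1 - p))), a,
          function(g) list(matrix(as.numeric(g) * (p - y) / (p * (1 - p)) / n,
                                  ncol = 1)))
}

# mean squared error against a constant target
ad_mse_mean <- function(tp, a, y) {
  force(a)
  p <- tp$vals[[as.character(a)]]
  n <- length(p)
  ad_push(tp, matrix(mean((p - y)^2)), a,
          function(g) list(array(as.numeric(g) * 2 * (p - y) / n,
                                 dim = dim(as.matrix(p)))))
}

# l2 norm of each row, as an n x 1 node (guarded away from zero)
ad_rownorms <- function(tp, a, eps = 1e-12) {
  sq <- ad_square(tp, a)
  ss <- ad_rowsums(tp, sq)
  ad_sqrt(tp, ad_push(tp, tp$vals[[as.character(ss)]] + eps, ss, function(g) list(g)))
}

# stack matrix nodes vertically (rbind); parents may have differing row
# counts but equal column counts
ad_vconcat <- function(tp, ids) {
  ids <- as.integer(unlist(ids))
  vals <- lapply(ids, function(i) tp$vals[[as.character(i)]])
  nr <- vapply(vals, nrow, 1L)
  ends <- cumsum(nr)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_push(tp, do.call(rbind, vals), ids,
          function(g) lapply(seq_along(ids), function(j)
            g[starts[j]:ends[j], , drop = FALSE]))
}

# add a constant matrix (e.g. an attention mask of 0 / -1e30)
ad_add_const <- function(tp, a, M) {
  force(a)
  ad_push(tp, tp$vals[[as.character(a)]] + M, a, function(g) list(g))
}

# per-group column-wise max over row blocks; groups is an integer vector
# (one entry per row of A, values 1..k).  Backward routes each output
# entry to its argmax row, matching ad_colmax semantics per block.
ad_blockmax <- function(tp, a, groups, k) {
  force(a)
  A <- tp$vals[[as.character(a)]]
  d <- ncol(A)
  V <- matrix(0, k, d)
  arg <- matrix(0L, k, d)
  for (g in seq_len(k)) {
    rows <- which(groups == g)
    sub <- A[rows, , drop = FALSE]
    mi <- max.col(t(sub), ties.method = "first")
    arg[g, ] <- rows[mi]
    V[g, ] <- sub[cbind(mi, seq_len(d))]
  }
  ad_push(tp, V, a,
          function(g) {
            G <- array(0, dim = dim(A))
            G[cbind(as.vector(arg), rep(seq_len(d), each = k))] <-
              as.vector(g)
            list(G)
          })
}
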