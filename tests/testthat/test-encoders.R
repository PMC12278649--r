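# One shared tiny model for all encoder tests
enc_bundle <- tiny_bundle(seed = 11)
enc_model <- tiny_model(enc_bundle)

test_that("every encoder output has length dhid and finite entries", {
  dh <- enc_model$cfg$dhid
  for (id in names(enc_bundle$drugs)[1:4]) {
    s <- enc_model$static[[id]]
    v <- encode_smiles(enc_bundle$drugs[[id]]$payloads$SMILES, enc_model)
    expect_length(v, dh); expect_true(all(is.finite(v)))
    g <- enc_bundle$drugs[[id]]$payloads$GRAPH_2D
    if (is.null(g))
      g <- smiles_to_graph(enc_bundle$drugs[[id]]$payloads$SMILES)
    v <- encode_graph(g, enc_model)
    expect_length(v, dh); expect_true(all(is.finite(v)))
  }
  v <- encode_fixed_vector(rnorm(60), enc_model, "SENSITIVITY")
  expect_length(v, dh); expect_true(all(is.finite(v)))
  v <- encode_fixed_vector(rbinom(27, 1, 0.3), enc_model, "SIDE_EFFECTS")
  expect_length(v, dh)
  expect_error(encode_fixed_vector(rnorm(10), enc_model, "SENSITIVITY"),
               "length 60")
})

test_that("SMILES encoder is deterministic and separates distinct strings", {
  v1 <- encode_smiles("CCO", enc_model)
  v2 <- encode_smiles("CCO", enc_model)
  expect_identical(v1, v2)
  set.seed(21)
  for (i in 1:20) {
    a <- gen_smiles_one(); b <- gen_smiles_one()
    if (a == b) next
    expect_false(isTRUE(all.equal(encode_smiles(a, enc_model),
                                  encode_smiles(b, enc_model))),
                 info = paste(a, b))
  }
})

test_that("graph encoder is exactly permutation invariant", {
  g <- smiles_to_graph("CC(N)C=O")
  base <- encode_graph(g, enc_model)
  set.seed(4)
  for (rep in 1:5) {
    perm <- sample(nrow(g$atoms))
    inv <- order(perm)
    g2 <- g
    g2$atoms <- g$atoms[perm, , drop = FALSE]
    rownames(g2$atoms) <- NULL
    g2$bonds$i <- inv[g$bonds$i]
    g2$bonds$j <- inv[g$bonds$j]
    expect_equal(encode_graph(g2, enc_model), base, tolerance = 1e-12)
  }
  # single-atom graph: mean pool equals max pool by construction
  g1 <- smiles_to_graph("C")
  expect_length(encode_graph(g1, enc_model), enc_model$cfg$dhid)
})

test_that("target expansion matches a brute-force neighbor sort", {
  b <- enc_bundle
  expect_identical(expand_target_genes(c("g001"), b$ppi, 0), "g001")
  adj <- pairviews:::ppi_adjacency(b$ppi)
  set.seed(8)
  genes <- sample(b$ppi$nodes, 5)
  got <- expand_target_genes(genes, b$ppi, 2)
  want <- genes
  for (g in genes) {
    e <- adj[[g]]
    if (is.null(e)) next
    df <- data.frame(nb = e$nb, w = e$w)
    df <- df[order(-df$w, df$nb), ]
    want <- c(want, df$nb[seq_len(min(2, nrow(df)))])
  }
  expect_setequal(got, unique(want))
  # star graph: fewer neighbors than k_g returns them all
  star <- structure(list(edges = data.frame(
    from = "hub", to = c("n1", "n2", "n3"), weight = 1),
    nodes = c("hub", "n1", "n2", "n3")), class = "ppi_network")
  expect_setequal(expand_target_genes("hub", star, 5),
                  c("hub", "n1", "n2", "n3"))
})

test_that("gene-set encoding is order invariant and equals the mean oracle", {
  gs <- enc_model$gene_ids[1:10]
  v1 <- encode_gene_set(gs, enc_model)
  v2 <- encode_gene_set(rev(gs), enc_model)
  expect_equal(v1, v2, tolerance = 1e-12)
  # brute-force mean then linear map
  idx <- match(gs, enc_model$gene_ids)
  pooled <- numeric(enc_model$cfg$gene_dim)
  for (i in idx) pooled <- pooled + enc_model$params$gene_table[i, ]
  pooled <- pooled / length(idx)
  want <- as.numeric(matrix(pooled, 1) %*% enc_model$params$target_W +
                       enc_model$params$target_b)
  expect_equal(v1, want, tolerance = 1e-10)
  # singleton
  v <- encode_gene_set(gs[1], enc_model)
  w <- as.numeric(matrix(enc_model$params$gene_table[idx[1], ], 1) %*%
                    enc_model$params$target_W + enc_model$params$target_b)
  expect_equal(v, w, tolerance = 1e-10)
  expect_warning(encode_gene_set(c(gs[1], "nope"), enc_model), "dropping")
})

test_that("fixed-vector encoder equals an explicit matrix product", {
  v <- rnorm(60)
  got <- encode_fixed_vector(v, enc_model, "SENSITIVITY")
  want <- numeric(enc_model$cfg$dhid)
  for (j in seq_along(want))
    want[j] <- sum(v * enc_model$params$sens_W[, j]) +
      enc_model$params$sens_b[1, j]
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("text fallback featurizer is deterministic and matches a re-implementation", {
  expect_identical(hash_text_features("kinase inhibitor", 16),
                   hash_text_features("kinase inhibitor", 16))
  # independent second implementation of the same hash scheme
  oracle <- function(text, dim) {
    toks <- regmatches(tolower(text),
                       gregexpr("[a-z0-9]+", tolower(text)))[[1]]
    v <- numeric(dim)
    for (tk in toks) {
      h <- 5381
      for (ch in strsplit(tk, "")[[1]])
        h <- (h * 31 + utf8ToInt(ch)) %% 4294967291
      v[h %% dim + 1] <- v[h %% dim + 1] + 1
    }
    v
  }
  for (s in c("kinase inhibitor", "EGFR; receptor antagonist", "a b a"))
    expect_equal(hash_text_features(s, 32), oracle(s, 32), info = s)
})

test_that("3D and text encoders honor the missingness contract", {
  # find a drug with and one without the 3D payload
  has3 <- names(Filter(function(s) "GEOM_3D" %in% s$avail,
                       enc_model$static))
  no3 <- setdiff(names(enc_model$static), has3)
  if (length(has3)) {
    v <- encode_3d(has3[1], enc_model)
    expect_length(v, enc_model$cfg$dhid)
  }
  if (length(no3)) {
    expect_null(encode_3d(no3[1], enc_model))
    expect_false("GEOM_3D" %in% model_availability(enc_model, no3[1]))
  }
})

test_that("RWR profiles are probability vectors with the exact 2-node fixed point", {
  path2 <- structure(list(edges = data.frame(from = "a", to = "b",
                                             weight = 1),
                          nodes = c("a", "b")), class = "ppi_network")
  P <- rwr_node_profiles(path2, alpha = 0.5)
  expect_equal(P["a", ], c(a = 2 / 3, b = 1 / 3), tolerance = 1e-5)
  single <- structure(list(edges = data.frame(from = character(0),
                                              to = character(0),
                                              weight = numeric(0)),
                           nodes = "x"), class = "ppi_network")
  expect_message(P1 <- rwr_node_profiles(single), "isolated")
  expect_equal(as.numeric(P1), 1)

  b <- tiny_bundle(seed = 19, n_genes = 10)
  P <- rwr_node_profiles(b$ppi, alpha = 0.5, tol = 1e-10)
  expect_true(all(P >= -1e-12))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residual check of the fixed-point recurrence
  A <- matrix(0, 10, 10, dimnames = list(b$ppi$nodes, b$ppi$nodes))
  A[cbind(match(b$ppi$edges$from, b$ppi$nodes),
          match(b$ppi$edges$to, b$ppi$nodes))] <- b$ppi$edges$weight
  A <- A + t(A)
  Tm <- sweep(A, 2, colSums(A), "/")
  resid <- max(abs(t(P) - ((1 - 0.5) * (Tm %*% t(P)) + 0.5 * diag(10))))
  expect_lt(resid, 1e-8)
})

test_that("ontology embeddings: twins coincide, full-rank SVD reconstructs", {
  # two leaves hanging off the same parent are structural twins
  tw <- structure(list(edges = data.frame(
    from = c("root", "root", "mid", "mid"),
    to = c("mid", "x", "t1", "t2"), weight = 1),
    nodes = c("mid", "root", "t1", "t2", "x")), class = "ppi_network")
  # twin profiles are swaps of each other (the self-visit entry always
  # distinguishes them), so their embeddings agree in norm and in the
  # distance to every other node
  emb <- ontology_embeddings(tw, dim = 3)$embeddings
  expect_equal(sum(emb["t1", ]^2), sum(emb["t2", ]^2), tolerance = 1e-8)
  for (nd in c("mid", "root", "x"))
    expect_equal(sum((emb["t1", ] - emb[nd, ])^2),
                 sum((emb["t2", ] - emb[nd, ])^2), tolerance = 1e-8)
  b <- tiny_bundle(seed = 23)
  n <- length(b$ontology$nodes)
  R <- rwr_node_profiles(b$ontology, 0.5, tol = 1e-12, max_iter = 500)
  full <- ontology_embeddings(b$ontology, dim = n, tol = 1e-12,
                              max_iter = 500)
  sv <- svd(R)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_equal(recon, R, tolerance = 1e-8, ignore_attr = TRUE)
  # captured variance of a dim-2 embedding equals the top-2 share
  e2 <- ontology_embeddings(b$ontology, dim = 2, tol = 1e-12,
                            max_iter = 500)
  expect_equal(sum(e2$embeddings^2), sum(sv$d[1:2]^2), tolerance = 1e-6)
  expect_error(ontology_embeddings(b$ontology, dim = n + 1), "exceeds")
})

test_that("cross-modal InfoNCE: uniform scores give log N, dominance gives ~0, oracle agrees", {
  for (N in c(2, 4, 8)) {
    Z <- matrix(0, N, 3)   # all scores equal (all zero)
    expect_equal(infonce_2d3d(Z, Z), log(N), tolerance = 1e-10)
  }
  Z <- diag(4) * 50
  expect_lt(infonce_2d3d(Z, Z), 1e-6)
  set.seed(31)
  z2 <- matrix(rnorm(12), 4); z3 <- matrix(rnorm(12), 4)
  S <- z2 %*% t(z3)
  loss <- 0
  for (i in 1:4) {
    loss <- loss - 0.5 / 4 * log(exp(S[i, i]) / sum(exp(S[i, ])))
    loss <- loss - 0.5 / 4 * log(exp(S[i, i]) / sum(exp(S[, i])))
  }
  expect_equal(infonce_2d3d(z2, z3), loss, tolerance = 1e-10)
  expect_error(infonce_2d3d(z2[1, , drop = FALSE], z3[1, , drop = FALSE]),
               "N >= 2")
})

test_that("time embedding: t=0 pattern, constant norm, direct values", {
  expect_equal(time_embedding(0, 8), rep(c(0, 1), 4))
  for (t in sample(0:500, 20))
    expect_equal(sum(time_embedding(t, 512)^2), 256, tolerance = 1e-9)
  v <- time_embedding(1, 512)
  expect_equal(v[1], sin(1), tolerance = 1e-12)
  expect_equal(v[2], cos(1), tolerance = 1e-12)
  expect_error(time_embedding(3, 7), "even")
})

test_that("cell-line context: threshold is >=, one-hop expansion, empty set warns", {
  expr <- c(g1 = 500, g2 = 100, g3 = 400)
  expect_setequal(overexpressed_genes(expr, 400), c("g1", "g3"))
  chain <- structure(list(edges = data.frame(
    from = c("g1", "g2"), to = c("g2", "g3"), weight = 1),
    nodes = c("g1", "g2", "g3")), class = "ppi_network")
  expect_setequal(overexpressed_genes(c(g1 = 500, g2 = 1, g3 = 1),
                                      400, chain), c("g1", "g2"))
  expect_setequal(overexpressed_genes(expr, 400, NULL), c("g1", "g3"))
  low <- stats::setNames(rep(1, length(enc_model$gene_ids)),
                         enc_model$gene_ids)
  expect_warning(ctxf <- cell_line_context(low, enc_model), "threshold")
  expect_equal(ctxf$vector, numeric(enc_model$cfg$dhid))
})

test_that("interaction-type context looks up registered embeddings only", {
  b <- tiny_bundle(seed = 13)
  m <- suppressWarnings(pairviews_model(
    b$drugs, tiny_config(), "ddi", ppi = b$ppi,
    type_ids = c("t1", "t2", "t3")))
  v <- interaction_type_context("t2", m)
  expect_length(v$vector, m$cfg$dhid)
  expect_identical(v$vector, interaction_type_context("t2", m)$vector)
  expect_error(interaction_type_context("t9", m), "unknown")
  # distinct rows after random init
  expect_gt(min(dist(m$params$type_emb)), 0)
})

test_that("batched sequence/graph encoders equal the per-drug encoders", {
  b <- enc_bundle
  m <- enc_model
  ids <- names(b$drugs)
  tp <- ad_tape(8192L)
  P <- pairviews:::push_params(tp, m$params)
  DE <- pairviews:::tape_drug_embeddings(tp, P, m, ids)
  SB <- ad_value(tp, DE$SMILES$node)
  for (i in seq_along(ids)) {
    expect_equal(as.numeric(SB[i, ]),
                 encode_smiles(b$drugs[[ids[i]]]$payloads$SMILES, m),
                 tolerance = 1e-10)
  }
  GB <- ad_value(tp, DE$GRAPH_2D$node)
  ghas <- names(DE$GRAPH_2D$index)
  for (i in seq_along(ghas)) {
    g <- smiles_to_graph(b$drugs[[ghas[i]]]$payloads$SMILES)
    expect_equal(as.numeric(GB[i, ]), encode_graph(g, m),
                 tolerance = 1e-10)
  }
})
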