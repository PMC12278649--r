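test_that("FPKM to TPM: uniform column, million-sum identity, per-entry oracle, idempotence", {
  m <- matrix(1, 4, 1, dimnames = list(paste0("g", 1:4), "c1"))
  expect_equal(as.numeric(fpkm_to_tpm(m)), rep(250000, 4))
  set.seed(97)
  m <- matrix(runif(250, 0, 50), 50, 5,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("c%d", 1:5)))
  tpm <- fpkm_to_tpm(m)
  expect_equal(colSums(tpm), rep(1e6, 5), tolerance = 1e-6,
               ignore_attr = TRUE)
  for (j in 1:5) for (i in sample(50, 5))
    expect_equal(tpm[i, j], m[i, j] / sum(m[, j]) * 1e6)
  expect_equal(unclass(fpkm_to_tpm(tpm)), unclass(tpm),
               ignore_attr = TRUE, tolerance = 1e-12)
  m[, 2] <- 0
  expect_error(fpkm_to_tpm(m), "c2")
})

test_that("BestResponse takes the minimum change at or after day 10", {
  tr <- xeno_trajectory("x1", "d1", "d2", c(3, 10, 17), c(0.5, -0.2, 0.1))
  expect_equal(best_response(tr), -0.2)
  tr1 <- xeno_trajectory("x1", "d1", "d2", 10, 0.0)
  expect_equal(best_response(tr1), 0.0)
  set.seed(101)
  for (i in 1:20) {
    tt <- sort(sample(0:30, 8))
    dv <- rnorm(8); dv[tt == 0] <- 0
    tr <- xeno_trajectory("x", "a", "b", tt, dv)
    if (!any(tt >= 10)) {
      expect_error(best_response(tr), "day 10")
    } else {
      expect_equal(best_response(tr), min(dv[tt >= 10]))
    }
  }
  expect_error(xeno_trajectory("x", "a", "b", c(3, 3), c(0, 0)),
               "strictly increasing")
  expect_error(xeno_trajectory("x", "a", "b", c(0, 3), c(0.5, 0)),
               "day 0")
})

test_that("splits are deterministic, partition the data, and satisfy leakage constraints", {
  set.seed(103)
  for (rep in 1:50) {
    nd <- sample(6:12, 1); nc <- sample(4:8, 1)
    drugs <- sprintf("d%02d", seq_len(nd))
    tri <- expand.grid(drug_a = drugs, drug_b = drugs,
                       context = sprintf("c%d", seq_len(nc)),
                       stringsAsFactors = FALSE)
    tri <- tri[tri$drug_a != tri$drug_b, ]
    tri$label <- rbinom(nrow(tri), 1, 0.3)
    mode <- sample(c("vanilla", "by_combination", "by_cell_line",
                     "ddi_one_new_drug", "ddi_two_new_drugs"), 1)
    seed <- sample(1e4, 1)
    sp <- make_splits(tri, mode, seed = seed)
    sp2 <- make_splits(tri, mode, seed = seed)
    expect_identical(sp, sp2)
    expect_equal(length(intersect(sp$train, sp$test)), 0L)
    expect_equal(length(intersect(sp$train, sp$valid)), 0L)
    if (mode %in% c("vanilla", "by_combination", "by_cell_line"))
      expect_setequal(c(sp$train, sp$valid, sp$test), seq_len(nrow(tri)))
    if (mode == "by_combination") {
      pk <- function(i) paste(pmin(tri$drug_a[i], tri$drug_b[i]),
                              pmax(tri$drug_a[i], tri$drug_b[i]))
      expect_equal(length(intersect(pk(sp$train), pk(sp$test))), 0L)
    }
    if (mode == "by_cell_line")
      expect_equal(length(intersect(tri$context[sp$train],
                                    tri$context[sp$test])), 0L)
    if (mode %in% c("ddi_one_new_drug", "ddi_two_new_drugs")) {
      seen <- unique(c(tri$drug_a[sp$train], tri$drug_b[sp$train]))
      new_count <- (!tri$drug_a[sp$test] %in% seen) +
        (!tri$drug_b[sp$test] %in% seen)
      if (mode == "ddi_one_new_drug") expect_true(all(new_count == 1))
      else expect_true(all(new_count == 2))
    }
  }
  tri <- data.frame(drug_a = "a", drug_b = "b", context = "c", label = 1)
  expect_error(make_splits(tri, "vanilla"), "too small")
})

test_that("vanilla split sizes follow the 60/20/20 fractions", {
  tri <- data.frame(drug_a = "a", drug_b = "b",
                    context = sprintf("c%d", 1:100),
                    label = rbinom(100, 1, 0.5))
  sp <- make_splits(tri, "vanilla", seed = 7)
  expect_equal(length(sp$train), 60)
  expect_equal(length(sp$valid), 20)
  expect_equal(length(sp$test), 20)
})

test_that("metrics: perfect and chance-level closed forms", {
  y <- c(1, 1, 0, 0, 1, 0)
  perfect <- c(0.9, 0.8, 0.1, 0.2, 0.99, 0.3)
  m <- eval_metrics(y, perfect)
  expect_equal(m$bacc, 1); expect_equal(m$f1, 1)
  expect_equal(m$kappa, 1); expect_equal(m$auprc, 1)
  const <- rep(0.7, 6)
  m <- eval_metrics(y, const)
  expect_equal(m$bacc, 0.5); expect_equal(m$kappa, 0)
  expect_error(eval_metrics(rep(1, 4), runif(4)), "both classes")
})

test_that("metrics match an independent reference on 200 random sets", {
  has_e1071 <- requireNamespace("e1071", quietly = TRUE)
  ref_auprc <- function(y, s) {
    # oracle: walk the ranked list and accumulate average precision
    ord <- order(s, decreasing = TRUE)
    y <- y[ord]; s <- s[ord]
    ap <- 0; tp <- 0
    i <- 1
    n <- length(y)
    while (i <= n) {
      j <- i
      while (j < n && s[j + 1] == s[i]) j <- j + 1
      block_tp <- sum(y[i:j])
      tp <- tp + block_tp
      prec <- tp / j
      ap <- ap + prec * block_tp / sum(y)
      i <- j + 1
    }
    ap
  }
  set.seed(107)
  for (rep in 1:200) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(1:3, 1))  # ties likely
    m <- eval_metrics(y, s)
    call <- as.integer(s >= 0.5)
    tpr <- sum(call & y) / sum(y)
    tnr <- sum(!call & !y) / sum(!y)
    expect_equal(m$bacc, (tpr + tnr) / 2)
    prec <- if (sum(call) == 0) 0 else sum(call & y) / sum(call)
    rec <- tpr
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    expect_equal(m$f1, f1, tolerance = 1e-12)
    expect_equal(m$auprc, ref_auprc(y, s), tolerance = 1e-10)
    if (has_e1071) {
      tab <- table(factor(call, levels = 0:1), factor(y, levels = 0:1))
      expect_equal(m$kappa, e1071::classAgreement(tab)$kappa,
                   tolerance = 1e-10)
    }
  }
})

test_that("regression metrics agree with stats::cor", {
  set.seed(109)
  y <- rnorm(30); s <- y + rnorm(30)
  m <- eval_metrics(y, s, mode = "regression")
  expect_equal(m$pearson, cor(y, s))
  expect_equal(m$spearman, cor(y, s, method = "spearman"))
})

test_that("DDI negative sampling: count, disjointness, determinism, coverage", {
  drugs <- sprintf("d%02d", 1:10)
  types <- c("t1", "t2", "t3")
  set.seed(113)
  pos <- data.frame(drug_a = sample(drugs, 10, TRUE),
                    drug_b = sample(drugs, 10, TRUE),
                    context = sample(types, 10, TRUE))
  pos <- pos[pos$drug_a != pos$drug_b, ]
  neg <- negative_sample_ddi(pos, drugs, types, seed = 5)
  expect_equal(nrow(neg), nrow(pos))
  key <- function(df) paste(pmin(df$drug_a, df$drug_b),
                            pmax(df$drug_a, df$drug_b), df$context)
  expect_equal(length(intersect(key(neg), key(pos))), 0L)
  expect_false(anyDuplicated(key(neg)) > 0)
  expect_identical(negative_sample_ddi(pos, drugs, types, seed = 5), neg)
  # exhaustion error
  expect_error(negative_sample_ddi(
    data.frame(drug_a = rep("a", 5), drug_b = rep("b", 5),
               context = paste0("t", 1:5)),
    c("a", "b"), paste0("t", 1:5)), "exhausted")
  # near-uniform drug usage over many draws
  big <- negative_sample_ddi(pos[0, ], drugs, types, seed = 9)
  pos2 <- data.frame(drug_a = character(0), drug_b = character(0),
                     context = character(0))
  counts <- integer(length(drugs)); names(counts) <- drugs
  for (rep in 1:200) {
    nn <- negative_sample_ddi(pos, drugs, types, seed = rep)
    tb <- table(c(nn$drug_a, nn$drug_b))
    counts[names(tb)] <- counts[names(tb)] + tb
  }
  expect_lt(max(counts) / min(counts), 1.5)
})

test_that("three-drug prediction averages the pairwise calls order-invariantly", {
  b <- tiny_bundle(seed = 127)
  m <- tiny_model(b)
  ctx <- build_context_cache(m, b$expr, b$ppi)
  ids <- names(b$drugs)[1:3]
  cidx <- colnames(b$expr)[1]
  r1 <- predict_three_drug(ids, cidx, m, ctx)
  r2 <- predict_three_drug(rev(ids), cidx, m, ctx)
  expect_equal(r1$probability, r2$probability, tolerance = 1e-12)
  expect_equal(r1$probability, mean(r1$pairwise), tolerance = 1e-12)
  # equals externally computed mean of the three pair predictions
  prs <- combn(sort(ids), 2)
  want <- mean(apply(prs, 2, function(pr)
    predict_synergy(pr[1], pr[2], cidx, m, ctx)$probability))
  expect_equal(r1$probability, want, tolerance = 1e-12)
  expect_error(predict_three_drug(c(ids[1], ids[1], ids[2]), cidx, m, ctx),
               "distinct")
})

test_that("batch prediction equals per-item prediction and boundary calls positive", {
  b <- tiny_bundle(seed = 131)
  m <- tiny_model(b)
  ctx <- build_context_cache(m, b$expr, b$ppi)
  tri <- b$triplets[1:7, ]
  batch <- predict_pairs(m, tri, ctx, chunk = 3L)
  for (i in seq_len(nrow(tri))) {
    one <- predict_synergy(tri$drug_a[i], tri$drug_b[i], tri$context[i],
                           m, ctx)
    expect_equal(batch$prediction[i], one$probability, tolerance = 1e-10)
  }
  expect_identical(batch$call, as.integer(batch$prediction >= 0.5))
})

test_that("permissive trajectories sort time points; best response is order invariant", {
  tt <- c(14, 3, 10, 0, 21)
  dv <- c(-0.1, 0.4, 0.2, 0, -0.3)
  tr <- xeno_trajectory("x", "a", "b", tt, dv, permissive = TRUE)
  expect_identical(tr$t, sort(as.integer(tt)))
  expect_equal(best_response(tr), -0.3)
  expect_error(xeno_trajectory("x", "a", "b", tt, dv), "increasing")
})

test_that("order-averaged prediction is symmetric in the drug pair", {
  b <- tiny_bundle(seed = 139)
  m <- tiny_model(b)
  ctx <- build_context_cache(m, b$expr, b$ppi)
  tri <- b$triplets[1:4, ]
  swapped <- tri
  swapped$drug_a <- tri$drug_b; swapped$drug_b <- tri$drug_a
  p1 <- predict_pairs(m, tri, ctx, average_orders = TRUE)$prediction
  p2 <- predict_pairs(m, swapped, ctx, average_orders = TRUE)$prediction
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("self-paired (single-drug) records pass through the pipeline", {
  b <- tiny_bundle(seed = 149)
  m <- tiny_model(b)
  ctx <- build_context_cache(m, b$expr, b$ppi)
  tri <- data.frame(drug_a = "d01", drug_b = "d01",
                    context = colnames(b$expr)[1], label = 0,
                    time_days = NA_integer_)
  p <- predict_pairs(m, tri, ctx)
  expect_true(p$prediction > 0 && p$prediction < 1)
  na <- length(model_availability(m, "d01"))
  fw <- pairviews:::forward_batch(m, m$params, tri, ctx)
  expect_equal(length(fw$plan$key), na * na)
})
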