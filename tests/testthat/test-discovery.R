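test_that("candidate-triplet enumeration: closed form and brute-force oracle", {
  drugs <- sprintf("d%02d", 1:3)
  r <- enumerate_candidate_triplets(drugs, "c1")
  expect_equal(r$ordered_count, 6L)
  expect_equal(nrow(r$novel), 3L)

  set.seed(137)
  drugs <- sprintf("d%02d", 1:7)
  ctx <- sprintf("c%d", 1:4)
  # observed triplets in random (anchor, library) order
  obs <- data.frame(drug_a = sample(drugs, 30, TRUE),
                    drug_b = sample(drugs, 30, TRUE),
                    context = sample(ctx, 30, TRUE))
  obs <- obs[obs$drug_a != obs$drug_b, ]
  r <- enumerate_candidate_triplets(drugs, ctx, obs)
  expect_equal(r$ordered_count, 7 * 6 * 4)
  # brute force: loop all unordered (a<b, c), novel iff neither order seen
  seen <- paste(obs$drug_a, obs$drug_b, obs$context)
  novel <- 0L
  for (a in drugs) for (b in drugs) for (cc in ctx) {
    if (a >= b) next
    if (!(paste(a, b, cc) %in% seen) && !(paste(b, a, cc) %in% seen))
      novel <- novel + 1L
  }
  expect_equal(nrow(r$novel), novel)
  # canonical order and no duplicates
  expect_true(all(r$novel$drug_a < r$novel$drug_b))
  expect_false(anyDuplicated(paste(r$novel$drug_a, r$novel$drug_b,
                                   r$novel$context)) > 0)
  expect_error(enumerate_candidate_triplets(
    drugs, ctx, data.frame(drug_a = "zz", drug_b = "d01",
                           context = "c1")), "unknown drug")
})

test_that("gene-pair construction follows the threshold and excludes self-pairs", {
  preds <- data.frame(drug_a = "dA", drug_b = "dB", context = "c1",
                      prediction = 0.95)
  tg <- list(dA = "T1", dB = character(0))
  ov <- list(c1 = c("G1", "G2"))
  r <- build_gene_pairs(preds, 0.9, tg, ov)
  expect_equal(nrow(r$pairs), 2L)
  expect_setequal(r$pairs$gene_over, c("G1", "G2"))
  expect_true(all(r$pairs$gene_target == "T1"))

  low <- preds; low$prediction <- 0.5
  expect_equal(nrow(build_gene_pairs(low, 0.9, tg, ov)$pairs), 0L)

  # self-pairs excluded
  r <- build_gene_pairs(preds, 0.9, list(dA = "G1", dB = character(0)), ov)
  expect_false(any(r$pairs$gene_over == r$pairs$gene_target))

  # random instance vs nested-loop oracle
  set.seed(139)
  genes <- sprintf("g%02d", 1:15)
  preds <- data.frame(drug_a = sample(sprintf("d%d", 1:5), 20, TRUE),
                      drug_b = sample(sprintf("d%d", 1:5), 20, TRUE),
                      context = sample(c("c1", "c2"), 20, TRUE),
                      prediction = runif(20))
  tg <- lapply(stats::setNames(nm = sprintf("d%d", 1:5)), function(d)
    sample(genes, sample(0:3, 1)))
  ov <- lapply(stats::setNames(nm = c("c1", "c2")), function(cc)
    sample(genes, 5))
  r <- build_gene_pairs(preds, 0.5, tg, ov)
  want <- new.env()
  skipped <- 0L
  for (i in which(preds$prediction >= 0.5)) {
    t2 <- unique(c(tg[[preds$drug_a[i]]], tg[[preds$drug_b[i]]]))
    o2 <- ov[[preds$context[i]]]
    if (!length(t2) || !length(o2)) { skipped <- skipped + 1L; next }
    for (go in o2) for (gt in t2) if (go != gt)
      want[[paste(go, gt)]] <- TRUE
  }
  expect_equal(nrow(r$pairs), length(ls(want)))
  expect_equal(r$skipped, skipped)
  expect_lte(nrow(r$pairs),
             sum(vapply(which(preds$prediction >= 0.5), function(i) {
               t2 <- unique(c(tg[[preds$drug_a[i]]],
                              tg[[preds$drug_b[i]]]))
               length(t2) * length(ov[[preds$context[i]]])
             }, 1)))
})

test_that("SDL filtering is an oriented set intersection", {
  gp <- data.frame(gene_over = c("A", "B", "C"),
                   gene_target = c("X", "Y", "Z"),
                   support = c(2L, 1L, 4L))
  sdl0 <- data.frame(gene_over = character(0),
                     gene_essential = character(0))
  r <- filter_sdl(gp, sdl0)
  expect_equal(nrow(r$pairs), 0L)
  expect_length(r$genes, 0L)

  sdl_all <- data.frame(gene_over = c("A", "B", "C", "Q"),
                        gene_essential = c("X", "Y", "Z", "Q2"))
  r <- filter_sdl(gp, sdl_all)
  expect_equal(r$pairs$support, gp$support)
  expect_setequal(r$genes, c("A", "B", "C", "X", "Y", "Z"))

  # orientation matters: reversed pairs do not match
  sdl_rev <- data.frame(gene_over = "X", gene_essential = "A")
  expect_equal(nrow(filter_sdl(gp, sdl_rev)$pairs), 0L)

  set.seed(149)
  gp2 <- data.frame(gene_over = sample(LETTERS, 40, TRUE),
                    gene_target = sample(LETTERS, 40, TRUE),
                    support = 1L)
  gp2 <- gp2[gp2$gene_over != gp2$gene_target, ]
  sdl2 <- data.frame(gene_over = sample(LETTERS, 40, TRUE),
                     gene_essential = sample(LETTERS, 40, TRUE))
  r <- filter_sdl(gp2, sdl2)
  want <- intersect(paste(gp2$gene_over, gp2$gene_target),
                    paste(sdl2$gene_over, sdl2$gene_essential))
  expect_setequal(paste(r$pairs$gene_over, r$pairs$gene_target), want)
})

test_that("patient labels follow the 70% rule and are cohort-order invariant", {
  set.seed(151)
  genes <- c("GO1", "GT1", "GO2", "GT2")
  cohort <- matrix(runif(4 * 100, 0, 10), 4, 100,
                   dimnames = list(genes, sprintf("p%03d", 1:100)))
  pathway <- structure(list(
    pairs = data.frame(gene_over = c("GO1", "GO2"),
                       gene_target = c("GT1", "GT2"), support = 1L),
    genes = genes), class = "pathway_result")
  q70 <- apply(cohort, 1, quantile, 0.70)
  q30 <- apply(cohort, 1, quantile, 0.30)
  # planted: GO1 high + GT1 mutated -> activated
  pt <- stats::setNames(c(q70[["GO1"]] + 1, q70[["GT1"]], 0, 10), genes)
  expect_identical(patient_pathway_label(pt, "GT1", pathway, cohort),
                   "activated")
  # no pair satisfied
  pt2 <- stats::setNames(rep(5, 4), genes)
  pt2[["GO1"]] <- q70[["GO1"]] - 1; pt2[["GO2"]] <- q70[["GO2"]] - 1
  expect_identical(patient_pathway_label(pt2, character(0), pathway,
                                         cohort), "not_activated")
  # direct rule-evaluation oracle over 100 synthetic patients
  for (j in sample(100, 25)) {
    pt <- cohort[, j]
    mut <- if (runif(1) < 0.3) sample(genes, 1) else character(0)
    want <- "not_activated"
    for (k in 1:2) {
      go <- pathway$pairs$gene_over[k]; gt <- pathway$pairs$gene_target[k]
      if (pt[[go]] > q70[[go]] &&
          ((gt %in% mut) || pt[[gt]] < q30[[gt]]))
        want <- "activated"
    }
    got <- patient_pathway_label(pt, mut, pathway, cohort)
    expect_identical(got, want, info = j)
    # invariance to patient column order
    perm <- cohort[, sample(100)]
    expect_identical(patient_pathway_label(pt, mut, pathway, perm), want)
  }
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  expect_equal(fishers_exact(5, 5, 5, 5, "two.sided"), 1.0)
  expect_equal(fishers_exact(10, 0, 0, 10, "greater"),
               1 / choose(20, 10), tolerance = 1e-12)
  expect_warning(p <- fishers_exact(0, 0, 3, 4), "degenerate")
  expect_equal(p, 1)
  # full enumeration oracle over the hypergeometric support
  enum_p <- function(a, b, c, d, sided) {
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
    probs <- vapply(lo:hi, function(x)
      exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)),
      numeric(1))
    pa <- probs[a - lo + 1]
    if (sided == "greater") sum(probs[(a:hi) - lo + 1])
    else sum(probs[probs <= pa * (1 + 1e-7)])
  }
  set.seed(157)
  for (i in 1:100) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fishers_exact(a, b, c, d, "greater"),
                 enum_p(a, b, c, d, "greater"), tolerance = 1e-12,
                 info = paste(a, b, c, d))
    expect_equal(fishers_exact(a, b, c, d, "two.sided"),
                 enum_p(a, b, c, d, "two.sided"), tolerance = 1e-9,
                 info = paste(a, b, c, d))
  }
})

test_that("DDI class network: filters, enrichment and brute-force agreement", {
  # all probabilities below threshold -> empty network
  preds <- data.frame(drug_a = "d1", drug_b = "d2", context = "t1",
                      prediction = 0.5)
  expect_message(net <- ddi_class_network(preds, list(d1 = "A", d2 = "B")),
                 "no prediction")
  expect_equal(nrow(net), 0L)

  # one class pair holds every occurrence of one type against a balanced
  # background: enrichment survives alpha = 0.05
  set.seed(163)
  mk <- function(cls_a, cls_b, type, n)
    data.frame(drug_a = paste0(cls_a, "_", sample(5, n, TRUE)),
               drug_b = paste0(cls_b, "_", sample(5, n, TRUE)),
               context = type, prediction = runif(n, 0.92, 0.99))
  preds <- rbind(mk("A", "B", "tX", 12),
                 mk("C", "D", "tY", 12), mk("A", "D", "tY", 12))
  classes <- list()
  for (d in unique(c(preds$drug_a, preds$drug_b)))
    classes[[d]] <- sub("_.*", "", d)
  net <- ddi_class_network(preds, classes, top_types = 50,
                           prob_threshold = 0.9, per_drug_cap = 100,
                           alpha = 0.05)
  expect_true(any(net$class_a == "A" & net$class_b == "B" &
                    net$type == "tX"))
  # brute-force re-derivation of every reported p-value
  for (i in seq_len(nrow(net))) {
    cp <- c(net$class_a[i], net$class_b[i])
    inside <- mapply(function(a, b) {
      setequal(sort(c(classes[[a]], classes[[b]])), sort(cp)) ||
        all(cp %in% c(classes[[a]], classes[[b]]))
    }, preds$drug_a, preds$drug_b)
    is_ty <- preds$context == net$type[i]
    a <- sum(inside & is_ty); b <- sum(inside & !is_ty)
    cc <- sum(!inside & is_ty); d <- sum(!inside & !is_ty)
    expect_equal(net$p_value[i],
                 fisher.test(rbind(c(a, b), c(cc, d)),
                             alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
  # the per-drug cap keeps only the most confident interactions
  many <- mk("A", "B", "tZ", 30)
  many$drug_a <- "A_1"
  net2 <- ddi_class_network(rbind(preds, many), classes,
                            per_drug_cap = 5, alpha = 1.1)
  expect_lte(sum(net2$a[net2$type == "tZ"]), 5)
})
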