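# Deterministic synthetic-fixture generators for every input the
# framework consumes: drug tables with controllable per-modality
# missingness, PPI / ontology / SDL networks, expression matrices,
# labeled triplets with a planted two-modality rule, and xenograft
# trajectories.  Every generator is a pure function of (spec, seed).

#' Fixture specification
#'
#' @param n_drugs Number of drugs (>= 2).
#' @param n_contexts Number of contexts (cell lines / xenograft models).
#' @param n_genes Gene vocabulary size (>= 5).
#' @param missingness Named numeric vector of per-modality drop rates in
#'   `[0, 1]`; the SMILES modality is always present regardless of the
#'   requested rate (the input format guarantees it).  Unnamed modalities
#'   default to 0.
#' @param noise Label-flip probability for the planted rule.
#' @param expr_boost_frac Fraction of genes boosted above the
#'   over-expression threshold in each context.
#' @param xeno_noise Lognormal volume-measurement noise (sdlog).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_drugs = 12L, n_contexts = 6L, n_genes = 30L,
                         missingness = c(TARGET = 0.1, GEOM_3D = 0.1,
                                         TEXT = 0.2, ONTOLOGY = 0.2,
                                         SIDE_EFFECTS = 0.3,
                                         SENSITIVITY = 0.1),
                         noise = 0.05, expr_boost_frac = 0.3,
                         xeno_noise = 0.05, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_genes >= 5L, n_contexts >= 1L,
            all(missingness >= 0), all(missingness <= 1),
            noise >= 0, noise <= 1)
  rates <- stats::setNames(numeric(8L), modality_ids())
  rates[names(missingness)] <- missingness
  rates["SMILES"] <- 0
  rates["GRAPH_2D"] <- 0   # derivable from SMILES
  structure(list(n_drugs = as.integer(n_drugs),
                 n_contexts = as.integer(n_contexts),
                 n_genes = as.integer(n_genes), missingness = rates,
                 noise = noise, expr_boost_frac = expr_boost_frac,
                 xeno_noise = xeno_noise, seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_gene_ids <- function(spec) sprintf("g%03d", seq_len(spec$n_genes))
fixture_context_ids <- function(spec) sprintf("ctx%02d",
                                              seq_len(spec$n_contexts))

# Valence-safe SMILES from a tiny closed grammar: C-heavy chains with
# optional single-atom branches on carbons, occasional double bonds and
# an occasional all-carbon ring closure.
gen_smiles_one <- function() {
  n <- sample(3:8, 1L)
  els <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  ring <- n >= 5L && stats::runif(1) < 0.3
  if (ring) { els[1] <- "C"; els[n] <- "C" }
  out <- ""
  for (i in seq_len(n)) {
    if (i > 1L && els[i] == "C" && els[i - 1L] == "C" &&
        i < n && stats::runif(1) < 0.15)
      out <- paste0(out, "=")
    out <- paste0(out, els[i])
    if (i == 1L && ring) out <- paste0(out, "1")
    if (i > 1L && i < n && els[i] == "C" &&
        !endsWith(out, "=") && stats::runif(1) < 0.25)
      out <- paste0(out, "(", sample(c("C", "O", "N"), 1L), ")")
  }
  if (ring) out <- paste0(out, "1")
  out
}

#' Generate a synthetic drug table
#'
#' Drugs carry valence-safe SMILES from a closed grammar plus per-modality
#' payloads dropped i.i.d. at the spec's missingness rates (SMILES never
#' missing).  The latent (pre-drop) payloads are also returned: the
#' planted labeling rule in [gen_triplets()] is a function of the latent
#' drug properties, so modality missingness acts as feature noise rather
#' than label noise.
#'
#' @param spec A [fixture_spec()].
#' @param ontology Optional ontology graph whose node ids the ontology
#'   payload draws from; defaults to the one from [gen_networks()].
#' @return List: `drugs` (observed records), `latent` (records before
#'   modality dropping).
#' @export
gen_drugs <- function(spec, ontology = NULL) {
  if (is.null(ontology)) ontology <- gen_networks(spec)$ontology
  set.seed(spec$seed + 101L)
  genes <- fixture_gene_ids(spec)
  words <- c("kinase", "inhibitor", "receptor", "agonist", "antagonist",
             "topoisomerase", "antimetabolite", "alkylating", "mitotic",
             "checkpoint", "demethylase", "protease")
  latent <- vector("list", spec$n_drugs)
  ids <- sprintf("d%02d", seq_len(spec$n_drugs))
  for (i in seq_len(spec$n_drugs)) {
    p <- list(SMILES = gen_smiles_one())
    p$TARGET <- sample(genes, sample(2:4, 1L))
    p$GEOM_3D <- round(stats::rnorm(8L), 6)
    p$TEXT <- paste(sample(words, 3L), collapse = " ")
    p$ONTOLOGY <- sample(ontology$nodes, 1L)
    p$SIDE_EFFECTS <- stats::rbinom(SIDE_EFFECT_LEN, 1L, 0.15)
    p$SENSITIVITY <- round(stats::rnorm(SENSITIVITY_LEN), 6)
    latent[[i]] <- drug_record(ids[i], p)
  }
  names(latent) <- ids
  observed <- lapply(latent, function(d) {
    keep <- d$payloads
    for (m in setdiff(names(keep), "SMILES")) {
      if (stats::runif(1) < spec$missingness[[m]]) keep[[m]] <- NULL
    }
    drug_record(d$drug_id, keep)
  })
  names(observed) <- ids
  list(drugs = observed, latent = latent)
}

#' Generate synthetic networks
#'
#' A PPI network by seeded preferential attachment over the gene
#' vocabulary (no self-loops), a random rooted ontology tree over
#' synthetic drug classes, and a directed SDL pair list sampled from the
#' gene pairs.
#'
#' @param spec A [fixture_spec()].
#' @param n_onto Ontology node count (default 12).
#' @param n_sdl Number of SDL pairs (default `2 * n_genes`).
#' @return List: `ppi` (`ppi_network`), `ontology` (`ppi_network` over
#'   `onto*` nodes, a tree), `sdl` (`data.frame` `gene_over`,
#'   `gene_essential`).
#' @export
gen_networks <- function(spec, n_onto = 12L, n_sdl = 2L * spec$n_genes) {
  set.seed(spec$seed + 202L)
  genes <- fixture_gene_ids(spec)
  n <- length(genes)
  deg <- rep(1L, 2L); from <- genes[1]; to <- genes[2]
  for (i in 3:n) {
    k <- min(2L, i - 1L)
    tgt <- sample(i - 1L, k, prob = deg[seq_len(i - 1L)])
    from <- c(from, rep(genes[i], k)); to <- c(to, genes[tgt])
    deg <- c(deg, k)
    deg[tgt] <- deg[tgt] + 1L
  }
  ed <- data.frame(from = pmin(from, to), to = pmax(from, to),
                   weight = round(stats::runif(length(from), 0.1, 1), 3),
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$from, ed$to)), ]
  rownames(ed) <- NULL
  ppi <- structure(list(edges = ed, nodes = csort(genes)),
                   class = "ppi_network")
  onodes <- sprintf("onto%02d", seq_len(n_onto))
  parent <- vapply(2:n_onto, function(i) sample(i - 1L, 1L), 1L)
  oed <- data.frame(from = onodes[parent], to = onodes[2:n_onto],
                    weight = 1, stringsAsFactors = FALSE)
  ont <- structure(list(edges = data.frame(
    from = pmin(oed$from, oed$to), to = pmax(oed$from, oed$to),
    weight = 1, stringsAsFactors = FALSE), nodes = csort(onodes)),
    class = "ppi_network")
  pr <- matrix(genes[vapply(seq_len(n_sdl * 3L), function(i)
    sample(n, 2L), integer(2))], ncol = 2L, byrow = TRUE)
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  pr <- pr[!duplicated(paste(pr[, 1], pr[, 2])), , drop = FALSE]
  pr <- pr[seq_len(min(n_sdl, nrow(pr))), , drop = FALSE]
  sdl <- data.frame(gene_over = pr[, 1], gene_essential = pr[, 2],
                    stringsAsFactors = FALSE)
  list(ppi = ppi, ontology = ont, sdl = sdl)
}

#' Generate a synthetic expression matrix
#'
#' Per context: a low baseline (50-200 TPM) for every gene, with a seeded
#' context-specific fraction of genes boosted well above the default
#' over-expression threshold of 400 TPM (450-900).  Values are plain TPM
#' magnitudes; columns are not renormalized to one million because the
#' gene vocabulary is a small subsample of a transcriptome.
#'
#' @param spec A [fixture_spec()].
#' @return Matrix (genes x contexts) with `unit` attribute `"TPM"`.
#' @export
gen_expression <- function(spec) {
  set.seed(spec$seed + 303L)
  genes <- fixture_gene_ids(spec)
  ctx <- fixture_context_ids(spec)
  m <- matrix(stats::runif(length(genes) * length(ctx), 50, 200),
              length(genes), length(ctx), dimnames = list(genes, ctx))
  nb <- max(1L, round(spec$expr_boost_frac * length(genes)))
  for (j in seq_along(ctx)) {
    hot <- sample(length(genes), nb)
    m[hot, j] <- stats::runif(nb, 450, 900)
  }
  m <- round(m, 2)
  attr(m, "unit") <- "TPM"
  m
}

# the planted labeling rule: synergy iff drug A is broadly sensitizing
# (latent sensitivity mean above the cohort median) AND drug B targets a
# gene over-expressed in the context
planted_rule <- function(latent, expr, threshold = 400) {
  sens_mean <- vapply(latent, function(d)
    mean(d$payloads$SENSITIVITY), numeric(1))
  med <- stats::median(sens_mean)
  over <- lapply(colnames(expr), function(cid)
    rownames(expr)[expr[, cid] >= threshold])
  names(over) <- colnames(expr)
  function(a, b, cid) {
    as.integer(sens_mean[[a]] > med &&
                 any(latent[[b]]$payloads$TARGET %in% over[[cid]]))
  }
}

#' Generate labeled triplets with a planted rule
#'
#' Ordered drug pairs crossed with contexts, labeled by a two-modality
#' rule — synergy iff drug A's latent sensitivity profile has an
#' above-median mean AND drug B targets a gene over-expressed in the
#' context — then flipped independently at the spec's noise rate.  The
#' rule spans two modalities on opposite sides of the pair, so no single
#' modality suffices to recover it.
#'
#' @param spec A [fixture_spec()].
#' @param latent Latent drug records from [gen_drugs()].
#' @param expr Expression matrix from [gen_expression()].
#' @param n_triplets Number of triplets to sample from the ordered
#'   candidate space (default: all of it).
#' @return `data.frame`: `drug_a`, `drug_b`, `context`, `label`,
#'   `label_clean` (pre-noise), `time_days` (NA).
#' @export
gen_triplets <- function(spec, latent, expr, n_triplets = NULL) {
  set.seed(spec$seed + 404L)
  ids <- names(latent)
  grid <- expand.grid(drug_b = ids, drug_a = ids,
                      context = colnames(expr),
                      stringsAsFactors = FALSE)[, c("drug_a", "drug_b",
                                                    "context")]
  grid <- grid[grid$drug_a != grid$drug_b, , drop = FALSE]
  if (!is.null(n_triplets) && n_triplets < nrow(grid))
    grid <- grid[sample(nrow(grid), n_triplets), , drop = FALSE]
  rule <- planted_rule(latent, expr)
  clean <- mapply(rule, grid$drug_a, grid$drug_b, grid$context)
  flip <- stats::rbinom(length(clean), 1L, spec$noise)
  grid$label <- as.integer(xor(clean, flip))
  grid$label_clean <- as.integer(clean)
  grid$time_days <- NA_integer_
  rownames(grid) <- NULL
  grid
}

#' Generate xenograft trajectories
#'
#' Exponential tumor growth `Vol_t = exp((g - e) t)` with model-specific
#' growth rate `g`, pair-specific treatment effect `e` and multiplicative
#' lognormal measurement noise, sampled at days 0, 3, 7, 10, 14, 17, 21.
#' Day 0 is noiseless by construction (the relative change is measured
#' against it).
#'
#' @param spec A [fixture_spec()].
#' @param drugs Named list of drug records (pairs are sampled from it).
#' @param n_pairs Drug pairs per xenograft model (default 4).
#' @return List of `xeno_trajectory` objects.
#' @export
gen_xenograft <- function(spec, drugs, n_pairs = 4L) {
  set.seed(spec$seed + 505L)
  days <- c(0L, 3L, 7L, 10L, 14L, 17L, 21L)
  ids <- names(drugs)
  out <- list()
  for (mi in seq_len(spec$n_contexts)) {
    mid <- sprintf("xg%02d", mi)
    g <- stats::runif(1, 0.05, 0.15)
    for (pi in seq_len(n_pairs)) {
      pr <- sample(ids, 2L)
      e <- stats::runif(1, 0, 0.2)
      vol <- exp((g - e) * days)
      noise <- exp(stats::rnorm(length(days), 0, spec$xeno_noise))
      noise[1] <- 1
      vol <- vol * noise
      dvol <- (vol - vol[1]) / vol[1]
      out[[length(out) + 1L]] <-
        xeno_trajectory(mid, pr[1], pr[2], days, dvol)
    }
  }
  out
}

#' Generate the complete fixture bundle
#'
#' Convenience wrapper producing every input at once with consistent
#' seeding: networks, drugs (observed + latent), expression, labeled
#' triplets and xenograft trajectories.
#'
#' @param spec A [fixture_spec()].
#' @param n_triplets Optional triplet subsample size.
#' @return Named list: `spec`, `ppi`, `ontology`, `sdl`, `drugs`,
#'   `latent`, `expr`, `triplets`, `trajectories`.
#' @export
gen_fixture_bundle <- function(spec = fixture_spec(), n_triplets = NULL) {
  nets <- gen_networks(spec)
  dr <- gen_drugs(spec, nets$ontology)
  expr <- gen_expression(spec)
  tri <- gen_triplets(spec, dr$latent, expr, n_triplets)
  traj <- gen_xenograft(spec, dr$drugs)
  list(spec = spec, ppi = nets$ppi, ontology = nets$ontology,
       sdl = nets$sdl, drugs = dr$drugs, latent = dr$latent, expr = expr,
       triplets = tri, trajectories = traj)
}

#' Write a fixture bundle to disk
#'
#' Serializes the bundle into the package's plain-text formats: drug
#' table, PPI and ontology edge lists, SDL pairs, expression matrix and
#' triplet table.
#'
#' @param bundle From [gen_fixture_bundle()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_drug_table(bundle$drugs, file.path(dir, "drugs.tsv"))
  write_edge_list(bundle$ppi, file.path(dir, "ppi.tsv"))
  write_edge_list(bundle$ontology, file.path(dir, "ontology.tsv"))
  utils::write.table(bundle$sdl, file.path(dir, "sdl_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_expression_matrix(bundle$expr, file.path(dir, "expression.tsv"))
  write_triplet_table(bundle$triplets[, c("drug_a", "drug_b", "context",
                                          "label", "time_days")],
                      file.path(dir, "triplets.tsv"))
  invisible(dir)
}
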