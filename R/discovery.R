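# Downstream interpretation: novel-triplet enumeration, drug-sensitive
# pathway mining through synthetic-dosage-lethality (SDL) interactions,
# patient pathway-activation labels, and the Fisher's-exact interaction
# network between drug classes.

#' Enumerate candidate triplets not yet measured
#'
#' The ordered candidate space over `n` drugs and `m` contexts has
#' `n*(n-1)*m` triplets.  A triplet is novel iff neither ordering of its
#' drug pair appears among the observed triplets; novel triplets are
#' reported once, in canonical (lexicographic) drug order.
#'
#' @param drugs Character vector of drug ids.
#' @param contexts Character vector of context ids.
#' @param observed Optional `data.frame` with `drug_a`, `drug_b`,
#'   `context` (orderings may differ from canonical).
#' @return List: `ordered_count` (the full ordered space size) and
#'   `novel` (`data.frame` of canonical unordered novel triplets).
#' @export
enumerate_candidate_triplets <- function(drugs, contexts, observed = NULL) {
  stopifnot(length(drugs) >= 2L, length(contexts) >= 1L)
  n <- length(drugs); m <- length(contexts)
  ordered_count <- n * (n - 1) * m
  obs_keys <- character(0)
  if (!is.null(observed) && nrow(observed)) {
    unknown <- setdiff(unique(c(observed$drug_a, observed$drug_b)), drugs)
    if (length(unknown))
      stop("observed triplets reference unknown drug(s): ",
           paste(unknown, collapse = ", "))
    obs_keys <- unique(paste(pmin(observed$drug_a, observed$drug_b),
                             pmax(observed$drug_a, observed$drug_b),
                             observed$context, sep = "\r"))
  }
  pairs <- utils::combn(csort(drugs), 2L)
  grid <- data.frame(
    drug_a = rep(pairs[1, ], times = m),
    drug_b = rep(pairs[2, ], times = m),
    context = rep(contexts, each = ncol(pairs)),
    stringsAsFactors = FALSE)
  keys <- paste(grid$drug_a, grid$drug_b, grid$context, sep = "\r")
  novel <- grid[!(keys %in% obs_keys), , drop = FALSE]
  rownames(novel) <- NULL
  list(ordered_count = ordered_count, novel = novel)
}

#' Build gene pairs from high-confidence synergistic predictions
#'
#' Keeps triplets predicted at or above `threshold`, and for each emits
#' the Cartesian product of the context's over-expressed genes with the
#' combination's target genes, oriented (over-expressed, target).
#' Self-pairs (the same gene on both sides) are excluded.  Pairs are
#' deduplicated with support counts (number of contributing triplets).
#'
#' @param predictions `data.frame` with `drug_a`, `drug_b`, `context`,
#'   `prediction` in (0, 1).
#' @param threshold Minimum predicted probability (default 0.9).
#' @param drug_targets Named list: drug id -> character vector of target
#'   genes.
#' @param overexpressed Named list: context id -> character vector of
#'   over-expressed genes.
#' @return List: `pairs` (`data.frame` `gene_over`, `gene_target`,
#'   `support`) and `skipped` (triplets that passed the threshold but had
#'   no targets or no over-expressed genes).
#' @export
build_gene_pairs <- function(predictions, threshold = 0.9, drug_targets,
                             overexpressed) {
  keep <- predictions[predictions$prediction >= threshold, , drop = FALSE]
  counts <- new.env(parent = emptyenv())
  skipped <- 0L
  for (i in seq_len(nrow(keep))) {
    tg <- unique(c(drug_targets[[keep$drug_a[i]]],
                   drug_targets[[keep$drug_b[i]]]))
    ov <- overexpressed[[keep$context[i]]]
    if (length(tg) == 0L || length(ov) == 0L) {
      skipped <- skipped + 1L
      next
    }
    for (go in ov) for (gt in tg) {
      if (go == gt) next
      k <- paste(go, gt, sep = "\r")
      counts[[k]] <- if (is.null(counts[[k]])) 1L else counts[[k]] + 1L
    }
  }
  ks <- ls(counts)
  if (length(ks) == 0L) {
    pairs <- data.frame(gene_over = character(0),
                        gene_target = character(0), support = integer(0),
                        stringsAsFactors = FALSE)
  } else {
    sp <- strsplit(ks, "\r", fixed = TRUE)
    pairs <- data.frame(
      gene_over = vapply(sp, `[`, "", 1L),
      gene_target = vapply(sp, `[`, "", 2L),
      support = vapply(ks, function(k) counts[[k]], 1L),
      stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$gene_over, pairs$gene_target,
                         method = "radix"), ]
    rownames(pairs) <- NULL
  }
  list(pairs = pairs, skipped = skipped)
}

#' Filter gene pairs through an SDL network
#'
#' Keeps the oriented gene pairs (over-active, essential) that occur in
#' the synthetic-dosage-lethality network: the over-expressed gene plays
#' the over-active role and the drug target the essential role.
#'
#' @param gene_pairs `data.frame` from [build_gene_pairs()]`$pairs`.
#' @param sdl `data.frame` with `gene_over` and `gene_essential` columns
#'   (directed pairs), e.g. read with [read_sdl_pairs()].
#' @return List (`pathway_result`): `pairs` (surviving rows with
#'   support), `genes` (union of endpoints).
#' @export
filter_sdl <- function(gene_pairs, sdl) {
  sdl_keys <- paste(sdl$gene_over, sdl$gene_essential, sep = "\r")
  keys <- paste(gene_pairs$gene_over, gene_pairs$gene_target, sep = "\r")
  keep <- gene_pairs[keys %in% sdl_keys, , drop = FALSE]
  rownames(keep) <- NULL
  structure(list(pairs = keep,
                 genes = csort(unique(c(keep$gene_over,
                                       keep$gene_target)))),
            class = "pathway_result")
}

#' Read a directed SDL pair list
#'
#' Two-column whitespace/TAB file: over-active gene, essential gene.
#' Self-pairs are dropped.
#'
#' @param path File path.
#' @return `data.frame` with `gene_over`, `gene_essential`.
#' @export
read_sdl_pairs <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("gene_over", "gene_essential"),
                          stringsAsFactors = FALSE)
  df[df$gene_over != df$gene_essential, , drop = FALSE]
}

#' Patient pathway-activation label
#'
#' A gene is highly expressed in a patient iff its expression exceeds the
#' cohort's 70th percentile for that gene; it is inhibited iff it is
#' mutated or its expression is below the cohort's 30th percentile
#' (lower than 70% of patients).  The pathway is activated iff at least
#' one pathway pair has its essential (target) gene inhibited and its
#' over-active gene highly expressed.  Percentiles use linear
#' interpolation and strict inequalities at the boundary.
#'
#' @param expr Named expression vector of one patient.
#' @param mutated Character vector of the patient's mutated genes.
#' @param pathway A `pathway_result` from [filter_sdl()].
#' @param cohort Expression matrix (genes x patients) supplying the
#'   percentile references.
#' @return `"activated"` or `"not_activated"`.
#' @export
patient_pathway_label <- function(expr, mutated, pathway, cohort) {
  q <- function(g, p) stats::quantile(cohort[g, ], p, names = FALSE)
  for (i in seq_len(nrow(pathway$pairs))) {
    go <- pathway$pairs$gene_over[i]
    ge <- pathway$pairs$gene_target[i]
    if (is.null(ge)) ge <- pathway$pairs$gene_essential[i]
    if (!(go %in% rownames(cohort)) || !(ge %in% rownames(cohort)) ||
        !(go %in% names(expr)) || !(ge %in% names(expr))) {
      message("patient_pathway_label: pair ", go, "->", ge,
              " skipped (gene missing from cohort)")
      next
    }
    high <- expr[[go]] > q(go, 0.70)
    inhibited <- (ge %in% mutated) || expr[[ge]] < q(ge, 0.30)
    if (high && inhibited) return("activated")
  }
  "not_activated"
}

#' Fisher's exact test on a 2x2 table
#'
#' Hypergeometric exact p-value; one-sided enrichment (`"greater"`) by
#' default, two-sided by the point-probability rule.  Degenerate margins
#' (an empty row or column) give p = 1 with a warning.
#'
#' @param a,b,c,d Nonnegative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @param sided `"greater"` or `"two.sided"`.
#' @return P-value.
#' @export
fishers_exact <- function(a, b, c, d, sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- matrix(c(a, c, b, d), 2L)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("degenerate margins; p = 1")
    return(1)
  }
  stats::fisher.test(m, alternative = sided)$p.value
}

#' Drug-class interaction network by Fisher's exact test
#'
#' From per-(pair, type) predicted probabilities: restrict to the
#' `top_types` most frequent interaction types, drop predictions below
#' `prob_threshold`, keep each drug's `per_drug_cap` most confident
#' interactions, then for every (class pair, type) build the 2x2 table
#' (within this class pair vs not) x (this type vs others) over the
#' surviving interactions and keep edges with one-sided enrichment
#' p < `alpha`.  Drugs belonging to several classes count in every class
#' pair they span.
#'
#' @param predictions `data.frame` with `drug_a`, `drug_b`, `context`
#'   (interaction type) and `prediction`.
#' @param drug_classes Named list: drug id -> character vector of class
#'   ids.
#' @param top_types Number of most frequent types kept (default 50).
#' @param prob_threshold Minimum probability (default 0.9).
#' @param per_drug_cap Most confident interactions kept per drug
#'   (default 100).
#' @param alpha Significance threshold (default 0.05).
#' @param sided Sidedness of the test (default one-sided enrichment).
#' @return `data.frame` of network edges: `class_a`, `class_b`, `type`,
#'   the 2x2 counts and `p_value`; zero rows if nothing survives.
#' @export
ddi_class_network <- function(predictions, drug_classes, top_types = 50L,
                              prob_threshold = 0.9, per_drug_cap = 100L,
                              alpha = 0.05,
                              sided = c("greater", "two.sided")) {
  sided <- match.arg(sided)
  empty <- data.frame(class_a = character(0), class_b = character(0),
                      type = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  tb <- table(predictions$context)
  ord <- order(-as.integer(tb), names(tb), method = "radix")
  types <- names(tb)[ord][seq_len(min(top_types, length(tb)))]
  kept <- predictions[predictions$context %in% types &
                        predictions$prediction >= prob_threshold, ,
                      drop = FALSE]
  if (nrow(kept) == 0L) {
    message("ddi_class_network: no prediction survives the filters")
    return(empty)
  }
  # per-drug confidence cap: an interaction survives iff it is within the
  # cap for every drug it involves
  ok <- rep(TRUE, nrow(kept))
  for (dg in unique(c(kept$drug_a, kept$drug_b))) {
    rows <- which(kept$drug_a == dg | kept$drug_b == dg)
    if (length(rows) > per_drug_cap) {
      drop <- rows[order(-kept$prediction[rows])][-seq_len(per_drug_cap)]
      ok[drop] <- FALSE
    }
  }
  kept <- kept[ok, , drop = FALSE]
  if (nrow(kept) == 0L) {
    message("ddi_class_network: per-drug cap removed every prediction")
    return(empty)
  }
  # class-pair labels per interaction (drugs may be in several classes)
  cp_of <- function(i) {
    ca <- drug_classes[[kept$drug_a[i]]]
    cb <- drug_classes[[kept$drug_b[i]]]
    if (is.null(ca) || is.null(cb)) return(character(0))
    unique(as.vector(outer(ca, cb, function(x, y)
      paste(pmin(x, y), pmax(x, y), sep = "\r"))))
  }
  cps <- lapply(seq_len(nrow(kept)), cp_of)
  all_cp <- unique(unlist(cps))
  out <- empty
  N <- nrow(kept)
  for (cp in all_cp) {
    inside <- vapply(cps, function(x) cp %in% x, TRUE)
    for (ty in unique(kept$context)) {
      is_ty <- kept$context == ty
      a <- sum(inside & is_ty); b <- sum(inside & !is_ty)
      cc <- sum(!inside & is_ty); d <- N - a - b - cc
      p <- suppressWarnings(fishers_exact(a, b, cc, d, sided))
      if (p < alpha) {
        cls <- strsplit(cp, "\r", fixed = TRUE)[[1]]
        out <- rbind(out, data.frame(
          class_a = cls[1], class_b = cls[2], type = ty,
          a = a, b = b, c = cc, d = d, p_value = p,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (nrow(out)) out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
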