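# Domain types and file plumbing shared by all modules.

# locale-independent character sort: id orderings feed vocabulary and
# embedding-row layouts, so they must not depend on LC_COLLATE
csort <- function(x) sort(x, method = "radix")

#' The eight drug modalities
#'
#' Canonical, ordered identifiers for the eight drug representations the
#' framework can consume: the SMILES string, the 2D molecular graph, the
#' target gene set, the 3D-aligned embedding, the textual-description
#' embedding, the ontology position, the 27-type side-effect indicator and
#' the 60-cell-line sensitivity profile.  The ordering is stable and is used
#' everywhere views are enumerated, so view indices are reproducible.
#'
#' @return Character vector of length 8, in canonical order.
#' @export
#' @examples
#' modality_ids()
modality_ids <- function() {
  c("SMILES", "GRAPH_2D", "TARGET", "GEOM_3D",
    "TEXT", "ONTOLOGY", "SIDE_EFFECTS", "SENSITIVITY")
}

SIDE_EFFECT_LEN <- 27L
SENSITIVITY_LEN <- 60L

#' Construct a drug record
#'
#' A drug record is a drug id plus a named list of per-modality payloads.
#' Absent modalities are simply absent keys: missingness is data and is
#' never imputed.
#'
#' @param drug_id Character scalar.
#' @param payloads Named list; names must be a subset of [modality_ids()].
#'   Expected payload types: `SMILES` a string, `GRAPH_2D` a `mol_graph`,
#'   `TARGET` a character vector of gene ids, `GEOM_3D`/`TEXT` numeric
#'   vectors (precomputed embeddings), `ONTOLOGY` a node id string,
#'   `SIDE_EFFECTS` a binary vector of length 27, `SENSITIVITY` a numeric
#'   vector of length 60.
#' @return An object of class `drug_record`.
#' @export
drug_record <- function(drug_id, payloads) {
  stopifnot(is.character(drug_id), length(drug_id) == 1L, nzchar(drug_id))
  if (length(payloads) == 0L)
    stop("drug '", drug_id, "': at least one modality payload is required")
  bad <- setdiff(names(payloads), modality_ids())
  if (length(bad))
    stop("drug '", drug_id, "': unknown modality key(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(payloads$SIDE_EFFECTS) &&
      length(payloads$SIDE_EFFECTS) != SIDE_EFFECT_LEN)
    stop("drug '", drug_id, "': side-effect payload must have length ",
         SIDE_EFFECT_LEN, ", got ", length(payloads$SIDE_EFFECTS))
  if (!is.null(payloads$SENSITIVITY) &&
      length(payloads$SENSITIVITY) != SENSITIVITY_LEN)
    stop("drug '", drug_id, "': sensitivity payload must have length ",
         SENSITIVITY_LEN, ", got ", length(payloads$SENSITIVITY))
  structure(list(drug_id = drug_id, payloads = payloads),
            class = "drug_record")
}

#' @export
print.drug_record <- function(x, ...) {
  cat("<drug_record> ", x$drug_id, " [",
      paste(names(x$payloads), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Modalities available for a drug record
#'
#' @param drug A `drug_record`.
#' @return Character vector, a subset of [modality_ids()] in canonical order.
#' @export
available_modalities <- function(drug) {
  intersect(modality_ids(), names(drug$payloads))
}

# ---- inline vector dialect ----------------------------------------------
# Multi-valued cells in single-file tables are semicolon-separated decimals
# (vectors) or semicolon-separated tokens (gene sets).

format_vec <- function(x) paste(format(x, digits = 17, trim = TRUE,
                                       scientific = FALSE), collapse = ";")
parse_vec <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}
parse_tokens <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  strsplit(s, ";", fixed = TRUE)[[1]]
}

#' Read a drug table
#'
#' Reads a TSV (or CSV) drug table into a list of [drug_record()]s.  A
#' `smiles` column is required; the optional columns `targets`, `embed_3d`,
#' `embed_text` (or `text` with a raw description string), `ontology`,
#' `side_effects` and `sensitivity` populate the other modalities.  Vector
#' cells use the semicolon dialect.  Empty cells leave the modality absent.
#'
#' @param path File path.
#' @param sep Field separator, `"\t"` by default.
#' @return Named list of `drug_record`s, keyed by drug id.
#' @export
read_drug_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  if (!"drug_id" %in% names(df) || !"smiles" %in% names(df))
    stop("drug table must have 'drug_id' and 'smiles' columns")
  dup <- df$drug_id[duplicated(df$drug_id)]
  if (length(dup))
    stop("duplicate drug_id(s): ", paste(unique(dup), collapse = ", "))
  out <- vector("list", nrow(df))
  cell <- function(col, i) {
    if (!col %in% names(df)) return(NA_character_)
    v <- df[[col]][i]
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }
  for (i in seq_len(nrow(df))) {
    p <- list()
    sm <- cell("smiles", i)
    if (is.na(sm)) stop("row ", i, ": smiles column is required and empty")
    p$SMILES <- sm
    tg <- parse_tokens(cell("targets", i))
    if (!is.null(tg)) p$TARGET <- tg
    v3 <- parse_vec(cell("embed_3d", i))
    if (!is.null(v3)) p$GEOM_3D <- v3
    vt <- parse_vec(cell("embed_text", i))
    if (!is.null(vt)) {
      p$TEXT <- vt
    } else {
      txt <- cell("text", i)
      if (!is.na(txt)) p$TEXT <- txt
    }
    on <- cell("ontology", i)
    if (!is.na(on)) p$ONTOLOGY <- on
    se <- parse_vec(cell("side_effects", i))
    if (!is.null(se)) {
      if (length(se) != SIDE_EFFECT_LEN)
        stop("row ", i, " (", df$drug_id[i], "): side_effects has length ",
             length(se), ", expected ", SIDE_EFFECT_LEN)
      p$SIDE_EFFECTS <- se
    }
    sn <- parse_vec(cell("sensitivity", i))
    if (!is.null(sn)) {
      if (length(sn) != SENSITIVITY_LEN)
        stop("row ", i, " (", df$drug_id[i], "): sensitivity has length ",
             length(sn), ", expected ", SENSITIVITY_LEN)
      p$SENSITIVITY <- sn
    }
    out[[i]] <- drug_record(df$drug_id[i], p)
  }
  names(out) <- df$drug_id
  out
}

#' Write a drug table
#'
#' Inverse of [read_drug_table()]: serializes records field-for-field so a
#' read/write round trip preserves payload presence exactly.
#'
#' @param drugs Named list of `drug_record`s.
#' @param path Output path.
#' @export
write_drug_table <- function(drugs, path) {
  col <- function(f) vapply(drugs, f, character(1))
  df <- data.frame(
    drug_id = col(function(d) d$drug_id),
    smiles = col(function(d) d$payloads$SMILES),
    targets = col(function(d)
      if (is.null(d$payloads$TARGET)) "" else
        paste(d$payloads$TARGET, collapse = ";")),
    embed_3d = col(function(d)
      if (is.null(d$payloads$GEOM_3D)) "" else format_vec(d$payloads$GEOM_3D)),
    embed_text = col(function(d)
      if (is.null(d$payloads$TEXT) || is.character(d$payloads$TEXT)) "" else
        format_vec(d$payloads$TEXT)),
    text = col(function(d)
      if (is.character(d$payloads$TEXT)) d$payloads$TEXT else ""),
    ontology = col(function(d)
      if (is.null(d$payloads$ONTOLOGY)) "" else d$payloads$ONTOLOGY),
    side_effects = col(function(d)
      if (is.null(d$payloads$SIDE_EFFECTS)) "" else
        format_vec(d$payloads$SIDE_EFFECTS)),
    sensitivity = col(function(d)
      if (is.null(d$payloads$SENSITIVITY)) "" else
        format_vec(d$payloads$SENSITIVITY)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled triplet table
#'
#' Columns: `drug_a`, `drug_b`, `context`, `label`, and optionally
#' `time_days` for xenograft records.  Labels are binary 0/1 for
#' classification tasks or real tumor-volume-change fractions for
#' regression.
#'
#' @param path File path.
#' @param drugs Optional named list of `drug_record`s; if given, every
#'   triplet drug id must resolve in it.
#' @return `data.frame` with the columns above.
#' @export
read_triplet_table <- function(path, drugs = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("drug_a", "drug_b", "context", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("triplet table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(drugs)) {
    unknown <- setdiff(unique(c(df$drug_a, df$drug_b)), names(drugs))
    if (length(unknown))
      stop("triplet table references unknown drug(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!"time_days" %in% names(df)) df$time_days <- NA_integer_
  df
}

#' Write a triplet table
#' @param triplets `data.frame` as returned by [read_triplet_table()].
#' @param path Output path.
#' @export
write_triplet_table <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' TSV with gene ids as row labels and context (cell line / xenograft model /
#' patient) ids as column labels.  Values must be nonnegative.  The unit is
#' recorded in the `"unit"` attribute for downstream conversion with
#' [fpkm_to_tpm()].
#'
#' @param path File path.
#' @param unit `"TPM"` or `"FPKM"`.
#' @return Numeric matrix (genes x contexts) with the `unit` attribute set.
#' @export
read_expression_matrix <- function(path, unit = c("TPM", "FPKM")) {
  unit <- match.arg(unit)
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("expression matrix has non-numeric entries")
  if (is.null(rownames(m)) || any(!nzchar(rownames(m))))
    stop("expression matrix is missing gene labels")
  if (is.null(colnames(m)) || any(!nzchar(colnames(m))))
    stop("expression matrix is missing context labels")
  if (any(m < 0))
    stop("expression matrix contains negative values (first at gene '",
         rownames(m)[which(rowSums(m < 0) > 0)[1]], "')")
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix
#' @param m Matrix from [read_expression_matrix()].
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Whitespace- or TAB-separated two-column file (optional third numeric
#' weight column).  Returns a symmetric, simple graph: duplicate and
#' reversed edges are collapsed and self-loops are dropped (with a message
#' reporting how many).
#'
#' @param path File path.
#' @return A `ppi_network`: list with `edges` (data.frame `from`, `to`,
#'   `weight`) and `nodes` (character vector).  Edges are stored with
#'   `from < to` lexicographically.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(parts) < 2L)
      stop("edge list line ", i, " is unparseable: '", lines[i], "'")
    wt <- 1
    if (length(parts) >= 3L) {
      wt <- suppressWarnings(as.numeric(parts[3]))
      if (is.na(wt))
        stop("edge list line ", i, " has a non-numeric weight: '",
             parts[3], "'")
    }
    from[i] <- parts[1]; to[i] <- parts[2]; w[i] <- wt
  }
  self <- from == to
  if (any(self))
    message("read_edge_list: dropped ", sum(self), " self-loop(s)")
  from2 <- pmin(from[!self], to[!self])
  to2 <- pmax(from[!self], to[!self])
  ed <- data.frame(from = from2, to = to2, weight = w[!self],
                   stringsAsFactors = FALSE)
  ed <- ed[!duplicated(paste(ed$from, ed$to, sep = "\r")), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(edges = ed,
                 nodes = csort(unique(c(from, to)))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " undirected edges\n", sep = "")
  invisible(x)
}

#' Write an edge list
#' @param net A `ppi_network` (or any list with an `edges` data.frame).
#' @param path Output path.
#' @param weights Write the weight column? Default `TRUE`.
#' @export
write_edge_list <- function(net, path, weights = TRUE) {
  ed <- net$edges
  if (!weights) ed <- ed[, c("from", "to")]
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# adjacency lookup: named list node -> data.frame(neighbor, weight)
ppi_adjacency <- function(net) {
  adj <- new.env(parent = emptyenv())
  add <- function(a, b, w) {
    cur <- if (is.null(adj[[a]])) list(nb = character(0), w = numeric(0))
           else adj[[a]]
    cur$nb <- c(cur$nb, b); cur$w <- c(cur$w, w)
    adj[[a]] <- cur
  }
  for (i in seq_len(nrow(net$edges))) {
    add(net$edges$from[i], net$edges$to[i], net$edges$weight[i])
    add(net$edges$to[i], net$edges$from[i], net$edges$weight[i])
  }
  adj
}

#' Run configuration
#'
#' Bundles every tunable parameter of the model and training loop.  The
#' defaults follow the reference configuration for cell-line synergy
#' prediction: hidden size 512, a 6-layer SMILES transformer (width 512), a
#' 6-layer graph encoder (width 384), top-k aggregation with k = 8, two
#' sampled view pairs per batch for the auxiliary and consistency terms,
#' all three consistency/auxiliary weights at 0.01, batch size 128, and an
#' over-expression threshold of 400 TPM for context gene sets.
#'
#' @param dhid Shared embedding size (even; time embeddings pair sin/cos).
#' @param smiles_layers,smiles_dim Transformer depth and width.
#' @param graph_layers,graph_dim Message-passing depth and width.
#' @param gene_dim Width of the learnable gene-embedding table.
#' @param text_dim Width of the hashed bag-of-tokens fallback featurizer.
#' @param onto_dim Ontology embedding dimension (RWR + SVD).
#' @param top_k Number of view predictions kept by the aggregator.
#' @param r Number of modality pairs sampled per batch.
#' @param lambda_aux,lambda_infonce,lambda_mse Loss weights.
#' @param batch_size,steps,warmup_steps,lr,poly_power Optimizer schedule:
#'   Adam with linear warmup then polynomial decay of power `poly_power`.
#' @param dropout Dropout rate (training mode only).
#' @param clip_norm Global gradient-norm clip applied each step (0
#'   disables clipping).
#' @param expr_threshold Over-expression threshold (TPM) for context genes.
#' @param k_g Number of PPI nearest neighbors per target gene.
#' @param rwr_alpha,rwr_tol,rwr_max_iter Random-walk-with-restart controls.
#' @param shortcut One of `"topk_mean"` (divide the retained top-k sum by
#'   k) or `"all_mean"` (divide by k the sum of all predictions).
#' @param gene_pool `"mean"` or `"sum"` pooling for gene sets.
#' @param max_smiles_len Token truncation length for the SMILES encoder.
#' @param seed Integer seed controlling every random draw.
#' @return A `run_config` list.
#' @export
run_config <- function(dhid = 512L, smiles_layers = 6L, smiles_dim = 512L,
                       graph_layers = 6L, graph_dim = 384L,
                       gene_dim = 64L, text_dim = 64L, onto_dim = 16L,
                       top_k = 8L, r = 2L,
                       lambda_aux = 0.01, lambda_infonce = 0.01,
                       lambda_mse = 0.01,
                       batch_size = 128L, steps = 1000L,
                       warmup_steps = 40L, lr = 1e-4, poly_power = 1,
                       dropout = 0.1, expr_threshold = 400,
                       k_g = 5L, rwr_alpha = 0.5, rwr_tol = 1e-6,
                       rwr_max_iter = 100L,
                       clip_norm = 1.0,
                       shortcut = c("topk_mean", "all_mean"),
                       gene_pool = c("mean", "sum"),
                       max_smiles_len = 128L, seed = 1L) {
  shortcut <- match.arg(shortcut)
  gene_pool <- match.arg(gene_pool)
  stopifnot(top_k >= 1L, dhid %% 2L == 0L,
            lambda_aux >= 0, lambda_infonce >= 0, lambda_mse >= 0,
            r >= 1L, dropout >= 0, dropout < 1)
  cfg <- list(dhid = as.integer(dhid), smiles_layers = as.integer(smiles_layers),
              smiles_dim = as.integer(smiles_dim),
              graph_layers = as.integer(graph_layers),
              graph_dim = as.integer(graph_dim),
              gene_dim = as.integer(gene_dim), text_dim = as.integer(text_dim),
              onto_dim = as.integer(onto_dim),
              top_k = as.integer(top_k), r = as.integer(r),
              lambda_aux = lambda_aux, lambda_infonce = lambda_infonce,
              lambda_mse = lambda_mse,
              batch_size = as.integer(batch_size), steps = as.integer(steps),
              warmup_steps = as.integer(warmup_steps), lr = lr,
              poly_power = poly_power, dropout = dropout,
              clip_norm = clip_norm,
              expr_threshold = expr_threshold, k_g = as.integer(k_g),
              rwr_alpha = rwr_alpha, rwr_tol = rwr_tol,
              rwr_max_iter = as.integer(rwr_max_iter),
              shortcut = shortcut, gene_pool = gene_pool,
              max_smiles_len = as.integer(max_smiles_len),
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @return [read_run_config()]: a `run_config`; unknown keys are an error.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# 32-bit multiplicative string hash (deterministic across platforms;
# stays in double-exact integer range)
string_hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 4294967291
  h
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Hash a configuration for logging
#'
#' A short deterministic hex digest of the configuration contents (FNV-1a
#' over the serialized key=value lines), so logs and checkpoints can state
#' exactly which configuration produced them.
#'
#' @param cfg A `run_config`.
#' @return 8-hex-digit character scalar.
#' @export
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", as.integer(string_hash32(s) %% 2147483647))
}
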