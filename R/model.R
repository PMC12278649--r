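# Model assembly: parameter initialization, per-drug static feature cache,
# and the shared forward pass that the trainer and all predictors use.

glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}
zeros <- function(nr, nc) matrix(0, nr, nc)

init_params <- function(cfg, dims, task) {
  P <- list()
  ds <- cfg$smiles_dim; dg <- cfg$graph_dim; dh <- cfg$dhid
  P$tok_emb <- glorot(dims$vocab_size, ds)
  for (l in seq_len(cfg$smiles_layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      P[[paste0("sm_", nm, l)]] <- glorot(ds, ds)
    for (nm in c("bq", "bk", "bv", "bo"))
      P[[paste0("sm_", nm, l)]] <- zeros(1, ds)
    P[[paste0("sm_W1", l)]] <- glorot(ds, 2L * ds)
    P[[paste0("sm_b1", l)]] <- zeros(1, 2L * ds)
    P[[paste0("sm_W2", l)]] <- glorot(2L * ds, ds)
    P[[paste0("sm_b2", l)]] <- zeros(1, ds)
  }
  P$smiles_out_W <- glorot(ds, dh); P$smiles_out_b <- zeros(1, dh)
  P$g_in_W <- glorot(dims$atom_dim, dg); P$g_in_b <- zeros(1, dg)
  for (l in seq_len(cfg$graph_layers)) {
    P[[paste0("g_W", l)]] <- glorot(2L * dg, dg)
    P[[paste0("g_b", l)]] <- zeros(1, dg)
  }
  P$g_pool_W <- glorot(2L * dg, dh); P$g_pool_b <- zeros(1, dh)
  P$gene_table <- glorot(max(dims$n_genes, 1L), cfg$gene_dim)
  P$target_W <- glorot(cfg$gene_dim, dh); P$target_b <- zeros(1, dh)
  P$cell_W <- glorot(cfg$gene_dim, dh); P$cell_b <- zeros(1, dh)
  P$g3d_W <- glorot(dims$d3_in, dh); P$g3d_b <- zeros(1, dh)
  P$text_W <- glorot(dims$dtext_in, dh); P$text_b <- zeros(1, dh)
  P$onto_W <- glorot(dims$donto_in, dh); P$onto_b <- zeros(1, dh)
  P$sides_W <- glorot(SIDE_EFFECT_LEN, dh); P$sides_b <- zeros(1, dh)
  P$sens_W <- glorot(SENSITIVITY_LEN, dh); P$sens_b <- zeros(1, dh)
  if (task == "ddi") {
    P$aug_W <- glorot(2L * dh, 2L * dh); P$aug_b <- zeros(1, 2L * dh)
    P$type_emb <- glorot(max(dims$n_types, 1L), dh)
    P$ddi_wc <- glorot(3L * dh, dh)
    P$ddi_wz <- glorot(2L * dh, dh)
  } else {
    P$aug_W <- glorot(3L * dh, 2L * dh); P$aug_b <- zeros(1, 2L * dh)
    P$head_W1 <- glorot(2L * dh, dh); P$head_b1 <- zeros(1, dh)
    P$head_w2 <- glorot(dh, 1L); P$head_b2 <- zeros(1, 1L)
  }
  # zero-initialized affine weights: at step 0 the aggregate is exactly the
  # mean of the retained top-k predictions
  P$w_nll <- zeros(64L, 1L)
  P
}

push_params <- function(tp, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ad_leaf(tp, params[[nm]])
  out
}

# row-normalized adjacency used as the message operator (rows with no
# neighbors stay zero: such atoms receive no messages)
message_operator <- function(graph) {
  A <- graph_adjacency_matrix(graph)
  rs <- rowSums(A)
  rs[rs == 0] <- 1
  A / rs
}

#' Initialize a drug-pair view model
#'
#' Assembles everything the forward pass needs: the frozen SMILES token
#' vocabulary and atom-feature scheme (built from the supplied drug table),
#' the shared learnable gene-embedding table over the union of PPI nodes,
#' target genes and expression genes, fixed ontology embeddings
#' (random-walk-with-restart + SVD over the ontology graph), per-drug
#' static features for every available modality, and freshly initialized
#' parameters (seeded from the configuration).
#'
#' @param drugs Named list of `drug_record`s (see [read_drug_table()]).
#' @param cfg A [run_config()].
#' @param task `"synergy"` (binary classification), `"xenograft"`
#'   (regression, optional time embedding) or `"ddi"` (typed binary
#'   classification with a bilinear head).
#' @param ppi Optional `ppi_network` for target expansion and context
#'   gene sets.
#' @param ontology Optional ontology graph (`ppi_network` container) for
#'   the ontology modality.
#' @param expr Optional expression matrix (genes x contexts) from
#'   [read_expression_matrix()]; used to enlarge the gene vocabulary.
#' @param type_ids Character vector of interaction types (DDI task only).
#' @param phi2d Optional alignment-trained 2D encoder from [align_2d3d()];
#'   supplies the 3D-view representation for drugs without a precomputed
#'   3D embedding payload.
#' @return A `pairviews_model`.
#' @export
pairviews_model <- function(drugs, cfg, task = c("synergy", "xenograft",
                                                 "ddi"),
                            ppi = NULL, ontology = NULL, expr = NULL,
                            type_ids = NULL, phi2d = NULL) {
  task <- match.arg(task)
  drugs <- derive_graph_payloads(drugs)
  vocab <- smiles_vocab(vapply(drugs, function(d)
    d$payloads$SMILES, character(1)))
  elems <- csort(unique(unlist(lapply(drugs, function(d)
    if (is.null(d$payloads$GRAPH_2D)) character(0)
    else d$payloads$GRAPH_2D$atoms$element))))
  if (length(elems) == 0L) elems <- ORGANIC_ELEMENTS
  gene_ids <- csort(unique(c(
    if (!is.null(ppi)) ppi$nodes else character(0),
    unlist(lapply(drugs, function(d) d$payloads$TARGET)),
    if (!is.null(expr)) rownames(expr) else character(0))))
  onto_tab <- NULL
  if (!is.null(ontology)) {
    onto_tab <- ontology_embeddings(
      ontology, dim = min(cfg$onto_dim, length(ontology$nodes)),
      alpha = cfg$rwr_alpha, tol = cfg$rwr_tol,
      max_iter = cfg$rwr_max_iter)
  }
  d3_in <- NULL; dtext_in <- NULL
  for (d in drugs) {
    if (is.null(d3_in) && !is.null(d$payloads$GEOM_3D))
      d3_in <- length(d$payloads$GEOM_3D)
    if (is.null(dtext_in) && is.numeric(d$payloads$TEXT))
      dtext_in <- length(d$payloads$TEXT)
  }
  if (is.null(d3_in)) d3_in <- if (!is.null(phi2d)) phi2d$out_dim else 8L
  if (is.null(dtext_in)) dtext_in <- cfg$text_dim
  dims <- list(vocab_size = length(vocab),
               atom_dim = length(elems) + 1L + 7L + 5L + 1L,
               n_genes = length(gene_ids),
               d3_in = d3_in, dtext_in = dtext_in,
               donto_in = if (is.null(onto_tab)) 1L else onto_tab$dim,
               n_types = length(type_ids))
  set.seed(cfg$seed)
  params <- init_params(cfg, dims, task)
  adj <- if (!is.null(ppi)) ppi_adjacency(ppi) else NULL
  static <- lapply(drugs, function(d) {
    s <- list()
    s$tok_ids <- NULL
    if (!is.null(d$payloads$SMILES)) {
      tk <- tokenize_smiles(d$payloads$SMILES)
      if (length(tk) > cfg$max_smiles_len) {
        warning("SMILES for '", d$drug_id, "' truncated to ",
                cfg$max_smiles_len, " tokens")
        tk <- c(tk[seq_len(cfg$max_smiles_len - 1L)], CLS_TOKEN)
      }
      s$tok_ids <- token_ids(tk, vocab)
    }
    if (!is.null(d$payloads$GRAPH_2D)) {
      s$atom_feat <- atom_features(d$payloads$GRAPH_2D, elems)
      s$msg_op <- message_operator(d$payloads$GRAPH_2D)
    }
    if (!is.null(d$payloads$TARGET)) {
      tg <- d$payloads$TARGET
      if (!is.null(adj)) tg <- expand_target_genes(tg, adj, cfg$k_g)
      idx <- match(tg, gene_ids)
      s$target_idx <- idx[!is.na(idx)]
      if (length(s$target_idx) == 0L) s$target_idx <- NULL
    }
    if (!is.null(d$payloads$GEOM_3D)) {
      s$v3 <- as.numeric(d$payloads$GEOM_3D)
    } else if (!is.null(phi2d) && !is.null(d$payloads$GRAPH_2D)) {
      s$v3 <- phi2d_encode(phi2d, d$payloads$GRAPH_2D, elems)
    }
    if (!is.null(d$payloads$TEXT)) {
      s$vtext <- if (is.numeric(d$payloads$TEXT)) as.numeric(d$payloads$TEXT)
                 else hash_text_features(d$payloads$TEXT, cfg$text_dim)
    }
    if (!is.null(d$payloads$ONTOLOGY) && !is.null(onto_tab) &&
        d$payloads$ONTOLOGY %in% rownames(onto_tab$embeddings)) {
      s$vonto <- as.numeric(onto_tab$embeddings[d$payloads$ONTOLOGY, ])
    }
    s$sides <- d$payloads$SIDE_EFFECTS
    s$sens <- d$payloads$SENSITIVITY
    avail <- c(
      SMILES = !is.null(s$tok_ids), GRAPH_2D = !is.null(s$atom_feat),
      TARGET = !is.null(s$target_idx), GEOM_3D = !is.null(s$v3),
      TEXT = !is.null(s$vtext), ONTOLOGY = !is.null(s$vonto),
      SIDE_EFFECTS = !is.null(s$sides), SENSITIVITY = !is.null(s$sens))
    s$avail <- names(avail)[avail]
    s
  })
  names(static) <- names(drugs)
  structure(list(cfg = cfg, task = task, params = params,
                 vocab = vocab, element_vocab = elems,
                 gene_ids = gene_ids, onto_table = onto_tab,
                 type_ids = type_ids, static = static,
                 drug_ids = names(drugs),
                 plan_cache = new.env(parent = emptyenv())),
            class = "pairviews_model")
}

#' @export
print.pairviews_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("<pairviews_model> task=", x$task, ", ", length(x$drug_ids),
      " drugs, dhid=", x$cfg$dhid, ", ", np, " parameters (config ",
      config_hash(x$cfg), ")\n", sep = "")
  invisible(x)
}

#' Modalities available for a drug under a model
#' @param model A `pairviews_model`.
#' @param drug_id Drug id present in the model's drug table.
#' @return Character vector of modality ids in canonical order.
#' @export
model_availability <- function(model, drug_id) {
  s <- model$static[[drug_id]]
  if (is.null(s)) stop("unknown drug: '", drug_id, "'")
  intersect(modality_ids(), s$avail)
}

# ---- exported single-input encoder wrappers -----------------------------

#' Encode a SMILES string
#'
#' Tokenizes, runs the transformer encoder, and returns the transformed
#' `[CLS]` embedding.  Deterministic in evaluation mode.
#'
#' @param smiles SMILES string.
#' @param model A `pairviews_model`.
#' @return Numeric vector of length `dhid`.
#' @export
encode_smiles <- function(smiles, model) {
  tk <- tokenize_smiles(smiles)
  if (length(tk) > model$cfg$max_smiles_len) {
    warning("SMILES truncated to ", model$cfg$max_smiles_len, " tokens")
    tk <- c(tk[seq_len(model$cfg$max_smiles_len - 1L)], CLS_TOKEN)
  }
  ids <- token_ids(tk, model$vocab)
  tp <- ad_tape(2048L)
  P <- push_params(tp, model$params)
  out <- tape_encode_smiles(tp, P, model$cfg, ids)
  as.numeric(ad_value(tp, out))
}

#' Encode a molecular graph
#'
#' Residual message passing over the atom graph followed by the
#' concatenated mean/max pooling and one transformation layer.  Exactly
#' permutation invariant.
#'
#' @param graph A `mol_graph` (see [smiles_to_graph()]).
#' @param model A `pairviews_model`.
#' @return Numeric vector of length `dhid`.
#' @export
encode_graph <- function(graph, model) {
  if (nrow(graph$atoms) == 0L) stop("empty molecular graph")
  feat <- atom_features(graph, model$element_vocab)
  tp <- ad_tape(2048L)
  P <- push_params(tp, model$params)
  out <- tape_encode_graph(tp, P, model$cfg, feat, message_operator(graph))
  as.numeric(ad_value(tp, out))
}

#' Encode the 3D-augmented view of a drug
#'
#' Applies the 3D transformation layer to the drug's 3D-view
#' representation: a precomputed embedding payload if present, otherwise
#' the output of an alignment-trained 2D encoder.  If neither is
#' available the modality is reported absent (`NULL`), not an error.
#'
#' @param drug_id Drug id in the model.
#' @param model A `pairviews_model`.
#' @return Numeric vector of length `dhid`, or `NULL` if the modality is
#'   absent.
#' @export
encode_3d <- function(drug_id, model) {
  s <- model$static[[drug_id]]
  if (is.null(s)) stop("unknown drug: '", drug_id, "'")
  if (is.null(s$v3)) return(NULL)
  tp <- ad_tape()
  P <- push_params(tp, model$params)
  out <- tape_encode_fixed(tp, P, s$v3, P$g3d_W, P$g3d_b)
  as.numeric(ad_value(tp, out))
}

#' Encode the text modality of a drug
#'
#' Applies the text transformation layer to the fixed (non-trained) text
#' representation: a precomputed description embedding, or the hashed
#' bag-of-tokens fallback for raw description strings.
#'
#' @param drug_id Drug id in the model.
#' @param model A `pairviews_model`.
#' @return Numeric vector of length `dhid`, or `NULL` if absent.
#' @export
encode_text <- function(drug_id, model) {
  s <- model$static[[drug_id]]
  if (is.null(s)) stop("unknown drug: '", drug_id, "'")
  if (is.null(s$vtext)) return(NULL)
  tp <- ad_tape()
  P <- push_params(tp, model$params)
  out <- tape_encode_fixed(tp, P, s$vtext, P$text_W, P$text_b)
  as.numeric(ad_value(tp, out))
}

# ---- batched drug embeddings on the tape --------------------------------

# Returns, for each modality, a node whose rows are embeddings for the
# drugs (among `drug_ids`) that have the modality, plus an index map
# drug_id -> row.  Loop encoders (SMILES, graph) run per drug; fixed-width
# modalities run as a single stacked matmul.
tape_drug_embeddings <- function(tp, P, model, drug_ids) {
  cfg <- model$cfg
  st <- model$static[drug_ids]
  out <- list()
  # SMILES + graph: all drugs batched through one tape subgraph
  has <- drug_ids[vapply(st, function(s) "SMILES" %in% s$avail, TRUE)]
  if (length(has)) {
    node <- tape_encode_smiles_batch(
      tp, P, cfg, lapply(model$static[has], `[[`, "tok_ids"))
    out$SMILES <- list(node = node,
                       index = stats::setNames(seq_along(has), has))
  }
  has <- drug_ids[vapply(st, function(s) "GRAPH_2D" %in% s$avail, TRUE)]
  if (length(has)) {
    node <- tape_encode_graph_batch(
      tp, P, cfg, lapply(model$static[has], `[[`, "atom_feat"),
      lapply(model$static[has], `[[`, "msg_op"))
    out$GRAPH_2D <- list(node = node,
                         index = stats::setNames(seq_along(has), has))
  }
  # target gene sets: per-drug pooling then stack
  has <- drug_ids[vapply(st, function(s) "TARGET" %in% s$avail, TRUE)]
  if (length(has)) {
    rows <- lapply(has, function(id)
      tape_encode_gene_set(tp, P, cfg, model$static[[id]]$target_idx,
                           "target"))
    node <- if (length(rows) == 1L) rows[[1]] else ad_rbind_rows(tp, rows)
    out$TARGET <- list(node = node,
                       index = stats::setNames(seq_along(has), has))
  }
  # fixed-vector modalities: one stacked linear map each
  fixed <- list(GEOM_3D = list(f = "v3", W = "g3d_W", b = "g3d_b"),
                TEXT = list(f = "vtext", W = "text_W", b = "text_b"),
                ONTOLOGY = list(f = "vonto", W = "onto_W", b = "onto_b"),
                SIDE_EFFECTS = list(f = "sides", W = "sides_W",
                                    b = "sides_b"),
                SENSITIVITY = list(f = "sens", W = "sens_W", b = "sens_b"))
  for (m in names(fixed)) {
    has <- drug_ids[vapply(st, function(s) m %in% s$avail, TRUE)]
    if (!length(has)) next
    V <- do.call(rbind, lapply(has, function(id)
      as.numeric(model$static[[id]][[fixed[[m]]$f]])))
    node <- tape_linear(tp, ad_leaf(tp, V),
                        P[[fixed[[m]]$W]], P[[fixed[[m]]$b]])
    out[[m]] <- list(node = node,
                     index = stats::setNames(seq_along(has), has))
  }
  out
}
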