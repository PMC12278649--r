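# SMILES tokenization and a small molecular-graph parser.
#
# The token grammar is closed: bracket atoms are single tokens, the
# two-character elements Cl/Br are kept whole, ring-closure digits and bond
# symbols are their own tokens, and anything else maps to UNK.  The graph
# parser covers linear/branched/ring molecules over the organic subset
# (B, C, N, O, P, S, F, Cl, Br, I and their aromatic forms), which is what
# the synthetic fixture grammar emits; arbitrary real-world SMILES beyond
# that subset should be converted upstream with a chemistry toolkit.

SMILES_TOKEN_RE <- paste0(
  "\\[[^\\]]+\\]|Cl|Br|Si|Se|@@|",
  "[BCNOPSFIbcnops]|%[0-9]{2}|[0-9]|[=#$:/\\\\.+\\-()@]")

CLS_TOKEN <- "[CLS]"
UNK_TOKEN <- "[UNK]"

#' Tokenize a SMILES string
#'
#' Splits a SMILES string on a fixed regular-expression grammar
#' (multi-character elements such as `Cl`/`Br` stay whole, bracket atoms are
#' single tokens, ring digits and bond symbols are individual tokens) and
#' appends the special `[CLS]` token whose contextual embedding represents
#' the whole molecule.  Characters outside the grammar become `[UNK]`.
#'
#' @param smiles Nonempty SMILES string.
#' @return Character vector of tokens ending in `[CLS]`.
#' @export
#' @examples
#' tokenize_smiles("CCO")
#' tokenize_smiles("CCl")
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a nonempty string")
  m <- gregexpr(SMILES_TOKEN_RE, smiles, perl = TRUE)[[1]]
  toks <- regmatches(smiles, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (covered < nchar(smiles)) {
    # mark unmatched characters as UNK in position order
    pos <- rep(FALSE, nchar(smiles))
    for (i in seq_along(toks))
      pos[m[i]:(m[i] + attr(m, "match.length")[i] - 1L)] <- TRUE
    full <- character(0)
    i <- 1L; ti <- 1L
    while (i <= nchar(smiles)) {
      if (pos[i]) {
        full <- c(full, toks[ti])
        i <- i + nchar(toks[ti]); ti <- ti + 1L
      } else {
        full <- c(full, UNK_TOKEN)
        i <- i + 1L
      }
    }
    toks <- full
  }
  c(toks, CLS_TOKEN)
}

#' Build a frozen SMILES token vocabulary
#'
#' The vocabulary is frozen at training time from the training drug table
#' plus the special tokens; tokens unseen at prediction time map to
#' `[UNK]`.
#'
#' @param smiles_strings Character vector of training SMILES.
#' @return Character vector: `[CLS]`, `[UNK]`, then sorted observed tokens.
#' @export
smiles_vocab <- function(smiles_strings) {
  toks <- unique(unlist(lapply(smiles_strings, tokenize_smiles)))
  c(CLS_TOKEN, UNK_TOKEN, csort(setdiff(toks, c(CLS_TOKEN, UNK_TOKEN))))
}

token_ids <- function(tokens, vocab) {
  idx <- match(tokens, vocab)
  idx[is.na(idx)] <- match(UNK_TOKEN, vocab)
  idx
}

# ---- SMILES -> molecular graph ------------------------------------------

ORGANIC_ELEMENTS <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic element subset, aromatic lowercase forms, branches,
#' ring closures (single digits and `%nn`), explicit bond orders (`-`, `=`,
#' `#`) and bracket atoms with charges.  Returns atoms with element,
#' aromatic flag and formal charge, plus a bond list with orders.
#'
#' @param smiles SMILES string.
#' @return A `mol_graph`: list with `atoms` (data.frame `element`,
#'   `aromatic`, `charge`) and `bonds` (data.frame `i`, `j`, `order`).
#' @export
#' @examples
#' g <- smiles_to_graph("c1ccccc1")
#' nrow(g$atoms)  # 6 aromatic carbons
smiles_to_graph <- function(smiles) {
  toks <- tokenize_smiles(smiles)
  toks <- toks[toks != CLS_TOKEN]
  element <- character(0); aromatic <- logical(0); charge <- integer(0)
  bi <- integer(0); bj <- integer(0); border <- numeric(0)
  prev <- NA_integer_
  stack <- integer(0)
  rings <- list()        # ring digit -> c(atom, order)
  pend_order <- NA_real_
  add_atom <- function(el, arom, ch) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    charge <<- c(charge, ch)
    length(element)
  }
  add_bond <- function(a, b, ord) {
    bi <<- c(bi, a); bj <<- c(bj, b); border <<- c(border, ord)
  }
  for (tk in toks) {
    if (tk %in% ORGANIC_ELEMENTS || tk %in% tolower(c("b", "c", "n", "o",
                                                      "p", "s"))) {
      arom <- tk %in% c("b", "c", "n", "o", "p", "s")
      el <- if (arom) toupper(tk) else tk
      a <- add_atom(el, arom, 0L)
      if (!is.na(prev)) {
        ord <- if (!is.na(pend_order)) pend_order
               else if (arom && aromatic[prev]) 1.5 else 1
        add_bond(prev, a, ord)
      }
      prev <- a; pend_order <- NA_real_
    } else if (grepl("^\\[", tk)) {
      inner <- sub("^\\[", "", sub("\\]$", "", tk))
      ch <- 0L
      chm <- regmatches(inner, regexpr("[+-]+[0-9]*$", inner))
      if (length(chm) && nzchar(chm)) {
        sign <- if (substr(chm, 1, 1) == "+") 1L else -1L
        num <- sub("^[+-]+", "", chm)
        ch <- if (nzchar(num)) sign * as.integer(num)
              else sign * nchar(gsub("[0-9]", "", chm))
        inner <- sub("[+-]+[0-9]*$", "", inner)
      }
      inner <- gsub("H[0-9]*$", "", inner)   # drop explicit hydrogen counts
      arom <- inner %in% c("b", "c", "n", "o", "p", "s")
      el <- if (arom) toupper(inner) else inner
      a <- add_atom(el, arom, ch)
      if (!is.na(prev)) {
        ord <- if (!is.na(pend_order)) pend_order
               else if (arom && aromatic[prev]) 1.5 else 1
        add_bond(prev, a, ord)
      }
      prev <- a; pend_order <- NA_real_
    } else if (tk == "(") {
      stack <- c(stack, prev)
    } else if (tk == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES '", smiles, "'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (tk %in% c("-", "=", "#", ":")) {
      pend_order <- switch(tk, "-" = 1, "=" = 2, "#" = 3, ":" = 1.5)
    } else if (grepl("^[0-9]$", tk) || grepl("^%[0-9]{2}$", tk)) {
      key <- sub("^%", "", tk)
      if (is.null(rings[[key]])) {
        rings[[key]] <- c(prev, if (is.na(pend_order)) NA else pend_order)
        pend_order <- NA_real_
      } else {
        open <- rings[[key]]
        ord <- if (!is.na(pend_order)) pend_order
               else if (!is.na(open[2])) open[2]
               else if (aromatic[open[1]] && aromatic[prev]) 1.5 else 1
        add_bond(open[1], prev, ord)
        rings[[key]] <- NULL
        pend_order <- NA_real_
      }
    } else if (tk == ".") {
      prev <- NA_integer_
    }
    # stereo marks (/ \ @ @@) carry no graph information here; skipped
  }
  if (length(element) == 0L)
    stop("SMILES '", smiles, "' contains no atoms")
  structure(list(
    atoms = data.frame(element = element, aromatic = aromatic,
                       charge = charge, stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj, order = border)),
    class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", nrow(x$atoms), " atoms, ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

#' Derive 2D-graph payloads from SMILES
#'
#' Adds a `GRAPH_2D` payload (parsed molecular graph) to every drug record
#' that has a SMILES payload but no graph yet.  Drugs whose SMILES cannot
#' be parsed keep the modality absent (with a message).
#'
#' @param drugs Named list of `drug_record`s.
#' @return The updated list.
#' @export
derive_graph_payloads <- function(drugs) {
  for (id in names(drugs)) {
    d <- drugs[[id]]
    if (!is.null(d$payloads$GRAPH_2D) || is.null(d$payloads$SMILES)) next
    g <- tryCatch(smiles_to_graph(d$payloads$SMILES), error = function(e) NULL)
    if (is.null(g)) {
      message("derive_graph_payloads: could not parse SMILES for '", id, "'")
      next
    }
    d$payloads$GRAPH_2D <- g
    drugs[[id]] <- d
  }
  drugs
}

# Atom feature matrix: element one-hot (over a frozen element vocabulary
# + other), degree 0-6, formal charge -2..+2, aromatic flag.
atom_features <- function(graph, element_vocab = ORGANIC_ELEMENTS) {
  n <- nrow(graph$atoms)
  deg <- integer(n)
  if (nrow(graph$bonds)) {
    tb <- table(factor(c(graph$bonds$i, graph$bonds$j), levels = seq_len(n)))
    deg <- as.integer(tb)
  }
  deg <- pmin(deg, 6L)
  el <- match(graph$atoms$element, element_vocab)
  el[is.na(el)] <- length(element_vocab) + 1L
  ch <- pmin(pmax(graph$atoms$charge, -2L), 2L) + 3L
  n_el <- length(element_vocab) + 1L
  F <- matrix(0, n, n_el + 7L + 5L + 1L)
  F[cbind(seq_len(n), el)] <- 1
  F[cbind(seq_len(n), n_el + deg + 1L)] <- 1
  F[cbind(seq_len(n), n_el + 7L + ch)] <- 1
  F[, n_el + 7L + 5L + 1L] <- as.numeric(graph$atoms$aromatic)
  F
}

graph_adjacency_matrix <- function(graph) {
  n <- nrow(graph$atoms)
  A <- matrix(0, n, n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      A[graph$bonds$i[k], graph$bonds$j[k]] <- 1
      A[graph$bonds$j[k], graph$bonds$i[k]] <- 1
    }
  }
  A
}
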