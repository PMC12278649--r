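# Shared tiny fixtures, built in code.

tiny_bundle <- function(seed = 3L, n_drugs = 8L, n_contexts = 4L,
                        n_genes = 20L) {
  suppressWarnings(gen_fixture_bundle(
    fixture_spec(n_drugs = n_drugs, n_contexts = n_contexts,
                 n_genes = n_genes, seed = seed)))
}

tiny_config <- function(seed = 7L, steps = 10L, ...) {
  run_config(dhid = 16L, smiles_dim = 16L, smiles_layers = 1L,
             graph_dim = 16L, graph_layers = 1L, gene_dim = 16L,
             text_dim = 16L, onto_dim = 4L, batch_size = 16L,
             steps = steps, warmup_steps = 2L, lr = 1e-3,
             dropout = 0.1, seed = seed, ...)
}

tiny_model <- function(bundle, cfg = tiny_config(), task = "synergy",
                       ...) {
  suppressWarnings(pairviews_model(bundle$drugs, cfg, task,
                                   ppi = bundle$ppi,
                                   ontology = bundle$ontology,
                                   expr = bundle$expr, ...))
}

# a tiny edge-list file written on the fly
write_tmp_edges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
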