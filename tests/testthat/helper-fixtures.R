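# Small shared simulation bundle, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    cfg <- dretarget::simulate_config(
      n_chromosomes = 3, chrom_length = 2e6, n_genes = 30, n_dhs = 200,
      go_modules = 5, seed = 42)
    .fixture_env$bundle <- dretarget::simulate_dataset(cfg)
  }
  .fixture_env$bundle
}

small_run <- function() {
  if (is.null(.fixture_env$run)) {
    .fixture_env$run <- dretarget::run_dre_pipeline(small_bundle())
  }
  .fixture_env$run
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# tiny four-gene GO corpus: root -> a -> {b, c}; g1 in b, g2 in c,
# g3/g4 only at the root
toy_corpus <- function(min_genes = 1) {
  terms <- tibble::tibble(
    term = c("root", "a", "b", "c"),
    name = c("root", "mid", "leaf b", "leaf c"),
    namespace = "biological_process",
    parents = list(character(0), "root", "a", "a"),
    obsolete = FALSE)
  ann <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    term = c("b", "c", "root", "root"),
    evidence = "EXP")
  dretarget::build_go_corpus(terms, ann, min_genes = min_genes)
}
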