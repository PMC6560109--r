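# One default synthetic bundle, generated once per test run and shared by the
# classification-closure, ranking and pipeline tests.
.bundle_cache <- new.env(parent = emptyenv())

default_bundle_dir <- function() {
  if (is.null(.bundle_cache$dir)) {
    dir <- file.path(tempdir(), "sncatalog_default_bundle")
    withr::with_options(list(sncatalog.quiet = TRUE), {
      simulate_bundle(simulation_config(seed = 20190611L), dir)
    })
    .bundle_cache$dir <- dir
  }
  .bundle_cache$dir
}

default_verify <- function() {
  if (is.null(.bundle_cache$verify)) {
    withr::with_options(list(sncatalog.quiet = TRUE), {
      .bundle_cache$verify <- verify_bundle(default_bundle_dir())
    })
  }
  .bundle_cache$verify
}

default_gene_stats <- function() {
  if (is.null(.bundle_cache$stats)) {
    v <- default_verify()
    models <- read_gene_models(file.path(default_bundle_dir(), "genes.gff3"),
                               file.path(default_bundle_dir(), "genome.fa"))
    .bundle_cache$stats <- aggregate_gene_stats(v$classified, models,
                                                v$consequences)
  }
  .bundle_cache$stats
}

read_truth <- function(name) {
  read.delim(file.path(default_bundle_dir(), name), na.strings = ".",
             stringsAsFactors = FALSE)
}

quiet <- function(expr) {
  withr::with_options(list(sncatalog.quiet = TRUE), expr)
}
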