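# The default-cohort pipeline runs are shared across acceptance tests; they
# are computed once per test session and cached here.
.cohort_cache <- new.env(parent = emptyenv())

default_cohort_run <- function(which = c("a", "b")) {
  which <- match.arg(which)
  key <- paste0("run_", which)
  if (is.null(.cohort_cache[[key]])) {
    out <- file.path(tempdir(), paste0("eosmap_default_run_", which))
    unlink(out, recursive = TRUE)
    cfg <- run_config(out, seed = 20L)
    .cohort_cache[[key]] <- run_pipeline(cfg)
  }
  .cohort_cache[[key]]
}
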