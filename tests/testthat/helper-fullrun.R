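# Memoized full-scale synthetic pipeline run (catalog proportions of the
# curated maize reference), shared by the acceptance tests.
.full_run_cache <- new.env(parent = emptyenv())

full_synth_bundle <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.full_run_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("lrrminer-full-", seed))
    cfg <- pipeline_config(out_dir = dir, seed = seed,
                           simulate = simulation_config(seed = seed),
                           bootstrap_replicates = 100)
    .full_run_cache[[key]] <- suppressMessages(run_pipeline(cfg))
  }
  .full_run_cache[[key]]
}
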