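# the default-configuration pipeline chain, run once (via the CLI surface)
# and shared across tests that interrogate its outputs

.pipeline_cache <- new.env(parent = emptyenv())

default_chain <- function() {
  if (!is.null(.pipeline_cache$dir)) return(.pipeline_cache)
  d <- file.path(tempdir(), "partpgs_chain")
  unlink(d, recursive = TRUE)
  t0 <- Sys.time()
  statuses <- vapply(
    c("simulate", "zmatrix", "cluster", "coloc", "enrich", "pgs",
      "survive", "scan", "report"),
    function(s) suppressMessages(suppressWarnings(
      run_cli(c(s, "--outdir", d, "--seed", "1")))),
    integer(1))
  .pipeline_cache$dir <- d
  .pipeline_cache$statuses <- statuses
  .pipeline_cache$elapsed_s <- as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs"))
  .pipeline_cache
}
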