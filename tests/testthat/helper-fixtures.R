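## Shared fixtures, computed lazily and cached for the whole test session.

## A small planted genome exercising every event type quickly.
tiny_sim_config <- function(seed = 101) {
  sim_config(
    n_chroms = 2L, chrom_len = 3e5,
    full_by_subfamily = c(GGERV10A = 2L, GGERV10B = 2L, GGERV10C1 = 1L,
                          GGERV10C2 = 2L, GGERV10D = 2L),
    solo_by_subfamily = c(GGERV10A = 3L, GGERV10B = 3L, GGERV10C1 = 2L,
                          GGERV10C2 = 2L, GGERV10D = 2L),
    truncated_by_subfamily = c(GGERV10A = 1L, GGERV10B = 1L, GGERV10C1 = 1L,
                               GGERV10C2 = 1L, GGERV10D = 1L),
    gag_state_counts = c(intact = 5L, frameshifted = 2L, pbs_deficient = 1L,
                         absent = 1L),
    gene_rate_per_mb = 20, gene_len_meanlog = log(8000),
    seed = seed
  )
}

tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ervscan_tiny_sim")
      cache <<- simulate_genome(tiny_sim_config(), out_dir = dir)
    }
    cache
  }
})

## The default-scale study-condition run (planted 49/483/61), shared by the
## acceptance blocks.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "ervscan_default_sim")
      sim <- simulate_genome(sim_config(seed = 20210124L), out_dir = dir)
      cfg <- pipeline_config_from_sim(sim$paths,
                                      out_dir = file.path(dir, "out"),
                                      n_boot = 25, seed = 7, verbose = FALSE)
      res <- suppressWarnings(run_pipeline(cfg))
      cache <<- list(sim = sim, res = res)
    }
    cache
  }
})

consensus_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_consensus_set(2024)
    cache
  }
})

## Handcrafted repeat-hit rows for locus-builder unit tests.
make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      chrom = r$chrom %||% "chr1", start = r$start, end = r$end,
      strand = r$strand %||% "+", repeat_name = r$name,
      repeat_class = "LTR/ERVL", cons_start = 1L,
      cons_end = r$end - r$start, divergence_pct = 1,
      linkage_id = as.character(r$id), stringsAsFactors = FALSE
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
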