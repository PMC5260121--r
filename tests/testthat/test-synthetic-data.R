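test_that("consensus set has the published lengths, motifs and A-block", {
  cons <- consensus_fixture()
  expect_equal(unname(nchar(cons$ltr)),
               c(295L, 382L, 329L, 336L, 332L))
  for (s in cons$ltr) {
    tir <- check_tir(s)
    expect_true(tir$starts_tgttg && tir$ends_caaca)
  }
  ## the 24-nt duplication: twice in the A-like consensus, at most once
  ## elsewhere
  n_hits <- vapply(cons$ltr, function(s)
    length(gregexpr(ervscan:::DUP24, s, fixed = TRUE)[[1]]), integer(1))
  expect_equal(unname(n_hits[["GGERV10A"]]), 2L)
  expect_true(all(n_hits[names(n_hits) != "GGERV10A"] <= 1))
})

test_that("consensus construction is deterministic in the seed", {
  a <- make_consensus_set(5)
  b <- make_consensus_set(5)
  c <- make_consensus_set(6)
  expect_identical(a$ltr, b$ltr)
  expect_identical(a$internal, b$internal)
  expect_false(identical(a$ltr, c$ltr))
})

test_that("consensuses are mutually diverged by at least 5%", {
  cons <- consensus_fixture()$ltr
  pairs <- utils::combn(names(cons), 2)
  for (i in seq_len(ncol(pairs))) {
    d <- ervscan:::consensus_distance(cons[[pairs[1, i]]],
                                      cons[[pairs[2, i]]])
    expect_gte(d, 0.05)
  }
})

test_that("LTR pairs evolve with the Poisson expectation", {
  cons <- consensus_fixture()$ltr[["GGERV10B"]]  # 382 nt
  pr0 <- evolve_ltr_pair(cons, age_myr = 0, mu = 0.0019)
  expect_identical(pr0$ltr5, pr0$ltr3)
  set.seed(81)
  mu <- 0.0019; age <- 3.7; len <- nchar(cons)
  diffs <- replicate(1000, {
    pr <- evolve_ltr_pair(cons, age, mu)
    ervscan:::hamming(pr$ltr5, pr$ltr3)
  })
  expected <- 2 * mu * age * len  # ~5.4 differing sites
  expect_lt(abs(mean(diffs) - expected) / expected, 0.10)
})

test_that("K2P on evolved pairs is consistent with 2*mu*age", {
  cons <- consensus_fixture()$ltr[["GGERV10C2"]]
  set.seed(82)
  mu <- 0.0019; age <- 3.7
  ds <- replicate(500, {
    pr <- evolve_ltr_pair(cons, age, mu)
    k2p_distance(pr$ltr5, pr$ltr3)$d
  })
  expect_lt(abs(mean(ds) - 2 * mu * age) / (2 * mu * age), 0.10)
})

test_that("truth records and annotation rows are mutually consistent", {
  sim <- tiny_sim()
  expect_equal(sort(unique(sim$hits$linkage_id)),
               sort(as.character(seq_len(nrow(sim$truth)))))
  ## every truth record spans exactly its component hits
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    rows <- sim$hits[sim$hits$chrom == tr$chrom & sim$hits$start >= tr$start &
                       sim$hits$end <= tr$end, ]
    expect_gte(nrow(rows), 1L)
    expect_equal(min(rows$start), tr$start)
    expect_equal(max(rows$end), tr$end)
    expect_equal(length(unique(rows$linkage_id)), 1L)
    n_expect <- switch(tr$type, full_length = 3L, solo_ltr = 1L,
                       truncated = 2L)
    expect_equal(nrow(rows), n_expect)
  }
  ## planted TSD flanks the element as a direct repeat
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    chromseq <- sim$genome[[tr$chrom]]
    left <- substr(chromseq, tr$start - tr$tsd_len + 1, tr$start)
    right <- substr(chromseq, tr$end + 1, tr$end + tr$tsd_len)
    expect_identical(left, tr$tsd_seq)
    expect_identical(right, tr$tsd_seq)
  }
})

test_that("background GC tracks the configured fraction", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 1e6,
                    full_by_subfamily = c(GGERV10A = 0L, GGERV10B = 1L,
                                          GGERV10C1 = 0L, GGERV10C2 = 0L,
                                          GGERV10D = 0L),
                    solo_by_subfamily = c(GGERV10A = 1L, GGERV10B = 0L,
                                          GGERV10C1 = 0L, GGERV10C2 = 0L,
                                          GGERV10D = 0L),
                    truncated_by_subfamily = c(GGERV10A = 0L, GGERV10B = 0L,
                                               GGERV10C1 = 0L,
                                               GGERV10C2 = 0L, GGERV10D = 0L),
                    gag_state_counts = c(intact = 1L, frameshifted = 0L,
                                         pbs_deficient = 0L, absent = 0L),
                    chimeras = list(), seed = 83)
  sim <- simulate_genome(cfg)
  gc <- ervscan:::gc_percent(sim$genome[[1]])
  expect_lt(abs(gc - 41), 0.5)
})

test_that("simulation output is byte-identical for a fixed seed", {
  cfg <- tiny_sim_config(seed = 84)
  d1 <- file.path(tempdir(), "sim_det1")
  d2 <- file.path(tempdir(), "sim_det2")
  s1 <- simulate_genome(cfg, out_dir = d1)
  s2 <- simulate_genome(cfg, out_dir = d2)
  expect_identical(readLines(file.path(d1, "truth.tsv")),
                   readLines(file.path(d2, "truth.tsv")))
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(s1$hits, s2$hits)
})

test_that("a zero-event configuration yields an empty locus list", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 2e5,
                    full_by_subfamily = c(GGERV10A = 0L, GGERV10B = 0L,
                                          GGERV10C1 = 0L, GGERV10C2 = 0L,
                                          GGERV10D = 0L),
                    solo_by_subfamily = c(GGERV10A = 0L, GGERV10B = 0L,
                                          GGERV10C1 = 0L, GGERV10C2 = 0L,
                                          GGERV10D = 0L),
                    truncated_by_subfamily = c(GGERV10A = 0L, GGERV10B = 0L,
                                               GGERV10C1 = 0L,
                                               GGERV10C2 = 0L, GGERV10D = 0L),
                    gag_state_counts = c(intact = 0L, frameshifted = 0L,
                                         pbs_deficient = 0L, absent = 0L),
                    chimeras = list(), seed = 85)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_length(assemble_loci(sim$hits), 0L)
})

test_that("an overcrowded genome fails loudly", {
  cfg <- sim_config(n_chroms = 1L, chrom_len = 6e4, edge_margin = 1000L,
                    seed = 86)
  expect_error(simulate_genome(cfg), "cannot place events")
})

test_that("the optional indel mode produces deletion-bearing LTR copies", {
  cfg <- tiny_sim_config(seed = 87)
  cfg$ltr_indel_prob <- 0.5
  sim <- simulate_genome(cfg)
  lens_by_sf <- split(nchar(stats::na.omit(sim$truth$ltr5_seq)),
                      sim$truth$subfamily[!is.na(sim$truth$ltr5_seq)])
  ## at least some copies are shorter than their consensus
  shorter <- vapply(names(lens_by_sf), function(sf)
    any(lens_by_sf[[sf]] < nchar(sim$consensuses$ltr[[sf]])), logical(1))
  expect_true(any(shorter))
})
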