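test_that("proviral role patterns classify as the expected locus classes", {
  ## full provirus: LTR - internal - LTR under one linkage id
  full <- assemble_loci(make_hits(
    list(start = 1000, end = 1300, name = "GGERV10B-LTR", id = 1),
    list(start = 1300, end = 3300, name = "GGERV10B-int", id = 1),
    list(start = 3300, end = 3600, name = "GGERV10B-LTR", id = 1)))
  expect_length(full, 1)
  expect_equal(full[[1]]$classification, "full_length")
  expect_equal(full[[1]]$components$role, c("LTR5", "INTERNAL", "LTR3"))

  ## lone LTR far from anything else
  solo <- assemble_loci(make_hits(
    list(start = 1000, end = 1300, name = "GGERV10C2-LTR", id = 1),
    list(start = 11300, end = 11600, name = "GGERV10C2-LTR", id = 2)))
  expect_length(solo, 2)
  expect_true(all(vapply(solo, function(l) l$classification, "") ==
                    "solo_ltr"))
  expect_equal(solo[[1]]$components$role, "LTR_SOLO")

  ## internal followed by one LTR: truncated
  trunc <- assemble_loci(make_hits(
    list(start = 1000, end = 2200, name = "GGERV10D-int", id = 1),
    list(start = 2200, end = 2500, name = "GGERV10D-LTR", id = 1)))
  expect_equal(trunc[[1]]$classification, "truncated")

  ## LTR sandwiched between internals is irregular -> truncated
  irr <- assemble_loci(make_hits(
    list(start = 1000, end = 1500, name = "GGERV10B-int", id = 1),
    list(start = 1500, end = 1800, name = "GGERV10B-LTR", id = 1),
    list(start = 1800, end = 2400, name = "GGERV10B-int", id = 1)))
  expect_true(irr[[1]]$irregular)
  expect_equal(irr[[1]]$classification, "truncated")

  ## two LTRs, internal deleted, close together: one truncated locus
  twoltr <- assemble_loci(make_hits(
    list(start = 1000, end = 1300, name = "GGERV10B-LTR", id = 1),
    list(start = 1400, end = 1700, name = "GGERV10B-LTR", id = 2)))
  expect_length(twoltr, 1)
  expect_equal(twoltr[[1]]$classification, "truncated")
})

test_that("distinct linkage ids merge only within the gap and same stem", {
  hits <- make_hits(
    list(start = 1000, end = 1300, name = "GGERV10B-LTR", id = 1),
    list(start = 1400, end = 3000, name = "GGERV10B-int", id = 2),
    list(start = 3100, end = 3400, name = "GGERV10B-LTR", id = 3))
  expect_length(assemble_loci(hits, max_gap_bp = 500), 1)
  expect_length(assemble_loci(hits, max_gap_bp = 50), 3)
  ## different stems never merge
  hits2 <- make_hits(
    list(start = 1000, end = 1300, name = "GGERV10B-LTR", id = 1),
    list(start = 1350, end = 1650, name = "GGERV10D-LTR", id = 2))
  expect_length(assemble_loci(hits2), 2)
})

test_that("every hit lands in exactly one locus, independent of row order", {
  sim <- tiny_sim()
  loci <- assemble_loci(sim$hits)
  n_comp <- sum(vapply(loci, function(l) nrow(l$components), integer(1)))
  expect_equal(n_comp, nrow(sim$hits))
  set.seed(4)
  shuffled <- sim$hits[sample(nrow(sim$hits)), ]
  loci2 <- assemble_loci(shuffled)
  t1 <- table(vapply(loci, function(l) l$classification, ""))
  t2 <- table(vapply(loci2, function(l) l$classification, ""))
  expect_equal(t1, t2)
})

test_that("simulated class counts are recovered exactly", {
  sim <- tiny_sim()
  loci <- assemble_loci(sim$hits)
  got <- table(vapply(loci, function(l) l$classification, ""))
  want <- table(sim$truth$type)
  expect_equal(as.vector(got[names(want)]), as.vector(want))
})

test_that("extract_ltrs returns planted sequences in element orientation", {
  sim <- tiny_sim()
  loci <- assemble_loci(sim$hits)
  tab <- loci_table(loci)
  truth <- sim$truth
  for (i in seq_along(loci)) {
    l <- loci[[i]]
    tr <- truth[truth$chrom == l$chrom & truth$start == l$start, ]
    expect_equal(nrow(tr), 1L)
    lt <- extract_ltrs(l, sim$genome)
    if (!is.na(tr$ltr5_seq)) expect_identical(lt$ltr5, tr$ltr5_seq)
    if (!is.na(tr$ltr3_seq) && tr$type == "full_length")
      expect_identical(lt$ltr3, tr$ltr3_seq)
  }
})

test_that("minus-strand loci are reverse-complemented on extraction", {
  ltr <- "TGTTGACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACAACA"
  genome <- c(chr1 = paste0(strrep("A", 50), revcomp(ltr), strrep("T", 50)))
  loci <- assemble_loci(make_hits(
    list(start = 50, end = 50 + nchar(ltr), name = "GGERV10B-LTR",
         id = 1, strand = "-")))
  lt <- extract_ltrs(loci[[1]], genome)
  expect_identical(lt$ltr5, ltr)
})

test_that("N-heavy LTRs are flagged low quality", {
  genome <- c(chr1 = paste0(strrep("A", 20), strrep("N", 200),
                            strrep("ACGT", 30), strrep("T", 20)))
  loci <- assemble_loci(make_hits(
    list(start = 20, end = 320, name = "GGERV10B-LTR", id = 1)))
  lt <- extract_ltrs(loci[[1]], genome)
  expect_true(lt$low_quality[["ltr5"]])
})
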