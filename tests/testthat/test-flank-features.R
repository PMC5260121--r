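fake_locus <- function(chrom, start, end) {
  list(chrom = chrom, start = start, end = end)
}

test_that("planted TSDs are found at the planted length", {
  genome <- c(chr1 = paste0(strrep("G", 40), "ACGT", strrep("T", 30),
                            "ACGT", strrep("G", 40)))
  loc <- fake_locus("chr1", 44L, 74L)
  tsd <- detect_tsd(loc, genome)
  expect_true(tsd$is_match)
  expect_equal(tsd$length, 4L)
  expect_equal(tsd$left_seq, "ACGT")
})

test_that("mismatching flanks report no TSD; off-chromosome flanks flag edge", {
  genome <- c(chr1 = paste0(strrep("A", 40), strrep("T", 30),
                            strrep("C", 40)))
  tsd <- detect_tsd(fake_locus("chr1", 40L, 70L), genome)
  expect_false(tsd$is_match)
  expect_equal(tsd$mismatches, 3L)
  edge <- detect_tsd(fake_locus("chr1", 2L, 30L), genome)
  expect_false(edge$is_match)
  expect_true(edge$edge)
})

test_that("no spurious TSDs beyond chance on random flanks", {
  set.seed(55)
  n <- 400
  false_hits <- 0
  for (i in seq_len(n)) {
    genome <- c(chr1 = random_dna(60, 0.5))
    tsd <- detect_tsd(fake_locus("chr1", 25L, 35L), genome)
    if (tsd$is_match) false_hits <- false_hits + 1
  }
  ## chance rate for a kmin=3 exact match is about 4^-3 per locus
  expect_lt(false_hits / n, 0.05)
})

test_that("terminal motif checks respect the motif pair and its symmetry", {
  good <- paste0("TGTTG", strrep("A", 50), "CAACA")
  expect_equal(unlist(check_tir(good)), c(starts_tgttg = TRUE,
                                          ends_caaca = TRUE))
  bad5 <- paste0("TGCTG", strrep("A", 50), "CAACA")
  expect_equal(unlist(check_tir(bad5)), c(starts_tgttg = FALSE,
                                          ends_caaca = TRUE))
  ## the motifs are mutual reverse complements, so the check is
  ## strand-symmetric for a passing LTR
  expect_equal(unlist(check_tir(revcomp(good))),
               c(starts_tgttg = TRUE, ends_caaca = TRUE))
})

test_that("flank GC is computed over both flanks, excluding the element", {
  genome <- c(chr1 = paste0(strrep("GC", 50), strrep("A", 30),
                            strrep("CG", 50)))
  loc <- fake_locus("chr1", 100L, 130L)
  expect_equal(gc_window(loc, genome, window_bp = 100), 100)
  genome2 <- c(chr1 = paste0(strrep("ATGC", 25), strrep("A", 30),
                             strrep("ATGC", 25)))
  expect_equal(gc_window(fake_locus("chr1", 100L, 130L), genome2,
                         window_bp = 100), 50)
})

test_that("flank GC is strand-symmetric", {
  set.seed(9)
  fwd <- random_dna(500, 0.45)
  genome_f <- c(chr1 = fwd)
  genome_r <- c(chr1 = revcomp(fwd))
  loc_f <- fake_locus("chr1", 200L, 300L)
  loc_r <- fake_locus("chr1", 500L - 300L, 500L - 200L)
  expect_equal(gc_window(loc_f, genome_f, 200), gc_window(loc_r, genome_r, 200))
})

test_that("N bases drop out of the GC denominator", {
  genome <- c(chr1 = paste0(strrep("N", 40), strrep("G", 10), strrep("A", 20),
                            strrep("C", 10), strrep("N", 40)))
  expect_equal(gc_window(fake_locus("chr1", 50L, 70L), genome, 100), 100)
})

test_that("gene density counts any window overlap and normalizes per Mb", {
  genes <- data.frame(
    chrom = "chr1",
    start = c(10e3, 200e3, 500e3, 900e3, 999999, 3e6),
    end = c(20e3, 240e3, 520e3, 950e3, 1.05e6, 3.1e6),
    strand = "+", gene_id = paste0("g", 1:6), feature_kind = "gene",
    stringsAsFactors = FALSE)
  loc <- fake_locus("chr1", 1e6, 1.001e6)
  gd <- gene_density(loc, genes, window_bp = 2e6, chrom_len = 4e6)
  ## g1..g4 inside upstream window, g5 overlaps the window edge by 1 bp
  ## (still counted), g6 is outside
  expect_equal(gd$count, 5L)
  expect_equal(gd$genes_per_mb, 2.5)
})

test_that("genic context follows exonic > intronic > intergenic precedence", {
  genes <- data.frame(
    chrom = "chr1", start = c(1000L, 2000L), end = c(9000L, 2500L),
    strand = "+", gene_id = c("g1", "g1"),
    feature_kind = c("gene", "exon"), stringsAsFactors = FALSE)
  expect_equal(genic_context(fake_locus("chr1", 3000L, 3400L), genes),
               "intronic")
  expect_equal(genic_context(fake_locus("chr1", 2499L, 2900L), genes),
               "exonic")  # 1 bp exon overlap wins
  expect_equal(genic_context(fake_locus("chr1", 50000L, 50400L), genes),
               "intergenic")
  ## order independence
  expect_equal(genic_context(fake_locus("chr1", 2499L, 2900L),
                             genes[2:1, ]), "exonic")
})
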