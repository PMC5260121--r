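test_that("LTRs are assigned to the generating consensus", {
  cons <- consensus_fixture()$ltr
  ## exact copy: distance 0
  call <- assign_subfamily(cons[["GGERV10B"]], cons)
  expect_equal(call$name, "GGERV10B")
  expect_equal(call$distance, 0)
  ## 5% mutated copy of D still maps to D with a clear margin
  set.seed(31)
  mut <- evolve_seq(cons[["GGERV10D"]], age_myr = 1, mu = 0.05)$seq
  call <- assign_subfamily(mut, cons)
  expect_equal(call$name, "GGERV10D")
  expect_gt(call$margin, 0.02)
  ## unrelated sequence is unassigned
  set.seed(32)
  expect_equal(assign_subfamily(random_dna(330, 0.5), cons)$name,
               "unassigned")
})

test_that("assignment prefers the generating consensus for divergence <= 10%", {
  cons <- consensus_fixture()$ltr
  set.seed(77)
  violations <- 0; total <- 0
  for (sf in names(cons)) {
    for (r in 1:20) {
      mut <- evolve_seq(cons[[sf]], age_myr = 1, mu = 0.10)$seq
      total <- total + 1
      if (assign_subfamily(mut, cons)$name != sf) violations <- violations + 1
    }
  }
  expect_lte(violations / total, 0.01)
})

test_that("chimera calls require discordant LTRs with confident margins", {
  cons <- consensus_fixture()$ltr
  set.seed(41)
  ## planted recombinant: 5' D-like, 3' B-like
  l5 <- evolve_seq(cons[["GGERV10D"]], 3.7, 0.0019)$seq
  l3 <- evolve_seq(cons[["GGERV10B"]], 3.7, 0.0019)$seq
  cc <- detect_chimera(l5, l3, cons)
  expect_true(cc$chimeric)
  expect_equal(cc$locus_subfamily, "chimeric")
  ## concordant pair is not chimeric
  b5 <- evolve_seq(cons[["GGERV10B"]], 3.7, 0.0019)$seq
  b3 <- evolve_seq(cons[["GGERV10B"]], 3.7, 0.0019)$seq
  cc2 <- detect_chimera(b5, b3, cons)
  expect_false(cc2$chimeric)
  expect_equal(cc2$locus_subfamily, "GGERV10B")
  ## discordant names but sub-threshold margin: not chimeric, flagged
  c5 <- list(name = "GGERV10B", distance = 0.01, margin = 0.001)
  c3 <- list(name = "GGERV10C1", distance = 0.011, margin = 0.2)
  low <- ervscan:::chimera_call(c5, c3, margin_min = 0.02)
  expect_false(low$chimeric)
  expect_equal(low$flag, "discordant_low_margin")
  ## one unassigned LTR: partial, never chimeric
  set.seed(42)
  cc3 <- detect_chimera(l5, random_dna(330, 0.5), cons)
  expect_false(cc3$chimeric)
  expect_equal(cc3$flag, "partial")
})

test_that("multiple alignment applies the 50-bp deletion exclusion", {
  cons <- consensus_fixture()$ltr
  base <- cons[["GGERV10B"]]
  seqs <- c(a = base, b = base, c = base,
            short = substr(base, 61, nchar(base)))  # 60 bp deletion
  out <- build_subfamily_msa(seqs, max_deletion = 50)
  expect_equal(out$excluded, "short")
  expect_equal(rownames(out$msa), c("a", "b", "c"))
  ## identical sequences align without gaps
  expect_false(any(out$msa == "-"))
  expect_error(build_subfamily_msa(c(a = base,
                                     short = substr(base, 151, 382)),
                                   max_deletion = 50), "insufficient")
})

test_that("a planted deletion yields a gap block of the planted width", {
  cons <- consensus_fixture()$ltr
  base <- cons[["GGERV10B"]]
  del10 <- paste0(substr(base, 1, 100), substr(base, 111, nchar(base)))
  out <- build_subfamily_msa(c(a = base, b = base, d = del10))
  expect_equal(sum(out$msa["d", ] == "-"), 10L)
  expect_equal(ncol(out$msa), nchar(base))
})

test_that("diagnostic segments recover a planted subfamily-private block", {
  set.seed(61)
  core <- random_dna(120, 0.5)
  block <- random_dna(24, 0.5)
  with_block <- paste0(substr(core, 1, 60), block, substr(core, 61, 120))
  seqs <- c(A1 = with_block, A2 = with_block,
            B1 = core, B2 = core, C1 = core, C2 = core)
  labels <- c("A", "A", "B", "B", "C", "C")
  msa <- build_subfamily_msa(seqs, max_deletion = 200)$msa
  segs <- find_diagnostic_segments(msa, rownames(msa) |>
                                     substr(1, 1))
  a_only <- segs[segs$present_in == "A", ]
  expect_equal(nrow(a_only), 1L)
  expect_equal(a_only$length, 24L)
  expect_equal(a_only$segment_seq, block)
  ## invariance to row order and row duplication
  perm <- sample(nrow(msa))
  segs2 <- find_diagnostic_segments(msa[perm, ], substr(rownames(msa)[perm],
                                                        1, 1))
  expect_equal(segs2[order(segs2$col_start), ], segs[order(segs$col_start), ],
               ignore_attr = TRUE)
  dup <- rbind(msa, msa[1, , drop = FALSE])
  segs3 <- find_diagnostic_segments(dup, substr(rownames(dup), 1, 1))
  expect_equal(segs3[order(segs3$col_start), ], segs[order(segs$col_start), ],
               ignore_attr = TRUE)
})

test_that("shared blocks produce segments with the sharing subfamily sets", {
  set.seed(62)
  core <- random_dna(150, 0.5)
  blk1 <- random_dna(15, 0.5)  # present in C1 and C2
  blk2 <- random_dna(12, 0.5)  # present in C1 and D
  insert <- function(s, pos, blk) paste0(substr(s, 1, pos), blk,
                                         substr(s, pos + 1, nchar(s)))
  c1 <- insert(insert(core, 100, blk2), 50, blk1)
  c2 <- insert(core, 50, blk1)
  d <- insert(core, 100, blk2)
  b <- core
  seqs <- c(B1 = b, B2 = b, C1a = c1, C1b = c1, C2a = c2, C2b = c2,
            D1 = d, D2 = d)
  labels <- c("B", "B", "C1", "C1", "C2", "C2", "D", "D")
  msa <- build_subfamily_msa(seqs, max_deletion = 200)$msa
  segs <- find_diagnostic_segments(msa, labels, min_len = 10)
  expect_true("C1,C2" %in% segs$present_in)
  expect_true("C1,D" %in% segs$present_in)
})

test_that("an alignment with no variation yields no segments", {
  msa <- do.call(rbind, rep(list(ervscan:::seq_to_chars(strrep("ACGT", 30))),
                            4))
  rownames(msa) <- c("a1", "a2", "b1", "b2")
  segs <- find_diagnostic_segments(msa, c("A", "A", "B", "B"))
  expect_equal(nrow(segs), 0L)
})
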