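## Frozen closed-form value: P = 0.10, Q = 0.05 gives
## d = -1/2 ln(0.75) - 1/4 ln(0.90), evaluated independently at high
## precision (Rmpfr-free: the expression below is exact to double precision).
K2P_REF <- 0.5 * log(4 / 3) + 0.25 * log(10 / 9)

test_that("K2P distance matches the closed form at high precision", {
  ## build a pair with exactly 10 transitions and 5 transversions in 100 cols
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.10)
  expect_equal(k$Q, 0.05)
  expect_equal(k$d, K2P_REF, tolerance = 1e-12)
  expect_equal(round(k$d, 6), 0.170181)
  ## symmetry and the identity case
  expect_equal(k2p_distance(b, a)$d, k$d)
  expect_equal(k2p_distance(a, a)$d, 0)
})

test_that("gap and N columns are dropped pairwise", {
  a <- "ACGTACGTAC"
  b <- "ACG-ACGTNC"
  k <- k2p_distance(a, b)
  expect_equal(k$n_sites, 8L)
  expect_equal(k$d, 0)
})

test_that("saturated pairs and empty overlaps are errors", {
  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)), "saturated")
  expect_error(k2p_distance("---", "AAA"), "valid")
})

test_that("K2P agrees with an independent implementation on random pairs", {
  set.seed(13)
  for (r in 1:25) {
    a <- random_dna(300, 0.5)
    b <- evolve_seq(a, age_myr = stats::runif(1, 1, 40), mu = 0.0019)$seq
    mine <- k2p_distance(a, b)$d
    bin <- ape::as.DNAbin(rbind(a = ervscan:::seq_to_chars(tolower(a)),
                                b = ervscan:::seq_to_chars(tolower(b))))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("K2P dominates the p-distance", {
  set.seed(14)
  for (r in 1:200) {
    a <- random_dna(200, 0.5)
    b <- evolve_seq(a, age_myr = stats::runif(1, 0, 30), mu = 0.0019)$seq
    ca <- ervscan:::seq_to_chars(a); cb <- ervscan:::seq_to_chars(b)
    p <- mean(ca != cb)
    expect_gte(k2p_distance(a, b)$d, p - 1e-12)
  }
})

test_that("insertion age is d/(2 mu), linear in d and inverse in mu", {
  expect_equal(estimate_age(0), 0)
  expect_equal(estimate_age(0.0038, mu = 0.0019), 1.0)
  d <- c(0.001, 0.01, 0.1)
  expect_equal(estimate_age(2 * d), 2 * estimate_age(d))
  expect_equal(estimate_age(d, mu = 2 * 0.0019),
               estimate_age(d, mu = 0.0019) / 2)
})

test_that("subfamily rho age is 0 for identical LTRs and scales with mu", {
  cons <- consensus_fixture()$ltr[["GGERV10C1"]]
  same <- c(a = cons, b = cons, c = cons)
  expect_equal(subfamily_age(same)$age_myr, 0)
  set.seed(15)
  seqs <- vapply(1:8, function(i)
    evolve_seq(cons, 4, 0.0019)$seq, character(1))
  names(seqs) <- paste0("s", 1:8)
  a1 <- subfamily_age(seqs, mu = 0.0019)$age_myr
  a2 <- subfamily_age(seqs, mu = 0.0038)$age_myr
  expect_equal(a1, 2 * a2)
})

test_that("simulated LTR pairs recover their target age", {
  cons <- consensus_fixture()$ltr[["GGERV10B"]]
  set.seed(16)
  for (target in c(1.0, 3.7)) {
    est <- replicate(60, {
      pr <- evolve_ltr_pair(cons, target, 0.0019)
      estimate_age(k2p_distance(pr$ltr5, pr$ltr3)$d)
    })
    expect_lt(abs(mean(est) - target) / target, 0.15)
  }
})

test_that("three taxa solve the exact three-point formulas", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  pl <- tree_path_lengths(tr)
  expect_equal(pl["a", "b"], 5)
  expect_equal(pl["a", "c"], 9)
  expect_equal(pl["b", "c"], 10)
  expect_error(nj_tree(D[1:2, 1:2]), "n >= 3")
})

## Brute-force least-squares oracle over the three unrooted 4-taxon
## topologies; returns the winning split as a sorted pair.
ls_best_quartet <- function(D) {
  labs <- rownames(D)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4))
  rss <- vapply(pairs, function(pr) {
    ## topology: (pr) | rest. Path matrix over the 5 edges
    ## order: e1..e4 pendant (taxon 1..4), e5 internal
    other <- setdiff(1:4, pr)
    rows <- t(combn(4, 2))
    X <- t(apply(rows, 1, function(ij) {
      e <- numeric(5)
      e[ij[1]] <- 1; e[ij[2]] <- 1
      same_side <- (all(ij %in% pr)) || (all(ij %in% other))
      if (!same_side) e[5] <- 1
      e
    }))
    y <- D[rows]
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, numeric(1))
  pr <- pairs[[which.min(rss)]]
  side <- labs[pr]
  if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
  paste(sort(side), collapse = "|")
}

test_that("NJ recovers random additive quartets exactly", {
  set.seed(17)
  wins <- 0
  for (r in 1:100) {
    ## random topology and positive branch lengths -> additive matrix
    labs <- c("t1", "t2", "t3", "t4")
    pr <- sort(sample(4, 2))
    other <- setdiff(1:4, pr)
    bl <- stats::runif(5, 0.05, 1)
    D <- matrix(0, 4, 4, dimnames = list(labs, labs))
    for (i in 1:3) for (j in (i + 1):4) {
      same <- (all(c(i, j) %in% pr)) || (all(c(i, j) %in% other))
      D[i, j] <- D[j, i] <- bl[i] + bl[j] + if (same) 0 else bl[5]
    }
    tr <- nj_tree(D)
    split <- setdiff(ervscan:::tree_splits(tr), character(0))
    truth_split <- {
      side <- labs[pr]
      if ("t1" %in% side) side <- setdiff(labs, side)
      paste(sort(side), collapse = "|")
    }
    oracle <- ls_best_quartet(D)
    expect_equal(truth_split, oracle)  # oracle agrees with the generator
    if (identical(split, truth_split)) wins <- wins + 1
    ## additive matrices are reproduced exactly as path lengths
    pl <- tree_path_lengths(tr)[labs, labs]
    expect_lt(max(abs(pl - D)), 1e-9)
  }
  expect_equal(wins, 100)
})

test_that("NJ topology matches the reference implementation", {
  set.seed(18)
  for (r in 1:10) {
    n <- 8
    coords <- matrix(stats::runif(n * 3), n)
    D <- as.matrix(stats::dist(coords))
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- nj_tree(D)
    ref <- ape::nj(stats::as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("simulated subfamilies come out monophyletic", {
  cons <- consensus_fixture()$ltr
  set.seed(19)
  seqs <- character(0); labels <- character(0)
  for (sf in names(cons)) {
    for (i in 1:4) {
      nm <- paste0(sf, "_", i)
      seqs[nm] <- evolve_seq(cons[[sf]], 4, 0.0019)$seq
      labels[nm] <- sf
    }
  }
  msa <- build_subfamily_msa(seqs, max_deletion = 200)$msa
  tr <- nj_tree(k2p_matrix(msa))
  for (sf in names(cons)) {
    expect_true(ape::is.monophyletic(tr, names(labels)[labels == sf]))
  }
})

test_that("bootstrap supports are reproducible and strong under clear signal", {
  cons <- consensus_fixture()$ltr
  set.seed(21)
  seqs <- c(
    vapply(1:4, function(i) evolve_seq(cons[["GGERV10B"]], 3, 0.0019)$seq,
           character(1)),
    vapply(1:4, function(i) evolve_seq(cons[["GGERV10A"]], 3, 0.0019)$seq,
           character(1)))
  names(seqs) <- c(paste0("b", 1:4), paste0("a", 1:4))
  msa <- build_subfamily_msa(seqs, max_deletion = 200)$msa
  b1 <- bootstrap_supports(msa, n_reps = 100, seed = 5)
  b2 <- bootstrap_supports(msa, n_reps = 100, seed = 5)
  expect_identical(b1$supports, b2$supports)
  ## the A/B separating split has maximal support (canonical key is the
  ## side not containing the alphabetically first tip, i.e. the b-side)
  sep <- vapply(names(b1$supports), function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    setequal(side, paste0("a", 1:4)) || setequal(side, paste0("b", 1:4))
  }, logical(1))
  expect_true(any(sep))
  expect_gt(b1$supports[sep][1], 95)
  ## zero replicates: empty supports, no error
  b0 <- bootstrap_supports(msa, n_reps = 0)
  expect_length(b0$supports, 0)
})
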