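## Synthetic subfamily consensus construction and neutral sequence evolution.
##
## Five LTR consensuses mirror the study family's subfamily structure: the
## published per-subfamily LTR lengths (295/382/329/336/332 nt), the fixed
## terminal motifs TGTTG...CAACA, subfamily-specific deletion blocks (which
## the diagnostic-segment scan recovers), and a 24-nt tandem duplication
## private to the A-like subfamily. One internal-region consensus carries a
## planted pbs motif, a 450-codon gag ORF and a polypurine tract.
## Consensuses are synthetic stand-ins, not Repbase sequences.

SUBFAMILIES <- c("GGERV10A", "GGERV10B", "GGERV10C1", "GGERV10C2", "GGERV10D")

LTR_LENGTHS <- c(GGERV10A = 295L, GGERV10B = 382L, GGERV10C1 = 329L,
                 GGERV10C2 = 336L, GGERV10D = 332L)

## the 24-nt duplication diagnostic for the A-like subfamily
DUP24 <- "GCGTAGCGAGGGAAACGAGGTGTG"

## subfamily-specific deletion blocks on the 382-nt ancestral LTR
## (1-based inclusive); B keeps the full ancestor.
LTR_DEL_BLOCKS <- list(
  GGERV10A = list(c(20L, 130L)),                     # 111 nt; +24 dup = 295
  GGERV10B = list(),
  GGERV10C1 = list(c(140L, 179L), c(190L, 202L)),    # 40 + 13 -> 329
  GGERV10C2 = list(c(140L, 179L), c(210L, 215L)),    # 40 + 6 -> 336
  GGERV10D = list(c(225L, 274L))                     # 50 -> 332
)
DUP24_SITE <- c(300L, 323L)  # ancestor coordinates of the 24-mer

#' Build the synthetic subfamily consensus set
#'
#' Deterministic given `seed`: the same seed reproduces the same consensus
#' sequences byte for byte.
#'
#' @param seed RNG seed.
#' @param sub_rate per-subfamily substitution rate from the ancestral LTR
#'   (default 0.04; pairwise consensus divergence about twice that).
#' @param internal_len internal-region length in nt (default 2000).
#' @return list with `ltr` (named character, one consensus per subfamily),
#'   `internal` (intact internal-region consensus), `pbs_motif`, `gag`
#'   (nt range), `ppt` (nt range), `variants` (internal-region variants per
#'   planted gag state, with positions protected during evolution), and
#'   `internal_len`.
#' @export
make_consensus_set <- function(seed = 1, sub_rate = 0.04,
                               internal_len = 2000L) {
  set.seed(seed)
  anc_len <- 382L
  anc <- seq_to_chars(random_dna(anc_len, gc = 0.5))
  anc[1:5] <- seq_to_chars("TGTTG")
  anc[(anc_len - 4):anc_len] <- seq_to_chars("CAACA")
  anc[DUP24_SITE[1]:DUP24_SITE[2]] <- seq_to_chars(DUP24)
  tir_pos <- c(1:5, (anc_len - 4):anc_len, DUP24_SITE[1]:DUP24_SITE[2])
  ltr <- vapply(SUBFAMILIES, function(sf) {
    ch <- anc
    n_sub <- round(sub_rate * anc_len)
    sites <- sample(setdiff(seq_len(anc_len), tir_pos), n_sub)
    for (p in sites) ch[p] <- mutate_base(ch[p], ts_tv_ratio = 2)
    keep <- rep(TRUE, anc_len)
    for (blk in LTR_DEL_BLOCKS[[sf]]) keep[blk[1]:blk[2]] <- FALSE
    ch <- ch[keep]
    if (sf == "GGERV10A") {
      ## tandem-duplicate the 24-mer (map site through the deletion)
      shift <- sum(!keep[seq_len(DUP24_SITE[1] - 1)])
      a <- DUP24_SITE[1] - shift; b <- DUP24_SITE[2] - shift
      ch <- c(ch[1:b], ch[a:b], ch[(b + 1):length(ch)])
    }
    s <- chars_to_seq(ch)
    ## re-assert the terminal motifs
    substr(s, 1, 5) <- "TGTTG"
    substr(s, nchar(s) - 4, nchar(s)) <- "CAACA"
    s
  }, character(1))
  stopifnot(all(nchar(ltr) == LTR_LENGTHS[names(ltr)]))
  internal <- build_internal(internal_len)
  variants <- build_internal_variants(internal)
  list(ltr = ltr, internal = internal$seq, pbs_motif = internal$pbs_motif,
       gag = internal$gag, ppt = internal$ppt, variants = variants,
       internal_len = internal_len)
}

## Internal-region consensus layout:
##   [1..18] pbs | spacer | [61..1413] gag (ATG + 449 sense codons + TAA)
##   | spacer | 15-nt polypurine tract ending 11 nt before the 3' end.
build_internal <- function(internal_len) {
  stopifnot(internal_len >= 1500)
  pbs <- random_dna(18, gc = 0.5)
  gag_start <- 61L
  n_codons <- 449L
  codons <- replicate(n_codons, {
    repeat {
      c3 <- chars_to_seq(sample(DNA_BASES, 3, replace = TRUE))
      if (!c3 %in% STOP_CODONS) return(c3)
    }
  })
  gag <- paste0("ATG", paste0(codons, collapse = ""), "TAA")
  gag_end <- gag_start + nchar(gag) - 1L  # 1413
  ppt_end <- internal_len - 11L
  ppt_start <- ppt_end - 14L
  spacer1 <- random_dna(gag_start - 1L - 18L, gc = 0.5)
  spacer2 <- random_dna(ppt_start - 1L - gag_end, gc = 0.5)
  ppt <- chars_to_seq(sample(PURINES, 15, replace = TRUE))
  tail3 <- random_dna(internal_len - ppt_end, gc = 0.5)
  seq <- paste0(pbs, spacer1, gag, spacer2, ppt, tail3)
  stopifnot(nchar(seq) == internal_len)
  list(seq = seq, pbs_motif = pbs, gag = c(gag_start, gag_end),
       ppt = c(ppt_start, ppt_end))
}

## Internal-region variants for the planted gag states. Each carries the
## positions that must not mutate during evolution (`protect`) and the
## codon ranges that must stay stop-free (`orf_ranges`, frame anchored at
## the range start).
build_internal_variants <- function(internal) {
  seq <- internal$seq
  gag <- internal$gag
  ppt_pos <- internal$ppt[1]:internal$ppt[2]
  pbs_pos <- 1:18
  variants <- list()
  variants$intact <- list(
    seq = seq, protect = c(pbs_pos, ppt_pos),
    orf_ranges = list(gag), pbs_intact = TRUE
  )
  ## frameshifted: one base inserted mid-gag (after codon 224); the
  ## downstream gag codons shift into a new frame but remain the original
  ## stop-free triplets. Two stops are planted at the junction -- TAA in the
  ## original frame right after the insertion, TGA in the shifted frame just
  ## upstream of it -- pinning the two sub-ORFs that jointly cover gag.
  p_ins <- gag[1] + 672L  # codon boundary: 224 original codons end at p_ins-1
  ch <- seq_to_chars(seq)
  ch[(p_ins - 5L):(p_ins - 3L)] <- c("T", "G", "A")  # shifted-frame stop
  fs <- c(ch[1:(p_ins - 1L)], "T", ch[p_ins:length(ch)])
  fs[p_ins + 1L] <- "A"; fs[p_ins + 2L] <- "A"       # TAA in original frame
  fs_seq <- chars_to_seq(fs)
  variants$frameshifted <- list(
    seq = fs_seq,
    protect = c(pbs_pos, ppt_pos + 1L, (p_ins - 6L):(p_ins + 3L)),
    orf_ranges = list(c(gag[1], p_ins - 1L), c(p_ins - 2L, gag[2] + 1L)),
    pbs_intact = TRUE
  )
  ## pbs-deficient: pbs replaced by a remote sequence (>= 6 mismatches)
  repeat {
    scram <- random_dna(18, gc = 0.5)
    if (hamming(scram, internal$pbs_motif) >= 6) break
  }
  pd <- seq
  substr(pd, 1, 18) <- scram
  variants$pbs_deficient <- list(
    seq = pd, protect = c(pbs_pos, ppt_pos),
    orf_ranges = list(gag), pbs_intact = FALSE
  )
  ## gag absent: gag region re-randomized with stop codons seeded in every
  ## forward frame about every 45 codons
  ab <- seq_to_chars(seq)
  ab[gag[1]:gag[2]] <- seq_to_chars(random_dna(gag[2] - gag[1] + 1L, 0.5))
  stop_pos <- integer(0)
  phase <- 0L
  pos <- gag[1]
  while (pos + 2L <= gag[2]) {
    q <- pos + ((phase - pos) %% 3)
    if (q + 2L <= gag[2]) {
      ab[q:(q + 2L)] <- c("T", "A", "A")
      stop_pos <- c(stop_pos, q:(q + 2L))
    }
    phase <- (phase + 1L) %% 3L
    pos <- pos + 45L
  }
  variants$absent <- list(
    seq = chars_to_seq(ab), protect = c(pbs_pos, ppt_pos, stop_pos),
    orf_ranges = list(), pbs_intact = TRUE
  )
  variants
}

## One substitution of a base: transition with probability R/(R+1), else a
## uniform transversion.
mutate_base <- function(base, ts_tv_ratio = 2) {
  if (!base %in% DNA_BASES) return(base)
  if (stats::runif(1) < ts_tv_ratio / (ts_tv_ratio + 1)) {
    TRANSITION[[base]]
  } else {
    sample(TRANSVERSIONS[[base]], 1)
  }
}

#' Evolve a sequence neutrally for a given age
#'
#' Applies Poisson(mu * age * length) substitutions at distinct sites,
#' transition:transversion weighted by `ts_tv_ratio`. Sites in `protect` are
#' never mutated; substitutions that would create a stop codon inside an
#' `orf_ranges` reading frame are redrawn (or skipped), keeping planted ORFs
#' stop-free.
#'
#' @param seq DNA string.
#' @param age_myr age in million years.
#' @param mu substitutions/site/myr.
#' @param ts_tv_ratio transition:transversion ratio (default 2).
#' @param protect integer positions excluded from mutation.
#' @param orf_ranges list of c(start, end) 1-based nt ranges whose reading
#'   frame (anchored at start) must stay stop-free.
#' @return list with seq, n_sub (substitutions applied).
#' @export
evolve_seq <- function(seq, age_myr, mu, ts_tv_ratio = 2,
                       protect = integer(0), orf_ranges = list()) {
  stopifnot(age_myr >= 0, mu >= 0)
  ch <- seq_to_chars(seq)
  len <- length(ch)
  lam <- mu * age_myr * len
  n <- stats::rpois(1, lam)
  sites <- setdiff(seq_len(len), protect)
  if (n > length(sites)) n <- length(sites)
  if (n == 0) return(list(seq = seq, n_sub = 0L))
  hit <- sample(sites, n)
  applied <- 0L
  for (p in hit) {
    old <- ch[p]
    if (!old %in% DNA_BASES) next
    cand <- mutate_base(old, ts_tv_ratio)
    rng <- orf_range_of(p, orf_ranges)
    if (!is.null(rng)) {
      alts <- sample(setdiff(DNA_BASES, old))
      alts <- unique(c(cand, alts))
      cand <- NA_character_
      for (a in alts) {
        if (!makes_stop(ch, p, a, rng)) { cand <- a; break }
      }
      if (is.na(cand)) next
    }
    ch[p] <- cand
    applied <- applied + 1L
  }
  list(seq = chars_to_seq(ch), n_sub = applied)
}

orf_range_of <- function(p, orf_ranges) {
  for (rng in orf_ranges) if (p >= rng[1] && p <= rng[2]) return(rng)
  NULL
}

makes_stop <- function(ch, p, new_base, rng) {
  cod_start <- rng[1] + 3L * ((p - rng[1]) %/% 3L)
  if (cod_start + 2L > rng[2]) return(FALSE)  # partial trailing codon
  cod <- ch[cod_start:(cod_start + 2L)]
  cod[p - cod_start + 1L] <- new_base
  chars_to_seq(cod) %in% STOP_CODONS
}

#' Evolve an LTR pair from a consensus to a target insertion age
#'
#' Both LTRs are identical at insertion and then evolve independently, so
#' each receives Poisson(mu * age * len) substitutions and the expected
#' pairwise divergence is about 2 * mu * age.
#'
#' @param consensus LTR consensus sequence.
#' @inheritParams evolve_seq
#' @return list with ltr5, ltr3, div5, div3 (realized divergence from the
#'   consensus, percent).
#' @export
evolve_ltr_pair <- function(consensus, age_myr, mu = 0.0019,
                            ts_tv_ratio = 2) {
  e5 <- evolve_seq(consensus, age_myr, mu, ts_tv_ratio)
  e3 <- evolve_seq(consensus, age_myr, mu, ts_tv_ratio)
  len <- nchar(consensus)
  list(ltr5 = e5$seq, ltr3 = e3$seq,
       div5 = 100 * hamming(e5$seq, consensus) / len,
       div3 = 100 * hamming(e3$seq, consensus) / len)
}
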