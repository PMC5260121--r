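## Flanking-sequence features of an ERV locus: target-site duplications,
## the fixed LTR terminal motifs, GC content and gene context of the
## surrounding region.

#' Detect the target-site duplication (TSD) of a locus
#'
#' Integration duplicates a short stretch of host DNA, leaving identical
#' direct repeats immediately 5' and 3' of the element. The detector returns
#' the longest k in `[kmin, kmax]` for which the k-mer immediately upstream
#' of the locus equals the k-mer immediately downstream (exact match, genome
#' orientation). If none matches, the kmin-mers are reported with their
#' mismatch count.
#'
#' @param locus an `erv_locus`, or a list with chrom/start/end.
#' @param genome named character vector of chromosome sequences.
#' @param kmin,kmax search range in nt (defaults 3 and 8).
#' @return list with left_seq, right_seq, length, is_match, mismatches, edge.
#' @export
detect_tsd <- function(locus, genome, kmin = 3, kmax = 8) {
  stopifnot(kmin >= 1, kmax >= kmin)
  chromseq <- genome[[locus$chrom]]
  n <- nchar(chromseq)
  if (locus$start - kmax < 0 || locus$end + kmax > n) {
    return(list(left_seq = NA_character_, right_seq = NA_character_,
                length = NA_integer_, is_match = FALSE,
                mismatches = NA_integer_, edge = TRUE))
  }
  for (k in seq(kmax, kmin)) {
    left <- substr(chromseq, locus$start - k + 1L, locus$start)
    right <- substr(chromseq, locus$end + 1L, locus$end + k)
    if (identical(toupper(left), toupper(right))) {
      return(list(left_seq = toupper(left), right_seq = toupper(right),
                  length = k, is_match = TRUE, mismatches = 0L, edge = FALSE))
    }
  }
  left <- toupper(substr(chromseq, locus$start - kmin + 1L, locus$start))
  right <- toupper(substr(chromseq, locus$end + 1L, locus$end + kmin))
  list(left_seq = left, right_seq = right, length = kmin, is_match = FALSE,
       mismatches = hamming(left, right), edge = FALSE)
}

#' Check the fixed LTR terminal motifs
#'
#' GGERV10-family LTRs begin with TGTTG and end with CAACA (mutual reverse
#' complements, the family's terminal inverted repeat). Case-insensitive
#' prefix/suffix tests.
#'
#' @param ltr_seq LTR sequence in element orientation (length >= 10).
#' @return list with starts_tgttg, ends_caaca.
#' @export
check_tir <- function(ltr_seq) {
  stopifnot(nchar(ltr_seq) >= 10)
  s <- toupper(ltr_seq)
  list(
    starts_tgttg = startsWith(s, "TGTTG"),
    ends_caaca = endsWith(s, "CAACA")
  )
}

#' GC content of the windows flanking a locus
#'
#' GC% over `window_bp/2` upstream plus `window_bp/2` downstream of the locus
#' (the element's own sequence is excluded). N bases are excluded from the
#' denominator; windows are clipped at chromosome ends and the realized
#' length is used.
#'
#' @inheritParams detect_tsd
#' @param window_bp total window size in bp (even; default 20000, i.e. 10 kb
#'   per side).
#' @return GC percent in \[0, 100\], or NA if no valid bases.
#' @export
gc_window <- function(locus, genome, window_bp = 20000) {
  stopifnot(window_bp %% 2 == 0)
  half <- window_bp / 2
  chromseq <- genome[[locus$chrom]]
  up <- substr_clip(chromseq, locus$start - half + 1L, locus$start)
  down <- substr_clip(chromseq, locus$end + 1L, locus$end + half)
  gc_percent(paste0(up, down))
}

#' Gene density around a locus
#'
#' Counts genes whose span overlaps the flanking windows (`window_bp/2` per
#' side, element excluded; any-overlap rule) and converts to genes per Mb
#' using the realized (clipped) flank length, so density is unbiased near
#' chromosome ends.
#'
#' @inheritParams detect_tsd
#' @param genes data.frame from [read_gene_annotation()].
#' @param window_bp total window size in bp (default 2e6, i.e. 1 Mb per side).
#' @param chrom_len length of the locus chromosome (for clipping); if NA the
#'   windows are only clipped at 0.
#' @return list with count and genes_per_mb.
#' @export
gene_density <- function(locus, genes, window_bp = 2e6, chrom_len = NA) {
  half <- window_bp / 2
  w1 <- c(max(0, locus$start - half), locus$start)
  w2_end <- if (is.na(chrom_len)) locus$end + half else
    min(chrom_len, locus$end + half)
  w2 <- c(locus$end, w2_end)
  g <- genes[genes$feature_kind == "gene" & genes$chrom == locus$chrom, ,
             drop = FALSE]
  overlaps <- function(w) g$start < w[2] & g$end > w[1]
  count <- sum(overlaps(w1) | overlaps(w2))
  realized <- (w1[2] - w1[1]) + (w2[2] - w2[1])
  list(count = count, genes_per_mb = count / (realized / 1e6))
}

#' Genic context of a locus
#'
#' Precedence exonic > intronic > intergenic: a locus overlapping any exon is
#' exonic; otherwise a locus overlapping a gene span is intronic; otherwise
#' intergenic.
#'
#' @inheritParams gene_density
#' @return one of "exonic", "intronic", "intergenic".
#' @export
genic_context <- function(locus, genes) {
  on_chrom <- genes[genes$chrom == locus$chrom, , drop = FALSE]
  hit <- function(kind) {
    f <- on_chrom[on_chrom$feature_kind == kind, , drop = FALSE]
    any(f$start < locus$end & f$end > locus$start)
  }
  if (hit("exon")) return("exonic")
  if (hit("gene")) return("intronic")
  "intergenic"
}
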