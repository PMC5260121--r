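## Simplified proviral structure assessment of full-length loci: gag ORF
## integrity (intact / frameshifted / absent), primer-binding-site (pbs)
## detection just downstream of the 5' LTR, and polypurine-tract (PPT)
## detection just upstream of the 3' LTR. Alignment-free heuristics over the
## internal region -- a deliberate simplification of retroviral-motif chain
## reconstruction; every threshold is a parameter.

#' Default structure-scan parameters
#'
#' @param pbs_search_bp window downstream of the 5' LTR in which a pbs motif
#'   match (<= 1 mismatch) must start (default 30).
#' @param ppt_search_bp window upstream of the 3' LTR searched for a purine
#'   tract (default 30).
#' @param ppt_min_len minimum PPT window length (default 10).
#' @param ppt_min_purine minimum purine fraction in the PPT window
#'   (default 0.9).
#' @param min_codons minimum ORF length reported, in codons (default 100).
#' @param gag_min_codons minimum codons for an intact gag call (default 400).
#' @param frameshift_max_gap maximum nt gap between the two ORFs of a
#'   frameshifted gag (default 30).
#' @return named list of parameters.
#' @export
structure_params <- function(pbs_search_bp = 30, ppt_search_bp = 30,
                             ppt_min_len = 10, ppt_min_purine = 0.9,
                             min_codons = 100, gag_min_codons = 400,
                             frameshift_max_gap = 30) {
  list(pbs_search_bp = pbs_search_bp, ppt_search_bp = ppt_search_bp,
       ppt_min_len = ppt_min_len, ppt_min_purine = ppt_min_purine,
       min_codons = min_codons, gag_min_codons = gag_min_codons,
       frameshift_max_gap = frameshift_max_gap)
}

#' Maximal stop-free ORF runs in all six frames
#'
#' Frames 1..3 read the forward sequence at offsets 0..2; frames -1..-3 read
#' the reverse complement. Runs are maximal stop-codon-free codon stretches
#' of at least `min_codons`; coordinates are 1-based nt positions on the
#' strand read (forward coordinates for + frames).
#'
#' @param seq DNA sequence.
#' @param min_codons minimum run length in codons (default 100).
#' @return data.frame with frame, start, end, codons.
#' @export
find_orfs <- function(seq, min_codons = 100) {
  out <- list()
  scan_frame <- function(s, offset, frame_label) {
    n <- nchar(s)
    ncod <- (n - offset) %/% 3
    if (ncod < 1) return(NULL)
    starts <- offset + 1 + 3 * (seq_len(ncod) - 1)
    codons <- substring(s, starts, starts + 2)
    is_stop <- codons %in% STOP_CODONS
    r <- rle(!is_stop)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    runs <- which(r$values & r$lengths >= min_codons)
    if (length(runs) == 0) return(NULL)
    data.frame(
      frame = frame_label,
      start = starts[starts_idx[runs]],
      end = starts[ends_idx[runs]] + 2,
      codons = r$lengths[runs]
    )
  }
  s <- toupper(seq)
  rc <- revcomp(s)
  for (f in 0:2) {
    out[[length(out) + 1]] <- scan_frame(s, f, f + 1L)
    out[[length(out) + 1]] <- scan_frame(rc, f, -(f + 1L))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      codons = integer()))
  }
  do.call(rbind, out)
}

#' Scan the proviral structure of a full-length locus
#'
#' @param internal_seq internal-region sequence in element orientation (the
#'   stretch between the LTRs).
#' @param pbs_motifs character vector of candidate pbs motifs.
#' @param params list from [structure_params()].
#' @return list (StructureReport): pbs_found, pbs_offset, ppt_found,
#'   ppt_offset, orfs (data.frame), gag_state, notes.
#' @export
scan_structure <- function(internal_seq, pbs_motifs,
                           params = structure_params()) {
  s <- toupper(internal_seq)
  n <- nchar(s)
  if (n < 300) {
    return(list(pbs_found = FALSE, pbs_offset = NA_integer_,
                ppt_found = FALSE, ppt_offset = NA_integer_,
                orfs = find_orfs(s, params$min_codons),
                gag_state = "absent", notes = "internal too short"))
  }
  pbs <- find_pbs(s, pbs_motifs, params$pbs_search_bp)
  ppt <- find_ppt(s, params$ppt_search_bp, params$ppt_min_len,
                  params$ppt_min_purine)
  orfs <- find_orfs(s, params$min_codons)
  gag <- call_gag_state(orfs, n, params)
  list(pbs_found = pbs$found, pbs_offset = pbs$offset,
       ppt_found = ppt$found, ppt_offset = ppt$offset,
       orfs = orfs, gag_state = gag, notes = NA_character_)
}

## Best pbs motif match (<= 1 mismatch) starting within search_bp of the
## internal-region 5' end; offset is 0-based from that end.
find_pbs <- function(s, motifs, search_bp) {
  best <- list(found = FALSE, offset = NA_integer_, mismatches = NA_integer_)
  for (motif in toupper(motifs)) {
    L <- nchar(motif)
    max_start <- min(search_bp, nchar(s) - L + 1)
    if (max_start < 1) next
    for (st in seq_len(max_start)) {
      mm <- hamming(substr(s, st, st + L - 1), motif)
      if (mm <= 1 && (!best$found || mm < best$mismatches ||
                      (mm == best$mismatches && st - 1 < best$offset))) {
        best <- list(found = TRUE, offset = st - 1L, mismatches = mm)
      }
    }
  }
  best
}

## Purine-rich window of >= min_len nt within the last search_bp of the
## internal region; offset is 0-based from the internal-region 3' end to the
## window end.
find_ppt <- function(s, search_bp, min_len, min_purine) {
  n <- nchar(s)
  tail_seq <- substr(s, max(1, n - search_bp + 1), n)
  ch <- seq_to_chars(tail_seq)
  pur <- as.integer(ch %in% PURINES)
  L <- length(pur)
  if (L < min_len) return(list(found = FALSE, offset = NA_integer_))
  cs <- cumsum(c(0, pur))
  for (w in seq(min(L, search_bp), min_len)) {
    fr <- (cs[(w + 1):(L + 1)] - cs[1:(L + 1 - w)]) / w
    hit <- which(fr >= min_purine)
    if (length(hit)) {
      win_end <- hit[length(hit)] + w - 1  # rightmost qualifying window
      return(list(found = TRUE, offset = L - win_end))
    }
  }
  list(found = FALSE, offset = NA_integer_)
}

## gag state from forward-frame ORFs: intact needs a >= gag_min_codons ORF
## starting in the 5' third; frameshifted needs two sub-threshold ORFs in
## different frames jointly covering a gag-sized span with a small gap
## (overlap allowed).
call_gag_state <- function(orfs, internal_len, params) {
  fwd <- orfs[orfs$frame > 0, , drop = FALSE]
  third <- internal_len / 3
  intact <- fwd$codons >= params$gag_min_codons & fwd$start <= third
  if (any(intact)) return("intact")
  if (nrow(fwd) >= 2) {
    for (i in seq_len(nrow(fwd))) {
      for (j in seq_len(nrow(fwd))) {
        if (fwd$frame[i] == fwd$frame[j]) next
        o1 <- fwd[i, ]; o2 <- fwd[j, ]
        if (o1$start > third) next
        if (o2$start < o1$start || o2$end <= o1$end) next
        gap <- o2$start - o1$end - 1
        if (gap > params$frameshift_max_gap) next
        span_codons <- (o2$end - o1$start + 1) / 3
        if (span_codons >= params$gag_min_codons) return("frameshifted")
      }
    }
  }
  "absent"
}
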