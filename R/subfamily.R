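## LTR subfamily assignment, chimeric-provirus detection, and the scan for
## diagnostic alignment segments that partition subfamilies.
##
## Subfamily calls use an identity-based distance from a global pairwise
## alignment with free end gaps (robust to ragged LTR edges); the K2P model
## is reserved for dating.

#' Assign an LTR to the closest subfamily consensus
#'
#' Aligns the LTR globally (end gaps free) against each consensus and scores
#' distance = 1 - matches / mean(sequence lengths). The minimum-distance
#' consensus wins; `margin` is the gap to the runner-up. Distances above
#' `max_dist` for every consensus yield an `unassigned` call.
#'
#' @param ltr_seq LTR sequence (element orientation).
#' @param consensuses named character vector of subfamily consensus sequences
#'   (at least 2).
#' @param max_dist maximum distance for a confident call (default 0.5).
#' @return list with name (or "unassigned"), distance, margin, and the full
#'   distance vector.
#' @export
assign_subfamily <- function(ltr_seq, consensuses, max_dist = 0.5) {
  d <- subfamily_distances(ltr_seq, consensuses)[1, ]
  make_call(d, max_dist)
}

make_call <- function(d, max_dist = 0.5) {
  ord <- order(d, names(d))
  best <- ord[1]
  margin <- d[ord[2]] - d[ord[1]]
  name <- if (d[best] > max_dist) "unassigned" else names(d)[best]
  list(name = name, distance = unname(d[best]), margin = unname(margin),
       distances = d)
}

#' Distances of many LTRs to every subfamily consensus
#'
#' Vectorized over LTRs: one pairwise-alignment pass per consensus.
#' Distance = 1 - matches / mean(sequence lengths), from a global alignment
#' with free end gaps. Normalizing by sequence length (not just aligned
#' columns) keeps short spurious overlaps from masquerading as high
#' identity, so unrelated sequences score near 1.
#'
#' @param ltr_seqs character vector of LTR sequences.
#' @param consensuses named character vector of consensus sequences (>= 2).
#' @return numeric matrix, rows = LTRs, cols = consensuses.
#' @export
subfamily_distances <- function(ltr_seqs, consensuses) {
  stopifnot(length(consensuses) >= 2, !is.null(names(consensuses)))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                 baseOnly = FALSE)
  pat <- Biostrings::DNAStringSet(ltr_seqs)
  d <- vapply(consensuses, function(cons) {
    aln <- Biostrings::pairwiseAlignment(
      pat, Biostrings::DNAString(cons), type = "overlap",
      substitutionMatrix = sm, gapOpening = 5, gapExtension = 2)
    d <- 1 - Biostrings::pid(aln, type = "PID4") / 100
    ifelse(is.na(d), 1, d)
  }, numeric(length(ltr_seqs)))
  d <- matrix(d, nrow = length(ltr_seqs),
              dimnames = list(names(ltr_seqs), names(consensuses)))
  d
}

## 1 - identity over aligned columns, end gaps free ("overlap" alignment).
consensus_distance <- function(seq1, seq2) {
  subfamily_distances(seq1, stats::setNames(c(seq2, seq2), c("a", "b")))[1, 1]
}

#' Call the subfamily of a full-length locus and flag chimeras
#'
#' A locus is chimeric when its 5' and 3' LTRs are confidently assigned to
#' different subfamily consensuses -- both margins at least `margin_min` --
#' the signature of template switching / recombination between proviruses.
#' Otherwise the locus takes the shared best name (ties broken toward the 5'
#' LTR call, flagged).
#'
#' @param ltr5_seq,ltr3_seq LTR sequences in element orientation.
#' @param consensuses named character vector of consensus sequences.
#' @param margin_min minimum assignment margin on both LTRs before a
#'   discordant pair is called chimeric (default 0.02).
#' @param max_dist passed to [assign_subfamily()].
#' @return list (SubfamilyCall): ltr5_best, ltr3_best, locus_subfamily
#'   ("chimeric" for chimeras), chimeric, flag.
#' @export
detect_chimera <- function(ltr5_seq, ltr3_seq, consensuses,
                           margin_min = 0.02, max_dist = 0.5) {
  c5 <- assign_subfamily(ltr5_seq, consensuses, max_dist)
  c3 <- assign_subfamily(ltr3_seq, consensuses, max_dist)
  chimera_call(c5, c3, margin_min)
}

## Chimera logic over two per-LTR calls (shared with the pipeline's
## batch path).
chimera_call <- function(c5, c3, margin_min = 0.02) {
  flag <- NA_character_
  if (c5$name == "unassigned" || c3$name == "unassigned") {
    subfam <- if (c5$name != "unassigned") c5$name else c3$name
    return(list(ltr5_best = c5, ltr3_best = c3, locus_subfamily = subfam,
                chimeric = FALSE, flag = "partial"))
  }
  chimeric <- c5$name != c3$name &&
    c5$margin >= margin_min && c3$margin >= margin_min
  if (chimeric) {
    subfam <- "chimeric"
  } else if (c5$name == c3$name) {
    subfam <- c5$name
  } else {
    subfam <- c5$name  # discordant but within margin: keep 5' call, flag it
    flag <- "discordant_low_margin"
  }
  list(ltr5_best = c5, ltr3_best = c3, locus_subfamily = subfam,
       chimeric = chimeric, flag = flag)
}

#' Multiple alignment of LTR sequences (mafft)
#'
#' Sequences whose length is more than `max_deletion` bp below the median are
#' excluded before alignment (heavily deleted LTRs distort the alignment) and
#' reported. Alignment is progressive via the mafft program.
#'
#' @param ltr_seqs named character vector (>= 2 sequences).
#' @param max_deletion exclusion threshold in bp (default 50).
#' @return list with `msa` (character matrix, rows = sequences) and
#'   `excluded` (names of dropped sequences).
#' @export
build_subfamily_msa <- function(ltr_seqs, max_deletion = 50) {
  stopifnot(length(ltr_seqs) >= 2, !is.null(names(ltr_seqs)))
  lens <- nchar(ltr_seqs)
  med <- stats::median(lens)
  excluded <- names(ltr_seqs)[lens < med - max_deletion]
  keep <- setdiff(names(ltr_seqs), excluded)
  if (length(keep) < 2) stop("insufficient sequences after length filter")
  aligned <- run_mafft(ltr_seqs[keep])
  msa <- do.call(rbind, lapply(aligned, function(s)
    seq_to_chars(toupper(s))))
  rownames(msa) <- names(aligned)
  list(msa = msa, excluded = excluded)
}

## mafft wrapper: aligned sequences back as a named character vector.
run_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") stop("mafft program not found on PATH")
  fin <- tempfile(fileext = ".fa")
  on.exit(unlink(fin), add = TRUE)
  ## use positional names to dodge FASTA header mangling
  tmp_names <- paste0("s", seq_along(seqs))
  write_fasta(stats::setNames(unname(seqs), tmp_names), fin)
  out <- system2("mafft", c("--auto", "--quiet", fin), stdout = TRUE)
  aligned <- parse_fasta_lines(out)
  stats::setNames(unname(aligned[tmp_names]), names(seqs))
}

parse_fasta_lines <- function(lines) {
  hdr <- grepl("^>", lines)
  idx <- cumsum(hdr)
  nm <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1),
                 collapse = "")
  stats::setNames(toupper(seqs), nm)
}

#' Find diagnostic alignment segments that partition subfamilies
#'
#' A column is informative when every subfamily's rows agree on a majority
#' residue (gap counts as a state) at or above `agreement`, and those
#' majority residues split the subfamilies into at least two groups. Maximal
#' runs of `min_len`+ informative columns sharing the same partition become
#' segments; `present_in` is the set of subfamilies carrying the non-gap
#' state (for pure substitution partitions, the smaller -- derived -- group).
#'
#' @param msa character matrix (rows = sequences, cols = alignment columns).
#' @param labels subfamily label per row.
#' @param min_len minimum segment length in columns (default 10).
#' @param agreement minimum within-subfamily majority fraction (default 0.8).
#' @return data.frame with col_start, col_end (0-based half-open),
#'   length, present_in (comma-joined), segment_seq, flag.
#' @export
find_diagnostic_segments <- function(msa, labels, min_len = 10,
                                     agreement = 0.8) {
  stopifnot(is.matrix(msa), nrow(msa) == length(labels))
  subfams <- sort(unique(labels))
  stopifnot(length(subfams) >= 2)
  ncol_msa <- ncol(msa)
  maj <- matrix(NA_character_, nrow = length(subfams), ncol = ncol_msa,
                dimnames = list(subfams, NULL))
  ok <- matrix(FALSE, nrow = length(subfams), ncol = ncol_msa,
               dimnames = list(subfams, NULL))
  for (s in subfams) {
    rows <- msa[labels == s, , drop = FALSE]
    for (j in seq_len(ncol_msa)) {
      tab <- sort(table(rows[, j]), decreasing = TRUE)
      top <- sort(names(tab)[tab == max(tab)])[1]  # deterministic tie-break
      maj[s, j] <- top
      ok[s, j] <- max(tab) / nrow(rows) >= agreement
    }
  }
  partition_key <- function(j) {
    groups <- split(subfams, maj[, j])
    groups <- lapply(groups, sort)
    paste(sort(vapply(groups, paste, character(1), collapse = ",")),
          collapse = "|")
  }
  informative <- vapply(seq_len(ncol_msa), function(j) {
    all(ok[, j]) && length(unique(maj[, j])) >= 2
  }, logical(1))
  keys <- rep(NA_character_, ncol_msa)
  keys[informative] <- vapply(which(informative), partition_key, character(1))
  segs <- list()
  j <- 1
  while (j <= ncol_msa) {
    if (!informative[j]) { j <- j + 1; next }
    k <- j
    while (k + 1 <= ncol_msa && informative[k + 1] &&
           identical(keys[k + 1], keys[j])) k <- k + 1
    if (k - j + 1 >= min_len) {
      segs[[length(segs) + 1]] <- make_segment(msa, labels, maj, subfams, j, k)
    }
    j <- k + 1
  }
  if (length(segs) == 0) {
    return(data.frame(col_start = integer(), col_end = integer(),
                      length = integer(), present_in = character(),
                      segment_seq = character(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, segs)
}

make_segment <- function(msa, labels, maj, subfams, j, k) {
  cols <- j:k
  gap_frac <- vapply(subfams, function(s)
    mean(maj[s, cols] == "-"), numeric(1))
  flag <- NA_character_
  if (any(gap_frac >= 0.5)) {
    present <- subfams[gap_frac < 0.5]
    if (any(gap_frac == 1)) flag <- "all_gap_subfamily_excluded"
  } else {
    ## pure substitution partition: the smaller group is taken as derived
    groups <- split(subfams, maj[, j])
    sizes <- vapply(groups, length, integer(1))
    smallest <- sort(names(groups)[sizes == min(sizes)])[1]
    present <- groups[[smallest]]
  }
  rows <- msa[labels %in% present, cols, drop = FALSE]
  cons <- apply(rows, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    sort(names(tab)[tab == max(tab)])[1]
  })
  data.frame(
    col_start = j - 1L, col_end = k, length = k - j + 1L,
    present_in = paste(sort(present), collapse = ","),
    segment_seq = gsub("-", "", paste0(cons, collapse = "")),
    flag = flag, stringsAsFactors = FALSE
  )
}
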