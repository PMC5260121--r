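## Assembling repeat hits into ERV loci and classifying them.
##
## A RepeatMasker run fragments one provirus into LTR and internal-region
## hits; fragments of a single element usually share the linkage ID. Hits are
## first grouped by linkage_id, then adjacent groups are merged when they sit
## on the same chromosome and strand, their gap is small, and their repeat
## names share a subfamily stem (the name without the -LTR/-int suffix).

#' Assemble repeat hits into ERV loci
#'
#' @param hits data.frame of repeat hits (see [read_rmsk()]).
#' @param max_gap_bp maximum gap between hit groups with distinct linkage ids
#'   that are still merged into one locus (default 500).
#' @return list of `erv_locus` objects, ordered by chromosome and start. Each
#'   locus carries its component hits with roles (LTR5/INTERNAL/LTR3/LTR_SOLO),
#'   a classification (full_length / solo_ltr / truncated), and an
#'   `irregular` flag for role patterns that violate the proviral layout.
#' @export
assemble_loci <- function(hits, max_gap_bp = 500) {
  stopifnot(max_gap_bp >= 0)
  if (nrow(hits) == 0) return(list())
  hits <- hits[order(hits$chrom, hits$start), ]
  rownames(hits) <- NULL
  ## stage 1: group by linkage id (scoped per chromosome for safety)
  key <- paste(hits$chrom, hits$linkage_id, sep = "\r")
  groups <- split(seq_len(nrow(hits)), key)
  protos <- lapply(groups, function(ix) hits[ix, , drop = FALSE])
  ## stage 2: merge same-chrom, same-strand, same-stem groups within max_gap_bp
  span <- function(p) c(min(p$start), max(p$end))
  ord <- order(vapply(protos, function(p) p$chrom[1], character(1)),
               vapply(protos, function(p) min(p$start), numeric(1)))
  protos <- protos[ord]
  merged <- list()
  for (p in protos) {
    if (length(merged) > 0) {
      last <- merged[[length(merged)]]
      same <- last$chrom[1] == p$chrom[1] &&
        last$strand[1] == p$strand[1] &&
        length(intersect(subfamily_stem(last$repeat_name),
                         subfamily_stem(p$repeat_name))) > 0
      gap <- min(p$start) - max(last$end)
      if (same && gap <= max_gap_bp) {
        merged[[length(merged)]] <- rbind(last, p)
        next
      }
    }
    merged[[length(merged) + 1]] <- p
  }
  loci <- lapply(seq_along(merged), function(i) {
    new_locus(merged[[i]], locus_id = sprintf("locus_%04d", i))
  })
  loci
}

## Subfamily stem of a repeat name: drop the -LTR / -int suffix.
subfamily_stem <- function(name) {
  unique(sub("[-_](LTR|int)$", "", name, ignore.case = TRUE))
}

new_locus <- function(comp, locus_id) {
  comp <- comp[order(comp$start), ]
  rownames(comp) <- NULL
  strand <- comp$strand[1]
  is_ltr <- grepl("[-_]LTR$", comp$repeat_name, ignore.case = TRUE)
  is_int <- grepl("[-_]int$", comp$repeat_name, ignore.case = TRUE)
  ## element orientation: for minus-strand loci the genomic-last hit is 5'-most
  ord <- if (strand == "-") rev(seq_len(nrow(comp))) else seq_len(nrow(comp))
  roles <- rep(NA_character_, nrow(comp))
  irregular <- FALSE
  int_pos <- which(is_int[ord])
  ltr_pos <- which(is_ltr[ord])
  if (length(int_pos) == 0) {
    if (length(ltr_pos) == 1) {
      roles[ord[ltr_pos]] <- "LTR_SOLO"
    } else if (length(ltr_pos) >= 2) {
      ## two LTRs, internal deleted: keep proviral roles, classified truncated
      roles[ord[ltr_pos[1]]] <- "LTR5"
      roles[ord[ltr_pos[length(ltr_pos)]]] <- "LTR3"
      if (length(ltr_pos) > 2)
        roles[ord[ltr_pos[-c(1, length(ltr_pos))]]] <- "LTR5"
    }
  } else {
    first_int <- min(int_pos); last_int <- max(int_pos)
    for (k in ltr_pos) {
      if (k < first_int) roles[ord[k]] <- "LTR5"
      else if (k > last_int) roles[ord[k]] <- "LTR3"
      else { roles[ord[k]] <- "LTR5"; irregular <- TRUE }  # LTR between internals
    }
    roles[ord[int_pos]] <- "INTERNAL"
  }
  roles[is.na(roles)] <- "INTERNAL"
  comp$role <- roles
  locus <- structure(list(
    locus_id = locus_id,
    chrom = comp$chrom[1],
    start = min(comp$start),
    end = max(comp$end),
    strand = strand,
    components = comp,
    irregular = irregular
  ), class = "erv_locus")
  locus$classification <- classify_locus(locus)
  locus
}

#' Classify an assembled locus
#'
#' Deterministic, total labelling: `full_length` when the locus has a 5' LTR,
#' at least one internal-region hit and a 3' LTR (and a regular layout);
#' `solo_ltr` when it is a single LTR with no internal hit (the recombination
#' remnant); `truncated` otherwise. Truncated loci are retained in reports
#' but excluded from dating and subfamily-consensus work downstream.
#'
#' @param locus an `erv_locus`.
#' @return one of "full_length", "solo_ltr", "truncated".
#' @export
classify_locus <- function(locus) {
  roles <- locus$components$role
  if (isTRUE(locus$irregular)) return("truncated")
  if ("LTR5" %in% roles && "INTERNAL" %in% roles && "LTR3" %in% roles) {
    return("full_length")
  }
  if (identical(roles, "LTR_SOLO")) return("solo_ltr")
  "truncated"
}

#' Extract LTR sequences of a locus in element orientation
#'
#' Slices the genome at the LTR components and reverse-complements
#' minus-strand loci so the returned sequences read 5'->3' in element
#' orientation. Sequences with more than `max_n_frac` N are flagged low
#' quality (they are excluded from alignments downstream).
#'
#' @param locus an `erv_locus`.
#' @param genome named character vector of chromosome sequences.
#' @param max_n_frac maximum tolerated N fraction before flagging (default 0.2).
#' @return list with `ltr5`, `ltr3` (NULL where inapplicable; for solo loci
#'   the single LTR is returned as `ltr5`), and `low_quality` (named logical).
#' @export
extract_ltrs <- function(locus, genome, max_n_frac = 0.2) {
  stopifnot(locus$chrom %in% names(genome))
  chromseq <- genome[[locus$chrom]]
  stopifnot(locus$end <= nchar(chromseq))
  comp <- locus$components
  grab <- function(role) {
    rows <- comp[comp$role == role, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    s <- paste0(vapply(seq_len(nrow(rows)), function(i)
      substr(chromseq, rows$start[i] + 1L, rows$end[i]), character(1)),
      collapse = "")
    s <- toupper(s)
    if (locus$strand == "-") s <- revcomp(s)
    s
  }
  ltr5 <- grab("LTR5")
  ltr3 <- grab("LTR3")
  solo <- grab("LTR_SOLO")
  if (!is.null(solo)) ltr5 <- solo
  lq <- c(
    ltr5 = !is.null(ltr5) && n_fraction(ltr5) > max_n_frac,
    ltr3 = !is.null(ltr3) && n_fraction(ltr3) > max_n_frac
  )
  list(ltr5 = ltr5, ltr3 = ltr3, low_quality = lq)
}

#' Extract the internal-region sequence of a locus in element orientation
#'
#' Concatenates the INTERNAL components (5' to 3' in element orientation),
#' reverse-complementing minus-strand loci.
#'
#' @inheritParams extract_ltrs
#' @return character scalar, or NULL when the locus has no internal hits.
#' @export
extract_internal <- function(locus, genome) {
  comp <- locus$components
  rows <- comp[comp$role == "INTERNAL", , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  chromseq <- genome[[locus$chrom]]
  slices <- vapply(seq_len(nrow(rows)), function(i)
    toupper(substr(chromseq, rows$start[i] + 1L, rows$end[i])), character(1))
  if (locus$strand == "-") {
    slices <- rev(vapply(slices, revcomp, character(1)))
  }
  paste0(slices, collapse = "")
}

#' @export
print.erv_locus <- function(x, ...) {
  cat(sprintf("<erv_locus %s> %s:%d-%d (%s) %s, %d component hit(s)\n",
              x$locus_id, x$chrom, x$start, x$end, x$strand,
              x$classification, nrow(x$components)))
  invisible(x)
}

#' Loci as a data.frame (one row per locus)
#' @param loci list of `erv_locus`.
#' @return data.frame with locus_id, chrom, start, end, strand,
#'   classification, n_components, subfamily stem(s).
#' @export
loci_table <- function(loci) {
  if (length(loci) == 0) {
    return(data.frame(locus_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      classification = character(), n_components = integer(),
                      stem = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(loci, function(l) {
    data.frame(
      locus_id = l$locus_id, chrom = l$chrom, start = l$start, end = l$end,
      strand = l$strand, classification = l$classification,
      n_components = nrow(l$components),
      stem = paste(subfamily_stem(l$components$repeat_name), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
}
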