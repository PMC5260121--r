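## Readers and writers for the standard formats the pipeline touches.
## Internal convention: all coordinates are 0-based half-open. The only
## conversions live here, at the IO boundary (RepeatMasker .out and GFF3 are
## 1-based inclusive on disk; UCSC rmsk genoStart and BED are already 0-based).

#' Read repeat annotation (RepeatMasker .out or UCSC rmsk dialect)
#'
#' Parses repeat hits and keeps rows whose repeat name matches `name_pattern`
#' (the family of interest; the study family is GGERV10). Coordinates are
#' returned 0-based half-open. RepeatMasker's linkage ID column, which groups
#' fragments of one element, is preserved as `linkage_id`; strand `C` maps
#' to `-`.
#'
#' @param path file path.
#' @param dialect `"rm_out"` (whitespace-tokenized 15-column RepeatMasker
#'   output, 1-based inclusive coordinates) or `"ucsc_rmsk"` (tab-separated
#'   UCSC table dump, 0-based `genoStart`).
#' @param name_pattern regular expression a row's repeat name must match;
#'   use `""` to keep everything.
#' @return data.frame with columns chrom, start, end, strand, repeat_name,
#'   repeat_class, cons_start, cons_end, divergence_pct, linkage_id.
#' @export
read_rmsk <- function(path, dialect = c("rm_out", "ucsc_rmsk"),
                      name_pattern = "GGERV10") {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (dialect == "rm_out") {
    hits <- parse_rm_out(lines)
  } else {
    hits <- parse_ucsc_rmsk(lines)
  }
  if (nzchar(name_pattern)) {
    hits <- hits[grepl(name_pattern, hits$repeat_name), , drop = FALSE]
  }
  rownames(hits) <- NULL
  validate_hits(hits)
  hits
}

empty_hits <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), repeat_name = character(),
    repeat_class = character(), cons_start = integer(),
    cons_end = integer(), divergence_pct = numeric(),
    linkage_id = character(), stringsAsFactors = FALSE
  )
}

parse_rm_out <- function(lines) {
  ## skip the two header lines + blank line if present
  is_header <- grepl("^\\s*(SW|score)\\b", lines) | !nzchar(trimws(lines))
  data_lines <- which(!is_header)
  if (length(data_lines) == 0) return(empty_hits())
  rows <- lapply(data_lines, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 15) {
      stop("malformed rm_out row at line ", i, ": expected >= 15 fields, got ",
           length(f))
    }
    begin <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(begin) || is.na(end)) {
      stop("malformed rm_out row at line ", i, ": non-numeric coordinates")
    }
    strand <- if (f[9] == "C") "-" else f[9]
    ## consensus coords: for + strand (begin, end, (left)); for C ((left), end, begin)
    strip <- function(x) suppressWarnings(as.integer(gsub("[()]", "", x)))
    if (strand == "+") {
      cs <- strip(f[12]); ce <- strip(f[13])
    } else {
      cs <- strip(f[14]); ce <- strip(f[13])
    }
    data.frame(
      chrom = f[5], start = begin - 1L, end = end, strand = strand,
      repeat_name = f[10], repeat_class = f[11],
      cons_start = cs, cons_end = ce,
      divergence_pct = as.numeric(f[2]), linkage_id = f[15],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

parse_ucsc_rmsk <- function(lines) {
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(empty_hits())
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 17) {
      stop("malformed ucsc_rmsk row at line ", i,
           ": expected 17 tab-separated fields, got ", length(f))
    }
    gs <- suppressWarnings(as.integer(f[7]))
    ge <- suppressWarnings(as.integer(f[8]))
    if (is.na(gs) || is.na(ge)) {
      stop("malformed ucsc_rmsk row at line ", i, ": non-numeric coordinates")
    }
    data.frame(
      chrom = f[6], start = gs, end = ge, strand = f[10],
      repeat_name = f[11], repeat_class = f[12],
      cons_start = abs(suppressWarnings(as.integer(f[14]))),
      cons_end = suppressWarnings(as.integer(f[15])),
      divergence_pct = as.numeric(f[3]) / 10,
      linkage_id = f[17], stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

validate_hits <- function(hits) {
  if (nrow(hits) == 0) return(invisible(hits))
  bad <- which(!(hits$start < hits$end))
  if (length(bad)) stop("repeat hit with start >= end at row ", bad[1])
  bad <- which(!hits$strand %in% c("+", "-"))
  if (length(bad)) stop("repeat hit with bad strand at row ", bad[1])
  bad <- which(hits$divergence_pct < 0 | hits$divergence_pct > 100)
  if (length(bad)) stop("divergence_pct outside [0,100] at row ", bad[1])
  invisible(hits)
}

#' Write repeat hits in RepeatMasker .out layout
#' @param hits data.frame as returned by [read_rmsk()].
#' @param path output path.
#' @export
write_rm_out <- function(hits, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end     (left)  repeat    class/family  begin  end  (left)   ID",
    ""
  )
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    strand <- if (h$strand == "-") "C" else "+"
    cons <- if (strand == "+") {
      sprintf("%d %d (0)", h$cons_start, h$cons_end)
    } else {
      sprintf("(0) %d %d", h$cons_end, h$cons_start)
    }
    paste(
      "1000", sprintf("%.1f", h$divergence_pct), "0.0", "0.0",
      h$chrom, h$start + 1L, h$end, "(0)", strand,
      h$repeat_name, h$repeat_class, cons, h$linkage_id,
      sep = "  "
    )
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write repeat hits in the UCSC rmsk tab-separated dialect
#' @inheritParams write_rm_out
#' @export
write_ucsc_rmsk <- function(hits, path) {
  hdr <- paste(c("#bin", "swScore", "milliDiv", "milliDel", "milliIns",
                 "genoName", "genoStart", "genoEnd", "genoLeft", "strand",
                 "repName", "repClass", "repFamily", "repStart", "repEnd",
                 "repLeft", "id"), collapse = "\t")
  rows <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    paste(c(0, 1000, round(h$divergence_pct * 10), 0, 0,
            h$chrom, h$start, h$end, 0, h$strand,
            h$repeat_name, h$repeat_class, h$repeat_class,
            h$cons_start, h$cons_end, 0, h$linkage_id), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a genome (or consensus set) from FASTA
#'
#' @param path FASTA file.
#' @return named character vector, one upper-case sequence per record; names
#'   are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Write named sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read gene annotation from BED or GFF3
#'
#' BED rows become `gene` features; GFF3 contributes both `gene` and `exon`
#' features (exons linked to their gene via `Parent`). Coordinates are
#' returned 0-based half-open.
#'
#' @param path annotation file.
#' @param format `"bed"` or `"gff3"`.
#' @return data.frame with columns chrom, start, end, strand, gene_id,
#'   feature_kind.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  empty <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), gene_id = character(), feature_kind = character(),
    stringsAsFactors = FALSE
  )
  if (length(readLines(path, n = 1)) == 0) return(empty)
  gr <- rtracklayer::import(path, format = format)
  if (length(gr) == 0) return(empty)
  md <- S4Vectors::mcols(gr)
  if (format == "bed") {
    ids <- if (!is.null(md$name)) as.character(md$name) else
      paste0("gene", seq_along(gr))
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
      gene_id = ids, feature_kind = "gene", stringsAsFactors = FALSE
    )
  } else {
    kind <- as.character(md$type)
    keep <- kind %in% c("gene", "exon")
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]; kind <- kind[keep]
    ids <- character(length(gr))
    is_gene <- kind == "gene"
    ids[is_gene] <- as.character(md$ID[is_gene])
    if (any(!is_gene)) {
      parents <- md$Parent[!is_gene]
      ids[!is_gene] <- vapply(as.list(parents), function(p)
        if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    }
    out <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", "+", as.character(GenomicRanges::strand(gr))),
      gene_id = ids, feature_kind = kind, stringsAsFactors = FALSE
    )
  }
  genes <- out[out$feature_kind == "gene", ]
  if (anyDuplicated(genes$gene_id)) {
    warning("duplicate gene_id in annotation; keeping all rows")
  }
  bad <- which(!(out$start < out$end))
  if (length(bad)) stop("gene annotation row with start >= end at row ", bad[1])
  rownames(out) <- NULL
  out
}

#' Write the per-locus report (TSV) and a JSON summary
#'
#' Joins the per-locus tables produced by the pipeline stages on `locus_id`
#' and writes one TSV row per locus. Loci missing from any stage table get NA
#' fields (with a warning). A JSON summary with per-class and per-subfamily
#' counts (full-length and solo-LTR separately) is written next to the TSV.
#'
#' @param loci data.frame with at least locus_id, chrom, start, end, strand,
#'   classification.
#' @param calls,ages,contexts,structure optional data.frames keyed by
#'   `locus_id` with subfamily calls, age estimates, genomic context and
#'   structure columns.
#' @param path output TSV path; the summary goes to `<path>_summary.json`.
#' @param extra_summary named list merged into the JSON summary (parameter
#'   echo, seeds, ...).
#' @return the merged data.frame, invisibly.
#' @export
write_locus_report <- function(loci, calls = NULL, ages = NULL,
                               contexts = NULL, structure = NULL, path,
                               extra_summary = list()) {
  tab <- loci
  for (part in list(calls, ages, contexts, structure)) {
    if (is.null(part)) next
    missing_ids <- setdiff(tab$locus_id, part$locus_id)
    if (length(missing_ids)) {
      warning("locus ids missing from a stage table: ",
              paste(utils::head(missing_ids, 5), collapse = ", "),
              if (length(missing_ids) > 5) ", ..." else "")
    }
    tab <- merge(tab, part, by = "locus_id", all.x = TRUE, sort = FALSE)
  }
  tab <- tab[order(tab$chrom, tab$start), ]
  rownames(tab) <- NULL
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  summary <- locus_summary(tab)
  summary <- c(summary, extra_summary)
  json_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(tab)
}

## Per-class and per-subfamily counts for the JSON summary.
locus_summary <- function(tab) {
  cls <- table(tab$classification)
  by_subfam <- function(class_name) {
    sub <- tab[tab$classification == class_name, ]
    if (nrow(sub) == 0 || is.null(sub$subfamily)) return(list())
    as.list(table(sub$subfamily[!is.na(sub$subfamily)]))
  }
  list(
    total_loci = nrow(tab),
    class_counts = as.list(cls),
    full_length_by_subfamily = by_subfam("full_length"),
    solo_ltr_by_subfamily = by_subfam("solo_ltr")
  )
}
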