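## End-to-end orchestration: ingest -> assemble -> classify -> flank
## features -> subfamily/chimera -> dating -> phylogeny -> structure scan
## -> report.

#' Pipeline configuration
#'
#' All inputs are file paths; all stage parameters are explicit (unknown
#' arguments are an error). Paths are validated before any stage runs.
#'
#' @param genome genome FASTA.
#' @param rmsk repeat annotation file.
#' @param rmsk_dialect `"rm_out"` or `"ucsc_rmsk"`.
#' @param consensus FASTA of subfamily LTR consensus sequences.
#' @param genes optional gene annotation (BED or GFF3).
#' @param gene_format `"bed"` or `"gff3"`.
#' @param pbs_motifs optional FASTA of pbs motifs for the structure scan.
#' @param out_dir output directory (created if needed); NULL for no files.
#' @param name_pattern repeat-name filter (default "GGERV10").
#' @param max_gap_bp locus merge gap (default 500).
#' @param margin_min chimera margin threshold (default 0.02).
#' @param max_dist unassigned-call distance threshold (default 0.5).
#' @param mu substitutions/site/myr for dating (default 0.0019).
#' @param tsd_kmin,tsd_kmax TSD search range (defaults 3 and 8).
#' @param gc_window_bp GC window (default 20000).
#' @param gene_window_bp gene-density window (default 2e6).
#' @param msa_max_deletion LTR deletion-exclusion threshold (default 50).
#' @param diag_min_len,diag_agreement diagnostic-segment parameters
#'   (defaults 10 and 0.8).
#' @param structure list from [structure_params()].
#' @param n_boot bootstrap replicates for the LTR phylogeny (default 1000).
#' @param seed RNG seed (bootstrap resampling).
#' @param verbose log per-stage record counts (default TRUE).
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(genome, rmsk, rmsk_dialect = c("rm_out",
                                                           "ucsc_rmsk"),
                            consensus, genes = NULL,
                            gene_format = c("gff3", "bed"),
                            pbs_motifs = NULL, out_dir = NULL,
                            name_pattern = "GGERV10", max_gap_bp = 500,
                            margin_min = 0.02, max_dist = 0.5, mu = 0.0019,
                            tsd_kmin = 3, tsd_kmax = 8,
                            gc_window_bp = 20000, gene_window_bp = 2e6,
                            msa_max_deletion = 50, diag_min_len = 10,
                            diag_agreement = 0.8,
                            structure = structure_params(),
                            n_boot = 1000, seed = 1, verbose = TRUE) {
  cfg <- as.list(environment())
  cfg$rmsk_dialect <- match.arg(rmsk_dialect)
  cfg$gene_format <- match.arg(gene_format)
  structure(cfg, class = "pipeline_config")
}

#' Pipeline configuration from a simulated-genome output directory
#'
#' Convenience wrapper wiring the file paths written by [simulate_genome()]
#' into [pipeline_config()].
#'
#' @param sim_paths the `paths` element of a [simulate_genome()] result.
#' @param ... further arguments to [pipeline_config()].
#' @export
pipeline_config_from_sim <- function(sim_paths, ...) {
  pipeline_config(
    genome = sim_paths$genome, rmsk = sim_paths$rmsk_out,
    rmsk_dialect = "rm_out", consensus = sim_paths$consensus_ltr,
    genes = sim_paths$genes_gff3, gene_format = "gff3",
    pbs_motifs = sim_paths$pbs, ...
  )
}

#' Run the full characterization pipeline
#'
#' @param config a [pipeline_config()].
#' @return list with loci, table (per-locus report), calls, ages, contexts,
#'   structure, summary, tree (with bootstrap node labels), supports,
#'   segments, msa, dist. When `config$out_dir` is set, writes report.tsv,
#'   report_summary.json, tree.nwk, dist.tsv, segments.tsv, ltr_msa.fa.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (config$verbose) message("[ervscan] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  ## pre-flight
  for (f in c(config$genome, config$rmsk, config$consensus, config$genes,
              config$pbs_motifs)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("input file not found: ", f)
    }
  }

  ## ingest
  genome <- stage("ingest", read_genome_fasta(config$genome))
  hits <- stage("ingest", read_rmsk(config$rmsk, config$rmsk_dialect,
                                    config$name_pattern))
  consensuses <- stage("ingest", read_genome_fasta(config$consensus))
  genes <- if (!is.null(config$genes)) {
    stage("ingest", read_gene_annotation(config$genes, config$gene_format))
  } else NULL
  pbs_motifs <- if (!is.null(config$pbs_motifs)) {
    unname(stage("ingest", read_genome_fasta(config$pbs_motifs)))
  } else character(0)
  bad_chrom <- setdiff(hits$chrom, names(genome))
  if (length(bad_chrom)) {
    stop("stage 'ingest' failed: annotation chromosome(s) absent from ",
         "genome: ", paste(bad_chrom, collapse = ", "))
  }
  log_msg(nrow(hits), " repeat hits on ", length(genome), " chromosomes")

  ## assemble + classify
  loci <- stage("assemble", assemble_loci(hits, config$max_gap_bp))
  tab <- loci_table(loci)
  log_msg(length(loci), " loci: ",
          paste(names(table(tab$classification)),
                table(tab$classification), collapse = ", "))

  ## LTR extraction
  ltrs <- stage("extract", lapply(loci, extract_ltrs, genome = genome))
  names(ltrs) <- tab$locus_id

  ## flank features
  contexts <- stage("flank_features",
                    flank_feature_table(loci, genome, genes, config))

  ## subfamily + chimera
  calls <- stage("subfamily",
                 subfamily_call_table(loci, ltrs, consensuses, config))

  ## dating
  ages <- stage("dating", age_table(loci, ltrs, config))
  subfam_ages <- stage("dating",
                       subfamily_age_table(loci, ltrs, calls, config))

  ## phylogeny + diagnostic segments over full-length LTRs
  phylo <- stage("phylogeny",
                 ltr_phylogeny(loci, ltrs, calls, config))

  ## structure scan
  struct <- stage("structure_scan",
                  structure_table(loci, genome, pbs_motifs, config))

  ## report
  summary <- pipeline_summary(tab, calls, ages, contexts, struct,
                              subfam_ages, loci, ltrs, config)
  out <- list(loci = loci, calls = calls, ages = ages, contexts = contexts,
              structure = struct, subfamily_ages = subfam_ages,
              tree = phylo$tree, supports = phylo$supports,
              segments = phylo$segments, msa = phylo$msa,
              dist = phylo$dist, summary = summary)
  merged <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    merged <- write_locus_report(tab, calls, ages, contexts, struct,
                                 path = p("report.tsv"),
                                 extra_summary = summary)
    if (!is.null(phylo$tree)) {
      ape::write.tree(phylo$tree, p("tree.nwk"))
      utils::write.table(phylo$dist, p("dist.tsv"), sep = "\t",
                         quote = FALSE, col.names = NA)
    }
    if (!is.null(phylo$segments)) {
      utils::write.table(phylo$segments, p("segments.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (!is.null(phylo$msa)) {
      write_fasta(apply(phylo$msa, 1, chars_to_seq), p("ltr_msa.fa"))
    }
  } else {
    merged <- suppressWarnings(
      Reduce(function(a, b) merge(a, b, by = "locus_id", all.x = TRUE,
                                  sort = FALSE),
             Filter(Negate(is.null), list(tab, calls, ages, contexts,
                                          struct))))
  }
  out$table <- merged
  log_msg("done: ", nrow(tab), " loci reported")
  out
}

## ---- stage helpers -------------------------------------------------------

flank_feature_table <- function(loci, genome, genes, config) {
  rows <- lapply(loci, function(l) {
    tsd <- detect_tsd(l, genome, config$tsd_kmin, config$tsd_kmax)
    gc <- gc_window(l, genome, config$gc_window_bp)
    if (!is.null(genes)) {
      gd <- gene_density(l, genes, config$gene_window_bp,
                         chrom_len = nchar(genome[[l$chrom]]))
      gcl <- genic_context(l, genes)
    } else {
      gd <- list(count = NA_integer_, genes_per_mb = NA_real_)
      gcl <- NA_character_
    }
    data.frame(
      locus_id = l$locus_id, tsd_match = tsd$is_match,
      tsd_len = if (tsd$is_match) tsd$length else NA_integer_,
      tsd_seq = if (tsd$is_match) tsd$left_seq else NA_character_,
      tsd_edge = tsd$edge, gc_pct = gc, gene_count = gd$count,
      genes_per_mb = gd$genes_per_mb, genic_class = gcl,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

subfamily_call_table <- function(loci, ltrs, consensuses, config) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  cls <- vapply(loci, function(l) l$classification, character(1))
  ## gather every callable LTR once, compute distances in one batch
  seqs <- character(0); owner <- character(0); which_ltr <- character(0)
  for (i in seq_along(loci)) {
    if (cls[i] == "truncated") next  # excluded from subfamily analysis
    lt <- ltrs[[i]]
    if (!is.null(lt$ltr5) && !lt$low_quality[["ltr5"]]) {
      seqs <- c(seqs, lt$ltr5); owner <- c(owner, ids[i])
      which_ltr <- c(which_ltr, "ltr5")
    }
    if (cls[i] == "full_length" && !is.null(lt$ltr3) &&
        !lt$low_quality[["ltr3"]]) {
      seqs <- c(seqs, lt$ltr3); owner <- c(owner, ids[i])
      which_ltr <- c(which_ltr, "ltr3")
    }
  }
  empty <- data.frame(
    locus_id = character(), subfamily = character(), chimeric = logical(),
    ltr5_subfamily = character(), ltr5_dist = numeric(),
    ltr5_margin = numeric(), ltr3_subfamily = character(),
    ltr3_dist = numeric(), ltr3_margin = numeric(), call_flag = character(),
    stringsAsFactors = FALSE)
  if (length(seqs) == 0) return(empty)
  D <- subfamily_distances(seqs, consensuses)
  rows <- lapply(seq_along(loci), function(i) {
    if (cls[i] == "truncated") return(NULL)
    sel5 <- which(owner == ids[i] & which_ltr == "ltr5")
    sel3 <- which(owner == ids[i] & which_ltr == "ltr3")
    c5 <- if (length(sel5)) make_call(D[sel5, ], config$max_dist) else NULL
    c3 <- if (length(sel3)) make_call(D[sel3, ], config$max_dist) else NULL
    if (cls[i] == "full_length" && !is.null(c5) && !is.null(c3)) {
      cc <- chimera_call(c5, c3, config$margin_min)
      data.frame(
        locus_id = ids[i], subfamily = cc$locus_subfamily,
        chimeric = cc$chimeric, ltr5_subfamily = c5$name,
        ltr5_dist = c5$distance, ltr5_margin = c5$margin,
        ltr3_subfamily = c3$name, ltr3_dist = c3$distance,
        ltr3_margin = c3$margin, call_flag = cc$flag,
        stringsAsFactors = FALSE)
    } else if (!is.null(c5) || !is.null(c3)) {
      cx <- if (!is.null(c5)) c5 else c3
      data.frame(
        locus_id = ids[i], subfamily = cx$name, chimeric = FALSE,
        ltr5_subfamily = if (!is.null(c5)) c5$name else NA_character_,
        ltr5_dist = if (!is.null(c5)) c5$distance else NA_real_,
        ltr5_margin = if (!is.null(c5)) c5$margin else NA_real_,
        ltr3_subfamily = if (!is.null(c3)) c3$name else NA_character_,
        ltr3_dist = if (!is.null(c3)) c3$distance else NA_real_,
        ltr3_margin = if (!is.null(c3)) c3$margin else NA_real_,
        call_flag = NA_character_, stringsAsFactors = FALSE)
    } else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

age_table <- function(loci, ltrs, config) {
  rows <- lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    if (l$classification != "full_length") return(NULL)
    lt <- ltrs[[i]]
    if (is.null(lt$ltr5) || is.null(lt$ltr3) || any(lt$low_quality))
      return(NULL)
    pair <- align_pair(lt$ltr5, lt$ltr3)
    k <- tryCatch(k2p_distance(pair[1], pair[2]), error = function(e) NULL)
    if (is.null(k)) return(NULL)
    data.frame(locus_id = l$locus_id, P = k$P, Q = k$Q, k2p_d = k$d,
               age_myr = estimate_age(k$d, config$mu),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(), P = numeric(), Q = numeric(),
                      k2p_d = numeric(), age_myr = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## Pair alignment for K2P: equal lengths pass through; otherwise global
## alignment with Biostrings.
align_pair <- function(a, b) {
  if (nchar(a) == nchar(b)) return(c(a, b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

## Per-subfamily rho ages over the full-length, non-chimeric LTR sets.
subfamily_age_table <- function(loci, ltrs, calls, config) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  out <- list()
  for (sf in sort(unique(stats::na.omit(calls$subfamily)))) {
    if (sf %in% c("chimeric", "unassigned")) next
    members <- calls$locus_id[calls$subfamily == sf & !calls$chimeric]
    seqs <- character(0)
    for (id in members) {
      i <- match(id, ids)
      if (loci[[i]]$classification != "full_length") next
      lt <- ltrs[[i]]
      if (any(lt$low_quality)) next
      seqs <- c(seqs, stats::setNames(c(lt$ltr5, lt$ltr3),
                                      paste0(id, c("_5p", "_3p"))))
    }
    if (length(seqs) < 3) next
    msa <- build_subfamily_msa(seqs, config$msa_max_deletion)$msa
    est <- subfamily_age(msa, config$mu)
    out[[length(out) + 1]] <- data.frame(
      subfamily = sf, n_ltrs = length(seqs), age_myr = est$age_myr,
      mean_d = est$mean_d, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(subfamily = character(), n_ltrs = integer(),
                      age_myr = numeric(), mean_d = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

## NJ phylogeny + bootstrap + diagnostic segments over all callable
## full-length LTRs (labelled per-LTR by their own subfamily call).
ltr_phylogeny <- function(loci, ltrs, calls, config) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  seqs <- character(0); labels <- character(0)
  for (i in seq_along(loci)) {
    if (loci[[i]]$classification != "full_length") next
    row <- calls[calls$locus_id == ids[i], , drop = FALSE]
    if (nrow(row) == 0) next
    lt <- ltrs[[i]]
    if (!is.null(lt$ltr5) && !lt$low_quality[["ltr5"]] &&
        !is.na(row$ltr5_subfamily) && row$ltr5_subfamily != "unassigned") {
      seqs <- c(seqs, stats::setNames(lt$ltr5, paste0(ids[i], "_5p")))
      labels <- c(labels, row$ltr5_subfamily)
    }
    if (!is.null(lt$ltr3) && !lt$low_quality[["ltr3"]] &&
        !is.na(row$ltr3_subfamily) && row$ltr3_subfamily != "unassigned") {
      seqs <- c(seqs, stats::setNames(lt$ltr3, paste0(ids[i], "_3p")))
      labels <- c(labels, row$ltr3_subfamily)
    }
  }
  if (length(seqs) < 4 || length(unique(labels)) < 2) {
    return(list(tree = NULL, supports = NULL, segments = NULL, msa = NULL,
                dist = NULL))
  }
  built <- build_subfamily_msa(seqs, config$msa_max_deletion)
  msa <- built$msa
  labels <- labels[match(rownames(msa), names(seqs))]
  segments <- find_diagnostic_segments(msa, labels, config$diag_min_len,
                                       config$diag_agreement)
  D <- k2p_matrix(msa)
  boot <- bootstrap_supports(msa, n_reps = config$n_boot,
                             seed = config$seed)
  list(tree = boot$tree, supports = boot$supports, segments = segments,
       msa = msa, dist = D)
}

structure_table <- function(loci, genome, pbs_motifs, config) {
  rows <- lapply(loci, function(l) {
    if (l$classification != "full_length") return(NULL)
    internal <- extract_internal(l, genome)
    if (is.null(internal)) return(NULL)
    rep <- scan_structure(internal, pbs_motifs, config$structure)
    data.frame(
      locus_id = l$locus_id, gag_state = rep$gag_state,
      pbs_found = rep$pbs_found, pbs_offset = rep$pbs_offset,
      ppt_found = rep$ppt_found, ppt_offset = rep$ppt_offset,
      n_orfs = nrow(rep$orfs), notes = rep$notes, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(locus_id = character(), gag_state = character(),
                      pbs_found = logical(), pbs_offset = integer(),
                      ppt_found = logical(), ppt_offset = integer(),
                      n_orfs = integer(), notes = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## The run summary mirroring the study's table quantities.
pipeline_summary <- function(tab, calls, ages, contexts, struct,
                             subfam_ages, loci, ltrs, config) {
  ids <- vapply(loci, function(l) l$locus_id, character(1))
  cls <- stats::setNames(tab$classification, tab$locus_id)
  full_ids <- tab$locus_id[tab$classification == "full_length"]
  solo_ids <- tab$locus_id[tab$classification == "solo_ltr"]
  ## chimeric loci attributed to the subfamily of their internal-region hit
  full_subfam <- vapply(full_ids, function(id) {
    row <- calls[calls$locus_id == id, , drop = FALSE]
    if (nrow(row) == 0) return(NA_character_)
    if (isTRUE(row$chimeric)) {
      l <- loci[[match(id, ids)]]
      int <- l$components[l$components$role == "INTERNAL", , drop = FALSE]
      if (nrow(int)) return(subfamily_stem(int$repeat_name[1]))
    }
    row$subfamily
  }, character(1))
  solo_subfam <- vapply(solo_ids, function(id) {
    row <- calls[calls$locus_id == id, , drop = FALSE]
    if (nrow(row) == 0) NA_character_ else row$subfamily
  }, character(1))
  ## LTR lengths by per-LTR subfamily over full-length + solo loci
  len_by_sf <- list()
  for (i in seq_along(loci)) {
    if (cls[[ids[i]]] == "truncated") next
    row <- calls[calls$locus_id == ids[i], , drop = FALSE]
    if (nrow(row) == 0) next
    lt <- ltrs[[i]]
    add <- function(sf, s) {
      if (is.na(sf) || sf %in% c("unassigned")) return()
      len_by_sf[[sf]] <<- c(len_by_sf[[sf]], nchar(s))
    }
    if (!is.null(lt$ltr5)) add(row$ltr5_subfamily, lt$ltr5)
    if (!is.null(lt$ltr3)) add(row$ltr3_subfamily, lt$ltr3)
  }
  ctx_full <- contexts[contexts$locus_id %in% full_ids, , drop = FALSE]
  genic <- table(factor(ctx_full$genic_class,
                        levels = c("intergenic", "intronic", "exonic")))
  genic_pct <- if (nrow(ctx_full)) 100 * as.numeric(genic) / nrow(ctx_full)
    else rep(NA_real_, 3)
  names(genic_pct) <- names(genic)
  mean_or_na <- function(x) if (length(x) && any(!is.na(x)))
    mean(x, na.rm = TRUE) else NA_real_
  list(
    total_loci = nrow(tab),
    class_counts = as.list(table(tab$classification)),
    n_after_truncation_filter = sum(tab$classification != "truncated"),
    full_length_by_subfamily = as.list(table(stats::na.omit(full_subfam))),
    solo_ltr_by_subfamily = as.list(table(stats::na.omit(solo_subfam))),
    copy_number_by_subfamily = as.list(table(stats::na.omit(
      c(full_subfam, solo_subfam)))),
    mean_ltr_length_by_subfamily = lapply(len_by_sf, mean),
    mean_flank_gc_pct = mean_or_na(ctx_full$gc_pct),
    mean_genes_per_mb = mean_or_na(ctx_full$genes_per_mb),
    genic_class_pct = as.list(genic_pct),
    tsd_match_pct = if (nrow(contexts))
      100 * mean(contexts$tsd_match[!contexts$tsd_edge]) else NA_real_,
    subfamily_age_myr = stats::setNames(as.list(subfam_ages$age_myr),
                                        subfam_ages$subfamily),
    chimeric_loci = calls$locus_id[calls$chimeric],
    structure_state_pct = if (nrow(struct)) as.list(
      100 * table(factor(struct$gag_state,
                         levels = c("intact", "frameshifted", "absent"))) /
        nrow(struct)) else list(),
    pct_full_length_with_pbs_and_gag = if (nrow(struct))
      100 * mean(struct$gag_state == "intact" & struct$pbs_found)
      else NA_real_,
    parameters = config_echo(config)
  )
}

config_echo <- function(config) {
  keep <- setdiff(names(config), c("verbose"))
  cfg <- unclass(config)[keep]
  cfg$structure <- unclass(cfg$structure)
  cfg
}
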