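## Whole-genome simulation with planted ERV events and full ground truth.
##
## Default configuration mirrors the study conditions: 49 full-length loci
## (two of them chimeric), 483 solo-LTRs and 61 truncated copies (593 total)
## across five subfamilies with the published per-subfamily counts, on an
## AT-rich background (GC 0.41) with genes at 3.83 per Mb. Each event is
## inserted with a duplicated target site; substitution-only evolution keeps
## the dating model exact (an optional indel mode exercises the deletion
## filter).

#' Simulation configuration with study-condition defaults
#'
#' @param n_chroms number of chromosomes (default 5).
#' @param chrom_len chromosome length in bp (default 4e6).
#' @param background_gc background GC fraction (default 0.41).
#' @param full_by_subfamily named counts of full-length events per subfamily
#'   (default 7/13/6/10/13; includes the chimeric events below).
#' @param solo_by_subfamily named counts of solo-LTR events
#'   (default 20/12/111/241/99).
#' @param truncated_by_subfamily named counts of truncated events
#'   (default 3/3/13/29/13).
#' @param chimeras list of chimeric-event specs (ltr5/ltr3/internal
#'   subfamily); each replaces one full-length event of its internal
#'   subfamily. Defaults mirror the two published recombinants
#'   (5' D-like / 3' B-like, and 5' C2-like / 3' C1-like).
#' @param ages_myr named mean insertion age per subfamily (myr); B-like is
#'   youngest at 3.7.
#' @param age_sdlog lognormal spread of per-element ages (default 0.15).
#' @param mu substitutions/site/myr (default 0.0019).
#' @param ts_tv_ratio transition:transversion ratio (default 2).
#' @param tsd_len_range planted TSD lengths (default 4:6).
#' @param gag_state_counts counts of planted structure states over the
#'   full-length events (default intact 31 / frameshifted 15 /
#'   pbs_deficient 3 / absent 0).
#' @param gene_rate_per_mb gene density (default 3.83).
#' @param gene_len_meanlog,gene_len_sdlog lognormal gene lengths (defaults
#'   log(12000), 0.6).
#' @param ltr_indel_prob probability that an LTR copy receives one deletion
#'   (default 0: substitution-only).
#' @param ltr_indel_mean mean deletion length (geometric; default 30).
#' @param min_event_gap minimum bp between planted events (default 2000).
#' @param edge_margin minimum bp between an event and a chromosome end
#'   (default 12000).
#' @param seed RNG seed.
#' @return named list (class `sim_config`). Unknown arguments are an error
#'   by construction.
#' @export
sim_config <- function(n_chroms = 5L,
                       chrom_len = 4e6,
                       background_gc = 0.41,
                       full_by_subfamily = c(GGERV10A = 7L, GGERV10B = 13L,
                                             GGERV10C1 = 6L, GGERV10C2 = 10L,
                                             GGERV10D = 13L),
                       solo_by_subfamily = c(GGERV10A = 20L, GGERV10B = 12L,
                                             GGERV10C1 = 111L,
                                             GGERV10C2 = 241L,
                                             GGERV10D = 99L),
                       truncated_by_subfamily = c(GGERV10A = 3L,
                                                  GGERV10B = 3L,
                                                  GGERV10C1 = 13L,
                                                  GGERV10C2 = 29L,
                                                  GGERV10D = 13L),
                       chimeras = list(
                         list(ltr5 = "GGERV10D", ltr3 = "GGERV10B",
                              internal = "GGERV10B"),
                         list(ltr5 = "GGERV10C2", ltr3 = "GGERV10C1",
                              internal = "GGERV10C2")),
                       ages_myr = c(GGERV10A = 5.0, GGERV10B = 3.7,
                                    GGERV10C1 = 5.5, GGERV10C2 = 6.0,
                                    GGERV10D = 4.5),
                       age_sdlog = 0.15,
                       mu = 0.0019,
                       ts_tv_ratio = 2,
                       tsd_len_range = c(4L, 6L),
                       gag_state_counts = c(intact = 31L, frameshifted = 15L,
                                            pbs_deficient = 3L, absent = 0L),
                       gene_rate_per_mb = 3.83,
                       gene_len_meanlog = log(12000),
                       gene_len_sdlog = 0.6,
                       ltr_indel_prob = 0,
                       ltr_indel_mean = 30,
                       min_event_gap = 2000L,
                       edge_margin = 12000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    all(unlist(cfg[c("full_by_subfamily", "solo_by_subfamily",
                     "truncated_by_subfamily")]) >= 0),
    background_gc >= 0, background_gc <= 1,
    sum(gag_state_counts) == sum(full_by_subfamily),
    length(chimeras) <= sum(full_by_subfamily),
    mu > 0, all(tsd_len_range >= 1)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with planted ERV events
#'
#' Generates the background genome, places genes (with exons), plants every
#' configured event with a duplicated target site, and emits repeat
#' annotation in both RepeatMasker dialects plus the ground-truth table.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes genome.fa,
#'   truth.tsv, rmsk.out, rmsk_ucsc.tsv, genes.bed, genes.gff3,
#'   consensus_ltr.fa, pbs_motifs.fa.
#' @return list with genome (named character), truth (data.frame), hits
#'   (annotation data.frame), genes (data.frame), consensuses, config,
#'   and paths (when written).
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cons <- make_consensus_set(config$seed)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  background <- stats::setNames(
    vapply(chrom_names, function(x)
      random_dna(config$chrom_len, config$background_gc), character(1)),
    chrom_names)
  genes_bg <- place_genes(config, chrom_names)
  plan <- event_plan(config)
  if (nrow(plan) == 0) {
    spliced <- list(genome = background, truth = empty_truth(),
                    hits = empty_hits(), genes = genes_bg)
  } else {
    events <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      events[[i]] <- build_event(plan[i, ], cons, config)
    }
    placed <- place_events(events, background, genes_bg, config)
    spliced <- splice_genome(background, placed, genes_bg)
  }
  truth <- spliced$truth
  hits <- spliced$hits
  genes <- spliced$genes
  out <- list(genome = spliced$genome, truth = truth, hits = hits,
              genes = genes, consensuses = cons, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_fasta(out$genome, p("genome.fa"))
    utils::write.table(truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_rm_out(hits, p("rmsk.out"))
    write_ucsc_rmsk(hits, p("rmsk_ucsc.tsv"))
    write_genes_bed(genes, p("genes.bed"))
    write_genes_gff3(genes, p("genes.gff3"))
    write_fasta(cons$ltr, p("consensus_ltr.fa"))
    write_fasta(c(pbs1 = cons$pbs_motif), p("pbs_motifs.fa"))
    out$paths <- list(
      genome = p("genome.fa"), truth = p("truth.tsv"),
      rmsk_out = p("rmsk.out"), rmsk_ucsc = p("rmsk_ucsc.tsv"),
      genes_bed = p("genes.bed"), genes_gff3 = p("genes.gff3"),
      consensus_ltr = p("consensus_ltr.fa"), pbs = p("pbs_motifs.fa")
    )
  }
  out
}

## ---- internals -----------------------------------------------------------

empty_truth <- function() {
  data.frame(
    locus_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), type = character(),
    subfamily = character(), sf5 = character(), sf3 = character(),
    chimeric = logical(), age_myr = numeric(), tsd_seq = character(),
    tsd_len = integer(), gag_state = character(), ltr5_seq = character(),
    ltr3_seq = character(), stringsAsFactors = FALSE
  )
}

## The per-event plan: type, subfamilies, age, structure state, tsd length.
event_plan <- function(config) {
  rows <- list()
  add <- function(type, sf, ltr5 = sf, ltr3 = sf, chimeric = FALSE) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, subfamily = sf, sf5 = ltr5, sf3 = ltr3,
      chimeric = chimeric, stringsAsFactors = FALSE)
  }
  chim_left <- config$chimeras
  for (sf in names(config$full_by_subfamily)) {
    n <- config$full_by_subfamily[[sf]]
    for (k in seq_len(n)) {
      ## the first events of a chimera's internal subfamily become chimeric
      idx <- which(vapply(chim_left, function(c) c$internal == sf,
                          logical(1)))
      if (length(idx) > 0) {
        spec <- chim_left[[idx[1]]]
        chim_left[[idx[1]]] <- NULL
        add("full_length", sf, spec$ltr5, spec$ltr3, chimeric = TRUE)
      } else {
        add("full_length", sf)
      }
    }
  }
  for (sf in names(config$solo_by_subfamily)) {
    n <- config$solo_by_subfamily[[sf]]
    for (k in seq_len(n)) add("solo_ltr", sf)
  }
  for (sf in names(config$truncated_by_subfamily)) {
    n <- config$truncated_by_subfamily[[sf]]
    for (k in seq_len(n)) add("truncated", sf)
  }
  if (length(rows) == 0) {
    return(data.frame(type = character(), subfamily = character(),
                      sf5 = character(), sf3 = character(),
                      chimeric = logical(), gag_state = character(),
                      age_myr = numeric(), tsd_len = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  plan <- do.call(rbind, rows)
  ## planted structure states over the full-length events, randomized order
  n_full <- sum(plan$type == "full_length")
  states <- rep(names(config$gag_state_counts), config$gag_state_counts)
  plan$gag_state <- NA_character_
  plan$gag_state[plan$type == "full_length"] <- sample(states)
  ## per-element age around the subfamily mean (lognormal, mean-preserving)
  mean_age <- config$ages_myr[plan$subfamily]
  plan$age_myr <- stats::rlnorm(nrow(plan),
                                meanlog = log(mean_age) -
                                  config$age_sdlog^2 / 2,
                                sdlog = config$age_sdlog)
  plan$tsd_len <- sample(seq(config$tsd_len_range[1], config$tsd_len_range[2]),
                         nrow(plan), replace = TRUE)
  plan$strand <- sample(c("+", "-"), nrow(plan), replace = TRUE)
  plan
}

## Build one event: element sequence (element orientation), component layout,
## evolved LTRs, realized divergences.
build_event <- function(ev, cons, config) {
  mu <- config$mu; R <- config$ts_tv_ratio
  comp <- list()  # (name, seq, cons_start, cons_end, div)
  add_comp <- function(name, seq, cs, ce, div) {
    comp[[length(comp) + 1]] <<- list(name = name, seq = seq,
                                      cons_start = cs, cons_end = ce,
                                      div = div)
  }
  ltr5 <- ltr3 <- NA_character_
  if (ev$type == "full_length") {
    p5 <- evolve_seq(cons$ltr[[ev$sf5]], ev$age_myr, mu, R)
    p3 <- evolve_seq(cons$ltr[[ev$sf3]], ev$age_myr, mu, R)
    ltr5 <- maybe_indel(p5$seq, config)
    ltr3 <- maybe_indel(p3$seq, config)
    var <- cons$variants[[ev$gag_state]]
    int <- evolve_seq(var$seq, ev$age_myr, mu, R,
                      protect = var$protect, orf_ranges = var$orf_ranges)
    add_comp(paste0(ev$sf5, "-LTR"), ltr5, 1L, nchar(cons$ltr[[ev$sf5]]),
             100 * hamming_safe(ltr5, cons$ltr[[ev$sf5]]))
    add_comp(paste0(ev$subfamily, "-int"), int$seq, 1L, nchar(var$seq),
             100 * hamming(int$seq, var$seq) / nchar(var$seq))
    add_comp(paste0(ev$sf3, "-LTR"), ltr3, 1L, nchar(cons$ltr[[ev$sf3]]),
             100 * hamming_safe(ltr3, cons$ltr[[ev$sf3]]))
  } else if (ev$type == "solo_ltr") {
    p <- evolve_seq(cons$ltr[[ev$subfamily]], ev$age_myr, mu, R)
    ltr5 <- maybe_indel(p$seq, config)
    add_comp(paste0(ev$subfamily, "-LTR"), ltr5, 1L,
             nchar(cons$ltr[[ev$subfamily]]),
             100 * hamming_safe(ltr5, cons$ltr[[ev$subfamily]]))
  } else {  # truncated: one LTR plus a partial internal region
    p <- evolve_seq(cons$ltr[[ev$subfamily]], ev$age_myr, mu, R)
    ltr <- maybe_indel(p$seq, config)
    int_full <- evolve_seq(cons$internal, ev$age_myr, mu, R)$seq
    part_len <- round(0.6 * nchar(int_full))
    n_int <- nchar(int_full)
    if (stats::runif(1) < 0.5) {
      ## 5' LTR retained, internal truncated at its 3' side
      ltr5 <- ltr
      part <- substr(int_full, 1, part_len)
      add_comp(paste0(ev$subfamily, "-LTR"), ltr, 1L,
               nchar(cons$ltr[[ev$subfamily]]),
               100 * hamming_safe(ltr, cons$ltr[[ev$subfamily]]))
      add_comp(paste0(ev$subfamily, "-int"), part, 1L, part_len,
               100 * hamming(part, substr(cons$internal, 1, part_len)) /
                 part_len)
    } else {
      ltr3 <- ltr
      part <- substr(int_full, n_int - part_len + 1, n_int)
      add_comp(paste0(ev$subfamily, "-int"), part,
               n_int - part_len + 1L, n_int,
               100 * hamming(part, substr(cons$internal,
                                          n_int - part_len + 1, n_int)) /
                 part_len)
      add_comp(paste0(ev$subfamily, "-LTR"), ltr, 1L,
               nchar(cons$ltr[[ev$subfamily]]),
               100 * hamming_safe(ltr, cons$ltr[[ev$subfamily]]))
    }
  }
  elem <- paste0(vapply(comp, function(x) x$seq, character(1)),
                 collapse = "")
  list(plan = ev, components = comp, elem = elem, elem_len = nchar(elem),
       ltr5 = ltr5, ltr3 = ltr3)
}

## Hamming divergence tolerant of an indel-shortened copy.
hamming_safe <- function(seq, cons) {
  n <- min(nchar(seq), nchar(cons))
  hamming(substr(seq, 1, n), substr(cons, 1, n)) / nchar(cons)
}

maybe_indel <- function(seq, config) {
  if (config$ltr_indel_prob <= 0 ||
      stats::runif(1) >= config$ltr_indel_prob) return(seq)
  len <- nchar(seq)
  dlen <- min(stats::rgeom(1, 1 / config$ltr_indel_mean) + 1L, len - 20L)
  start <- sample.int(len - dlen - 10L, 1) + 5L
  paste0(substr(seq, 1, start - 1), substr(seq, start + dlen, len))
}

## Gene placement on the background (background coordinates, 0-based).
place_genes <- function(config, chrom_names) {
  rows <- list()
  gid <- 0L
  for (chrom in chrom_names) {
    ## conditioned-Poisson placement: the expected count at the configured
    ## rate, uniform positions, overlap resolved by redrawing (keeps the
    ## realized gene density at the nominal rate)
    n <- round(config$gene_rate_per_mb * config$chrom_len / 1e6)
    if (n == 0) next
    lens <- pmax(500, round(stats::rlnorm(n, config$gene_len_meanlog,
                                          config$gene_len_sdlog)))
    placed <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      g_start <- NA
      for (try in seq_len(200)) {
        s <- sample.int(config$chrom_len - lens[i] - 1, 1)
        if (nrow(placed) == 0 ||
            !any(placed[, 1] < s + lens[i] & placed[, 2] > s)) {
          g_start <- s
          break
        }
      }
      if (is.na(g_start)) next  # crowded; give up on this gene
      g_end <- g_start + lens[i]
      placed <- rbind(placed, c(g_start, g_end))
      gid <- gid + 1L
      id <- sprintf("gene_%04d", gid)
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, start = g_start, end = g_end, strand = "+",
        gene_id = id, feature_kind = "gene", stringsAsFactors = FALSE)
      ## exons inside the gene
      n_ex <- 1L + stats::rpois(1, 2)
      ex_len <- round(stats::runif(n_ex, 150, 400))
      ex_start <- sort(sample.int(max(g_end - g_start - max(ex_len), 1),
                                  n_ex)) + g_start
      prev_end <- -1
      for (e in seq_len(n_ex)) {
        es <- ex_start[e]; ee <- min(es + ex_len[e], g_end)
        if (es <= prev_end || ee <= es) next
        prev_end <- ee
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, start = es, end = ee, strand = "+",
          gene_id = id, feature_kind = "exon", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), feature_kind = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

## Choose non-overlapping insertion points (background coordinates), at
## least min_event_gap apart, away from chromosome ends and outside exons,
## with a non-homopolymer target k-mer.
place_events <- function(events, background, genes_bg, config) {
  chrom_names <- names(background)
  chrom_len <- nchar(background[[1]])
  exons <- genes_bg[genes_bg$feature_kind == "exon", , drop = FALSE]
  reserved <- stats::setNames(
    lapply(chrom_names, function(x) matrix(numeric(0), ncol = 2)),
    chrom_names)
  placed <- vector("list", length(events))
  order_ix <- sample(length(events))  # placement order independent of plan
  for (i in order_ix) {
    ev <- events[[i]]
    k <- ev$plan$tsd_len
    ok <- FALSE
    for (try in seq_len(2000)) {
      chrom <- sample(chrom_names, 1)
      p <- sample.int(chrom_len - 2L * config$edge_margin, 1) +
        config$edge_margin
      span <- c(p - config$min_event_gap, p + ev$elem_len +
                  config$min_event_gap)
      res <- reserved[[chrom]]
      if (nrow(res) > 0 &&
          any(res[, 1] < span[2] & res[, 2] > span[1])) next
      ex <- exons[exons$chrom == chrom, , drop = FALSE]
      if (nrow(ex) > 0 &&
          any(ex$start < p + ev$elem_len & ex$end > p - k)) next
      tsd <- substr(background[[chrom]], p, p + k - 1)
      if (length(unique(seq_to_chars(tsd))) == 1) next  # homopolymer
      reserved[[chrom]] <- rbind(res, span)
      placed[[i]] <- c(ev, list(chrom = chrom, p = p, tsd = tsd))
      ok <- TRUE
      break
    }
    if (!ok) stop("cannot place events: genome too crowded")
  }
  placed
}

## Splice all events into the background, duplicating the target site, and
## emit final-coordinate truth, annotation, and lifted gene models.
splice_genome <- function(background, placed, genes_bg) {
  chrom_names <- names(background)
  truth_rows <- list(); hit_rows <- list(); gene_shift <- list()
  genome <- background
  for (chrom in chrom_names) {
    evs <- Filter(function(e) e$chrom == chrom, placed)
    if (length(evs) == 0) { gene_shift[[chrom]] <- cbind(0, 0); next }
    evs <- evs[order(vapply(evs, function(e) e$p, numeric(1)))]
    bg <- background[[chrom]]
    pieces <- character(0)
    prev <- 1L
    shift <- 0L
    shifts <- matrix(0, nrow = length(evs), ncol = 2)  # (bg pos, added)
    for (j in seq_along(evs)) {
      e <- evs[[j]]
      k <- nchar(e$tsd)
      elem_genomic <- if (e$plan$strand == "-") revcomp(e$elem) else e$elem
      pieces <- c(pieces, substr(bg, prev, e$p + k - 1L), elem_genomic)
      start0 <- (e$p + k - 1L) + shift  # 0-based element start
      end0 <- start0 + e$elem_len
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        locus_id = NA_character_, chrom = chrom, start = start0, end = end0,
        strand = e$plan$strand, type = e$plan$type,
        subfamily = e$plan$subfamily, sf5 = e$plan$sf5, sf3 = e$plan$sf3,
        chimeric = e$plan$chimeric, age_myr = e$plan$age_myr,
        tsd_seq = e$tsd, tsd_len = k, gag_state = e$plan$gag_state,
        ltr5_seq = e$ltr5, ltr3_seq = e$ltr3, stringsAsFactors = FALSE)
      hit_rows[[length(hit_rows) + 1]] <-
        component_hits(e, chrom, start0, length(truth_rows))
      shift <- shift + k + e$elem_len
      shifts[j, ] <- c(e$p, k + e$elem_len)
      prev <- e$p
    }
    pieces <- c(pieces, substr(bg, prev, nchar(bg)))
    genome[[chrom]] <- paste0(pieces, collapse = "")
    gene_shift[[chrom]] <- shifts
  }
  truth <- do.call(rbind, truth_rows)
  ## ids in coordinate order
  ord <- order(truth$chrom, truth$start)
  truth <- truth[ord, ]
  truth$locus_id <- sprintf("sim_%04d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  hits <- do.call(rbind, hit_rows)
  hits <- hits[order(hits$chrom, hits$start), ]
  rownames(hits) <- NULL
  ## lift gene models through the insertions
  genes <- genes_bg
  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      sh <- gene_shift[[genes$chrom[i]]]
      if (is.null(sh) || nrow(sh) == 0) next
      genes$start[i] <- genes$start[i] + sum(sh[sh[, 1] <= genes$start[i], 2])
      genes$end[i] <- genes$end[i] + sum(sh[sh[, 1] <= genes$end[i], 2])
    }
  }
  list(genome = genome, truth = truth, hits = hits, genes = genes)
}

## Annotation rows for one event at its final genomic position.
component_hits <- function(e, chrom, start0, linkage_num) {
  comps <- e$components
  offs <- cumsum(c(0, vapply(comps, function(x) nchar(x$seq), numeric(1))))
  L <- e$elem_len
  rows <- lapply(seq_along(comps), function(ci) {
    cmp <- comps[[ci]]
    off <- offs[ci]; l <- nchar(cmp$seq)
    if (e$plan$strand == "+") {
      gs <- start0 + off
    } else {
      gs <- start0 + L - off - l
    }
    data.frame(
      chrom = chrom, start = gs, end = gs + l, strand = e$plan$strand,
      repeat_name = cmp$name, repeat_class = "LTR/ERVL",
      cons_start = cmp$cons_start, cons_end = cmp$cons_end,
      divergence_pct = round(cmp$div, 2),
      linkage_id = sprintf("%d", linkage_num), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write gene models to BED4 (genes only)
#' @param genes data.frame with feature_kind.
#' @param path output path.
#' @export
write_genes_bed <- function(genes, path) {
  g <- genes[genes$feature_kind == "gene", , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", g$chrom, g$start, g$end, g$gene_id),
             path)
  invisible(path)
}

#' Write gene models (genes + exons) to GFF3
#' @inheritParams write_genes_bed
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$feature_kind == "gene") {
      attr <- sprintf("ID=%s", g$gene_id)
    } else {
      attr <- sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, i, g$gene_id)
    }
    lines <- c(lines, sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, g$feature_kind, g$start + 1L, g$end,
                              g$strand, attr))
  }
  writeLines(lines, path)
  invisible(path)
}
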