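---
title: "Characterizing endogenous retrovirus loci with ervscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing endogenous retrovirus loci with ervscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Endogenous retroviruses (ERVs) are germ-line remnants of retroviral
infections. A freshly integrated provirus carries two identical long
terminal repeats (LTRs) around an internal *gag–pro–pol–env* region, plus a
short target-site duplication (TSD) of host DNA on each side. Over time
three things happen that this package measures:

* the two LTRs accumulate substitutions independently, so their divergence
  clocks the insertion;
* homologous recombination between the LTRs excises the internal region,
  leaving a solo-LTR;
* substitutions and indels erode the internal genes (frameshifted or lost
  *gag*, degraded primer-binding site), so structure reflects decay.

`ervscan` rebuilds this natural history for a young avian ERV family
(GGERV10-like, five LTR subfamilies) starting from nothing but a genome
FASTA, RepeatMasker-style repeat annotation, gene annotation, and
per-subfamily LTR consensus sequences. A synthetic-genome generator plants
loci with complete ground truth so the whole pipeline is testable offline.

## Pipeline stages and their models

### Locus assembly and classification

RepeatMasker fragments one element into `-LTR` and `-int` hits; fragments of
one element usually share the annotation linkage ID. `assemble_loci()`
groups hits by linkage ID and then merges neighboring groups on the same
strand and subfamily stem when their gap is at most `max_gap_bp` (default
500 bp). The published census was curated by manual inspection whose rules
are not recorded; the gap rule is our automated stand-in and is deliberately
conservative and configurable. Classification is a total function of the
role pattern: 5' LTR + internal + 3' LTR is `full_length`; a lone LTR is
`solo_ltr`; everything else (including a two-LTR locus whose internal region
was deleted, and irregular layouts such as an LTR between two internal
fragments) is `truncated`. Truncated loci stay in the report but are
excluded from subfamily analysis and dating, mirroring the study design.

### Flank features

* **TSD** (`detect_tsd`): the longest k in 3–8 nt with an exact match
  between the k-mers immediately flanking the locus. Exact matching with
  "longest wins" is used because the source census reports TSDs without
  stating a matching rule; the range covers the 4–6 nt the generator
  plants with the chance-match floor k = 3.
* **Terminal motifs** (`check_tir`): the family's fixed LTR ends
  TGTTG…CAACA (mutual reverse complements), tested as case-insensitive
  prefix/suffix.
* **GC** (`gc_window`): GC% over 10 kb per side (20 kb total), element
  excluded, N bases excluded from the denominator, windows clipped at
  chromosome ends with the realized length used.
* **Gene density** (`gene_density`): genes overlapping 1 Mb per side
  (any-overlap rule), converted to genes/Mb using the realized (clipped)
  flank length. Using the realized length keeps the density unbiased near
  chromosome ends; on an unclipped window it reduces to count/2 exactly.
  The source text is ambiguous about whether "2 Mb" is total or per side;
  we read it as total (1 Mb per side), configurable.
* **Genic context** (`genic_context`): exonic ≻ intronic ≻ intergenic by
  any-overlap precedence.

### Subfamily assignment and chimeras

Each LTR is aligned against every consensus (global alignment with free end
gaps) and scored `1 - matches / mean(sequence lengths)` (Biostrings PID4).
We deliberately do not use identity over aligned columns alone: with free
end gaps a short spurious overlap of a random sequence can reach high
column-wise identity, and the unassigned threshold (distance > 0.5) would
never fire. Normalizing by sequence length preserves the estimand for
near-full-length LTRs — the use case — and pushes unrelated sequences
toward 1.

A full-length locus is **chimeric** when its two LTRs are confidently
assigned to different consensuses, both with margin (runner-up minus best)
at least `margin_min = 0.02`. This is the template-switching signature of
the two published recombinant proviruses, one with a D-like 5' LTR on a
B-type body and one with a C2-like 5' LTR and C1-like 3' LTR. With
consensuses at least ~5% apart and LTR copies a few percent diverged, the
margins at stake are an order of magnitude above 0.02, which is why the
detector can be both fully sensitive and specific on planted data.

Diagnostic segments (`find_diagnostic_segments`) recover the
subfamily-partitioning alignment regions: a column is informative when each
subfamily has at least 80% internal agreement on a majority residue (gap is
a state) and the majorities split the subfamilies into two or more groups;
maximal runs of at least 10 informative columns with the same partition
become segments. `present_in` is the gap-free side; for pure substitution
partitions the smaller group is reported as carrying the derived state. The
80% agreement default tolerates within-subfamily polymorphism without
erasing real regions; both knobs are parameters.

Multiple alignment is delegated to the mafft program (progressive
alignment); LTR copies more than 50 bp shorter than the subfamily median
are excluded beforehand and reported, following the published exclusion
rule for heavily deleted LTRs.

### Dating

`k2p_distance` implements the Kimura 2-parameter closed form
`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with pairwise deletion of gap/N
columns (the common MEGA-style default). Element age is `d / (2*mu)`
because both LTRs mutate independently after insertion. Subfamily age uses
a rho-style proxy for the published network analysis, whose exact procedure
is not reproducible from the text: build the column-majority consensus of
the subfamily's full-length LTRs and average the K2P distance of each LTR
to it, then divide by `mu` (one lineage's accumulation since the ancestor).
The default rate is `mu = 0.0019`/site/myr (0.19%/myr as used for the
published age estimates); the 0.20–0.26% range quoted elsewhere in the
source is accepted through the `mu` argument.

A practical caveat worth stating: with ~12 full-length elements per
subfamily, ~380-nt LTRs and this mutation rate, a subfamily-age estimate is
informed by only ~60–100 expected substitutions, so its Monte-Carlo
coefficient of variation is ~10–13%. That spread is a property of the study
conditions, not of the estimator; recovery tests therefore use a 20%
band for subfamily ages and average replicate batches for element-age
recovery.

### Phylogeny

`nj_tree` is a from-scratch neighbor-joining implementation (deterministic
lowest-index tie-break). Negative branch lengths are clamped to zero with
the deficit moved to the sister branch, preserving the path length between
the joined taxa. On additive matrices it reproduces all pairwise path
lengths to 1e-9, which the tests exploit as an exact oracle.
`bootstrap_supports` resamples alignment columns, rebuilds the tree, and
counts, for each internal bipartition of the reference tree, the percentage
of replicates containing it (default 1000 replicates, seeded). Bipartitions
are canonicalized by the side not containing the alphabetically first tip,
independent of each replicate's join order.

### Structure scan

`scan_structure` is an explicit, alignment-free simplification of
retroviral-motif chain reconstruction; only the output categories of the
published analysis are reproduced, and every threshold is a parameter with
a non-authoritative default: pbs = best match of a user-supplied motif with
at most 1 mismatch starting within 30 bp of the 5' LTR; PPT = a window of
at least 10 nt with at least 90% purines within 30 bp of the 3' LTR; ORFs =
maximal stop-free runs of at least 100 codons in all six frames. *gag* is
`intact` if an ORF of at least 400 codons starts in the 5' third of the
internal region; `frameshifted` if two sub-threshold ORFs in different
frames jointly cover a gag-sized span with a gap of at most 30 nt (overlap
allowed — a 1-bp insertion makes the two reading frames overlap around the
junction); otherwise `absent`.

## The synthetic genome generator

`sim_config()` defaults are the study conditions: 49 full-length (two
chimeric), 483 solo-LTR and 61 truncated insertions with the published
per-subfamily counts; five consensuses with the published LTR lengths
(295/382/329/336/332 nt), TGTTG…CAACA ends, subfamily-specific deletion
blocks, and a 24-nt tandem duplication private to the A-like subfamily;
structure states 31 intact / 15 frameshifted / 3 pbs-deficient; background
GC 0.41 and 3.83 genes/Mb (the published flanking-region values);
`mu = 0.0019`, transition:transversion 2:1, TSD lengths 4–6 nt. Mean
subfamily ages are published only for the B-like subfamily (3.7 myr, the
youngest); the remaining defaults (A 5.0, C1 5.5, C2 6.0, D 4.5 myr) were
fixed once as plausible for a family that expanded over the last few
million years, with B youngest. Per-element ages are lognormal around the
subfamily mean (sdlog 0.15, mean-preserving).

The genome is 5 chromosomes x 4 Mb (20 Mb). This is the smallest size that
carries 593 events at a 2-kb minimum spacing while leaving the 2-Mb
gene-density windows mostly unclipped; all statistics are window-local, so
a larger genome changes only runtime.

Generator choices that exist to keep planted truth exactly recoverable
(and that real data would not honor):

* substitution-only evolution by default, so LTR pairs stay alignment-free
  and the dating model is exact; an optional indel mode
  (`ltr_indel_prob`) produces deletion-bearing copies to exercise the
  50-bp exclusion filter;
* planted pbs/PPT motifs and frameshift-junction stops are excluded from
  mutation, and substitutions that would create a stop inside a
  planted-intact gag ORF are redrawn — otherwise neutral evolution would
  stochastically flip planted structure states and "100% recovery" would
  be unattainable by any scanner;
* target sites whose duplicated k-mer is a homopolymer are rejected,
  because a homopolymer TSD extends the longest-equal-flank match beyond
  the planted length by construction;
* genes are placed at the exact expected count with uniform positions
  (conditioned-Poisson) and overlap resolved by redrawing, so the realized
  gene density equals the nominal rate; a Poisson-drawn total count would
  fluctuate ~11% on 20 Mb and make rate recovery ill-posed at this scale;
* insertion points avoid exons (a minimal stand-in for purifying
  selection), so planted loci are intergenic or intronic, as in the
  published census.

Consequently, passing tests demonstrate correct bookkeeping, correct
estimators under the stated models, and exact recovery of planted signal;
they do not demonstrate robustness to nested insertions, segmental
duplications, assembly gaps, or alignment ambiguity in real genomes.

## Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open; converters live only in
readers and writers (RepeatMasker `.out` and GFF3 are 1-based inclusive on
disk, UCSC rmsk and BED are 0-based). Strand `C` means minus. K2P is
undefined (error) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`, or when no valid
columns remain. GC of an all-N window is NA. Loci with more than 20% N in
an LTR are flagged and excluded from alignments. Majority/tie decisions
(consensus building, diagnostic-segment states, NJ Q-criterion) break
deterministically toward the lexicographically or index-first option, so
every run is reproducible; all stochastic steps (generator, bootstrap) are
seeded and the seeds are echoed into the run summary.

## Known limitations

* The locus merge rule is a heuristic replacement for manual curation;
  pathological nesting of elements can split or join loci differently.
* The rho-style subfamily age is a documented proxy, not a reimplementation
  of the published network procedure; whether that procedure divided by mu
  or 2*mu is unrecorded, and both conventions are reachable via arguments.
* The structure scanner's thresholds cannot be validated against the
  published per-locus structure table without the real genome; only the
  category definitions are reproduced.
* Transcription-factor-site scanning, PCR design, and population
  genotyping from the original study are out of scope, as is de novo
  subfamily discovery.

## Reproducing the study-scale numbers

The `analysis/` scripts run the four steps (simulate, characterize, date,
structure/environment) and write their tables under `results/`;
`scripts/acceptance.R` performs the same end-to-end run from scratch and
writes the headline quantities as JSON. Both complete in a few minutes on
one CPU; the only heavyweight steps are the 20-Mb genome build (~10 s) and
the 1000-replicate bootstrap over ~100 LTRs (~1–2 min).
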