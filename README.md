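# ervscan

Characterization of endogenous retrovirus (ERV) loci from repeat
annotation, built around the natural history of a young avian ERV family
(GGERV10-like, five LTR subfamilies): assemble loci from RepeatMasker-style
hits, classify them as full-length proviruses, solo-LTRs, or truncated
copies, detect target-site duplications (TSDs) and the fixed LTR terminal
motifs TGTTG…CAACA, assign each LTR to a subfamily consensus and flag
chimeric (recombinant) proviruses, date insertions from 5′–3′ LTR
divergence, profile the flanking genomic environment, scan proviral
structure (*gag* ORF integrity, primer-binding site, polypurine tract), and
build a bootstrapped neighbor-joining LTR phylogeny. A synthetic-genome
generator plants all of this with full ground truth, so the entire pipeline
is testable without downloading a genome.

It is aimed at people studying transposable-element landscapes —
annotating an ERV family in a new assembly, dating its expansion, or
building a planted-truth benchmark for an annotation workflow.

## The models at the core

* **Insertion dating.** At integration the two LTRs are identical; both
  then accumulate neutral substitutions. With the Kimura 2-parameter
  distance `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` (P, Q = transition and
  transversion proportions; gap/N columns dropped pairwise), the element
  age is `t = d / (2μ)` with `μ = 0.0019` substitutions/site/myr by
  default. A subfamily's age uses a rho-style estimator: mean K2P distance
  of its full-length LTRs to their column-majority consensus, divided
  by `μ`.
* **Solo-LTR formation.** Recombination between a provirus's LTRs leaves a
  single LTR behind; classification separates these from truncated decay
  products, which are excluded from dating and subfamily analysis.
* **Chimera detection.** A full-length locus whose 5′ and 3′ LTRs are
  confidently assigned to different subfamily consensuses (both margins
  ≥ 0.02 under a length-normalized, end-gap-free alignment distance) is
  called chimeric — the signature of template switching between
  proviruses.
* **Phylogeny.** From-scratch neighbor joining (negative branches clamped,
  deficit shifted to the sister edge) over the K2P matrix of all
  full-length LTRs, with seeded column-resampling bootstrap supports
  (1000 replicates by default).

## Worked example

The `analysis/` directory holds the four study steps as numbered scripts.
Step 1 builds the default 20-Mb study genome: 593 planted insertions — 49
full-length (two chimeric), 483 solo-LTRs, 61 truncated — across five
subfamilies with published LTR lengths, GC-0.41 background, 3.83 genes/Mb:

```sh
Rscript analysis/01_simulate_genome.R
Rscript analysis/02_characterize_loci.R
```

prints (abridged):

```
loci: 593 total = 49 full-length + 483 solo-LTR + 61 truncated
after excluding truncated copies: 532 loci in 5 subfamilies
copy numbers: GGERV10A=27, GGERV10B=25, GGERV10C1=117, GGERV10C2=251, GGERV10D=112
chimeric proviruses: locus_0162, locus_0426
TSD detected at 3-8 nt for 100.0% of loci
```

i.e. the pipeline recovers the planted census exactly: every locus found
and classified correctly, both recombinants flagged, every target-site
duplication recovered at its planted length. Step 3 dates the insertions
and builds the LTR tree:

```
  subfamily n_ltrs age_myr   mean_d
1  GGERV10A     14    5.29 0.010060
2  GGERV10B     24    4.23 0.008031
3 GGERV10C1     12    5.52 0.010490
4 GGERV10C2     18    6.43 0.012210
5  GGERV10D     26    4.25 0.008069
youngest subfamily: GGERV10B at 4.23 myr
  GGERV10A: 14 LTRs, monophyletic: TRUE
  ...
```

`age_myr` is the rho estimate from `mean_d` (K2P to the subfamily
consensus) at μ = 0.0019/site/myr; the B-like subfamily comes out youngest,
and every subfamily's LTRs form a clean clade in the NJ tree (the chimeric
proviruses' two LTRs landing in different clades, as they should). With
~12 elements per subfamily these ages carry ~10–13% Monte-Carlo spread —
a property of the sample size, not the estimator. Step 4 summarizes
structure and environment:

```
31/49 (63.3%) full-length proviruses retain pbs + intact gag
15 (30.6%) carry a frameshifted gag; 3 lack a usable pbs
             metric value
1 mean_flank_gc_pct 41.22
2 mean_genes_per_mb  3.91
3    pct_intergenic 95.92
```

Each script writes its tables under `results/`.

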