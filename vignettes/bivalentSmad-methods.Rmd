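---
title: "Methods: Smad2/3 targets and bivalent chromatin resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Smad2/3 targets and bivalent chromatin resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

TGF-β priming of bone-marrow-derived macrophages (BMMs) changes which
genes respond to RANKL during osteoclast differentiation. This package
implements the integrative screen that nominates effector genes of that
priming: genes that (i) are bound by Smad2/3 near their promoter, (ii)
carry a bivalent H3K4me3(+)/H3K27me3(+) promoter that resolves to
H3K4me3-only upon TGF-β, and — as optional additional filters — (iii) are
transcriptionally induced by TGF-β and repressed during the RANKL time
course. *Nedd9* is the archetype of a gene satisfying all four, and the
synthetic-data generator plants a "Nedd9-like" truth class so the whole
chain can be validated end to end against known ground truth.

The pipeline stages are:

1. **Binned coverage.** Aligned read intervals are assigned to fixed
   `bin_size` (default 100 bp) bins by their midpoint. No strand shift or
   fragment extension is applied; at this resolution the midpoint rule is
   adequate, and it keeps binning a pure counting operation.
2. **Signal ratio.** The "peak signal ratio" of a ChIP track is its
   library-size-normalized bin density over a reference density. With an
   input library, `ratio = ((chip + p)/lib_chip) / ((input + p)/lib_input)`
   with pseudocount `p = 1` read per bin. Without one, the reference is a
   flat background estimated from the ChIP track itself.
3. **Peak calling.** Maximal runs of bins at or above a ratio threshold
   (8 for Smad2/3 and H3K4me3, 5 for H3K27me3), merged across gaps up to
   `merge_gap` and filtered to at least `min_width`. The summit is the
   centre of the maximum-ratio bin, leftmost on ties, so output is fully
   deterministic.
4. **Peak-to-gene assignment.** A gene is a Smad2/3 target if a peak
   *summit* falls in the strand-oriented window from 10 kb upstream of the
   TSS to the end of the first intron (gene end for intronless models);
   a gene is K4(+)/K27(+) in a condition if a mark summit falls within
   ±1 kb of the TSS. All window bounds are inclusive.
5. **Chromatin-state transitions.** K4/K27 status before and after TGF-β
   yields one of 16 transition labels; the label of interest is
   `K4+K27+ -> K4+K27-` (bivalent resolution).
6. **Expression.** Array intensities are normalized per array to mean
   100, probes must exceed 70 (strictly) at some timepoint to be kept,
   and fold change at each timepoint is taken relative to 0 h with
   strict >2 / <0.5 up/down cutoffs.
7. **Enrichment statistics.** 2×2 fold enrichment with Pearson's
   chi-square (df = 1, no continuity correction by default), and the
   GSEA running enrichment score over ranked fold-change lists with a
   gene-set-label permutation p-value.
8. **Candidate selection.** By default the intersection of (i) and (ii);
   flags add (iii).

## Coordinate conventions

Internally all intervals are `GRanges`/`IRanges`, i.e. 1-based closed
coordinates, the native convention of the R genomics stack. BED and
bedGraph input/output (0-based half-open) are converted only at the
readers and writers, so no other code ever reasons about conventions.
The TSS is `start` on `+` genes and `end` on `-` genes; "upstream" means
lower coordinates on `+` and higher on `-`, and all windows are built in
transcription orientation before being clipped to chromosome bounds.
One pre-collapsed model per gene is required; isoform resolution is out
of scope, and which transcript represents a gene is the caller's choice.

## Background estimation for the signal ratio

The ratio threshold is the analysis's only peak-calling knob, so the
denominator matters. When no input library is available the obvious
estimator — the genome-wide *mean* bin count — is biased upward by the
very enrichment being detected: with enriched regions covering a few
percent of a small genome, the mean can rise 25% or more, silently
tightening the effective threshold. `ratio_track()` therefore defaults
to the genome-wide *median* bin count, which is unaffected as long as
enriched bins are a minority, and exposes `background = "mean"` for the
naive estimator and `control =` for a true input track. With Poisson
background at 2 reads/bin, a 10-fold enriched region and threshold 8,
the median-based ratio detects ~90% of enriched bins while a background
bin exceeds the threshold with probability ~10⁻⁹, so false peaks are
essentially absent at desk scale.

## Peak geometry defaults

`merge_gap` and `min_width` default to 300 bp. ChIP fragments are
200–300 bp, so features narrower than a fragment are not resolvable and
sub-fragment gaps between above-threshold runs are sampling noise, not
biology. In simulation these values let one planted 1-kb region surface
as one called peak (rather than a main call plus stray 1–2-bin
fragments at the edges) without merging distinct planted regions, which
sit many kilobases apart. Both are per-call arguments.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which the pipeline is validated.

* **Genome.** Two 2-Mb chromosomes carrying 100 non-overlapping genes
  with 2–5 exons (exons 200–500 bp, introns 500–2000 bp) on both strands.
  The minimum intergenic gap defaults to 12 kb so that every 10-kb
  promoter window lies in its own intergenic space: a planted peak is
  then attributable to exactly one gene, which is what makes exact
  candidate-set recovery a meaningful test. (Dense configurations — e.g.
  100 genes on 1 Mb with 2-kb gaps for peak-level benchmarks — are
  available by argument; there, window collisions are accepted because
  only peak coordinates are scored.)
* **Truth classes.** Each gene belongs to one of eight classes fixing
  Smad2/3 binding, the K4/K27 state before/after TGF-β, a TGF-β
  expression fold and a RANKL profile (see `truth_classes()`). The
  `nedd9_like` class (10% of genes) is the planted positive: target ∧
  bivalent→K4-only ∧ 4-fold TGF-β induction ∧ RANKL repression to 0.25
  at 72 h. The other classes cover targets without resolution,
  resolution without binding, RANKL repression without binding, silent
  genes below the expression floor, and stable K4/K27 configurations,
  so each selection criterion has genes that fail exactly one of them.
* **Reads.** Uniform Poisson background at 0.02 reads/bp plus
  `(fold − 1) ×` background inside planted regions (default fold 15;
  Smad2/3 regions are 1 kb and histone-mark regions 2 kb, centred on the
  TSS). Reads are fixed 50-bp intervals from sampled midpoints — no
  fragment-size model, since only binned coverage is consumed.
  `total_sequenced` is back-computed so the mapped fraction is 0.717.
* **Expression.** Per-probe lognormal baselines (median ≈ 250, log-sd
  0.4; ~10% of secondary probes and all probes of silent genes fall
  below the 70 floor), multiplied by the class effect and by lognormal
  noise with σ = 0.15 per measurement — typical single-array
  reproducibility. Two probes per gene exercise the
  highest-mean-intensity collapse rule.
* **Determinism.** Every output is a pure function of (config, seed);
  each (module, sample) pair has its own RNG stream derived from the
  master seed by a stable string hash, so adding a sample never perturbs
  the others, and re-running any stage is byte-identical.

What the generator does *not* emulate: mappability and GC bias,
duplicate reads, replicate variance, probe cross-hybridization, and
isoform structure. Passing tests therefore demonstrate the correctness
of the analysis logic under its stated model, not robustness to every
artifact of real libraries.

## Statistical choices

* **Chi-square.** Pearson's statistic on the 2×2 table without Yates
  correction (counts in this design are large); the correction is a
  flag, and expected counts below 5 are flagged in the result. Fold
  enrichment is the set's frequency inside the category over its
  frequency in the universe; the universe is always an explicit
  argument, never inferred.
* **GSEA.** The running sum increments by `|score|^p / Σ|score|^p` at
  hits (default `p = 1` on log2 fold-change scores, so an x-fold rise
  and an x-fold drop weigh equally) and decrements by `1/(N − N_h)` at
  misses; the ES is the signed extremum. Because this design has one
  array per timepoint, sample-label permutation is impossible; the
  p-value instead permutes gene-set labels over the ranked universe,
  `p = (1 + #{|ES*| ≥ |ES|}) / (n_perm + 1)`, which is exact under
  exchangeability and never returns 0. The tests verify a 4.95%
  rejection rate at α = 0.05 over 2000 null replicates.
* **Fold-change floor.** Ratios use `max(value, ε)` with ε = 1 intensity
  unit in numerator and denominator, so near-zero background-subtracted
  baselines cannot produce unbounded ratios.
* **Collapse rule.** Gene-level ranking and categories use each gene's
  highest-mean-intensity probe (the best-measured one), with identifier
  tie-breaks; probe-level outputs remain available.

## Open choices pinned by this implementation

* The promoter window's downstream bound is the *end* of the first
  intron (in transcription order); `window_end = "intron_start"` gives
  the shorter variant.
* RANKL repression means ratio < 0.5 at *any* of 24/48/72 h by default
  (`rankl_down_mode = "all"` for the stricter reading).
* Membership of a peak in any window is judged by its summit, uniformly
  for binding regions and histone marks.
* Intronless genes use the gene end as the window bound.

## Problem sizes

The bundled validation runs at desk scale, chosen so the full suite and
the acceptance script each finish in minutes on one core: a 4-Mb
genome / 100 genes / ~10⁵ reads per track for the end-to-end run, a
1-Mb dense genome with 30 planted 10-fold regions for peak-recovery
benchmarking, 1000 fuzzed tables and 100 fuzzed ranked lists for the
oracle-equivalence checks, and 2000 × 999 permutations for null
calibration. Genome-scale inputs (10⁷ reads, 10⁴ genes) run through the
same code paths; only memory for the bin vectors grows.

## Known limitations

* Window-collision handling at high gene density is deliberate but
  crude: a peak in two overlapping windows marks both genes as targets.
* The background estimate is global; locally elevated background (e.g.
  copy-number gain) is not modelled. Supplying an input library
  switches to a true per-bin reference.
* No FDR control across peaks or gene sets; thresholds are fixed ratios
  by design, matching the analysis this package reproduces.
* GSEA leading-edge reporting follows the positive/negative extremum
  convention; no normalized ES across multiple gene sets is computed.
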