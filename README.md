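# bivalentSmad

An integrative ChIP-seq + expression pipeline for identifying
TGF-β–Smad2/3 target genes in bone-marrow-derived macrophages (BMMs)
whose bivalent H3K4me3(+)/H3K27me3(+) promoter resolves to
H3K4me3-only upon TGF-β, and whose expression is TGF-β-induced and
RANKL-repressed — the chromatin/expression signature by which *Nedd9*
was nominated as an effector of TGF-β priming in osteoclastogenesis.
It is written for computational biologists who want that screen as a
reusable, tested, fully seeded analysis rather than a one-off script.

## What it computes

* **Signal-ratio peak calling.** Reads are binned (100 bp, midpoint
  rule) and the *peak signal ratio* of each bin is the
  library-normalized ChIP density over a reference density — an input
  track when available, otherwise a robust (median) genome-wide
  background. Peaks are maximal runs of bins with ratio ≥ threshold
  (Smad2/3 and H3K4me3: 8; H3K27me3: 5), merged across ≤ 300-bp gaps;
  each peak carries a summit (centre of the max-ratio bin).
* **Target-gene assignment.** Gene *g* is a Smad2/3 target iff some
  summit lies in the strand-oriented window
  [TSS − 10 kb, end of first intron]; K4(+)/K27(+) status uses summits
  within ±1 kb of the TSS, per condition (TGF-β− / TGF-β+).
* **Transition classification.** Each gene gets one of the 16
  (state before → state after) labels over {K4±K27±}; the label of
  interest is the bivalent resolution K4+K27+ → K4+K27−.
* **Expression analysis.** Per-array normalization to mean intensity
  100, a strict > 70 expression floor, fold change
  r(t) = max(x_t, ε)/max(x_0, ε) with strict > 2 / < 0.5 categories,
  and ranked gene lists (highest-mean-intensity probe per gene).
* **Enrichment statistics.** 2×2 fold enrichment
  (a/(a+c)) / ((a+b)/N) with Pearson's χ² (df = 1), and the GSEA
  running enrichment score ES (signed extremum of the weighted
  hit/miss running sum) with a gene-set-label permutation p-value
  p = (1 + #{|ES*| ≥ |ES|})/(n_perm + 1).
* **Candidate selection.** Candidates = Smad2/3 targets ∩
  bivalent-resolving genes, optionally ∩ TGF-β-up (r(24 h) > 2) ∩
  RANKL-down (r < 0.5 at any of 24/48/72 h).
* **Synthetic data with planted truth.** `simulate_dataset()` builds a
  toy genome, plants binding sites, promoter marks and expression
  effects by gene class (including the canonical "Nedd9-like" class),
  and writes GFF3/BED/TSV/YAML/JSON — so the whole pipeline is testable
  offline against ground truth.

## Worked example

Simulate the default study conditions (4-Mb genome, 100 genes, 10 of
them planted Nedd9-like) and run the full analysis at the published
thresholds:

```r
library(bivalentSmad)

sim <- simulate_dataset(sim_config(seed = 7), "simdata")
cfg <- pipeline_config(
  annotation      = sim$paths$annotation,
  sample_sheet    = sim$paths$samples,
  expression_tgfb = sim$paths$expression_tgfb,
  expression_rankl = sim$paths$expression_rankl,
  out_dir = "out", gsea_nperm = 999, seed = 7)
report <- run_full(cfg)
```

which logs, stage by stage:

```
sample Smad23_TGFb_plus: 89539 reads mapped (71.7%)
peaks smad: 35 regions (ratio >= 8)
Smad2/3 target genes: 35 of 100
K4(+): 80 / 80 (TGFb-/+); K27(+): 40 / 20
bivalent -> K4-only genes: 20
expressed: TGFb 150 probes (86 genes); RANKL 160 probes (88 genes)
GSEA tgfb: ES = 0.816 (permutation p = 0.001)
GSEA rankl: ES = -0.665 (permutation p = 0.001)
candidates: 10 gene(s)
```

Reading the output: all 35 planted Smad2/3 binding regions are called
and assigned to their genes; 20 genes lose K27 while keeping K4 upon
TGF-β (K27(+) drops 40 → 20); Smad2/3 targets are strongly enriched at
the top of the TGF-β-induced ranking (ES = 0.816) and at the bottom of
the RANKL ranking (ES = −0.665), both at the permutation floor
p = 1/1000; and the intersection of targets with resolving promoters
returns exactly the ten planted Nedd9-like genes:

```r
report$candidates
#>  [1] "g007" "g046" "g049" "g051" "g053" "g056" "g060" "g068" "g079" "g084"
```

`out/` holds the per-sample peak BEDs, TSS metaprofiles, gene-state and
evidence tables, and `report.json` with all stage counts and statistics;
re-running the same config regenerates it byte-identically.

A thin CLI wrapper with `simulate` and `run` subcommands is installed
under `inst/scripts/bivalent-smad`.

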