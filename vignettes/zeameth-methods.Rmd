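---
title: "Methods: windowed DMR calling, methylation-expression association, and the bottleneck selection test"
author: "zeameth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed DMR calling, methylation-expression association, and the bottleneck selection test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zeameth)
```

## The scientific setting

Plant genomes carry cytosine methylation in three sequence contexts —
CG, CHG and CHH (H = A, C or T). In maize, CHG methylation is
maintained by chromomethylases, so natural or induced variation in a
chromomethylase gene shows up twice in whole-genome bisulfite (WGBS)
data: as a shift in the genome-wide CHG level, and as thousands of
locus-specific differentially methylated regions (DMRs). Those DMRs in
turn sit near genes whose expression responds, and the gene itself can
carry a population-genetic signature of selection if one allele rose
in frequency during domestication.

`zeameth` implements that full analysis arc at desk scale:

1. ingest Bismark-style cytosine reports;
2. call DMRs in 100-bp windows, in two modes (a population-haplotype
   mode with a per-region *t*-test, and a mutant-versus-wild-type
   threshold mode);
3. annotate DMRs against gene bodies, 2-kb promoters and transposable
   elements, and test differentially expressed genes (DEGs) for
   enrichment among DMR-associated genes;
4. estimate nucleotide diversity (`pi`, Watterson's `theta`) from
   population alignments and test an observed derived/ancestral
   diversity ratio against a neutral domestication-bottleneck
   coalescent.

Everything runs on seeded synthetic data with truth tables, generated
by the package itself, so each stage is testable without any external
download.

## Population-mode DMR calling

The haplotype procedure compares two groups of inbred lines:

* Per line, only cytosines covered by **>= 2 reads** count.
* The genome is tiled into non-overlapping **100-bp windows** (the
  final window of a chromosome is truncated; partial windows are
  kept).
* A window is retained when **strictly more than 50%** of lines in
  *both* groups have at least **3** cytosine sites of the requested
  context in it (**6** for CHH).
* Retained adjacent windows are merged into regions — merging happens
  *before* testing in this mode — and the per-line region level is
  recomputed as the weighted level (sum of methylated reads over sum
  of total reads).
* A *t*-test compares the two groups per region; regions pass with
  **p < 0.05** and an absolute group-mean difference above **10%**
  (CG/CHG) or **5%** (CHH). `direction = "hypo"` means the focal
  group is less methylated than the declared reference.

Choices where the procedure is underdetermined, made once and exposed
as switches:

* **t-test flavour.** The procedure says only "t-test"; we default to
  Welch (unequal variances) with the pooled-variance Student form
  available (`test = "student"`). For the group sizes involved the two
  rarely disagree.
* **Degenerate regions.** When both groups have zero variance the test
  statistic is undefined; such regions return `p = 1` (no call) rather
  than propagating `NaN`. Regions with fewer than two non-missing
  per-line levels in either group are skipped and counted, not errors.
* **"6 methylation sites" for CHH** is read as six covered cytosine
  positions, parallel to the CG/CHG site-count rule, not six
  methylated reads.
* **A site counts for a line** only when covered by >= 2 reads in that
  line — one coverage rule serves both the site filter and the window
  retention rule.
* **Group means** are taken over lines with a defined region level;
  missing levels are dropped, never imputed.
* **Symmetric CG sites are not strand-collapsed**; window statistics
  count sites as reported. This is documented rather than configurable
  because collapsing would change site counts against the retention
  thresholds.
* **No multiple-testing correction** by default (raw p < 0.05 is the
  procedure); `fdr = TRUE` applies Benjamini-Hochberg for users who
  want it.

## Pairwise-mode DMR calling

The mutant-versus-wild-type procedure is threshold-based and —
deliberately mirroring its description — filters *before* merging:

* windows need >= **2x average coverage** and the same per-context
  site minima (3/3/6) in *both* samples;
* CG/CHG windows are kept at an absolute level difference **>= 60%**;
  CHH windows under the compound rule: **> 20%** difference with one
  sample **< 5%** and the other **> 25%** methylated;
* surviving adjacent windows are merged, and merged-region levels and
  the difference are recomputed (no re-thresholding after the merge).

The two modes therefore order merge and test differently; both orders
are kept as stated rather than unified.

## Annotation and expression association

Promoters are the 2-kb strand-aware upstream interval of the
transcript; overlap is >= 1 bp on 0-based half-open intervals, so a
DMR starting exactly at a transcript end does not hit it. A DMR may
hit several classes (gene body, promoter, TE) and is intergenic only
if it hits none. A gene is *DMR-associated* when a DMR overlaps its
body or promoter; a distance parameter (`max_gap`, default 0) widens
this to "within N bp" because gene lists for downstream ontology work
are sometimes built that way — the two definitions are exposed rather
than silently reconciled.

DEG status (FDR < 0.05 and |log2FC| > 1) is recomputed from the
numeric columns on read, never trusted from the input file. Enrichment
of DEGs among DMR-associated genes against the expressed-gene
background uses the classical two-proportion chi-square with Yates
continuity correction (`prop.test` semantics; the correction can be
disabled). The background universe is the caller-supplied *expressed*
gene set, not all annotated genes. Group comparisons of phenotypes or
global methylation levels use the Mann-Whitney U test, exact when both
samples are small (product of sizes <= 400) and tie-free, otherwise
the tie-corrected normal approximation.

## Diversity and the selection test

`pi` is the mean over sequence pairs of the per-site difference
fraction with pairwise deletion (sites where either sequence has `N`
or a gap are excluded for that pair). Sliding profiles use 100-bp
windows advanced by 25 bp; the last window is the final *full* window
— trailing partial windows are dropped, matching the convention of the
standard diversity software, and deliberately unlike the DMR tiling,
which truncates. Watterson's estimator is `S / (a_{n-1} L)`.

The coalescent simulator is ms-style: time in units of 4N0
generations, piecewise-constant relative sizes (pair coalescence rate
2/x in an epoch of size x), infinite-sites mutations placed on
branches as a Poisson process with rate `theta` per unit branch
length, so at constant size `E[S] = theta * a_{n-1}` and
`E[pi] = theta`. With `rho > 0`, crossover recombination is simulated
on the ancestral recombination graph (lineages carry interval maps of
ancestral material; locally fixed segments are dropped). The default
is `rho = 0`: over a ~360-bp fragment, recombination is negligible.

The domestication bottleneck is a piecewise-constant history: relative
size 1 back to `t_start`, then `severity * n_ancestral` for
`duration`, then the ancestral size. The published analyses cite their
bottleneck parameterisation from earlier work without printing it, so
here *all* demography parameters are explicit configuration. The
defaults (`t_start = 0.015`, `duration = 0.0025`, `severity = 0.05`)
encode a domestication event on the order of 10^4 generations ago for
a maize-scale effective population size, with a transient reduction to
a few percent of the ancestral size — a mild, genome-wide-plausible
null. They are starting points to be replaced with a concrete
parameterisation when real data are analysed.

The selection test simulates, per replicate, an independent derived
sample under the bottleneck and an ancestral sample at constant size,
both at the ancestral-data `theta` (estimated from teosinte via
Watterson); replicates with zero ancestral diversity are redrawn and
counted. The p-value is one-sided on the lower tail with the add-one
convention, `p = (1 + #{ratio_i <= obs}) / (n_reps + 1)`, so it is
never exactly zero — selection at the locus *reduces* retained
diversity below the neutral-bottleneck expectation. The derived and
ancestral samples share no genealogy; modelling maize and teosinte as
diverged demes with migration is out of scope. The ratio
`pi_derived / pi_ancestral` is the test statistic; to condition only
on the derived diversity, pass the observed maize `pi` divided by the
theta-scaled expectation instead — the ratio is the default because it
is what the headline figure reports.

## The synthetic-data model

The generators emulate the study designs, not raw reads:

* **Cytosine catalog.** CG and CHG sites concentrate in dense
  methylated islands (default 200 bp long, exponential gaps of mean
  500 bp, island densities 100 and 60 sites/kb) over a sparse
  dispersed background (10 and 2 sites/kb); CHH sites are dispersed
  (80/kb). This two-level placement mirrors the TE-island structure of
  maize chromatin and matters for the caller: merged regions are
  compact and site-rich, as in real data, instead of arbitrarily long
  runs or 3-site fragments.
* **Counts.** Coverage is Poisson (mean 10; zero-coverage sites arise
  naturally and exercise the filters). Methylated counts are
  beta-binomial around the group-by-context mean with precision 20 —
  real WGBS is overdispersed, and binomial noise would make the
  calibration tests anti-conservative. Noise is independent per site
  and line; there are no per-line random global effects, so the
  per-region *t*-test sees exchangeable lines.
* **Baselines** are maize-like: CG 0.85, CHG 0.70, CHH 0.05.
* **Planting.** Population-mode DMRs (default: 30 regions of two
  100-bp windows, additive effect -0.3 on the focal group's CHG mean)
  are placed on windows that already satisfy the site-count
  eligibility rule, with at least one window of separation — recovery
  then measures the caller, not the luck of the site catalog. A jitter
  option shifts region boundaries off the window grid to test boundary
  behaviour. Pairwise-mode regions use heavily methylated wild-type
  levels (CHG 0.85 vs mutant 0.15; CHH 0.35 vs 0.02) so they cross the
  60% and compound-CHH rules by construction, on top of a genome-wide
  mutant depletion (CHG x0.55, CHH x0.5, CG untouched) that stays
  below the pairwise thresholds.
* **Expression.** Genes overlapping planted hypomethylated regions
  (body or 2-kb promoter) are DEGs with probability 0.101, others with
  0.078 — the two rates the enrichment comparison is designed around —
  with up-regulation biased 2:1 among coupled genes.
* **Alignments.** One coalescent replicate per population rendered
  onto a random 360-bp reference as biallelic substitutions; 21
  ancestral (teosinte-like) and 20 derived sequences. The bundled
  "selected locus" fixture uses a severe bottleneck (severity 0.01,
  duration 0.01) so the derived class shows clearly reduced diversity;
  across seeds its realised `pi` ratio falls below 1 in roughly 95% of
  draws.

What the generators do **not** model: read-level errors and bisulfite
non-conversion, per-line global methylation variance, linked site
structure beyond the island geometry, TE sequence content, and any
mapping artefacts. Passing the planted-truth tests therefore shows the
callers implement their rules correctly and recover strong effects
under realistic overdispersion — not that they are robust to every
failure mode of real WGBS data.

## Problem sizes and numerical conventions

The bundled analyses and tests run on two 50-kb chromosomes (about
14,000 cytosines per line, twelve lines), 10,000-replicate coalescent
checks against the closed forms, and a 200-trial uniformity experiment
for the selection-test null at 119 replicates per test — sizes chosen
so the whole suite completes in a few minutes on one core while
keeping Monte-Carlo standard errors small relative to the tolerances
tested.

Other conventions: internal coordinates are 0-based half-open
everywhere (cytosine reports are read/written 1-based per the Bismark
convention, GFF3 1-based inclusive, BED 0-based half-open); merged
regions are maximal and never adjacent; empty DMR sets serialise to
empty files and summarise without division; every stochastic function
takes an explicit seed and is byte-reproducible from it.

## Known limitations

* The population-mode caller inherits the procedure's raw p < 0.05
  rule; at genome scale that implies a substantial false-discovery
  rate, which is why the optional BH flag exists.
* Merging before testing (population mode) dilutes planted effects
  whose neighbours are also retained; the planted-truth sensitivity
  reflects that reality rather than idealising it.
* The coalescent selection test treats the derived and ancestral
  samples as independent draws, ignores migration, and is only as good
  as the demography supplied to it.
* `pi` with pairwise deletion can use different site sets for
  different pairs; heavily gapped alignments should be inspected
  before trusting window profiles.
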