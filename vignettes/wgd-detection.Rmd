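---
title: "Detecting and dating ancient whole-genome duplications from transcriptomes"
author: "paleodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating ancient whole-genome duplications from transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodup)
```

## The problem

An ancient whole-genome duplication (WGD, polyploidy) leaves a
characteristic footprint in a transcriptome: a burst of paralog pairs of
nearly identical age, superimposed on the continuous "L-shaped"
background of small-scale duplications (SSDs) that arise and are lost at
a roughly steady rate.  Because synonymous substitutions are
approximately neutral, the number of synonymous substitutions per
synonymous site between two paralogs (Ks) is a usable proxy for the age
of their duplication.  paleodup implements a complete pipeline to
detect and date such events in a clade of closely related species —
here the dogwoods (*Cornus*), eight species plus two outgroups
(*Alangium*, ACH, and the more distant *Dichroa*, DFE) — with three
mutually reinforcing lines of evidence:

1. **Ks/age distributions of paralogs.**  Gaussian mixture models fitted
   to the paralog Ks distribution (and, after conversion to absolute
   ages, to the pooled multi-species age distribution) identify
   candidate duplication bursts.
2. **Gene-count likelihoods.**  A linear birth–death model of gene copy
   number across a dated species tree, with a binomial retention step at
   hypothesised WGD positions, scores alternative placements of the
   event by likelihood.
3. **Dated gene trees.**  Gene trees whose topology shows a duplication
   in the ingroup common ancestor yield direct date estimates for the
   event, pooled and summarised by a mixture fit.

The rates pipeline feeding line 1 is also implemented in full: ortholog
and paralog pair identification from similarity hits, ORF inference,
codon alignment and NG86 estimation of Ks, Ka and Ka/Ks.

## Per-species clock calibration

Rates of molecular evolution differ among lineages, so a single clock
across all species would distort cross-species age comparisons.  Each
species instead gets a *local* synonymous clock calibrated from the
peaks of its ortholog Ks distributions against the two outgroups:

$$C_{Ks} = \frac{1}{2}\left(\frac{Ks_A}{2\,T_A} + \frac{Ks_D}{2\,T_D}\right),$$

where $Ks_A$ is the kernel-density peak of ortholog Ks against the
nearer outgroup, whose divergence node has age $T_A = 80.21$ myr, and
$Ks_D$ the peak against the root outgroup at $T_D = 95.75$ myr.  The
factor 2 splits a pairwise divergence between the two lineages, which
assumes equal rates along both — a stated simplification: rate variation
between a species and the outgroup lineage is not corrected.  The node
ages are configuration constants (they come from a fossil-calibrated
species-tree analysis that this package does not re-run).

Paralog Ks converts to age as $T = Ks / (2\,C_{Ks})$, and dating is
restricted to a 0–200 myr window; the Ks ceiling $2\,C_{Ks}\,T_{max}$
makes that window explicit in Ks units:

```{r clock}
cal <- calibrateClock(0.4334, 0.5051, 80.21, 95.75, species = "CAL")
cal
```

`kdePeak()` uses a Gaussian kernel with the nrd0 bandwidth rule
($0.9\,\min(\hat\sigma, IQR/1.349)\,n^{-1/5}$, the long-standing default
of R's `density`) on a 512-point grid, returning the grid argmax.  No
sub-grid refinement is applied: the grid spacing is far finer than the
4-significant-digit precision at which peaks are reported.  Clocks are
reported at 3 significant figures and Ks ceilings at 2 decimals.

## Homolog pairing

Paralogs are within-species best matches and orthologs between-species
best matches in an all-by-all similarity search (e-value ≤ 1e-6,
identity ≥ 40%).  Where the upstream search is external, `readTabularHits()`
consumes the standard 12-column tabular format; for self-contained
desk-scale runs, `allVsAllAlign()` provides an internal Smith–Waterman
aligner with an ungapped Karlin–Altschul e-value approximation
(lambda solved numerically for the scoring scheme, K fixed at 0.1).

Design choices where the procedure is underdetermined:

* "Best match" ranks by bitscore, ties broken by longer alignment, then
  lexicographic subject id, so output never depends on input order.
* A pair is emitted only when the two genes are each other's best match
  (reciprocal best hit), the standard orthology heuristic;
  `requireReciprocal = FALSE` relaxes this to one-sided best matches.
* Isoform redundancy: paralog hits between transcripts of the same
  parent gene are removed before ranking.  The parent is derived from
  the id by a configurable regex (default strips a trailing `_i<n>` or
  `.<n>` suffix, the common assembler convention).
* Multiple hits between one gene pair collapse to the longest alignment.
* Self-hits are always discarded.

Retained pairs must have ≥ 150 bp aligned at ≥ 60% identity (closed
thresholds), guaranteeing at least 50 codons for rate estimation.

## Rate estimation

`inferCds()` replaces a dedicated coding-region predictor with a
six-frame scan for the longest stop-free codon stretch (≥ 150 nt; the
ORF need not begin with ATG unless `requireAtg = TRUE`, since assembled
transcripts are frequently 5'-truncated).  `codonAlignPair()` aligns the
translated proteins globally (BLOSUM62, gap open 10, extend 0.5 —
conventional defaults) and back-translates; every column containing a
gap is removed rather than the whole pair being dropped, and pairs with
fewer than 50 ungapped codons are rejected.  Dropping columns rather
than pairs is a deliberate choice between two defensible readings of a
"no gaps" filter; it retains more pairs while still estimating rates
from strictly ungapped codon columns only.

`ng86Rates()` implements the NG86 counting estimator with the standard
genetic code:

* per-codon synonymous site fractions, averaged over the two sequences;
  single-nucleotide changes that would create a stop codon contribute
  nothing to the synonymous count, and $N = 3L - S$, so $S + N$ equals
  the alignment length exactly;
* observed differences classified by averaging over all minimal
  mutational pathways between the two codons, excluding pathways through
  stop codons (in the rare case that every pathway is blocked, all
  pathways are averaged);
* Jukes–Cantor correction $d = -\tfrac34\ln(1 - \tfrac43 p)$ of both
  proportions.  At $p \ge 3/4$ the distance is undefined: the pair is
  flagged saturated and excluded from dating, never clamped.
* $\omega = Ka/Ks$ is undefined at $Ks = 0$.

A counting estimator was chosen over a maximum-likelihood codon model
because every step is auditable against a brute-force pathway
enumeration, which the test suite does exactly on small alignments;
codon-frequency-corrected variants could be added behind the same
interface.  The headline clock and window quantities do not depend on
this choice, since they derive from KDE peaks supplied as inputs.

## Mixture modelling of Ks and age distributions

`fitGmm()` fits a k-component univariate normal mixture by EM.
Numerical policy:

* **Starts.**  100 random starts (flat-Dirichlet weights, means drawn
  from data quantiles, data-sd scales) plus 100 k-means starts with
  k-means++ seeding, by default.  Each start runs a short screening EM
  (25 iterations); the best few (5) are polished to convergence.  All
  start seeds derive deterministically from one seed, and the data are
  sorted internally, so the fit is invariant to input order.
* **Convergence.**  $|\Delta \log L| < 10^{-8}$ (relative), at most
  1000 iterations.  The log-likelihood trace is recorded and asserted
  non-decreasing at every iteration.
* **Variance floor.**  $10^{-6}$ on the Ks scale, $10^{-2}$ on the myr
  scale, preventing singular components.
* **BIC.** $-2\log L + (3k-1)\ln n$; `selectModel()` scans k = 2..5 by
  default (k = 1 is allowed, e.g. for gene-tree date fits) and keeps the
  minimum-BIC fit with the full per-k table.

Components containing more than 20% of the pairs (strict inequality)
are retained; component means and standard deviations convert to ages
through the species' clock.  Age-window labels (≤ 25 myr
"SSD-candidate", 40–120 myr "WGD-candidate") are a reporting
convenience, not an inference — mixture components in the steep part of
an L-shaped background are known to be distribution-fitting artifacts
rather than genuine duplication bursts, and should be interpreted
accordingly.  For pooled analyses the per-species ages (each computed
with its own clock) are concatenated and fitted on the myr scale
directly.

## Ka/Ks through time

`binOmega()` summarises omega in half-open 5-myr bins tiling [0, 200)
— an age of exactly 5.0 falls in [5, 10) — reporting mean, median and
the fraction of pairs with omega > 1 per bin; pairs with undefined
omega are excluded and counted.  Both mean and median are emitted
because either may be wanted as the summary statistic; neither is
privileged.  `omegaShiftReport()` compares mean omega in the bins
before and after a WGD age descriptively; no significance test is
attached.

## Gene-count placement of the WGD

Copy numbers evolve by a linear birth–death process (shared rates
$\lambda, \mu$ across branches — one global background process) on the
dated species tree; at a WGD each extant copy independently leaves a
surviving duplicate with retention probability $q$.  Five placement
hypotheses are scored: H1 a single WGD on the ingroup+ACH stem; H2 on
the ingroup stem; H3 ingroup stem + ACH stem; H4 BW stem + non-BW stem
(the two sides of the deepest ingroup split); H5 ACH stem + both
ingroup stems.

Implementation decisions:

* **Transition probabilities** use the standard closed form
  (composition of independent single-lineage processes; the
  $\lambda = \mu$ limit handled analytically), assembled into matrices
  over copy-number states 0..20 (the truncation bound, configurable;
  row sums are checked to 1e-8 in the regimes exercised).
* **Likelihood** by Felsenstein pruning over states, with per-node
  scaling.  The WGD enters as a binomial thinning matrix at the branch
  midpoint.
* **Conditioning.**  Families enter the data only if present in ≥ 2
  ingroup species and ≥ 1 outgroup, so by default the likelihood is
  conditioned on exactly that observability event.  The conditioning
  probability is computed by an augmented pruning that tracks (copy
  state, ingroup species present capped at two, outgroup present) —
  a direct computation that stays numerically stable where
  complementary-event formulas suffer catastrophic cancellation.
  `condition = "none"` disables it.
* **Root prior**: one copy at the root (geometric optional).
* **Search.**  Retention rates live on the grid 0, 0.1, ..., 1.
  `qSearch = "grid"` profiles $(\lambda, \mu)$ at every grid
  combination (exact but exponential in the number of events);
  the default `"joint"` optimises $(\log\lambda, \log\mu,
  \mathrm{logit}\,q)$ jointly, screens the neighbouring grid
  combinations at the fitted rates, and re-optimises the rates at the
  best combination.  Hypotheses are compared by AIC
  ($p = 2 + \#\text{events}$) and Akaike weights.

## Gene-tree screen

A dated gene tree is evidence for a duplication in the ingroup common
ancestor when it contains a node with exactly two ingroup-only daughter
clades, each containing at least one species from either side of the
deepest ingroup split (BW: CAL/CCO; non-BW: the rest), with the
outgroup ACH outside both.  The node's age is the duplication date.
When several nodes qualify, the oldest is reported — a WGD necessarily
predates within-clade duplications; occurrences are counted in the
output.  Dates below the 68-myr fossil minimum for the calibrated node
are flagged, not corrected.  The far outgroup is pruned from a tree
when its tip-to-root path strictly exceeds twice the median path of the
other taxa (a rule standing in for a manual curation step).  Passing
dates are pooled and fitted with the mixture machinery (k = 1..3 by
default); the dominant component summarises the event date.

## The synthetic cohort

Every pipeline input can be generated with planted truth
(`simulateCohort()`), so the whole analysis is testable end to end
without sequence archives.  The generator defaults are the study
conditions:

| quantity | default | basis |
|---|---|---|
| species clocks | recomputed from the eight published ortholog-Ks peaks (2.67–3.29 × 10⁻³ /site/myr) | published summaries |
| WGD components | 74, 22, 7 myr; proportions 0.25/0.20/0.15; sd 5/3/2 myr | the three pooled peaks; proportions and sds chosen once as plausible burst widths |
| SSD background | exponential, decay 0.05 /myr | simplest L-shaped generator; decay chosen once |
| ortholog Ks scatter | sd 0.08 (Ks units) | free parameter; no noise model is published |
| divergence ages | 80.21 / 95.75 myr | fixed calibration constants |
| gene counts | 3000 families, λ = μ = 0.002 /copy/myr, WGD on ingroup stem, q = 0.1 | q from the published best fit; rates typical for gene turnover |
| gene trees | 98 trees, duplication age N(76.1, 2.7), dropout 0.15/leaf | published screen size and date; dropout chosen once |

Species-tree node ages other than the two calibration nodes and the
ingroup crown (placed at 72.77 myr, the old end of its published range)
are not individually published; the remaining ages in
`cornusSpeciesTree()` are synthetic stand-ins inside conventional ranges
for the group.  They matter only to the simulators.

What the generator does *not* emulate: read-level sequencing error,
assembly artifacts and isoform redundancy beyond the id convention, Ks
saturation noise, gene conversion between paralogs, and lineage-specific
rate variation within a species.  Passing recovery tests therefore
demonstrate the correctness and calibration of the estimators under the
model's own assumptions, not robustness to every artifact of real
transcriptome data.

Codon pairs are generated by placing Poisson numbers of synonymous and
nonsynonymous single-nucleotide substitutions (never creating stops) on
a uniform sense-codon background — deliberately a *counting* process,
not a continuous-time codon model, so it exercises the estimator's
multiple-hit correction without sharing its machinery.  Likewise the
gene-count simulator is an exact event-level (Gillespie) simulation,
independent of the closed-form transition probabilities it is tested
against.

## Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately chosen
sizes: 2000 paralog pairs per species (pooled over eight species) for
mixture recovery, 3000 gene families for placement recovery over twenty
simulation seeds, 98 gene-tree dates, 50 replicates of 500-codon pairs
for estimator calibration, and brute-force oracle comparisons on
instances small enough to enumerate (alignments ≤ 10 codons, hit tables
≤ 20 genes, two-leaf count histories).  Mixture fits at these sizes use
reduced multi-start schedules (5 + 5 starts, short screening runs);
recovery is insensitive to the schedule because the planted components
are well separated.  Every stochastic step takes an explicit seed, and
a fixed seed reproduces outputs byte-identically, including the
pipeline run manifest.

## Known limitations

* Ks-based dating inherits saturation artifacts: components at large Ks
  can be spurious, which is why dating is windowed and deep components
  are interpreted cautiously.
* The calibration attributes half of each ortholog divergence to the
  focal lineage; asymmetric rates bias clocks proportionally.
* Gaussian components imposed on an L-shaped SSD background misfit its
  steep young end; young components should not be read as WGDs.
* The placement model shares one birth and one death rate across the
  tree and allows one WGD per branch; per-branch rate classes and
  nested events are out of scope.
* The gene-tree screen requires the outgroup in the tree and dated
  nodes; it does not infer or re-date trees.
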