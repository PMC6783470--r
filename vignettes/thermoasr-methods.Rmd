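---
title: "Inferring ancestral growth temperatures from protein composition"
author: "thermoasr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancestral growth temperatures from protein composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoasr)
library(ape)
```

## The idea

Proteins of thermophiles are enriched in charged residues (arginine,
lysine, aspartate, glutamate) at the expense of polar non-charged ones
(glutamine, asparagine, serine, threonine): salt bridges stabilise folds at
high temperature, while the polar set is prone to deamidation and
backbone flexibility. The **CvP bias** summarises this in one number,

$$\mathrm{CvP} = 100 \cdot \frac{n_\mathrm{charged} - n_\mathrm{polar}}
{n_\mathrm{counted}}\ \text{percentage points},$$

where only the 20 canonical residues are counted (gaps and the ambiguity
codes X/B/Z are dropped from numerator *and* denominator, so missing data
never dilute the bias). Across prokaryotes with known growth optima, CvP of
a conserved marker protein correlates linearly with the organism's optimal
growth temperature (OGT). For the concatenated subunits of methyl-coenzyme
M reductase (McrABG) — the enzyme at the heart of methanogenesis and
anaerobic methane/alkane oxidation — the package ships the published
calibration as the built-in model `"hua2019"`:

$$\mathrm{OGT} = 6.7548 \cdot \mathrm{CvP} + 13.858 \quad (R^2 = 0.7288).$$

CvP is on the percentage-point scale: with the coefficients above, the
biologically occupied CvP range of roughly 3–13 points maps onto 35–100 °C.

Composing this calibration with ancestral sequence reconstruction turns a
gene tree into a thermal history: reconstruct the residues of each internal
node, score their CvP, and read off a temperature. The pipeline has four
stages, each exposed as its own function and orchestrated by
`runPipeline()`.

## Calibration with corrections

`fitCalibration()` is ordinary least squares of OGT on CvP, but the point
set matters more than the fit. `buildCalibrationPoints()` applies three
corrections that reflect how OGT panels are actually assembled:

* **Psychrophile exclusion** (default on). Cold-adapted archaea achieve
  flexibility by a different compositional route and sit off the line;
  flagged records are dropped.
* **The 37 °C collapse** (default on, temperature configurable). Culture
  collections over-represent host-associated mesophiles whose tabled OGT is
  the incubator's 37 °C. The whole group is replaced by a *single* point at
  its mean CvP — a deliberate design choice (one averaged point, not a
  reweighting), because it is the most direct reading of averaging the
  group's CvPs. A `collapse = "duplicates"` switch extends the rule to every
  duplicated OGT value for sensitivity analysis.
* **Gene copies count separately.** A species with two marker copies
  contributes two points with the same OGT, one per copy. Copies are keyed
  by a `copy_id` column; sequence ids for extra copies follow the
  convention `taxon|copy_id`.

$R^2$ is reported as the squared Pearson correlation; the slope's t-test
p-value is retained as a diagnostic only.

## Rooting by minimal ancestor deviation

Gene trees come out of ML programs unrooted, and no outgroup exists for a
gene family that spans the deepest archaeal splits. MAD rooting uses only
the molecular-clock expectation: for the true root, every leaf pair's
ancestor should lie midway along the path between them. For a candidate
root at distance $x$ from endpoint $i$ of a branch, a pair $(b, c)$
spanning that branch deviates by $|2(d_{ib} + x)/d_{bc} - 1|$; a same-side
pair is judged at the fixed node where its two paths meet. The branch
score is the root-mean-square deviation over *all* pairs, with $x$ set to
the closed-form minimiser of the spanning pairs' summed squares, clamped
to the branch. `madRoot()` evaluates every branch, roots at the global
minimum, and reports all candidates plus an ambiguity index
(best/second-best score, in $(0,1]$; near 1 means the root is poorly
determined). Deviations are ratios, so scores are invariant under uniform
rescaling of the tree. Zero-length branches are scored at $x = 0$ rather
than skipped, because real ML trees contain them. Correctness is anchored
in the test suite by a dense grid-search oracle that re-derives every
pair's ancestor independently.

## Marginal ancestral reconstruction

`marginalAncestralProfiles()` implements empirical-Bayes marginal
reconstruction under a reversible empirical amino-acid model (LG shipped
as the default, WAG as an alternative, both as plain-text exchangeability
tables) with discrete-gamma rate heterogeneity:

* the rate matrix is $Q_{ij} = s_{ij}\pi_j$, normalised to one expected
  substitution per site; transition matrices come from the symmetrised
  eigendecomposition ($\pi^{1/2}$ similarity transform), which is exact for
  reversible models and cheap to reuse across branches;
* among-site variation uses $k$ equal-probability gamma categories whose
  rates are the means of the quantile slices (mean exactly 1); $k = 10$ is
  the default, matching common practice for this marker, and the shape can
  be fixed or fitted by Brent search on $[0.02, 100]$;
* equilibrium frequencies default to alignment-empirical "+F" with add-one
  smoothing;
* the downward pass is Felsenstein pruning with per-node, per-column
  scaling (20-state models on deep trees underflow without it); the upward
  pass propagates outside vectors, and the posterior at node $v$ is
  $L_v(a)U_v(a)$ normalised per column, mixed over categories with the
  per-column category weights;
* gaps and ambiguity codes are missing data (all-ones partials): every
  column is reconstructed at every node, and a `maskGappyColumns` flag
  optionally restricts ancestral CvP to columns under 50 % gaps;
* the per-column MAP residue breaks exact ties alphabetically, for
  determinism.

Branch lengths are taken from the input tree by default;
`optimizeBranchLengths()` offers coordinate-wise ML re-estimation (Brent
per branch on $[0, 20]$, sweeps until the gain drops below $10^{-3}$),
off by default because fixed input lengths are cheaper and reproducible.
Both conventions exist in published workflows, and the choice is exposed
rather than hidden.

Two CvP variants are computed for every internal node and reported side by
side: the CvP of the MAP sequence (`cvp_map`, the headline column, closest
to classic ASR practice) and the posterior-weighted expectation
(`cvp_expected`, which integrates over reconstruction uncertainty). For
leaves both equal the observed row CvP.

## The synthetic-data generator

Real panels and alignments for this problem are assembled from hundreds of
genomes; the package instead ships generators whose ground truth is fully
recorded, so every stage is testable end to end.

`makeCalibrationPanel()` emulates the statistical structure of an OGT
panel: an over-represented mesophile group (18 of 37 species at exactly
37 °C by default), flagged psychrophiles (drawn 5–15 °C and offset +2.5
CvP points off the line, emulating their distinct adaptation), remaining
species uniform over 45–100 °C, and CvP targets from the true line plus
Gaussian noise (default sd 1.5 points, a realistic scatter for a
single-protein proxy). Sequences realise each target to the nearest value
achievable with integer residue counts — an $L$-residue sequence can only
realise multiples of $100/L$, so the table carries both the exact target
(`cvp`) and the realised value (`cvp_realized`); at the default
$L = 1000$ the quantisation is at most 0.05 points.

`simulateDataset()` builds a full problem: a Yule tree (uniform leaf
splitting, exponential branch lengths), a Brownian OGT trajectory along it
(child = parent + $N(0, \sigma^2 \ell)$, clamped to the plausible
[5, 110] °C), a per-node residue composition realising each node's OGT
exactly (probability mass moved between the charged and polar classes,
proportionally within each class, the 12 unclassified residues untouched —
isolating exactly the signal the analysis assumes), and a non-stationary
alignment in which each branch evolves columns under the *child's*
equilibrium with shared LG exchangeabilities. Rate categories are drawn
once per column at the root and inherited, matching the likelihood's
assumption. There are no indels; gap handling is exercised separately with
masked columns.

What the generator does *not* emulate: site-specific composition
(CAT-like profiles), within-branch composition interpolation, indels,
alignment error, or selection on specific sites. Passing tests therefore
show the machinery is correct and the inference is recoverable when the
model family matches the data — not that real McrABG alignments satisfy
those assumptions.

## Numerical choices

* Transition-matrix entries below zero by round-off (≥ −1e-12) are clipped;
  rows must still sum to 1 within 1e-10. A distance of exactly 0 returns
  the exact identity so that degenerate zero-length configurations are
  scored exactly.
* Column likelihoods mix categories by log-sum-exp; impossible columns
  (e.g. conflicting residues across a zero-length path) yield −Inf with a
  warning rather than an error.
* Model validity enforces detailed balance ($\pi_i Q_{ij} = \pi_j Q_{ji}$
  within 1e-10) — non-reversible inputs are rejected at construction, which
  is what licenses the pulley principle and the marginal two-pass
  algorithm.
* MAD ties across branches break on the smallest branch index; MAP ties
  break alphabetically; annotation tables are emitted in preorder — all
  purely for byte-level reproducibility, which the suite asserts.

## Suite sizes and what the tests measure

The test suite works at desk scale, chosen to keep the full run in a
couple of minutes: enumeration oracles on 4-leaf, 3-column, 2-category
instances (exact to 1e-10); an 8-leaf pulley fixture (1e-8); gamma-shape
recovery at 16 leaves x 2000 columns (±0.2); branch-length recovery at 6
leaves x 2500 columns (median relative error under 15 %); and an
end-to-end suite of 10 seeds at 32 leaves x 3000 columns, root OGT 95 °C,
diffusion 8 °C per unit sqrt-branch-length, mean branch length 0.5
substitutions/site.

On that end-to-end suite the root-OGT mean absolute error is ~3.5 °C
(asserted ≤ 10 °C). The per-node correlation between true and estimated
internal OGTs is more demanding: at 3000 columns a single composition
estimate carries ~6 °C of sampling noise, the same order as the simulated
signal, and pilot runs show even an oracle reading the *true* ancestral
sequences only exceeds $r = 0.7$ in a minority of seeds. The suite asserts
the $r \ge 0.7$-in-8/10 bar regardless, and it fails under these
conditions; the failure is a property of the signal-to-noise regime, not
of the reconstruction machinery, which the enumeration and oracle tests
pin down exactly. Users applying the pipeline to real markers should read
this as: single-node temperature estimates carry several degrees of
composition-sampling uncertainty, while broad gradients (hot root, cooler
tips) and clade-level contrasts are recovered reliably.

## Worked example

```{r example, eval = FALSE}
truth <- simulateDataset(nLeaves = 16, nColumns = 1500, rootOgt = 95,
                         sigma = 8, seed = 11)
res <- runPipeline(truth@alignment, truth@tree,
                   ogtTable = truth@ogtTable, calibration = NULL,
                   rooting = "pre-rooted", alpha = 0.8, k = 4)
head(annotations(res))
summarizeCladeOgt(res, truth@tree$tip.label)   # the root's annotation
```

## Known limitations

* The calibration is a single-marker proxy; its residual scatter
  (published $R^2 \approx 0.73$) translates to roughly ±10 °C on
  individual predictions even before reconstruction uncertainty.
* Marginal (not joint) reconstruction only; no free-rate mixtures, codon
  models, topology search or model selection — trees and model choice are
  inputs.
* The stationary, reversible likelihood is mis-specified for data whose
  composition genuinely drifts (which is exactly the signal being
  exploited); the posterior-expected CvP is therefore shrunk toward the
  global composition, attenuating extreme ancestral temperatures. The
  MAP-based variant is less shrunk but noisier.
* MAD rooting assumes an approximate clock; for strongly rate-shifted
  gene families the reported ambiguity index should be inspected.
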