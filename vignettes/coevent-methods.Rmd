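---
title: "Methods: combinatorial biomarker discovery in cell-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: combinatorial biomarker discovery in cell-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevent)
```

This vignette documents the statistical model behind `coevent`, the
tunable parameters and why their defaults are what they are, the
numerical choices in the inflection-point estimator, what the synthetic
panels emulate (and what they deliberately do not), and the package's
validation scenarios.

## The genomic-event model

A *genomic event* is the unit of analysis: a binary indicator per
(cell line, locus) that is true when the locus carries a coding mutation
and/or a copy-number aberration. Copy-number calls use gene-level total
copy number: 0 is a homozygous deletion, ≥ 8 an amplification
(`build_event_matrix()`, arguments `deletion_value` and
`amplification_threshold`). Both thresholds are conventional for
PICNIC-style integer copy number on cancer cell lines; lowering the
amplification threshold can only add events (monotonicity is tested).
Sub-loci such as `CDKN2A(p14)` are distinct loci and are never merged
into their parent symbol: the p14/p16 reading frames of CDKN2A are
genuinely different biomarkers. Cell lines and loci are kept in
lexicographic order everywhere, so all downstream outputs are
reproducible without tracking input order. Loci with zero events in the
analysed subset are dropped before tuple enumeration and recorded in the
`dropped_loci` attribute — the potential pair space is defined over
*affected* loci.

A cell line screened with a drug but lacking genomic characterisation is
retained for response calling (it shapes the rank curve) and excluded
from association testing; frequencies always use the number of
genomically characterised lines tested with that drug as denominator.

## Sensitive/resistant calling from the rank curve

Per drug, the tested lines' GI values are rank-ordered ascending (ties
broken lexicographically by cell-line identifier, so the ordering is a
pure function of the data). The curve is modelled as a degree-9
polynomial in the rank rescaled to [0, 1]; degree is configurable and is
automatically reduced when the Vandermonde condition number exceeds
1e10. The boundary is the *inflection point*: the smallest rank at which
|f''| of the fitted polynomial attains its maximum, ranks within a
relative tolerance of 1e-9 of the maximum counting as attaining it.
Profiles whose interior |f''| never exceeds 1e-8 (flat or linear
profiles) are *degenerate*: no partition is made unless a viability cap
applies.

Numerical choices that matter:

* **Edge exclusion.** Least-squares polynomial fits ring near the ends
  of the interval: on step-like profiles the fitted |f''| at the 2nd-5th
  rank can exceed the knee curvature by an order of magnitude. The
  extremum search therefore excludes 5% of ranks (at least one) at each
  end (`edge_exclude`), not just the two endpoint ranks. The knee of
  interest sits at the sensitive-minority boundary, well inside this
  margin for any usable screen.
* **Global-max reading.** "First inflection" is read as the first
  attainment of the *global* interior maximum of |f''|; a first-local-
  extremum variant is available (`first_local = TRUE`) for curves with a
  shallow early knee and a steep resistant tail.
* **Boundary ties.** All lines whose GI equals the cutoff value are
  assigned resistant, so tied lines never straddle the boundary; in
  gIC50 mode with distinct values this makes |sensitive| equal the
  inflection rank exactly.
* **Viability cap.** For viability-ratio screens the cutoff is
  min(inflection GI, 0.78) — whichever gives the greater sensitivity; a
  degenerate inflection with a cap falls back to the cap alone.
  Inflections are always computed per screen, so training and test
  cohorts of one drug get independent cutoffs.

The estimator has a known small-sample bias: the fitted polynomial
smooths the knee over a window of roughly n/(2·degree) ranks, and the
curvature maximum can sit 1-3 ranks before the true corner. On hinge
profiles of 100 lines this amounts to ≤ 0.03 in sensitive-fraction
terms at degree 11, ≤ 0.06 at degree 9 — visible in the fraction-recovery
test, and the reason that test runs at degree 11.

## The independence model and disequilibrium classes

If events arise independently, the expected co-event count for loci with
marginal frequencies f_a, f_b among N lines is E = N·f_a·f_b (three-way
product for triples). Observed counts are compared to E with the
two-cell goodness of fit

χ² = (O − E)² · (1/E + 1/(N − E)),  p = P(χ²₁ ≥ χ²).

Two conventions are deliberate:

* **`rounded` rounding** (the default for population scans) rounds
  E to the nearest integer, half away from zero, *before* the test.
  Printed exclusivity tables carry integer predicted counts, and their
  p-values only reproduce when the test uses the rounded count (e.g.
  O = 8, E = 20, N = 294 gives p = 0.005444; the unrounded E = 20.47
  gives p = 0.00455). `rounding = "exact"` uses E as-is.
* **No continuity correction** anywhere; the printed p-values reproduce
  without one.

Classes at level α (default 0.05): *mutually exclusive* — O = 0 with
E > 0 and p ≤ α; *partially exclusive* — 0 < observed < predicted,
p ≤ α; *co-selected* — observed > predicted, p ≤ α; otherwise *none*.
Pairs with E ≤ 0 or E ≥ N are flagged `untestable`, never silently
NaN. Pair scans score the full potential space (strict exclusivity is
only visible at O = 0); triple scans score observed triples only, the
potential triple space being too large to materialise usefully.

The statistic treats E as fixed although the marginals are estimated
in-sample. Under independence the variance of O − N·f̂_a·f̂_b is
N·f_a(1−f_a)·f_b(1−f_b), smaller than the E(N−E)/N the statistic
assumes, so the test is mildly *conservative*; with the mostly-rare
marginal ladder used in the synthetic panels the realised type-I rate at
α = 0.05 is ≈ 0.04 (measured in the calibration test). This is a
property of the published form of the statistic, retained by design.

## Per-drug association testing

Single events use the two-sided Fisher exact test; the package's Fisher
p-values are checked against full hypergeometric enumeration for every
2×2 table with total ≤ 30. Co-events use the Pearson 2×2 chi-square
without correction as the primary p-value; because printed per-drug
co-event p-values cannot be unambiguously matched to either the plain or
the Yates-corrected variant from their marginal counts, both are emitted
(`p_value`, `p_value_yates`) and the plain one is primary. Secondary
diagnostics re-apply the observed-vs-predicted goodness of fit *within*
the sensitive and within the resistant subpopulation, using marginals
computed in that subpopulation (panel-wide marginals behind
`subpop_marginals = "whole"`; the subpopulation reading is the default
because the question is disequilibrium *given* membership).

Selection rules: prevalence > 12% of S or of R (`powered`), S/R
fold-change strictly outside [1/1.5, 1.5], p ≤ 0.05. The S/R ratio
carries an `Inf` sentinel when the event is absent from resistant lines
(rendered `inf` in reports). Co-events additionally require ≥ 4 carrier
lines (`min_count`), the smallest co-event count worth reporting —
smaller tuples cannot reach stable fold estimates. Ranked reports order
by p, then carrier count, then |log S/R| with the sentinel first, then
tuple label — a deterministic total order.

## Lineage interaction and subtraction

The default lineage test is a proportional goodness of fit: the m
carriers of (tuple, lineage) among tested lines should split between S
and R as (m·n_S/n, m·n_R/n); the same two-cell χ²₁ applies. A Fisher
2×2 alternative (`null = "fisher_2x2"`) is provided; both agree in
direction on small tables and the choice is reported, not hidden. Pairs
with fewer than 3 carriers are returned untested (`min_carriers`):
below that the chi-square is meaningless.

Subtraction removes *all* cell lines of every lineage that individually
reached significance and re-tests the tuple on the remainder (Fisher for
singles, 2×2 chi-square for co-events). A lineage used to declare
significance never contributes lines to the residual test, which is what
makes the residual an internal cross-validation. "No power" — the event
occurring in ≤ 12% of remaining S and R lines, or an empty remainder —
is a first-class output state. Note the procedure's intrinsic floor:
after a correct subtraction the residual test is still an α-level test,
so on truly lineage-confined effects about 5% of residual tests will be
significant by chance.

## Response clustering

GI profiles are median-centered and then normalized per compound
(columns), following the Cluster-3.0 convention in which "normalize"
scales a column to unit sum of squares (`unit_variance = TRUE` gives the
unit-SD reading). Centering per compound makes scores potency-free;
row operations are never applied. Missing (untested) entries stay
missing; correlations are pairwise-complete with at least 3 shared
positions, and entities that cannot reach a defined distance to the rest
are shed as singletons (reported, with a warning) rather than imputed.
Clustering is UPGMA (average linkage) on d = 1 − r; merge heights are
verified against a naive cubic implementation. Both drug and cell-line
axes are supported.

## What the synthetic panels emulate

`panel_config()` defaults describe a large screening panel: 300 cell lines,
260 loci, 20 lineages of unequal size (linearly decreasing weights —
real panels are dominated by a few common lineages). Marginal event
frequencies follow the Beta(1.1, 12) quantile ladder clipped to
[0.01, 0.6]: most loci in the 1-15% range with a TP53-like upper tail —
the shape of gene-level event frequencies in cell-line compendia.
Pairwise couplings plant P(A∧B) = λ·f_a·f_b exactly, with couplings
restricted to disjoint pairs so the joint law stays exact without
graphical-model machinery. Lineage enrichment multiplies event *odds*
within a lineage and is applied before coupling. Drug screens are
generated as GI = baseline × Π(shifts) × exp(ε): gIC50 baselines are
log-normal with median 650 nM (the scale of typical inflection cutoffs),
viability baselines concentrate near 0.9 so the 0.78 cap rule is
actually exercised; sensitizing shifts are < 1.

The panels deliberately do **not** emulate: mutational signatures or
hotspot structure, clonal phylogeny, copy-number segment correlation
along chromosomes, dose-response curve shape (GI values are scalar),
batch effects, or misidentified cell lines. A pipeline that passes the
synthetic tests is validated for its statistical logic, not for
robustness to those real-data pathologies.

## Validation scenarios

Three scenario generators pin down behaviour that single-operation tests
cannot:

* **Knee benchmark** (`two_regime_profile()`): a flat sensitive plateau
  followed by a steeply rising resistant ramp, with noise small relative
  to the per-rank ramp increment. Two flat plateaus joined by a jump are
  *not* used: a polynomial smoother turns a jump into a bipolar
  curvature signature whose extrema sit ±n/(2·degree) ranks from the
  jump, so no polynomial-based knee finder can agree with a discrete
  second-difference locator to ±2 ranks there; and on shallow ramps the
  discrete locator itself is dominated by order-statistic spacing noise.
  The hinge shape gives a single-signed curvature bump centred on the
  knee and a well-defined discrete oracle; profiles of 50-80 lines give
  exact-to-±2 agreement at the default degree.
* **Epistasis benchmark** (`epistasis_panel()`): a 500-line
  viability-mode screen (the scale of the larger published viability
  screens) where only lines carrying *both* planted events (each at
  marginal 0.7) are shifted, by ×0.844 around a 0.9 baseline with
  log-noise 0.21. The design is a closed-form power calculation: with
  complete penetrance a correct caller makes S exactly the co-carrier
  set, forcing each single-locus S/R ratio above 2 (freq_S = 1,
  freq_R = f/(1+f) ≤ 1/2) — an epistatic effect that is clean enough is
  *always* visible in its singles. The chosen shift/noise give ≈ 55%
  penetrance in co-carriers against ≈ 25% background sensitivity below
  the 0.78 cap, which leaves the pair strongly selected (expected 2×2
  χ² ≈ 25) while both singles sit near S/R ≈ 1.3, inside the fold band.
* **Lineage benchmarks** (`lineage_effect_panel()`): *confined* — the
  marker is 30-fold odds-enriched in one lineage and the drug sensitizes
  that lineage only, so the marker's association must vanish under
  subtraction; *independent* — the marker itself sensitizes carriers
  with partial penetrance everywhere, so the association must survive
  subtraction of whichever (few) lineages individually reach
  significance. Partial penetrance matters here too: with complete
  penetrance every lineage with ≥ 3 carriers interacts significantly and
  the subtraction removes the entire panel.

Problem sizes in the test suite (100 independence panels, 100 coupling
replicates per λ, 50 epistasis and 2×50 lineage replicates, 100 knee
profiles, exhaustive Fisher tables to n = 30) were chosen to keep the
whole suite in the few-minutes range on one core while leaving the
simulation-based rates at least two standard errors inside their
acceptance bands.

## Known limitations

* The inflection estimator is only meaningful when the profile has a
  genuine sensitive minority; on featureless unimodal profiles the
  global-max rule parks the knee near the (excluded margin of the)
  resistant tail, and such calls should be treated as degenerate by the
  analyst. The viability cap substantially stabilises calls in
  viability mode; gIC50 mode has no analogous guard.
* The goodness-of-fit disequilibrium test is mildly conservative (see
  above) and, with `rounded` rounding, discrete in E; tuples with
  E rounding to 0 are untestable even when E_raw > 0.
* Triples are scored only when observed; a strictly mutually exclusive
  triple with co-occurring sub-pairs is invisible to the triple scan.
* Lineage subtraction assumes lineage labels are complete and exact;
  lines with unknown lineage form their own "unknown" stratum.
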