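---
title: "Fuzzy AHP-TOPSIS for scaffold material selection: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy AHP-TOPSIS for scaffold material selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffoldmcdm)
```

## The decision problem

Selecting a biodegradable composite for a load-bearing bone scaffold is a
multi-criteria problem with genuinely conflicting requirements: compressive
strength and stiffness close to cortical bone (roughly 100–150 MPa and
12–18 GPa), open porosity above ~50–60% for vascularisation, degradation
synchronised with the 3–6 month bone-healing window, high cell viability,
and manageable manufacturing cost. No candidate material wins on every
axis; the formulations with the best mechanics tend to have the worst
porosity or the most uncertain biology.

A second, equally important problem is that literature-reported property
values disagree. The same composite measured in different labs — different
printing parameters, filler loadings, testing protocols — yields property
*intervals*, not values. Collapsing an interval to its midpoint discards
exactly the information (worst-case bounds) that a clinically conservative
selection should weigh.

`scaffoldmcdm` addresses both problems with a hybrid fuzzy
multi-criteria decision analysis: evidence is modelled as triangular fuzzy
numbers (TFNs), criterion weights come from fuzzy pairwise expert
judgements (fuzzy AHP, Chang's extent analysis), and candidates are ranked
by fuzzy TOPSIS with a crisp midpoint counterpart for comparison and a
scenario battery for robustness.

## Triangular fuzzy numbers

A TFN $\tilde A = (l, m, u)$, $l \le m \le u$, encodes a pessimistic
bound, a modal value and an optimistic bound. A reported interval $[a, b]$
is fuzzified as $(a, \tfrac{a+b}{2}, b)$; qualitative judgements use the
five-label 1–9 scale VL $(1,1,3)$, L $(1,3,5)$, M $(3,5,7)$, H $(5,7,9)$,
VH $(7,9,9)$. Arithmetic follows the standard triangular approximations:
component-wise addition and (non-negative) multiplication,
$\tilde A^{-1} \approx (1/u, 1/m, 1/l)$, and the component-wise geometric
mean for consolidating several judgements of the same quantity. The
product and reciprocal are approximations — the exact results are not
triangular — and both are restricted to the positive domain where the
approximation is well behaved; `tfn_mul()` rejects negative components
outright. Separation between TFNs is the vertex distance
$$d(\tilde A, \tilde B) = \sqrt{\tfrac13\left[(l_1-l_2)^2 + (m_1-m_2)^2 + (u_1-u_2)^2\right]},$$
which reduces to $|a - b|$ on crisp numbers. This crisp reduction — every
operation collapsing to ordinary real arithmetic when $l = m = u$ — is the
package's primary internal oracle and is exercised throughout the tests.

Where a single representative value is needed (consistency checking,
weights-given mode), two defuzzification conventions are offered: the
centroid $(l+m+u)/3$, the default, and the graded mean $(l+4m+u)/6$.
Neither is privileged mathematically; the centroid is the most common
convention, and the choice is an explicit argument everywhere it matters
so crisp summaries are auditable.

## Weight derivation (fuzzy AHP)

Experts compare criteria pairwise on the linguistic scale, giving
reciprocal TFN matrices ($M_{ji} = M_{ij}^{-1}$, unit diagonal). A panel
is consolidated by the entry-wise geometric mean; because floating-point
geometric means of reciprocal entries drift slightly off reciprocity, the
lower triangle is recomputed as the exact reciprocal of the aggregated
upper triangle, restoring the type invariant exactly.

Crisp weights come from Chang's extent analysis: fuzzy synthetic extents
$S_i = \sum_j M_{ij} \otimes \big(\sum_k \sum_j M_{kj}\big)^{-1}$,
possibility degrees
$$V(S_2 \ge S_1) = \begin{cases} 1 & m_2 \ge m_1\\ 0 & l_1 \ge u_2\\
\frac{l_1 - u_2}{(m_2 - u_2) - (m_1 - l_1)} & \text{otherwise,}\end{cases}$$
scores $d_i = \min_{k \ne i} V(S_i \ge S_k)$, and normalisation. Extent
analysis genuinely assigns zero weight to a criterion whose extent lies
wholly below another's; the package surfaces this as a warning rather than
silently renormalising over fewer criteria, and rejects the fully
degenerate all-zero case. This behaviour appears quickly with narrow
fuzzy spreads and weight ratios above roughly 2–3, which is worth knowing
before interpreting a zero weight as "irrelevant criterion".

Consistency is checked on the defuzzified matrix: the principal eigenvalue
$\lambda_{\max}$ is extracted by power iteration (convergence tolerance
$10^{-10}$; exact on consistent matrices), then
$CI = (\lambda_{\max} - n)/(n - 1)$ and $CR = CI/RI$ with Saaty's
random-index constants for $3 \le n \le 10$; $CR < 0.10$ passes.

The package also runs in *weights-given* mode: when a study supplies local
fuzzy weights directly (as the packaged case study does), they are
accepted as a `weight_vector` with crisp globals either supplied or
derived by defuzzification and normalisation.

## Ranking (fuzzy TOPSIS)

Given an alternatives × criteria TFN matrix and fuzzy weights, the
ranking proceeds in four steps, all data-driven:

1. **Normalisation.** Benefit column $j$: divide each cell by
   $u_j^* = \max_i u_{ij}$. Cost column $j$: with $l_j^- = \min_i l_{ij}$,
   the cell becomes $(l_j^-/u,\; l_j^-/m,\; l_j^-/l)$. All cells land in
   $[0,1]^3$; benefit columns are exactly scale-invariant.
2. **Weighting.** $\tilde v_{ij} = \tilde r_{ij} \otimes \tilde w_j$
   (component-wise).
3. **Ideals and distances.** The fuzzy positive/negative ideal solutions
   are the per-criterion component-wise maxima/minima of the weighted
   normalised cells — observed envelopes, not the fixed
   $(1,1,1)/(0,0,0)$ convention. Separations are summed vertex distances:
   $d_i^* = \sum_j d(\tilde v_{ij}, A_j^*)$, likewise $d_i^-$.
4. **Closeness.** $CC_i = d_i^-/(d_i^* + d_i^-) \in [0,1]$; rank by
   descending $CC_i$, ties broken deterministically by ascending
   alternative code.

**Target-range criteria.** Degradation rate is neither benefit nor cost:
values inside the healing window $[12, 26]$ weeks are ideal. Each vertex
passes through the desirability
$g(t) = t/lo$ below the window, $1$ inside, and
$\max\{0,\, 1 - (t - hi)/(T - hi)\}$ above, with decay anchor $T$
defaulting to 200 weeks — the largest upper bound in the case-study
degradation column, so the slowest-degrading candidate's worst case sits
exactly at zero desirability. Because $g$ is non-monotone, transformed
vertices are re-sorted to restore TFN ordering; the column is then a
benefit criterion on $[0,1]$. The anchor is configurable; rankings are
insensitive to moderate changes but the transform itself is a modelling
choice, not reproduced from any source.

**Degenerate inputs.** Fewer than two alternatives has no ideal spread
and is rejected; an alternative coinciding with both ideals (all
alternatives identical) makes $CC$ undefined and is rejected rather than
patched; cost columns containing zeros are rejected because the flip
divides by cell components.

**Crisp counterpart.** `run_crisp_topsis()` collapses every cell and
weight to its modal value and runs classical TOPSIS (same normalisation
formulas degenerated to ratios, city-block distances) in an independent
code path. On fully crisp inputs the two arms agree to $10^{-9}$ — a
genuine dual-route check, since they share no pipeline code.

## Sensitivity analysis

Five standard scenarios perturb the baseline weights: Baseline;
Biological Focus (cell viability and degradation doubled, strength and
modulus halved); Mechanical Focus (the reverse); Equal Weights (every
criterion 1/6); Cost Focus (cost pinned to 40%, the rest scaled
proportionally into 60%). Porosity stays at baseline in both focus
scenarios, entering only through renormalisation, because the focus
definitions name exactly the two mechanical and two biological criteria.

Scenario semantics, which the original description leaves open, are fixed
as follows: *multiply* directives scale a criterion's crisp weight and its
fuzzy triple by the same factor; *set-to* directives pin the crisp share
exactly and set the fuzzy triple to that crisp share (a share is an
absolute statement, not a rescaling of the baseline's shape — and this is
what makes the Equal scenario genuinely symmetric in the criteria, so its
ranking is invariant to permuting criterion labels, a tested property).
After directives, crisp weights are renormalised to sum exactly to 1,
keeping closeness coefficients comparable across scenarios.

## The packaged case study

The fixture (`load_study_fixture()`, `study_weights()`,
`published_ranking()`) is a five-composite, six-criterion study: PLA/HA,
PCL/HA, PLGA/BG, PLA/CNT and PLA/Mg scored on compressive strength (MPa),
elastic modulus (GPa), porosity (%), degradation rate (weeks, target
window 12–26), cell viability (%) and a 1–9 manufacturing-cost index,
with fuzzy local weights $(0.20,0.25,0.30)$, $(0.15,0.20,0.25)$,
$(0.10,0.15,0.20)$, $(0.10,0.15,0.20)$, $(0.15,0.20,0.25)$,
$(0.05,0.05,0.10)$ and crisp global shares 25.2%, 18.4%, 12.1%, 12.1%,
21.5%, 10.7%.

Two caveats are flagged in the fixture itself:

* **The cost column is an assumption.** The source tables print the five
  property criteria only. The packaged cost-index TFNs are linguistic
  ratings (PLA/HA L, PCL/HA L, PLGA/BG M, PLA/CNT H, PLA/Mg M) chosen
  from the candidates' documented fabrication profiles and mapped through
  the 1–9 scale. Every cost-dependent headline holds *under this
  documented assumption*; supply your own matrix to change it.
* **Published distance magnitudes are not recoverable.** The reference
  table's printed $d^*/d^-$ values sum to ≈ 11.2–11.8 per alternative,
  which no weighted-normalised pipeline can produce (weighted normalised
  cells are bounded by the weight components, so summed vertex distances
  over six criteria stay well below 2). The published closeness
  coefficients are therefore not numerically reproduced here; the
  reproduction targets are the *rank structure* — the top candidate, and
  its stability across scenarios — plus the internal consistency of the
  published table itself, which the test suite checks by recomputing
  $CC$ from the printed distance columns. (One printed row, PLA/CNT, is
  internally inconsistent beyond its own rounding: $6.10/11.24 = 0.5427$
  against a printed 0.544; the corresponding assertion is left failing
  rather than widened.)

```{r study}
dm <- load_study_fixture()
w  <- study_weights()
run_fuzzy_topsis(dm, w)
run_sensitivity(dm, build_default_scenarios(w), w)$stability
```

PLA/HA ranks first and keeps rank 1 in all five scenarios, matching the
reference conclusion; its margin reflects consistent mid-to-high
performance on every axis rather than peak performance on any one.
Notably, under the packaged cost assumption the crisp midpoint analysis
*also* ranks PLA/HA first (PLA/CNT second): the fuzzy-vs-crisp rank
inversion sometimes reported for this kind of data depends on the cost
column, which is exactly the unrecoverable part of the source data —
another reason the cost assumption is kept loud.

## Synthetic data with known ground truth

Because the study's underlying literature measurements are unpublished,
validation rests on generators whose ground truth is planted:

* `gen_dominant_matrix()` draws each cell as three sorted samples of
  $b_j e^{\sigma z}$ (criterion-level base $b_j$, standard normal $z$) —
  log-normal noise keeps everything strictly positive, and one knob
  $\sigma$ controls inter-alternative spread and cell fuzziness together
  ($\sigma = 0$ collapses to identical crisp rows). A designated
  alternative can be pushed 5% past the component-wise best envelope of
  the others, making it strictly dominant: it must rank first under any
  non-negative weights, which is the weight-independent oracle used in
  200-instance batteries.
* `gen_interval_evidence()` simulates $n$ noisy studies of one property
  and reports their range; the fuzzified midpoint converges to the true
  value as noise shrinks.
* `gen_consistent_comparison_matrix()` builds reciprocal TFN matrices
  centred on true ratios $w_i/w_j$ with controllable multiplicative
  perturbation and fuzzy half-width — at zero perturbation the
  consistency ratio is 0 and extent analysis recovers the generating
  weight order.

All generators are pure functions of their seed and leave the caller's
RNG state untouched.

What the generators deliberately do **not** emulate: the empirical
distribution of the ten source studies' measurements (unpublished),
correlations between criteria (real composites trade strength against
porosity; synthetic cells are independent), and heavy-tailed or censored
measurement error. Passing the synthetic batteries therefore demonstrates
algorithmic correctness — dominance consistency, scale invariance, crisp
reduction, oracle agreement — not calibration against real laboratory
variability.

## Numerical conventions and problem sizes

Floating comparisons use absolute tolerance $10^{-9}$ unless a test
states otherwise; the independent straight-line oracle matches the
pipeline to $10^{-12}$; TFN reciprocal involution holds to $10^{-12}$.
Property batteries run 100 crisp-reduction instances, 200 dominance
instances, and 3×3 oracle instances under fixed seeds — sizes at which
every property has either held universally or failed loudly during
development, while the full suite runs in well under a minute. Reported
closeness coefficients are rounded to 3 d.p. in reports and CSV display
columns; full precision is retained internally and in the value columns.

## Known limitations

* Chang extent analysis can zero-out criteria (see above); treat zero
  weights as a method artefact to investigate, not a substantive finding.
* The TFN product/reciprocal are triangular approximations; downstream
  quantities inherit that approximation, as in all fuzzy AHP/TOPSIS
  practice.
* The target-range desirability is piecewise linear with a configurable
  decay anchor; other shapes (e.g. asymmetric smooth penalties) are
  plausible and would shift closeness coefficients, though not, in the
  packaged study, the top rank.
* Classification labels ("Optimal", "Suitable—Balanced", …) are free-text
  report annotations supplied with the data, never computed.
* The five-candidate, six-criterion case study is a fixed snapshot;
  adding alternatives (the ideals are data-driven envelopes) can change
  intermediate ranks.
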