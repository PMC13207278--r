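# scaffoldmcdm

Fuzzy multi-criteria decision analysis for biomaterial selection, built
around the problem of choosing a biodegradable polymer-matrix composite
for load-bearing bone-tissue-engineering scaffolds. The package is for
biomaterials researchers and decision analysts who need to rank candidate
materials on conflicting criteria when the underlying evidence is a set
of disagreeing literature intervals rather than single values.

## What it computes

Evidence is modelled as triangular fuzzy numbers (TFNs)
Ã = (l, m, u): a reported interval [a, b] becomes (a, (a+b)/2, b), and
qualitative ratings map through the five-label scale VL (1,1,3) …
VH (7,9,9). On top of that atom the package provides:

* **Fuzzy AHP weights** — expert pairwise-comparison matrices are
  consolidated by entry-wise geometric mean and converted to crisp
  criterion weights by Chang's extent analysis
  (Sᵢ = Σⱼ Mᵢⱼ ⊗ (Σₖ Σⱼ Mₖⱼ)⁻¹, possibility degrees V(Sᵢ ≥ Sₖ),
  normalised minima), with consistency checking
  (CR = CI/RI, CI = (λmax − n)/(n − 1), pass when CR < 0.10).
* **Fuzzy TOPSIS ranking** — linear-scale normalisation, component-wise
  fuzzy weighting, data-driven fuzzy positive/negative ideal solutions
  (per-criterion component-wise extrema), summed vertex distances
  d(Ã, B̃) = √{⅓[(l₁−l₂)² + (m₁−m₂)² + (u₁−u₂)²]}, and closeness
  coefficients CCᵢ = dᵢ⁻/(dᵢ* + dᵢ⁻). Target-range criteria (degradation
  synchronised to bone healing, window 12–26 weeks) pass through a
  piecewise-linear desirability first. A crisp midpoint TOPSIS provides
  the comparison arm.
* **Sensitivity analysis** — five standard weighting scenarios
  (baseline, biological focus, mechanical focus, equal weights, cost
  focus) with a rank-stability summary.
* **Synthetic generators** — decision matrices with planted dominant
  alternatives, simulated inter-study evidence intervals, and
  near-consistent fuzzy comparison matrices with known weight order, so
  every stage is testable against ground truth.

The five-composite case study (PLA/HA, PCL/HA, PLGA/BG, PLA/CNT, PLA/Mg
on strength, modulus, porosity, degradation, cell viability, cost) ships
as a packaged fixture, including its reference ranking table. The
cost-index column is a documented package assumption (the source tables
do not print it) — see the vignette.

## Worked example

```r
library(scaffoldmcdm)

dm <- load_study_fixture()   # 5 alternatives x 6 criteria of TFNs
w  <- study_weights()        # fuzzy local weights + crisp globals
run_fuzzy_topsis(dm, w)
#> Fuzzy TOPSIS ranking
#>  rank code    name    cc d_pos d_neg                         label
#>     1   A1  PLA/HA 0.812 0.108 0.464                       Optimal
#>     2   A5  PLA/Mg 0.528 0.264 0.295             Suitable—Balanced
#>     3   A4 PLA/CNT 0.510 0.272 0.283        Suitable—High Strength
#>     4   A3 PLGA/BG 0.379 0.348 0.212 Sub-optimal—Rapid Degradation
#>     5   A2  PCL/HA 0.246 0.419 0.137      Sub-optimal—Low Strength
```

PLA/HA wins not by peaking on any criterion but by avoiding every
disqualifier: it has no critical weakness on strength, biology or
degradation timing, so it sits closest to the positive ideal and farthest
from the negative one (cc = d⁻/(d* + d⁻)). Robustness of that conclusion:

```r
run_sensitivity(dm, build_default_scenarios(w), w)$stability
#>  code min_rank max_rank top_count
#>    A1        1        1         5
#>    A2        2        5         0
#>    A3        4        5         0
#>    A4        2        4         0
#>    A5        2        3         0
```

PLA/HA holds rank 1 in all five weighting scenarios; the volatile
candidates (PCL/HA, PLGA/BG) swing between rank 2 and rank 5 as the
weight emphasis moves between biology and mechanics.

Deriving weights from your own expert panel instead:

```r
panel <- read_panel_json("panel.json")      # TFN or linguistic entries
agg   <- aggregate_panel(panel)
consistency_ratio(agg)                      # CR < 0.10 expected
chang_extent_weights(agg)
```

A command-line wrapper (`inst/cli/scaffoldmcdm.R`) exposes the same
pipeline as `rank`, `crisp`, `ahp`, `sensitivity`, `simulate` and
`fixture` subcommands writing CSV/JSON reports with provenance records.

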