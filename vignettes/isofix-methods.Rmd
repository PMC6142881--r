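---
title: "Quantifying symbiotic N2 fixation from 15N natural abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying symbiotic N2 fixation from 15N natural abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isofix)
```

## The method

Legumes in symbiosis with rhizobia draw nitrogen from two pools: the
soil and the atmosphere. Because biological N2 fixation discriminates
only weakly among N isotopes while soil N is usually enriched in 15N,
the 15N "signature" of a legume falls between that of soil-grown,
non-fixing plants and that of a plant living entirely on fixed N2. The
natural-abundance method turns this dilution into a quantitative
estimate.

All isotope measurements are expressed in delta notation,

$$\delta^{15}\mathrm{N}\ (\unicode{x2030}) =
  \frac{R_{sample} - R_{atm}}{R_{atm}} \times 1000,$$

where $R$ is the $^{15}$N/$^{14}$N abundance ratio and
$R_{atm} = 0.0036765$ is the atmospheric standard (`delta15n()`,
`R_ATMOSPHERE`). The percentage of plant N derived from the atmosphere
is then

$$\%Ndfa = \frac{\delta^{15}\mathrm{N}_{ref} -
  \delta^{15}\mathrm{N}_{leg}}
  {\delta^{15}\mathrm{N}_{ref} - B} \times 100,$$

with three ingredients:

* $\delta^{15}\mathrm{N}_{ref}$ — the arithmetic mean delta-15N over
  all non-fixing reference species sampled at a site
  (`reference_means()`); it proxies the signature of plant-available
  soil N.
* $\delta^{15}\mathrm{N}_{leg}$ — the legume shoot value.
* $B$ — the delta-15N a legume attains when fully dependent on
  fixation, measured on glasshouse plants grown in N-free culture. $B$
  calibrates the isotopic fractionation of the fixation pathway
  itself; since field samples are shoots, we use the mean *shoot*
  delta-15N of the glasshouse landraces as $B$ (`b_value()`).
  Whole-plant values, the N-content-weighted organ means
  $$\delta^{15}\mathrm{N}_{whole} =
  \frac{\delta_s N_s + \delta_r N_r}{N_s + N_r},$$
  are computed for reporting (`whole_plant_delta15n()`) but are never
  substituted for the shoot-based $B$: mixing a whole-plant $B$ with
  shoot-sampled field material would bias %Ndfa because roots are
  systematically less depleted than shoots.

Per-hectare budgets follow from per-plant arithmetic: shoot N content
(mg/plant) is dry matter times %N; N-fixed (kg/ha) is the fixed
fraction of shoot N scaled by plant density; soil N uptake is the
remainder:

$$\mathrm{Nfixed} = \frac{\%Ndfa}{100} \times N_{shoot} \times D,
\qquad \mathrm{Nsoil} = N_{total} - \mathrm{Nfixed}.$$

The default density, $D = 2 / (0.20 \times 0.60)\,\mathrm{m^2} =
166\,666.7$ plants/ha, encodes the 20 cm x 60 cm planting grid with
two plants per hole used in the field design this package mirrors; it
is a plain argument everywhere it enters.

## Aggregation order

`run_full_analysis()` computes every quantity per plant first and only
then averages within a treatment cell, reporting mean ± SE (SE =
SD/sqrt(replicates)). The alternative — plugging cell means into the
formulas — is *not* equivalent: %Ndfa x N content is a product, and
the mean of products differs from the product of means whenever the
two covary within a cell. On the published summary tables this
package ships as fixtures, recomputing N-fixed from cell means
deviates from the per-plot-aggregated published values by up to ~5%
in cells with strong within-cell covariance, which is why the
pipeline insists on per-plant computation and why table-reproduction
tests allow a few percent of slack on kg/ha quantities while holding
%Ndfa to ±0.5 points.

## Out-of-range %Ndfa

Measurement noise can push individual %Ndfa estimates outside
[0, 100] (a legume slightly *more* enriched than the reference, or
more depleted than $B$). The estimator returns the raw value and
flags offenders (`ndfa_out_of_range` attribute, surfaced in the
report's warning list); an optional `clamp = TRUE` truncates to
[0, 100]. Raw-by-default was chosen because truncation biases cell
means upward/downward asymmetrically and hides data problems; the
clamp exists for budget tables that must stay physical. If the
reference mean equals $B$ the denominator vanishes and the analysis
aborts with an explanatory error rather than returning infinities.

## The statistical layer

The field design is a balanced two-site x five-landrace x
two-inoculation factorial with four replicate plots.
`factorial_anova()` fits the fixed-effects factorial (optionally with
an additive block term) through `stats::aov`; under balance the
classical sequential sums of squares are unambiguous (Type I = Type
III), and the suite verifies them against a brute-force
mean-decomposition oracle. Unbalanced data are rejected outright —
with unequal replication the SS decomposition is convention-dependent
and silently picking one would mislead. A numerically negligible
residual SS (noise-free responses) is reported as the sentinel
F = Inf with p = 0.

Mean separation uses Duncan's multiple range test (`duncan_mrt()`).
For a span of $p$ ranked means the critical range is
$q_{1-\alpha_p}(p, df)\sqrt{MS_e/n}$ with the protection level
$\alpha_p = 1 - (1-\alpha)^{p-1}$; studentized-range quantiles come
from `stats::qtukey` (numerical quantiles, cross-checked in the test
suite against independently computed table values). Letters are
assigned one per maximal homogeneous span, and per the test's
protection rule a span inside a homogeneous span is never re-tested,
which guarantees transitive-consistent letters. Following protected
usage, `trial_stats_report()` separates means only when the omnibus
F for that factor is significant at $\alpha$ (default 0.05);
`protected = FALSE` disables the gate.

Correlation/regression panels (`pearson_correlation()`,
`linear_regression()`) are thin wrappers over `stats::cor.test` and
`stats::lm`, reported per site for the standard symbiosis
relationships (%Ndfa vs soil N uptake, shoot DM vs N content and
N-fixed, delta-15N vs %Ndfa).

## SSR scanning

The companion sequence component asks a small, exact question: which
1–6 nt motifs occur as maximal tandem arrays in an amplicon, and how
far does each aligned sequence sit from the alignment consensus?

`scan_ssrs()` reports maximal, non-extendable tandem runs with
1-based inclusive coordinates; the reported extent covers whole
copies only (`end - start + 1 = unit x count`). Motifs are reported
as found (no rotation canonicalisation, so a "CT" array is "CT", not
"TC"), with an optional canonical mode. Runs whose unit is itself
periodic are reported at their shortest period, and when runs of
different unit length overlap, the longer run wins. Default minimum
counts are 8 for mononucleotide, 5 for dinucleotide and 4 for longer
motifs — conventional microsatellite search settings, since no
threshold is dictated by the data themselves. One convention caveat:
because trailing partial copies are trimmed, a run whose full span is
not an exact unit multiple changes its anchor under
reverse-complementation; the mirror-symmetry property is exact for
exact-multiple arrays, which is how the suite tests it.

`consensus_mismatches()` builds a per-column majority consensus over
unambiguous bases; tie columns are excluded for every sequence, a gap
or `N` never forms consensus, and a gap under a base consensus counts
as a mismatch — the most conservative reading of a "nucleotide
mismatch difference". Counting against a majority consensus (rather
than against one designated sequence, or summed pairwise) is an
interpretation; the three definitions differ and downstream users
comparing to externally reported mismatch counts should check which
one was meant.

## The synthetic world

`trial_sim_config()` / `generate_trial()` emulate the study design:
every measurement is an independent Gaussian draw around a configured
true cell mean. Defaults are set at the magnitudes of a West African
Kersting's groundnut trial — shoot DM 15–27 g/plant, shoot N near 3%,
legume delta-15N +1.0 to +1.9 permil, site reference means +3.95 and
+3.04 permil (SD 0.63 / 0.88, nine species per site), glasshouse
shoot values −3.68 / −3.99 permil — with within-cell SDs set to twice
the cell SEs typical of such trials (SE x sqrt(4 reps)): 2.0 g for
shoot DM, 0.25 permil for delta-15N, 0.25 points for %N. Organ N
contents for the glasshouse plants (100 mg shoot / 50 mg root) are
plausible magnitudes chosen once, since no published values exist for
them.

What the generator does *not* emulate: spatial field trends and block
effects, non-Gaussian or correlated measurement error, and any
mechanistic coupling between nodulation and fixation. Correlation
between shoot DM and N content arises structurally (content = DM x
%N), not from a covariance parameter. Passing the recovery tests
therefore shows the *arithmetic and statistical machinery* is
correct, not that real field data meet these assumptions.

`generate_ssr_sequences()` plants exact tandem arrays into uniform
random background and resamples the two flanking bases where needed
so a planted run cannot extend by chance — this makes
"every planted array is recovered at its exact coordinates" a sharp,
deterministic property rather than a probabilistic one.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds; generators
  save and restore the caller's RNG state.
* Residual-SS zero detection uses a relative threshold of 1e-10
  against the model SS.
* Budget closure (N-fixed + soil N = total N) is exact by
  construction per plant; cell means close to floating tolerance.
* The suite's Monte-Carlo sizes — 1 000 null trials for ANOVA type-I
  calibration, 10 x 20 cells for 2-SE %Ndfa coverage, 1 000 planted
  500-nt sequences for scanner/oracle equivalence, 200 power
  simulations — were chosen as the smallest sizes at which the
  binomial noise of the checked rates is well inside the asserted
  bands.

## Limitations

* The B value is treated as a constant of the landrace set; genotype-
  or age-dependent B variation propagates directly into %Ndfa and is
  not modelled.
* The block structure of the original randomized-complete-block
  layout is supported only as an additive factor; block x treatment
  interactions and mixed models are out of scope.
* Only the natural-abundance variant is implemented; 15N-enriched
  (labelled-fertilizer) designs need different estimators.
* Grain moisture is taken as reported; no correction is applied.
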