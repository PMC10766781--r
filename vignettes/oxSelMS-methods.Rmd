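---
title: "Models and methods behind oxSelMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind oxSelMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxSelMS)
```

`oxSelMS` quantifies how selectively an ESI source ionizes oxidized
triacylglycerols (oxTAGs) relative to their non-oxidized precursors in
flow-injection MS, and finds the ionization conditions that maximize that
selectivity. This vignette explains the underlying models, the tunable
parameters, and the design choices made where the design was genuinely
open.

## The combinatorial composition model

NMR quantifies oxidation *groups*, not oxidized *molecules*: aldehyde,
epoxide and hydroperoxide concentrations in mol per kg TAG. To normalize MS
areas we need the fraction of TAG molecules at each oxidation degree, so we
bridge the two with a deliberately simple combinatorial model resting on
two assumptions:

1. **At most one oxidized group per fatty-acid chain.** Multiply-oxidized
   chains are rare in predominantly mono-unsaturated oils, so a chain
   carries 0 added oxygens, 1 (epoxide or aldehyde) or 2 (hydroperoxide).
   Chain-shortened aldehydic degradation products ("2.5 glycerides") are
   counted as intact mono-oxygenated chains; their levels are low in the
   reference oil and they are otherwise out of scope.
2. **A mean TAG molecular mass**, default 885 g/mol (triolein, the dominant
   TAG of rapeseed oil). This converts 1 kg of oil into
   `1000/885 = 1.13` mol TAG and three times as many mol of chains.

With `molFA = 3·1000/M`, the per-chain fractions are
`p1 = (aldehyde + epoxide)/molFA`, `p2 = hydroperoxide/molFA`,
`p0 = 1 − p1 − p2`. Treating the three *sn* positions as independent draws
gives the trinomial distribution of the total added oxygens k per TAG,

$$P(k) \;=\; \sum_{i+j+l=3,\; j+2l=k} \frac{3!}{i!\,j!\,l!}\;
p_0^i\,p_1^j\,p_2^l, \qquad k = 0,\dots,6,$$

equivalently an enumeration of the $3^3 = 27$ ordered chain-state triples
(`enumerateOxTriples()`). Degrees 5 and 6 are computed and reported but
flagged negligible below a configurable 0.5 % threshold, the conventional
cut for this kind of composition estimate.

```{r nmr}
prof <- faProfileFromNmr(oxidizedRapeseedOilNmr(), digits = 3)
tagOxDistribution(prof)
```

**Numerical precision.** The pipeline computes at full double precision by
default. The `digits` argument of `faProfileFromNmr()` optionally rounds
`p1`/`p2` to a reported precision first (recomputing `p0` as the
complement). This exists because worked examples in the literature are
computed from fractions quoted at three decimals, and reproducing such a
printed distribution to the 0.01-percentage-point level requires carrying
the intermediates at the same precision; at full precision the zero-degree
term differs by about 0.15 percentage points. Both paths are exercised in
the test suite.

## Adducts, mass windows and areas

Neutral TAGs ionize in positive mode as [M+NH₄]⁺, [M+Na]⁺ and minor [M+H]⁺
adducts. Target m/z values are computed from elemental formulas
(monoisotopic by default, nominal optionally), each oxidation degree adding
15.9949 Da. Quadrupole survey tables quote observed masses at unit
resolution; the package computes theoretical masses and matches such tables
within ±0.7 Da, because theoretical values are reproducible whereas
instrument calibration offsets are not.

Stage-1 selectivity integrates two fixed mass windows (non-ox 880–910 Da,
ox 912–970 Da for oil, analogous pairs for OOO/OOL standards). Windows are
**half-open** `[lo, hi)` so a centroid falls in exactly one window of a
partition — boundary handling is a convention, not a measurement, and this
one makes window areas exactly additive. Stage-2 uses extracted-ion areas
with a ±0.35 Da default tolerance, matching unit-resolution targets quoted
to one decimal; it is configurable for other instruments.

Multiple scans of a flow-injection run are **summed**, not averaged: areas
then scale identically for oxidized and non-oxidized species and the
selectivity ratio is invariant, so the choice cannot bias results. The
integration convention (sum over scans rather than apex) is likewise
documented as a convention: figure-level data cannot arbitrate it.

## The selectivity factor

$$S = \frac{A_{ox}/f_{ox}}{A_{nonox}/f_{nonox}}$$

with $f$ the model composition fractions. $S$ is dimensionless, invariant
under global intensity rescaling, and equals the pure ionization-efficiency
ratio when peaks are isolated and no in-source fragmentation occurs.
Degenerate cases are handled explicitly: a zero non-oxidized area yields an
`Inf` sentinel (flagged, excluded from ANOVA with a logged count — a
statistic cannot digest infinities), and a zero composition fraction (fresh
oil) is a hard error, since normalization is then undefined.

Replicates are averaged *after* computing per-replicate selectivity, which
preserves the error-bar semantics of replicate spread; averaging areas
first differs only at second order in the noise.

## The 3^(5−1) design

Five source factors — additive type (NH₄Fo / NaOAc / NaI, categorical),
additive concentration (0.05/0.1/0.2 mM), sheath gas temperature
(150/250/350 °C), capillary voltage (2000/3500/5000 V), nozzle voltage
(500/1000/1500 V) — in a regular one-third fraction of the 3⁵ factorial: 81
runs, the full factorial on A–D with `E = A+B+C+D (mod 3)` on level
indices. The defining word has length 5 (resolution V), so main effects
(2 df each) and two-way interactions (4 df each) are aliased only with
three-way and higher terms. Run numbering is lexicographic over (A,B,C,D).
This default generator-plus-numbering reproduces every published condition
set we could cross-check (e.g. set #42 = NaOAc, 0.1 mM, 250 °C, 5000 V,
1500 V), so it appears to be the same fraction used in the original
campaigns; the generator remains configurable for other regular fractions.
The concentration levels follow the condition descriptions (0.05/0.1/0.2 mM
for every additive); a published level table lists "5/10/20" for NH₄Fo,
which we treat as a typesetting artifact since every quoted condition uses
the millimolar values.

Validation checks are structural: 81 distinct runs, each factor level 27
times, each ordered level pair 9 times, and closure of the run set under
GF(3) addition (the fraction is a linear code).

## ANOVA, Tukey comparisons and recommendation

Per response (one species × oxidation degree × adduct — responses are never
pooled, as significance patterns differ between compounds), `stats::aov`
fits the 15-term model. On the balanced orthogonal fraction the sequential
sums of squares coincide with types II/III, so the type question is moot;
balance is a precondition. All factors enter as unordered 3-level factors —
additive type is genuinely categorical, and treating the numeric factors
categorically avoids assuming linearity over their wide ranges. A `log`
response transform is exposed (and used in calibration tests) because the
generator's noise is multiplicative, making log-selectivity exactly
Gaussian under the null; raw selectivity is the default for fidelity to
common practice. α = 0.05 throughout, with no correction across responses —
a documented limitation, matching standard usage.

`recommendConditions()` ranks condition sets by mean z-scored selectivity
across responses (so strong responders do not dominate), breaks ties by
lower replicate SD, and reports per-factor Tukey winners. Responses that
are numerically constant are skipped: their F ratios would be
floating-point noise, and the result is flagged "no discrimination".

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions: 81 condition sets × 2 replicates (duplicate injection being the
norm for such campaigns), centroided sticks at the target-ion m/z values,
and intensity

`amount × P(k) × eff × adductWeight(additive, adduct) × oxBoost(condition) × noise`.

- **Adduct weights** key the adduct pattern to the additive (NH₄Fo → mainly
  ammoniated with minor protonated/sodiated; Na salts → sodiated), the
  qualitative behavior of real sources.
- **Factor effect curves** multiply oxidized-species intensity per factor
  level. The planted default mirrors the qualitative narrative of real
  campaigns — additive type dominant (NaOAc 6×, NaI 4× vs NH₄Fo),
  concentration and temperature peaking at mid level, high capillary
  voltage ≈2×, nozzle voltage inert — placing the optimum at
  (NaOAc, 0.1 mM, 250 °C, 5000 V, ·), i.e. run #42. This is a test
  scenario, not a claim of reproducing measured selectivity magnitudes;
  published values (6.6, 13.0, 120, …) appear only as planted efficiency
  ratios in oracle tests.
- **Leakage** moves a fraction f of each oxidized stick to the species'
  non-oxidized m/z, emulating in-source fragmentation with oxygen loss;
  total intensity is conserved, and stage-1 selectivity decreases
  monotonically in f while isolated stage-2 ions are biased the same
  direction — the known bidirectional-overlap limitation of window-based
  selectivity.
- **Noise** is multiplicative log-normal with unit mean and CV 10 % by
  default, the magnitude of typical ESI intensity variability; campaigns
  are deterministic under a seed.

What the generator does **not** emulate: isotope envelopes, profile peak
shapes, matrix/suppression effects, interferent lipid classes (available
only as an explicit option), or drift over injection time. Passing tests
therefore demonstrate correctness of the *analysis* under a known ground
truth, not instrument realism.

## Problem sizes and calibration checks

The statistical tests run at deliberately small problem sizes chosen to
keep the suite quick while leaving the checks well-powered: oracle
equivalence of the composition model on 100 random profiles; ANOVA type-I
calibration on 500 seeded null campaigns (single species, single adduct,
one oxidation degree — the smallest spectra that still exercise the full
pipeline), asserting the mean rejection rate over the 15 model terms within
two binomial standard errors of 0.05; and planted-optimum recovery in at
least 18 of 20 seeded campaigns at noise CV 0.1.

## Known limitations

- The composition model ignores multiply-oxidized chains and treats all
  chains as oxidizing identically; real OOL oxidizes faster than OOO, which
  shifts per-species fractions in real oils.
- Selectivity magnitudes from standards do not transfer quantitatively to
  oils (matrix effects); the pipeline treats each sample's records
  separately for this reason.
- The mzML writer emits minimal centroided documents (uncompressed 64-bit);
  it is meant for fixtures and round-trip validation, not as a general
  converter.
- With a single replicate and the full two-way model, residual degrees of
  freedom drop to 30 of 81; the fit refuses to proceed only when the model
  saturates completely.
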