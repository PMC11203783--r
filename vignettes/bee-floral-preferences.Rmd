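---
title: "Modelling bee floral-trait preferences: colour space, choice models, and antennal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bee floral-trait preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

beechoice analyses two-choice preference experiments with bees, together with
the sensory measurements that usually accompany them: reflectance spectra of
the artificial flowers, electroantennographic (GC-EAD) response tables for the
scent compounds, and weighings of rewarding flowers that differ in depth. This
vignette explains the models, the parameters that matter, the synthetic-data
generator, and the numerical and design choices, in that order.

## The hexagon colour-vision model

Bees are trichromats with UV, blue and green photoreceptors. The package
models what a bee sees when a coloured stimulus is viewed against an adapting
background (typically green foliage or, in an experiment, a green cardboard).

For receptor $i \in \{U, B, G\}$ with sensitivity $S_i(\lambda)$, stimulus
reflectance $I_S(\lambda)$, background reflectance $I_B(\lambda)$ and
illuminant $D(\lambda)$, the adapted quantum catch is

$$P_i = R_i \int I_S(\lambda)\, S_i(\lambda)\, D(\lambda)\, d\lambda,
\qquad
R_i = \frac{1}{\int I_B(\lambda)\, S_i(\lambda)\, D(\lambda)\, d\lambda}.$$

The von Kries factor $R_i$ expresses receptor adaptation to the background:
the background itself always yields $P = (1,1,1)$, whatever the illuminant
scale — which is why the D65 normalisation (mean 1 over the grid) is pure
convention and provably without effect on any locus (there is a test for
this). Excitation follows the saturating transform $E_i = P_i/(P_i+1)$, so
the background maps to $(0.5, 0.5, 0.5)$, and the two-dimensional hexagon
coordinates are

$$x = \frac{\sqrt{3}}{2}(E_G - E_U), \qquad
  y = E_B - \tfrac{1}{2}(E_U + E_G).$$

The background sits at the origin; the pure-receptor corners are at distance
1 (the hexagon circumradius, an upper bound for any physical stimulus — a
property verified on $10^5$ random excitation triplets). Two derived
quantities matter for preference experiments:

* **Centre distance** $\sqrt{x^2+y^2}$: how strongly a stimulus differs from
  the adapted background. The experimental design this package accompanies
  calls this quantity *achromatic contrast*; most colour-vision literature
  would call it chromatic contrast or spectral purity. Because the
  terminology collides, the conventional green-receptor contrast
  $|E_G - 0.5|$ is exposed separately as `green_contrast` and never
  conflated with the centre distance.
* **Hue angle**: the direction of the locus, 0° at vertical-up. Whether the
  angle increases clockwise or counterclockwise is a convention the
  underlying definition leaves open; the package defaults to clockwise,
  which places the green vertex at 120° and a yellow long-pass stimulus in
  the 120–180° sector, and the orientation is a documented argument
  (`orientation`) everywhere an angle is produced.

```{r}
library(beechoice)
spectra <- gen_cardboard_spectra()
loci <- contrast_report(spectra, background = "green_background")
autoplot(loci)
hexagon_distances(loci)
```

### Receptor sensitivities and the illuminant

Receptor curves default to A1 visual-pigment templates at the honeybee peak
wavelengths 344 nm (UV), 436 nm (blue) and 544 nm (green), generated from
the alpha band of the Govardovskii nomogram. The beta band is deliberately
omitted: it would add a secondary UV mode to the long-wavelength templates,
breaking the unimodality the rest of the machinery assumes, and its
contribution is largely cancelled by background adaptation. Measured
sensitivity curves can be swapped in through any spectra CSV
(`read_spectra_csv()`), since bee species differ little in their visual
pigments but measured data always beat a template.

The illuminant defaults to CIE standard daylight D65, embedded as the
canonical 5 nm tabulation (300–780 nm) and interpolated onto the working
grid. A flat illuminant is available for controlled comparisons.

### Numerical choices

All spectral inputs are resampled by linear interpolation onto one shared
grid (default 300–700 nm at 1 nm — the range relevant to bee vision) and
integrated with the trapezoidal rule. This is deterministic and agrees with
a 0.1 nm quadrature oracle to relative error below $10^{-4}$ on smooth
spectra, which is far below any biologically meaningful difference.
Extrapolation outside a spectrum's measured range is refused rather than
zero-filled. Hue angles are undefined (NA) within $10^{-6}$ hexagon units of
the centre. Reflectance may exceed 1 up to a ceiling of 1.2, tolerating
calibration artefacts near strong reflectors.

## Two-choice preference models

Each record is one bee's first choice between two variants of a single
floral trait (colour hue, achromatic contrast, corolla size, scent
complexity, flower depth). `fit_two_choice()` fits a binomial logistic
model. The outcome coding is a single fixed rule — *success = alphabetically
second variant label* — which keeps signs consistent across traits and is
overridable via `success`. For the intercept-only model the maximum
likelihood solution has the closed form

$$\hat\beta_0 = \ln(a/b), \qquad \mathrm{SE} = \sqrt{1/a + 1/b},$$

for $a$ successes and $b$ failures. `intercept_closed_form()` implements it
as an independent oracle; the iterative GLM (fitted with a tightened IRLS
tolerance of $10^{-12}$) matches it to $10^{-6}$, property-tested over
random counts. Complete separation (a variant never chosen) is reported as
a signed infinite estimate with a `separation` flag rather than an error or
a bias-corrected estimate, keeping the contract transparent.

Global models pool species as a fixed factor. Experimental block structure
(the base colour in contrast experiments, the mixture identity in scent
experiments) also enters as a fixed factor: per-species pooled results of
the motivating design are exactly consistent with fixed-effect fits, and a
variance component estimated from two or three blocks would be meaningless;
a random-intercept model remains a plausible alternative reading for larger
designs.

Significance is a two-sided Wald test at $\alpha = 0.05$, strict inequality
(p exactly 0.05 is "no preference"), with no multiple-testing correction —
matching common practice for these designs, where each trait is one planned
comparison.

### Recovering counts from published coefficients

Published tables often print the intercept estimate and standard error but
not the raw counts. Because the intercept-only fit is a closed form of
$(a, b)$, the counts can be recovered by exhaustive search
(`recover_counts()`): among all integer pairs with $a + b \le 500$ whose
closed-form values round to the printed ones at three decimals, return the
pair minimising the squared discrepancy, and report how many pairs matched.
Occasionally two pairs reproduce the printed (estimate, SE) but differ in
the third decimal of $z$; supplying the printed $z$ as an additional filter
(`z_value`) resolves the ambiguity. Recovered pairs are reconstructions and
are labelled as such throughout.

```{r}
recover_counts(1.099, 0.320)   # 39 vs 13 choices
recover_counts(0.937, 0.155)   # 148 vs 58
```

## EAG activity scoring and mixture arithmetic

GC-EAD response calling from raw traces is out of scope (no amplitude
threshold generalises across preparations); the module ingests binary
antenna × compound tables, one row per antenna from a distinct female.
`activity_summary()` reports responders, sample size, the raw fraction and
a percentage; a compound is *active* for a species when at least half of
the tested antennae responded — an inclusive threshold, so 5 of 10 counts
as active. Display rounding is configurable (`round` vs `truncate`, since
printed tables sometimes truncate 4/6 to 66%), but classification always
uses the raw fraction, so a display convention can never change an activity
call.

Mixture arithmetic is deliberately plain: equal-part mixtures at a total of
10 µg substances per mL pentane give 2.5 µg/mL per substance in a
four-compound mixture and 0.83 µg/mL in a twelve-compound mixture, and an
applied aliquot of 30 µL × 10 µg/mL delivers 300 ng. Some published
protocols print applied masses a factor of ten lower than their stated
volumes and concentrations imply; the package computes strictly from the
inputs and leaves the discrepancy visible rather than silently adopting
either number.

## Consumption analysis

Rewarding artificial flowers are weighed before the experiment, after 40
minutes and after 2 hours; `consumption_rates()` converts the weight drop
into mg/h per flower, clipping small negative differences (evaporation,
scale noise) to zero with a warning. Flat and deep flowers are compared
with a Mann–Whitney U test implemented with midranks: exact enumeration of
all labellings for combined samples up to 12 (exhaustive and therefore
correct under ties, which `stats::wilcox.test` refuses to do exactly), and
a normal approximation with tie correction above that. On tie-free data the
exact path agrees with `wilcox.test` to machine precision.

## The synthetic-data generator

No raw data accompany the motivating study design, so the package generates
every input it needs, deterministically under a seed (`bee_scenario()`).
The generator emulates:

* **Cardboard spectra** — smooth parametric families: a long-pass logistic
  step for yellow (5% to 70% reflectance around 500 nm), a Gaussian blue
  bump (450 nm, σ 30 nm), a mid-band green background (550 nm, σ 50 nm),
  and *light* variants built as convex mixtures of parent and background.
  Mixing toward the background guarantees the structure measured cardboards
  show — same hue direction, smaller centre distance — and the default
  weights (0.39 for light yellow, 0.78 for light blue) mirror the ratio of
  published centre distances for those cardboard types (0.091/0.234 and
  0.169/0.217). Absolute distances are *not* calibrated: the measured
  spectra are unpublished, so printed distances serve only as qualitative
  ordering checks.
* **Choices** — independent Bernoulli first choices per trait × species
  cell. Default cell sizes are the count reconstructions from the published
  coefficients (e.g. 52 and 206 approaches for the hue experiments); the
  one internally inconsistent published row (size, halictid species, where
  the printed SE contradicts the printed z) uses a plausible
  reconstruction assuming the SE is a misprint of 0.339, i.e. 12 vs 32
  choices.
* **EAG tables** — Bernoulli responses at per-compound response rates, with
  a `force_counts` mode that reproduces exact responder counts (10, 10 and
  6 antennae per species) for fixture grids.
* **Consumption** — lognormal per-flower rates with depth-specific means
  (defaults 90 vs 30 mg/h, σ~log~ 0.5, 9 flowers per arm, mirroring a
  threefold flat/deep ratio at the published replication level), and
  weights derived as initial weight minus rate × elapsed time, hence
  nonincreasing by construction.

What the generator does **not** emulate: positional or temporal
autocorrelation in choices (bees revisiting, learning within a session),
scent-mark avoidance, antenna-to-antenna sensitivity correlations, or
measurement noise in weighings. Passing tests on synthetic data therefore
demonstrate that the estimators recover the parameters of this idealised
process at realistic sample sizes — not that real assays satisfy the
independence assumptions.

Problem sizes used in the test suite were chosen to make sampling
distributions tight enough for sharp assertions while keeping the whole
suite fast: $10^4$ choices for parameter recovery (binomial error ±0.03),
$10^5$ excitation triplets for the circumradius bound, and 200 replicates
for the null-uniformity and power checks of the depth experiment (80%
power at a threefold rate ratio with 9 flowers per arm).

## Known limitations

* The hexagon model is deterministic; receptor-noise discrimination models
  (ΔS/JND) and detection thresholds are out of scope, so centre distances
  order stimuli but do not predict discriminability.
* Count recovery is exact inversion of a rounding, not inference: when
  several integer pairs match the printed rounding the ambiguity is
  reported, and recovered counts should never be presented as data.
* The fixed-factor treatment of experimental blocks is a modelling choice
  appropriate for two or three blocks; designs with many blocks should fit
  a proper mixed model instead.
* EAG activity calls inherit whatever response-calling the analyst applied
  to the raw traces; the 50% rule is a convention, and with 6 antennae the
  threshold sits exactly on 3 responders.
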