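---
title: "Enzyme characterization with enzchar: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enzyme characterization with enzchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzchar)
```

enzchar implements the complete quantitative characterization chain for a
hydrolytic enzyme: assay calibration and units, Michaelis–Menten kinetics,
inhibition-mode classification, activation and inactivation thermodynamics,
screening/response-surface optimization of expression, and protein sequence
properties. This vignette is the package's own account of the underlying
models, the unit conventions that matter, the choices made where the design
was genuinely open, and what the synthetic-data generators do and do not
emulate. The running example is CelC307, a GH5 endoglucanase from the
thermophile *Cohnella* sp. A01, whose published parameter tables ship with
the package as reference data (`celc307_*()`).

## Activity units and profiles

One enzyme unit (U) liberates 1 µmol of reducing sugar per minute, measured
against a linear DNS calibration (`fit_linear_calibration()`, ordinary least
squares). Absorbances below the calibration intercept would imply negative
product; `activity_units()` clamps these to zero and flags them, because a
blank cannot consume sugar. Profiles are normalized with the maximum mapped
to 100% (`relative_activity_profile()`); ties resolve to the first
occurrence so exactly one entry is 100%, and replicates are averaged first
with their spread carried as metadata — the convention used for
triplicate bench assays.

## Michaelis–Menten kinetics

`fit_michaelis_menten()` fits $v = V_{max} S / (K_m + S)$ by
Levenberg–Marquardt least squares with the classical starting heuristics
($V_{max,0} = \max v$; $K_{m,0}$ = substrate at half-max, interpolated) and
a relative-change convergence tolerance of $10^{-8}$ within 500 iterations.
Weighting is uniform by default — the common software default — with an
optional $1/v^2$ relative mode. Standard errors and the $K_m$–$V_{max}$
covariance come from the local quadratic approximation at the optimum; the
covariance matters later for the inhibition classifier.

Units are deliberately conservative: $K_m$ stays in the unit the data were
supplied in, and conversion to molar happens only where a molar quantity is
required, namely in $k_{cat}/K_m$ (`catalytic_constants()`). A $K_m$ in
mg/ml cannot be converted without the substrate's molar mass, so the
catalytic efficiency is then omitted with a warning rather than silently
mis-scaled. $k_{cat}$ is an *input* by default: for CelC307 the printed
$V_{max}$ (62.58 U/mg), molar mass (56.86 kDa) and $k_{cat}$
(0.1043 s⁻¹) are mutually inconsistent ($V_{max} \cdot M/60 \approx
59$ s⁻¹), so deriving one from the others would manufacture agreement that
the source data do not contain. The derivation is available explicitly via
`mw_kDa`.

`lineweaver_burk()` reports the double-reciprocal line
($\mathrm{slope} = K_m/V_{max}$, intercept $1/V_{max}$) with back-derived
parameters. On noiseless data these equal the nonlinear fit; on noisy data
they differ — the reciprocal transform inflates low-velocity errors — and
both are reported, nonlinear values being authoritative.

## Inhibition-mode classification

`simulate_inhibition_series()` generates, and `classify_inhibition_mode()`
recognizes, the four canonical mechanisms through their apparent-parameter
laws (inhibitor concentration $I$, inhibition constant $K_i$):

| mechanism | $K_m^{app}$ | $V_{max}^{app}$ |
|---|---|---|
| competitive | $K_m(1 + I/K_i)$ | $V_{max}$ |
| non-competitive | $K_m$ | $V_{max}/(1 + I/K_i)$ |
| uncompetitive | $K_m/(1 + I/K_i)$ | $V_{max}/(1 + I/K_i)$ |
| mixed ($\alpha$) | $K_m\frac{1 + I/K_i}{1 + I/(\alpha K_i)}$ | $V_{max}/(1 + I/(\alpha K_i))$ |

The verdict uses the rule table on shifts relative to the uninhibited
control: $V_{max}$ down with $K_m$ steady → non-competitive; $K_m$ up with
$V_{max}$ steady → competitive; both down proportionally (parallel
double-reciprocal lines) → uncompetitive; both shifted non-proportionally →
mixed. Two thresholds govern "steady" and "parallel": a minimum relevant
effect (10% relative shift; 2% relative slope difference) *and* a
statistical guard of twice the shift's propagated standard error. The
statistical component is essential, not cosmetic: at a realistic 3% assay
noise the fitted $K_m$ has a relative standard error of roughly 8–10%, so a
bare percentage threshold reads fit noise as a $K_m$ shift and mislabels
non-competitive series as mixed and uncompetitive series (whose line slopes
are only estimated, never exactly parallel) almost always. With the
combined criterion the classifier recovers the generating mechanism in
92–99% of seeded series per mechanism at that noise level. Shifts must also
act in a consistent direction and grow with inhibitor concentration;
anything else returns `"indeterminate"` with diagnostics rather than a
guess. Classification always uses the nonlinear-fit parameters; the
Lineweaver–Burk geometry (`lb_intersections()`, closed-form pairwise
intersections labelled on-x-axis / on-y-axis / parallel) is attached as
corroborating evidence, mirroring how the mechanism is argued graphically.

## Activation thermodynamics

The Arrhenius engine (`fit_arrhenius()`) regresses $\ln k$ on $1/T$;
$E_a = -\mathrm{slope} \cdot R$. For the catalytic $E_a^\ddagger$ the
sensible fitting window is the ascending limb of the temperature–activity
profile (up to the optimum) — above it, inactivation contaminates the rates.
The Eyring step uses the standard reduced rate
$k^\ddagger = k\,h/(k_B T)$ and $\Delta G^\ddagger = -RT \ln k^\ddagger$;
a formulation of the reduced rate without the temperature factor appears in
some write-ups but is not dimensionally meaningful, so the standard form is
used throughout. $\Delta H^\ddagger = E_a - RT$ and $\Delta S^\ddagger =
(\Delta H^\ddagger - \Delta G^\ddagger)/T$ hold exactly by construction,
and the entropy is reported signed *and* in magnitude, because published
tables sometimes print the magnitude only.

Two compatibility conventions are explicit parameters rather than silent
defaults:

* **`km_unit_mode`** for $\Delta G^\ddagger_{E\text{-}S} = -RT\ln(1/K_m)$:
  thermodynamic convention expresses $K_m$ in molar units, but the CelC307
  reference value (±2.01 kJ/mol with $K_a = 2.17$) is only obtained with
  $K_m$ in mM. Default is molar; `"mM"` reproduces the table.
* **`dG_override_kJ_mol`** in `activation_thermo()`: the reference
  $\Delta G^\ddagger = 58.60$ kJ/mol is not derivable from the reference
  $k_{cat}$ under any standard unit choice (the Eyring value is
  82.71 kJ/mol). The override lets the downstream entropy be computed from
  the published value while the record keeps both numbers and an
  `dG_overridden` flag — the discrepancy is carried, never erased.

## Irreversible thermal inactivation

`fit_inactivation_rate()` fits $\ln([\mathrm{Act}]_t/[\mathrm{Act}]_0) =
-k_{in} t$ by zero-intercept least squares — the model forces the log
fraction through the origin, giving the closed form
$k_{in} = -\sum t \ln f / \sum t^2$ — with a free-intercept diagnostic fit
reported alongside. Derived quantities are the exact first-order
identities $t_{1/2} = \ln 2 / k_{in}$ and $D = \ln 10 / k_{in}$ (a
formulation of $D$ as $RT/k_{in}$ circulates but is dimensionally
inconsistent and reproduces no published table, so the standard decimal
reduction time is used). Their ratio $D/t_{1/2} = \ln 10/\ln 2 \approx
3.32$ is parameter-free, which makes it a sharp consistency probe for any
published table.

`inactivation_profile()` chains the stages: per-temperature $k_{in}$ →
$t_{1/2}$, $D$ → Arrhenius $E_a^{\#}$ → per-temperature
$\Delta G^{\#}, \Delta H^{\#}, \Delta S^{\#}$. The Eyring `rate_unit_mode`
defaults to the standard per-second convention; the `"per_minute"` mode
feeds the per-minute numeral directly into the reduced-rate expression,
which is how the CelC307 reference table's $\Delta G^{\#} \approx 87.6$
kJ/mol at 40 °C was evidently computed (the two differ by
$RT\ln 60 \approx 10.7$ kJ/mol). Unusable temperatures are dropped with a
warning and the profile continues on the rest.

## What the consistency checker flags

`celc307_consistency()` recomputes every derivable quantity of the
reference tables from its own printed inputs. For CelC307 it finds, and the
test suite asserts rather than hides:

* $\Delta G^\ddagger$: printed 58.60, Eyring from the printed $k_{cat}$
  gives 82.71 kJ/mol;
* $E_a^{\#}$: printed 59.29, the Arrhenius refit of the five printed
  $k_{in}$ gives ≈ 67.95 kJ/mol;
* the printed $t_{1/2}$ and $D$ columns are ≈ 10× larger than
  $\ln 2/k_{in}$ and $\ln 10/k_{in}$, and mutually inconsistent (printed
  $D/t_{1/2} \approx 3.75 \ne \ln 10/\ln 2$). The internally consistent
  values from the printed 40 °C rate are $t_{1/2} = 42.79$ min and
  $D = 142.1$ min.

Meanwhile the reproducible chain — $k_{cat}/K_m = 226.7$,
$\Delta H^\ddagger = 22.76$, $\Delta G^\ddagger_{E\text{-}T} = -14.12$,
$\Delta H^{\#} = 56.69$, $\Delta G^{\#} = 87.56$ (per-minute mode) — is
confirmed to a few parts in $10^4$, the residual being the 313 vs
313.15 K ambiguity; temperatures are converted once, centrally, as
$T(\mathrm{K}) = T(°\mathrm{C}) + 273.15$.

## Screening and response-surface methodology

`plackett_burman_design()` builds the standard 12-run matrix from the
cyclic generator row plus the all-minus row; columns are balanced and
pairwise orthogonal for any number of factors up to 11, with unassigned
columns serving as dummy (error) columns. `pb_effect_screen()` estimates
each main effect as the mean response difference between its two levels and
tests it against the dummy-column pseudo-error (one df per dummy column),
the convention of the common DOE packages; Lenth's pseudo-SE is available
as an alternative.

The 20-run design that optimized CelC307 expression is labelled
Box–Behnken in the source study, but its geometry — extreme factor levels
at coded ±1.682 (pH 3.97/9.02, 13.18/46.81 °C, OD 0.06/1.23) — identifies
it as a *rotatable central composite* (axial distance $\alpha = 8^{1/4}$);
a Box–Behnken design has no points beyond ±1. The package provides both
constructors and uses the CCD for the reproduction path. The two distinct
center-point predicted values in the published run table (51.01 vs 51.44)
reveal a two-block analysis — factorial block with four center runs, axial
block with two — and that block split yields exactly the published
pure-error df (4) and block SS (0.61).

`fit_response_surface()` fits the full quadratic in natural units (for
reporting, matching the published polynomial) and in coded units (for the
ANOVA). Coded levels are taken from factor specifications when available;
for plain data frames the center is inferred as the most replicated level
(the center point) and the coded unit as the smallest nonzero level
distance (the factorial spacing) — inferring it from the column *range*
would scale axial points to ±1 and distort the per-term sums of squares.
Term SS are partial (drop-one) on the coded fit; the residual splits into
lack of fit and pure error over replicated design points within blocks.
Refitting the 20 published runs reproduces the published model F (15.31 vs
15.34) and lack-of-fit F (0.659 vs 0.657) to a few parts per thousand, and
the published polynomial's coefficients to ~1%.

`optimize_response()` solves the stationary point exactly and, when it is
a saddle or out of bounds (as for CelC307, whose fitted surface is a
saddle), maximizes over the bound box by dense grid plus local ascent. On
the study's bounds (pH 5–8, 20–40 °C, OD 0.3–1.0) the published polynomial
peaks at ≈ 55.7 U/ml near pH 7.8, 20 °C, OD 1.0 — notably, the published
*predicted* optimum of 58.4 U/ml exceeds anything the published polynomial
can reach on those bounds; both numbers are surfaced and neither is
asserted as truth.

## Protein sequence properties

`translate_dna()` translates codon-by-codon under the standard code, stops
at the first stop codon, and maps N-containing codons to X.
`protein_properties()` computes the ProtParam-style indices: average
molecular weight (Expasy residue masses + one water), isoelectric point by
bisection on the Bjellqvist charge function (residue-specific N-terminal
pKa values, special C-terminal D/E values; converged when the net charge
magnitude is below $10^{-4}$ — the charge is strictly decreasing in pH so
the bisection bracket is valid), the Guruprasad instability index
$(10/L)\sum \mathrm{DIWV}$ over consecutive dipeptides, the aliphatic
index, and GRAVY (mean Kyte–Doolittle hydropathy). Unknown residues (X)
are skipped with the effective length renormalized, and a warning. The
Bjellqvist set was chosen — and made the only pKa set — because it is what
the Expasy service uses, hence what published pI values (5.85 for CelC307)
were computed with. The indices are validated against an independent
reference implementation on fixed peptides; for strongly acidic sequences
whose isoelectric point lies below pH 4 the bisection finds the true zero
of the charge function, which bounded pI searches cannot reach.

The CelC307 coding sequence itself (GenBank MN105992.1) is not shipped:
it is not printed in the study and redistribution is left to the user, who
can drop the FASTA into `inst/extdata/MN105992.1.fasta` to activate the
corresponding verification test (491 aa; 56.86 kDa; pI 5.85).

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameters and seed, and every
noiseless output is an exact fixed point of its fitting stage — the
backbone of the test suite. Defaults mirror the CelC307 magnitudes:
`simulate_mm_dataset()` uses Km 0.46, Vmax 62.58 on the assay's 0.625–20
substrate grid with triplicates and 3% relative noise (typical triplicate
assay CV); `simulate_inactivation_panel()` uses Ea# 59.29 kJ/mol with the
pre-exponential fixed so $k_{in}(40\,°C) = 0.0162$ min⁻¹;
`simulate_doe_response()` defaults to the published polynomial with unit
noise. The inhibition generator defaults to a mid-grid Km (2) and Vmax 50
with $K_i = 0.5$ mM and levels 0/0.5/1 mM: apparent-Km shifts must stay
identifiable on the fixed substrate window, and a Km at the far low end of
the grid would conflate mechanism with design limitation.

Noise is additive Gaussian truncated at zero (activities cannot be
negative); in the tested regimes (≤ 5%) the truncation bias is negligible
relative to the noise itself. The generators do **not** emulate systematic
assay artifacts — substrate depletion during the assay, product inhibition,
biphasic inactivation, plate-position effects, or non-Gaussian outliers —
so passing tests demonstrate correctness of the estimators under the
stated stochastic model, not robustness to every bench pathology.

## Numerical choices and limitations

* NLS bounds at zero prevent negative kinetic parameters; a Km collapsing
  to the zero boundary (velocity flat in substrate) is an error, not a
  result.
* The grid/ascent fallback in `optimize_response()` uses a 50³ grid
  refined by L-BFGS-B; for the smooth 3-factor quadratics involved this
  localizes boundary optima to machine precision.
* Problem sizes in the test suite — 200 seeded Michaelis–Menten
  recoveries, 100 series per inhibition mechanism, 100-seed coefficient
  coverage, 200-seed pure-error calibration — were chosen as the smallest
  runs whose pass/fail verdicts are stable across reruns.
* Out of scope: Hill/allosteric kinetics, substrate inhibition, tight
  binding (Morrison) inhibition and global $K_i$ estimation, biphasic
  (Lumry–Eyring) inactivation, heat-capacity models, D-/I-optimal design
  search, desirability-based multi-response optimization, and any
  structure-based inference from the protein sequence.
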