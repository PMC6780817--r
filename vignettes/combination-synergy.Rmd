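---
title: "Quantifying two-drug synergy with the median-effect model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-drug synergy with the median-effect model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combindex)
```

## The model

Cell-viability data from an MTT-style assay enter the package as percent
viability relative to the vehicle control,

$$V = 100\,\frac{A_{\text{treated}} - A_{\text{media}}}
                {A_{\text{vehicle}} - A_{\text{media}}},$$

and are converted to the affected fraction $f_a = 1 - V/100$ (the fraction
of cells killed or growth-inhibited), with $f_u = 1 - f_a$. Single-agent
concentration-response is described by the mass-action median-effect
equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^{m},$$

where $D_m$ is the median-effect dose (the IC50) and $m$ the shape
exponent: $m = 1$ is a hyperbolic (first-order) curve, $m > 1$ sigmoidal.
Taking base-10 logs linearises the model,
$\log(f_a/f_u) = m\,\log D - m\,\log D_m$, and `fit_median_effect()` fits
this line by unweighted ordinary least squares — the classical
median-effect plot. The correlation coefficient $r$ of the plot measures
conformity of the data to the mass-action model. The fitted curve inverts
in closed form, $D_x = D_m\,(f_a/f_u)^{1/m}$, which supplies every
"dose-for-effect" quantity downstream (IC75, IC90, IC95, ...).

For a two-drug mixture administered at a fixed molar ratio $a\!:\!b$
(the constant-ratio, "diagonal" design), the mixture curve is fitted on the
**total molar dose** $d = d_a + d_b$, and the component doses at any effect
level are recovered from the ratio fractions $d_a = d\,a/(a+b)$,
$d_b = d\,b/(a+b)$. The two-term (mutually exclusive) combination index at
inhibition level $f_a$ is

$$\mathrm{CI}(f_a) \;=\; \frac{d_a}{D_{x,a}(f_a)} + \frac{d_b}{D_{x,b}(f_a)},$$

with $D_{x,a}, D_{x,b}$ the single-agent doses producing the same effect.
CI $< 1$ indicates synergism, $= 1$ additivity, $> 1$ antagonism. The
dose-reduction index $\mathrm{DRI}_x = D_{x}(f_a)/d_x$ satisfies
$1/\mathrm{DRI}_a + 1/\mathrm{DRI}_b = \mathrm{CI}$ identically, and the
isobologram's normalised coordinates $(d_a/D_{x,a},\, d_b/D_{x,b})$ sum to
the CI, so a point below the additivity segment is exactly a synergistic
one. These identities are exact algebra, and the test suite checks them to
$10^{-9}$ on random inputs.

## Tunable parameters

* `eps` (default 0.005) — clipping margin for $f_a$. The log-linearisation
  is undefined at $f_a \in \{0, 1\}$, so fractions outside
  $[\varepsilon, 1-\varepsilon]$ are moved to the bound and flagged. Two
  policies are provided: `clip = "retain"` (default) keeps clipped points at
  the bound, which is robust for small designs; `clip = "exclude"` drops
  them, which is the usual choice for wide screening layouts whose extreme
  doses saturate the response, and is what the package's own analysis
  pipelines use. Negative computed viabilities (over-kill wells reading
  below the blank) are clipped to 0 and flagged before conversion.
* `fa_levels` (default 0.50, 0.75, 0.90, 0.95) — the inhibition levels at
  which CI is reported, matching the IC50-IC95 columns of the conventional
  summary table.
* `additivity_band` (default 0.90-1.10) — CI values inside this band are
  labelled "additivity" in reports. Published heat maps shade values near 1
  as additive without stating the cut-offs; the conventional nearly-additive
  band is used and is configurable.
* Equipotent-ratio rounding (`potency_ratio()`): the potency ratio
  $D_{m,b}/D_{m,a}$ is rounded to the nearest multiple of ten, half-up
  (59.3 becomes 60, giving a 1:60 design), falling back to the nearest
  integer when the tens rounding would give zero.
* Replicate handling: $f_a$ is computed per well and all wells within a
  drug x trial stratum are pooled into one fit; per-trial fits are kept
  separate, and CI is summarised as mean ± SEM across independent trials.
* Concentrations are nM throughout; readers convert on input.

## The synthetic-data generator

`synthetic_truth()` plants a fully known ground truth: per-drug
$(D_m, m)$, a Loewe interaction level $\alpha$, Gaussian well noise on the
viability scale, the plate layout, and a seed. The default pair emulates a
steep, potent agent ($D_m = 6$ nM, $m = 2$) against a shallower one ~60-fold
less potent ($D_m = 356$ nM, $m = 1$), probed in quadruplicate half-log
series over three independent trials — the layout of a typical combination
study. The default well noise, sigma = 3 viability points, is plausible
MTT replicate scatter chosen once for all simulations; published work
reports SEMs across trials rather than per-well scatter, and 3 points
reproduces SEMs of that order for quadruplicates.

Mixture wells are generated by solving the planted Loewe relation

$$\frac{d_a}{D_{x,a}(f_a)} + \frac{d_b}{D_{x,b}(f_a)} = \alpha$$

for $f_a$ by bisection (the left side is strictly decreasing in $f_a$;
tolerance $10^{-10}$, at most 200 iterations, non-bracketable doses clipped
and flagged). By construction the **true** CI of the generated surface is
$\alpha$ at every achieved effect level, so $\alpha = 1$ generates exact
additivity, $\alpha = 0.5$ a surface whose CI should be recovered as 0.5,
and so on. Interaction is a property of the mixture: wells with one drug
absent (single-agent margins of a checkerboard, parallel single-agent
controls) always follow the plain single-agent curve, whatever $\alpha$.
Administration-schedule effects are emulated, when requested, as
multipliers on $\alpha$ per schedule — a phenomenological device for
testing report machinery, not a pharmacokinetic model.

Impedance traces are generated as logistic vehicle growth times a
dose- and time-dependent survival factor. The `direct_kill` mode uses a
cumulative-exposure kill (rate proportional to dose^exponent x time), which
makes the time-resolved IC50 strictly decreasing; the `senescence` mode
adds a transient size/attachment bump peaking ~24 h post-treatment and
delays the kill by 48 h, reproducing the signature profile of DNA-damaging,
senescence-inducing agents, whose traces transiently exceed the vehicle
before declining.

## Exactness of the additivity null, and a known limitation

A point that shapes both the package's validation strategy and how results
on real data should be read: the Chou-Talalay CI is estimated through a
median-effect refit of the mixture curve. When the two drugs share the
slope $m$, an exactly Loewe-additive constant-ratio mixture is itself a
median-effect curve with the same $m$ and
$D_m^{\text{mix}} = \alpha / (r_a/D_{m,a} + r_b/D_{m,b})$ — the refit is
exact, and the estimated CI equals the planted $\alpha$ at every effect
level. When the slopes differ, the additive mixture is **not** within the
median-effect family; the refit then carries a model-approximation error
that depends on the dose range (with $m = 2$ vs $m = 1$ drugs and a wide
half-log layout, the refit CI of a truly additive pair can read as low as
~0.8 at IC50). This is a property of the classical method itself, not of
this implementation. Consequently:

* the package's additivity-null and interaction-recovery validation
  experiments (and the reproduction script) use a shared-slope pair with
  the realistic potencies 6 nM and 356 nM, the regime in which CI = 1 under
  additivity is an exact prediction rather than an approximation;
* on real drugs with unequal slopes, CI values within roughly ±0.2 of 1
  should not be over-interpreted, which is one reason the additivity band
  defaults to (0.90, 1.10) and published analyses emphasise CI patterns
  across effect levels rather than single values.

## Dose placement in the recovery experiments

The median-effect plot is fitted on $\log(f_a/f_u)$, whose sensitivity to
viability noise is $1/(f_a f_u \ln 10)$ — it explodes as doses saturate the
response. With 3-point viability noise, a well at $f_a = 0.99$ contributes
roughly 1.6 units of noise on the plot scale (versus ~0.06 at
$f_a = 0.5$), and the clipping bound censors that noise asymmetrically.
Screening layouts spanning many decades are therefore fine for finding a
curve but poor for *estimating* its parameters. The package's recovery
experiments place their 8 doses as a 1.4-fold geometric series centred on
the (planted) IC50, spanning $f_a \approx 0.1$-$0.9$ for $m = 2$ — the
identifiable range an analyst would use for CI estimation — and fit with
`clip = "exclude"`. Under these conditions the median recovered
interaction level is within 5% of the planted $\alpha$ for
$\alpha \in \{0.5, 1, 1.5\}$ (100 simulations, 3 trials each), and the
median fitted $(D_m, m)$ are within ~2-4% of truth.

## Kinetics: numerical choices

The time-resolved IC50 fits the sigmoidal variable-slope (four-parameter
logistic) model
$y = \text{bottom} + (\text{top}-\text{bottom})/(1 + 10^{(\log D - \log \mathrm{IC}_{50})\,h})$
to the normalized cell index versus dose at each requested time point
(instantaneous snapshots, nearest grid time). Constraints:
$\text{bottom} \ge 0$; the top plateau is anchored to the vehicle level by
default (`anchor_top = FALSE` frees it); the hill slope is sign-free. The
optimiser is Levenberg-Marquardt with box constraints, started strictly
inside the box at heuristic values (vehicle level, the dose nearest the
half-response, $h = 1$). Time points with less than a 10% dose-response
span, a non-converging fit, a non-positive fitted hill, or an IC50 more
than a decade outside the tested range are flagged
(`no_gradient` / `no_convergence` / `out_of_range`) rather than fabricated.

Normalization divides each well by its value at the grid point nearest the
treatment time (instruments sample every 30 min at steady state, so the
nearest-point convention is within 15 min of the true treatment time);
it is idempotent and scale-invariant, and a non-positive index at treatment
is a degenerate-well error.

The kinetic-shape classifier uses two thresholds chosen to separate the
qualitative classes seen in impedance data and exposed as arguments: a
*rise* is the trace exceeding the vehicle by 5% sustained for at least 2 h;
a *decline* is falling 20% below the treatment-time level after the trace's
peak. Rise + decline is `dna_damage_like`, decline alone `direct_kill`, an
endpoint plateau within ±0.15 of the treatment level `cytostatic`, anything
else `none`. Raising the rise threshold can only demote `dna_damage_like`
to `direct_kill`, never the reverse.

## Problem sizes

The validation suite runs, among others: 100-repeat recovery simulations at
three interaction levels (3 trials x 8 doses x 4 replicates each, ~70 s
total), 1000-draw property checks of the CI/DRI/isobole identities, and
kinetic recovery on 289-point traces at 9 dose levels; these sizes give
stable medians while keeping a full run around half a minute.

## What passing tests do and do not show

The generator emulates the assay's design (serial dilutions, replicate
wells, independent trials, vehicle/media controls) and a well-behaved noise
model. It does not emulate plate-position effects, pipetting error
correlated within dilution series, receptor-level deviations from
mass-action, mixtures whose interaction varies with effect level (except
through the documented $\alpha(f_a)$-free multiplier device), or
instrument drift in impedance traces. Recovery of planted parameters
therefore validates the *estimators*, not the biological assumptions; on
real data the median-effect plot's $r$ and the agreement of CI across
effect levels and analysis views (curve shift, isobologram, checkerboard)
remain the practical checks.

## Worked pipeline

```{r pipeline}
truth <- synthetic_truth(
  drug_a = list(label = "A", Dm = 6, m = 2),
  drug_b = list(label = "B", Dm = 356, m = 2),
  alpha = 0.5, sigma_viability = 3, trials = 3, seed = 11,
  doses_a = 6 * 1.4^seq(-3.5, 3.5, by = 1),
  doses_b = 356 * 1.4^seq(-3.5, 3.5, by = 1))
design <- combination_design("A", "B", 1L, 60L)
plate <- generate_combination_plate(truth, design,
                                    total_doses = 182 * 1.4^seq(-3.5, 3.5, by = 1))
profile <- analyze_combination(plate, design, clip = "exclude")
profile
ci_summary_report(list(profile))[, c("schedule", "ratio", "n_trials",
                                     "ci_ic50", "class_ic50", "class_ic95")]
```
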