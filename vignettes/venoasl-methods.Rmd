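---
title: "Quantifying venous ASL signal: models, calibration, and statistics"
author: "venoasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying venous ASL signal: models, calibration, and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Arterial spin labelling (ASL) measures perfusion by magnetically labelling
inflowing blood water and subtracting label from control images. In healthy
brains the labelled water exchanges into tissue at the capillary bed, so the
difference signal is interpreted as cerebral blood flow (CBF). In severe
anemia — sickle cell anemia (SCA) being the motivating population — ASL maps
show conspicuous signal in the *sagittal sinus*, the large midline draining
vein. Labelled water arriving in a vein has, by definition, transited the
circulation without exchanging: a potential marker of arteriovenous shunting.
`venoasl` implements the full quantitative chain needed to study this
phenomenon: voxel-wise CBF from a single inflow-time (singleTI) pCASL
acquisition, joint voxel-wise CBF and bolus arrival time (BAT) from a
multi inflow-time (multiTI) PASL acquisition, the physiological calibration
both need, venous ROI construction, and the group/association statistics —
exercised end-to-end on a synthetic digital-phantom cohort.

Because no gold-standard comparison is made, fitted CBF and BAT values —
especially in venous voxels, where an arterial kinetic model is being applied
to a blood pool — are *relative* quantities. The package treats them as such
throughout: comparisons, correlations and regressions are the endpoint, not
absolute flow.

## Signal models

### Single-TI pCASL

With label duration $\tau$, post-labeling delay $PLD$, labeling efficiency
$\alpha$, blood–brain partition coefficient $\lambda$ and blood longitudinal
relaxation time $T_{1b}$, the single-delay quantification is

$$
CBF = \frac{6000\,\lambda\,\Delta M\, e^{PLD/T_{1b}}}
{2\,\alpha\,T_{1b}\,M_0\,\bigl(1 - e^{-\tau/T_{1b}}\bigr)}
\quad\text{(mL/100g/min)} .
$$

Defaults are $\lambda = 0.9$ mL/g, $\alpha = 0.85$, $\tau = 1.8$ s,
$PLD = 1.5$ s; $T_{1b}$ is subject-specific (below). `pcasl_forward()` is the
exact algebraic inverse, used by the simulator; the pair inverts to machine
precision, which the test suite asserts at $10^{-10}$ relative error.
Negative difference signal maps to negative CBF — deliberately not clipped,
because masking and ROI policy are downstream decisions. The proton-density
image is used as acquired (TR 4 s); no correction for incomplete relaxation
is applied, a scaling caveat shared by the acquisitions this emulates.

### Multi-TI PASL: the general kinetic model

For a pulsed label clipped to temporal width $\tau$ by Q2TIPS saturation
(applied 700 ms after labeling, hence $\tau = 0.7$ s), the difference signal
at inflow time $t$ follows the Buxton general kinetic model with a box-car
arterial input arriving at the bolus arrival time $\Delta t$ (BAT):

* $t < \Delta t$: no label has arrived, $\Delta M = 0$;
* $\Delta t \le t < \Delta t + \tau$ (bolus in transit):
  $\Delta M(t) = 2 M_{0b} f\,(t - \Delta t)\,\alpha\, e^{-t/T_{1b}}\, q(t)$;
* $t \ge \Delta t + \tau$ (bolus complete):
  $\Delta M(t) = 2 M_{0b} f\,\alpha\,\tau\, e^{-t/T_{1b}}\, q(t)$,

where $f = CBF/6000$ (mL/g/s), $1/T_{1,app} = 1/T_{1,tissue} + f/\lambda$,
$k = 1/T_{1b} - 1/T_{1,app}$, and $q(t)$ is the standard clearance factor.
The implementation evaluates the equivalent decayed-delivery form
$2 M_{0b} f \alpha\, e^{-t/T_{1,app}}\, (e^{-k u_1} - e^{-k u_2})/k$ through
`expm1`, which is continuous at both regime breakpoints and passes smoothly
through the degenerate $k \to 0$ case (threshold $|k \cdot \Delta u| <
10^{-8}$, where the analytic limit $u_2 - u_1$ is substituted). Blood
magnetization uses the standard convention $M_{0b} = M_0/\lambda$,
configurable via `pasl_params(m0_scale=)`.

Defaults: $\lambda = 0.9$, $\alpha = 0.98$, $\tau = 0.7$ s,
$T_{1,tissue} = 1.9$ s. The single fixed $T_{1,tissue}$ — midway between
anemic and normal blood T1 — is a deliberate venous-first choice: the target
signal is a blood pool, and per-tissue relaxation models would buy little for
the sinus while complicating the fit. It overestimates tissue CBF (multiTI
tissue values run higher than singleTI ones, as expected) but leaves BAT and
all correlations untouched. No multi-compartment or dispersion model is
offered; that is out of scope by design.

`pasl_kinetic_numeric()` evaluates the same physics as an explicit
delivery–residue–decay convolution by adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-9}$). It shares no algebra
with the closed form and is the oracle in the test suite, which requires
agreement to $10^{-6}$ relative error over 50 random parameter draws
spanning CBF 20–2500 mL/100g/min and BAT 0.2–2.0 s.

## Physiological calibration

**Arterial oxygen content.** $CaO_2 = 1.34 \cdot Hb \cdot SpO_2 +
0.003 \cdot pO_2$ (mL O2/dL), with $SpO_2$ stored as a fraction; the
carriage constant is quoted per percent-saturation/100, so the units cancel
and `compute_cao2(10, 1, 100)` is 13.7. A saturation above 1.5 is rejected
as an accidental percent input rather than silently rescaled — percent/
fraction confusion is the classic failure mode here. $pO_2$ defaults to
100 Torr (room air) and is configurable.

**Blood T1.** Anemia lengthens blood T1, so a population with hematocrits
near 0.24 cannot share a textbook $T_{1b}$ with controls near 0.41. The
calibration is affine in relaxation rate,
$1/T_{1b} = a + b\cdot Hct + c\,(1 - SpO_2)$, a pluggable coefficient set
(`t1_blood_coefficients()`). The published form of this calibration does not
reprint its coefficients, so the defaults were solved once against two
anchor means — 1.99 s at (Hct 0.24, SpO2 0.97) and 1.77 s at (0.41, 0.99) —
with $c$ fixed at 0.2 s$^{-1}$ (deoxyhemoglobin raises R1 modestly); two
anchors cannot identify three coefficients. The result is validated only
against those anchors, within their reported spreads, and is strictly
decreasing in hematocrit across the valid range (property-tested on a
grid). Estimates falling outside a configurable physiological window
(default 1.3–2.6 s) raise a calibration error. Methemoglobin effects are
not modelled. Missing hematology is imputed by group means (patient
hemoglobin, control SpO2) or an age/sex reference table for control
Hb/Hct, with per-field flags; non-missing values are never altered.

## Preprocessing and reliable voxels

The singleTI difference volumes are averaged voxel-wise over the 10 repeats.
Noise is estimated from four ghost-free background squares of width 5 voxels
placed in the in-plane corners of the field of view, pooled over all slices
and volumes (per-volume statistics are available; pooling is the default
because EPI ghosts propagate along the phase axis, leaving the corners clean
on every slice). A voxel is *reliable* when its difference signal exceeds
the background mean plus one SD on at least one volume; the comparison is
strict (`>`), the multiplier configurable. The multiTI fit additionally
skips voxels with fewer than 3 above-noise points — two parameters cannot be
estimated from fewer. Registration is out of scope (inputs are pre-aligned);
a center-of-mass drift check (`qc_series_drift()`) mirrors a
motion-exclusion policy without re-implementing it.

## Voxel-wise fitting

`fit_multiti()` minimises the residual sum of squares over $(CBF, \Delta t)$
per voxel with bounds $CBF \in [0, 3000]$ mL/100g/min and
$\Delta t \in [0, \max TI]$. The generous upper bound is not a bug guard: in
venous voxels apparent CBF around 2500 is genuinely observed, and clamping
it would silently bias the venous tail this package exists to measure.

The objective is multi-modal in BAT at low SNR (shifting the curve by one TI
is a good local optimum), so the fit multi-starts over a BAT grid — by
default every TI. Each start gets a linear CBF initialiser from the
unit-amplitude curve; starts are ranked by initial RSS and the best four are
polished by bounded L-BFGS-B (`factr = 10`, `parscale` matched to the CBF
scale, `ndeps = 10^{-6}`). Ties in final RSS break toward the smallest BAT,
the earliest physically plausible arrival. A line-search stall at the
machine-precision stopping rule (optim code 52) on an already-optimal point
is treated as convergence; iteration overflow is not. A fitted arrival at or
beyond the last TI predicts zero signal everywhere — CBF is then
unidentified, reported as 0 and flagged degenerate, as are fits pinned at
either CBF bound. Noiseless recovery is exact to better than $10^{-4}$
relative over a grid spanning tissue and venous regimes (CBF 20–2500, BAT
0.3–2.0 s); at peak SNR 10 the median errors over 500 simulated voxels are
about 0.03 s in BAT and 4% in CBF, comfortably inside the 0.1 s / 10%
acceptance bands.

## Regions of interest

Gray-matter, white-matter and sinus masks are inputs (anatomical
segmentation and vein-atlas registration are external concerns); each is
eroded with a cubic box of width 2 to shave partial-volume rims. An
even-width box has no central voxel, so the origin convention matters: the
origin sits at the lower-corner voxel, hence a solid cube of side $n$ erodes
to side $n-1$ — documented because the alternative convention gives $n-2$.

ASL coverage of the sinus is partial and variable in practice, so the
venous endpoint is a *high-signal* sinus ROI: the threshold is the 90th
percentile (linear-interpolation definition, `quantile` type 7) of the
finite singleTI CBF values inside the sinus mask, and voxels at or above it
are retained — exactly 10% for distinct-valued inputs. The ROI is defined
once, from the singleTI CBF map, and then applied to the multiTI CBF and
BAT maps, so all three map families are sampled at the same locations.
Percentile computation uses finite-valued voxels only, and every ROI mean
reports a coverage fraction alongside.

## The synthetic cohort and phantom

The generator is the package's study-conditions statement, not a tuning
surface. `cohort_spec()` defaults plant, for 90 patients and 40 controls:

* hematology — patient Hb $\sim N(8.6, 1.2)$ g/dL, control
  $N(13.2, 1.0)$; Hct tracking Hb at $\approx 0.03$/unit; SpO2 0.97/0.99.
  CaO2 and blood T1 are then *derived*, not drawn.
* the nine ROI features at the group means and SDs of the motivating
  cohort (GM singleTI CBF 54.06 (7.78) vs 42.52 (7.13), WM 31.25 (4.82) vs
  22.91 (4.49), and so on). Skewed variables — the three sinus CBF features
  and SCI burden — are lognormal, with meanlog/sdlog back-computed from
  medians and interquartile ranges; the rest are normal with SDs taken
  directly or derived from IQRs.
* a negative CaO2→CBF coupling within patients (target $|r| = 0.45$,
  implemented so the marginal SD still matches the configured value);
* cognition: IQ coupled to log sinus multiTI CBF at $-3.94$ IQ points per
  log unit, PSI to WM multiTI CBF at $-0.29$ per mL/100g/min, with residual
  SDs matching the reported cognitive spreads;
* treatment prevalences (hydroxycarbamide 0.36, transfusion 0.07) and SCI
  prevalences 0.41/0.10.

The digital phantom is a GM elliptic annulus around a WM core with a
posterior midline sinus cylinder, constant across slices, leaving the four
corner squares background everywhere. Difference images are simulated
directly from the forward models plus homoscedastic Gaussian noise (default
SD 1.5 signal units against $M_0 \approx 1000$, single-repeat peak SNR
roughly 5–10 — a realistic operating point for background-suppressed 3D
GRASE difference images; the emulated protocol reports no noise figure, so
this was chosen once and left alone). What the phantom deliberately does
*not* model: raw control/label pairs, motion, ghosting, partial-volume
mixing at compartment boundaries, or within-compartment heterogeneity
beyond an optional lognormal jitter. Passing tests therefore demonstrate
correctness of the estimation chain under its own assumptions, not
robustness to acquisition artifacts.

Each subject carries a derived `subject_seed`, so image simulation is
independently reproducible per subject; the whole pipeline is deterministic
given the config seeds.

## Statistics

The statistical stage mirrors a normality-gated, FDR-stratified analysis:

* **Gate.** Shapiro–Wilk per group at $\alpha = 0.05$ (the level is a
  package choice; the source analysis does not state one). If either group
  rejects, the nonparametric branch is taken — per-group assessment is
  stricter than pooling and avoids calling a mixture normal.
* **Group comparisons.** Independent t-test on the parametric branch —
  Welch by default, because the planted venous-BAT variances differ
  fourfold between groups and Welch is also what an R `t.test()` call
  produces unless equal variances are requested (`var_equal = TRUE`
  restores the pooled form). Mann–Whitney U otherwise, with rank-biserial
  correlation as its effect size; Cohen's d (pooled SD) is always reported.
* **Adjustment.** "Age- and sex-adjusted" means OLS residuals plus the
  grand mean — this preserves units and scale so adjusted values can be
  plotted against CaO2 directly. Non-normal features are log-transformed
  first (flagged in the output). Single-sex subsets drop the sex term with
  a warning rather than failing on a collinear design.
* **FDR.** Benjamini–Hochberg step-up, applied *independently within each
  stratum* of participant group × parameter-map family (singleTI CBF,
  multiTI CBF, multiTI BAT). `bh_fdr()` takes arbitrary stratum keys; it is
  `p.adjust(, "BH")` per stratum, verified against a brute-force step-up
  implementation on all vector lengths up to 8.
* **Cognition models.** OLS of a cognitive score on a hemodynamic predictor
  plus the pre-selected covariates (age, sex, hydroxycarbamide, chronic
  transfusion, SCI burden, intracranial volume, education decile), on
  complete cases, gated on an uncorrected univariate $p < 0.1$ screen
  (enforced but overridable; gate decisions are returned, not corrected —
  the screen is explicitly pre-correction). Reported per term:
  unstandardised $b$, standardised $\beta = b\,\mathrm{sd}(x)/\mathrm{sd}(y)$,
  95% CI, $p$, and partial correlation $t/\sqrt{t^2 + \mathrm{df}}$.
  `glance()` adds descriptive assumption checks (residual normality,
  a heteroscedasticity screen, residual-vs-fitted correlation) rather than
  a composite omnibus test.

Under the global null, BH's any-rejection rate per stratum equals the
nominal level, so the type-I property is checked as a one-sided bound at
nominal + 2 Monte-Carlo SEs over 200 replicate null cohorts — a point
estimate sitting *at* 0.05 should not fail the check half the time.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the voxel-wise machinery at
deliberately modest sizes — phantoms of 24–32 voxels per axis with a handful
of fully imaged subjects, 500-voxel noise studies, 100–200 replicate cohort
tables — sizes at which every result above is stable and the whole suite
completes in a few minutes. All of them scale linearly in voxels and
subjects through the same code paths. Other numerical choices worth knowing:
percentiles use R's default type-7 interpolation; ROI means ignore
non-finite voxels and report coverage; background SD uses the $n-1$
denominator; the YAML config round-trips at 15 significant digits; NIfTI
maps are written through RNifti (float32 on disk).

## Limitations

Fitted venous "CBF" has no absolute interpretation; only comparisons are
meaningful. The fixed tissue T1 inflates tissue CBF from the multiTI fit.
The phantom's clean geometry cannot expose registration, ghosting or
partial-volume failure modes, and the T1-blood calibration is anchored at
exactly two physiological points — outside the anemic-to-normal hematocrit
range it extrapolates. The cognition generator plants a single dominant
pathway (venous CBF → IQ); real cognitive data are not that obliging.
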