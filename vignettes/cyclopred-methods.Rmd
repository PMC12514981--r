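---
title: "Methods: lens-derived features, synthetic cohorts, and the prediction pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lens-derived features, synthetic cohorts, and the prediction pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclopred)
```

# The problem and the model

Accommodative tonus makes non-cycloplegic autorefraction read more myopic
than the eye's true (cycloplegic) refraction, most strongly in young
children. `cyclopred` predicts the cycloplegic sphere from measurements
that are all available *before* cycloplegia. Its premise is physical: the
shift lives in the crystalline lens, so features that proxy the lens's
optical state should carry the signal. Since routine examinations do not
image the lens, those proxies are computed from the SRK/T intraocular-lens
power formula, which expresses the lens power a given eye geometry
requires from keratometry, axial length and anterior chamber depth alone.

## Paraxial optics assumptions

Everything is first-order (paraxial) optics on a schematic eye:

* aqueous and vitreous share one refractive index, `n_a = 1.336`; the
  keratometric index difference is `Δn = 0.333`; the crystalline lens is a
  homogeneous thick lens of index `n_L = 1.40` with its posterior surface
  power fixed at `F_p = 9.26` D (Bennett–Rabbetts model eye). The lens is
  *not* gradient-index; `F_p` does not vary with accommodation — both are
  deliberate simplifications.
* the measured ACD stands in for the effective lens position in the SRK/T
  denominator: the formulas describe the measured, phakic eye rather than
  a pseudophakic prediction.
* radii are stored as positive magnitudes; powers in diopters; lengths in
  mm, converted to meters (`LT/1000`) wherever they multiply powers.
* the printed renderings of the anterior-surface relations in the source
  literature are typographically ambiguous; the package adopts the
  standard, dimensionally consistent paraxial forms — thick-lens inversion
  `F_a = (F − F_p) / (1 − (LT/1000/n_L) F_p)` and surface relation
  `r_a = 1000 (n_L − n_a) / F_a` — which are the unique readings under
  which `F_p = 9.26` D and `n_L = 1.40` make sense. The same applies to
  the principal-plane distance `p′ = −(n′/F)·F_a·(LT/1000/n_L)·10³` mm
  with the image-side index `n′ = n_a` (the lens is immersed in media of
  index 1.336 on both sides).

The spherical equivalent fed to the ametropic and contact-lens variants is
the **non-cycloplegic** `SE = S + C/2` from autorefraction: the features
must be computable before cycloplegia, which is the entire point of the
exercise.

## Feature groups

The control group uses 14 traditional features (gender, age, S, IOP, AL,
CCT, IOP/CCT, AL/CCT, K1, K2, Km, r, AL/CR, VCD). Each experimental group
adds ACD, LT, the group's IOL variant, `F_a`, `r_a`, and the ratios
AL/ACD, AL/LT, AL/VCD, LT/`r_a`, ACD/`r_a`. Two conventions the data
sources leave open are fixed here for reproducibility: VCD is derived as
`AL − CCT − ACD − LT` (no measured VCD column exists), CCT enters the
ratio features in mm (keeping AL/CCT dimensionless of order 40; µm input
is accepted with `cct_unit = "um"`), and gender is coded 0 = male,
1 = female. The "S" feature is the sphere alone, not SE, matching the
separate treatment of S and C throughout the analysis. Rows whose derived
features are incomputable (missing inputs, degenerate geometry such as
`LOPT ≤ ACD`) keep `NA` cells rather than being dropped; imputation
handles them downstream.

# The synthetic cohort generator

No clinical dataset is distributed, so `generate_cohort()` manufactures
cohorts with the statistical structure the analysis assumes. Its defaults
*are* the study conditions: 306 eyes of 153 subjects, ages uniform on
4–15 (shared by fellow eyes), non-cycloplegic sphere mean −1.53 D and SD
2.17 D truncated to [−7.5, +10.5] D, cylinder −0.87 ± 0.75 D under the
C ≤ 0 convention, cycloplegic shift 0.34 ± 0.53 D declining with age, and
a fellow-eye Gaussian-copula correlation of 0.8 (real fellow eyes are
highly correlated; configurable).

Design choices worth knowing:

* **Tonus model.** The shift is `dS ~ Gamma` with conditional mean
  `E[dS | age, LT, ACD] = 0.34 · (1 + 0.15·(9.5 − age)) ·
  exp(2.2·ΔLT − 2.2·ΔACD − σ²/2)` where ΔLT, ΔACD are deviations from the
  age-conditional biometry means. The multiplicative form keeps `dS ≥ 0`
  without clamping, so the marginal mean and SD equal the configured
  0.34/0.53 *exactly* (the per-eye coefficient of variation is solved in
  closed form). Roughly half of the shift's variance is mediated by lens
  geometry (thicker lens, shallower chamber ⇒ more tonus), about a tenth
  by age, the rest idiosyncratic. This mediation is the generator's causal
  premise: control features can remove the age-linked part, but only the
  groups that see ACD/LT and the SRK/T-derived features can remove the
  lens-linked part — which is what the experiment is designed to detect.
  The opposite signs on LT and ACD matter: the control group observes
  their *sum* (through `AL − VCD − CCT`) but not the difference.
* **Optical consistency.** A latent crystalline-lens power is recorded per
  eye from the reduced-eye relation
  `P_lens = (1336/AL − Km − S_cyclo)/0.62` (0.62 ≈ the effectivity of
  power at the lens plane referred to the cornea), so each eye's
  cycloplegic refraction is consistent with its axial length, corneal
  power and a plausible ~23 D lens. The generator's purpose is statistical
  structure, not anatomical fidelity.
* **Cylinder truncation.** The printed cylinder moments describe data that
  are ≤ 0 by convention, so the generator moment-matches the *truncated*
  normal: the pre-truncation parameters are solved numerically
  (Nelder–Mead on the closed-form truncated moments) at generation time.
* **Biometry.** Age-trended normals (AL 23.6 ± 0.45 mm growing 0.12 mm/yr
  and lengthening 0.38 mm per diopter of myopic residual; Km 43.5 ± 1.4 D;
  ACD 3.60 ± 0.25 mm; LT 3.45 ± 0.20 mm; CCT 0.55 ± 0.035 mm;
  IOP 15.5 ± 2.5 mmHg), rejection-resampled into physiologic bounds.
  Keratometric astigmatism is tied to the refractive cylinder.

What the generator does **not** emulate: measurement error structure of
real autorefractors (quantisation to 0.25 D steps), axis distributions
biased with-the-rule, longitudinal progression, ethnic or clinic-specific
biometry mixtures, and any nonlinearity in the true tonus–lens relation
beyond the lognormal form. Passing tests on these cohorts therefore show
the pipeline *recovers structure it is designed to recover* — they are
evidence about the software, not about clinical performance on real eyes.

## Accommodation series

`generate_accommodation_series()` emulates AS-OCT measurements of 16 eyes
under stimuli of 0–6 D. Radius changes follow the generating quadratics
(anterior `AccD = 0.01x² − 1.21x − 0.02` on a signed-change axis,
posterior `AccD = −2.40x² + 9.30x − 0.60` on a magnitude-decrease axis);
each per-stimulus change is the real quadratic root continuous with the
near-zero root — the branch choice that keeps the series anchored at the
relaxed state — plus Gaussian noise (defaults 0.15 mm ACR, 0.05 mm PCR).
Because the quadratics have small nonzero intercepts, the root at zero
stimulus is not exactly zero; the generator therefore keeps two
coordinate systems: the `delta_*` columns carry the exact quadratic
coordinates (so refitting noiseless series returns the generating
coefficients to machine precision), while the measured radii are
re-referenced to the zero-stimulus measurement, making the analysis-side
`delta_radii()` changes exactly zero at baseline, as a clinician would
reference them. Fits on the radius-referenced axis flip the anterior
linear coefficient's sign and shift it by `2a·x₀` (≈ 10⁻⁴ for the
anterior, ≈ 3% for the posterior surface); the magnitudes that matter —
the zero-accommodation slopes — are unaffected at the anterior surface
and well within the tolerance used for the posterior one.

The posterior mm-per-diopter rate deserves a flag: the reciprocal of the
posterior slope is 1/9.30 ≈ 0.11 mm/D, while full-range means computed
over 0–6 D are larger because the quadratic curvature matters away from
the origin. The package reports the small-accommodation reciprocal
(`mm_per_diopter_small_acc()`) and leaves full-range averaging to the
user, without asserting which convention any particular source used.

# The prediction pipeline

Decisions where the procedure was genuinely open, and the package's
choices:

* **Imputation**: per-column medians computed on training rows only and
  reused on test rows — deterministic, order-free, leakage-safe.
* **Split**: `round(0.8·n)` training rows (306 → 245/61), eye-level by
  default since the evaluation is per-eye; a subject-grouped split is
  available (`subject_grouped_split = TRUE`) and is the right choice when
  generalisation to new subjects is the claim.
* **LASSO**: penalty chosen by the CV-minimum rule rather than the
  one-standard-error rule; the screen is meant to drop clearly redundant
  features, not to sparsify aggressively, and CV-min retains the larger
  sets the feature design anticipates. The screen never returns an empty
  set (it falls back to the least-penalised model with a nonzero
  coefficient), and coefficients below 1e−10 are treated as zero to
  absorb coordinate-descent noise on collinear columns.
* **Boosting**: squared-error objective, 5-fold CV over the default grid
  learning rate {0.05, 0.1, 0.3} × depth {2, 3, 4} × subsample
  {0.7, 1.0} × L2 {0.1, 1, 10} at 100 rounds, single-threaded for exact
  reproducibility; the best cell is refit on all training rows. The CV
  table is retained in the fit for inspection.
* **Testing scale**: the package's own tests and examples use a reduced
  2 × 2 grid at 60 rounds and cohorts of 80–306 eyes — at these problem
  sizes a full four-group experiment runs in a few seconds, and ten-seed
  ordering studies in about a minute, which is the scale the test suite
  adopts.
* **Statistics**: two-sided paired t-tests at α = 0.05 without
  multiplicity correction across the four groups (raw p-values are
  reported); Bland–Altman limits are `mean ± 1.96·SD` of the differences;
  age subgroups are 4–8 and 9–15 years by floored age, with bins under
  five eyes flagged.
* **Baselines**: ordinary least squares and an RBF support-vector
  regressor (cost CV-tuned over {0.1, 1, 10}) on the same screened
  features and the same split. The linear baseline is labelled linear —
  a logistic model has no place with a continuous target.

## Degenerate inputs and numerical conventions

Domain errors (non-positive keratometry, `LOPT ≤ ACD`, the vertex
singularity `SE = 1/0.012`, zero surface power, imaginary posterior
sagitta `r_p < LT/2`) raise immediately in the scalar operations but are
masked to `NA` cells during bulk feature building. Zero-variance paired
differences flag the t-test as degenerate instead of dividing by zero. A
constant-response quadratic fit returns the flat polynomial with its
goodness of fit flagged rather than erroring, so baseline-only series are
representable. Axis angles are degrees in [0, 180) at every interface and
radians internally.

# Known limitations

* The SRK/T-derived "lens power" is a proxy, not a measurement; its value
  as a feature rests on the generator's (and, in reality, the eye's)
  lens-mediated shift actually projecting onto SRK/T geometry.
* The generator's parametric forms (lognormal mediation, gamma tonus,
  normal biometry) are calibration choices; none is claimed to be the
  true clinical joint distribution, and performance numbers obtained on
  synthetic cohorts should never be quoted as clinical accuracy.
* The accommodation analysis is pooled across eyes; per-eye random
  effects would be the next refinement for real AS-OCT data.
* Only the sphere is predicted. The cylinder's cycloplegic change is
  within typical measurement error, and power-vector components J0/J45
  are provided as descriptors, not as prediction targets.
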