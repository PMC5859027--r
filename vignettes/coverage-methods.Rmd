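---
title: "Whole-heart versus 3-slice perfusion scoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-heart versus 3-slice perfusion scoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nuclear myocardial perfusion imaging covers the whole left ventricle;
conventional CMR perfusion acquires three short-axis slices (basal,
mid-ventricular, apical, ~10 mm each). Whether that truncated coverage
costs diagnostic accuracy — and whether an "ischemic burden" measured from
three slices is exchangeable with a whole-heart one — is a protocol-design
question that is hard to answer with two serial stress CMR studies per
patient. `polartpd` implements the alternative: score whole-heart polar
maps quantitatively, re-score the *same* maps under a retrospective 3-slice
mask, and compare the two scores patient by patient.

## The scoring model

**Grid.** A polar map is an `R × A` matrix of non-negative relative uptake,
rings running apex → base, sectors counterclockwise from the anterior wall
(viewed from the apex). The default 24 × 36 grid is configurable and every
operation is resolution-agnostic; the source software's internal sampling
density is not published, so the default is a choice, not a claim.

**Segments, zones, weights.** Rings are split into four radial zones (apex
cap, apical, mid, basal) and the standard AHA 17 segments: 6 basal, 6 mid,
4 apical, apex cap = segment 17. Pixel area weights are `w = 2r − 1` — the
annulus area of an equal-width ring on the display disc. With the default
equal-quarter zone split this reproduces the conventional bullseye display
areas: apex 1/16, apical 3/16, mid 5/16, basal 7/16 of the surface. We
considered the alternative of a thin apex cap (1/8 of rings, ≈ 1.6% of
weighted area) and rejected it as a default: with so small an apex no
apex-confined defect can ever reach the 3% TPD positivity threshold, which
contradicts the clinically observed severe apical defects scoring ~5–6%
whole-heart TPD while being missed by 3-slice coverage. An apex cap worth
6.25% of the surface makes a full-thickness severity-0.8 apical defect score
exactly 5.0% — the phenomenon under study. Since TPD ratios are
weight-normalized, the weighting perturbs rather than drives the results.

**Normalization.** Maps are scaled so that the mean of the brightest decile
of pixels equals 100 — a robust "most-normal myocardium" anchor that ignores
defects covering < 90% of the surface, and makes all downstream scoring
invariant to the acquisition's arbitrary count scale. The degenerate
all-zero map cannot be normalized and is deliberately passed through
unnormalized: it is maximally abnormal against any limits and must score
TPD = 100, not raise an error. A corollary worth knowing: a *uniform*
global deficit (balanced multivessel disease) renormalizes to a
normal-looking map — a real and known blind spot of relative-uptake
quantification, reproduced faithfully here.

**Normal limits.** Per gender, per pixel: mean μ and mean absolute
deviation (MAD) across ≥ 2 normalized defect-free maps (default cohorts: 50
per gender). A pixel is abnormal when `(μ − v)/MAD ≥ 3.0` (one-sided —
super-normal uptake is never abnormal; boundary inclusive). For Gaussian
noise MAD/SD → √(2/π) ≈ 0.798, so 3.0 MAD ≈ 2.4 SD, consistent with the
usual "≈ 2.5 SD" characterization; the test suite verifies the ratio on
5000 simulated normals. The MAD is floored at 1.0 normalized-uptake unit so
near-deterministic pixels cannot produce unbounded deviations. No spatial
smoothing is applied to the limits.

**Severity and TPD.** Severity of an abnormal pixel is the fractional
deficit `s = min(1, (μ − v)/μ)`; TPD is the area-weighted mean of `s` over
abnormal pixels inside the coverage mask, as a percent of the *masked* area.
The severity map is a configuration hook (`severity_fun`) because the exact
integration used by the clinical software is not published; the fractional
deficit satisfies both published anchors (zero uptake → 100%, sub-threshold
deviations → excluded). The 3-slice TPD denominator is the masked area
(a "normalized percentage"), so a uniform whole-field defect scores the
same under both masks and the two scores share the 3% cutoff scale; a
whole-LV denominator would make every 3-slice score ~3.2× smaller and the
shared cutoff meaningless.

**3-slice mask.** In each of the apical, mid and basal zones, the two
consecutive rings centred on the zone midpoint (0-based local offsets
`floor((n−1)/2)` and `+1`; both rings of a 2-ring zone). Deterministic
floor tie-breaking; all sectors included; apex-cap rings never included.

## The synthetic cohort: what it emulates, what it does not

The generator states the studied world once:

* **Disease mixture** (n = 651): disease-free 187, 1-vessel 232, 2-vessel
  127, 3-vessel 70, branch-only 35 — drawn per patient; vessels uniform
  among combinations; gender 57% male.
* **Baseline maps**: gender-specific level (male 90, female 86) with a mild
  apex-to-base gradient (−8), plus Gaussian pixel noise SD 8 on the 0–100
  scale, truncated at 0. Noise is applied to the underlying signal *before*
  defects multiply it, so a severity-1.0 defect produces exactly zero
  uptake.
* **Defects**: contiguous regions grown from a random seed pixel inside the
  vessel territory (LAD: segments 1, 2, 7, 8, 13, 14, 17; RCA: 3, 4, 9,
  10, 15; LCX: 5, 6, 11, 12, 16) until the requested fraction of territory
  area is covered; uptake multiplied by `1 − severity`. Epicardial defects
  draw severity ~ U(0.3, 0.9) and extent ~ U(0.1, 0.6); branch-only
  disease is a small-extent defect (U(0.03, 0.15)) in the parent territory
  (no imaging phenotype is published for it). Contiguity matters: scattered
  pixels would understate the slice-coverage effect under study.
* **Apex-confined LAD phenotype**: among non-silent single-vessel LAD
  cases, 30% are severe apex-cap-confined defects (severity U(0.5, 0.95),
  extent U(0.8, 1.0)) — the discordance class observed clinically, where
  roughly half the whole-heart-only detections were primarily apical.
* **Imperfect truth coupling.** Two mechanisms decouple ≥ 70% stenosis from
  the perfusion phenotype, as in referral populations: a stenotic vessel is
  hemodynamically *silent* with probability 0.3 (pressure-wire studies
  find a comparable fraction of angiographically significant lesions
  non-ischemic), and any patient carries a mild artifactual defect with
  probability 0.4 (attenuation, microvascular disease). Without them the
  synthetic AUC saturates near 1; with them it sits in the realistic
  0.80–0.90 band. These rates were fixed from that reasoning before the
  acceptance checks were run, and are not tuned per seed.

What a green test establishes: the *mechanism* (apical defects missed by
the mask, negative 3-slice bias, preserved AUC) and the correctness of the
arithmetic. What it does not: the clinical magnitudes. Real attenuation
artifacts are spatially structured, noise is count-dependent, defect
severity profiles are graded rather than uniform — so exact published
cohort statistics (AUC 0.855/0.843, bias −1.19%) are reproduced as bands
and signs, not values.

## Statistics

All authored against their primary definitions, two-tailed, α = 0.05:

* **AUC**: Mann–Whitney estimator with midrank tie handling; tested against
  exhaustive pair counting.
* **DeLong paired test**: structural-components covariance of the two
  correlated AUCs; variance validated against a 10,000-resample bootstrap
  (within 10%). The degenerate zero-variance case (identical scores)
  reports p = 1 with a warning flag. Calibration note: the type-I check
  perturbs one score by 0.25 score-SD units; with much smaller
  perturbations the AUC difference is nearly discrete and the normal
  approximation turns conservative (~3% rejection) — a property of the
  test, not a bug.
* **Optimal cutoff**: Youden's J over observed score values, decision rule
  `score ≥ t`, ties toward the lower threshold. On default synthetic
  cohorts both scores select cutoffs in the vicinity of the 3% landmark.
* **McNemar**: exact two-tailed binomial on discordant pairs when
  `n01 + n10 < 25`, χ² with continuity correction otherwise (the switch
  point is a convention; the published comparison (26, 4) falls in the χ²
  branch either way).
* **Bland–Altman**: differences are 3-slice − whole-heart; bias ± 1.96·SD
  limits; t-based bias CI and p; identical pairs degrade to p = 1.
* **Regression**: OLS of whole-heart on 3-slice TPD with t-based intercept
  CI; R² is the squared Pearson correlation.
* **Discordance classifier**: a whole-heart-only detection is an
  "apical miss" when its largest per-segment extent lies in segments 13–17.
  "Mainly apical" has no published quantitative definition; dominant-extent
  is the obvious operationalization and is validated by planted-truth
  recovery (≥ 5-fold enrichment of apex-confined cases).

## Numerical and degenerate-input choices

* Abnormality boundary inclusive (`≥ 3.0` MAD); positivity inclusive
  (`TPD ≥ 3%`).
* Ring allocation by largest remainder with minimum counts (1 apex ring,
  2 per slice-bearing zone) enforced by borrowing from the largest zone.
* Normalization is idempotent; all-zero maps are rejected by
  normalization but accepted by scoring (TPD = 100).
* The study RNG is one master seed split into per-stage seeds, so changing
  the patient count does not perturb the normal limits.
* Reports serialize deterministically: the same seed yields byte-identical
  JSON and CSV.

## Known limitations

* Starts at the polar map: no reconstruction, contouring, gating, or rest
  imaging.
* Per-patient detection only; per-vessel localization accuracy is out of
  scope.
* The generator does not stratify by stress mode, does not model
  count-dependent noise, and its artifact model is spatially unstructured.
* The negative 3-slice bias, while structural (apex mass is never sampled),
  is small in the synthetic world (≈ −0.1% at the default seed) and can
  flip marginally positive on individual seeds; real defects concentrate
  apically/distally more than territory-uniform region growth does, which
  is why the clinical bias (−1.19%) is an order of magnitude larger.
* Published sensitivities (84.5% vs 80.1%) sit above the synthetic ones
  (~72% vs ~68%): the synthetic silent-vessel rate is applied per vessel
  independently, which penalizes single-vessel sensitivity more than the
  clinical data suggest. The paired *difference* — the quantity under
  study — reproduces in sign and approximate size.
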