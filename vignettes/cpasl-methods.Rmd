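---
title: "Methods: multi-delay ASL quantification of choroid plexus perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-delay ASL quantification of choroid plexus perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpasl)
```

## The measurement problem

The choroid plexus is the fenestrated-capillary tissue in the cerebral
ventricles that secretes cerebrospinal fluid. Its perfusion is of interest
as a window on CSF production, but the organ is a thin sheet suspended in
CSF, so at any practical MRI resolution every voxel is a mixture of choroid
plexus tissue and CSF. Arterial spin labeling (ASL) measures perfusion
without contrast agents: arterial blood water is magnetically labeled and
the label–control difference signal ΔM is proportional to the amount of
labeled water delivered. Acquiring ΔM at several observation times —
combinations of labeling duration τ and post-labeling delay w — samples the
inflow and washout of the label, which makes blood flow, arrival time, and
the label's tissue relaxation time jointly estimable.

## Kinetic model

`asl_relative_signal()` implements the single-compartment dynamic pCASL
model

$$\frac{\Delta M}{M_0} = 2\,\alpha\, f'\, T_1\, e^{-\delta/T_{1a}}
\left( e^{-\max(w-\delta,\,0)/T_1} - e^{-\max(w+\tau-\delta,\,0)/T_1} \right)$$

Assumptions: plug delivery of a rectangular bolus (no dispersion), label
decays with the arterial $T_{1a}$ until it arrives at transit time
$\delta$, with the tissue $T_1$ thereafter, and the voxel is a single
well-mixed compartment. No two-compartment exchange, bolus dispersion, or
echo-time (T2/T2*) effects are modeled.

Two consequences of the functional form are load-bearing and are asserted
as test invariants: the signal is *exactly linear* in $f$ (so a voxel
containing a fraction $w_n$ of tissue flowing at $F_n$ produces the signal
of apparent flow $f_n = w_n F_n$), and for $w \ge \delta$ consecutive
delays decay mono-exponentially with the tissue $T_1$
($s(w+h)/s(w) = e^{-h/T_1}$), which is what makes the long choroid plexus
$T_1$ detectable from the late-delay tail.

### Units

$f$ is stored and reported in ml/100 g/min everywhere; inside the model it
is divided by 6000 (→ ml/g/s) so that $\Delta M / M_0$ is dimensionless
with realistic magnitude (~10⁻²–10⁻³). Negative or non-finite analytic
inputs are rejected, not clamped, so simulation bugs surface early.

### Fixed constants

| constant | meaning | default | unit |
|---|---|---|---|
| $\alpha_1$ | inversion (labeling) efficiency | 0.8 | — |
| $\alpha_2$ | background-suppression efficiency | 0.75 | — |
| $T_{1a}$ | arterial blood T1 at 3 T | 1.65 | s |
| $\lambda$ | brain–blood partition coefficient | 0.9 | ml/g |
| $T_{sat}$ | proton-density saturation recovery time | 2 | s |
| $T_{1g}$ | gray-matter T1 (M0 calibration) | 1.5 | s |
| $\rho$ | tissue density | 1.08 | g/ml |
| $v$ | voxel volume | 0.064 | ml |

$\alpha = \alpha_1 \alpha_2 = 0.6$; the factors are kept as separate fields
so either can be overridden. $\lambda = 0.9$ is the brain value, used as an
approximation because no choroid-plexus-specific partition coefficient is
established. The voxel volume default corresponds to a 4 mm isotropic ASL
grid and is configurable (analysis may run on a resampled grid); the
pipeline always derives it from the NIfTI header.

### M0 calibration

`compute_m0()` inverts the saturation-recovery attenuation of the
proton-density reference scan:
$M_0 = M_{PD} / (\lambda (1 - e^{-T_{sat}/T_{1g}}))$, with $M_{PD}$ the
mean proton-density signal over the gray-matter mask. One global $M_0$
normalizes both regions, i.e. gray matter serves as reference tissue. The
proton-density image accompanies each observation time; the pipeline
averages the per-OT gray-matter means before applying the formula (the
phantom's references are identical across OTs, so this is exact there).

### Observation-time schedule

The default `ot_schedule()` is the 12-point design
τ = (1.5, 2, 2.5, 3, 3.5, 4, 4, 4, 4, 4, 4, 4) s,
w = (0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 1.2, 1.7, 2.2, 2.7, 3.2, 3.7) s:
six τ-varying points at the minimum delay constrain $f$ and $\delta$; six
w-varying points at fixed τ constrain the washout $T_1$. The minimum delay
0.7 s is assumed shorter than any transit time, which motivates the
$\delta \ge 0.7$ s fit bound.

## Parameter estimation

`fit_series()` minimizes the unweighted residual sum of squares between the
model curve and the observed relative signal, subject to box constraints.

* **Bounds.** Lower: $f \ge 10$ ml/100 g/min, $\delta \ge 0.7$ s,
  $T_1 \ge 1$ s (protocol values). Upper bounds are this package's choice
  (the protocol states none): $f \le 300$ ml/100 g/min, $\delta \le 4$ s
  (beyond max w + min τ the arrival is unobservable), $T_1 \le 5$ s (CSF
  ceiling) — generous physiological ranges that keep the optimizer stable.
* **Optimizer.** Bounded quasi-Newton (`stats::nlminb`, PORT) on the sum of
  squares with numerical derivatives; relative tolerance 10⁻¹², at most 200
  iterations per start. A trust-region least-squares routine would be the
  textbook choice but none is available in base R; best-of-restarts with
  PORT achieves the same contract, and noiseless recovery tests pass at
  ~10⁻¹⁴ relative error.
* **Multi-start.** The $\max(\cdot,0)$ arrival kinks make the residual
  surface piecewise-smooth in $\delta$ with flat regions, so the default
  start (δ = 1.0 s, T1 = 1.5 s) is complemented by `n_starts − 1` restarts
  with δ on a grid over [0.7, 3.7] s and T1 jittered by a seeded
  log-normal factor. Because the model is linear in $f$, each start's $f$
  is its closed-form least-squares value at that (δ, T1), clamped to the
  bounds — this eliminated the one local-minimum failure (late arrival,
  δ ≈ 3.2 s) observed with naive jittered starts. Identical inputs and
  seed give bitwise-identical results.
* **Weighting.** Uniform across observation times. Acquisition TR varies
  per OT in practice, but per-OT noise levels are not available to the
  model, so no weighting is attempted.
* **Diagnostics.** $R^2 = 1 - SS_{res}/SS_{tot}$ on the fitted curve;
  `bound_hit` flags estimates within 10⁻⁶ of a bound in scaled
  coordinates; an all-zero observation terminates at the lower bounds with
  flags set and undefined $R^2$ (zero observed variance).

`fit_roi()` averages ΔM over the mask *before* fitting (mean-then-fit) —
the estimator used for regional perfusion, which suppresses voxel noise
ahead of the nonlinear step. By linearity in $f$, a mean over voxels that
share (δ, T1) fits the mean flow exactly. `fit_voxelwise()` runs
independent per-voxel fits; failures become missing values and a tally,
never an abort. Whether regional $R^2$ should be computed on the ROI-mean
curve or averaged over voxels is not pinned down by the protocol; this
package computes it on the ROI-mean curve.

## Partial volume, total flow, weight correction

Fitted flow is *apparent* flow: with tissue fraction $w_n$ and actual flow
$F_n$, a voxel produces $f_n = w_n F_n$ (CSF contributes no ASL signal).
No voxelwise partial-volume correction is attempted — choroid plexus
segmentation at ASL resolution is not reliable enough — and this matches
the protocol's deliberate choice to report apparent flow. Instead:

* `total_flow()`: $F = \rho v N \bar f / 100$ (ml/min) over the region —
  the $w_n$ cancel in the sum, so the total is partial-volume-insensitive.
* `weight_corrected_flow()`: dividing $F$ by the choroid plexus mass in
  the lateral ventricles (whole-organ mass × fraction located there)
  yields a specific flow in ml/100 g/min. With the literature values
  0.80 ml/min, 2 g and 50%, this gives 80 ml/100 g/min. The ratio to gray
  matter flow is reported as computed from the package's own outputs, not
  hard-coded.

## The synthetic phantom

Real multi-delay choroid plexus ASL data are not publicly available, so
`phantom_spec()`/`simulate_subject()` provide the test bed. The geometry is
deterministic: an ellipsoidal cortical gray-matter shell (two voxels
thick), interior white matter, two mirrored ellipsoidal CSF ventricles
elongated anterior–posterior, and a thin choroid plexus sheet along each
posterior ventricle wall carrying a uniform partial-volume fraction
(default 0.5). The gray-matter probability map is 1 on gray matter with a
one-voxel 0.5 rim at the outer surface, so the strict `> 0.5` threshold of
`threshold_mask()` selects the interior gray matter and exercises the
boundary convention.

Signals are generated by the forward model itself, with
$M_0 = $ `compute_m0(m_pd_gm)` and proton-density volumes constant on
tissue — so the analysis-side calibration recovers the generating $M_0$
exactly, and with zero noise the full analysis is an exact inverse of the
generator (to optimizer tolerance). Defaults state the emulated world:
gray matter (f = 53.74 ml/100 g/min, δ = 1.31 s, T1 = 1.85 s) and choroid
plexus actual flow 80 ml/100 g/min (δ = 1.24 s, T1 = 2.33 s) at
partial-volume fraction 0.5 — i.e. apparent flow 40. White matter
(f = 20, δ = 1.5, T1 = 1.1) exists only for geometric realism and is not
asserted against anything.

Choices where the emulated protocol is silent:

* **Noise.** Zero-mean Gaussian on the difference signal, one SD for all
  OTs, default `noise_sd = 2.5e-4` (ΔM/M0 units): this puts the
  gray-matter peak signal (~5×10⁻³) at curve SNR ≈ 20, the level at which
  the noisy-recovery properties are stated. The in-vivo SNR of the
  original acquisition is not published; this default is a declared free
  parameter, not a claim.
* **Cohort variation.** `simulate_cohort()` multiplies template parameters
  by independent unit-mean log-normal factors with coefficient of
  variation 0.25 (the reported ~25% inter-subject variation of regional
  flow); cv = 0 yields identical subjects.
* **Resolution.** Everything lives on one grid; the T1-weighted↔ASL
  registration/resampling chain is out of scope, so partial volume enters
  directly through $w_n$ rather than through resolution mismatch.

**What a green phantom test does and does not establish.** It establishes
that the estimator inverts the forward model under the stated geometry,
noise model, and schedule — identifiability, correctness of the
arithmetic, and the partial-volume bookkeeping. It does not establish
robustness to dispersion, motion, registration error, vascular artifacts,
T2/T2* decay, or spatially varying partial volume, none of which the
phantom contains.

## Group statistics

`summarize_subjects()` uses the population SD (divisor $n$) by default:
recomputing the published cohort SDs from the per-subject rows matches the
printed values (7.01, 10.07, 0.20, 0.30) under divisor $n$, not $n-1$. The
divisor is a switch. (The printed gray-matter T1 SD of 0.10 matches
neither exactly — the original authors presumably used unrounded
per-subject values — hence the ±0.02 comparison tolerance.)

`wilcoxon_exact_paired()` computes the exact two-sided paired
signed-rank p by full enumeration of all $2^n$ sign assignments of the
ranked absolute differences (recursive doubling over ranks; ties share
average ranks; zero differences are dropped before ranking, the classic
treatment; all-zero differences return p = 1 with a degenerate flag). The
two-sided p is $\min(1,\, 2\min(P(W \le W_{obs}), P(W \ge W_{obs})))$. At
n = 7 with all differences of one sign this gives the minimum attainable
p = 2/128 = 0.015625 — the exact version matters precisely because the
normal approximation is unreliable at such n. Tests verify the
enumeration against an explicit 2ⁿ sign-matrix oracle and against
`stats::wilcox.test(exact = TRUE)` on tie-free data.

`group_report()` flags significance at 0.02 and applies no
multiple-testing correction (deliberately, matching the reference
analysis).

## Pipeline and I/O

Volumes move as NIfTI-1 (`read_nifti()`/`write_nifti()`, a minimal
single-file codec written for this package because no R NIfTI reader is
available in the target environment; it is cross-validated against
nibabel in the test suite). Masks must already live on the data grid —
registration is explicitly out of scope. ΔM inputs are assumed already
label–control subtracted and averaged, and in consistent units across OTs
(scanner-side per-OT scaling must have been undone upstream). Voxel
volume is always derived from the NIfTI header spacing. Configurations
round-trip through JSON; every run logs the resolved configuration and
seed; reports contain only finite numbers with missing fits as explicit
empty markers.

## Numerical and testing choices

* Noiseless recovery is asserted at 10⁻³ relative (observed ~10⁻¹⁴);
  noisy recovery at curve SNR 20 is asserted at the stated bounds (median
  relative error of f ≤ 10%, T1 ≤ 15%) for the *choroid-plexus-like*
  generating parameters — the method's target tissue; for gray-matter-like
  (short T1) curves flow precision at this SNR is intrinsically at the
  edge of the 10% figure, so only the T1 bound and the separation of the
  two tissues' recovered-T1 distributions are asserted there.
* The joint ΔM/M0 rescaling invariance of fits is asserted at 10⁻⁶
  relative (rescaled inputs differ in the last floating-point ulp, so
  bitwise identity is not attainable).
* Acceptance-scale simulations (7-subject cohort) run noiseless at 48³ so
  the whole suite stays within a small CPU budget; module tests use 28³.

## Known limitations

Single-compartment model without dispersion or exchange; no T2/T2*
correction (the choroid plexus likely has short venous-like T2, biasing
flow downward at long echo times); no voxelwise partial-volume correction;
no registration or segmentation (masks are inputs); exact Wilcoxon limited
to n ≤ 20 non-zero differences; NIfTI support limited to the scalar
datatypes and header fields the pipeline uses.
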