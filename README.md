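# cpasl

Quantification of **choroid plexus perfusion** from multi-delay
pseudo-continuous arterial spin labeling (pCASL) MRI, in R.

The choroid plexus secretes cerebrospinal fluid, and its blood flow is a
candidate marker of CSF production and blood–CSF-barrier function. ASL
measures perfusion non-invasively by magnetically labeling arterial blood
water and observing the label–control difference signal ΔM. Because the
choroid plexus is a thin sheet bathed in CSF, any achievable voxel mixes
tissue and CSF, so a voxel's measured flow is an *apparent* flow
f = w·F (partial-volume fraction w times actual flow F); summing apparent
flow over the region cancels w and yields a partial-volume-insensitive
total flow.

## The model

For a labeling duration τ and post-labeling delay w, the single-compartment
dynamic ASL model gives the relative difference signal

    ΔM/M0 = 2 α f′ T1 e^(−δ/T1a) · ( e^(−max(w−δ,0)/T1) − e^(−max(w+τ−δ,0)/T1) )

with α = α₁α₂ the effective labeling efficiency (0.8 × 0.75), f′ the blood
flow in ml/g/s (f [ml/100 g/min] / 6000), δ the arterial transit time, T1a
the arterial-blood T1 (1.65 s), and T1 the tissue relaxation time of the
labeled water after exchange. M0 is calibrated from a saturation-recovery
proton-density scan, M0 = M_PD / (λ(1 − e^(−Tsat/T1g))). A 12-point
(τ, w) schedule — six growing labeling durations at w = 0.7 s, then six
growing delays at τ = 4 s — tracks inflow and washout, making (f, δ, T1)
jointly identifiable. They are estimated per voxel or per region by
constrained nonlinear least squares with lower bounds
f ≥ 10 ml/100 g/min, δ ≥ 0.7 s, T1 ≥ 1 s.

Region totals and the weight correction follow
F_total = ρ·v·N·f̄/100 (ml/min) and
f_specific = 100·F_total/(m_CP·fraction_in_lateral_ventricles).

Because no in-vivo data accompany the method (IRB restrictions), the
package ships a synthetic digital phantom — cortical gray-matter shell,
white matter, CSF-filled lateral ventricles, and a sheet-like choroid
plexus with controllable partial-volume fraction — whose forward
simulation uses exactly the model above, enabling end-to-end recovery
tests.

## Worked example

Group statistics on the bundled reference cohort (seven healthy adults,
published regional values):

```r
library(cpasl)
group_report(reference_cohort())
#> Group perfusion table (7 subjects)
#>        gm_f gm_att gm_t1   cp_f cp_att cp_t1
#> Mean 53.743  1.307 1.849 39.486  1.237 2.329
#> SD    7.007  0.116 0.094 10.067  0.200 0.302
#> Paired Wilcoxon (gray matter vs choroid plexus), exact two-sided p:
#>   flow  p = 0.015625 (significant at 0.02)
#>   att   p = 0.312500
#>   t1    p = 0.015625 (significant at 0.02)
```

The mean row reads: gray matter flows at ~53.7 ml/100 g/min with T1 1.85 s,
while the choroid plexus shows lower *apparent* flow (~39.5, a partial
volume artifact) and a distinctly longer T1 (2.33 s, p = 2/2⁷ = 0.015625
by exact enumeration) — the longer T1 is consistent with labeled water
passing into CSF.

Simulate one noiseless subject and recover the choroid plexus parameters:

```r
sim <- simulate_subject(phantom_spec(grid_shape = c(28, 28, 28), noise_sd = 0))
cst <- acquisition_constants(voxel_volume = sim$voxel_volume_ml)
cp  <- sim$truth$label_volume == 4
fit <- fit_roi(sim$delta_m, cp, sim$m0, cst)
fit
#> ASL kinetic fit: f = 40.00 ml/100g/min, delta = 1.240 s, T1 = 2.330 s (R2 = 1.0000)
total_flow(fit$params$f, sum(cp), cst)
#> [1] 1.990656   # ml/min over the 72-voxel (4.61 ml) phantom region
weight_corrected_flow(0.80, 2, 0.5)
#> [1] 80         # ml/100 g/min: 0.80 ml/min, 2 g organ, 50% in the ventricles
```

The fitted apparent flow is 40 = 0.5 × 80: the phantom generates choroid
plexus voxels at partial-volume fraction 0.5 and actual flow
80 ml/100 g/min, and the fit recovers the apparent value exactly. The
weight correction converts a measured total flow of 0.80 ml/min into
80 ml/100 g/min of choroid plexus tissue.

A full simulate → fit → report run:

```r
run_pipeline(run_config(out_dir = "demo_run", n_subjects = 7, seed = 1))
```

or from the shell via the CLI wrapper
(`Rscript $(Rscript -e 'cat(system.file("cli","cpasl.R",package="cpasl"))') pipeline --out-dir demo_run`),
writing NIfTI volumes, per-subject summaries and the group report CSV.

## Layout

- `R/` — kinetic model (`asl_relative_signal`, `compute_m0`, `total_flow`,
  `weight_corrected_flow`), fitting (`fit_series`, `fit_roi`,
  `fit_voxelwise`), phantom (`phantom_spec`, `simulate_subject`,
  `simulate_cohort`), group statistics (`wilcoxon_exact_paired`,
  `group_report`), NIfTI-1 I/O, pipeline + CLI.
- `vignettes/cpasl-methods.Rmd` — model, assumptions, and design choices.
- `tests/testthat/` — unit, property and acceptance suites.
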