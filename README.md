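# diffent

Single-particle-tracking analysis of intracellular diffusion and its
thermodynamic interpretation, for cell biophysicists studying how
ATP-dependent mechanical work shapes the motion, entropy and
phase-separation state of cell contents.

Intracellular objects (vesicles, organelles) move by anomalous diffusion:
their mean square displacement follows MSD(Δt) = 2 n K<sub>α</sub> Δt<sup>α</sup>,
with diffusion coefficient K<sub>α</sub> (µm²/s<sup>α</sup>) and diffusion
power α. Because translocations at a long enough lag are near-Gaussian with
variance 2 K<sub>α</sub> Δt<sup>α</sup>, each tracked cell maps onto a
generalized-entropy scale

&nbsp;&nbsp;S = ¼ ln(4πe · K<sub>α</sub> Δt<sup>α</sup>),&nbsp;&nbsp;
E = 4π · K<sub>α</sub> Δt<sup>α</sup>,&nbsp;&nbsp; S = ¼ + ¼ ln E,

so that at constant energy (thermodynamic equilibrium, e.g. after ATP
depletion) K<sub>α</sub> = E/(4π) · Δt<sup>−α</sup> — a negative
α–K<sub>α</sub> coupling — while mechanical work raises both parameters and
splits the power as α = α<sub>e</sub> + α<sub>work</sub>, with
α<sub>e</sub> = a·K<sub>α</sub><sup>b</sup> fitted on the equilibrium arm.
Cell-content homogeneity (a liquid–liquid phase-separation proxy) is
quantified as the coefficient of variation of fluorescence inside the cell
footprint and correlated with the diffusion and entropy measures in a
paired active/depleted design.

The package provides:

* `synth` generators with exact ground truth — fractional-Brownian
  trajectories (`simulate_fbm_trajectory`), DIC-like stacks
  (`render_stack`), phase-separated reporter images (`render_llps_image`)
  and full paired cohorts (`generate_cohort`);
* the imaging chain — `to_8bit`, `threshold_segment` (band or Otsu,
  8-connected labeling), `size_distribution`, `threshold_sensitivity`;
* tracking and fitting — `link`, `compute_msd`, `fit_power_law`;
* the thermodynamic core — `particle_entropy`, `total_energy`,
  `constant_energy_curve`, `fit_elastic_regression`, `decompose_alpha`,
  `entropy_decomposition`;
* homogeneity — `compute_cv`, `noise_cv_impact`;
* cohort statistics — `paired_compare`, `regress_power`, `regress_exp`,
  `run_cohort_analysis`.

## Worked example

The `analysis/` scripts run the whole study on a simulated 12-cell paired
cohort (`Rscript analysis/01_simulate_cohort.R` … `04_figures.R`). At the
default study conditions and seed 1 the pipeline prints:

```
Paired cohort analysis (12 paired cells, dt_eval = 3 s)
  elasticity regression (depleted arm): alpha_e = 0.0258 * K^-0.591 (p = 0.0259)
  paired alpha   : t = 9.32, p = 1.49e-06, mean diff = 0.536
  paired k_alpha : t = 6.29, p = 5.95e-05, mean diff = 0.0169
  paired entropy : t = 11.5, p = 1.74e-07, mean diff = 0.51
  alpha_vs_k_depleted        b = -0.591, p = 0.0259 (n = 12)
  cv_vs_k_active             b = -0.674, p = 2.21e-05 (n = 12)
  cv_vs_alpha_work_active    b = -0.851, p = 6.52e-06 (n = 12)
  cv_vs_entropy_active       b = -1.78, p = 3.44e-07 (n = 12)
  ...
```

Reading: active cells diffuse faster and more persistently than the same
cells after ATP depletion (higher K<sub>α</sub>, α, entropy; paired
t-tests); the depleted arm shows the negative α–K<sub>α</sub> power-law
coupling expected on a constant-energy curve; and in active cells the
homogeneity CV falls with K<sub>α</sub>, α<sub>work</sub> and entropy —
cells doing more mechanical work keep their contents more mixed. The
report's `directions` field summarizes these expectations as booleans.

A minimal programmatic session:

```r
library(diffent)
sim <- generate_cohort(cohort_spec(seed = 1), detail = "full")
rec <- records_from_cohort(sim)     # MSD fit + footprint CV per cell/arm
rep <- run_cohort_analysis(rec, dt_eval = 3)
rep$directions
```

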