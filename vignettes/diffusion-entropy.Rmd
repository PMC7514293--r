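---
title: "From intracellular diffusion to generalized entropy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From intracellular diffusion to generalized entropy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffent)
```

## The model

Intracellular objects — vesicles, organelles, membraneless condensates — move
through a crowded viscoelastic medium that is kept out of thermodynamic
equilibrium by ATP-dependent mechanical fluctuations. Their motion is
anomalous diffusion: the mean square displacement over a time lag $\Delta t$
follows a power law

$$\mathrm{MSD}(\Delta t) = 2\,n\,K_\alpha\,\Delta t^{\alpha},$$

with $n$ spatial dimensions, a generalized diffusion coefficient $K_\alpha$
(µm²/s$^\alpha$) and a diffusion power $\alpha$: sub-diffusive below 1,
Brownian at 1, super-diffusive above 1.

Because each measured translocation at a sufficiently long lag is the sum of
many microscopic steps, the translocation distribution is close to Gaussian
with variance $\sigma^2 = 2 K_\alpha \Delta t^{\alpha}$ per dimension. Its
differential entropy then maps diffusion onto a thermodynamic scale. Under
the half-Gaussian convention for the distribution of energy-level square
roots, the per-particle generalized entropy and total-energy scale are

$$S = \tfrac{1}{4}\ln\!\big(4\pi e\,K_\alpha\,\Delta t^{\alpha}\big), \qquad
  E = 4\pi\,K_\alpha\,\Delta t^{\alpha},$$

tied by the exact identity $S = \tfrac14 + \tfrac14\ln E$. All
proportionality constants are fixed at 1 in a single unit system (µm, s).
Differential entropy is **not** unit-invariant, so entropies are comparable
only within this convention; the package never mixes unit systems, and the
published regression coefficients it uses as worked examples are tied to
their own (unreported) unit convention — they are therefore always refitted
on the data at hand in the analyses.

Two consequences of the energy relation organize the whole study:

* **Equilibrium**: at constant energy, $K_\alpha = \frac{E}{4\pi}\Delta
  t^{-\alpha}$ — a strictly decreasing level set in the
  $(\alpha, K_\alpha)$ plane (for $\Delta t > 1$ s), so cells without
  mechanical work should show a *negative* $\alpha$–$K_\alpha$ coupling.
* **Non-equilibrium**: added mechanical work raises both $K_\alpha$ and
  $\alpha$. The diffusion power splits as
  $\alpha_{\mathrm{non\text{-}e}} = \alpha_e + \alpha_{\mathrm{work}}$,
  where $\alpha_e$ is the elasticity-dominated equilibrium component. An
  empirical power law fitted on equilibrium (ATP-depleted) cells,
  $\alpha_e = a\,K_\alpha^{\,b}$ (published example: $a = 0.53$,
  $b = -0.46$), predicts $\alpha_e$ from a cell's $K_\alpha$, and
  $\alpha_{\mathrm{work}} = \alpha - \alpha_e$ follows by subtraction.

Although the published label for this regression is "exponential", the
printed formula is a power law, and the package implements it as such
(log–log least squares). Cells can land below the equilibrium curve and get
a negative $\alpha_{\mathrm{work}}$; these are flagged, never clipped, and
are excluded (with a message) only from log–log regressions where a
non-positive value has no logarithm.

### The entropy split

The printed two-term decomposition of the entropy is algebraically
inconsistent as stated (its two $\tfrac14\ln(2\pi e K \Delta t^{\cdot})$
terms sum to the total entropy *plus* $\tfrac14\ln(\pi e K)$, an offset that
depends on $K$). Since the single-formula entropy above is the primary
definition, the package anchors the split to it and defines

$$S_{\mathrm{elastic}} = \tfrac14\ln\!\big(4\pi e K_\alpha \Delta
t^{\alpha_e}\big), \qquad S_{\mathrm{work}} =
\tfrac{\alpha_{\mathrm{work}}}{4}\ln \Delta t,$$

which sum to the total entropy exactly (offset 0, tested to 1e-12 on a
parameter grid). The elastic term is the entropy the same cell would have
with work switched off; the work term is the purely lag-logarithmic
increment contributed by the extra diffusion power.

## The measurement pipeline

1. **Segmentation** (`to_8bit`, `threshold_segment`). Stacks are rescaled to
   8-bit (min–max, round-half-even) and thresholded by a gray-level *band*
   — DIC-imaged objects are dark with bright fringes, so an interval beats a
   single cut; `"otsu"` picks the cut automatically and takes the minority
   side as foreground. 8-connected components below `min_area = 4` px are
   discarded: too-narrow bands fragment objects into isolated pixels, and
   the floor suppresses that debris, while over-wide bands (more than half
   of all pixels) trigger a warning because they thicken contours and merge
   objects. Centroids are intensity-unweighted; at the ~0.3 µm object scale
   of these data, centroid precision is sufficient and no PSF fitting is
   attempted. `threshold_sensitivity` re-runs the whole chain across a set
   of bands and reports the spread of the fitted parameters, since the
   per-cell band choice is a manual step in practice.
2. **Linking** (`link`). Greedy nearest-neighbor in global distance order
   with a hard displacement cap, ties broken by smaller track id — fully
   deterministic, and exact whenever objects stay farther apart than twice
   the cap (verified against exhaustive assignment). No gap closing: a
   missed detection ends the track. Drift correction is out of scope (cells
   are adhered in the emulated protocol).
3. **MSD and fit** (`compute_msd`, `fit_power_law`). Per trajectory,
   squared displacements are time-averaged over *all* overlapping index
   pairs at each lag (the averaging scheme is not fixed by the original
   tracking tools; overlapping time-averaging is standard and extracts the
   most from 100-frame tracks); per cell, the unweighted mean across
   trajectories. The default lag grid is $k \cdot 0.3$ s, $k = 1..10$ —
   a 3 s window, long enough that cell size does not confine the motion.
   The fit is nonlinear least squares of $A\,\Delta t^{\alpha}$
   (initialized from the log–log regression; `minpack.lm` handles the
   zero-residual fixtures exactly), $K_\alpha = A / (2n)$, lags unweighted
   by default with inverse-variance weighting behind a flag. If the
   nonlinear fit fails, the log–log estimate is returned and flagged.
4. **Homogeneity** (`compute_cv`). The phase-separation (LLPS) proxy is the
   coefficient of variation of pixel intensities inside the cell footprint:
   homogeneous reporter, low CV; droplet-dominated, high CV. Population SD
   is used (footprints hold thousands of pixels; the convention is stated
   for determinism). The footprint is supplied or derived by Otsu; the
   whole-cell footprint is used (the original description is ambiguous
   between whole-cell and nuclear footprints; whole-footprint is the
   default and the mask argument makes it configurable).
   `noise_cv_impact` quantifies by Monte Carlo how additive imaging noise
   inflates the CV and compares it with the quadrature approximation
   $\sqrt{\mathrm{cv}^2 + (\sigma_{\mathrm{noise}}/\mu)^2}$ — at realistic
   noise (a few percent of the mean) the inflation is negligible.
5. **Cohort statistics** (`run_cohort_analysis`). Paired two-sided t-tests
   ($\alpha$, $K_\alpha$, entropy at $\Delta t_{\mathrm{eval}} = 3$ s — the
   maximal measured lag, where the log-shaped entropy has essentially
   saturated); the elasticity regression on the depleted arm; the
   decomposition of the active arm's $\alpha$; and power-law regressions of
   CV on $K_\alpha$, $\alpha$ and $\alpha_{\mathrm{work}}$ per arm. CV on
   entropy uses an *exponential* (log-linear) regression: entropy is itself
   logarithmic in energy, so this is exactly a power law in energy, and it
   stays defined when entropies are negative under the fixed unit
   convention. Significance is fixed at $p \le 0.05$ with no
   multiple-testing correction, matching the study design; a
   Benjamini–Hochberg option exists behind `p_adjust = TRUE`. Direction
   claims are reported as booleans plus the underlying coefficients and
   p-values — they describe the synthetic data, not proof of biology.

## The synthetic cohort

No microscopy data accompany the framework, so `generate_cohort` simulates
the full paired study with known ground truth:

* **Trajectories** are fractional Brownian motion with Hurst exponent
  $H = \alpha/2$, scaled so the per-dimension MSD is exactly
  $2 K_\alpha t^{\alpha}$ at every lag. Increments are sampled with exact
  covariance (cached Cholesky factor for short series, Davies–Harte
  circulant embedding for long ones) — no Euler-scheme bias, which the
  MSD-calibration tests rely on. $\alpha = 2$ is handled as the ballistic
  limit. Active-arm motion is generated as fBM at the *combined* power
  $\alpha_e + \alpha_{\mathrm{work}}$: the framework treats work as an
  additive change in the exponent, so no explicit force process is
  simulated, and whether real active motion has a crossover timescale is
  deliberately left outside the model.
* **Depleted arm**: per-cell $(K_\alpha, \alpha)$ on constant-energy curves
  $K_\alpha = E_i/(4\pi)\,3^{-\alpha}$, with a tight per-cell energy spread
  (`depleted_energy_sd = 0.1` on the log scale) and a broader inter-cell
  diffusion-power spread (`cell_noise_cv = 0.2`) — equilibrium cells
  cluster around a common energy level, which is what makes a single
  regression curve through the depleted arm meaningful at n = 12.
* **Active arm**: adds a per-cell lognormal $\alpha_{\mathrm{work}}$ (mean
  = difference of the arm means, log-SD 0.45) and enlarges $K_\alpha$
  proportionally to the cell's relative work (`k_work_coupling = 1`),
  because work pushes both parameters. The cell's droplet partition ratio
  is coupled negatively to its work (`work_cv_slope = -0.8`): cells doing
  more mechanical work are programmed to be more homogeneous. In the
  depleted arm the partition ratio is drawn independently of diffusion.
* **Defaults** emulate a 12-cell paired design at vesicle-scale diffusion
  (active $K_\alpha$ = 0.02 µm²/s$^\alpha$, $\alpha$ = 1.0; depleted 0.005
  and 0.6), 30 tracked objects per cell over 100 frames at 0.3 s, with
  small independent per-arm jitter standing in for measurement noise.
  Setting both arms' means equal produces a genuine null cohort — two
  independent draws around the same cell baseline — used for type-I-error
  calibration of the paired test.
* **Images**: stacks render dark disks (radius 0.05–1 µm, the
  vesicle/organelle size range) on a light background with additive
  Gaussian noise and reflective boundaries (chosen so boundaries stay out
  of the MSD regime in fixtures, as the 3 s window keeps them out in
  cells); LLPS images place non-overlapping droplets in a circular
  footprint with the dilute level set to conserve total intensity across
  partition ratios, so demixing redistributes fluorescence rather than
  creating it. All randomness descends from one master seed through a
  documented splitting scheme (`split_seed`), making every simulated data
  set bit-reproducible.

What the generator does *not* emulate: DIC optics (shear/interference
physics), 3-D motion, confinement or hop diffusion, per-particle
heterogeneity within a cell, partially-paired cohorts' biology (unpaired
cells are supported mechanically and excluded from paired tests), or any
crossover timescale in active motion. Passing tests therefore demonstrate
that the pipeline recovers what this generative model puts in — parameter
recovery, calibration, and direction recovery under programmed effects —
not that real cells behave this way.

## Numerical choices and problem sizes

* fGn sampling switches from Cholesky to circulant embedding above 256
  steps; if an embedding is not nonnegative-definite (possible for
  $\alpha$ very close to 2 at small n) it falls back to Cholesky. Both are
  exact.
* The parameter-recovery study runs 200 trajectories × 100 frames per
  cohort at $\alpha \in \{0.5, 0.8, 1.0, 1.2\}$ and $K_\alpha \in \{0.005,
  0.02\}$ over 20 seeds; direction recovery uses 100 full 12-cell cohorts;
  type-I calibration uses 500 parameter-level null cohorts. These sizes
  give Monte-Carlo error comfortably below the tested tolerances while
  keeping the whole suite a few minutes long.
* Degenerate inputs are contracts, not accidents: constant images map to
  all-zero 8-bit stacks; a paired test on identical arms is flagged
  degenerate instead of producing 0/0; a single-band sensitivity analysis
  reports zero spread; `dt = 1` s makes the constant-energy curve flat and
  warns (the lag term degenerates); an empty detection table yields an
  empty size histogram.
* Ties in linking break on the smaller track id; component labels are
  assigned in raster order of first pixel — both choices exist purely so
  results are deterministic and oracle-comparable.

## Known limitations

The entropy/energy values are meaningful only relative to the fixed µm/s
convention (no Boltzmann scaling); the elastic constant of the restoring
force is never estimated; the greedy linker is not a global assignment
tracker and will mis-link in dense fields (its guarantees hold for the
sparse fixtures it is used on); and the half-Gaussian step that turns the
translocation entropy prefactor from ½ into ¼ is adopted as a convention of
the framework rather than derived.
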