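# Paired synthetic cohorts: the same simulated cell measured in an active
# (ATP-replete, non-equilibrium) and a depleted (equilibrium) condition.
# Depleted-arm ground truth lies on constant-energy curves
# k_alpha = E_i / (4 pi) * dt^(-alpha) with a per-cell energy level E_i, so
# that alpha and K_alpha are negatively coupled across cells, as expected at
# equilibrium. The active arm adds a per-cell mechanical-work component
# alpha_work to the diffusion power and enlarges K_alpha, with K_alpha
# coupled positively to alpha_work (work pushes both). The cell's
# phase-separation state (droplet partition ratio) is coupled negatively to
# alpha_work in the active arm — cells doing more mechanical work are more
# homogeneous — and is independent of diffusion in the depleted arm.

#' Specify a paired active/depleted synthetic cohort
#'
#' Defaults emulate the study conditions of a 12-cell paired design with
#' vesicle-scale diffusion (K ~ 0.005-0.02 um^2/s^alpha, sub-diffusive
#' depleted cells, near-Brownian active cells) observed for 100 frames at
#' 0.3 s and evaluated over a 3 s lag window.
#'
#' @param n_cells number of paired cells (default 12).
#' @param active_k_mean,active_alpha_mean,depleted_k_mean,depleted_alpha_mean
#'   ground-truth cohort means of the diffusion parameters per arm. Equal
#'   active and depleted means define a zero-effect (null) cohort in which
#'   the two arms are independent draws from the same distribution.
#' @param depleted_energy_sd SD of the per-cell log energy level around the
#'   constant-energy baseline.
#' @param work_cv_slope exponent coupling the active-arm droplet partition
#'   ratio to `alpha_work` (negative: more work, more homogeneous).
#' @param cell_noise_cv inter-cell relative spread of the baseline diffusion
#'   power.
#' @param work_sdlog log-SD of the per-cell `alpha_work` around its mean.
#' @param k_work_coupling exponent tying the active-arm K_alpha enlargement
#'   to the cell's relative `alpha_work` (positive).
#' @param arm_alpha_sd,arm_lnk_sd independent per-arm (measurement-scale)
#'   jitter on alpha (additive) and log K_alpha.
#' @param partition_base baseline droplet/dilute partition ratio of the
#'   rendered LLPS images.
#' @param n_traj,n_frames,dt_frame trajectory sampling per cell and arm.
#' @param dt_eval lag (s) at which energies/entropies are defined (3 s, the
#'   maximal measured lag).
#' @param seed master RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cells = 12,
                        active_k_mean = 0.02, active_alpha_mean = 1.0,
                        depleted_k_mean = 0.005, depleted_alpha_mean = 0.6,
                        depleted_energy_sd = 0.1, work_cv_slope = -0.8,
                        cell_noise_cv = 0.2, work_sdlog = 0.45,
                        k_work_coupling = 1, arm_alpha_sd = 0.03,
                        arm_lnk_sd = 0.05, partition_base = 2.5,
                        n_traj = 30, n_frames = 100, dt_frame = 0.3,
                        dt_eval = 3, seed = NULL) {
  if (active_alpha_mean < depleted_alpha_mean ||
      active_k_mean < depleted_k_mean) {
    stop("active-arm means must be >= depleted-arm means ",
         "(set them equal for a null cohort)", call. = FALSE)
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a paired synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param detail `"parameters"` returns ground-truth per-cell parameters
#'   only (fast, for calibration studies); `"full"` additionally simulates
#'   the trajectory sets and renders the LLPS image for every cell and
#'   condition.
#' @return list of class `cohort_sim` with `params` (tibble: `cell_id`,
#'   `condition`, `k_alpha`, `alpha`, `alpha_work_true`, `energy_true`,
#'   `partition_ratio`) and, for `detail = "full"`, `cells` — a list with
#'   one entry per cell and condition holding `trajectories` (list of
#'   trajectory tibbles) and `llps` (rendered image + mask).
#' @export
generate_cohort <- function(spec, detail = c("full", "parameters")) {
  stopifnot(inherits(spec, "cohort_spec"))
  detail <- match.arg(detail)
  n <- spec$n_cells
  w_mean <- spec$active_alpha_mean - spec$depleted_alpha_mean
  k_ratio <- spec$active_k_mean / spec$depleted_k_mean
  E0 <- 4 * pi * spec$depleted_k_mean * spec$dt_eval^spec$depleted_alpha_mean

  par <- with_seed(split_seed(spec$seed %||% 0L, 0L), {
    base_alpha <- spec$depleted_alpha_mean *
      exp(stats::rnorm(n, 0, spec$cell_noise_cv))
    energy <- E0 * exp(stats::rnorm(n, 0, spec$depleted_energy_sd))
    alpha_dep <- pmin(pmax(base_alpha +
      stats::rnorm(n, 0, spec$arm_alpha_sd), 0.05), 2)
    k_dep <- energy / (4 * pi) * spec$dt_eval^(-alpha_dep) *
      exp(stats::rnorm(n, 0, spec$arm_lnk_sd))
    if (w_mean > 0) {
      alpha_work <- w_mean * exp(stats::rnorm(n, 0, spec$work_sdlog))
      work_rel <- alpha_work / w_mean
    } else {
      alpha_work <- rep(0, n)
      work_rel <- rep(1, n)
    }
    alpha_act <- pmin(pmax(base_alpha + alpha_work +
      stats::rnorm(n, 0, spec$arm_alpha_sd), 0.05), 2)
    k_act <- energy / (4 * pi) * spec$dt_eval^(-alpha_dep) * k_ratio *
      work_rel^spec$k_work_coupling *
      exp(stats::rnorm(n, 0, spec$arm_lnk_sd))
    part_act <- 1 + (spec$partition_base - 1) *
      work_rel^spec$work_cv_slope * exp(stats::rnorm(n, 0, 0.05))
    part_dep <- 1 + (spec$partition_base - 1) *
      exp(stats::rnorm(n, 0, 0.3))
    tibble::tibble(
      cell_id = rep(seq_len(n), 2),
      condition = rep(c("active", "depleted"), each = n),
      k_alpha = c(k_act, k_dep),
      alpha = c(alpha_act, alpha_dep),
      alpha_work_true = c(alpha_work, rep(0, n)),
      energy_true = rep(energy, 2),
      partition_ratio = c(part_act, part_dep)
    )
  })

  out <- list(params = par, spec = spec)
  if (detail == "full") {
    out$cells <- lapply(seq_len(nrow(par)), function(i) {
      row <- par[i, ]
      cell_seed <- split_seed(spec$seed %||% 0L, i)
      trajs <- lapply(seq_len(spec$n_traj), function(j) {
        simulate_fbm_trajectory(trajectory_spec(
          k_alpha = row$k_alpha, alpha = row$alpha,
          n_steps = spec$n_frames, dt_frame = spec$dt_frame,
          seed = split_seed(cell_seed, j)))
      })
      llps <- render_llps_image(llps_image_spec(
        height = 96, width = 96, n_droplets = 6, droplet_radius = 6,
        partition_ratio = row$partition_ratio, total_intensity = 1e6,
        noise_sd = 2, seed = split_seed(cell_seed, 10001L)))
      list(cell_id = row$cell_id, condition = row$condition,
           trajectories = trajs, llps = llps)
    })
  }
  class(out) <- "cohort_sim"
  out
}

#' Per-cell records from a simulated cohort
#'
#' Runs the measurement half of the pipeline on a `detail = "full"`
#' simulation: per cell and condition, ensemble MSD over the trajectory set,
#' power-law diffusion fit, and footprint-CV homogeneity from the rendered
#' LLPS image.
#'
#' @param sim a `cohort_sim` from [generate_cohort()] with `detail = "full"`.
#' @param k_max number of MSD lags (default 10).
#' @return tibble of per-cell records: `cell_id`, `condition`, `k_alpha`,
#'   `alpha`, `alpha_se`, `cv` — the input format of
#'   [run_cohort_analysis()].
#' @export
records_from_cohort <- function(sim, k_max = 10L) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (is.null(sim$cells)) {
    stop("simulation was generated with detail = \"parameters\"; ",
         "rerun generate_cohort(detail = \"full\")", call. = FALSE)
  }
  rows <- lapply(sim$cells, function(cell) {
    curve <- compute_msd(cell$trajectories, k_max = k_max,
                         dt_frame = sim$spec$dt_frame)
    fit <- fit_power_law(curve, n_dims = 2)
    cv <- compute_cv(cell$llps$image, cell$llps$mask)
    tibble::tibble(cell_id = cell$cell_id, condition = cell$condition,
                   k_alpha = fit$k_alpha, alpha = fit$alpha,
                   alpha_se = fit$alpha_se, cv = cv$cv)
  })
  do.call(rbind, rows)
}
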