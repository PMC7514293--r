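# The entropy/energy framework. A particle whose translocations at lag dt
# are Gaussian with variance 2 * k_alpha * dt^alpha carries a generalized
# (differential) entropy
#     S(k_alpha, alpha, dt) = (1/4) * ln(4 * pi * e * k_alpha * dt^alpha)
# and a total-energy scale
#     E(k_alpha, alpha, dt) = 4 * pi * k_alpha * dt^alpha,
# tied by the identity S = 1/4 + (1/4) * ln E. All proportionality constants
# are fixed at 1 in a single unit system (um, s); differential entropy is
# unit-dependent, so values are comparable only within this convention.
# Level sets of E give the constant-energy relation
#     k_alpha = E / (4 * pi) * dt^(-alpha),
# the negative k_alpha-alpha coupling expected at thermodynamic equilibrium.
# Out of equilibrium the diffusion power gains a mechanical-work component:
# alpha = alpha_e + alpha_work, with alpha_e predicted from k_alpha by a
# power-law regression fitted on ATP-depleted (equilibrium) cells.

#' Differential entropy of a Gaussian
#'
#' `(1/2) * ln(2 * pi * e * sigma2)`, in nats.
#'
#' @param sigma2 variance (> 0).
#' @return entropy in nats.
#' @export
gaussian_entropy <- function(sigma2) {
  stop_if_not_positive(sigma2, "sigma2")
  0.5 * log(2 * pi * exp(1) * sigma2)
}

#' Generalized entropy of a diffusing particle
#'
#' `(1/4) * ln(4 * pi * e * k_alpha * dt^alpha)` in nats: the half-Gaussian
#' entropy of the translocation distribution at lag `dt` under the
#' anomalous-diffusion law, with the proportionality constant fixed at 1
#' (units um, s). Logarithmic in `dt`, so moderate observation windows
#' already approximate the long-lag entropy well.
#'
#' @param k_alpha generalized diffusion coefficient, um^2/s^alpha (> 0).
#' @param alpha diffusion power.
#' @param dt evaluation time lag, s (> 0); the cohort default is the
#'   maximal measured lag, 3 s.
#' @return entropy in nats.
#' @export
particle_entropy <- function(k_alpha, alpha, dt) {
  stop_if_not_positive(k_alpha, "k_alpha")
  stop_if_not_positive(dt, "dt")
  0.25 * log(4 * pi * exp(1) * k_alpha * dt^alpha)
}

#' Total-energy scale of a diffusing particle
#'
#' `4 * pi * k_alpha * dt^alpha` (arbitrary units, constant fixed at 1):
#' the squared Gaussian integral of the translocation distribution, read as
#' the particle's average total energy level at lag `dt`.
#'
#' @inheritParams particle_entropy
#' @return energy in arbitrary units.
#' @export
total_energy <- function(k_alpha, alpha, dt) {
  stop_if_not_positive(k_alpha, "k_alpha")
  stop_if_not_positive(dt, "dt")
  4 * pi * k_alpha * dt^alpha
}

#' Constant-energy curve in the (alpha, K_alpha) plane
#'
#' The level set of [total_energy()]: `k_alpha = energy / (4 * pi) *
#' dt^(-alpha)`. For `dt > 1` s the curve decreases in `alpha` — the
#' negative diffusion-parameter coupling expected at equilibrium — with
#' slope `-energy * dt^(-alpha) * log(dt) / (4 * pi)`. At `dt = 1` the lag
#' term degenerates to 1 and the curve is flat (warned).
#'
#' @param energy total energy level (> 0).
#' @param dt time lag, s (> 0).
#' @param alphas vector of diffusion powers at which to evaluate.
#' @return numeric vector of `k_alpha` values, one per element of `alphas`.
#' @export
constant_energy_curve <- function(energy, dt, alphas) {
  stop_if_not_positive(energy, "energy")
  stop_if_not_positive(dt, "dt")
  if (dt == 1) {
    warning("dt = 1: dt^(-alpha) is identically 1, curve is constant",
            call. = FALSE)
  }
  energy / (4 * pi) * dt^(-alphas)
}

#' Fit the equilibrium elasticity regression alpha_e = a * K_alpha^b
#'
#' Log-log least squares of `alpha` on `k_alpha` over equilibrium
#' (ATP-depleted) cells. The fitted curve predicts the elasticity-dominated
#' diffusion power `alpha_e` from a cell's diffusion coefficient; for
#' equilibrium-like data the exponent `b` is expected negative (reported,
#' not enforced).
#'
#' @param k_alpha,alpha positive numeric vectors of equal length (>= 3):
#'   per-cell fitted diffusion parameters of the depleted arm.
#' @return list of class `elastic_regression`: `a`, `b`, `p_value` (slope
#'   test), `n`, `r_squared`.
#' @export
fit_elastic_regression <- function(k_alpha, alpha) {
  if (length(k_alpha) != length(alpha)) {
    stop("`k_alpha` and `alpha` must have equal length", call. = FALSE)
  }
  if (length(k_alpha) < 3) stop("need >= 3 cells", call. = FALSE)
  stop_if_not_positive(k_alpha, "k_alpha")
  stop_if_not_positive(alpha, "alpha")
  fit <- stats::lm(log(alpha) ~ log(k_alpha))
  sm <- quiet_lm_summary(fit)
  cf <- sm$coefficients
  out <- list(a = exp(cf[1, 1]), b = cf[2, 1],
              p_value = cf[2, 4], n = length(k_alpha),
              r_squared = sm$r.squared)
  class(out) <- "elastic_regression"
  out
}

#' Manually specify an elasticity regression
#'
#' Builds an `elastic_regression` object from known coefficients of the
#' power law `alpha_e = a * k_alpha^b`, e.g. for worked examples or for
#' applying a regression fitted elsewhere.
#'
#' @param a coefficient (> 0).
#' @param b exponent.
#' @return an `elastic_regression` object (without fit statistics).
#' @export
elastic_regression <- function(a, b) {
  stop_if_not_positive(a, "a")
  structure(list(a = a, b = b, p_value = NA_real_, n = NA_integer_,
                 r_squared = NA_real_),
            class = "elastic_regression")
}

#' @export
print.elastic_regression <- function(x, ...) {
  cat(sprintf("Elasticity regression: alpha_e = %.4g * K_alpha^%.4g\n",
              x$a, x$b))
  if (!is.na(x$p_value)) {
    cat(sprintf("  slope p = %.3g, n = %d, R^2 = %.3f\n", x$p_value, x$n,
                x$r_squared))
  }
  invisible(x)
}

#' Decompose the diffusion power into elasticity and work components
#'
#' `alpha_e = a * k_alpha^b` from the equilibrium regression;
#' `alpha_work = alpha - alpha_e` is the mechanical-work excess. A negative
#' `alpha_work` (cell below the equilibrium curve) is flagged, not clipped.
#'
#' @param fit a `diffusion_fit` (or a list with `k_alpha` and `alpha`).
#' @param reg an `elastic_regression`.
#' @return list: `alpha_e`, `alpha_work`, `negative_work` flag.
#' @export
decompose_alpha <- function(fit, reg) {
  stopifnot(inherits(reg, "elastic_regression"))
  stop_if_not_positive(fit$k_alpha, "k_alpha")
  alpha_e <- reg$a * fit$k_alpha^reg$b
  alpha_work <- fit$alpha - alpha_e
  list(alpha_e = alpha_e, alpha_work = alpha_work,
       negative_work = alpha_work < 0)
}

#' Split the particle entropy into elasticity and work terms
#'
#' The total entropy at the combined power `alpha_e + alpha_work` separates
#' exactly into an equilibrium term — the entropy the cell would have with
#' work switched off — and a work increment that is purely logarithmic in
#' the lag:
#' `elastic_term = (1/4) * ln(4 * pi * e * k_alpha * dt^alpha_e)`,
#' `work_term = (alpha_work / 4) * ln(dt)`.
#' The two terms sum to [particle_entropy()] at the combined power with zero
#' offset (the exact-sum convention adopted here; see the methods vignette
#' for why the split is anchored to the total entropy). With
#' `alpha_work = 0` the work term vanishes and the total reduces to the
#' equilibrium entropy.
#'
#' @param k_alpha diffusion coefficient (> 0).
#' @param alpha_e,alpha_work elasticity and work components of the power.
#' @param dt evaluation lag, s (> 0).
#' @return list: `elastic_term`, `work_term` (nats).
#' @export
entropy_decomposition <- function(k_alpha, alpha_e, alpha_work, dt) {
  stop_if_not_positive(k_alpha, "k_alpha")
  stop_if_not_positive(dt, "dt")
  list(
    elastic_term = 0.25 * log(4 * pi * exp(1) * k_alpha * dt^alpha_e),
    work_term = alpha_work / 4 * log(dt)
  )
}

#' Thermodynamic state of one cell
#'
#' Convenience wrapper evaluating entropy, energy and (optionally) the
#' alpha decomposition for one fitted cell at lag `dt_eval`.
#'
#' @param fit a `diffusion_fit` (or list with `k_alpha`, `alpha`).
#' @param dt_eval evaluation lag, s (default 3, the maximal measured lag).
#' @param reg optional `elastic_regression` for the alpha decomposition.
#' @return list of class `thermo_state`: `entropy_nats`, `energy_au`,
#'   `alpha_e`, `alpha_work` (NA without `reg`), `dt_eval`.
#' @export
thermo_state <- function(fit, dt_eval = 3, reg = NULL) {
  s <- particle_entropy(fit$k_alpha, fit$alpha, dt_eval)
  e <- total_energy(fit$k_alpha, fit$alpha, dt_eval)
  if (!is.null(reg)) {
    dec <- decompose_alpha(fit, reg)
    ae <- dec$alpha_e; aw <- dec$alpha_work
  } else {
    ae <- NA_real_; aw <- NA_real_
  }
  structure(list(entropy_nats = s, energy_au = e, alpha_e = ae,
                 alpha_work = aw, dt_eval = dt_eval),
            class = "thermo_state")
}
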