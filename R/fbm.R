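# Exact fractional Gaussian noise / fractional Brownian motion sampling.
#
# A trajectory with anomalous-diffusion parameters (k_alpha, alpha) is built
# from fractional Gaussian noise with Hurst exponent H = alpha / 2 and
# per-step variance 2 * k_alpha * dt^alpha, so that for every lag k the
# per-dimension displacement variance is exactly
#   Var(x_{i+k} - x_i) = 2 * k_alpha * (k * dt)^alpha.
# Two exact-covariance samplers are used: a cached Cholesky factor of the fGn
# covariance for short series and Davies-Harte circulant embedding for long
# ones. Both reproduce the target covariance exactly (no Euler-type
# discretization error), which the MSD-calibration tests rely on.

# autocovariance of unit-variance fGn at integer lags 0..m
fgn_acf <- function(m, H) {
  k <- 0:m
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# cache of Cholesky factors keyed by "n|H" (unit variance; scale applied later)
.fgn_cache <- new.env(parent = emptyenv())

fgn_chol <- function(n, H) {
  key <- sprintf("%d|%.17g", n, H)
  L <- .fgn_cache[[key]]
  if (is.null(L)) {
    g <- fgn_acf(n - 1, H)
    L <- chol(stats::toeplitz(g))
    .fgn_cache[[key]] <- L
  }
  drop(crossprod(L, stats::rnorm(n)))
}

fgn_davies_harte <- function(n, H) {
  m <- 2^ceiling(log2(n))
  g <- fgn_acf(m, H)
  row <- c(g, rev(g[2:m]))            # circulant first row, length 2m
  lambda <- Re(stats::fft(row))
  if (min(lambda) < -1e-8 * max(lambda)) {
    # circulant embedding not nonnegative-definite here; fall back to exact
    # Cholesky (can occur for H very close to 1 at small n)
    return(fgn_chol(n, H))
  }
  lambda[lambda < 0] <- 0
  M <- 2 * m
  z <- stats::rnorm(M)
  w <- complex(length.out = M)
  w[1] <- sqrt(lambda[1] / M) * z[1]
  w[m + 1] <- sqrt(lambda[m + 1] / M) * z[2]
  j <- 2:m
  re <- z[2 * j - 1]
  im <- z[2 * j]
  w[j] <- sqrt(lambda[j] / (2 * M)) * complex(real = re, imaginary = im)
  w[M + 2 - j] <- Conj(w[j])
  Re(stats::fft(w))[seq_len(n)]
}

# n unit-variance fGn samples with Hurst H in (0, 1)
fgn_sample <- function(n, H) {
  stopifnot(n >= 1, H > 0, H < 1)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  if (n <= 256) fgn_chol(n, H) else fgn_davies_harte(n, H)
}

#' Specify an anomalous-diffusion trajectory simulation
#'
#' Bundles the ground-truth parameters of one simulated trajectory obeying
#' the anomalous-diffusion law `MSD(t) = 2 * n_dims * k_alpha * t^alpha`.
#'
#' @param k_alpha generalized diffusion coefficient, um^2 / s^alpha (> 0).
#' @param alpha diffusion power in (0, 2]: < 1 sub-diffusive, 1 Brownian,
#'   > 1 super-diffusive, 2 ballistic.
#' @param n_steps number of recorded frames (>= 2).
#' @param dt_frame frame interval in seconds (> 0).
#' @param n_dims number of spatial dimensions (default 2).
#' @param seed RNG seed; identical spec + seed reproduce the trajectory
#'   bit for bit.
#' @return an object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(k_alpha, alpha, n_steps, dt_frame = 0.3,
                            n_dims = 2L, seed = NULL) {
  stop_if_not_positive(k_alpha, "k_alpha")
  stop_if_not_positive(dt_frame, "dt_frame")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 2) {
    stop("`alpha` must lie in (0, 2]", call. = FALSE)
  }
  if (n_steps < 2) stop("`n_steps` must be >= 2", call. = FALSE)
  structure(
    list(k_alpha = k_alpha, alpha = alpha, n_steps = as.integer(n_steps),
         dt_frame = dt_frame, n_dims = as.integer(n_dims), seed = seed),
    class = "trajectory_spec"
  )
}

#' Simulate a fractional-Brownian-motion trajectory
#'
#' Generates positions of one particle whose per-dimension mean square
#' displacement follows `2 * k_alpha * t^alpha` exactly at every lag.
#' Increments are exact fractional Gaussian noise with Hurst exponent
#' `alpha / 2`; `alpha = 2` is the ballistic limit (a straight line with a
#' Gaussian random velocity of variance `2 * k_alpha` per dimension).
#'
#' @param spec a [trajectory_spec()].
#' @return a tibble of class `trajectory` with columns `frame`, `t_s` and one
#'   position column per dimension (`x_um`, `y_um`, ...), starting at the
#'   origin at `t = 0`.
#' @examples
#' tr <- simulate_fbm_trajectory(trajectory_spec(0.02, 0.8, 100, seed = 1))
#' head(tr)
#' @export
simulate_fbm_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_inc <- spec$n_steps - 1L
  sd_step <- sqrt(2 * spec$k_alpha * spec$dt_frame^spec$alpha)
  H <- spec$alpha / 2
  pos <- with_seed(spec$seed, {
    vapply(seq_len(spec$n_dims), function(d) {
      inc <- if (spec$alpha == 2) {
        rep(stats::rnorm(1), n_inc)           # perfectly correlated steps
      } else {
        fgn_sample(n_inc, H)
      }
      c(0, cumsum(sd_step * inc))
    }, numeric(spec$n_steps))
  })
  dim_names <- c("x_um", "y_um", "z_um")
  if (spec$n_dims > 3) dim_names <- paste0("d", seq_len(spec$n_dims), "_um")
  out <- tibble::tibble(
    frame = seq_len(spec$n_steps) - 1L,
    t_s = (seq_len(spec$n_steps) - 1L) * spec$dt_frame
  )
  for (d in seq_len(spec$n_dims)) out[[dim_names[d]]] <- pos[, d]
  class(out) <- c("trajectory", class(out))
  attr(out, "spec") <- spec
  out
}

# positions of a trajectory tibble as a plain matrix (n_steps x n_dims)
trajectory_positions <- function(tr) {
  cols <- setdiff(names(tr), c("frame", "t_s", "particle_id", "cell_id"))
  as.matrix(tr[, cols, drop = FALSE])
}
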