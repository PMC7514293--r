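# Linking detections into trajectories and turning trajectories into
# per-cell MSD curves and anomalous-diffusion fits. The linker is a greedy
# nearest-neighbor in global distance order (MultiTracker-class simplicity,
# fully deterministic); the MSD is time-averaged over overlapping pairs
# within each trajectory and then ensemble-averaged (unweighted) across
# trajectories; the fit is nonlinear least squares of msd = A * lag^alpha
# with k_alpha = A / (2 * n_dims).

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame assignment is greedy in ascending pairwise distance over
#' all (track end, detection) pairs: the closest pair links first, links
#' longer than `max_disp` are forbidden, ties break on smaller particle id.
#' Unmatched detections start new trajectories; a track that misses a frame
#' ends (no gap closing). Trajectories shorter than `min_len` frames are
#' dropped.
#'
#' @param detections tibble with `frame`, `x_um`, `y_um` (sorted or not;
#'   frames are processed in order).
#' @param max_disp maximum frame-to-frame displacement, um (> 0).
#' @param min_len minimum trajectory length in frames.
#' @param dt_frame frame interval used to timestamp samples, s.
#' @return list of trajectory tibbles (`particle_id`, `frame`, `t_s`,
#'   `x_um`, `y_um`).
#' @export
link <- function(detections, max_disp, min_len = 2L, dt_frame = 0.3) {
  if (!is.numeric(max_disp) || max_disp <= 0) {
    stop("`max_disp` must be > 0", call. = FALSE)
  }
  if (nrow(detections) == 0) return(list())
  frames <- sort(unique(detections$frame))
  next_id <- 0L
  # active tracks: list of (id, frame, x, y); all points accumulated in `pts`
  active <- data.frame(id = integer(), x = numeric(), y = numeric(),
                       frame = integer())
  pts <- vector("list", 0)
  add_point <- function(id, frame, x, y) {
    pts[[length(pts) + 1]] <<- data.frame(particle_id = id, frame = frame,
                                          x_um = x, y_um = y)
  }
  for (fr in frames) {
    det <- detections[detections$frame == fr, , drop = FALSE]
    live <- active[active$frame == fr - 1L, , drop = FALSE]
    assigned_det <- rep(FALSE, nrow(det))
    assigned_trk <- rep(FALSE, nrow(live))
    if (nrow(live) > 0 && nrow(det) > 0) {
      dmat <- outer(live$x, det$x_um, "-")^2 + outer(live$y, det$y_um, "-")^2
      ord <- order(dmat, row(dmat))   # ascending distance, tie: smaller track
      for (k in ord) {
        if (dmat[k] > max_disp^2) break
        i <- row(dmat)[k]; j <- col(dmat)[k]
        if (assigned_trk[i] || assigned_det[j]) next
        assigned_trk[i] <- TRUE; assigned_det[j] <- TRUE
        active$x[active$id == live$id[i]] <- det$x_um[j]
        active$y[active$id == live$id[i]] <- det$y_um[j]
        active$frame[active$id == live$id[i]] <- fr
        add_point(live$id[i], fr, det$x_um[j], det$y_um[j])
      }
    }
    if (any(!assigned_det)) {
      for (j in which(!assigned_det)) {
        next_id <- next_id + 1L
        active <- rbind(active, data.frame(id = next_id, x = det$x_um[j],
                                           y = det$y_um[j], frame = fr))
        add_point(next_id, fr, det$x_um[j], det$y_um[j])
      }
    }
  }
  all_pts <- do.call(rbind, pts)
  out <- lapply(split(all_pts, all_pts$particle_id), function(d) {
    d <- d[order(d$frame), ]
    tibble::tibble(particle_id = d$particle_id[1], frame = d$frame,
                   t_s = d$frame * dt_frame, x_um = d$x_um, y_um = d$y_um)
  })
  out <- out[vapply(out, nrow, integer(1)) >= min_len]
  unname(out)
}

#' Per-cell ensemble MSD curve
#'
#' For each trajectory the squared displacement is time-averaged over all
#' overlapping index pairs at each lag `k * dt_frame`; the cell curve is the
#' unweighted mean across trajectories that reach that lag. Lags with no
#' observation are omitted.
#'
#' @param trajectories list of trajectory tibbles (or a single one).
#' @param k_max largest lag in frames (default 10, i.e. 3 s at 0.3 s frames).
#' @param dt_frame frame interval, s; taken from the first trajectory's
#'   timestamps when `NULL`.
#' @return tibble of class `msd_curve`: `lag_s`, `msd_um2`, `n_obs` (total
#'   displacement pairs entering the lag), `n_traj` (trajectories
#'   contributing).
#' @export
compute_msd <- function(trajectories, k_max = 10L, dt_frame = NULL) {
  if (inherits(trajectories, "data.frame")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  if (is.null(dt_frame)) {
    t1 <- trajectories[[1]]$t_s
    dt_frame <- min(diff(t1))
  }
  per_lag_sum <- numeric(k_max)
  per_lag_traj <- integer(k_max)
  per_lag_nobs <- integer(k_max)
  for (tr in trajectories) {
    p <- as.matrix(tr[, intersect(c("x_um", "y_um", "z_um"), names(tr)),
                      drop = FALSE])
    n <- nrow(p)
    if (n < 2) next
    for (k in seq_len(min(k_max, n - 1))) {
      d <- p[(k + 1):n, , drop = FALSE] - p[1:(n - k), , drop = FALSE]
      sq <- rowSums(d^2)
      per_lag_sum[k] <- per_lag_sum[k] + mean(sq)
      per_lag_traj[k] <- per_lag_traj[k] + 1L
      per_lag_nobs[k] <- per_lag_nobs[k] + length(sq)
    }
  }
  keep <- per_lag_traj > 0
  out <- tibble::tibble(
    lag_s = (seq_len(k_max) * dt_frame)[keep],
    msd_um2 = (per_lag_sum / pmax(per_lag_traj, 1L))[keep],
    n_obs = per_lag_nobs[keep],
    n_traj = per_lag_traj[keep]
  )
  class(out) <- c("msd_curve", class(out))
  out
}

#' Fit the anomalous-diffusion power law to an MSD curve
#'
#' Nonlinear least squares of `msd = A * lag^alpha` (one-term power model),
#' initialized from the log-log linear regression; `k_alpha = A / (2 *
#' n_dims)`. If the nonlinear fit fails to converge the log-log estimate is
#' returned with `fallback = TRUE`. Lags are unweighted by default;
#' `weights = "inverse_variance"` weights each lag by its observation count.
#'
#' @param curve an `msd_curve` from [compute_msd()] (needs >= 3 positive
#'   lags).
#' @param n_dims number of spatial dimensions of the tracked motion.
#' @param weights `"none"` (default) or `"inverse_variance"`.
#' @return list of class `diffusion_fit`: `k_alpha`, `alpha`, their standard
#'   errors, `n_dims`, `resid_norm`, `fallback`.
#' @export
fit_power_law <- function(curve, n_dims = 2L,
                          weights = c("none", "inverse_variance")) {
  weights <- match.arg(weights)
  ok <- curve$msd_um2 > 0
  if (sum(ok) < 3) stop("need >= 3 lags with positive MSD", call. = FALSE)
  lag <- curve$lag_s[ok]
  msd <- curve$msd_um2[ok]
  w <- if (weights == "inverse_variance") curve$n_obs[ok] else rep(1, sum(ok))
  ll <- stats::lm(log(msd) ~ log(lag), weights = w)
  start <- list(A = exp(stats::coef(ll)[[1]]), alpha = stats::coef(ll)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(msd ~ A * lag^alpha, start = start, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    A <- start$A; alpha <- start$alpha
    se <- summary(ll)$coefficients[, "Std. Error"]
    res <- sqrt(sum((msd - A * lag^alpha)^2))
    out <- list(k_alpha = A / (2 * n_dims), alpha = alpha,
                k_alpha_se = A * se[[1]] / (2 * n_dims), alpha_se = se[[2]],
                n_dims = as.integer(n_dims), resid_norm = res,
                fallback = TRUE)
  } else {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(NA_real_, NA_real_))
    out <- list(k_alpha = cf[["A"]] / (2 * n_dims), alpha = cf[["alpha"]],
                k_alpha_se = se[[1]] / (2 * n_dims), alpha_se = se[[2]],
                n_dims = as.integer(n_dims),
                resid_norm = sqrt(sum(stats::resid(fit)^2)),
                fallback = FALSE)
  }
  class(out) <- "diffusion_fit"
  out
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("Anomalous-diffusion fit (msd = 2*%d*K*t^a)\n", x$n_dims))
  cat(sprintf("  K_alpha = %.4g um^2/s^a (se %.2g)\n", x$k_alpha,
              x$k_alpha_se))
  cat(sprintf("  alpha   = %.4g (se %.2g)%s\n", x$alpha, x$alpha_se,
              if (isTRUE(x$fallback)) "  [log-log fallback]" else ""))
  invisible(x)
}
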