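test_that("linking rejects invalid max_disp and recovers separated tracks", {
  expect_error(link(tibble::tibble(frame = 0L, x_um = 0, y_um = 0),
                    max_disp = 0), "max_disp")
  # two objects always far apart: exact recovery
  det <- tibble::tibble(
    frame = rep(0:4, each = 2),
    x_um = rep(c(0, 10), 5) + rep(0.1 * (0:4), each = 2),
    y_um = rep(c(0, 0), 5))
  trajs <- link(det, max_disp = 1, min_len = 2)
  expect_length(trajs, 2)
  expect_equal(sort(vapply(trajs, nrow, integer(1))), c(5L, 5L))
  expect_equal(trajs[[1]]$x_um, 0.1 * (0:4))
})

test_that("a missed detection splits a track when gap closing is off", {
  det <- tibble::tibble(frame = c(0L, 1L, 3L, 4L),
                        x_um = c(0, 0.1, 0.3, 0.4), y_um = 0)
  trajs <- link(det, max_disp = 1, min_len = 2)
  expect_length(trajs, 2)
})

test_that("greedy linking is near-optimal and exact for wide spacing", {
  set.seed(31)
  max_disp <- 1
  for (rep in 1:20) {
    n <- sample(3:5, 1)
    # spacing > 2 * max_disp: greedy must equal the optimal assignment
    repeat {
      p1 <- cbind(stats::runif(n, 0, 30), stats::runif(n, 0, 30))
      if (n == 1 || min(stats::dist(p1)) > 2 * max_disp + 0.5) break
    }
    p2 <- p1 + matrix(stats::rnorm(2 * n, 0, 0.25), n, 2)
    expect_identical(greedy_matching(p1, p2, max_disp), seq_len(n))
    expect_equal(greedy_assignment_cost(p1, p2, max_disp),
                 optimal_assignment_cost(p1, p2, max_disp))
  }
  # crowded fixtures: greedy cost within 1.2x of the enumerated optimum
  for (rep in 1:20) {
    n <- 5
    p1 <- cbind(stats::runif(n, 0, 4), stats::runif(n, 0, 4))
    p2 <- p1 + matrix(stats::rnorm(2 * n, 0, 0.4), n, 2)
    g <- greedy_assignment_cost(p1, p2, max_disp)
    o <- optimal_assignment_cost(p1, p2, max_disp)
    expect_lte(g, 1.2 * o + 1e-12)
  }
})

test_that("MSD closed forms: stationary, ballistic drift, 3-4-5", {
  still <- tibble::tibble(frame = 0:9, t_s = 0.3 * (0:9), x_um = 1, y_um = 2)
  expect_true(all(compute_msd(still, k_max = 5)$msd_um2 == 0))
  drift <- tibble::tibble(frame = 0:9, t_s = (0:9) * 1,
                          x_um = 1 * (0:9), y_um = 0)
  m <- compute_msd(drift, k_max = 5, dt_frame = 1)
  expect_equal(m$msd_um2, (1:5)^2)
  two <- tibble::tibble(frame = 0:1, t_s = c(0, 0.3),
                        x_um = c(0, 3), y_um = c(0, 4))
  expect_equal(compute_msd(two, k_max = 3)$msd_um2, 25)
})

test_that("compute_msd equals the brute-force pairwise oracle", {
  set.seed(5)
  trajs <- lapply(1:10, function(i) {
    n <- sample(5:40, 1)
    tibble::tibble(frame = 0:(n - 1), t_s = 0.3 * (0:(n - 1)),
                   x_um = cumsum(stats::rnorm(n)),
                   y_um = cumsum(stats::rnorm(n)))
  })
  got <- compute_msd(trajs, k_max = 12, dt_frame = 0.3)
  ref <- brute_msd(trajs, 12, 0.3)
  expect_equal(got$msd_um2, ref$msd, tolerance = 1e-13)
  expect_equal(got$lag_s, ref$lag_s)
  expect_equal(got$n_obs, ref$n_obs)
})

test_that("power-law fit is exact on noise-free curves", {
  lag <- 0.3 * (1:10)
  curve <- tibble::tibble(lag_s = lag, msd_um2 = 4 * 0.02 * lag^0.8,
                          n_obs = 100, n_traj = 10)
  fit <- fit_power_law(curve, n_dims = 2)
  expect_lt(abs(fit$k_alpha - 0.02), 1e-10)
  expect_lt(abs(fit$alpha - 0.8), 1e-10)
  # ballistic: msd = t^2 means alpha = 2 and k = 1/(2 n)
  curve2 <- tibble::tibble(lag_s = lag, msd_um2 = lag^2, n_obs = 100,
                           n_traj = 10)
  fit2 <- fit_power_law(curve2, n_dims = 2)
  expect_lt(abs(fit2$alpha - 2), 1e-10)
  expect_lt(abs(fit2$k_alpha - 0.25), 1e-10)
  expect_error(fit_power_law(curve[1:2, ]), ">= 3 lags")
})

test_that("fit estimates are unit-consistent under rescaling", {
  set.seed(8)
  trajs <- lapply(1:50, function(s) simulate_fbm_trajectory(
    trajectory_spec(0.02, 0.8, 100, seed = s)))
  um <- fit_power_law(compute_msd(trajs, k_max = 10, dt_frame = 0.3))
  nm_trajs <- lapply(trajs, function(tr) {
    tr$x_um <- tr$x_um * 1e3; tr$y_um <- tr$y_um * 1e3; tr
  })
  nm <- fit_power_law(compute_msd(nm_trajs, k_max = 10, dt_frame = 0.3))
  expect_equal(nm$alpha, um$alpha, tolerance = 1e-8)
  expect_equal(nm$k_alpha / um$k_alpha, 1e6, tolerance = 1e-6)
})

test_that("alpha recovery improves with trajectory count", {
  rmse_at <- function(n_traj) {
    errs <- vapply(1:24, function(s) {
      trajs <- lapply(1:n_traj, function(j) simulate_fbm_trajectory(
        trajectory_spec(0.02, 0.8, 100,
                        seed = split_seed(1000 * s + n_traj, j))))
      fit <- fit_power_law(compute_msd(trajs, k_max = 10, dt_frame = 0.3))
      fit$alpha - 0.8
    }, numeric(1))
    sqrt(mean(errs^2))
  }
  e <- c(rmse_at(20), rmse_at(50), rmse_at(200))
  expect_true(all(diff(e) < 0))
})
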