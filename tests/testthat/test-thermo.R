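test_that("Gaussian differential entropy evaluates in closed form", {
  expect_equal(gaussian_entropy(1 / (2 * pi * exp(1))), 0)
  expect_equal(gaussian_entropy(1), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_entropy(4) - gaussian_entropy(1), 0.5 * log(4))
  expect_error(gaussian_entropy(0), "sigma2")
})

test_that("particle entropy evaluates and is logarithmic in the lag", {
  expect_equal(particle_entropy(1, 1, 1), 0.25 * log(4 * pi * exp(1)))
  expect_equal(round(particle_entropy(1, 1, 1), 5), 0.88276)
  expect_equal(round(particle_entropy(1, 1, 3), 5), 1.15741)
  # S(k, a, dt) - S(k, a, 1) = (a/4) ln dt for any inputs
  for (k in c(0.01, 1)) for (a in c(0.5, 1.3)) for (dt in c(0.3, 3, 10)) {
    expect_equal(particle_entropy(k, a, dt) - particle_entropy(k, a, 1),
                 a / 4 * log(dt))
  }
  expect_error(particle_entropy(-1, 1, 1), "k_alpha")
  expect_error(particle_entropy(1, 1, 0), "dt")
})

test_that("total energy evaluates and ties to entropy via S = 1/4 + ln(E)/4", {
  expect_equal(total_energy(1, 1, 1), 4 * pi)
  expect_equal(total_energy(1 / (4 * pi), 0.7, 1), 1)
  # identity on a 5 x 5 x 3 grid, machine precision
  for (k in c(0.001, 0.01, 0.1, 1, 10)) {
    for (a in c(0.2, 0.6, 1.0, 1.4, 1.8)) {
      for (dt in c(0.3, 1, 3)) {
        expect_lt(abs(particle_entropy(k, a, dt) -
                        (0.25 + 0.25 * log(total_energy(k, a, dt)))), 1e-12)
      }
    }
  }
})

test_that("entropy is monotone in its arguments", {
  ks <- exp(seq(log(1e-3), log(10), length.out = 30))
  expect_true(all(diff(particle_entropy(ks, 0.8, 3)) > 0))
  as <- seq(0.1, 2, length.out = 30)
  expect_true(all(diff(particle_entropy(0.02, as, 3)) > 0))   # dt > 1
  dts <- seq(0.5, 10, length.out = 50)
  s_dt <- particle_entropy(0.02, 0.8, dts)
  expect_true(all(diff(s_dt) > 0))
  expect_true(all(diff(diff(s_dt)) < 0))  # concave, saturating in the lag
})

test_that("constant-energy curves are level sets of the energy", {
  expect_equal(constant_energy_curve(4 * pi, 3, 0), 1)
  expect_equal(constant_energy_curve(4 * pi, 3, 1), 1 / 3)
  alphas <- seq(0.1, 1.9, by = 0.2)
  ks <- constant_energy_curve(2.5, 3, alphas)
  expect_true(all(diff(ks) < 0))
  expect_true(all(abs(total_energy(ks, alphas, 3) - 2.5) < 1e-12))
  # numerical slope at alpha = 1 matches -E dt^-a ln(dt) / (4 pi)
  h <- 1e-7
  num <- (constant_energy_curve(4 * pi, 3, 1 + h) -
            constant_energy_curve(4 * pi, 3, 1 - h)) / (2 * h)
  expect_lt(abs(num - (-4 * pi * 3^-1 * log(3) / (4 * pi))), 1e-6)
  expect_warning(constant_energy_curve(1, 1, c(0.5, 1)), "constant")
})

test_that("elasticity regression recovers exact power-law data", {
  k <- c(0.3, 0.7, 1.5, 3, 6)
  a <- 0.53 * k^-0.46
  reg <- fit_elastic_regression(k, a)
  expect_lt(abs(reg$a - 0.53), 1e-10)
  expect_lt(abs(reg$b - -0.46), 1e-10)
  flat <- fit_elastic_regression(k, rep(0.8, 5))
  expect_equal(flat$b, 0)
  expect_error(fit_elastic_regression(k[1:2], a[1:2]), ">= 3")
  expect_error(fit_elastic_regression(-k, a), "k_alpha")
})

test_that("alpha decomposition follows the elasticity regression", {
  reg <- elastic_regression(0.53, -0.46)
  dec <- decompose_alpha(list(k_alpha = 1, alpha = 1.0), reg)
  expect_equal(dec$alpha_e, 0.53)
  expect_equal(dec$alpha_work, 0.47)
  expect_false(dec$negative_work)
  neg <- decompose_alpha(list(k_alpha = 0.01, alpha = 0.5), reg)
  expect_true(neg$negative_work)   # flagged, not clipped
  expect_lt(neg$alpha_work, 0)
})

test_that("depleted cells decomposed with their own regression have ~zero work", {
  p <- generate_cohort(cohort_spec(seed = 17), "parameters")$params
  dep <- p[p$condition == "depleted", ]
  reg <- fit_elastic_regression(dep$k_alpha, dep$alpha)
  dec <- decompose_alpha(list(k_alpha = dep$k_alpha, alpha = dep$alpha), reg)
  expect_lt(abs(mean(dec$alpha_work)), stats::sd(dec$alpha_work))
})

test_that("entropy splits exactly into elasticity and work terms", {
  for (k in c(0.005, 0.1, 2)) for (ae in c(0.3, 0.6)) {
    for (aw in c(0, 0.2, 0.5)) for (dt in c(1.5, 3, 10)) {
      terms <- entropy_decomposition(k, ae, aw, dt)
      expect_equal(terms$elastic_term + terms$work_term,
                   particle_entropy(k, ae + aw, dt), tolerance = 1e-12)
    }
  }
  # no work: the work term vanishes and the total is the equilibrium entropy
  t0 <- entropy_decomposition(0.02, 0.6, 0, 3)
  expect_equal(t0$work_term, 0)
  expect_equal(t0$elastic_term, particle_entropy(0.02, 0.6, 3))
  # the work term grows with alpha_work at dt > 1
  w <- sapply(c(0.1, 0.3, 0.5), function(aw) {
    entropy_decomposition(0.02, 0.6, aw, 3)$work_term
  })
  expect_true(all(diff(w) > 0))
})

test_that("programmed active cohorts carry higher entropy than depleted", {
  hit <- vapply(1:40, function(s) {
    p <- generate_cohort(cohort_spec(seed = s), "parameters")$params
    s_arm <- tapply(particle_entropy(p$k_alpha, p$alpha, 3), p$condition,
                    mean)
    s_arm["active"] > s_arm["depleted"]
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
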