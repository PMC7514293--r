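# Paired-design statistics of the active vs ATP-depleted comparison:
# paired t-tests on the diffusion parameters and entropy, per-arm power-law
# regressions, the depleted-arm elasticity regression feeding the
# alpha_work decomposition of active cells, and the homogeneity (CV)
# correlation analyses, assembled into one report.

#' Paired two-sample comparison
#'
#' Two-sided paired Student's t-test on the per-cell differences
#' `post - pre`. Identical arms (zero-variance differences) are flagged as
#' degenerate rather than producing a spurious statistic.
#'
#' @param pre,post numeric vectors of equal length (>= 3), matched by cell.
#' @return list: `statistic`, `df`, `p_value`, `mean_diff`, `degenerate`.
#' @export
paired_compare <- function(pre, post) {
  if (length(pre) != length(post)) {
    stop("`pre` and `post` must have equal length", call. = FALSE)
  }
  if (length(pre) < 3) stop("need >= 3 pairs", call. = FALSE)
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, df = length(d) - 1L,
                p_value = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(d), degenerate = FALSE)
}

#' Power-law (log-log) regression between two positive quantities
#'
#' Least squares of `log(y) ~ log(x)`, reported as `y = a * x^b` with the
#' two-sided p-value for the slope. The form used for every correlation
#' panel of the cohort analysis (alpha ~ K_alpha, CV ~ K_alpha,
#' CV ~ alpha_work, CV ~ entropy).
#'
#' @param x,y positive numeric vectors (n >= 3 after exclusions).
#' @param drop_nonpositive drop pairs with a nonpositive `x` or `y` (with a
#'   message) instead of erroring; used for `CV ~ alpha_work`, where cells
#'   below the equilibrium curve have `alpha_work <= 0` and no defined log.
#' @return list: `a`, `b`, `p_value`, `n`, `n_excluded`, `r_squared`.
#' @export
regress_power <- function(x, y, drop_nonpositive = FALSE) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  n_exc <- sum(!ok)
  if (n_exc > 0) {
    if (!drop_nonpositive) {
      stop("x and y must be positive; set drop_nonpositive = TRUE to ",
           "exclude offending pairs", call. = FALSE)
    }
    message(sprintf("regress_power: excluded %d pair(s) with nonpositive ",
                    n_exc), "values")
  }
  if (sum(ok) < 3) stop("need >= 3 positive pairs", call. = FALSE)
  fit <- stats::lm(log(y[ok]) ~ log(x[ok]))
  sm <- quiet_lm_summary(fit)
  cf <- sm$coefficients
  list(a = exp(cf[1, 1]), b = cf[2, 1], p_value = cf[2, 4],
       n = sum(ok), n_excluded = n_exc,
       r_squared = sm$r.squared)
}

#' Exponential (semi-log) regression of a positive quantity on a covariate
#'
#' Least squares of `log(y) ~ x`, reported as `y = a * exp(b * x)`. Used for
#' the CV ~ entropy panels: entropy is itself logarithmic in energy
#' (`S = 1/4 + ln(E)/4`), so an exponential fit of CV on entropy is the
#' power-law fit of CV on energy, and it remains defined when the
#' (unit-convention-dependent) entropy values are negative.
#'
#' @param x numeric covariate.
#' @param y positive response.
#' @return list: `a`, `b`, `p_value`, `n`, `r_squared`.
#' @export
regress_exp <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(x) & is.finite(y) & y > 0
  if (sum(ok) < 3) stop("need >= 3 pairs with positive y", call. = FALSE)
  fit <- stats::lm(log(y[ok]) ~ x[ok])
  sm <- quiet_lm_summary(fit)
  cf <- sm$coefficients
  list(a = exp(cf[1, 1]), b = cf[2, 1], p_value = cf[2, 4], n = sum(ok),
       r_squared = sm$r.squared)
}

#' Full paired cohort analysis
#'
#' The study workflow over per-cell records: fit the elasticity regression
#' on the depleted (equilibrium) arm; decompose every cell's diffusion power
#' into `alpha_e + alpha_work` with it; evaluate entropy and energy at
#' `dt_eval`; run the paired tests (alpha, K_alpha, entropy) and the per-arm
#' power-law regressions (alpha ~ K, CV ~ K, CV ~ alpha, CV ~ alpha_work in
#' the active arm, CV ~ entropy); and report the qualitative expectations of
#' the active/depleted comparison as booleans.
#'
#' Unpaired cells are excluded from the paired tests (with a message) but
#' still enter their arm's regressions. If only one arm is present the
#' paired tests are degenerate (`NA`) and per-arm regressions are still
#' produced.
#'
#' @param records tibble with `cell_id`, `condition`
#'   (`"active"`/`"depleted"`), `k_alpha`, `alpha`, and optionally `cv`.
#' @param dt_eval entropy/energy evaluation lag, s (default 3).
#' @param alpha_level significance threshold (default 0.05).
#' @param p_adjust apply Benjamini-Hochberg across the regression p-values
#'   (off by default; the primary analysis reports unadjusted p-values).
#' @return list of class `cohort_report`: `cells` (augmented per-cell
#'   table), `elastic_regression`, `paired` (tests for alpha, k_alpha,
#'   entropy), `regressions` (named list of [regress_power()] results),
#'   `directions` (named logical vector of qualitative expectations),
#'   `n_pairs`.
#' @export
run_cohort_analysis <- function(records, dt_eval = 3, alpha_level = 0.05,
                                p_adjust = FALSE) {
  stopifnot(all(c("cell_id", "condition", "k_alpha", "alpha") %in%
                  names(records)))
  records <- records[records$condition %in% c("active", "depleted"), ]
  act <- records[records$condition == "active", ]
  dep <- records[records$condition == "depleted", ]
  has_cv <- "cv" %in% names(records)

  reg_el <- if (nrow(dep) >= 3) {
    fit_elastic_regression(dep$k_alpha, dep$alpha)
  } else NULL

  aug <- records
  aug$entropy_nats <- particle_entropy(aug$k_alpha, aug$alpha, dt_eval)
  aug$energy_au <- total_energy(aug$k_alpha, aug$alpha, dt_eval)
  if (!is.null(reg_el)) {
    dec <- decompose_alpha(list(k_alpha = aug$k_alpha, alpha = aug$alpha),
                           reg_el)
    aug$alpha_e <- dec$alpha_e
    aug$alpha_work <- dec$alpha_work
  } else {
    aug$alpha_e <- NA_real_
    aug$alpha_work <- NA_real_
  }

  # paired tests over cells present in both arms
  both <- intersect(act$cell_id, dep$cell_id)
  n_unpaired <- length(setdiff(union(act$cell_id, dep$cell_id), both))
  if (n_unpaired > 0) {
    message(sprintf("excluding %d unpaired cell(s) from paired tests",
                    n_unpaired))
  }
  degenerate_pair <- list(statistic = NA_real_, df = NA_integer_,
                          p_value = NA_real_, mean_diff = NA_real_,
                          degenerate = TRUE)
  if (length(both) >= 3) {
    a2 <- aug[aug$condition == "active", ]
    d2 <- aug[aug$condition == "depleted", ]
    a2 <- a2[match(both, a2$cell_id), ]
    d2 <- d2[match(both, d2$cell_id), ]
    paired <- list(
      alpha = paired_compare(d2$alpha, a2$alpha),
      k_alpha = paired_compare(d2$k_alpha, a2$k_alpha),
      entropy = paired_compare(d2$entropy_nats, a2$entropy_nats)
    )
  } else if (nrow(act) == 0 || nrow(dep) == 0) {
    paired <- list(alpha = degenerate_pair, k_alpha = degenerate_pair,
                   entropy = degenerate_pair)
  } else {
    stop("need >= 3 paired cells for the paired analysis", call. = FALSE)
  }

  safe_reg <- function(x, y, drop = FALSE) {
    tryCatch(regress_power(x, y, drop_nonpositive = drop),
             error = function(e) NULL)
  }
  aug_act <- aug[aug$condition == "active", ]
  aug_dep <- aug[aug$condition == "depleted", ]
  regs <- list(
    alpha_vs_k_depleted = safe_reg(aug_dep$k_alpha, aug_dep$alpha),
    alpha_vs_k_active = safe_reg(aug_act$k_alpha, aug_act$alpha)
  )
  if (has_cv) {
    regs$cv_vs_k_active <- safe_reg(aug_act$k_alpha, aug_act$cv)
    regs$cv_vs_k_depleted <- safe_reg(aug_dep$k_alpha, aug_dep$cv)
    regs$cv_vs_alpha_active <- safe_reg(aug_act$alpha, aug_act$cv)
    regs$cv_vs_alpha_depleted <- safe_reg(aug_dep$alpha, aug_dep$cv)
    regs$cv_vs_alpha_work_active <-
      safe_reg(aug_act$alpha_work, aug_act$cv, drop = TRUE)
    safe_exp <- function(x, y) {
      tryCatch(regress_exp(x, y), error = function(e) NULL)
    }
    regs$cv_vs_entropy_active <- safe_exp(aug_act$entropy_nats, aug_act$cv)
    regs$cv_vs_entropy_depleted <- safe_exp(aug_dep$entropy_nats,
                                            aug_dep$cv)
  }
  if (p_adjust) {
    ps <- vapply(regs, function(r) if (is.null(r)) NA_real_ else r$p_value,
                 numeric(1))
    adj <- stats::p.adjust(ps, method = "BH")
    for (i in seq_along(regs)) {
      if (!is.null(regs[[i]])) regs[[i]]$p_adjusted <- adj[[i]]
    }
  }

  neg_sig <- function(r) !is.null(r) && r$b < 0 && r$p_value <= alpha_level
  directions <- c(
    k_active_gt_depleted = nrow(act) > 0 && nrow(dep) > 0 &&
      mean(aug_act$k_alpha) > mean(aug_dep$k_alpha),
    alpha_active_gt_depleted = nrow(act) > 0 && nrow(dep) > 0 &&
      mean(aug_act$alpha) > mean(aug_dep$alpha),
    entropy_active_gt_depleted = nrow(act) > 0 && nrow(dep) > 0 &&
      mean(aug_act$entropy_nats) > mean(aug_dep$entropy_nats),
    alpha_k_negative_depleted = !is.null(regs$alpha_vs_k_depleted) &&
      regs$alpha_vs_k_depleted$b < 0,
    cv_k_negative_active = neg_sig(regs$cv_vs_k_active),
    cv_alpha_work_negative_active = neg_sig(regs$cv_vs_alpha_work_active),
    cv_entropy_negative_active = neg_sig(regs$cv_vs_entropy_active)
  )

  structure(list(cells = aug, elastic_regression = reg_el, paired = paired,
                 regressions = regs, directions = directions,
                 n_pairs = length(both), dt_eval = dt_eval,
                 alpha_level = alpha_level),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Paired cohort analysis (%d paired cells, dt_eval = %g s)\n",
              x$n_pairs, x$dt_eval))
  if (!is.null(x$elastic_regression)) {
    cat(sprintf("  elasticity regression (depleted arm): alpha_e = %.3g * K^%.3g (p = %.3g)\n",
                x$elastic_regression$a, x$elastic_regression$b,
                x$elastic_regression$p_value))
  }
  for (nm in names(x$paired)) {
    p <- x$paired[[nm]]
    if (isTRUE(p$degenerate)) {
      cat(sprintf("  paired %-8s: degenerate\n", nm))
    } else {
      cat(sprintf("  paired %-8s: t = %.3g, p = %.3g, mean diff = %.3g\n",
                  nm, p$statistic, p$p_value, p$mean_diff))
    }
  }
  for (nm in names(x$regressions)) {
    r <- x$regressions[[nm]]
    if (is.null(r)) next
    cat(sprintf("  %-26s b = %.3g, p = %.3g (n = %d)\n", nm, r$b,
                r$p_value, r$n))
  }
  cat("  qualitative directions:\n")
  for (nm in names(x$directions)) {
    cat(sprintf("    %-32s %s\n", nm, x$directions[[nm]]))
  }
  invisible(x)
}
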