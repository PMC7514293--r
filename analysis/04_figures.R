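#!/usr/bin/env Rscript
# Step 4 — figures mirroring the study's panel structure:
# per-cell MSD curves, paired alpha/K/entropy dot plots, the depleted-arm
# alpha~K scatter with constant-energy level sets, and the active-arm CV
# couplings. PDFs under results/figures/.

library(diffent)
library(ggplot2)

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
cells <- utils::read.csv("results/cohort_cells.csv")
traj <- utils::read.csv("results/trajectories.csv")

theme_set(theme_bw(base_size = 10))

# MSD curves per condition (pooled over cells)
msd_tab <- do.call(rbind, lapply(split(traj, traj$condition), function(d) {
  trajs <- lapply(split(d, interaction(d$cell_id, d$particle_id)),
                  function(tr) tibble::tibble(frame = tr$frame, t_s = tr$t_s,
                                              x_um = tr$x_um, y_um = tr$y_um))
  curve <- compute_msd(trajs, k_max = 10, dt_frame = 0.3)
  data.frame(condition = d$condition[1], lag_s = curve$lag_s,
             msd_um2 = curve$msd_um2)
}))
ggsave("results/figures/msd_curves.pdf", width = 4.5, height = 3.2,
  plot = ggplot(msd_tab, aes(lag_s, msd_um2, color = condition)) +
    geom_point() + geom_line() + scale_x_log10() + scale_y_log10() +
    labs(x = "time lag (s)", y = expression(MSD~(mu*m^2))))

# paired per-cell values
long <- do.call(rbind, lapply(c("alpha", "k_alpha", "entropy_nats"),
  function(v) data.frame(cell_id = cells$cell_id,
                         condition = cells$condition,
                         quantity = v, value = cells[[v]])))
ggsave("results/figures/paired_values.pdf", width = 6.5, height = 2.8,
  plot = ggplot(long, aes(condition, value, group = cell_id)) +
    geom_line(alpha = 0.4) + geom_point(aes(color = condition), size = 1.5) +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = NULL, y = NULL))

# depleted-arm alpha ~ K with constant-energy level sets
dep <- cells[cells$condition == "depleted", ]
alpha_grid <- seq(min(dep$alpha) * 0.8, max(dep$alpha) * 1.2,
                  length.out = 60)
levels_E <- stats::quantile(total_energy(dep$k_alpha, dep$alpha, 3),
                            c(0.25, 0.5, 0.75))
iso <- do.call(rbind, lapply(levels_E, function(E) {
  data.frame(E = sprintf("E = %.2g", E), alpha = alpha_grid,
             k_alpha = constant_energy_curve(E, 3, alpha_grid))
}))
ggsave("results/figures/alpha_vs_k_depleted.pdf", width = 4.5, height = 3.2,
  plot = ggplot(dep, aes(k_alpha, alpha)) +
    geom_line(data = iso, aes(group = E), linetype = 2, color = "grey55") +
    geom_point(color = "#00798c") + scale_x_log10() +
    labs(x = expression(K[alpha]~(mu*m^2/s^alpha)), y = expression(alpha)))

# active-arm CV couplings
act <- cells[cells$condition == "active", ]
cv_long <- rbind(
  data.frame(x = act$k_alpha, cv = act$cv, panel = "CV ~ K_alpha"),
  data.frame(x = act$alpha_work, cv = act$cv, panel = "CV ~ alpha_work"),
  data.frame(x = act$entropy_nats, cv = act$cv, panel = "CV ~ entropy"))
ggsave("results/figures/cv_couplings_active.pdf", width = 6.5, height = 2.6,
  plot = ggplot(cv_long, aes(x, cv)) + geom_point(color = "#d1495b") +
    geom_smooth(method = "lm", se = FALSE, linewidth = 0.4,
                color = "grey40") +
    facet_wrap(~panel, scales = "free_x") + labs(x = NULL, y = "CV"))

cat("wrote 4 figures under results/figures/\n")
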