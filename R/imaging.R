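# Segmentation of image stacks into per-frame object detections, following
# the classic DIC-tracking recipe: rescale to 8-bit, threshold by a gray-level
# band chosen from the histogram (or Otsu), label 8-connected components,
# and take unweighted component centroids. Pixel centers sit at integer
# coordinates with the origin at top-left; x = column * pixel_size, so all
# downstream geometry is in micrometres.

#' Convert an image stack to 8-bit
#'
#' Linear min-max rescale of the whole stack onto \[0, 255\], rounded to
#' integers with round-half-to-even. A constant stack has no dynamic range
#' and maps to all zeros.
#'
#' @param stack an [image_stack()].
#' @return the stack with integer-valued frames in \[0, 255\] and
#'   `bit_depth = 8`.
#' @export
to_8bit <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  f <- stack$frames
  rng <- range(f)
  if (rng[1] == rng[2]) {
    f[] <- 0
  } else {
    f <- round((f - rng[1]) / (rng[2] - rng[1]) * 255)
  }
  stack$frames <- f
  stack$bit_depth <- 8L
  stack
}

# Otsu threshold on an 8-bit histogram: gray level t maximizing between-class
# variance; foreground/background split is {<= t} vs {> t}.
otsu_threshold <- function(values) {
  h <- tabulate(as.integer(values) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

# Two-pass 8-connected component labeling with union-find.
# Returns an integer matrix of labels (0 = background), labels 1..n compact,
# numbered in raster order of first pixel.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (!mask[r, c]) next
      nb <- integer(0)
      if (r > 1) {
        if (c > 1 && lab[r - 1, c - 1] > 0) nb <- c(nb, lab[r - 1, c - 1])
        if (lab[r - 1, c] > 0) nb <- c(nb, lab[r - 1, c])
        if (c < w && lab[r - 1, c + 1] > 0) nb <- c(nb, lab[r - 1, c + 1])
      }
      if (c > 1 && lab[r, c - 1] > 0) nb <- c(nb, lab[r, c - 1])
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, c] <- nxt
      } else {
        roots <- vapply(unique(nb), find, integer(1))
        keep <- min(roots)
        lab[r, c] <- keep
        for (rt in roots) parent[rt] <- keep
      }
    }
  }
  if (nxt == 0L) return(lab)
  root <- vapply(seq_len(nxt), find, integer(1))
  pos <- which(lab > 0)
  lab[pos] <- root[lab[pos]]
  # compact labels in raster (row-major) order of first occurrence
  rm_labels <- as.vector(t(lab))
  uq <- unique(rm_labels[rm_labels > 0])
  remap <- integer(nxt)
  remap[uq] <- seq_along(uq)
  lab[pos] <- remap[lab[pos]]
  lab
}

#' Threshold and segment an image stack into detections
#'
#' Pixels whose gray level falls inside `band` (inclusive) are foreground;
#' 8-connected components smaller than `min_area` pixels are discarded as
#' fragmentation debris. `band = "otsu"` picks the Otsu cut on the pooled
#' 8-bit histogram and takes the minority side as foreground (objects are
#' sparse). A band covering more than half of all pixels triggers a warning:
#' over-wide bands thicken contours and merge neighboring objects.
#'
#' @param stack an 8-bit [image_stack()] (see [to_8bit()]).
#' @param band numeric `c(lo, hi)` gray-level interval, or `"otsu"`.
#' @param min_area minimum component area in pixels (default 4).
#' @return list with `binary` (logical array, same dim as frames) and
#'   `detections`, a tibble with one row per component: `frame`, `x_um`,
#'   `y_um`, `area_px`, `area_um2`, `eq_diam_um`.
#' @export
threshold_segment <- function(stack, band = "otsu", min_area = 4L) {
  stopifnot(inherits(stack, "image_stack"))
  f <- stack$frames
  if (identical(band, "otsu")) {
    t0 <- otsu_threshold(f)
    lower <- sum(f <= t0) <= sum(f > t0)
    band <- if (lower) c(0, t0) else c(t0 + 1L, 255)
  }
  if (length(band) != 2 || band[2] < band[1]) {
    stop("`band` must be c(lo, hi) with hi >= lo, or \"otsu\"", call. = FALSE)
  }
  sel <- f >= band[1] & f <= band[2]
  if (mean(sel) > 0.5) {
    warning("band selects more than 50% of pixels; expect contour ",
            "thickening and object unification", call. = FALSE)
  }
  px <- stack$pixel_size
  n_frames <- dim(f)[1]
  dets <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    lab <- label_components(matrix(sel[fr, , ], dim(f)[2], dim(f)[3]))
    if (max(lab) == 0L) next
    idx <- which(lab > 0, arr.ind = TRUE)
    labs <- lab[lab > 0]
    area <- tabulate(labs)
    keep <- which(area >= min_area)
    if (length(keep) == 0) next
    cy <- vapply(keep, function(l) mean(idx[labs == l, 1]), numeric(1))
    cx <- vapply(keep, function(l) mean(idx[labs == l, 2]), numeric(1))
    dets[[fr]] <- tibble::tibble(
      frame = fr - 1L,
      x_um = cx * px, y_um = cy * px,
      area_px = area[keep],
      area_um2 = area[keep] * px^2,
      eq_diam_um = 2 * sqrt(area[keep] * px^2 / pi)
    )
  }
  dets <- dets[!vapply(dets, is.null, logical(1))]
  detections <- if (length(dets)) do.call(rbind, dets) else
    tibble::tibble(frame = integer(), x_um = numeric(), y_um = numeric(),
                   area_px = integer(), area_um2 = numeric(),
                   eq_diam_um = numeric())
  list(binary = sel, detections = detections)
}

#' Histogram of equivalent object diameters
#'
#' Equivalent diameter of a detection is `2 * sqrt(area / pi)` — the diameter
#' of the disk with the same area. Used to confirm that segmented objects
#' fall in the intracellular vesicle/organelle size range (0.1 to ~1 um).
#'
#' @param detections detection tibble from [threshold_segment()].
#' @param breaks histogram breaks in um (passed to [graphics::hist()] logic);
#'   default 0 to 2 um in 0.1 um bins.
#' @return tibble with `bin_lo`, `bin_hi`, `count`. Empty input yields zero
#'   counts, not an error.
#' @export
size_distribution <- function(detections,
                              breaks = seq(0, 2, by = 0.1)) {
  d <- detections$eq_diam_um
  d <- d[d >= min(breaks) & d <= max(breaks)]
  counts <- if (length(d)) {
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    h$counts
  } else rep(0L, length(breaks) - 1)
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = counts)
}

#' Sensitivity of the diffusion fit to the thresholding band
#'
#' Re-runs the full segment-link-MSD-fit chain for each candidate band and
#' reports the per-band diffusion parameters together with their spread —
#' the analysis used to show that moderate band changes perturb K_alpha and
#' alpha only within a reported envelope.
#'
#' @param stack an 8-bit [image_stack()].
#' @param bands list of `c(lo, hi)` gray-level bands (>= 2 unless a single
#'   band's zero spread is wanted).
#' @param max_disp,min_len,k_max,min_particles tracking/fit settings; bands
#'   yielding fewer than `min_particles` trajectories are flagged and
#'   excluded from the spread.
#' @param min_area passed to [threshold_segment()].
#' @return list with `table` (tibble: band limits, k_alpha, alpha, n_traj,
#'   excluded flag) and `sd` (named vector: SD of k_alpha and alpha over
#'   included bands; 0 for a single band).
#' @export
threshold_sensitivity <- function(stack, bands, max_disp = 1, min_len = 10,
                                  k_max = 10, min_particles = 1,
                                  min_area = 4L) {
  rows <- lapply(bands, function(b) {
    seg <- threshold_segment(stack, band = b, min_area = min_area)
    trajs <- link(seg$detections, max_disp = max_disp, min_len = min_len)
    if (length(trajs) < min_particles) {
      return(tibble::tibble(band_lo = b[1], band_hi = b[2],
                            k_alpha = NA_real_, alpha = NA_real_,
                            n_traj = length(trajs), excluded = TRUE))
    }
    fit <- fit_power_law(compute_msd(trajs, k_max = k_max,
                                     dt_frame = stack$dt_frame), n_dims = 2)
    tibble::tibble(band_lo = b[1], band_hi = b[2], k_alpha = fit$k_alpha,
                   alpha = fit$alpha, n_traj = length(trajs),
                   excluded = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$excluded
  sd_out <- c(
    k_alpha = if (sum(ok) > 1) stats::sd(tab$k_alpha[ok]) else 0,
    alpha   = if (sum(ok) > 1) stats::sd(tab$alpha[ok]) else 0
  )
  list(table = tab, sd = sd_out)
}
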