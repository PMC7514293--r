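# Synthetic fluorescence images of a phase-separating reporter: bright
# droplets (dense phase) inside a circular cell footprint, with the total
# fluorescence fixed so that demixing redistributes intensity rather than
# creating it. The droplet/dilute intensity ratio plays the role of the
# partition coefficient; partition_ratio = 1 is a fully mixed cell.

#' Specify a synthetic phase-separation (LLPS) image
#'
#' @param height,width image size in pixels.
#' @param n_droplets number of dense-phase droplets.
#' @param droplet_radius droplet radius in pixels.
#' @param partition_ratio droplet / dilute intensity ratio (>= 1);
#'   1 renders a homogeneous footprint.
#' @param total_intensity conserved sum of pixel intensities over the
#'   footprint (before noise).
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed for droplet placement and noise.
#' @return an object of class `llps_image_spec`.
#' @export
llps_image_spec <- function(height = 128, width = 128, n_droplets = 5,
                            droplet_radius = 6, partition_ratio = 2,
                            total_intensity = 1e6, noise_sd = 0,
                            seed = NULL) {
  if (partition_ratio < 1) stop("`partition_ratio` must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stop_if_not_positive(total_intensity, "total_intensity")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         n_droplets = as.integer(n_droplets), droplet_radius = droplet_radius,
         partition_ratio = partition_ratio, total_intensity = total_intensity,
         noise_sd = noise_sd, seed = seed),
    class = "llps_image_spec"
  )
}

#' Render a synthetic LLPS image and its cell-footprint mask
#'
#' Droplets are placed without overlap inside a circular footprint by
#' rejection sampling (error after bounded retries). Intensities are set so
#' that the footprint sum equals `total_intensity` for every
#' `partition_ratio` at fixed geometry: the dilute level is
#' `total / (A_footprint + (p - 1) * A_droplets)` and droplet pixels carry
#' `p` times that level.
#'
#' @param spec an [llps_image_spec()].
#' @return list with `image` (numeric matrix) and `mask` (logical matrix of
#'   the cell footprint).
#' @export
render_llps_image <- function(spec) {
  stopifnot(inherits(spec, "llps_image_spec"))
  h <- spec$height; w <- spec$width
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  R <- 0.45 * min(h, w)                       # footprint radius, px
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rr - cy)^2 + (cc - cx)^2 <= R^2

  r_d <- spec$droplet_radius
  if (spec$n_droplets > 0 && r_d >= R) {
    stop("droplet_radius must be smaller than the footprint radius",
         call. = FALSE)
  }
  centers <- with_seed(split_seed(spec$seed %||% 0L, 0L), {
    placed <- matrix(NA_real_, spec$n_droplets, 2)
    for (i in seq_len(spec$n_droplets)) {
      ok <- FALSE
      for (try in 1:2000) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * (R - r_d - 1)
        cand <- c(cy + rad * sin(ang), cx + rad * cos(ang))
        sep <- i == 1 || all(sqrt(rowSums((placed[seq_len(i - 1), ,
                drop = FALSE] - matrix(cand, i - 1, 2, byrow = TRUE))^2)) >
                2 * r_d + 1)
        if (sep) { placed[i, ] <- cand; ok <- TRUE; break }
      }
      if (!ok) stop("could not place droplets without overlap", call. = FALSE)
    }
    placed
  })

  droplet <- matrix(FALSE, h, w)
  for (i in seq_len(spec$n_droplets)) {
    droplet <- droplet |
      ((rr - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= r_d^2)
  }
  droplet <- droplet & mask

  a_foot <- sum(mask)
  a_drop <- sum(droplet)
  dilute <- spec$total_intensity /
    (a_foot + (spec$partition_ratio - 1) * a_drop)
  img <- matrix(0, h, w)
  img[mask] <- dilute
  img[droplet] <- dilute * spec$partition_ratio

  if (spec$noise_sd > 0) {
    img <- img + with_seed(split_seed(spec$seed %||% 0L, 1L),
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
  }
  list(image = img, mask = mask)
}
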