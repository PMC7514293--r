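# DIC-like synthetic image stacks: dark disks on a light background moving
# along simulated anomalous-diffusion trajectories, for exercising the
# thresholding/tracking chain against known ground truth.

#' Specify a synthetic image-stack simulation
#'
#' @param height,width frame size in pixels.
#' @param pixel_size um per pixel.
#' @param n_frames number of frames.
#' @param dt_frame frame interval, s.
#' @param objects list of objects, each a list with elements
#'   `spec` (a [trajectory_spec()] whose `n_steps`/`dt_frame` are overridden
#'   by the stack), `radius_um` (in \[0.05, 1\] um, the vesicle/organelle size
#'   range the tracking stage targets) and `contrast` (intensity drop of the
#'   dark disk below background).
#' @param background_level,noise_sd background intensity and additive
#'   Gaussian noise SD (intensity units); `noise_sd >= 0`.
#' @param seed master RNG seed; object sub-streams are derived with
#'   [split_seed()].
#' @return an object of class `stack_spec`.
#' @export
stack_spec <- function(height, width, pixel_size = 0.1, n_frames = 100,
                       dt_frame = 0.3, objects = list(),
                       background_level = 200, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  stop_if_not_positive(pixel_size, "pixel_size")
  stop_if_not_positive(dt_frame, "dt_frame")
  for (ob in objects) {
    if (ob$radius_um < 0.05 || ob$radius_um > 1.0) {
      stop("object radii must lie in [0.05, 1] um", call. = FALSE)
    }
  }
  structure(
    list(height = as.integer(height), width = as.integer(width),
         pixel_size = pixel_size, n_frames = as.integer(n_frames),
         dt_frame = dt_frame, objects = objects,
         background_level = background_level, noise_sd = noise_sd,
         seed = seed),
    class = "stack_spec"
  )
}

#' Construct an image stack container
#'
#' @param frames 3-D numeric array (frame, row, col).
#' @param dt_frame frame interval, s (> 0).
#' @param pixel_size um per pixel (> 0).
#' @param bit_depth nominal bit depth of the intensity scale.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, dt_frame, pixel_size, bit_depth = 16L) {
  stopifnot(length(dim(frames)) == 3)
  stop_if_not_positive(dt_frame, "dt_frame")
  stop_if_not_positive(pixel_size, "pixel_size")
  structure(
    list(frames = frames, dt_frame = dt_frame, pixel_size = pixel_size,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

# reflect coordinates into [lo, hi]
reflect_into <- function(x, lo, hi) {
  if (hi <= lo) return(rep((lo + hi) / 2, length(x)))
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Render a synthetic image stack with ground-truth trajectories
#'
#' Each object follows a simulated anomalous-diffusion trajectory (started at
#' a non-overlapping random position inside the frame) and is drawn as a dark
#' disk on the light background; additive Gaussian noise is applied last.
#' Trajectories are reflected at the frame margins so objects never leave the
#' field of view (reflections only occur if an excursion reaches the margin,
#' which the short observation window makes rare by design).
#'
#' @param spec a [stack_spec()].
#' @return a list with `stack` (an [image_stack()]) and `truth` (a tibble of
#'   ground-truth positions: `particle_id`, `frame`, `t_s`, `x_um`, `y_um`).
#' @export
render_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  W_um <- spec$width * spec$pixel_size
  H_um <- spec$height * spec$pixel_size
  n_obj <- length(spec$objects)
  frames <- array(spec$background_level,
                  dim = c(spec$n_frames, spec$height, spec$width))
  truth <- vector("list", n_obj)

  if (n_obj > 0) {
    # non-overlapping starting positions, margin one radius from the border
    starts <- with_seed(split_seed(spec$seed %||% 0L, 0L), {
      placed <- matrix(NA_real_, n_obj, 2)
      radii <- vapply(spec$objects, function(o) o$radius_um, numeric(1))
      for (i in seq_len(n_obj)) {
        for (try in 1:1000) {
          cand <- c(stats::runif(1, radii[i], W_um - radii[i]),
                    stats::runif(1, radii[i], H_um - radii[i]))
          ok <- i == 1 || all(sqrt(rowSums((placed[seq_len(i - 1), ,
                 drop = FALSE] - matrix(cand, i - 1, 2, byrow = TRUE))^2)) >
                 radii[i] + radii[seq_len(i - 1)])
          if (ok) { placed[i, ] <- cand; break }
        }
        if (anyNA(placed[i, ])) {
          stop("could not place objects without overlap", call. = FALSE)
        }
      }
      placed
    })

    for (i in seq_len(n_obj)) {
      ob <- spec$objects[[i]]
      tspec <- ob$spec
      tspec$n_steps <- spec$n_frames
      tspec$dt_frame <- spec$dt_frame
      tspec$n_dims <- 2L
      tspec$seed <- split_seed(spec$seed %||% 0L, i)
      tr <- simulate_fbm_trajectory(tspec)
      x <- reflect_into(starts[i, 1] + tr$x_um, ob$radius_um, W_um - ob$radius_um)
      y <- reflect_into(starts[i, 2] + tr$y_um, ob$radius_um, H_um - ob$radius_um)
      truth[[i]] <- tibble::tibble(
        particle_id = i, frame = tr$frame, t_s = tr$t_s, x_um = x, y_um = y)
      r_px <- ob$radius_um / spec$pixel_size
      for (f in seq_len(spec$n_frames)) {
        cx <- x[f] / spec$pixel_size        # x = column * pixel_size
        cy <- y[f] / spec$pixel_size
        cols <- max(1, floor(cx - r_px - 1)):min(spec$width, ceiling(cx + r_px + 1))
        rows <- max(1, floor(cy - r_px - 1)):min(spec$height, ceiling(cy + r_px + 1))
        dist2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
        inside <- dist2 <= r_px^2
        if (any(inside)) {
          sub <- frames[f, rows, cols]
          sub[inside] <- sub[inside] - ob$contrast
          frames[f, rows, cols] <- sub
        }
      }
    }
  }

  if (spec$noise_sd > 0) {
    frames <- frames + with_seed(split_seed(spec$seed %||% 0L, n_obj + 1L),
      array(stats::rnorm(length(frames), 0, spec$noise_sd), dim = dim(frames)))
  }
  list(
    stack = image_stack(frames, spec$dt_frame, spec$pixel_size),
    truth = if (n_obj > 0) do.call(rbind, truth) else
      tibble::tibble(particle_id = integer(), frame = integer(),
                     t_s = numeric(), x_um = numeric(), y_um = numeric())
  )
}
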