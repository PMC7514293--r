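# File interchange: multi-page grayscale TIFF stacks, trajectory CSV in the
# (cell_id, particle_id, frame, t_s, x_um, y_um) layout, and per-cell fit
# records as CSV.

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @param dt_frame frame interval, s.
#' @param pixel_size um per pixel.
#' @return an [image_stack()]; intensities are kept on their native integer
#'   scale (the tiff reader's \[0, 1\] floats are rescaled by 2^bit_depth - 1).
#' @export
read_stack_tiff <- function(path, dt_frame, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bps <- attr(pages[[1]], "bits.per.sample") %||% 16L
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]    # drop extra channels
    arr[i, , ] <- p * (2^bps - 1)
  }
  image_stack(arr, dt_frame = dt_frame, pixel_size = pixel_size,
              bit_depth = as.integer(bps))
}

#' Write an image stack as multi-page grayscale TIFF
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, bit_depth = stack$bit_depth) {
  mx <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(stack$frames)[1]), function(i) {
    m <- stack$frames[i, , ]
    pmin(pmax(m / mx, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}

#' Write trajectories to CSV
#'
#' Long format: `cell_id`, `particle_id`, `frame`, `t_s`, `x_um`, `y_um`.
#'
#' @param trajectories list of trajectory tibbles.
#' @param path output CSV path.
#' @param cell_id cell identifier stored with every row.
#' @return `path`, invisibly.
#' @export
write_trajectories_csv <- function(trajectories, path, cell_id = 1L) {
  rows <- lapply(seq_along(trajectories), function(i) {
    tr <- trajectories[[i]]
    pid <- if ("particle_id" %in% names(tr)) tr$particle_id else i
    data.frame(cell_id = cell_id, particle_id = pid, frame = tr$frame,
               t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read trajectories from CSV
#'
#' @param path CSV in the layout of [write_trajectories_csv()].
#' @return named list (by cell) of lists of trajectory tibbles.
#' @export
read_trajectories_csv <- function(path) {
  d <- utils::read.csv(path)
  lapply(split(d, d$cell_id), function(cell) {
    unname(lapply(split(cell, cell$particle_id), function(tr) {
      tr <- tr[order(tr$frame), ]
      tibble::tibble(particle_id = tr$particle_id[1], frame = tr$frame,
                     t_s = tr$t_s, x_um = tr$x_um, y_um = tr$y_um)
    }))
  })
}
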