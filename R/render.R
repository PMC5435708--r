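# Rendering simulated trajectories into 8-bit grayscale image stacks that
# emulate the video microscopy geometry: 2.75 px/um, cells drawn as filled
# anti-aliased ellipses with a constant 2-pixel apparent size broadening
# (the diffraction overestimate that detection later subtracts).

#' Render trajectories into a grayscale image stack
#'
#' Each cell is drawn on each frame as a filled ellipse (4x4 subpixel
#' coverage anti-aliasing) centred on its position, aligned with its
#' orientation, with semi-axes (length/2, width/2) scaled to pixels plus
#' one pixel of apparent broadening per semi-axis (2 pixels on the full
#' axis). Gaussian read noise rides on a constant background; frames are
#' clamped to 8-bit. Cells leaving the arena are clipped with a warning.
#'
#' @param trajectories list of [trajectory()] objects on a common frame grid.
#' @param cfg a [sim_config()]; `arena` sets the field of view.
#' @param pixel_scale pixels per um (default 2.75).
#' @param background background gray level (8-bit counts).
#' @param cell_intensity peak added intensity of a cell (8-bit counts).
#' @param noise_sd Gaussian noise sd (8-bit counts).
#' @param broadening_px apparent full-axis broadening in pixels.
#' @return a numeric array (rows y, columns x, frames) with values in
#'   0..255 and attributes `pixel_scale` and `background`.
#' @export
render_frames <- function(trajectories, cfg, pixel_scale = 2.75,
                          background = 10, cell_intensity = 120,
                          noise_sd = 2, broadening_px = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  npx <- max(8L, round(cfg$arena * pixel_scale))
  frames <- if (length(trajectories))
    sort(unique(unlist(lapply(trajectories, function(tr) tr$frame)))) else 0:0
  stack <- array(0, dim = c(npx, npx, length(frames)))
  clipped <- FALSE
  for (fi in seq_along(frames)) {
    img <- matrix(background, npx, npx)
    for (tr in trajectories) {
      row <- which(tr$frame == frames[fi])
      if (!length(row)) next
      a <- tr$length_um[row] / 2 * pixel_scale + broadening_px / 2
      b <- tr$width_um[row] / 2 * pixel_scale + broadening_px / 2
      cx <- tr$x_um[row] * pixel_scale
      cy <- tr$y_um[row] * pixel_scale
      th <- tr$orientation_rad[row]
      if (cx - a < 0 || cx + a > npx || cy - a < 0 || cy + a > npx)
        clipped <- TRUE
      cols <- max(1L, floor(cx - a)):min(npx, ceiling(cx + a))
      rows <- max(1L, floor(cy - a)):min(npx, ceiling(cy + a))
      if (!length(cols) || !length(rows)) next
      # 4x4 subpixel coverage of the rotated ellipse
      sub <- (1:4 - 0.5) / 4
      cov <- matrix(0, length(rows), length(cols))
      for (sy in sub) for (sx in sub) {
        px <- outer(rep(1, length(rows)), cols - 1 + sx)
        py <- outer(rows - 1 + sy, rep(1, length(cols)))
        dx <- px - cx; dy <- py - cy
        xr <- dx * cos(th) + dy * sin(th)
        yr <- -dx * sin(th) + dy * cos(th)
        cov <- cov + ((xr / a)^2 + (yr / b)^2 <= 1)
      }
      img[rows, cols] <- img[rows, cols] + cell_intensity * cov / 16
    }
    img <- img + stats::rnorm(npx * npx, 0, noise_sd)
    stack[, , fi] <- round(pmin(pmax(img, 0), 255))
  }
  if (clipped) warning("some cells extend beyond the arena and were clipped")
  attr(stack, "pixel_scale") <- pixel_scale
  attr(stack, "background") <- background
  attr(stack, "frames") <- frames
  stack
}

#' Write an image stack as a multi-page 8-bit TIFF
#'
#' @param stack array as returned by [render_frames()] (values 0..255).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a single- or multi-page TIFF into a stack array
#'
#' @param path TIFF file path.
#' @param pixel_scale pixels per um recorded on the returned stack.
#' @return numeric array (rows, columns, frames) scaled to 0..255.
#' @export
read_tiff_stack <- function(path, pixel_scale = 2.75) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]] * 255
  attr(stack, "pixel_scale") <- pixel_scale
  stack
}
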