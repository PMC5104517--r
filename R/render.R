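# Image-formation model: each nucleus is an isotropic Gaussian spot on a
# constant background; Poisson shot noise, additive Gaussian read noise,
# 16-bit clipping. Pixels are 0-based with y down; a point at x um sits at
# pixel coordinate x / pixel_size - 0.5 (pixel centres at (i + 0.5) * px).

#' Convert between micrometre and 0-based pixel-centre coordinates
#'
#' @param x_um,x_px Coordinates in um / 0-based pixels.
#' @param pixel_size_um Pixel size (um/px).
#' @return The converted coordinate vector.
#' @export
um_to_px <- function(x_um, pixel_size_um) x_um / pixel_size_um - 0.5

#' @rdname um_to_px
#' @export
px_to_um <- function(x_px, pixel_size_um) (x_px + 0.5) * pixel_size_um

# Add Gaussian spots to an image matrix (rows = y, cols = x).
.add_spots <- function(img, x_um, y_um, amp, ip) {
  px <- ip$pixel_size_um
  sd_px <- ip$spot_sd_um / px
  r <- ceiling(4 * sd_px)
  H <- nrow(img); W <- ncol(img)
  cx <- um_to_px(x_um, px); cy <- um_to_px(y_um, px)
  for (i in seq_along(cx)) {
    if (amp[i] <= 0) next
    xc <- round(cx[i]); yc <- round(cy[i])
    xs <- max(0, xc - r):min(W - 1, xc + r)
    ys <- max(0, yc - r):min(H - 1, yc + r)
    if (!length(xs) || !length(ys)) next
    gx <- exp(-(xs - cx[i])^2 / (2 * sd_px^2))
    gy <- exp(-(ys - cy[i])^2 / (2 * sd_px^2))
    img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + amp[i] * outer(gy, gx)
  }
  img
}

.apply_camera_noise <- function(img, ip) {
  if (isTRUE(ip$noise)) {
    v <- stats::rpois(length(img), lambda = as.vector(img))
    v <- v + stats::rnorm(length(v), 0, ip$read_noise_sd)
    img[] <- v
  }
  img[] <- pmin(pmax(round(img), 0), 65535)
  img
}

#' Render one multichannel frame of the monolayer
#'
#' Draws every cell inside the field of view as a Gaussian spot in three
#' channels: a constant-amplitude nuclear stain, mKO2-Cdt1 (red) scaled by
#' the cell's red level, and mAG-Geminin (green) scaled by its green level.
#' The field of view is anchored at (0, 0) in monolayer coordinates, so
#' after a stretch, cells displaced beyond the camera field leave the image.
#'
#' @param state An `sc_monolayer` state.
#' @param ip An [imaging_params()] object.
#' @return A numeric array `H x W x 3` with dimnames on the third margin
#'   `c("nuclear", "red", "green")`, values in 0..65535.
#' @export
render_frame <- function(state, ip = imaging_params()) {
  stopifnot(inherits(state, "sc_monolayer"))
  W <- round(ip$fov_um[1] / ip$pixel_size_um)
  H <- round(ip$fov_um[2] / ip$pixel_size_um)
  cells <- state$cells
  inview <- cells$x >= 0 & cells$x < ip$fov_um[1] &
    cells$y >= 0 & cells$y < ip$fov_um[2]
  cells <- cells[inview, , drop = FALSE]
  base <- matrix(ip$background, H, W)
  out <- array(0, dim = c(H, W, 3),
               dimnames = list(NULL, NULL, c("nuclear", "red", "green")))
  amps <- list(nuclear = rep(ip$nuclear_amp, nrow(cells)),
               red = ip$fluor_gain * cells$red,
               green = ip$fluor_gain * cells$green)
  for (ch in names(amps)) {
    img <- .add_spots(base, cells$x, cells$y, amps[[ch]], ip)
    out[, , ch] <- .apply_camera_noise(img, ip)
  }
  out
}

#' Render a two-channel marker snapshot (nuclear + generic marker)
#'
#' Emulates fixed-sample marker stains whose nuclear intensity is
#' proportional to the cell's current transcriptional activity, e.g. nuclear
#' beta-catenin or a transcriptional reporter: the marker spot amplitude is
#' `marker_gain * A_i` with the same image-formation model as
#' [render_frame()].
#'
#' @param state An `sc_monolayer` state.
#' @param marker_gain Peak counts per unit activity.
#' @param ip An [imaging_params()] object.
#' @return A numeric array `H x W x 2`, channels `c("nuclear", "marker")`.
#' @export
render_marker_snapshot <- function(state, marker_gain = 1000,
                                   ip = imaging_params()) {
  stopifnot(inherits(state, "sc_monolayer"))
  W <- round(ip$fov_um[1] / ip$pixel_size_um)
  H <- round(ip$fov_um[2] / ip$pixel_size_um)
  cells <- state$cells
  inview <- cells$x >= 0 & cells$x < ip$fov_um[1] &
    cells$y >= 0 & cells$y < ip$fov_um[2]
  cells <- cells[inview, , drop = FALSE]
  base <- matrix(ip$background, H, W)
  out <- array(0, dim = c(H, W, 2),
               dimnames = list(NULL, NULL, c("nuclear", "marker")))
  out[, , 1] <- .apply_camera_noise(
    .add_spots(base, cells$x, cells$y, rep(ip$nuclear_amp, nrow(cells)), ip), ip)
  out[, , 2] <- .apply_camera_noise(
    .add_spots(base, cells$x, cells$y, marker_gain * cells$activity, ip), ip)
  out
}
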