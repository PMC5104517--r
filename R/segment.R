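# Nuclear segmentation and per-nucleus quantification.
#
# The recipe is the canonical interpretation of a Hoechst-based routine:
# Gaussian smoothing -> rolling-ball background subtraction (grayscale
# opening) -> global Otsu threshold -> hole filling -> distance-transform
# watershed to split touching nuclei -> removal of small objects. All scale
# parameters are exposed through analysis_params().

# Separable truncated-Gaussian smoothing with replicated edges; matches an
# FFT Gaussian filter to machine precision away from the border and is much
# faster on frame sizes that are poor FFT lengths.
.gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  ri <- seq_len(n)
  for (j in seq_along(k)) {
    s <- j - r - 1L
    out <- out + k[j] * x[pmin(pmax(ri + s, 1L), n), , drop = FALSE]
  }
  out2 <- matrix(0, n, m)
  ci <- seq_len(m)
  for (j in seq_along(k)) {
    s <- j - r - 1L
    out2 <- out2 + k[j] * out[, pmin(pmax(ci + s, 1L), m), drop = FALSE]
  }
  out2
}

#' Segment nuclei from a nuclear-stain image
#'
#' @param img 2D numeric matrix (rows = y, cols = x), raw camera counts.
#' @param params An [analysis_params()] object.
#' @return A list with `labels` (integer matrix, 0 = background, objects
#'   1..N) and `records`, the [measure_nuclei()] table of the nuclear
#'   channel (`label`, `x_px`, `y_px`, `area_px2`, `mean_nuclear`).
#' @export
segment_nuclei <- function(img, params = analysis_params()) {
  if (length(dim(img)) != 2)
    stop("segment_nuclei expects a single 2D nuclear-channel image")
  x <- img / 65535
  sm <- .gauss_smooth(x, params$smooth_sigma_px)
  if (params$bg_radius_px > 0) {
    brush <- EBImage::makeBrush(2 * params$bg_radius_px + 1, shape = "disc")
    bg <- EBImage::opening(sm, brush)
    sub <- sm - bg
  } else sub <- sm
  rng <- range(sub)
  if (diff(rng) < 1e-9) {
    labels <- matrix(0L, nrow(img), ncol(img))
    return(list(labels = labels,
                records = measure_nuclei(labels, list(nuclear = img))))
  }
  thr <- EBImage::otsu(EBImage::Image(sub), range = rng)
  mask <- EBImage::fillHull(sub > thr)
  dm <- EBImage::distmap(mask)
  ws <- EBImage::watershed(dm, tolerance = params$ws_tolerance_px, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(ws)), nrow(img), ncol(img))
  ## drop small objects and relabel 1..N
  if (max(labels) > 0) {
    areas <- tabulate(labels, nbins = max(labels))
    keep <- which(areas >= params$min_area_px2)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0
    labels[pos] <- remap[labels[pos]]
  }
  list(labels = labels, records = measure_nuclei(labels, list(nuclear = img)))
}

#' Measure per-nucleus area, centroid and channel intensities
#'
#' Centroids are intensity-unweighted label centroids in 0-based pixel
#' coordinates (x rightward, y downward).
#'
#' @param labels Integer label matrix (0 = background).
#' @param channels Named list of channel image matrices, same dimensions as
#'   `labels`.
#' @return A data frame with one row per label: `label`, `x_px`, `y_px`,
#'   `area_px2`, and one `mean_<channel>` column per channel.
#' @export
measure_nuclei <- function(labels, channels) {
  if (!is.list(channels)) channels <- list(value = channels)
  for (ch in channels)
    if (!identical(dim(ch), dim(labels)))
      stop("channel dimensions must match the label image")
  nmax <- max(labels)
  out <- data.frame(label = seq_len(nmax))
  if (nmax == 0) {
    out <- data.frame(label = integer(0), x_px = numeric(0), y_px = numeric(0),
                      area_px2 = integer(0))
    for (nm in names(channels)) out[[paste0("mean_", nm)]] <- numeric(0)
    return(out)
  }
  lab <- as.vector(labels)
  inobj <- lab > 0
  lab <- lab[inobj]
  H <- nrow(labels)
  idx0 <- which(inobj) - 1L              # 0-based linear index, column-major
  col0 <- idx0 %/% H                     # x (0-based)
  row0 <- idx0 %% H                      # y (0-based)
  area <- tabulate(lab, nbins = nmax)
  sx <- rowsum(as.numeric(col0), lab)[, 1]
  sy <- rowsum(as.numeric(row0), lab)[, 1]
  out$x_px <- sx / area
  out$y_px <- sy / area
  out$area_px2 <- area
  for (nm in names(channels)) {
    v <- as.vector(channels[[nm]])[inobj]
    out[[paste0("mean_", nm)]] <- rowsum(v, lab)[, 1] / area
  }
  out
}

#' Whole-image cytoplasmic intensity by nuclear-pixel exclusion
#'
#' Dilates the nuclear mask by `dilation_px` and averages the channel over
#' the complement, emulating cytoplasmic quantification in which pixels
#' associated with nuclear objects are eliminated from analysis.
#'
#' @param labels Integer label matrix.
#' @param channel Channel image matrix.
#' @param dilation_px Dilation radius applied to the nuclear mask (px).
#' @return A list with `mean_intensity` and `n_pixels` (complement size).
#' @export
measure_cytoplasm <- function(labels, channel, dilation_px = 2) {
  if (!identical(dim(channel), dim(labels)))
    stop("channel dimensions must match the label image")
  stopifnot(dilation_px >= 0)
  mask <- labels > 0
  if (dilation_px > 0)
    mask <- EBImage::dilate(mask, EBImage::makeBrush(2 * dilation_px + 1,
                                                     shape = "disc")) > 0
  comp <- !mask
  if (!any(comp))
    stop("dilated nuclear mask covers the whole image: no cytoplasm left")
  list(mean_intensity = mean(channel[comp]), n_pixels = sum(comp))
}

#' Threshold-based positive/negative classification
#'
#' A record is positive when its mean intensity in `channel` exceeds
#' `threshold`. The threshold must be kept constant between compared
#' conditions.
#'
#' @param records A [measure_nuclei()] table.
#' @param channel Channel name (matching a `mean_<channel>` column).
#' @param threshold Intensity threshold.
#' @return A list with `positive` (logical per record) and
#'   `percent_positive`.
#' @export
classify_positive <- function(records, channel, threshold) {
  if (nrow(records) == 0)
    stop("no records: percent positive is undefined on an empty frame")
  col <- paste0("mean_", channel)
  if (!col %in% names(records)) stop("no such channel: ", channel)
  pos <- records[[col]] > threshold
  list(positive = pos, percent_positive = 100 * mean(pos))
}
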