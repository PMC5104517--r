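# Disk formats: 16-bit multi-page TIFF stacks with a YAML sidecar carrying
# the physical metadata (pixel size, frame interval, channel names, page
# order), plus plain-CSV ground truth and run-configuration logging.

#' Write a simulated time-lapse as a multi-page 16-bit TIFF
#'
#' Pages are ordered frame-major, channel within frame (frame 0 channel 1,
#' frame 0 channel 2, ...). A YAML sidecar `<path>.yml` records pixel size,
#' frame interval, channel names and page order.
#'
#' @param tl An `sc_timelapse` with `frames` kept, or a list of `H x W x C`
#'   arrays.
#' @param path Output TIFF path.
#' @param ip Imaging parameters (taken from `tl` when available).
#' @return `path`, invisibly.
#' @export
write_timelapse_tiff <- function(tl, path, ip = NULL) {
  frames <- if (inherits(tl, "sc_timelapse")) tl$frames else tl
  if (is.null(frames)) stop("no frames: simulate with keep_stack = TRUE")
  if (is.null(ip) && inherits(tl, "sc_timelapse")) ip <- tl$ip
  channels <- dimnames(frames[[1]])[[3]]
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(frames[[1]])[3]))
  pages <- list()
  for (fr in frames)
    for (c in seq_len(dim(fr)[3]))
      pages[[length(pages) + 1L]] <- fr[, , c] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(pixel_size_um = ip$pixel_size_um,
               frame_interval_min = ip$frame_interval_min,
               channels = as.list(channels),
               n_frames = length(frames),
               page_order = "frame_major_then_channel",
               bit_depth = 16)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' Read a time-lapse TIFF written by [write_timelapse_tiff()]
#'
#' @param path TIFF path; the sidecar `<path>.yml` must be present.
#' @return A list with `frames` (list of `H x W x C` arrays, counts in
#'   0..65535) and `meta` (the sidecar contents).
#' @export
read_timelapse_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(meta$channels)
  nt <- length(pages) / nc
  stopifnot(nt == round(nt))
  frames <- vector("list", nt)
  for (t in seq_len(nt)) {
    H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
    arr <- array(0, dim = c(H, W, nc),
                 dimnames = list(NULL, NULL, unlist(meta$channels)))
    for (c in seq_len(nc)) arr[, , c] <- pages[[(t - 1) * nc + c]] * 65535
    frames[[t]] <- arr
  }
  list(frames = frames, meta = meta)
}

#' Write simulation ground truth as CSV
#'
#' Produces `cells.csv` (frame, cell_id, x_um, y_um, phase, red, green) and
#' `events.csv` (time_h, type, parent_id, daughter1_id, daughter2_id; for
#' G1-to-S entries `parent_id` is the entering cell).
#'
#' @param tl An `sc_timelapse`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(tl, dir) {
  stopifnot(inherits(tl, "sc_timelapse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- tl$cells[, c("frame", "cell_id", "x_um", "y_um", "phase",
                        "red", "green")]
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  ev <- tl$events
  ev$parent_id <- ifelse(ev$type == "g1s_entry", ev$cell_id, ev$parent_id)
  utils::write.csv(ev[, c("time_h", "type", "parent_id", "daughter1_id",
                          "daughter2_id")],
                   file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' Log the resolved configuration and seed of a run
#'
#' @param path Output YAML path.
#' @param seed Integer seed.
#' @param ... Parameter objects ([sim_params()], [imaging_params()],
#'   [analysis_params()], [condition()]) or plain lists; stored under their
#'   argument names.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, seed, ...) {
  cfg <- lapply(list(...), function(x) lapply(unclass(x), function(v)
    if (is.numeric(v) && length(v) > 1) as.list(v) else v))
  yaml::write_yaml(c(list(seed = as.integer(seed)), cfg), path)
  invisible(path)
}
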