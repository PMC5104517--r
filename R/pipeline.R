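# End-to-end quantification: render/segment/measure every frame (streamed,
# so full-length movies never hold the whole stack in memory), then track,
# annotate divisions, classify Fucci traces and count events.

#' Quantify one multichannel frame
#'
#' Segments the nuclear channel, measures every channel per nucleus, and
#' estimates the per-channel background as the whole-image cytoplasmic
#' intensity (nuclear-pixel exclusion).
#'
#' @param frame `H x W x C` array with a `"nuclear"` channel (channel names
#'   on the third margin).
#' @param params An [analysis_params()] object.
#' @return Nucleus table with `label`, `x_px`, `y_px`, `area_px2`,
#'   `mean_<channel>` and `bg_<channel>` columns.
#' @export
quantify_frame <- function(frame, params = analysis_params()) {
  channels <- dimnames(frame)[[3]]
  if (is.null(channels) || !"nuclear" %in% channels)
    stop("frame must carry channel names including 'nuclear'")
  seg <- segment_nuclei(frame[, , "nuclear"], params)
  chans <- lapply(channels, function(ch) frame[, , ch])
  names(chans) <- channels
  rec <- measure_nuclei(seg$labels, chans)
  for (ch in channels) {
    bg <- if (max(seg$labels) > 0)
      measure_cytoplasm(seg$labels, chans[[ch]],
                        params$nuclear_dilation_px)$mean_intensity
    else mean(chans[[ch]])
    rec[[paste0("bg_", ch)]] <- bg
  }
  rec
}

#' Quantify a whole stack of frames
#'
#' @param frames List of `H x W x C` arrays (e.g. `tl$frames` or
#'   [read_timelapse_tiff()] output).
#' @param params An [analysis_params()] object.
#' @return Row-bound [quantify_frame()] tables with a 0-based `frame`
#'   column.
#' @export
quantify_stack <- function(frames, params = analysis_params()) {
  out <- lapply(seq_along(frames), function(i) {
    rec <- quantify_frame(frames[[i]], params)
    rec$frame <- rep(i - 1L, nrow(rec))
    rec[, c("frame", setdiff(names(rec), "frame"))]
  })
  do.call(rbind, out)
}

#' Run the full analysis of one simulated experiment
#'
#' Simulates a condition, renders and quantifies every frame on the fly,
#' builds tracks, annotates divisions, classifies the Fucci traces and
#' counts cell-cycle events. This is the single-command analogue of one live
#' imaging experiment.
#'
#' @param cond Condition object or preset name.
#' @param duration_h Movie duration (h).
#' @param seed Integer seed.
#' @param sim,ip,ap Parameter objects.
#' @return A list of class `sc_analysis`: `nuclei` (per-frame measurements),
#'   `geminin` (per-frame percent Geminin-positive), `tracks`, `events`
#'   ([count_cycle_events()]), `traces`, `gt` (ground-truth tables), and
#'   `metrics` (named numerics: `mean_percent_green`,
#'   `mitoses_per_h_per_0p1mm2`, `accumulated`, `divided`,
#'   `gt_mitoses`, `gt_s_entries`).
#' @export
analyze_timelapse <- function(cond = "control", duration_h = 24, seed = 1,
                              sim = sim_params(), ip = imaging_params(),
                              ap = analysis_params()) {
  tl <- simulate_timelapse(cond, duration_h = duration_h, seed = seed,
                           sim = sim, ip = ip, keep_stack = FALSE,
                           frame_fun = function(fr, f, state)
                             quantify_frame(fr, ap))
  nuclei <- do.call(rbind, lapply(seq_along(tl$frame_results), function(i) {
    rec <- tl$frame_results[[i]]
    if (nrow(rec)) cbind(frame = i - 1L, rec)
  }))
  rownames(nuclei) <- NULL
  px <- ip$pixel_size_um

  net <- nuclei
  for (ch in c("nuclear", "red", "green"))
    net[[paste0("mean_", ch)]] <- nuclei[[paste0("mean_", ch)]] -
      nuclei[[paste0("bg_", ch)]]
  gem <- geminin_fraction_series(net, ap$green_threshold)

  pts <- data.frame(frame = nuclei$frame, label = nuclei$label,
                    x_um = px_to_um(nuclei$x_px, px),
                    y_um = px_to_um(nuclei$y_px, px),
                    red = net$mean_red, green = net$mean_green)
  tracks <- build_tracks(pts, ap$max_displacement_um, ap$max_gap)
  tracks <- annotate_divisions(tracks, ap$split_radius_um,
                               ap$split_window_frames)
  parents <- tracks$lineage$parent_track_id
  fi <- tl$frame_interval_h
  traces <- lapply(split(tracks$points, tracks$points$track_id), function(tp)
    classify_trace(tp$frame, tp$red, tp$green,
                   ap$ratio_on, ap$ratio_off,
                   has_daughters = tp$track_id[1] %in% parents,
                   frame_interval_h = fi))
  events <- count_cycle_events(traces, tracks$lineage,
                               frame_area_mm2 = prod(ip$fov_um) / 1e6,
                               bin_hours = 1, frame_interval_h = fi,
                               total_hours = max(duration_h, fi))
  gt_ev <- tl$events
  metrics <- c(mean_percent_green = mean(gem$percent_green, na.rm = TRUE),
               mitoses_per_h_per_0p1mm2 = events$mitoses_per_h_per_0p1mm2,
               accumulated = events$accumulated, divided = events$divided,
               gt_mitoses = sum(gt_ev$type == "mitosis"),
               gt_s_entries = sum(gt_ev$type == "g1s_entry"))
  structure(list(nuclei = nuclei, geminin = gem, tracks = tracks,
                 traces = traces, events = events,
                 gt = list(cells = tl$cells, events = gt_ev),
                 cond = tl$cond, seed = seed, metrics = metrics),
            class = "sc_analysis")
}

#' @export
print.sc_analysis <- function(x, ...) {
  cat("<sc_analysis>\n")
  print(round(x$metrics, 3))
  invisible(x)
}

#' Phase composition of a monolayer state
#'
#' @param state An `sc_monolayer`.
#' @return Named fractions over `G0`, `G1`, `S`, `G2`, `M`.
#' @export
phase_fractions <- function(state) {
  stopifnot(inherits(state, "sc_monolayer"))
  tab <- table(factor(state$cells$phase, levels = c("G0", "G1", "S", "G2", "M")))
  stats::setNames(as.numeric(tab) / nrow(state$cells), names(tab))
}
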