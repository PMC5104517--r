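# Fucci trace classification and cell-cycle event counting.
#
# The readout follows the reporter semantics: mKO2-Cdt1 (red) marks G0/G1,
# mAG-Geminin (green) marks S/G2 from S entry until its degradation at
# mitosis, so a red-to-green transition is a G1-to-S entry and a
# green-to-red (or green-to-split) transition is a mitosis.

#' Classify a Fucci fluorescence trace into RED / GREEN phases
#'
#' Applies hysteresis on the green balance ratio `green / (green + red)`
#' (background-subtracted intensities): a frame is called GREEN once the
#' ratio rises above `on_threshold` and reverts to RED only when it falls
#' below `off_threshold`. The S entry is the first GREEN call; a mitosis is
#' called at a GREEN-to-RED collapse, or at a GREEN track end when the track
#' has annotated daughters. At most one RED-to-GREEN and one GREEN-to-RED
#' transition are retained per track (later excursions are ignored and
#' counted in `n_extra_transitions`).
#'
#' @param frames Integer frame numbers (strictly increasing).
#' @param red_series,green_series Per-frame background-subtracted mean
#'   intensities.
#' @param on_threshold,off_threshold Hysteresis thresholds; `on > off`.
#' @param has_daughters Logical: does the track end in an annotated split?
#' @param frame_interval_h Frame interval (h) for dwell-time conversion.
#' @return A list of class `sc_phase_trace`: `frames`, `calls` (character
#'   RED/GREEN/UNKNOWN), `s_entry_frame`, `mitosis_frame`, `sg2_dwell_hours`,
#'   `n_extra_transitions`.
#' @export
classify_trace <- function(frames, red_series, green_series,
                           on_threshold = 0.6, off_threshold = 0.4,
                           has_daughters = FALSE, frame_interval_h = 0.25) {
  if (!(on_threshold > off_threshold))
    stop("hysteresis requires on_threshold > off_threshold")
  stopifnot(length(frames) == length(red_series),
            length(frames) == length(green_series))
  tot <- red_series + green_series
  ratio <- ifelse(tot > 0, green_series / tot, NA_real_)
  n <- length(frames)
  calls <- character(n)
  state <- "RED"
  s_entry <- NA_integer_; collapse <- NA_integer_
  extra <- 0L
  for (i in seq_len(n)) {
    r <- ratio[i]
    if (is.na(r)) {
      calls[i] <- "UNKNOWN"
      next
    }
    if (state == "RED" && r > on_threshold) {
      if (is.na(s_entry)) {
        state <- "GREEN"
        s_entry <- frames[i]
      } else extra <- extra + 1L         # second rise: ignored
    } else if (state == "GREEN" && r < off_threshold) {
      state <- "RED"
      if (is.na(collapse)) collapse <- frames[i]
    }
    calls[i] <- state
  }
  mitosis <- NA_integer_
  if (!is.na(s_entry)) {
    if (!is.na(collapse)) mitosis <- collapse
    else if (has_daughters && calls[n] == "GREEN") mitosis <- frames[n]
  }
  dwell <- if (!is.na(s_entry))
    ((if (!is.na(mitosis)) mitosis else frames[n]) - s_entry) * frame_interval_h
  else NA_real_
  structure(list(frames = frames, calls = calls,
                 s_entry_frame = s_entry, mitosis_frame = mitosis,
                 sg2_dwell_hours = dwell,
                 started_red = n > 0 && calls[1] == "RED",
                 n_extra_transitions = extra),
            class = "sc_phase_trace")
}

#' Per-frame percentage of Geminin-positive nuclei
#'
#' Applies [classify_positive()] frame-wise with one fixed green threshold.
#' Frames with no nuclei yield `NA` (flagged missing, not zero).
#'
#' @param records Nucleus table with `frame` and `mean_green` columns
#'   (background-subtracted).
#' @param green_threshold Fixed intensity threshold.
#' @param frames Optional frame numbers to report (default: all in
#'   `records`).
#' @return Data frame `frame`, `n_nuclei`, `percent_green`.
#' @export
geminin_fraction_series <- function(records, green_threshold,
                                    frames = sort(unique(records$frame))) {
  out <- data.frame(frame = frames, n_nuclei = 0L,
                    percent_green = NA_real_)
  for (k in seq_along(frames)) {
    rec <- records[records$frame == frames[k], , drop = FALSE]
    out$n_nuclei[k] <- nrow(rec)
    if (nrow(rec))
      out$percent_green[k] <-
        classify_positive(rec, "green", green_threshold)$percent_positive
  }
  out
}

#' Count cell-cycle events from classified traces
#'
#' Tallies G1-to-S entries and mitoses into hourly bins and reports rates
#' both per movie-frame area and normalized per 0.1 mm^2. A mitosis is
#' counted only when the fluorescence collapse and the lineage split agree
#' (tracks with only one cue are tallied as warnings). Cumulative totals
#' follow the single-cell-tracking readout: `accumulated` counts tracks with
#' an observed red-to-green transition, `divided` the subset that then
#' divided (red to green to red), so `divided <= accumulated` always.
#'
#' @param traces Named list of `sc_phase_trace` (names = track ids).
#' @param lineage Lineage table from [annotate_divisions()].
#' @param frame_area_mm2 Imaged area (mm^2); the movie frame is 0.43 mm^2.
#' @param bin_hours Bin width (h).
#' @param frame_interval_h Frame interval (h).
#' @param total_hours Movie duration (h).
#' @return A list of class `sc_event_counts`: `bins` (data frame
#'   `bin_start_h`, `mitoses`, `s_entries`, `mitoses_per_h_per_0p1mm2`,
#'   `s_entries_per_h_per_0p1mm2`), `accumulated`, `divided`,
#'   `n_mitoses`, `n_s_entries`, `warnings` (list with
#'   `split_without_green`, `collapse_without_split`), `frame_area_mm2`.
#' @export
count_cycle_events <- function(traces, lineage, frame_area_mm2 = 0.43,
                               bin_hours = 1, frame_interval_h = 0.25,
                               total_hours = NULL) {
  track_ids <- as.integer(names(traces))
  s_entry <- vapply(traces, function(tr) as.numeric(tr$s_entry_frame), 0)
  mito <- vapply(traces, function(tr) as.numeric(tr$mitosis_frame), 0)
  started_red <- vapply(traces, function(tr) isTRUE(tr$started_red), TRUE)
  had_green <- !is.na(s_entry)
  parents <- lineage$parent_track_id
  has_split <- track_ids %in% parents

  confirmed <- had_green & !is.na(mito) & has_split
  split_wo_green <- track_ids[has_split & !had_green]
  collapse_wo_split <- track_ids[!is.na(mito) & !has_split]

  if (is.null(total_hours)) {
    fmax <- max(c(1, vapply(traces, function(tr) max(tr$frames), 0)))
    total_hours <- fmax * frame_interval_h
  }
  brks <- seq(0, max(bin_hours, ceiling(total_hours / bin_hours) * bin_hours),
              by = bin_hours)
  mid <- function(fr) fr * frame_interval_h
  bin_of <- function(t) pmin(findInterval(t, brks, left.open = TRUE,
                                          rightmost.closed = TRUE) + 0,
                             length(brks) - 1)
  nb <- length(brks) - 1
  mit_t <- mid(mito[confirmed])
  se_t <- mid(s_entry[had_green & started_red])
  mit_bin <- tabulate(pmax(bin_of(mit_t), 1), nbins = nb)
  se_bin <- tabulate(pmax(bin_of(se_t), 1), nbins = nb)
  norm <- bin_hours * frame_area_mm2 / 0.1
  bins <- data.frame(bin_start_h = brks[-length(brks)],
                     mitoses = mit_bin, s_entries = se_bin,
                     mitoses_per_h_per_0p1mm2 = mit_bin / norm,
                     s_entries_per_h_per_0p1mm2 = se_bin / norm)
  accumulated <- sum(had_green & started_red)
  divided <- sum(had_green & started_red & confirmed)
  structure(list(bins = bins,
                 accumulated = accumulated, divided = divided,
                 n_mitoses = sum(confirmed), n_s_entries = length(se_t),
                 mitoses_per_h_per_0p1mm2 =
                   sum(mit_bin) / (total_hours * frame_area_mm2 / 0.1),
                 warnings = list(split_without_green = split_wo_green,
                                 collapse_without_split = collapse_wo_split),
                 frame_area_mm2 = frame_area_mm2,
                 total_hours = total_hours),
            class = "sc_event_counts")
}

#' @export
print.sc_event_counts <- function(x, ...) {
  cat(sprintf(paste0("<sc_event_counts> %d mitoses, %d S entries over %.0f h ",
                     "(%.2f mitoses/h/0.1 mm^2); accumulated %d, divided %d\n"),
              x$n_mitoses, x$n_s_entries, x$total_hours,
              x$mitoses_per_h_per_0p1mm2, x$accumulated, x$divided))
  invisible(x)
}
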