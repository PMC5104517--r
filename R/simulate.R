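#' Simulate a Fucci time-lapse experiment with ground truth
#'
#' Orchestrates the full in-silico experiment: monolayer initialization with
#' maturation, stretch at the strain onset (if the condition is strained),
#' and an advance/render loop at the imaging frame interval. Returns the
#' rendered stack (optional) together with a per-frame ground-truth cell
#' table and the event table (G1-to-S entries and mitoses), which serve as
#' the oracle for every downstream quantification stage.
#'
#' @param cond An [condition()] object or preset name (see
#'   [condition_preset()]).
#' @param duration_h Movie duration (h); 0 gives a single frame at t = 0.
#' @param seed Integer seed; the run is bit-reproducible given
#'   (condition, seed, parameters).
#' @param sim An [sim_params()] object.
#' @param ip An [imaging_params()] object.
#' @param maturation_hours Maturation passed to the initializer.
#' @param equilibration_h Untreated basal-turnover segment simulated between
#'   maturation and the first frame (h). It models the interval between the
#'   contact-inhibited maturation and the imaged assay (mounting on the
#'   stretcher, medium refresh, treatment preparation), during which the
#'   monolayer relaxes from deep quiescence to its documented steady
#'   turnover, so that control movies open at the ~10% Geminin-positive
#'   baseline and stay stationary. Treatments and stretch only ever start at
#'   movie time 0.
#' @param keep_stack Keep rendered frames in memory (list of `H x W x 3`
#'   arrays). Set `FALSE` for long runs and use `frame_fun` instead.
#' @param frame_fun Optional `function(frame, frame_index, state)` called on
#'   every rendered frame (frame_index is 0-based); its results are returned
#'   in `$frame_results`. When `NULL` and `keep_stack = FALSE`, frames are
#'   not rendered at all (ground-truth-only simulation).
#' @return A list of class `sc_timelapse` with `frames` (or `NULL`),
#'   `frame_results`, `cells` (ground truth per frame: `frame`, `time_h`,
#'   `cell_id`, `x_um`, `y_um`, `phase`, `red`, `green`), `events`,
#'   `state` (final), `cond`, `sim`, `ip`, and `frame_interval_h`.
#' @examples
#' tl <- simulate_timelapse("control", duration_h = 1, seed = 1,
#'                          sim = sim_params(), ip = imaging_params(fov_um = c(150, 150)),
#'                          maturation_hours = 2)
#' dim(tl$frames[[1]])
#' @export
simulate_timelapse <- function(cond = "control", duration_h = 24, seed = 1,
                               sim = sim_params(), ip = imaging_params(),
                               maturation_hours = sim$maturation_hours,
                               equilibration_h = 12,
                               keep_stack = FALSE, frame_fun = NULL) {
  if (is.character(cond)) cond <- condition_preset(cond)
  stopifnot(inherits(cond, "sc_condition"), duration_h >= 0,
            equilibration_h >= 0)
  fi_h <- ip$frame_interval_min / 60
  state <- initialize_quiescent_monolayer(
    field_size_um = ip$fov_um, density_cells_mm2 = sim$density_cells_mm2,
    maturation_hours = maturation_hours, seed = seed, params = sim)
  if (equilibration_h > 0) {
    ctrl <- condition()
    t_end <- equilibration_h
    while (state$time < t_end - 1e-9)
      state <- advance_state(state, min(sim$step_hours, t_end - state$time),
                             ctrl)
    ## re-zero the clock: movie (and treatment) time starts at 0
    state$time <- 0
    state$cells$phase_entry <- state$cells$phase_entry - t_end
    state$events$time_h <- state$events$time_h - t_end
  }

  n_frames <- floor(duration_h / fi_h + 1e-9) + 1L
  render_needed <- keep_stack || !is.null(frame_fun)
  frames <- if (keep_stack) vector("list", n_frames) else NULL
  frame_results <- if (!is.null(frame_fun)) vector("list", n_frames) else NULL
  gt <- vector("list", n_frames)

  for (f in seq_len(n_frames) - 1L) {
    if (cond$strain_applied && !state$stretch_applied &&
        state$time >= cond$strain_onset_time - 1e-9) {
      state <- apply_stretch(state, cond$stretch_factor)
    }
    cells <- state$cells
    gt[[f + 1L]] <- data.frame(frame = f, time_h = state$time,
                               cell_id = cells$cell_id,
                               x_um = cells$x, y_um = cells$y,
                               phase = cells$phase,
                               red = cells$red, green = cells$green,
                               stringsAsFactors = FALSE)
    if (render_needed) {
      .restore_rng(state$rng)
      fr <- render_frame(state, ip)
      state$rng <- .capture_rng()
      if (keep_stack) frames[[f + 1L]] <- fr
      if (!is.null(frame_fun))
        frame_results[[f + 1L]] <- frame_fun(fr, f, state)
      rm(fr)
    }
    if (f < n_frames - 1L) {
      nstep <- max(1L, round(fi_h / sim$step_hours))
      for (k in seq_len(nstep)) state <- advance_state(state, fi_h / nstep, cond)
    }
  }
  structure(list(frames = frames, frame_results = frame_results,
                 cells = do.call(rbind, gt),
                 events = state$events[state$events$time_h > 1e-9, ],
                 state = state, cond = cond, sim = sim, ip = ip,
                 frame_interval_h = fi_h, seed = as.integer(seed)),
            class = "sc_timelapse")
}

#' @export
print.sc_timelapse <- function(x, ...) {
  cat(sprintf("<sc_timelapse> %d frames, %.0f min interval, %d cells at end, %d events\n",
              length(unique(x$cells$frame)), x$frame_interval_h * 60,
              nrow(x$state$cells), nrow(x$events)))
  invisible(x)
}

#' Simulate the fiducial-bead strain calibration fixture
#'
#' Emulates the measurement of applied strain from displacements of
#' fluorescent microspheres immobilized on the stretcher membrane: beads are
#' scattered uniformly over the field, the post-stretch positions are the
#' pre-stretch positions dilated about the field centre by `stretch_factor`,
#' and each coordinate of both snapshots is perturbed by Gaussian
#' localization noise of the stated pixel magnitude. Beads are returned in
#' matched order.
#'
#' @param n_beads Number of beads (>= 3; the similarity fit is
#'   underdetermined below that).
#' @param stretch_factor Linear stretch factor applied between snapshots.
#' @param localization_noise_px Localization noise sd, in pixels.
#' @param seed Integer seed.
#' @param field_um Field `c(width, height)` in um.
#' @param pixel_size_um Pixel size (um/px) used to scale the noise.
#' @return A list with matched `pre` and `post` n x 2 matrices (um).
#' @export
simulate_bead_fixture <- function(n_beads = 200, stretch_factor = 1.085,
                                  localization_noise_px = 0, seed = 1,
                                  field_um = c(656, 656),
                                  pixel_size_um = 0.65) {
  if (n_beads < 3)
    stop("n_beads must be >= 3: the similarity fit is underdetermined")
  stopifnot(stretch_factor >= 1, localization_noise_px >= 0)
  set.seed(as.integer(seed))
  pre <- cbind(stats::runif(n_beads, 0, field_um[1]),
               stats::runif(n_beads, 0, field_um[2]))
  ctr <- field_um / 2
  post <- sweep(sweep(pre, 2, ctr) * stretch_factor, 2, ctr, "+")
  sd_um <- localization_noise_px * pixel_size_um
  if (sd_um > 0)
    post <- post + matrix(stats::rnorm(2 * n_beads, 0, sd_um), n_beads, 2)
  colnames(pre) <- colnames(post) <- c("x_um", "y_um")
  list(pre = pre, post = post)
}
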