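test_that("a constant-red trace stays RED with no events", {
  tr <- classify_trace(0:20, red_series = rep(800, 21),
                       green_series = rep(0, 21))
  expect_true(all(tr$calls == "RED"))
  expect_true(is.na(tr$s_entry_frame) && is.na(tr$mitosis_frame))
  expect_error(classify_trace(0:5, 1:6, 1:6, on_threshold = 0.4,
                              off_threshold = 0.6), "hysteresis")
})

test_that("hysteresis keeps the GREEN call through mid-band dips", {
  # ratio path: 0.1, 0.7 (on), 0.5 (mid-band: stays GREEN), 0.3 (off), 0.5
  red <- c(900, 300, 500, 700, 500)
  green <- c(100, 700, 500, 300, 500)
  tr <- classify_trace(0:4, red, green)
  expect_identical(tr$calls, c("RED", "GREEN", "GREEN", "RED", "RED"))
  expect_identical(tr$s_entry_frame, 1L)
  expect_identical(tr$mitosis_frame, 3L)   # green-to-red collapse
  expect_identical(tr$n_extra_transitions, 0L)
})

test_that("S entry is called within the analytic hysteresis lag", {
  # reporter kinetics of the generator: red decays exp(-0.693 t) from 1,
  # green rises 0.3 t from the true S entry at frame 12
  fi <- 0.25
  fr <- 0:60
  t_in_s <- pmax((fr - 12) * fi, 0)
  red <- ifelse(fr < 12, 1, exp(-log(2) * t_in_s))
  green <- 0.3 * t_in_s
  # analytic crossing: 0.3 t / (0.3 t + e^(-0.693 t)) = 0.6
  t_cross <- uniroot(function(t) 0.3 * t - 1.5 * exp(-log(2) * t),
                     c(0.01, 10))$root
  lag_frames <- ceiling(t_cross / fi)
  tr <- classify_trace(fr, red * 1000, green * 1000, frame_interval_h = fi)
  expect_gte(tr$s_entry_frame, 12)
  expect_lte(tr$s_entry_frame, 12 + lag_frames)
  # dwell bookkeeping: (end - entry) * frame interval
  expect_equal(tr$sg2_dwell_hours, (60 - tr$s_entry_frame) * fi)
})

test_that("a green track ending in an annotated split is a mitosis", {
  red <- c(1000, 900, 50, 10, 5)
  green <- c(0, 30, 900, 1000, 1100)
  with_d <- classify_trace(0:4, red, green, has_daughters = TRUE)
  without <- classify_trace(0:4, red, green, has_daughters = FALSE)
  expect_identical(with_d$mitosis_frame, 4L)
  expect_true(is.na(without$mitosis_frame))
})

test_that("geminin fraction series matches frame-wise classification", {
  rec <- data.frame(frame = rep(0:2, each = 4),
                    mean_green = c(1, 1, 9, 9,  9, 9, 9, 9,  1, 1, 1, 9))
  gem <- geminin_fraction_series(rec, green_threshold = 5)
  expect_equal(gem$percent_green, c(50, 100, 25))
  for (f in 0:2)
    expect_equal(gem$percent_green[f + 1],
                 classify_positive(rec[rec$frame == f, ], "green",
                                   5)$percent_positive)
  gem2 <- geminin_fraction_series(rec, 5, frames = 0:3)
  expect_true(is.na(gem2$percent_green[4]))   # empty frame flagged, not zero
})

test_that("event counting handles empty input and unit conversion", {
  ec0 <- count_cycle_events(setNames(list(), character(0)),
                            data.frame(parent_track_id = integer(0)),
                            frame_area_mm2 = 0.43, total_hours = 24)
  expect_identical(ec0$n_mitoses, 0L)
  expect_true(all(ec0$bins$mitoses == 0))

  # 4.3 events per hour in a 0.43 mm^2 frame = 1.0 events/h/0.1 mm^2
  mk_trace <- function(mf) structure(list(frames = 0:96,
    calls = c(rep("RED", 2), rep("GREEN", mf - 2), rep("RED", 97 - mf)),
    s_entry_frame = 2L, mitosis_frame = as.integer(mf),
    sg2_dwell_hours = (mf - 2) * 0.25, started_red = TRUE,
    n_extra_transitions = 0L), class = "sc_phase_trace")
  n <- 4.3 * 20                       # 86 mitoses over 20 h
  traces <- lapply(seq_len(n), function(i) mk_trace(10 + (i %% 70)))
  names(traces) <- seq_len(n)
  lineage <- data.frame(parent_track_id = as.integer(seq_len(n)))
  ec <- count_cycle_events(traces, lineage, frame_area_mm2 = 0.43,
                           frame_interval_h = 0.25, total_hours = 20)
  expect_equal(ec$mitoses_per_h_per_0p1mm2, 1.0, tolerance = 1e-3)
  expect_lte(ec$divided, ec$accumulated)
})

test_that("counts equal the ground-truth event table on clean runs", {
  # jitter-free simulation, records taken at ground-truth positions with
  # ground-truth fluorophore levels: the whole chain (tracking, division
  # annotation, trace classification, counting) must reproduce the event
  # table exactly
  sim <- sim_params(jitter_sd_um = 0)
  ip <- imaging_params(fov_um = c(300, 300))
  tl <- simulate_timelapse("control", 12, seed = 13, sim = sim, ip = ip)
  gt <- tl$cells
  rec <- data.frame(frame = gt$frame, x_um = gt$x_um, y_um = gt$y_um,
                    red = gt$red * 1000, green = gt$green * 1000)
  tr <- annotate_divisions(build_tracks(rec, 1.5, 1), 6, 1)
  traces <- lapply(split(tr$points, tr$points$track_id), function(tp)
    classify_trace(tp$frame, tp$red, tp$green,
                   has_daughters = tp$track_id[1] %in%
                     tr$lineage$parent_track_id))
  ec <- count_cycle_events(traces, tr$lineage, frame_area_mm2 = 0.09,
                           frame_interval_h = 0.25, total_hours = 12)
  expect_identical(ec$n_mitoses, sum(tl$events$type == "mitosis"))
  expect_length(ec$warnings$split_without_green, 0)
  expect_lte(ec$divided, ec$accumulated)
})

test_that("cumulative division counts never exceed S/G2 accumulation", {
  an <- pipeline_run(acceptance_seeds[1])
  expect_lte(an$events$divided, an$events$accumulated)
  expect_identical(sum(an$events$bins$mitoses), an$events$n_mitoses)
})
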