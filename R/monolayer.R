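# RNG state is carried inside the monolayer state so that every run is
# bit-reproducible given (condition, seed, params), independent of the
# caller's RNG usage.
.restore_rng <- function(rng) assign(".Random.seed", rng, envir = globalenv())
.capture_rng <- function() get(".Random.seed", envir = globalenv())

.field_area_mm2 <- function(state) prod(state$field_size_um) / 1e6

.ci_suppression <- function(density, p) {
  1 / (1 + (density / p$ci_rho_half)^p$ci_power)
}

#' Effective transcriptional activity of each cell
#'
#' `A_i(t) = A0_i * (1 + beta_strain * s(t - onset) + beta_wnt)` where `s` is
#' a logistic onset centred `strain_activity_delay_h` after stretch; the Wnt
#' term applies when `wnt` or `cki_inhibited` is set. `icrt3` forces all
#' activities to zero.
#'
#' @param a0 Baseline activity vector.
#' @param cond An [condition()] object.
#' @param time Simulation time (h).
#' @param params An [sim_params()] object.
#' @return Numeric vector of effective activities.
#' @keywords internal
.effective_activity <- function(a0, cond, time, params) {
  if (cond$icrt3) return(rep(0, length(a0)))
  s <- 0
  if (cond$strain_applied && time >= cond$strain_onset_time) {
    s <- stats::plogis((time - cond$strain_onset_time -
                          params$strain_activity_delay_h) /
                         params$strain_activity_width_h)
  }
  w <- as.numeric(cond$wnt || cond$cki_inhibited)
  a0 * (1 + params$beta_strain * s + params$beta_wnt * w)
}

.draw_tail_a0 <- function(n, p) {
  lo <- stats::plnorm(p$theta2, p$a0_meanlog, p$a0_sdlog)
  stats::qlnorm(stats::runif(n, lo, 1), p$a0_meanlog, p$a0_sdlog)
}

.empty_events <- function() {
  data.frame(time_h = numeric(0), type = character(0), cell_id = integer(0),
             parent_id = integer(0), daughter1_id = integer(0),
             daughter2_id = integer(0), stringsAsFactors = FALSE)
}

#' Initialize a quiescent super-confluent monolayer
#'
#' Places cells on a jittered hexagonal packing at the requested density and
#' simulates a contact-inhibited maturation phase (G0-exit hazard suppressed
#' by the sensed density) under the untreated condition, after which at least
#' 95% of cells are quiescent (G0). Runs are deterministic given `seed`.
#'
#' @param field_size_um Field rectangle `c(width, height)` in um.
#' @param density_cells_mm2 Target density (cells/mm^2).
#' @param maturation_hours Simulated maturation duration (h).
#' @param seed Integer seed.
#' @param params An [sim_params()] object.
#' @return An `sc_monolayer` state: a list with `time` (h, 0 at handoff),
#'   `cells` (one row per cell: `cell_id`, `x`, `y` in um, `phase`,
#'   `phase_entry`, `tau_g1`, `trigger`, `a0`, `activity`, `red`, `green`),
#'   `field_origin_um`, `field_size_um`, `events`, and bookkeeping fields.
#' @examples
#' st <- initialize_quiescent_monolayer(c(200, 200), 1000, 4, seed = 1)
#' mean(st$cells$phase == "G0")
#' @export
initialize_quiescent_monolayer <- function(field_size_um = c(656, 656),
                                           density_cells_mm2 = 1000,
                                           maturation_hours = 48,
                                           seed = 1,
                                           params = sim_params()) {
  if (density_cells_mm2 <= 0)
    stop("density_cells_mm2 must be positive (cells/mm^2)")
  if (any(field_size_um <= 0))
    stop("field_size_um must span a positive area")
  set.seed(as.integer(seed))
  W <- field_size_um[1]; H <- field_size_um[2]
  d <- sqrt(2 / (sqrt(3) * density_cells_mm2 / 1e6))  # hex spacing (um)
  dy <- d * sqrt(3) / 2
  ys <- seq(dy / 2, H - dy / 4, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(j) {
    off <- if (j %% 2 == 0) d / 2 else 0
    xs <- seq(d / 2 + off, W - d / 4, by = d)
    cbind(xs, ys[j])
  }))
  n <- nrow(pts)
  pts <- pts + matrix(stats::rnorm(2 * n, 0, params$hex_jitter_um), n, 2)
  pts[, 1] <- pmin(pmax(pts[, 1], 0.01), W - 0.01)
  pts[, 2] <- pmin(pmax(pts[, 2], 0.01), H - 0.01)

  cells <- data.frame(
    cell_id = seq_len(n),
    x = pts[, 1], y = pts[, 2],
    phase = rep("G0", n),
    phase_entry = rep(-maturation_hours, n),
    tau_g1 = rep(NA_real_, n),
    trigger = rep("basal", n),
    a0 = stats::rlnorm(n, params$a0_meanlog, params$a0_sdlog),
    committed = rep(FALSE, n),
    red = rep(1, n), green = rep(0, n),
    stringsAsFactors = FALSE)
  cells$activity <- cells$a0

  state <- structure(list(
    time = -maturation_hours,
    cells = cells,
    field_origin_um = c(0, 0),
    field_size_um = field_size_um,
    events = .empty_events(),
    maturing = TRUE,
    stretch_applied = FALSE,
    n_initial = n,
    next_id = n + 1L,
    params = params,
    seed = as.integer(seed),
    rng = .capture_rng()), class = "sc_monolayer")

  ctrl <- condition()
  while (state$time < -1e-9) {
    dt <- min(params$step_hours, -state$time)
    state <- advance_state(state, dt, ctrl)
  }
  state$time <- 0
  state$maturing <- FALSE
  state
}

#' Advance the monolayer by one stochastic step
#'
#' Implements the two-threshold cell-cycle state machine. G0 cells exit at
#' hazard `h0` (suppressed by contact inhibition during maturation) plus a
#' mechanosensitive term while strained; spontaneous (basal-trigger) entrants
#' redraw their baseline activity from the upper tail (above `theta2`) and so
#' complete the cycle, while treatment-induced entrants keep their baseline
#' draw. G1 lasts an Erlang-distributed time after which the cell enters S if
#' its activity clears `theta1` and otherwise re-quiesces; S lasts `tau_s`;
#' G2 exits to mitosis at the graded hazard `k_m * A/theta2` once `A >=
#' theta2`. Mitosis is instantaneous: the parent is replaced by two adjacent
#' G1 daughters with red fluorescence restored. mKO2-Cdt1 relaxes towards its
#' plateau in G0/G1 and decays exponentially in S/G2; mAG-Geminin accumulates
#' linearly from S entry and is dropped to zero at mitosis.
#'
#' @param state An `sc_monolayer` state.
#' @param dt Step size (h); must be positive and at most 1.
#' @param cond An [condition()] object.
#' @return The advanced state.
#' @export
advance_state <- function(state, dt, cond) {
  stopifnot(inherits(state, "sc_monolayer"), dt > 0, dt <= 1)
  .restore_rng(state$rng)
  p <- state$params
  t0 <- state$time
  t1 <- t0 + dt
  cells <- state$cells
  n0 <- nrow(cells)
  A <- .effective_activity(cells$a0, cond, t0, p)
  events <- list()

  strain_on <- cond$strain_applied && t0 >= cond$strain_onset_time

  ## G0 exit (quiescence escape)
  g0 <- which(cells$phase == "G0")
  if (length(g0)) {
    dens <- nrow(cells) / .field_area_mm2(state)
    hb <- p$h0_exit * if (isTRUE(state$maturing)) .ci_suppression(dens, p) else 1
    hi <- if (strain_on) p$h_strain_exit else 0
    h <- hb + hi
    if (h > 0) {
      exit <- g0[stats::runif(length(g0)) < 1 - exp(-h * dt)]
      if (length(exit)) {
        basal <- stats::runif(length(exit)) < hb / h
        cells$trigger[exit] <- ifelse(basal, "basal", "induced")
        cells$a0[exit[basal]] <- .draw_tail_a0(sum(basal), p)
        cells$committed[exit] <- TRUE  # quiescence exit: the Yap arm fired
        cells$phase[exit] <- "G1"
        cells$phase_entry[exit] <- t1
        cells$tau_g1[exit] <- stats::rgamma(length(exit), shape = p$tau_g1_shape,
                                            rate = p$tau_g1_shape / p$tau_g1_mean)
      }
    }
  }

  ## G1 expiry: gated S entry or re-quiescence. Only cells that exited G0 in
  ## this cycle (commitment = the mechanosensitive/basal exit arm fired) test
  ## the theta1 gate; post-mitotic daughter G1 always re-quiesces, since
  ## beta-catenin activity alone cannot drive S entry without prior
  ## quiescence exit.
  g1 <- which(cells$phase == "G1" & (t1 - cells$phase_entry) >= cells$tau_g1)
  if (length(g1)) {
    pass <- cells$committed[g1] & A[g1] >= p$theta1
    toS <- g1[pass]
    if (length(toS)) {
      cells$phase[toS] <- "S"
      cells$phase_entry[toS] <- t1
      events$g1s <- data.frame(time_h = t1, type = "g1s_entry",
                               cell_id = cells$cell_id[toS],
                               parent_id = NA_integer_,
                               daughter1_id = NA_integer_,
                               daughter2_id = NA_integer_,
                               stringsAsFactors = FALSE)
    }
    back <- g1[!pass]
    if (length(back)) {
      cells$phase[back] <- "G0"
      cells$phase_entry[back] <- t1
      cells$tau_g1[back] <- NA_real_
      cells$committed[back] <- FALSE
    }
  }

  ## S -> G2 after the fixed S duration
  s2 <- which(cells$phase == "S" & (t1 - cells$phase_entry) >= p$tau_s)
  if (length(s2)) {
    cells$phase_entry[s2] <- cells$phase_entry[s2] + p$tau_s
    cells$phase[s2] <- "G2"
  }

  ## G2 -> M: graded hazard above the upper threshold
  g2 <- which(cells$phase == "G2")
  div <- integer(0)
  if (length(g2)) {
    hz <- ifelse(A[g2] >= p$theta2, p$k_m * A[g2] / p$theta2, 0)
    div <- g2[stats::runif(length(g2)) < 1 - exp(-hz * dt)]
  }

  ## fluorophore kinetics on the post-transition phases
  redphase <- cells$phase %in% c("G0", "G1")
  cells$red[redphase] <- 1 + (cells$red[redphase] - 1) * exp(-p$red_rise_rate * dt)
  cells$red[!redphase] <- cells$red[!redphase] * exp(-p$red_decay_rate * dt)
  cells$green[!redphase] <- pmin(cells$green[!redphase] + p$green_rise_rate * dt,
                                 p$green_max)
  cells$green[redphase] <- 0

  ## instantaneous mitosis: parent replaced by two adjacent G1 daughters
  if (length(div)) {
    nd <- length(div)
    ang <- stats::runif(nd, 0, 2 * pi)
    off <- p$nucleus_radius_um / 2
    dx <- off * cos(ang); dy <- off * sin(ang)
    ids <- state$next_id + seq_len(2 * nd) - 1L
    d1 <- ids[seq_len(nd)]; d2 <- ids[nd + seq_len(nd)]
    parent_ids <- cells$cell_id[div]
    px <- cells$x[div]; py <- cells$y[div]
    a0_new <- stats::rlnorm(2 * nd, p$a0_meanlog, p$a0_sdlog)
    tau_new <- stats::rgamma(2 * nd, shape = p$tau_g1_shape,
                             rate = p$tau_g1_shape / p$tau_g1_mean)
    daughters <- data.frame(
      cell_id = c(d1, d2),
      x = c(px + dx, px - dx), y = c(py + dy, py - dy),
      phase = "G1", phase_entry = t1,
      tau_g1 = tau_new, trigger = "basal",
      a0 = a0_new, committed = FALSE,
      red = p$daughter_red, green = 0,
      activity = a0_new, stringsAsFactors = FALSE)
    cells <- rbind(cells[-div, ], daughters)
    events$mit <- data.frame(time_h = t1, type = "mitosis",
                             cell_id = NA_integer_, parent_id = parent_ids,
                             daughter1_id = d1, daughter2_id = d2,
                             stringsAsFactors = FALSE)
    state$next_id <- state$next_id + 2L * nd
  }

  ## Brownian positional jitter (per-frame sd scaled to the step size),
  ## reflected at the field boundary
  nj <- nrow(cells)
  sd_step <- p$jitter_sd_um * sqrt(dt / 0.25)
  cells$x <- cells$x + stats::rnorm(nj, 0, sd_step)
  cells$y <- cells$y + stats::rnorm(nj, 0, sd_step)

  ## nuclear exclusion volume: nuclei closer than 2.5 radii (newly placed
  ## daughter pairs, or random-walk encounters) relax apart by up to 3/4 of a
  ## nuclear radius per frame each, so divided nuclei become optically
  ## resolvable within one frame, as in cytokinesis
  r_ex <- 2.5 * p$nucleus_radius_um
  if (nj >= 2) {
    dmat <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
    dmat[upper.tri(dmat, diag = TRUE)] <- Inf
    close <- which(dmat < r_ex, arr.ind = TRUE)
    if (nrow(close)) {
      push_max <- (0.75 * p$nucleus_radius_um) * (dt / 0.25)
      for (r in seq_len(nrow(close))) {
        i <- close[r, 1]; j <- close[r, 2]
        dx <- cells$x[i] - cells$x[j]; dy <- cells$y[i] - cells$y[j]
        d <- sqrt(dx^2 + dy^2)
        if (d < 1e-6) {
          a <- stats::runif(1, 0, 2 * pi); dx <- cos(a); dy <- sin(a); d <- 1
        }
        push <- min(push_max, (r_ex - d) / 2)
        cells$x[i] <- cells$x[i] + push * dx / d
        cells$y[i] <- cells$y[i] + push * dy / d
        cells$x[j] <- cells$x[j] - push * dx / d
        cells$y[j] <- cells$y[j] - push * dy / d
      }
    }
  }
  o <- state$field_origin_um; fs <- state$field_size_um
  refl <- function(v, lo, hi) {
    v <- ifelse(v < lo, 2 * lo - v, v)
    ifelse(v > hi, 2 * hi - v, v)
  }
  cells$x <- pmin(pmax(refl(cells$x, o[1], o[1] + fs[1]), o[1]), o[1] + fs[1])
  cells$y <- pmin(pmax(refl(cells$y, o[2], o[2] + fs[2]), o[2]), o[2] + fs[2])

  cells$activity <- .effective_activity(cells$a0, cond, t1, p)
  rownames(cells) <- NULL
  state$cells <- cells
  state$time <- t1
  if (length(events))
    state$events <- rbind(state$events, do.call(rbind, unname(events)))
  state$rng <- .capture_rng()
  stopifnot(nrow(cells) == n0 + length(div))
  state
}

#' Apply an equi-biaxial stretch to the monolayer
#'
#' Scales all positions and the field rectangle about the field centre by
#' `stretch_factor`, so that every pairwise distance is multiplied by exactly
#' that factor (pure isotropic dilation; the in-plane strain is
#' `stretch_factor - 1`).
#'
#' @param state An `sc_monolayer` state.
#' @param stretch_factor Linear stretch factor, >= 1.
#' @return The stretched state.
#' @export
apply_stretch <- function(state, stretch_factor) {
  stopifnot(inherits(state, "sc_monolayer"))
  if (stretch_factor < 1)
    stop("stretch_factor must be >= 1 (the device only stretches)")
  ctr <- state$field_origin_um + state$field_size_um / 2
  state$cells$x <- ctr[1] + stretch_factor * (state$cells$x - ctr[1])
  state$cells$y <- ctr[2] + stretch_factor * (state$cells$y - ctr[2])
  state$field_origin_um <- ctr - stretch_factor * state$field_size_um / 2
  state$field_size_um <- stretch_factor * state$field_size_um
  state$stretch_applied <- TRUE
  state
}

#' @export
print.sc_monolayer <- function(x, ...) {
  tab <- table(factor(x$cells$phase, levels = c("G0", "G1", "S", "G2", "M")))
  cat(sprintf("<sc_monolayer> t = %.2f h, %d cells in %.0f x %.0f um field\n",
              x$time, nrow(x$cells), x$field_size_um[1], x$field_size_um[2]))
  print(tab)
  invisible(x)
}
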