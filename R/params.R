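#' Default parameters of the monolayer simulator
#'
#' The defaults are calibrated so that two baseline observables of an
#' untreated super-confluent MDCK-like monolayer fall out of two parameters:
#' a basal S-entry flux of `lambda = h0_exit` ~ 0.01 entries/cell/h and a
#' total S/G2 dwell of ~10 h (`tau_s` plus the mean graded G2 exit time)
#' give a steady-state Geminin-positive fraction of `lambda * tau_sg2` ~ 10%
#' and a division rate of ~1/h per 0.1 mm^2 at 1000 cells/mm^2.
#'
#' The signalling model is a scalar per-cell transcriptional activity proxy
#' `A_i`: a cell-intrinsic baseline `A0_i` (log-normal) multiplied by
#' treatment terms, gated at a lower threshold `theta1` for the G1-to-S
#' transition and at a higher threshold `theta2` for mitotic entry, with the
#' mitotic hazard graded in `A_i/theta2` above threshold.
#'
#' @param density_cells_mm2 Plating density (cells/mm^2).
#' @param maturation_hours Simulated contact-inhibition maturation before the
#'   monolayer is considered quiescent (h).
#' @param h0_exit Basal G0-exit hazard during the assay phase (1/h). Equals
#'   the basal S-entry flux because spontaneous (basal-trigger) entrants carry
#'   high activity and complete the cycle.
#' @param ci_rho_half,ci_power Contact-inhibition suppression of the G0-exit
#'   hazard during maturation: multiplier `1/(1 + (density/ci_rho_half)^ci_power)`.
#' @param h_strain_exit Additional G0-exit hazard while strained (1/h); the
#'   mechanosensitive (Yap1-like) arm, active immediately on stretch.
#' @param tau_g1_mean,tau_g1_shape Mean (h) and Erlang shape of the G1 dwell.
#' @param tau_s Fixed S-phase duration (h).
#' @param k_m Mitotic entry hazard scale (1/h); the realized hazard is
#'   `k_m * A/theta2` for `A >= theta2`, zero below.
#' @param theta1,theta2 Lower (G1-to-S) and upper (G2-to-M) activity
#'   thresholds.
#' @param a0_meanlog,a0_sdlog Log-normal parameters of the baseline activity
#'   `A0_i`.
#' @param beta_strain,beta_wnt Multiplicative activity increments:
#'   `A = A0 * (1 + beta_strain * s(t) + beta_wnt)` where `s(t)` is the
#'   delayed sigmoidal strain response and the Wnt term applies to Wnt3A or
#'   CKI-inhibited (D4476) conditions.
#' @param strain_activity_delay_h Centre of the sigmoidal onset of
#'   strain-induced activity after stretch (h); reproduces S entry 6-8 h
#'   after strain.
#' @param strain_activity_width_h Width (h) of the sigmoidal onset.
#' @param red_rise_rate Recovery rate of mKO2-Cdt1 towards its plateau in
#'   G0/G1 (1/h).
#' @param red_decay_rate Degradation rate of mKO2-Cdt1 in S/G2 (1/h);
#'   default log(2) gives a 1 h half-life.
#' @param green_rise_rate Linear accumulation rate of mAG-Geminin from S
#'   entry (a.u./h).
#' @param green_max Saturation level of mAG-Geminin (a.u.).
#' @param daughter_red Initial mKO2-Cdt1 level of daughters at division.
#' @param jitter_sd_um Brownian positional jitter per 15-min frame (um).
#' @param nucleus_radius_um Nuclear radius (um); daughters are placed at
#'   +/- half this radius along a random axis.
#' @param hex_jitter_um Positional jitter of the initial hexagonal packing (um).
#' @param step_hours Internal integration step (h).
#' @return A named list of class `sc_sim_params`.
#' @export
sim_params <- function(density_cells_mm2 = 1000,
                       maturation_hours = 48,
                       h0_exit = 0.01,
                       ci_rho_half = 600,
                       ci_power = 2,
                       h_strain_exit = 0.02,
                       tau_g1_mean = 1,
                       tau_g1_shape = 2,
                       tau_s = 4,
                       k_m = 1 / 6,
                       theta1 = 1.8,
                       theta2 = 3.0,
                       a0_meanlog = 0,
                       a0_sdlog = 0.25,
                       beta_strain = 0.9,
                       beta_wnt = 2.5,
                       strain_activity_delay_h = 6,
                       strain_activity_width_h = 1,
                       red_rise_rate = 1,
                       red_decay_rate = log(2),
                       green_rise_rate = 0.3,
                       green_max = 2,
                       daughter_red = 0.5,
                       jitter_sd_um = 0.3,
                       nucleus_radius_um = 4,
                       hex_jitter_um = 0.8,
                       step_hours = 0.25) {
  p <- as.list(environment())
  stopifnot(p$density_cells_mm2 > 0, p$tau_s > 0, p$theta2 > p$theta1)
  class(p) <- "sc_sim_params"
  p
}

#' Default imaging parameters of the synthetic renderer
#'
#' The image-formation model draws each nucleus as an isotropic Gaussian spot
#' (sd = half the nuclear radius), adds a constant background, applies Poisson
#' shot noise and additive Gaussian read noise, and clips to 16 bits. The
#' field of view defaults to 656 x 656 um (~0.43 mm^2, one movie frame) at
#' 0.65 um/px, a 20x-objective scale.
#'
#' @param pixel_size_um Pixel size (um/px).
#' @param fov_um Field of view, `c(width, height)` in um.
#' @param frame_interval_min Frame interval (min).
#' @param nuclear_amp Peak amplitude of the nuclear-stain spot (counts).
#' @param fluor_gain Peak counts per unit fluorophore level (red and green).
#' @param background Constant background level (counts).
#' @param read_noise_sd Gaussian read noise sd (counts).
#' @param noise Logical; apply shot + read noise.
#' @param spot_sd_um Gaussian spot sd (um); default half the nuclear radius.
#' @return A named list of class `sc_imaging_params`.
#' @export
imaging_params <- function(pixel_size_um = 0.65,
                           fov_um = c(656, 656),
                           frame_interval_min = 15,
                           nuclear_amp = 2000,
                           fluor_gain = 3000,
                           background = 100,
                           read_noise_sd = 10,
                           noise = TRUE,
                           spot_sd_um = 2) {
  p <- as.list(environment())
  stopifnot(p$pixel_size_um > 0, all(p$fov_um > 0), p$frame_interval_min > 0)
  class(p) <- "sc_imaging_params"
  p
}

#' Treatment condition of a simulated experiment
#'
#' @param strain_applied Apply equi-biaxial stretch at `strain_onset_time`.
#' @param strain_onset_time Time of stretch application (h, movie time).
#' @param wnt Wnt3A-conditioned medium (activity increment `beta_wnt`).
#' @param cki_inhibited CKI inhibition (D4476); same activity arm as `wnt`.
#' @param icrt3 beta-catenin/TCF inhibition; forces effective activity to 0.
#' @param stretch_factor Linear stretch factor (>= 1); the default 1.085
#'   is the device's maximum-pressure calibration (8.5% strain).
#' @return A named list of class `sc_condition`.
#' @export
condition <- function(strain_applied = FALSE,
                      strain_onset_time = 0,
                      wnt = FALSE,
                      cki_inhibited = FALSE,
                      icrt3 = FALSE,
                      stretch_factor = 1.085) {
  stopifnot(stretch_factor >= 1)
  cond <- list(strain_applied = isTRUE(strain_applied),
               strain_onset_time = strain_onset_time,
               wnt = isTRUE(wnt),
               cki_inhibited = isTRUE(cki_inhibited),
               icrt3 = isTRUE(icrt3),
               stretch_factor = stretch_factor)
  class(cond) <- "sc_condition"
  cond
}

#' Named treatment presets
#'
#' Presets mirror the experimental arms: `control`, `strain`, `wnt`,
#' `strain-wnt`, `d4476`, `strain-d4476`, `strain-d4476-icrt3`.
#'
#' @param name Preset name.
#' @return An `sc_condition`.
#' @export
condition_preset <- function(name = c("control", "strain", "wnt", "strain-wnt",
                                      "d4476", "strain-d4476",
                                      "strain-d4476-icrt3")) {
  name <- match.arg(name)
  switch(name,
    "control" = condition(),
    "strain" = condition(strain_applied = TRUE),
    "wnt" = condition(wnt = TRUE),
    "strain-wnt" = condition(strain_applied = TRUE, wnt = TRUE),
    "d4476" = condition(cki_inhibited = TRUE),
    "strain-d4476" = condition(strain_applied = TRUE, cki_inhibited = TRUE),
    "strain-d4476-icrt3" = condition(strain_applied = TRUE,
                                     cki_inhibited = TRUE, icrt3 = TRUE))
}

#' Default analysis parameters for the quantification pipeline
#'
#' @param smooth_sigma_px Gaussian smoothing sd for segmentation (px).
#' @param bg_radius_px Rolling-ball (grayscale opening) radius for
#'   background subtraction (px).
#' @param ws_tolerance_px Watershed tolerance on the distance transform (px);
#'   the minimum seed separation depth for splitting touching nuclei.
#' @param min_area_px2 Minimum object area kept (px^2).
#' @param nuclear_dilation_px Dilation of the nuclear mask before cytoplasmic
#'   quantification (px).
#' @param green_threshold Fixed background-subtracted mean green intensity
#'   above which a nucleus is Geminin-positive; kept constant between
#'   compared conditions.
#' @param ratio_on,ratio_off Hysteresis thresholds on the green/(green+red)
#'   balance for trace classification.
#' @param max_displacement_um Linking gate (um); a few times the expected
#'   frame-to-frame displacement (so random-walk tails almost never break a
#'   link) while staying well below the first-frame separation of daughter
#'   nuclei, so a dividing parent always terminates.
#' @param max_gap Maximum frame gap bridged during track building.
#' @param split_radius_um Radius around a track terminus searched for
#'   daughter appearances (um).
#' @param split_window_frames Number of frames after a terminus searched for
#'   daughter appearances.
#' @return A named list of class `sc_analysis_params`.
#' @export
analysis_params <- function(smooth_sigma_px = 2,
                            bg_radius_px = 15,
                            ws_tolerance_px = 2,
                            min_area_px2 = 20,
                            nuclear_dilation_px = 2,
                            green_threshold = 150,
                            ratio_on = 0.6,
                            ratio_off = 0.4,
                            max_displacement_um = 1.5,
                            max_gap = 1,
                            split_radius_um = 6,
                            split_window_frames = 1) {
  p <- as.list(environment())
  stopifnot(p$ratio_on > p$ratio_off, p$max_displacement_um > 0)
  class(p) <- "sc_analysis_params"
  p
}
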