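#' Simulation configuration for synthetic single-cell KTR dynamics
#'
#' Bundles every parameter of the ground-truth generator: acquisition
#' timing, class structure (dividing vs non-dividing), activity dynamics,
#' ERK-Akt coupling, division-drop phenomenology, and cell motion.
#'
#' The defaults encode a 48 h time course sampled every 15 min with growth
#' factor added after 1 h of baseline, a rapid logistic rise to a noisy
#' plateau, and divisions falling between 16 and 36 h so that they land
#' inside the 8.5-40 h analysis window used by the downstream statistics.
#'
#' @param n_cells number of founder cells to simulate.
#' @param frac_dividing fraction of cells that divide, in \[0, 1\].
#' @param duration_h total imaging duration in hours.
#' @param sampling_interval_h frame spacing in hours (0.25 = every 15 min).
#' @param gf_time_h time of growth-factor addition, hours after the first
#'   (baseline) frame.
#' @param plateau_median_nondiv long-run plateau median C/N activity for
#'   non-dividing cells.
#' @param effect_size additive plateau offset for dividing cells, in C/N
#'   activity units. A scalar applies to both channels; a length-2 vector
#'   gives separate (ERK, Akt) offsets. The default makes the ERK
#'   association with division twice the Akt one, matching the study
#'   conditions the generator emulates.
#' @param noise_sd stationary standard deviation of the AR(1) activity
#'   noise, C/N units.
#' @param cell_sd standard deviation of the per-cell random plateau
#'   offset (cell-to-cell heterogeneity), C/N units; independent across
#'   channels, so that windowed medians of the two fate classes overlap
#'   as real single-cell data do without one channel's median carrying
#'   fate information about the other's. Uncorrelated cell variance
#'   dilutes the pooled (cell, time) ERK-Akt correlation below the rho
#'   targets; set `cell_sd = 0` for a noise-dominated plateau whose
#'   pooled correlation matches them.
#' @param ar_coeff AR(1) coefficient of the activity noise, in \[0, 1).
#' @param rho_div,rho_nondiv target ERK-Akt correlation of the activity
#'   noise for dividing / non-dividing cells, in \[-1, 1\].
#' @param division_window_h length-2 vector (lo, hi), hours: division times
#'   are drawn uniformly from this window. Must lie strictly inside
#'   (gf_time_h, duration_h).
#' @param drop_frac fractional C/N drop at division in (0, 1\]: observed
#'   C/N is multiplied by (1 - drop_frac) over the drop span.
#' @param drop_span_frames number of frames the division drop lasts (>= 1).
#' @param baseline_activity pre-stimulus C/N activity level.
#' @param rise_tau_h time constant (h) of the logistic post-stimulus rise.
#' @param arena_px length-2 (rows, cols): pixel arena for motion paths.
#' @param motion_sd_px per-frame random-walk step standard deviation, px.
#' @param boundary "reflect" keeps all cells inside the arena;
#'   "absorb" lets cells wander out (their nuclei are then absent from
#'   rendered frames, emulating cells leaving the field of view).
#' @param pulsing optional pulsatile activity mode (disabled by default;
#'   the modelled system shows sustained, non-pulsatile activation).
#' @param pulse_amp,pulse_period_h amplitude (C/N units) and period (h) of
#'   the optional sinusoidal pulsing component.
#' @param seed integer seed making the simulation fully reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cell_population()], [render_config()]
#' @export
sim_config <- function(n_cells = 100,
                       frac_dividing = 0.5,
                       duration_h = 48,
                       sampling_interval_h = 0.25,
                       gf_time_h = 1,
                       plateau_median_nondiv = 1.2,
                       effect_size = c(0.3, 0.15),
                       noise_sd = 0.1,
                       cell_sd = 0.12,
                       ar_coeff = 0.8,
                       rho_div = 0.3,
                       rho_nondiv = 0.7,
                       division_window_h = c(16, 36),
                       drop_frac = 0.5,
                       drop_span_frames = 2,
                       baseline_activity = 0.4,
                       rise_tau_h = 0.15,
                       arena_px = c(400, 400),
                       motion_sd_px = 0.8,
                       boundary = c("reflect", "absorb"),
                       pulsing = FALSE,
                       pulse_amp = 0.1,
                       pulse_period_h = 2,
                       seed = 1L) {
  boundary <- match.arg(boundary)
  if (length(n_cells) != 1 || n_cells <= 0 || n_cells != round(n_cells))
    stop("n_cells must be a positive integer")
  if (frac_dividing < 0 || frac_dividing > 1)
    stop("frac_dividing must lie in [0, 1]")
  if (duration_h <= 0 || sampling_interval_h <= 0)
    stop("duration_h and sampling_interval_h must be positive")
  if (length(division_window_h) != 2 || diff(division_window_h) <= 0)
    stop("division_window_h must be an increasing (lo, hi) pair")
  if (division_window_h[1] <= gf_time_h || division_window_h[2] >= duration_h)
    stop("division_window_h must lie strictly inside (gf_time_h, duration_h)")
  if (abs(rho_div) > 1 || abs(rho_nondiv) > 1)
    stop("rho_div and rho_nondiv must lie in [-1, 1]")
  if (ar_coeff < 0 || ar_coeff >= 1) stop("ar_coeff must lie in [0, 1)")
  if (drop_frac <= 0 || drop_frac > 1) stop("drop_frac must lie in (0, 1]")
  if (drop_span_frames < 1) stop("drop_span_frames must be >= 1")
  if (!length(effect_size) %in% c(1, 2))
    stop("effect_size must be a scalar or length-2 (ERK, Akt) vector")
  cfg <- list(
    n_cells = as.integer(n_cells), frac_dividing = frac_dividing,
    duration_h = duration_h, sampling_interval_h = sampling_interval_h,
    gf_time_h = gf_time_h,
    plateau_median_nondiv = plateau_median_nondiv,
    effect_size = if (length(effect_size) == 1) rep(effect_size, 2) else effect_size,
    noise_sd = noise_sd, cell_sd = cell_sd, ar_coeff = ar_coeff,
    rho_div = rho_div, rho_nondiv = rho_nondiv,
    division_window_h = division_window_h,
    drop_frac = drop_frac, drop_span_frames = as.integer(drop_span_frames),
    baseline_activity = baseline_activity, rise_tau_h = rise_tau_h,
    arena_px = as.integer(arena_px), motion_sd_px = motion_sd_px,
    boundary = boundary,
    pulsing = isTRUE(pulsing), pulse_amp = pulse_amp,
    pulse_period_h = pulse_period_h,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Number of frames implied by a simulation configuration
#'
#' Frame 0 is the first baseline image, so a 48 h course at 0.25 h spacing
#' has 48/0.25 + 1 = 193 frames.
#'
#' @param config a [sim_config()].
#' @return integer frame count.
#' @export
n_frames <- function(config) {
  as.integer(round(config$duration_h / config$sampling_interval_h)) + 1L
}

#' Frame times in hours
#'
#' @param config a [sim_config()].
#' @return numeric vector, `time_h = frame * sampling_interval_h` for
#'   frames 0, 1, ....
#' @export
frame_times <- function(config) {
  (seq_len(n_frames(config)) - 1) * config$sampling_interval_h
}

#' Rendering configuration for synthetic KTR movies
#'
#' Geometry and photometry of the movie renderer. Each cell is drawn as a
#' filled nuclear disk (nuclear-marker channel) plus a cytoplasmic annulus
#' (KTR channels); the split of a fixed total KTR intensity between the
#' two compartments encodes the cell's C/N ratio.
#'
#' `psf_sigma_px = 0` by default: the renderer's primary job is to provide
#' movies whose quantification has an exact closed-form ground truth, and
#' optical blur mixes compartment intensities at the boundaries. Blur can
#' be switched on for robustness checks.
#'
#' @param image_shape length-2 (rows, cols) in pixels.
#' @param nucleus_radius_px nuclear disk radius, px (>= 3).
#' @param cyto_radius_px outer radius of the cytoplasmic annulus, px
#'   (> nucleus_radius_px).
#' @param psf_sigma_px Gaussian blur sigma, px (0 = no blur).
#' @param background_offset additive camera background, intensity units.
#' @param flatfield_amplitude amplitude of the multiplicative shading
#'   field `1 + amplitude * f(x, y)` (0 = flat illumination).
#' @param gaussian_noise_sd additive Gaussian noise sd, intensity units.
#' @param total_ktr_intensity per-pixel intensity budget split between the
#'   nuclear and cytoplasmic compartments.
#' @return An object of class `render_config`.
#' @seealso [render_timelapse()]
#' @export
render_config <- function(image_shape = c(256, 256),
                          nucleus_radius_px = 8,
                          cyto_radius_px = 20,
                          psf_sigma_px = 0,
                          background_offset = 100,
                          flatfield_amplitude = 0,
                          gaussian_noise_sd = 0,
                          total_ktr_intensity = 1000) {
  if (cyto_radius_px <= nucleus_radius_px || nucleus_radius_px < 3)
    stop("need cyto_radius_px > nucleus_radius_px >= 3")
  if (background_offset < 0 || gaussian_noise_sd < 0 || total_ktr_intensity < 0)
    stop("intensities must be >= 0")
  cfg <- list(image_shape = as.integer(image_shape),
              nucleus_radius_px = nucleus_radius_px,
              cyto_radius_px = cyto_radius_px,
              psf_sigma_px = psf_sigma_px,
              background_offset = background_offset,
              flatfield_amplitude = flatfield_amplitude,
              gaussian_noise_sd = gaussian_noise_sd,
              total_ktr_intensity = total_ktr_intensity)
  class(cfg) <- "render_config"
  cfg
}
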