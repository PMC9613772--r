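#' Simulate a population of single cells with known division fates
#'
#' Generates ground-truth ERK/Akt activity time courses and motion paths
#' for `n_cells` cells. Exactly `round(frac_dividing * n_cells)` cells
#' divide, at times drawn uniformly from `division_window_h` (one division
#' per cell at most). Latent activity is a baseline followed by a rapid
#' logistic rise after growth-factor addition to a noisy plateau whose
#' long-run median is `plateau_median_nondiv` (plus `effect_size` for
#' dividing cells), with AR(1) noise whose per-frame ERK/Akt innovations
#' are bivariate normal at the class's target correlation (`rho_div` or
#' `rho_nondiv`). The observed C/N trace equals the latent activity except
#' at division, where it is multiplied by `1 - drop_frac` over
#' `drop_span_frames` frames (the steep drop a mitotic morphology change
#' produces); afterwards the trace continues as the tracked daughter.
#'
#' @param config a [sim_config()].
#' @param inhibit "none" (default), "erk" or "akt": clamp that channel's
#'   latent activity at baseline, emulating a specific pathway inhibitor
#'   in a perturbation experiment.
#' @param include_traces build the long trace table (set FALSE to skip
#'   it in statistics-only simulation studies; the per-cell series are
#'   always present).
#' @return A list with elements
#'   \describe{
#'     \item{cells}{list of ground-truth cells; each has `cell_id`,
#'       `divides`, `division_time_h` (NA if none), `division_frame`,
#'       `erk_activity`, `akt_activity` (latent), `cn_erk`, `cn_akt`
#'       (observed C/N incl. division drop), `path` (frames x 2 matrix of
#'       (row, col) pixel centroids) and `in_frame` (logical per frame).}
#'     \item{traces}{long data.frame: cell_id, frame (0-based), time_h,
#'       channel ("ERK"/"Akt"), cn_ratio.}
#'     \item{ground_truth}{data.frame: cell_id, divides, division_time_h,
#'       division_frame.}
#'     \item{config}{the input config (with `inhibit` recorded).}
#'   }
#' @examples
#' pop <- simulate_cell_population(sim_config(n_cells = 10, seed = 1))
#' table(pop$ground_truth$divides)
#' @export
simulate_cell_population <- function(config, inhibit = c("none", "erk", "akt"),
                                     include_traces = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  inhibit <- match.arg(inhibit)
  nf <- n_frames(config)
  tt <- frame_times(config)
  n <- config$n_cells

  set.seed(config$seed)
  n_div <- as.integer(round(config$frac_dividing * n))
  divides <- rep(FALSE, n)
  if (n_div > 0) divides[sample.int(n, n_div)] <- TRUE

  division_time <- rep(NA_real_, n)
  division_frame <- rep(NA_integer_, n)
  if (n_div > 0) {
    raw <- stats::runif(n_div, config$division_window_h[1],
                        config$division_window_h[2])
    fr <- as.integer(round(raw / config$sampling_interval_h))
    division_frame[divides] <- fr
    division_time[divides] <- fr * config$sampling_interval_h
  }

  paths <- simulate_paths(config, n, nf)

  # deterministic mean curve per channel; rise midpoint sits 5 time
  # constants past growth-factor addition so baseline is clean
  rise <- stats::plogis((tt - config$gf_time_h - 5 * config$rise_tau_h) /
                          config$rise_tau_h)
  pulse <- if (config$pulsing) {
    config$pulse_amp * sin(2 * pi * (tt - config$gf_time_h) /
                             config$pulse_period_h) * rise
  } else 0

  sd_innov <- config$noise_sd * sqrt(1 - config$ar_coeff^2)
  cells <- vector("list", n)
  # Per-cell plateau offsets are independent across channels, so one
  # channel's median carries no fate information beyond the other's;
  # rho targets apply to the within-cell per-frame innovations, and the
  # pooled (cell, time) correlation approaches them when the plateau is
  # noise-dominated (cell_sd small relative to noise_sd).
  for (i in seq_len(n)) {
    rho <- if (divides[i]) config$rho_div else config$rho_nondiv
    off <- stats::rnorm(2, sd = config$cell_sd)
    plateau <- config$plateau_median_nondiv + off +
      if (divides[i]) config$effect_size else c(0, 0)
    mean_erk <- config$baseline_activity +
      (plateau[1] - config$baseline_activity) * rise + pulse
    mean_akt <- config$baseline_activity +
      (plateau[2] - config$baseline_activity) * rise + pulse
    if (inhibit == "erk") mean_erk <- rep(config$baseline_activity, nf)
    if (inhibit == "akt") mean_akt <- rep(config$baseline_activity, nf)

    e <- ar1_bivariate(nf, config$ar_coeff, rho, config$noise_sd, sd_innov)
    erk <- mean_erk + e[, 1]
    akt <- mean_akt + e[, 2]

    cn_erk <- erk
    cn_akt <- akt
    if (divides[i]) {
      d0 <- division_frame[i] + 1L          # 1-based index of drop start
      d1 <- min(d0 + config$drop_span_frames - 1L, nf)
      cn_erk[d0:d1] <- cn_erk[d0:d1] * (1 - config$drop_frac)
      cn_akt[d0:d1] <- cn_akt[d0:d1] * (1 - config$drop_frac)
    }

    cells[[i]] <- list(
      cell_id = i, divides = divides[i],
      division_time_h = division_time[i],
      division_frame = division_frame[i],
      erk_activity = erk, akt_activity = akt,
      cn_erk = cn_erk, cn_akt = cn_akt,
      path = paths$path[[i]], in_frame = paths$in_frame[[i]])
  }

  traces <- NULL
  if (include_traces) {
    traces <- data.frame(
      cell_id = rep(rep(seq_len(n), each = nf), 2),
      frame = rep.int(seq_len(nf) - 1L, 2L * n),
      time_h = rep.int(tt, 2L * n),
      channel = rep(c("ERK", "Akt"), each = n * nf),
      cn_ratio = c(unlist(lapply(cells, `[[`, "cn_erk")),
                   unlist(lapply(cells, `[[`, "cn_akt"))))
    traces <- traces[order(traces$cell_id, traces$frame, traces$channel), ]
    rownames(traces) <- NULL
  }

  ground_truth <- data.frame(
    cell_id = seq_len(n), divides = divides,
    division_time_h = division_time, division_frame = division_frame)

  config$inhibit <- inhibit
  list(cells = cells, traces = traces, ground_truth = ground_truth,
       config = config)
}

# stationary bivariate AR(1): innovations correlated `rho`, marginal
# stationary sd `sd_stat`
ar1_bivariate <- function(nf, ar, rho, sd_stat, sd_innov) {
  z <- matrix(stats::rnorm(2L * nf), nf, 2)
  r <- min(max(rho, -1), 1)
  z[, 2] <- r * z[, 1] + sqrt(max(0, 1 - r^2)) * z[, 2]
  e <- matrix(0, nf, 2)
  e[1, ] <- z[1, ] * sd_stat
  if (nf > 1) for (t in 2:nf) e[t, ] <- ar * e[t - 1, ] + sd_innov * z[t, ]
  e
}

# random-walk motion paths; "reflect" keeps cells inside a safety margin,
# "absorb" drops a cell once it first leaves the arena
simulate_paths <- function(config, n, nf) {
  dims <- config$arena_px
  margin <- 26
  lo <- c(margin, margin)
  hi <- dims - margin - 1
  if (any(hi <= lo)) stop("arena_px too small for the placement margin")
  min_spacing <- 40

  start <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(2000)) {
      cand <- c(stats::runif(1, lo[1], hi[1]), stats::runif(1, lo[2], hi[2]))
      if (i == 1 || n > 48 ||     # spacing only enforced at renderable scale
          min(sqrt(rowSums((start[seq_len(i - 1), , drop = FALSE] -
                              matrix(cand, i - 1, 2, byrow = TRUE))^2))) >=
            min_spacing) {
        start[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not place cell ", i, " without overlap; ",
                      "enlarge arena_px or reduce n_cells")
  }

  path <- vector("list", n)
  in_frame <- vector("list", n)
  for (i in seq_len(n)) {
    steps <- matrix(stats::rnorm(2L * nf, sd = config$motion_sd_px), nf, 2)
    steps[1, ] <- 0
    p <- apply(steps, 2, cumsum) + matrix(start[i, ], nf, 2, byrow = TRUE)
    inside <- rep(TRUE, nf)
    if (config$boundary == "reflect") {
      for (k in 1:2) {
        span <- hi[k] - lo[k]
        x <- (p[, k] - lo[k]) %% (2 * span)
        p[, k] <- lo[k] + ifelse(x > span, 2 * span - x, x)
      }
    } else {
      out <- p[, 1] < 0 | p[, 1] > dims[1] - 1 | p[, 2] < 0 | p[, 2] > dims[2] - 1
      if (any(out)) inside[min(which(out)):nf] <- FALSE
    }
    path[[i]] <- p
    in_frame[[i]] <- inside
  }
  list(path = path, in_frame = in_frame)
}
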