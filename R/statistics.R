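#' Analysis window specification
#'
#' The default 8.5-40 h window (inclusive at both ends) covers the S-G2
#' phases after growth-factor treatment, past the restriction point, and
#' is the interval over which per-cell median activities and pooled
#' correlations are computed.
#'
#' @param t_lo_h,t_hi_h window ends in hours, `t_lo_h < t_hi_h`.
#' @param min_points minimum in-window frames for a windowed median to be
#'   reported (truncated traces with fewer frames yield `NA`).
#' @return object of class `window_spec`.
#' @export
window_spec <- function(t_lo_h = 8.5, t_hi_h = 40, min_points = 10) {
  if (t_lo_h >= t_hi_h) stop("need t_lo_h < t_hi_h")
  structure(list(t_lo_h = t_lo_h, t_hi_h = t_hi_h,
                 min_points = as.integer(min_points)),
            class = "window_spec")
}

#' Windowed median activity of a single-cell trace
#'
#' Median of the trace over frames whose time lies inside the window
#' (both ends inclusive). A trace truncated before a detected division
#' contributes only its surviving frames.
#'
#' @param trace numeric activity series (possibly truncated).
#' @param times_h frame times aligned with `trace` (only the first
#'   `length(trace)` entries are used).
#' @param window a [window_spec()].
#' @return the median, or `NA` when fewer than `min_points` frames fall
#'   inside the window.
#' @export
window_median <- function(trace, times_h, window = window_spec()) {
  if (length(times_h) < length(trace)) stop("times shorter than trace")
  t <- times_h[seq_along(trace)]
  sel <- t >= window$t_lo_h & t <= window$t_hi_h
  if (sum(sel) < window$min_points) return(NA_real_)
  stats::median(trace[sel])
}

#' Right-tailed Wilcoxon rank-sum test
#'
#' Tests whether `x` (dividing-cell medians) is stochastically greater
#' than `y` (non-dividing). The statistic is the sum of ranks of `x` in
#' the pooled sample. With `n_x + n_y <= 12` and no ties the p-value is
#' computed by exact enumeration of all rank assignments; otherwise by
#' the normal approximation with tie correction and a 0.5 continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list (class `ranksum_result`): statistic (rank-sum W of `x`),
#'   p_value, n_x, n_y, tail = "right", exact flag.
#' @examples
#' ranksum_right(c(4, 5, 6), c(1, 2, 3))$p_value  # 1/20 = 0.05
#' @export
ranksum_right <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  ties <- anyDuplicated(c(x, y)) > 0
  if (N <= 12 && !ties) {
    combs <- utils::combn(N, nx)
    sums <- colSums(matrix(seq_len(N)[combs], nrow = nx))
    p <- mean(sums >= W)
    exact <- TRUE
  } else {
    mu <- nx * (N + 1) / 2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    v <- nx * ny / 12 * ((N + 1) - tie_term)
    z <- (W - mu - 0.5) / sqrt(v)
    p <- stats::pnorm(z, lower.tail = FALSE)
    exact <- FALSE
  }
  structure(list(statistic = W, p_value = p, n_x = nx, n_y = ny,
                 tail = "right", exact = exact),
            class = "ranksum_result")
}

#' Logistic regression of division fate on windowed medians
#'
#' Binomial GLM with logit link, `divided ~ median_erk + median_akt`,
#' fitted by iteratively reweighted least squares. Reports the Wald
#' coefficient table and a convergence flag: the fit is flagged
#' non-converged when the IRLS loop fails, the score gradient at the
#' solution exceeds 1e-8, or fitted probabilities hit 0/1
#' (quasi-separation). Divergence is reported, never thrown.
#'
#' @param features data.frame with columns `median_erk`, `median_akt` and
#'   logical/0-1 `divided`; rows with missing medians are an error (drop
#'   them first).
#' @return list (class `logit_fit`): `coefficients` data.frame (term,
#'   estimate, std_error, z, p), `converged`, `separation`, `n`.
#' @export
fit_division_logit <- function(features) {
  need <- c("median_erk", "median_akt", "divided")
  if (!all(need %in% names(features))) stop("missing feature columns")
  if (anyNA(features[need])) stop("missing medians; drop incomplete rows")
  y <- as.integer(features$divided)
  if (length(unique(y)) < 2) stop("both classes required")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(divided ~ median_erk + median_akt,
               data = transform(features, divided = y),
               family = stats::binomial("logit"),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  X <- stats::model.matrix(fit)
  grad <- drop(crossprod(X, y - stats::fitted(fit)))
  converged <- fit$converged && !sep && sqrt(sum(grad^2)) < 1e-8
  cf <- stats::coef(fit)                 # NA for aliased terms
  s <- summary(fit)$coefficients
  se <- z <- p <- rep(NA_real_, length(cf))
  rows <- match(rownames(s), names(cf))
  se[rows] <- s[, 2]; z[rows] <- s[, 3]; p[rows] <- s[, 4]
  coefs <- data.frame(term = c("intercept", "median_erk", "median_akt"),
                      estimate = unname(cf), std_error = se,
                      z = z, p = p, row.names = NULL)
  structure(list(coefficients = coefs, converged = converged,
                 separation = sep, n = length(y)),
            class = "logit_fit")
}

#' Pooled ERK-Akt Pearson correlation for one fate class
#'
#' Pools every (cell, in-window timepoint) pair of one class and returns
#' the Pearson correlation between the paired ERK and Akt activities,
#' with the number of cell-time datapoint combinations. Truncated
#' dividing traces contribute only their surviving in-window frames.
#'
#' @param erk_points,akt_points equal-length paired activity vectors.
#' @param class_label "dividing" or "non-dividing" (recorded in output).
#' @return list (class `correlation_result`): r, n_points, class, band
#'   (NULL until set by [correlation_null_band()]).
#' @export
pooled_pearson <- function(erk_points, akt_points,
                           class_label = c("dividing", "non-dividing")) {
  class_label <- match.arg(class_label)
  ok <- is.finite(erk_points) & is.finite(akt_points)
  x <- erk_points[ok]; y <- akt_points[ok]
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 pooled points")
  structure(list(r = stats::cor(x, y), n_points = length(x),
                 class = class_label, band = NULL),
            class = "correlation_result")
}

#' Null / uncertainty specification for the pooled correlation
#'
#' @param mu length-2 mean vector (ERK, Akt).
#' @param cov 2x2 covariance matrix (symmetric positive semidefinite).
#' @param reps resampling replicates (default 1000).
#' @param percentiles band percentiles (default 5 and 95).
#' @param round_step band ends are rounded *up* to the next multiple
#'   (default 0.01); `round_mode = "half_up"` switches to conventional
#'   rounding for sensitivity checks.
#' @param round_mode "ceiling" (default) or "half_up".
#' @return object of class `correlation_null_spec`.
#' @export
correlation_null_spec <- function(mu, cov, reps = 1000,
                                  percentiles = c(5, 95),
                                  round_step = 0.01,
                                  round_mode = c("ceiling", "half_up")) {
  round_mode <- match.arg(round_mode)
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov))) || any(eigen(cov, TRUE)$values < -1e-10))
    stop("cov must be symmetric positive semidefinite")
  if (reps < 1) stop("reps must be >= 1")
  structure(list(mu = mu, cov = cov, reps = as.integer(reps),
                 percentiles = percentiles, round_step = round_step,
                 round_mode = round_mode),
            class = "correlation_null_spec")
}

round_band_end <- function(x, step, mode) {
  if (mode == "ceiling") ceiling(round(x / step, 9)) * step
  else round(x / step) * step
}

#' Resampling band for a pooled Pearson correlation
#'
#' Draws `n_points` paired samples from the bivariate normal with the
#' spec's mean and covariance, computes the Pearson correlation, repeats
#' `reps` times, and reports the (5th, 95th) percentile range of the
#' resampled coefficients, each end rounded up to the nearest 0.01.
#' Matched point counts are supplied per fate class so each class's
#' band reflects its own sample size.
#'
#' @param spec a [correlation_null_spec()].
#' @param n_points_per_class named integer vector of pooled point counts
#'   (>= 3 each).
#' @param seed integer seed.
#' @return named list of length-2 `(lo, hi)` bands, one per class.
#' @export
correlation_null_band <- function(spec, n_points_per_class, seed = 1L) {
  stopifnot(inherits(spec, "correlation_null_spec"),
            all(n_points_per_class >= 3))
  set.seed(seed)
  sx <- sqrt(spec$cov[1, 1]); sy <- sqrt(spec$cov[2, 2])
  rho <- if (sx > 0 && sy > 0) spec$cov[1, 2] / (sx * sy) else 0
  out <- vector("list", length(n_points_per_class))
  names(out) <- names(n_points_per_class)
  for (k in seq_along(n_points_per_class)) {
    n <- n_points_per_class[k]
    if (abs(abs(rho) - 1) < 1e-12 || sx == 0 || sy == 0) {
      r <- rep(if (sx == 0 || sy == 0) NA_real_ else sign(rho), spec$reps)
    } else {
      zx <- matrix(stats::rnorm(n * spec$reps), n)
      zy <- rho * zx + sqrt(1 - rho^2) * matrix(stats::rnorm(n * spec$reps), n)
      mx <- colMeans(zx); my <- colMeans(zy)
      sxx <- colMeans(zx^2) - mx^2
      syy <- colMeans(zy^2) - my^2
      sxy <- colMeans(zx * zy) - mx * my
      r <- sxy / sqrt(sxx * syy)
    }
    q <- stats::quantile(r, spec$percentiles / 100, names = FALSE, na.rm = TRUE)
    out[[k]] <- c(lo = round_band_end(q[1], spec$round_step, spec$round_mode),
                  hi = round_band_end(q[2], spec$round_step, spec$round_mode))
  }
  out
}

#' Perturbation-based crosstalk effect between two pathway nodes
#'
#' Quantifies whether inhibiting one node changes the other node's
#' activity trajectory: the effect is the time-averaged difference of the
#' population median trajectories (perturbed minus control) over the
#' analysis window, with a cell-level bootstrap confidence interval. An
#' edge is called present only when the CI excludes zero *and* the effect
#' magnitude clears a practical-significance floor (by default 10% of the
#' control trajectory's dynamic range in the window), formalizing a
#' "negligible effect" judgment.
#'
#' @param control,perturbed numeric matrices, cells x frames, on a shared
#'   time grid.
#' @param times_h frame times (hours) shared by both matrices.
#' @param window a [window_spec()] restricting the comparison.
#' @param n_boot bootstrap resamples (default 1000).
#' @param floor_frac practical-significance floor as a fraction of the
#'   control dynamic range (default 0.1); set 0 to disable.
#' @param conf CI coverage (default 0.95, percentile bootstrap).
#' @param seed integer seed for the bootstrap.
#' @return list (class `effect_result`): effect, ci (lo, hi),
#'   edge_present, floor, n_control, n_perturbed.
#' @export
crosstalk_effect <- function(control, perturbed, times_h,
                             window = window_spec(), n_boot = 1000,
                             floor_frac = 0.1, conf = 0.95, seed = 1L) {
  if (ncol(control) != ncol(perturbed) || ncol(control) != length(times_h))
    stop("control and perturbed must share the time grid")
  sel <- times_h >= window$t_lo_h & times_h <= window$t_hi_h
  if (!any(sel)) stop("window contains no timepoints")
  ctl <- control[, sel, drop = FALSE]
  per <- perturbed[, sel, drop = FALSE]
  med_c <- col_medians(ctl)
  med_p <- col_medians(per)
  effect <- mean(med_p - med_c)
  floor <- floor_frac * diff(range(med_c))
  set.seed(seed)
  boots <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    ic <- sample.int(nrow(ctl), replace = TRUE)
    ip <- sample.int(nrow(per), replace = TRUE)
    boots[b] <- mean(col_medians(per[ip, , drop = FALSE]) -
                       col_medians(ctl[ic, , drop = FALSE]))
  }
  a <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  edge <- (ci[1] > 0 || ci[2] < 0) && abs(effect) >= floor
  structure(list(effect = effect, ci = ci, edge_present = edge,
                 floor = floor, n_control = nrow(ctl),
                 n_perturbed = nrow(per)),
            class = "effect_result")
}
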