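test_that("windowed median honors the window, truncation and min_points", {
  tt <- seq(0, 48, by = 0.25)
  expect_equal(window_median(tt, tt), 24.25)        # median of 8.5..40
  expect_equal(window_median(rep(3.7, length(tt)), tt), 3.7)

  # truncation at 20 h: median over [8.5, 20] only, brute force
  trunc <- tt[tt <= 20]
  expect_equal(window_median(trunc, tt),
               median(trunc[trunc >= 8.5 & trunc <= 20]))

  # endpoints are inclusive
  w <- window_spec(1, 3, min_points = 1)
  expect_equal(window_median(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4), w), 2)

  # too few in-window points
  short <- tt[tt <= 9]
  expect_true(is.na(window_median(short, tt)))
})

test_that("rank-sum worked example and degenerate cases", {
  res <- ranksum_right(c(4, 5, 6), c(1, 2, 3))
  expect_equal(res$p_value, 0.05)
  expect_identical(res$statistic, 15)
  expect_true(res$exact)

  same <- ranksum_right(c(1, 2, 3, 4) + 10, c(1, 2, 3, 4) + 10)
  expect_lt(abs(same$p_value - 0.5), 0.1)

  expect_error(ranksum_right(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum path matches the independent enumeration oracle", {
  set.seed(61)
  for (rep in 1:60) {
    nx <- sample(1:6, 1); ny <- sample(1:6, 1)
    v <- sample(1000, nx + ny)          # no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    p_ref <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_lt(abs(ranksum_right(x, y)$p_value - p_ref), 1e-12)
  }
})

test_that("tied / large samples use the corrected normal approximation", {
  set.seed(62)
  x <- sample(1:8, 30, replace = TRUE)
  y <- sample(1:8, 35, replace = TRUE)
  p_ref <- wilcox.test(x, y, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(ranksum_right(x, y)$p_value - p_ref), 1e-10)
})

test_that("logistic fit is symmetric, consistent and flags separation", {
  # mirror-symmetric overlapping features, balanced classes -> zero
  # intercept (each row (e, a, 1) has a mirrored partner (-e, -a, 0))
  e <- c(1, -0.9, 0.2, -1, 0.9, -0.2)
  a <- c(0, 0.1, -1, 0, -0.1, 1)
  y <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  f <- fit_division_logit(data.frame(median_erk = e, median_akt = a,
                                     divided = y))
  expect_false(f$separation)
  expect_lt(abs(f$coefficients$estimate[1]), 1e-6)

  set.seed(9)
  n <- 5000
  erk <- rnorm(n); akt <- rnorm(n)
  y <- runif(n) < plogis(-1 + 2 * erk)
  fit <- fit_division_logit(data.frame(median_erk = erk, median_akt = akt,
                                       divided = y))
  expect_true(fit$converged)
  co <- fit$coefficients
  truth <- c(-1, 2, 0)
  expect_true(all(abs(co$estimate - truth) < 3 * co$std_error))

  sepdat <- data.frame(median_erk = c(-2, -1, 1, 2),
                       median_akt = c(0.1, -0.1, 0.2, -0.2),
                       divided = c(FALSE, FALSE, TRUE, TRUE))
  sfit <- fit_division_logit(sepdat)
  expect_false(sfit$converged)
  expect_true(sfit$separation)
  expect_gt(abs(sfit$coefficients$estimate[2]), 5)  # diverging slope

  expect_error(fit_division_logit(
    data.frame(median_erk = 1:4, median_akt = 1:4, divided = TRUE)),
    "both classes")
})

test_that("pooled Pearson correlation equals the textbook formula", {
  e <- c(1.2, 1.4, 1.1, 1.8, 1.6, 1.3)
  a <- c(0.9, 1.3, 1.0, 1.5, 1.6, 1.1)
  hand <- sum((e - mean(e)) * (a - mean(a))) /
    sqrt(sum((e - mean(e))^2) * sum((a - mean(a))^2))
  res <- pooled_pearson(e, a, "dividing")
  expect_equal(res$r, hand)
  expect_identical(res$n_points, 6L)

  expect_equal(pooled_pearson(e, 2 * e + 1, "dividing")$r, 1)
  expect_equal(pooled_pearson(e, -e, "non-dividing")$r, -1)
  expect_error(pooled_pearson(1:2, 1:2), "at least 3")
})

test_that("correlation band covers, degenerates and rounds as specified", {
  sp0 <- correlation_null_spec(mu = c(0, 0), cov = diag(2))
  b0 <- correlation_null_band(sp0, c(x = 10000), seed = 5)$x
  expect_gte(b0["lo"], -0.04)
  expect_lte(b0["hi"], 0.04)

  sing <- correlation_null_spec(mu = c(0, 0),
                                cov = matrix(c(1, 1, 1, 1), 2))
  bs <- correlation_null_band(sing, c(x = 50), seed = 1)$x
  expect_equal(unname(bs), c(1, 1))

  cv <- matrix(c(1, 0.6, 0.6, 1), 2)
  sp <- correlation_null_spec(mu = c(0, 0), cov = cv)
  b <- correlation_null_band(sp, c(x = 200), seed = 2)$x
  expect_true(b["lo"] <= 0.6 && 0.6 <= b["hi"])

  # band ends are ceiling-rounded to the next 0.01
  expect_identical(unname(b * 100), round(unname(b * 100)))
  raw <- quantile(c(0.5512, 0.553, 0.6241, 0.7), c(0.05, 0.95))
  expect_equal(ktrfate:::round_band_end(0.5512, 0.01, "ceiling"), 0.56)
  expect_equal(ktrfate:::round_band_end(0.55, 0.01, "ceiling"), 0.55)
  expect_equal(ktrfate:::round_band_end(-0.123, 0.01, "ceiling"), -0.12)
  expect_equal(ktrfate:::round_band_end(0.5512, 0.01, "half_up"), 0.55)

  expect_error(correlation_null_spec(c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "semidefinite")
})

test_that("crosstalk effect measures shifts and respects the floor", {
  set.seed(3)
  tt <- seq(0, 12, by = 0.25)
  rise <- plogis((tt - 1.5) / 0.2)
  ctl <- t(replicate(30, 0.4 + 0.8 * rise + rnorm(length(tt), sd = 0.05)))
  w <- window_spec(0, 12, min_points = 1)

  same <- crosstalk_effect(ctl, ctl, tt, w, n_boot = 200, seed = 1)
  expect_equal(same$effect, 0)
  expect_false(same$edge_present)

  shifted <- crosstalk_effect(ctl, ctl - 0.3, tt, w, n_boot = 200, seed = 1)
  expect_lt(abs(shifted$effect + 0.3), 1e-9)
  expect_true(shifted$edge_present)
  expect_true(shifted$ci[1] <= shifted$effect &&
                shifted$effect <= shifted$ci[2])

  # a shift below the practical floor is not an edge even if CI excludes 0
  tiny <- crosstalk_effect(ctl, ctl - 0.01, tt, w, n_boot = 200, seed = 1)
  expect_false(tiny$edge_present)

  expect_error(crosstalk_effect(ctl, ctl[, 1:10], tt, w), "time grid")
})
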