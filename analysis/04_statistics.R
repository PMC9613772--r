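#!/usr/bin/env Rscript
# Step 4: the statistical analysis.
#
# From the simulated study traces: windowed medians per cell, right-
# tailed rank-sum comparison of dividing vs non-dividing medians,
# logistic regression of division on (median ERK, median Akt), pooled
# ERK-Akt correlation per fate class with MVN resampling bands, and
# figures. Writes results/features.csv, results/stats_report.json and
# PNG figures under results/figures/.

suppressPackageStartupMessages({
  library(ktrfate)
  library(jsonlite)
})

if (!file.exists("results/traces.csv"))
  stop("run analysis/01_simulate.R first")
traces <- read_trace_csv("results/traces.csv")
res <- run_trace_pipeline(traces)
feat <- res$features
write.csv(feat, "results/features.csv", row.names = FALSE)

report <- list()

for (ch in c("median_erk", "median_akt")) {
  rs <- ranksum_right(feat[[ch]][feat$divided], feat[[ch]][!feat$divided])
  report[[paste0("ranksum_", ch)]] <-
    list(W = rs$statistic, p = rs$p_value, n_div = rs$n_x, n_nondiv = rs$n_y)
  message(sprintf("%s: dividing > non-dividing, right-tailed rank-sum p = %.3g",
                  ch, rs$p_value))
}

fit <- fit_division_logit(feat)
report$logit <- fit$coefficients
message("logistic regression of division on windowed medians:")
print(fit$coefficients)

pts <- pooled_points(res)
spec_of <- function(df) correlation_null_spec(mu = colMeans(df), cov = cov(df))
corr <- list()
for (cl in c("dividing", "nondividing")) {
  r <- pooled_pearson(pts[[cl]]$erk, pts[[cl]]$akt,
                      if (cl == "dividing") "dividing" else "non-dividing")
  band <- correlation_null_band(spec_of(pts[[cl]]),
                                stats::setNames(r$n_points, cl), seed = 4)[[cl]]
  corr[[cl]] <- list(r = r$r, n_points = r$n_points,
                     band_lo = band[["lo"]], band_hi = band[["hi"]])
  message(sprintf("%s: pooled r = %.3f (n = %d), 5-95%% MVN band (%.2f, %.2f)",
                  cl, r$r, r$n_points, band[["lo"]], band[["hi"]]))
}
report$correlation <- corr

write_json(report, "results/stats_report.json", auto_unbox = TRUE,
           digits = 6, dataframe = "rows")

## figures ---------------------------------------------------------------------
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  feat$fate <- ifelse(feat$divided, "dividing", "non-dividing")

  p1 <- ggplot(feat, aes(fate, median_erk, colour = fate)) +
    geom_jitter(width = 0.15, alpha = 0.5) +
    geom_boxplot(outlier.shape = NA, fill = NA) +
    labs(y = "median ERK activity, 8.5-40 h (C/N)", x = NULL) +
    theme_classic() + theme(legend.position = "none")
  ggsave("results/figures/medians_by_fate.png", p1, width = 4, height = 4,
         dpi = 150)

  p2 <- ggplot(feat, aes(median_erk, median_akt, colour = fate)) +
    geom_point(alpha = 0.6) +
    labs(x = "median ERK (C/N)", y = "median Akt (C/N)") +
    theme_classic()
  ggsave("results/figures/erk_vs_akt_medians.png", p2, width = 5, height = 4,
         dpi = 150)

  pooled <- rbind(cbind(pts$dividing, fate = "dividing"),
                  cbind(pts$nondividing, fate = "non-dividing"))
  p3 <- ggplot(pooled, aes(erk, akt)) +
    geom_point(alpha = 0.05, size = 0.3) +
    facet_wrap(~fate) +
    labs(x = "ERK activity (C/N)", y = "Akt activity (C/N)") +
    theme_classic()
  ggsave("results/figures/pooled_correlation.png", p3, width = 7, height = 3.5,
         dpi = 150)
  message("wrote figures under results/figures/")
}
message("wrote results/features.csv and results/stats_report.json")
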