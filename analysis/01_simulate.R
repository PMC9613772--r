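#!/usr/bin/env Rscript
# Step 1: simulate the study population.
#
# 300 cells imaged every 15 min for 48 h, growth factor at 1 h, half the
# cells dividing between 16 and 36 h. Writes the observed C/N trace table
# and the ground truth to results/, plus a small rendered demo movie
# (4 cells, 2 h) to scratch/ for visual inspection.

suppressPackageStartupMessages(library(ktrfate))

cfg <- sim_config(n_cells = 300, seed = 1)
pop <- simulate_cell_population(cfg)

dir.create("results", showWarnings = FALSE)
write_fixture(traces = pop$traces, out_dir = "results",
              ground_truth = pop$ground_truth)

n_div <- sum(pop$ground_truth$divides)
message(sprintf("simulated %d cells (%d dividing, %d non-dividing), %d frames each",
                cfg$n_cells, n_div, cfg$n_cells - n_div, n_frames(cfg)))
message("wrote results/traces.csv and results/ground_truth.csv")

# small movie for eyeballing the rendering (binary output -> scratch/)
demo_cfg <- sim_config(n_cells = 4, frac_dividing = 0.25, duration_h = 2,
                       division_window_h = c(1.2, 1.8), motion_sd_px = 0.5,
                       seed = 2)
demo <- simulate_cell_population(demo_cfg)
img <- render_timelapse(demo$cells, render_config(image_shape = c(400, 400)),
                        demo_cfg)
dir.create("scratch", showWarnings = FALSE)
write_fixture(images = img, out_dir = "scratch")
message("wrote demo movie TIFFs under scratch/")
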