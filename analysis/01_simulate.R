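#!/usr/bin/env Rscript
# Step 1 — simulate the two-group droplet experiment.
#
# Generates synthetic fluorescence scenes of a mucus droplet meeting a
# bacterial suspension for the two phenotypes:
#   suckling-like: low penetration (lambda_inf = 37 um), heavy bacterial
#     accumulation and aggregation just outside the droplet boundary;
#   weaned-like: high penetration (lambda_inf = 115 um), aggregates inside
#     the droplet, weak exterior accumulation.
# Two designs are written:
#   (a) endpoint: 7 samples x 4 replicate droplets per group, one frame at
#       T = 120 min (the design used for the group statistics);
#   (b) timecourse: 2 samples x 2 replicates per group, 13 frames over
#       0-120 min (for the lambda_p(t) curves).
# Scenes are 512 x 512 px at 2 um/px with the droplet center near a corner:
# roughly a one-quarter field of view of a full 916 +/- 96 um droplet, as in
# the reference acquisitions where the field covers part of each droplet.

suppressMessages(library(mucotrace))

seed <- 20260923L
sim_dir <- "scratch/simulated"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

quarter <- function(preset, ...)
  do.call(preset, list(image_shape = c(512L, 512L), pixel_size = 2,
                       droplet_center = c(20, 20), ...))

message("Generating endpoint experiment (7 x 4 per group, T = 120 min) ...")
man_end <- generate_group(
  quarter(preset_suckling, n_frames = 1L, t_start = 120),
  quarter(preset_weaned, n_frames = 1L, t_start = 120),
  n_per_group = 7L, replicates = 4L,
  out_dir = file.path(sim_dir, "endpoint"), seed = derive_seed(seed, 1L))
message("  ", nrow(man_end), " stacks written")

message("Generating timecourse experiment (2 x 2 per group, 13 frames) ...")
man_tc <- generate_group(
  quarter(preset_suckling, n_frames = 13L, frame_interval = 10),
  quarter(preset_weaned, n_frames = 13L, frame_interval = 10),
  n_per_group = 2L, replicates = 2L,
  out_dir = file.path(sim_dir, "timecourse"), seed = derive_seed(seed, 2L))
message("  ", nrow(man_tc), " stacks written")

message("Done. Ground-truth boundaries, parameter sidecars and manifests are ",
        "next to the stacks under ", sim_dir)
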