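#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study system.
#
# Two generators stand in for the all-atom production runs:
#   (a) confined Brownian particles in the star-modulated cylindrical pore
#       (the positional trajectory all spatial analyses run on), and
#   (b) exponential dwell processes for three species with different exit
#       rates (the residency ground truth for survival analysis), ordered
#       like the study system: cations resident longest, anions shortest.
#
# Outputs: results/synthetic_trajectory.txt (fixture dialect),
#          results/ground_truth.json

suppressPackageStartupMessages(library(poredyn))
dir.create("results", showWarnings = FALSE)
seed <- 20260923L

params <- pore_model_params(dt = 0.05, seed = seed)   # defaults = study pore
sim <- simulate_confined_brownian(params, n_particles = 150, duration = 1000)
write_fixture_trajectory(sim$traj, "results/synthetic_trajectory.txt")
cat(sprintf("trajectory: %d particles x %d frames (%.0f ps), pore R = %.1f A\n",
            sim$traj$n_particles, sim$traj$n_frames,
            max(sim$traj$times), params$radius))

species <- list(
  cation = dwell_process_params(lambda_in = 0.02, lambda_out = 0.02,
                                n_particles = 80, duration = 4000,
                                seed = seed + 1),
  water  = dwell_process_params(lambda_in = 0.05, lambda_out = 0.10,
                                n_particles = 80, duration = 4000,
                                seed = seed + 2),
  anion  = dwell_process_params(lambda_in = 0.01, lambda_out = 0.30,
                                n_particles = 80, duration = 4000,
                                seed = seed + 3))
dwells <- lapply(species, simulate_dwell_process)
for (sp in names(dwells)) {
  flags <- dwells[[sp]]$res$flags
  utils::write.csv(
    data.frame(time_ps = dwells[[sp]]$res$times,
               t(flags) * 1L, check.names = FALSE),
    sprintf("results/residency_%s.csv", sp), row.names = FALSE)
  cat(sprintf("%-6s: %5d inside dwells, true tau_half %.1f ps\n", sp,
              dwells[[sp]]$truth$n_events, dwells[[sp]]$truth$tau_half_true))
}

truth <- list(
  seed = seed,
  pore = params[c("radius", "length", "angular_amp", "angular_order",
                  "axial_amp", "axial_period", "D")],
  dwell = lapply(dwells, function(d)
    d$truth[c("lambda_in", "lambda_out", "tau_half_true", "n_events")]))
jsonlite::write_json(truth, "results/ground_truth.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = NA)
cat("ground truth written to results/ground_truth.json\n")
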