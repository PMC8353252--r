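make_channel_fixture <- function(tracked_pos, n_frames = 1) {
  # tracked particles at given lab positions + a standard backbone stack
  bb <- ring_stack(n_frames = n_frames)
  n_bb <- dim(bb)[1]
  n_tr <- nrow(tracked_pos)
  coords <- array(NA_real_, dim = c(n_tr + n_bb, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[seq_len(n_tr), , f] <- tracked_pos
    coords[n_tr + seq_len(n_bb), , f] <- bb[, , f]
  }
  make_traj(coords, groups = list(tracked = seq_len(n_tr),
                                  backbone = n_tr + seq_len(n_bb)))
}

test_that("cylinder criterion classifies midpoint inside and bulk outside", {
  pos <- rbind(c(25, 25, 25),      # on axis at channel midpoint
               c(50, 25, 25),      # R = 25: bulk
               c(25, 25, 48))      # axially beyond the pore
  traj <- make_channel_fixture(pos)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  expect_identical(as.vector(res$flags), c(TRUE, FALSE, FALSE))
  expect_error(classify_inside(traj, geom, "nope"), "nope")
})

test_that("classification equals a brute-force geometric check", {
  set.seed(31)
  nf <- 4
  pos0 <- matrix(runif(40 * 3, 5, 45), ncol = 3)
  bb <- ring_stack(n_frames = nf)
  coords <- array(NA_real_, dim = c(40 + dim(bb)[1], 3, nf))
  for (f in seq_len(nf)) {
    coords[1:40, , f] <- pos0 + matrix(rnorm(120, sd = 2), ncol = 3)
    coords[41:(40 + dim(bb)[1]), , f] <- bb[, , f]
  }
  traj <- make_traj(coords, groups = list(tracked = 1:40,
                                          backbone = 41:(40 + dim(bb)[1])))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  for (f in seq_len(nf)) {
    for (i in 1:40) {
      d <- coords[i, , f] - geom$origin[f, ]
      z <- sum(d * geom$axis[f, ])
      R <- sqrt(sum(d^2) - z^2)
      expect_identical(res$flags[i, f],
                       R <= 9 && z >= geom$z_lo[f] && z <= geom$z_hi[f])
    }
  }
})

test_that("occupancy statistics follow the flag columns", {
  flags <- matrix(TRUE, 4, 10)
  occ <- occupancy_stats(residency(flags), window_start = 0, window_end = 9)
  expect_equal(occ$mean, 4)
  expect_equal(occ$sd, 0)
  # alternating single particle: mean 0.5 over the full window
  flags <- matrix(rep(c(TRUE, FALSE), 5), nrow = 1)
  occ <- occupancy_stats(residency(flags), window_start = 0, window_end = 9)
  expect_equal(occ$mean, 0.5)
  expect_error(occupancy_stats(residency(flags), 100, 200), "window")
})

test_that("dwell-process occupancy matches the stationary two-state mean", {
  pars <- dwell_process_params(lambda_in = 0.02, lambda_out = 0.05,
                               n_particles = 150, duration = 3000, seed = 42)
  sim <- simulate_dwell_process(pars)
  occ <- occupancy_stats(sim$res, window_start = 300, window_end = 3000)
  p_in <- pars$lambda_in / (pars$lambda_in + pars$lambda_out)
  expected <- pars$n_particles * p_in
  # binomial SE at one frame; frames are correlated so use 3 SE of that
  se <- sqrt(pars$n_particles * p_in * (1 - p_in))
  expect_lt(abs(occ$mean - expected), 3 * se)
})

test_that("z-traces emit only inside frames and match brute-force histogram", {
  # one particle moving z = 0..9 relative to midpoint, always inside
  nf <- 10
  pos <- t(sapply(0:9, function(z) c(25, 25, 25 + z)))
  bb <- ring_stack(n_frames = nf)
  coords <- array(NA_real_, dim = c(1 + dim(bb)[1], 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- pos[f, ]
    coords[2:(1 + dim(bb)[1]), , f] <- bb[, , f]
  }
  traj <- make_traj(coords, groups = list(tracked = 1L,
                                          backbone = 2:(1 + dim(bb)[1])))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  zt <- z_traces(res, traj, geom, z_bin_width = 1)
  expect_equal(nrow(zt$traces), 10)
  expect_equal(diff(zt$traces$z_A), rep(1, 9), tolerance = 1e-9)
  expect_error(z_traces(res, traj, geom, z_bin_width = 0), "bin width")

  # randomized residency: histogram equals exhaustive (frame, bin) counting
  set.seed(7)
  nfr <- 25
  pos0 <- matrix(runif(12 * 3, 18, 32), ncol = 3)
  bb <- ring_stack(n_frames = nfr)
  coords <- array(NA_real_, dim = c(12 + dim(bb)[1], 3, nfr))
  for (f in seq_len(nfr)) {
    coords[1:12, , f] <- pos0 + matrix(rnorm(36, sd = 4), ncol = 3)
    coords[13:(12 + dim(bb)[1]), , f] <- bb[, , f]
  }
  traj <- make_traj(coords, groups = list(tracked = 1:12,
                                          backbone = 13:(12 + dim(bb)[1])))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  zt <- z_traces(res, traj, geom, z_bin_width = 2)
  edges <- c(zt$histogram$z_bin_center - 1, max(zt$histogram$z_bin_center) + 1)
  brute <- integer(nrow(zt$histogram))
  for (f in seq_len(nfr)) {
    zs <- sapply(which(res$flags[, f]), function(i)
      to_cylindrical(coords[i, , f, drop = FALSE], geom, f)$z)
    if (!length(zs)) next
    occupied <- unique(findInterval(zs, edges, rightmost.closed = TRUE))
    occupied <- occupied[occupied >= 1 & occupied <= length(brute)]
    brute[occupied] <- brute[occupied] + 1L
  }
  expect_equal(zt$histogram$frames_with_presence, brute)
  expect_true(all(zt$histogram$frames_with_presence <= nfr))
})

test_that("double-counting identity and relabeling invariance hold", {
  set.seed(13)
  flags <- matrix(runif(200) < 0.4, 10, 20)
  res <- residency(flags)
  expect_equal(sum(rowSums(flags)), sum(colSums(res$flags)))
  # relabeling particles leaves the z-presence histogram unchanged
  perm <- sample(10)
  pos0 <- matrix(runif(10 * 3, 20, 30), ncol = 3)
  bb <- ring_stack(n_frames = 20)
  coords <- array(NA_real_, dim = c(10 + dim(bb)[1], 3, 20))
  for (f in 1:20) {
    coords[1:10, , f] <- pos0
    coords[11:(10 + dim(bb)[1]), , f] <- bb[, , f]
  }
  traj <- make_traj(coords, groups = list(tracked = 1:10,
                                          backbone = 11:(10 + dim(bb)[1])))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  h1 <- z_traces(residency(flags, particle_ids = 1:10), traj, geom, 1)$histogram
  h2 <- z_traces(residency(flags[perm, ], particle_ids = perm), traj, geom,
                 1)$histogram
  expect_equal(h1$frames_with_presence, h2$frames_with_presence)
})
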