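maps_fixture <- function(tracked_coords, nf = NULL) {
  # tracked_coords: array (n x 3 x nf) of lab positions
  if (is.null(nf)) nf <- dim(tracked_coords)[3]
  bb <- ring_stack(n_frames = nf)
  n <- dim(tracked_coords)[1]
  coords <- array(NA_real_, dim = c(n + dim(bb)[1], 3, nf))
  coords[seq_len(n), , ] <- tracked_coords
  coords[n + seq_len(dim(bb)[1]), , ] <- bb
  make_traj(coords, groups = list(tracked = seq_len(n),
                                  backbone = n + seq_len(dim(bb)[1])))
}

test_that("point masses and symmetric clusters bin as expected", {
  pos <- array(rep(c(27, 25, 25), each = 1), dim = c(1, 3, 1))
  pos[1, , 1] <- c(27, 25, 25)
  traj <- maps_fixture(pos)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- residency(matrix(TRUE, 1, 1), times = 0)
  m <- planar_heatmap(traj, res, geom, "XY", bin_width = 0.5, window_start = 0)
  expect_equal(max(m$prob), 1)
  expect_equal(sum(m$prob), 1)
  # two symmetric clusters of equal size -> two cells at 0.5
  pos <- array(NA_real_, dim = c(2, 3, 1))
  pos[1, , 1] <- c(28, 25, 25); pos[2, , 1] <- c(22, 25, 25)
  traj <- maps_fixture(pos)
  res <- residency(matrix(TRUE, 2, 1), times = 0)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  m <- planar_heatmap(traj, res, geom, "XY", bin_width = 1, window_start = 0)
  expect_equal(sort(m$prob[m$prob > 0]), c(0.5, 0.5))
  expect_error(planar_heatmap(traj, residency(matrix(FALSE, 2, 1), times = 0),
                              geom, "XY", window_start = 0), "empty map")
})

test_that("planar maps equal a brute-force 2D count table", {
  set.seed(50)
  nf <- 5
  pos <- array(runif(50 * 3 * nf, 20, 30), dim = c(50, 3, nf))
  traj <- maps_fixture(pos)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  m <- planar_heatmap(traj, res, geom, "XY", bin_width = 1, window_start = 0)
  # brute force: accumulate channel-frame x, y of inside observations
  cnt <- matrix(0, length(m$x_edges) - 1, length(m$y_edges) - 1)
  for (f in seq_len(nf)) for (i in 1:50) {
    if (!res$flags[i, f]) next
    cyl <- to_cylindrical(pos[i, , f, drop = FALSE], geom, f)
    ix <- findInterval(cyl$x, m$x_edges, rightmost.closed = TRUE)
    iy <- findInterval(cyl$y, m$y_edges, rightmost.closed = TRUE)
    cnt[ix, iy] <- cnt[ix, iy] + 1
  }
  expect_equal(m$prob, cnt / sum(cnt), tolerance = 1e-12)
  expect_equal(sum(m$prob), 1, tolerance = 1e-9)
})

test_that("cylindrical maps normalize and respect ring symmetry", {
  set.seed(51)
  n <- 4000
  th <- runif(n, -pi, pi)
  pos <- array(NA_real_, dim = c(n, 3, 1))
  pos[, 1, 1] <- 25 + 5.3 * cos(th)   # bin-interior radius
  pos[, 2, 1] <- 25 + 5.3 * sin(th)
  pos[, 3, 1] <- 25
  traj <- maps_fixture(pos)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- residency(matrix(TRUE, n, 1), times = 0)
  m <- cylindrical_heatmap(traj, res, geom, r_bins = 9, theta_bins = 12,
                           window_start = 0)
  expect_equal(sum(m$prob), 1, tolerance = 1e-9)
  ring_row <- which(rowSums(m$prob) > 0.99)
  expect_length(ring_row, 1)
  probs <- m$prob[ring_row, ]
  expect_lt(max(abs(probs - 1 / 12)), 4 / sqrt(n))  # uniform within noise
})

test_that("six-fold modulated density peaks at angular harmonic 6", {
  p <- pore_model_params(angular_amp = 2, axial_amp = 0, seed = 60)
  smp <- generate_star_reference_density(p, 20000, seed = 61)
  spec <- theta_spectrum(smp$theta)
  expect_equal(which.max(spec), 6L)
})

test_that("XY map of a symmetric density is invariant under rotation", {
  # six-fold potential: rotating samples by 60 degrees leaves the map alike
  p <- pore_model_params(angular_amp = 2, axial_amp = 0, seed = 62)
  smp <- generate_star_reference_density(p, 30000, seed = 63)
  edges <- seq(0, 9, length.out = 7); tedges <- seq(-pi, pi, length.out = 13)
  t1 <- rtheta_table(smp$R, smp$theta, edges, tedges)
  th_rot <- smp$theta + pi / 3
  th_rot <- ifelse(th_rot >= pi, th_rot - 2 * pi, th_rot)
  t2 <- rtheta_table(smp$R, th_rot, edges, tedges)
  expect_lt(tv_dist(t1, t2), 0.05)
  # with modulation disabled: invariant under an arbitrary rotation
  p0 <- pore_model_params(angular_amp = 0, axial_amp = 0, seed = 64)
  smp0 <- generate_star_reference_density(p0, 30000, seed = 65)
  th_any <- smp0$theta + 1.13
  th_any <- th_any - 2 * pi * floor((th_any + pi) / (2 * pi))
  t3 <- rtheta_table(smp0$R, smp0$theta, edges, tedges)
  t4 <- rtheta_table(smp0$R, th_any, edges, tedges)
  expect_lt(tv_dist(t3, t4), 0.05)
})

test_that("XZ marginal over x reproduces the axial distribution", {
  # single tracked particle: counts marginalized over x equal the z
  # occupancy histogram (presence = counts when at most one particle)
  set.seed(55)
  nf <- 40
  pos <- array(NA_real_, dim = c(1, 3, nf))
  pos[1, 1, ] <- 25 + rnorm(nf, sd = 2)
  pos[1, 2, ] <- 25
  pos[1, 3, ] <- 25 + runif(nf, -15, 15)
  traj <- maps_fixture(pos)
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  res <- classify_inside(traj, geom, "tracked")
  m <- planar_heatmap(traj, res, geom, "XZ", bin_width = 2, window_start = 0)
  zmarg <- colSums(m$prob) * m$n_counts
  zt <- z_traces(res, traj, geom, z_bin_width = 2)
  h <- zt$histogram$frames_with_presence
  # align the two z grids before comparing
  centers_m <- (m$y_edges[-1] + m$y_edges[-length(m$y_edges)]) / 2
  matched <- sapply(centers_m, function(zc) {
    j <- which(abs(zt$histogram$z_bin_center - zc) < 1e-9)
    if (length(j)) h[j] else 0
  })
  expect_equal(as.numeric(zmarg), as.numeric(matched))
})

test_that("backbone overlays average to the ring geometry", {
  traj <- maps_fixture(array(c(25, 25, 25), dim = c(1, 3, 3)))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2)
  ov <- backbone_overlay(traj, geom, list(alpha_carbons = "backbone"), "XY")
  expect_equal(nrow(ov), 96)
  expect_equal(sqrt(ov$u^2 + ov$v^2), rep(9, 96), tolerance = 1e-9)
  expect_error(backbone_overlay(traj, geom, list(carbonyls = "missing"), "XY"),
               "missing")
})

test_that("overlay of a rigidly rotating ring is stationary in the co-rotating frame", {
  th0 <- seq(0, 2 * pi, length.out = 13)[-13]
  zs <- (1:8 - 4.5) * 4.9
  nf <- 6
  coords <- array(NA_real_, dim = c(96, 3, nf))
  for (f in seq_len(nf)) {
    phi <- (f - 1) * 0.4
    pts <- do.call(rbind, lapply(zs, function(z)
      cbind(9 * cos(th0 + phi), 9 * sin(th0 + phi), z)))
    coords[, , f] <- sweep(pts, 2, c(25, 25, 25), "+")
  }
  traj <- make_traj(coords, groups = list(backbone = 1:96, ref = 1L))
  geom <- fit_channel_axis(traj, "backbone", pore_radius = 9, z_pad = 2,
                           theta_ref_group = "ref")
  ov <- backbone_overlay(traj, geom, list(ca = "backbone"), "XY")
  # averaged points stay on the R = 9 circle (no smearing toward the center)
  expect_equal(sqrt(ov$u^2 + ov$v^2), rep(9, 96), tolerance = 1e-6)
})
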