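gas_fixture <- function(n_contrib = 250, nf = 30, box = 30, seed = 70) {
  # one fixed center at the box center + ideal-gas contributors
  set.seed(seed)
  coords <- array(NA_real_, dim = c(1 + n_contrib, 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- c(box / 2, box / 2, box / 2)
    coords[1 + seq_len(n_contrib), , f] <- matrix(runif(3 * n_contrib, 0, box),
                                                  ncol = 3)
  }
  make_traj(coords, box = rep(box, 3),
            groups = list(cation = 1L, water = 1 + seq_len(n_contrib)))
}

test_that("ideal-gas RDF is 1 within shot noise over 3-8 A", {
  traj <- gas_fixture()
  res <- residency(matrix(TRUE, 1, traj$n_frames), times = traj$times)
  prof <- rdf_decomposed(traj, res, "cation", "water", r_max = 8.5, dr = 0.5,
                         window_start = 0)
  sel <- prof$r >= 3 & prof$r <= 8
  counts <- prof$meta$counts[sel, 1]
  expect_true(all(abs(prof$g[sel, 1] - 1) <= 3 / sqrt(counts)))
})

test_that("a delta shell of contributors lands in a single RDF bin", {
  nf <- 2
  dirs <- matrix(rnorm(18), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  coords <- array(NA_real_, dim = c(7, 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- c(15, 15, 15)
    coords[2:7, , f] <- sweep(2.4 * dirs, 2, c(15, 15, 15), "+")
  }
  traj <- make_traj(coords, box = c(30, 30, 30),
                    groups = list(cation = 1L, water = 2:7))
  res <- residency(matrix(TRUE, 1, nf), times = traj$times)
  prof <- rdf_decomposed(traj, res, "cation", "water", r_max = 5, dr = 0.2,
                         window_start = 0)
  occupied <- which(prof$meta$counts[, 1] > 0)
  expect_length(occupied, 1)
  expect_lt(abs(prof$r[occupied] - 2.4), 0.1 + 1e-9)
})

test_that("RDF equals a brute-force pair histogram with identical normalization", {
  set.seed(71)
  nf <- 4
  coords <- array(runif(20 * 3 * nf, 0, 20), dim = c(20, 3, nf))
  traj <- make_traj(coords, box = c(20, 20, 20),
                    groups = list(cation = 1:3, water = 4:20))
  flags <- matrix(runif(3 * nf) < 0.8, 3, nf)
  flags[1, ] <- TRUE
  res <- residency(flags, times = traj$times)
  prof <- rdf_decomposed(traj, res, "cation", "water", r_max = 6, dr = 0.5,
                         window_start = 0)
  edges <- prof$edges
  cnt <- numeric(length(edges) - 1); n_obs <- 0
  for (f in seq_len(nf)) {
    for (ci in which(flags[, f])) {
      n_obs <- n_obs + 1
      for (w in 4:20) {
        d <- coords[ci, , f] - coords[w, , f]
        d <- d - round(d / 20) * 20
        r <- sqrt(sum(d^2))
        if (r < 6) {
          b <- findInterval(r, edges)
          cnt[b] <- cnt[b] + 1
        }
      }
    }
  }
  g_brute <- cnt / (n_obs * 17 * (4 / 3 * pi * diff(edges^3)) / 8000)
  expect_equal(prof$g[, 1], unname(g_brute), tolerance = 1e-12)
})

test_that("first-shell radius is the first post-peak minimum", {
  r <- seq(0.05, 8, by = 0.1)
  g <- 2.5 * exp(-(r - 2.4)^2 / 0.08) + 1 - 0.6 * exp(-(r - 3.0)^2 / 0.05)
  prof <- structure(list(r = r, g = matrix(g, ncol = 1,
                                           dimnames = list(NULL, "water")),
                         edges = c(r - 0.05, max(r) + 0.05)),
                    class = "poredyn_rdf")
  expect_lt(abs(first_shell_radius(prof, "water") - 3.0), 0.15)
  flat <- structure(list(r = r, g = matrix(1, length(r), 1,
                                           dimnames = list(NULL, "water"))),
                    class = "poredyn_rdf")
  expect_error(first_shell_radius(flat, "water"), "no first shell")
})

test_that("first-shell minimum of a two-peak curve sits at the analytic dip", {
  r <- seq(0.05, 10, by = 0.05)
  # two Gaussian shells; the analytic minimum between them is at the
  # zero of the derivative, here symmetric -> midpoint 3.5
  g <- 3 * exp(-(r - 2.5)^2 / 0.18) + 2 * exp(-(r - 4.5)^2 / 0.18) + 0.02
  prof <- structure(list(r = r, g = matrix(g, ncol = 1,
                                           dimnames = list(NULL, "w"))),
                    class = "poredyn_rdf")
  f <- function(x) 3 * exp(-(x - 2.5)^2 / 0.18) + 2 * exp(-(x - 4.5)^2 / 0.18)
  analytic <- stats::optimize(f, c(2.5, 4.5))$minimum
  expect_lt(abs(first_shell_radius(prof, "w") - analytic), 0.05 + 1e-9)
})

test_that("coordination numbers: direct count, brute force, RDF integral agree", {
  # fixed contributors at 2.0 A: mean 6, sd 0
  nf <- 2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  coords <- array(NA_real_, dim = c(7, 3, nf))
  for (f in seq_len(nf)) {
    coords[1, , f] <- c(15, 15, 15)
    coords[2:7, , f] <- sweep(2.0 * dirs, 2, c(15, 15, 15), "+")
  }
  traj <- make_traj(coords, box = c(30, 30, 30),
                    groups = list(cation = 1L, water = 2:7))
  res <- residency(matrix(TRUE, 1, nf), times = traj$times)
  tab <- coordination_numbers(traj, res, "cation", "water", 3.2,
                              window_start = 0)
  expect_equal(tab$mean, 6)
  expect_equal(tab$sd, 0)
  tab0 <- coordination_numbers(traj, res, "cation", "water", 1.0,
                               window_start = 0)
  expect_equal(tab0$mean, 0)

  # ideal gas: direct counting vs brute force vs 4 pi rho int g r^2 dr
  traj <- gas_fixture(n_contrib = 300, nf = 40, seed = 72)
  res <- residency(matrix(TRUE, 1, traj$n_frames), times = traj$times)
  rs <- 6
  tab <- coordination_numbers(traj, res, "cation", "water", rs,
                              window_start = 0)
  brute <- mean(sapply(seq_len(traj$n_frames), function(f) {
    d <- sweep(frame_positions(traj, f)[-1, ], 2, frame_positions(traj, f)[1, ])
    d <- d - round(d / 30) * 30
    sum(sqrt(rowSums(d^2)) <= rs)
  }))
  expect_equal(tab$mean, brute, tolerance = 1e-12)
  prof <- rdf_decomposed(traj, res, "cation", "water", r_max = 7, dr = 0.1,
                         window_start = 0)
  integral <- coordination_from_rdf(prof, "water", rs)
  expect_lt(abs(integral - tab$mean) / tab$mean, 0.02)
})

test_that("H-bond geometry criteria match hand values and brute force", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0), c(0, 2.9, 0))
  donors <- matrix(c(1L, 2L), ncol = 2)
  crit <- hbond_criteria(3.5, 150)
  hb <- count_hbonds(pos, donors, acceptors = 3L, crit)
  expect_equal(hb$count, 1)   # linear, 2.9 A
  expect_equal(hb$pairs$angle_deg, 180, tolerance = 1e-6)
  hb2 <- count_hbonds(pos, donors, acceptors = 4L, crit)
  expect_equal(hb2$count, 0)  # 90 degree geometry
  expect_error(count_hbonds(pos, matrix(1L, 1, 1), 3L, crit), "two-column")

  set.seed(73)
  pos <- matrix(runif(90, 0, 8), ncol = 3)
  donors <- cbind(1:10, 11:20)
  acceptors <- 21:30
  hb <- count_hbonds(pos, donors, acceptors, crit)
  brute <- 0
  for (i in 1:10) for (a in acceptors) {
    dda <- sqrt(sum((pos[a, ] - pos[i, ])^2))
    v1 <- pos[i, ] - pos[i + 10, ]; v2 <- pos[a, ] - pos[i + 10, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    if (dda <= 3.5 && ang >= 150) brute <- brute + 1
  }
  expect_equal(hb$count, brute)
})

test_that("H-bond counts are invariant under rigid rotation and translation", {
  set.seed(74)
  pos <- matrix(runif(90, 0, 8), ncol = 3)
  donors <- cbind(1:10, 11:20)
  crit <- hbond_criteria(3.5, 140)
  c1 <- count_hbonds(pos, donors, 21:30, crit)$count
  rot <- rotation_matrix(c(1, 1, 0), 0.7)
  pos2 <- sweep(pos %*% t(rot), 2, c(3, -2, 5), "+")
  c2 <- count_hbonds(pos2, donors, 21:30, crit)$count
  expect_equal(c1, c2)
})

test_that("theoretical inter-ring H-bond maximum is (n-1) * per-interface", {
  expect_equal(theoretical_max_hbonds(8, 12), 84L)
  expect_equal(theoretical_max_hbonds(1, 12), 0L)
  expect_equal(theoretical_max_hbonds(3, 12), 24L)
  # linear in both arguments
  for (n in 2:5) for (b in c(0, 6, 12))
    expect_equal(theoretical_max_hbonds(n, b), (n - 1) * b)
})
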