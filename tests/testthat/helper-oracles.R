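# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (double loops, direct enumeration) and
# never call the code paths they check.

# brute-force survival probability by enumeration over (origin, particle)
oracle_survival <- function(flags, kmax, convention = "continuous",
                            origins = "per_tau") {
  nf <- ncol(flags)
  vapply(0:kmax, function(k) {
    lim <- if (origins == "fixed") nf - kmax else nf - k
    vals <- numeric(0)
    for (t in seq_len(max(lim, 0))) {
      inside <- which(flags[, t])
      if (!length(inside)) next
      surv <- 0
      for (p in inside) {
        ok <- if (convention == "continuous") all(flags[p, t:(t + k)])
        else flags[p, t + k]
        surv <- surv + ok
      }
      vals <- c(vals, surv / length(inside))
    }
    mean(vals)
  }, numeric(1))
}

# independent linear-interpolation quantile (type-7 convention, hand-rolled)
oracle_quantile_lin <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# minimal trajectory: positions array (n_particles x 3 x n_frames)
make_traj <- function(coords, dt = 1, box = c(50, 50, 50), groups = list()) {
  trajectory(coords, times = (seq_len(dim(coords)[3]) - 1) * dt, box = box,
             groups = groups)
}

# stacked-ring backbone fixture: n_rings rings of n_per points, radius r,
# spacing dz, optionally rotated; replicated over n_frames
ring_stack <- function(n_rings = 8, n_per = 12, r = 9, dz = 4.9,
                       rot = diag(3), center = c(25, 25, 25), n_frames = 2) {
  th <- seq(0, 2 * pi, length.out = n_per + 1)[-(n_per + 1)]
  zs <- (seq_len(n_rings) - (n_rings + 1) / 2) * dz
  pts <- do.call(rbind, lapply(zs, function(z)
    cbind(r * cos(th), r * sin(th), z)))
  pts <- pts %*% t(rot)
  pts <- sweep(pts, 2, center, "+")
  coords <- array(rep(t(pts), n_frames),
                  dim = c(3, nrow(pts), n_frames))
  coords <- aperm(coords, c(2, 1, 3))
  coords
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# angular Fourier amplitude |<exp(i m theta)>| per harmonic
theta_spectrum <- function(theta, m_max = 12) {
  vapply(seq_len(m_max), function(m) Mod(mean(exp(1i * m * theta))),
         numeric(1))
}

# total-variation distance between two 2D probability tables
tv_dist <- function(p, q) sum(abs(p - q)) / 2

# 2D (R, theta) probability table of point samples on fixed edges
rtheta_table <- function(R, theta, r_edges, th_edges) {
  nr <- length(r_edges) - 1L; nt <- length(th_edges) - 1L
  ri <- findInterval(R, r_edges, rightmost.closed = TRUE)
  ti <- findInterval(theta, th_edges, rightmost.closed = TRUE)
  ok <- ri >= 1 & ri <= nr & ti >= 1 & ti <= nt
  m <- matrix(0, nr, nt)
  tb <- table(factor(ri[ok], levels = 1:nr), factor(ti[ok], levels = 1:nt))
  m[] <- as.numeric(tb)
  m / sum(m)
}
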