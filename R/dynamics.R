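#' Windowed mean velocities of inside particles
#'
#' Mean velocities are finite-difference estimates over fixed time windows
#' (default stride = window, i.e. non-overlapping): for each tracked
#' particle and each window during which it stays inside the pore at every
#' stored frame, the mean velocity is the unwrapped displacement across the
#' window divided by the window length, associated with the particle's
#' position at the start of the window.  Displacements are unwrapped by
#' accumulating minimum-image frame-to-frame steps, so crossing a periodic
#' boundary does not corrupt the estimate.
#'
#' @param traj a [trajectory()].
#' @param res a [residency()] for the tracked group (rows aligned with
#'   `particle_ids`).
#' @param geom channel geometry (for the cylindrical start position).
#' @param window window length in ps; must be a positive multiple of the
#'   frame spacing.
#' @param discard initial time to discard (ps).
#' @param stride spacing between window starts in ps; default `window`.
#' @return Data frame, one row per retained (particle, window): columns
#'   `particle_id`, `t_start_ps`, `x`, `y`, `z` (channel frame), `R_A`,
#'   `theta_rad`, `z_A`, `vx`, `vy`, `vz` (lab frame, A/ps), `speed`.
#' @export
windowed_velocities <- function(traj, res, geom, window = 10, discard = 0,
                                stride = window) {
  dt <- traj$dt_saved
  if (is.na(dt)) stop("single-frame trajectory has no velocities")
  wf <- round(window / dt)
  if (wf < 1L || abs(wf * dt - window) > 1e-6 * dt)
    stop("window must be a positive multiple of the frame spacing")
  sf <- max(1L, round(stride / dt))
  if (discard >= traj$times[traj$n_frames] - traj$times[1])
    stop("discard exceeds the trajectory span")
  first <- which(traj$times - traj$times[1] >= discard - 1e-9)[1]
  nf <- traj$n_frames
  starts <- seq.int(first, nf - wf, by = sf)
  if (!length(starts)) return(empty_velocity_samples())
  out <- vector("list", nrow(res$flags))
  for (i in seq_len(nrow(res$flags))) {
    pid <- res$particle_ids[i]
    pos <- t(traj$coords[pid, , ])           # nf x 3
    steps <- diff(pos)
    # minimum-image unwrap of frame-to-frame steps
    for (d in 1:3) {
      b <- traj$box[-1, d]
      steps[, d] <- steps[, d] - round(steps[, d] / b) * b
    }
    cum <- rbind(0, apply(steps, 2, cumsum)) # unwrapped displacement from frame 1
    f <- res$flags[i, ]
    runlen <- integer(nf); runlen[nf] <- as.integer(f[nf])
    if (nf > 1) for (t in (nf - 1L):1L)
      runlen[t] <- if (f[t]) runlen[t + 1L] + 1L else 0L
    keep <- starts[runlen[starts] >= wf + 1L]  # inside for every frame of the window
    if (!length(keep)) next
    disp <- cum[keep + wf, , drop = FALSE] - cum[keep, , drop = FALSE]
    vel <- disp / (wf * dt)
    cylrows <- do.call(rbind, lapply(seq_along(keep), function(j)
      to_cylindrical(pos[keep[j], , drop = FALSE], geom, keep[j])))
    out[[i]] <- data.frame(
      particle_id = pid, t_start_ps = traj$times[keep],
      x = cylrows$x, y = cylrows$y,
      R_A = cylrows$R, theta_rad = cylrows$theta, z_A = cylrows$z,
      vx = vel[, 1], vy = vel[, 2], vz = vel[, 3],
      speed = sqrt(rowSums(vel^2)))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_velocity_samples())
  samples <- do.call(rbind, out)
  attr(samples, "window_ps") <- window
  samples
}

empty_velocity_samples <- function() {
  s <- data.frame(particle_id = integer(), t_start_ps = numeric(),
                  x = numeric(), y = numeric(), R_A = numeric(),
                  theta_rad = numeric(), z_A = numeric(), vx = numeric(),
                  vy = numeric(), vz = numeric(), speed = numeric())
  s
}

#' Freedman-Diaconis histogram bin width
#'
#' `width = 2 * IQR * n^(-1/3)`, with the IQR computed by the
#' linear-interpolation quantile convention (`stats::quantile` type 7).
#' If the IQR is zero the width falls back to Scott's normal-reference rule
#' `3.49 * sd * n^(-1/3)`; if that is also zero (constant data) the width is
#' 0, which downstream histogramming treats as a single bin.
#'
#' @param samples numeric vector, length >= 2.
#' @return Bin width on the scale of `samples`.
#' @export
freedman_diaconis_binwidth <- function(samples) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2L) stop("at least 2 samples are required")
  iqr <- diff(stats::quantile(samples, c(0.25, 0.75), names = FALSE, type = 7))
  w <- 2 * iqr * n^(-1 / 3)
  if (w <= 0) w <- 3.49 * stats::sd(samples) * n^(-1 / 3)
  if (!is.finite(w) || w < 0) w <- 0
  w
}

#' Speed probability distribution with Freedman-Diaconis binning
#'
#' @param vel a [windowed_velocities()] data frame, or a numeric vector of
#'   speeds.
#' @return A `poredyn_speed_hist`: `edges` (A/ps), `prob` (sums to 1),
#'   `counts`, `binwidth`, `rule = "freedman-diaconis"`.
#' @export
speed_distribution <- function(vel) {
  speeds <- if (is.numeric(vel)) vel else vel$speed
  if (length(speeds) < 2L) stop("at least 2 speed samples are required")
  w <- freedman_diaconis_binwidth(speeds)
  lo <- min(speeds); hi <- max(speeds)
  if (w <= 0 || hi - lo < w * 1e-9) {        # degenerate: single bin
    edges <- c(lo - 0.5, hi + 0.5)
  } else {
    edges <- seq(lo, hi + w, by = w)
  }
  counts <- graphics::hist(speeds, breaks = edges, plot = FALSE,
                           right = FALSE, include.lowest = TRUE)$counts
  structure(list(edges = edges, prob = counts / sum(counts), counts = counts,
                 binwidth = w, rule = "freedman-diaconis"),
            class = "poredyn_speed_hist")
}

#' Position-velocity correlation maps in cylindrical coordinates
#'
#' Occupancy of window-start positions on an (R, theta) grid (probability,
#' sums to 1), plus the speed distribution conditioned on R and on theta:
#' 2D histograms (position bin x speed bin) where each occupied position
#' bin's speed column sums to 1.
#'
#' @param vel a [windowed_velocities()] data frame.
#' @param r_bins,theta_bins number of radial / angular bins (>= 1).
#' @param r_max radial extent of the grid; default the sample maximum.
#' @param speed_bins number of speed bins for the conditional maps.
#' @return A `poredyn_pv_map`: `occupancy` (r x theta matrix), bin edges,
#'   `speed_by_r`, `speed_by_theta` (matrices position-bin x speed-bin),
#'   `mean_speed_by_r`, `mean_speed_by_theta`.
#' @export
position_velocity_correlation <- function(vel, r_bins = 20, theta_bins = 24,
                                          r_max = NULL, speed_bins = 30) {
  if (nrow(vel) == 0L) stop("no velocity samples")
  stopifnot(r_bins >= 1L, theta_bins >= 1L)
  if (is.null(r_max)) r_max <- max(vel$R_A) * (1 + 1e-9)
  r_edges <- seq(0, r_max, length.out = r_bins + 1L)
  th_edges <- seq(-pi, pi, length.out = theta_bins + 1L)
  ri <- pmin(pmax(findInterval(vel$R_A, r_edges, rightmost.closed = TRUE), 1L), r_bins)
  keep <- vel$R_A <= r_max
  ri <- ri[keep]
  ti <- pmin(pmax(findInterval(vel$theta_rad[keep], th_edges,
                               rightmost.closed = TRUE), 1L), theta_bins)
  sp <- vel$speed[keep]
  occ <- matrix(0, r_bins, theta_bins)
  tab <- table(factor(ri, levels = seq_len(r_bins)),
               factor(ti, levels = seq_len(theta_bins)))
  occ[] <- as.numeric(tab)
  occ <- occ / sum(occ)
  s_edges <- seq(0, max(sp) * (1 + 1e-9) + 1e-12, length.out = speed_bins + 1L)
  si <- pmin(pmax(findInterval(sp, s_edges, rightmost.closed = TRUE), 1L), speed_bins)
  cond_hist <- function(pos_idx, n_pos) {
    m <- matrix(0, n_pos, speed_bins)
    tb <- table(factor(pos_idx, levels = seq_len(n_pos)),
                factor(si, levels = seq_len(speed_bins)))
    m[] <- as.numeric(tb)
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    m
  }
  mean_by <- function(pos_idx, n_pos)
    vapply(seq_len(n_pos), function(b) {
      x <- sp[pos_idx == b]
      if (length(x)) mean(x) else NA_real_
    }, numeric(1))
  structure(list(
    occupancy = occ, r_edges = r_edges, theta_edges = th_edges,
    speed_edges = s_edges,
    speed_by_r = cond_hist(ri, r_bins),
    speed_by_theta = cond_hist(ti, theta_bins),
    mean_speed_by_r = mean_by(ri, r_bins),
    mean_speed_by_theta = mean_by(ti, theta_bins),
    n_samples = length(sp)),
    class = "poredyn_pv_map")
}
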