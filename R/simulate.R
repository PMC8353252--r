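#' Parameters of the synthetic confined-pore model
#'
#' Defines a cylindrical pore with a harmonic soft wall, an optional
#' six-fold (by default) angular modulation of the potential and an axial
#' modulation mimicking the alternation between ring planes and inter-plane
#' regions of a stacked cyclic-peptide channel.  The modulation potential is
#' `U(R, theta, z) = -A_theta (R/R0)^2 cos(k theta) - A_z cos(2 pi z / period)`
#' (in units of kT), so angular structure is weak on the axis and strongest
#' near the wall, as observed for confined water; the wall adds
#' `0.5 k_wall (R - R0)^2` beyond the pore radius.
#'
#' Defaults emulate the study system: pore radius 9 A, eight axial periods
#' of 4.9 A (a 39.2 A channel), water-like diffusion 0.23 A^2/ps.
#'
#' @param radius pore radius R0 (angstrom).
#' @param length channel length (angstrom); the pore spans `[-length/2,
#'   length/2]` on the axis.
#' @param wall_k harmonic wall stiffness (kT / A^2).
#' @param angular_amp amplitude of the angular modulation (kT).
#' @param angular_order harmonic order k of the angular modulation (>= 1).
#' @param axial_amp amplitude of the axial modulation (kT).
#' @param axial_period axial modulation period (angstrom).
#' @param D diffusion coefficient of the simulated species (A^2/ps).
#' @param mobility_factor multiplier on D in the wall region (1 = uniform
#'   mobility); ramps linearly from 1 at `0.7 radius` to this value at the
#'   wall.
#' @param dt integration timestep (ps).
#' @param save_interval spacing of stored frames (ps).
#' @param axial_bc `"reflective"` or `"periodic"` axial boundaries.
#' @param seed integer RNG seed; a fixed seed gives bitwise-identical
#'   trajectories.
#' @return A `pore_model_params` list.
#' @export
pore_model_params <- function(radius = 9, length = 39.2, wall_k = 5,
                              angular_amp = 1.5, angular_order = 6,
                              axial_amp = 1.0, axial_period = 4.9,
                              D = 0.23, mobility_factor = 1,
                              dt = 0.02, save_interval = 1,
                              axial_bc = c("reflective", "periodic"),
                              seed = 1) {
  axial_bc <- match.arg(axial_bc)
  stopifnot(radius > 0, length > 0, dt > 0, save_interval > 0,
            angular_order >= 1, D > 0, wall_k >= 0, axial_period > 0)
  structure(list(radius = radius, length = length, wall_k = wall_k,
                 angular_amp = angular_amp, angular_order = angular_order,
                 axial_amp = axial_amp, axial_period = axial_period,
                 D = D, mobility_factor = mobility_factor, dt = dt,
                 save_interval = save_interval, axial_bc = axial_bc,
                 seed = as.integer(seed)),
            class = "pore_model_params")
}

# modulation + wall potential (kT) and Cartesian force at channel-frame points
pore_potential <- function(p, x, y, z) {
  R2 <- x^2 + y^2
  R <- sqrt(R2)
  th <- atan2(y, x)
  u_ang <- -p$angular_amp * (R2 / p$radius^2) * cos(p$angular_order * th)
  u_ax <- -p$axial_amp * cos(2 * pi * z / p$axial_period)
  over <- pmax(R - p$radius, 0)
  u_ang + u_ax + 0.5 * p$wall_k * over^2
}

pore_force <- function(p, x, y, z) {
  R2 <- x^2 + y^2
  R <- sqrt(R2)
  th <- atan2(y, x)
  k <- p$angular_order
  # dU/dR and (1/R) dU/dtheta of the angular term (regular at the axis)
  dU_dR <- -2 * p$angular_amp * R / p$radius^2 * cos(k * th) +
    p$wall_k * pmax(R - p$radius, 0)
  Ftan <- -p$angular_amp * (R / p$radius^2) * k * sin(k * th)  # -(1/R) dU/dth
  FR <- -dU_dR
  cs <- ifelse(R > 1e-12, x / pmax(R, 1e-12), 1)
  sn <- ifelse(R > 1e-12, y / pmax(R, 1e-12), 0)
  Fz <- -p$axial_amp * 2 * pi / p$axial_period * sin(2 * pi * z / p$axial_period)
  list(Fx = FR * cs - Ftan * sn, Fy = FR * sn + Ftan * cs, Fz = Fz)
}

local_D <- function(p, R) {
  ramp <- pmin(pmax((R - 0.7 * p$radius) / (0.3 * p$radius), 0), 1)
  p$D * (1 + (p$mobility_factor - 1) * ramp)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate confined Brownian particles in the model pore
#'
#' Overdamped Langevin (Euler-Maruyama) dynamics
#' `x <- x + D(x) F(x) dt + sqrt(2 D(x) dt) xi` with the confining wall and
#' modulation forces of [pore_model_params()], in kT units.  Trajectories
#' are saved every `save_interval` ps in the laboratory frame, with the
#' channel axis along z through the box center.  Reproducible: the same
#' seed gives an identical trajectory.
#'
#' @param params a [pore_model_params()].
#' @param n_particles number of particles.
#' @param duration simulated time (ps); must be at least 10 save intervals.
#' @param group_name name of the particle group on the returned trajectory.
#' @return List: `traj` (a [trajectory()] with one group covering all
#'   particles and a `"backbone"` helper group of 8 static reference rings),
#'   `truth` (true D, modulation depth/order, axial period, per-particle
#'   inside intervals on the saved grid).
#' @export
simulate_confined_brownian <- function(params, n_particles = 50,
                                       duration = 200,
                                       group_name = "tracked") {
  p <- params
  if (duration < 10 * p$save_interval)
    stop("duration must be at least 10 save intervals")
  # wall displacement per step at 1 A overshoot must stay below 0.5 A
  if (p$D * p$wall_k * p$dt > 0.5)
    stop("timestep too large for the wall stiffness: reduce dt (stability)")
  n_steps <- round(duration / p$dt)
  save_every <- max(1L, round(p$save_interval / p$dt))
  save_steps <- seq(0L, n_steps, by = save_every)
  n_frames <- length(save_steps)
  box <- c(4 * p$radius, 4 * p$radius, p$length + 4 * p$axial_period)
  center <- box / 2
  coords <- array(NA_real_, dim = c(n_particles, 3L, n_frames))
  with_seed(p$seed, {
    # start uniform inside the pore volume
    R0 <- sqrt(stats::runif(n_particles)) * 0.95 * p$radius
    th0 <- stats::runif(n_particles, -pi, pi)
    x <- R0 * cos(th0); y <- R0 * sin(th0)
    z <- stats::runif(n_particles, -0.48, 0.48) * p$length
    fi <- 1L
    for (s in 0:n_steps) {
      if (s == save_steps[fi]) {
        coords[, , fi] <- cbind(x + center[1], y + center[2], z + center[3])
        fi <- fi + 1L
        if (fi > n_frames) break
      }
      Fv <- pore_force(p, x, y, z)
      Dl <- local_D(p, sqrt(x^2 + y^2))
      sig <- sqrt(2 * Dl * p$dt)
      x <- x + Dl * Fv$Fx * p$dt + sig * stats::rnorm(n_particles)
      y <- y + Dl * Fv$Fy * p$dt + sig * stats::rnorm(n_particles)
      z <- z + Dl * Fv$Fz * p$dt + sig * stats::rnorm(n_particles)
      half <- p$length / 2
      if (p$axial_bc == "reflective") {
        z <- ifelse(z > half, 2 * half - z, z)
        z <- ifelse(z < -half, -2 * half - z, z)
      } else {
        z <- z - floor((z + half) / p$length) * p$length
      }
    }
  })
  # static backbone reference: 8 rings of 12 points at the pore radius
  ring_z <- (seq_len(8) - 4.5) * p$axial_period
  ring_th <- seq(0, 2 * pi, length.out = 13)[-13]
  bb <- do.call(rbind, lapply(ring_z, function(zz)
    cbind(p$radius * cos(ring_th) + center[1],
          p$radius * sin(ring_th) + center[2], zz + center[3])))
  n_bb <- nrow(bb)
  all_coords <- array(NA_real_, dim = c(n_particles + n_bb, 3L, n_frames))
  all_coords[seq_len(n_particles), , ] <- coords
  for (f in seq_len(n_frames)) all_coords[n_particles + seq_len(n_bb), , f] <- bb
  groups <- list(seq_len(n_particles), n_particles + seq_len(n_bb))
  names(groups) <- c(group_name, "backbone")
  traj <- trajectory(all_coords,
                     times = save_steps * p$dt,
                     box = box, groups = groups)
  # ground-truth residency on the saved grid
  flags <- matrix(FALSE, n_particles, n_frames)
  for (f in seq_len(n_frames)) {
    xx <- coords[, 1, f] - center[1]; yy <- coords[, 2, f] - center[2]
    zz <- coords[, 3, f] - center[3]
    flags[, f] <- (xx^2 + yy^2 <= p$radius^2) & (abs(zz) <= p$length / 2)
  }
  truth <- list(D = p$D, angular_amp = p$angular_amp,
                angular_order = p$angular_order,
                axial_period = p$axial_period,
                mobility_factor = p$mobility_factor,
                inside_flags = flags, seed = p$seed)
  list(traj = traj, truth = truth)
}

#' Parameters of the synthetic dwell process
#'
#' Each candidate particle alternates between outside and inside the pore
#' with independent exponential waiting times (entry rate `lambda_in`, exit
#' rate `lambda_out`); residence times are therefore i.i.d. exponential
#' with rate `lambda_out`, giving a ground-truth residence half-life
#' `ln(2) / lambda_out`.
#'
#' @param lambda_in entry rate (1/ps).
#' @param lambda_out exit rate (1/ps).
#' @param n_particles number of candidate particles.
#' @param duration process duration (ps); should be much longer than
#'   `1/lambda_out`.
#' @param dt_saved frame spacing of the sampled residency (ps).
#' @param seed integer RNG seed.
#' @return A `dwell_process_params` list.
#' @export
dwell_process_params <- function(lambda_in = 0.02, lambda_out = 0.05,
                                 n_particles = 100, duration = 2000,
                                 dt_saved = 1, seed = 1) {
  stopifnot(lambda_in > 0, lambda_out > 0, n_particles >= 1, duration > 0,
            dt_saved > 0)
  structure(list(lambda_in = lambda_in, lambda_out = lambda_out,
                 n_particles = as.integer(n_particles), duration = duration,
                 dt_saved = dt_saved, seed = as.integer(seed)),
            class = "dwell_process_params")
}

#' Simulate the exponential dwell process
#'
#' All particles start outside.  The continuous-time state path is sampled
#' on the frame grid to build the residency matrix; the true continuous
#' inside intervals are recorded as ground truth.
#'
#' @param params a [dwell_process_params()].
#' @return List: `res` (a [residency()]), `truth` (list with the true
#'   rates, all completed inside dwell times `dwell_times`, the inside
#'   `intervals` data frame, `n_events`, and `low_events` flag set when
#'   fewer than 50 inside dwells are expected).
#' @export
simulate_dwell_process <- function(params) {
  p <- params
  times <- seq(0, p$duration, by = p$dt_saved)
  nf <- length(times)
  flags <- matrix(FALSE, p$n_particles, nf)
  intervals <- list()
  dwell_times <- numeric(0)
  with_seed(p$seed, {
    for (i in seq_len(p$n_particles)) {
      t <- 0; inside <- FALSE
      while (t < p$duration) {
        w <- stats::rexp(1, if (inside) p$lambda_out else p$lambda_in)
        t2 <- t + w
        if (inside) {
          lo <- t; hi <- min(t2, p$duration)
          intervals[[length(intervals) + 1L]] <- c(i, lo, hi)
          if (t2 <= p$duration) dwell_times <- c(dwell_times, w)
          sel <- times >= lo - 1e-12 & times <= hi + 1e-12
          flags[i, sel] <- TRUE
        }
        inside <- !inside
        t <- t2
      }
    }
  })
  iv <- if (length(intervals))
    as.data.frame(do.call(rbind, intervals)) else
      data.frame(V1 = numeric(), V2 = numeric(), V3 = numeric())
  names(iv) <- c("particle", "t_in", "t_out")
  expected <- p$n_particles * p$duration / (1 / p$lambda_in + 1 / p$lambda_out)
  truth <- list(lambda_in = p$lambda_in, lambda_out = p$lambda_out,
                tau_half_true = log(2) / p$lambda_out,
                dwell_times = dwell_times, intervals = iv,
                n_events = length(dwell_times),
                low_events = expected < 50, seed = p$seed)
  list(res = residency(flags, times = times), truth = truth)
}

#' Boltzmann samples of the model pore density
#'
#' Draws positions by rejection sampling from `exp(-U(R, theta, z))` over
#' the pore volume (radially out to three wall standard deviations beyond
#' the pore radius, so the soft-wall tail matches the Brownian generator).
#' Used as the equilibrium reference for density-map tests.
#'
#' @param params a [pore_model_params()].
#' @param n_samples number of samples (>= 1).
#' @param seed integer RNG seed.
#' @return Data frame `x`, `y`, `z` (channel frame, angstrom), `R`, `theta`.
#' @export
generate_star_reference_density <- function(params, n_samples, seed = 1) {
  p <- params
  stopifnot(n_samples >= 1)
  r_max <- p$radius + if (p$wall_k > 0) 3 / sqrt(p$wall_k) else 0
  # lower bound of U over the sampled region, on a fine radial grid
  rg <- seq(0, r_max, length.out = 400)
  u_min <- min(-p$angular_amp * (rg / p$radius)^2 +
                 0.5 * p$wall_k * pmax(rg - p$radius, 0)^2) - p$axial_amp
  got <- 0L; tried <- 0
  out <- matrix(NA_real_, n_samples, 3)
  with_seed(seed, {
    while (got < n_samples) {
      m <- max(2L * (n_samples - got), 1000L)
      tried <- tried + m
      R <- sqrt(stats::runif(m)) * r_max
      th <- stats::runif(m, -pi, pi)
      z <- stats::runif(m, -p$length / 2, p$length / 2)
      x <- R * cos(th); y <- R * sin(th)
      u <- pore_potential(p, x, y, z)
      acc <- stats::runif(m) < exp(-(u - u_min))
      n_new <- min(sum(acc), n_samples - got)
      if (n_new > 0) {
        sel <- which(acc)[seq_len(n_new)]
        out[got + seq_len(n_new), ] <- cbind(x[sel], y[sel], z[sel])
        got <- got + n_new
      }
      if (tried > 1000 && got / tried < 1e-4)
        stop("rejection acceptance rate below 1e-4: modulation too strong")
    }
  })
  data.frame(x = out[, 1], y = out[, 2], z = out[, 3],
             R = sqrt(out[, 1]^2 + out[, 2]^2),
             theta = atan2(out[, 2], out[, 1]))
}
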