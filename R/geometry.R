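#' Fit the channel axis per frame
#'
#' The channel axis is the principal axis of the backbone point cloud: the
#' largest-variance eigendirection of the centered second-moment tensor,
#' computed independently per frame and sign-aligned frame to frame so the
#' axis never flips.  The per-frame origin is the backbone centroid; the
#' axial extent is the min/max backbone projection padded by `z_pad`.
#'
#' An optional `theta_ref_group` defines a co-rotating angular reference: the
#' in-plane unit vector from the axis toward that group's centroid.  With a
#' co-rotating reference the angular structure of the channel (e.g. the
#' six-fold star lobes) stays registered even if the tube rotates in the
#' laboratory frame.  Without it, the laboratory x-axis projected onto the
#' transverse plane is used.
#'
#' @param traj a [trajectory()].
#' @param backbone_group name of the group defining the channel backbone
#'   (>= 3 particles).
#' @param pore_radius nominal pore radius in angstrom (defines "inside").
#' @param z_pad axial padding in angstrom added beyond the backbone extent.
#' @param theta_ref_group optional group name for the co-rotating angular
#'   reference.
#' @param mode `"fitted"` (per-frame principal axis, default) or `"lab_z"`
#'   (laboratory z-axis through the backbone centroid).
#' @return A `poredyn_geom` with per-frame `origin` (n x 3), `axis` (n x 3
#'   unit rows), `e1`/`e2` (transverse frame), `z_lo`, `z_hi`, `z_mid`
#'   (per-frame, relative to the origin projection), and `pore_radius`.
#' @export
fit_channel_axis <- function(traj, backbone_group, pore_radius, z_pad = 2,
                             theta_ref_group = NULL,
                             mode = c("fitted", "lab_z")) {
  mode <- match.arg(mode)
  if (!backbone_group %in% names(traj$groups))
    stop(sprintf("group '%s' is not defined on the trajectory", backbone_group))
  idx <- traj$groups[[backbone_group]]
  if (length(idx) < 3L) stop("backbone group must contain at least 3 particles")
  if (pore_radius <= 0) stop("pore_radius must be > 0")
  nf <- traj$n_frames
  origin <- matrix(NA_real_, nf, 3)
  axis <- matrix(NA_real_, nf, 3)
  e1 <- matrix(NA_real_, nf, 3)
  z_lo <- numeric(nf); z_hi <- numeric(nf)
  ref_idx <- NULL
  if (!is.null(theta_ref_group)) {
    if (!theta_ref_group %in% names(traj$groups))
      stop(sprintf("group '%s' is not defined on the trajectory", theta_ref_group))
    ref_idx <- traj$groups[[theta_ref_group]]
  }
  prev_u <- NULL
  for (f in seq_len(nf)) {
    pts <- frame_positions(traj, f)[idx, , drop = FALSE]
    ctr <- colMeans(pts)
    origin[f, ] <- ctr
    cen <- sweep(pts, 2, ctr)
    if (mode == "lab_z") {
      u <- c(0, 0, 1)
    } else {
      mom <- crossprod(cen) / nrow(cen)
      if (max(abs(mom)) < 1e-12)
        stop("degenerate backbone point cloud: all points coincide")
      eg <- eigen(mom, symmetric = TRUE)
      u <- eg$vectors[, 1]
    }
    # sign continuity: never flip relative to the previous frame
    if (is.null(prev_u)) {
      if (u[3] < 0) u <- -u
    } else if (sum(u * prev_u) < 0) u <- -u
    prev_u <- u
    axis[f, ] <- u
    proj <- as.numeric(cen %*% u)
    z_lo[f] <- min(proj) - z_pad
    z_hi[f] <- max(proj) + z_pad
    # transverse reference direction
    if (!is.null(ref_idx)) {
      v <- colMeans(frame_positions(traj, f)[ref_idx, , drop = FALSE]) - ctr
    } else {
      v <- c(1, 0, 0)
    }
    v <- v - sum(v * u) * u
    if (sqrt(sum(v^2)) < 1e-9) {            # reference parallel to axis
      v <- c(0, 1, 0); v <- v - sum(v * u) * u
    }
    e1[f, ] <- v / sqrt(sum(v^2))
  }
  e2 <- t(vapply(seq_len(nf), function(f) cross3(axis[f, ], e1[f, ]),
                 numeric(3)))
  structure(
    list(origin = origin, axis = axis, e1 = e1, e2 = e2,
         z_lo = z_lo, z_hi = z_hi, z_mid = (z_lo + z_hi) / 2,
         pore_radius = pore_radius, n_frames = nf, mode = mode),
    class = "poredyn_geom")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.poredyn_geom <- function(x, ...) {
  cat(sprintf("<poredyn_geom> %d frames, pore radius %.2f A, mode '%s'\n",
              x$n_frames, x$pore_radius, x$mode))
  invisible(x)
}

#' Convert positions to channel-centered cylindrical coordinates
#'
#' `R` is the perpendicular distance to the channel axis, `theta` the angle
#' about the axis measured from the geometry's reference direction (in
#' `[-pi, pi)`), and `z` the signed axial projection relative to the channel
#' midpoint.  A point exactly on the axis gets `theta = 0` by convention.
#'
#' @param positions an `n x 3` matrix of Cartesian positions (angstrom).
#' @param geom a [fit_channel_axis()] result.
#' @param frame frame index selecting the per-frame axis.
#' @return Data frame with columns `R`, `theta`, `z` (and the channel-frame
#'   Cartesian components `x`, `y` for convenience).
#' @export
to_cylindrical <- function(positions, geom, frame) {
  if (frame < 1L || frame > geom$n_frames) stop("invalid frame index")
  if (!is.matrix(positions)) positions <- matrix(positions, ncol = 3)
  d <- sweep(positions, 2, geom$origin[frame, ])
  x <- as.numeric(d %*% geom$e1[frame, ])
  y <- as.numeric(d %*% geom$e2[frame, ])
  zax <- as.numeric(d %*% geom$axis[frame, ])
  R <- sqrt(x^2 + y^2)
  theta <- ifelse(R < 1e-12, 0, atan2(y, x))
  theta <- ifelse(theta >= pi, theta - 2 * pi, theta)   # [-pi, pi)
  data.frame(R = R, theta = theta, z = zax - geom$z_mid[frame], x = x, y = y)
}

#' Reconstruct Cartesian positions from cylindrical coordinates
#'
#' Inverse of [to_cylindrical()] for the same geometry and frame.
#'
#' @param cyl data frame with columns `R`, `theta`, `z`.
#' @param geom a `poredyn_geom`.
#' @param frame frame index.
#' @return `n x 3` matrix of Cartesian positions.
#' @export
from_cylindrical <- function(cyl, geom, frame) {
  x <- cyl$R * cos(cyl$theta)
  y <- cyl$R * sin(cyl$theta)
  zax <- cyl$z + geom$z_mid[frame]
  out <- outer(x, geom$e1[frame, ]) + outer(y, geom$e2[frame, ]) +
    outer(zax, geom$axis[frame, ])
  sweep(out, 2, geom$origin[frame, ], "+")
}
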