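#' 2D positional probability heatmap in a channel-aligned plane
#'
#' Counts inside-particle positions, expressed in the channel-aligned frame
#' (transverse components x, y and axial component z), over all frames in
#' the analysis window, binned on a regular grid and normalized by the total
#' number of inside counts so that the cells sum to 1.  The transverse axes
#' co-rotate with the channel when the geometry carries a theta reference
#' group, which keeps angular structure (e.g. star lobes) registered.
#'
#' @param traj a [trajectory()].
#' @param res a [residency()] for the mapped group.
#' @param geom channel geometry.
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @param bin_width bin width in angstrom (default 0.25).
#' @param window_start start of the analysis window (ps); default discards
#'   the first 10% of the trajectory.
#' @return A `poredyn_map2d`: `plane`, `x_edges`, `y_edges`, `prob` matrix
#'   (rows = first plane axis), `n_counts`.
#' @export
planar_heatmap <- function(traj, res, geom, plane = c("XY", "XZ", "YZ"),
                           bin_width = 0.25, window_start = NULL) {
  plane <- match.arg(plane)
  if (bin_width <= 0) stop("bin_width must be > 0")
  pts <- inside_channel_coords(traj, res, geom, window_start)
  if (nrow(pts) == 0L) stop("empty map: no inside counts in the window")
  ax <- switch(plane, XY = c("x", "y"), XZ = c("x", "z"), YZ = c("y", "z"))
  u <- pts[[ax[1]]]; v <- pts[[ax[2]]]
  ue <- bin_edges_covering(u, bin_width)
  ve <- bin_edges_covering(v, bin_width)
  prob <- bin2d(u, v, ue, ve)
  structure(list(plane = plane, x_edges = ue, y_edges = ve,
                 prob = prob / sum(prob), n_counts = nrow(pts),
                 bin_width = bin_width),
            class = "poredyn_map2d")
}

#' Positional probability heatmap on the (R, theta) grid
#'
#' As [planar_heatmap()] but on cylindrical coordinates.  Cell probability
#' is the raw count fraction: no 1/R Jacobian correction is applied, so the
#' map is the probability of positions, not a number density.  A
#' density-corrected variant (each cell divided by its annular-sector area,
#' then renormalized) is available with `jacobian = TRUE`.
#'
#' @param traj,res,geom,window_start as in [planar_heatmap()].
#' @param r_bins,theta_bins number of radial / angular bins (>= 1).
#' @param r_max radial extent; defaults to the pore radius.
#' @param jacobian apply the 1/R area correction (default `FALSE`).
#' @return A `poredyn_map2d` with `plane = "R-theta"`, `x_edges` = R edges,
#'   `y_edges` = theta edges.
#' @export
cylindrical_heatmap <- function(traj, res, geom, r_bins = 20, theta_bins = 24,
                                r_max = NULL, window_start = NULL,
                                jacobian = FALSE) {
  stopifnot(r_bins >= 1L, theta_bins >= 1L)
  if (is.null(r_max)) r_max <- geom$pore_radius
  pts <- inside_channel_coords(traj, res, geom, window_start)
  if (nrow(pts) == 0L) stop("empty map: no inside counts in the window")
  keep <- pts$R <= r_max
  if (!any(keep)) stop("empty map: no counts within r_max")
  re <- seq(0, r_max, length.out = r_bins + 1L)
  te <- seq(-pi, pi, length.out = theta_bins + 1L)
  prob <- bin2d(pts$R[keep], pts$theta[keep], re, te)
  if (jacobian) {
    area <- outer(diff(re^2) / 2, diff(te))   # annular sector areas
    prob <- prob / area
  }
  structure(list(plane = "R-theta", x_edges = re, y_edges = te,
                 prob = prob / sum(prob), n_counts = sum(keep),
                 jacobian = jacobian),
            class = "poredyn_map2d")
}

#' @export
print.poredyn_map2d <- function(x, ...) {
  cat(sprintf("<poredyn_map2d> %s plane, %d x %d cells, %d counts\n",
              x$plane, nrow(x$prob), ncol(x$prob), x$n_counts))
  invisible(x)
}

#' Time-averaged backbone reference overlay
#'
#' Averages the positions of named backbone atom groups (e.g. alpha carbons
#' and carbonyl oxygens) in the channel-aligned frame across frames, then
#' projects them to the requested plane.  With a co-rotating theta
#' reference the averaged points of a rigidly rotating ring stay sharp.
#'
#' @param traj a [trajectory()].
#' @param geom channel geometry.
#' @param groups named list of group names to overlay, e.g.
#'   `list(alpha_carbons = "ca", carbonyl_oxygens = "o")` where values are
#'   group names on the trajectory.
#' @param plane `"XY"`, `"XZ"` or `"YZ"`.
#' @return Data frame: `atom_class`, `u`, `v` (plane coordinates, angstrom).
#' @export
backbone_overlay <- function(traj, geom, groups, plane = c("XY", "XZ", "YZ")) {
  plane <- match.arg(plane)
  out <- lapply(names(groups), function(cls) {
    gname <- groups[[cls]]
    if (!gname %in% names(traj$groups))
      stop(sprintf("group '%s' is not defined on the trajectory", gname))
    idx <- traj$groups[[gname]]
    if (!length(idx)) stop(sprintf("group '%s' is empty", gname))
    acc <- matrix(0, length(idx), 3)
    for (f in seq_len(traj$n_frames)) {
      cyl <- to_cylindrical(frame_positions(traj, f)[idx, , drop = FALSE],
                            geom, f)
      acc <- acc + cbind(cyl$x, cyl$y, cyl$z)
    }
    acc <- acc / traj$n_frames
    sel <- switch(plane, XY = c(1, 2), XZ = c(1, 3), YZ = c(2, 3))
    data.frame(atom_class = cls, u = acc[, sel[1]], v = acc[, sel[2]])
  })
  do.call(rbind, out)
}

# channel-frame coordinates of every (inside particle, frame) observation
# within the analysis window
inside_channel_coords <- function(traj, res, geom, window_start = NULL) {
  times <- traj$times
  if (is.null(window_start)) window_start <- times[1] + 0.1 * diff(range(times))
  frames <- which(times >= window_start - 1e-9)
  rows <- vector("list", length(frames))
  for (j in seq_along(frames)) {
    f <- frames[j]
    ins <- res$flags[, f]
    if (!any(ins)) next
    pos <- frame_positions(traj, f)[res$particle_ids[ins], , drop = FALSE]
    rows[[j]] <- to_cylindrical(pos, geom, f)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(R = numeric(), theta = numeric(), z = numeric(),
                      x = numeric(), y = numeric()))
  do.call(rbind, rows)
}

bin_edges_covering <- function(x, w) {
  lo <- floor(min(x) / w) * w
  hi <- ceiling(max(x) / w) * w
  if (hi <= lo) hi <- lo + w
  seq(lo, hi + w / 2, by = w)
}

# 2D count matrix (u-bin x v-bin); values outside the edges are dropped
bin2d <- function(u, v, u_edges, v_edges) {
  nu <- length(u_edges) - 1L; nv <- length(v_edges) - 1L
  ui <- findInterval(u, u_edges, rightmost.closed = TRUE)
  vi <- findInterval(v, v_edges, rightmost.closed = TRUE)
  ok <- ui >= 1L & ui <= nu & vi >= 1L & vi <= nv
  m <- matrix(0, nu, nv)
  tb <- table(factor(ui[ok], levels = seq_len(nu)),
              factor(vi[ok], levels = seq_len(nv)))
  m[] <- as.numeric(tb)
  m
}
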