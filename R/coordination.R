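#' Contribution-decomposed radial distribution functions
#'
#' For each contributor species c, computes
#' `g_c(r) = <pair counts in [r, r+dr)> / (n_centers_inside * n_contributors_c * V_shell / V_box)`
#' averaged over window frames with at least one inside center.  Pair
#' distances use the minimum-image convention under the per-frame
#' orthorhombic box.  Normalizing by the number of centers, the number of
#' contributors and the ideal shell density gives the usual `g -> 1` bulk
#' limit for a uniform contributor gas.
#'
#' @param traj a [trajectory()].
#' @param res a [residency()] for the center group (e.g. a cation species);
#'   only inside centers contribute.
#' @param centers group name of the RDF centers.
#' @param contributors character vector of contributor group names (e.g.
#'   water oxygens, backbone carbonyl oxygens, chloride).
#' @param r_max,dr radial extent and shell width in angstrom
#'   (`r_max > dr > 0`).
#' @param window_start start of the analysis window (ps); default discards
#'   the first 10% of the trajectory.
#' @return A `poredyn_rdf`: `r` (shell midpoints), `g` (matrix shells x
#'   contributors), and `meta` (frame count, per-frame center counts,
#'   contributor counts, shell volumes, box volume) so every normalization
#'   factor is recomputable.
#' @export
rdf_decomposed <- function(traj, res, centers, contributors, r_max = 8,
                           dr = 0.1, window_start = NULL) {
  if (!(r_max > dr && dr > 0)) stop("require r_max > dr > 0")
  for (g in c(centers, contributors))
    if (!g %in% names(traj$groups))
      stop(sprintf("group '%s' is not defined on the trajectory", g))
  times <- traj$times
  if (is.null(window_start)) window_start <- times[1] + 0.1 * diff(range(times))
  frames <- which(times >= window_start - 1e-9)
  cidx <- traj$groups[[centers]]
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-9) edges <- c(edges, r_max)
  nb <- length(edges) - 1L
  counts <- matrix(0, nb, length(contributors),
                   dimnames = list(NULL, contributors))
  n_center_obs <- 0
  used <- 0L
  vbox <- numeric(0)
  for (f in frames) {
    ins <- res$flags[, f]
    if (!any(ins)) next
    used <- used + 1L
    box <- traj$box[f, ]
    vbox <- c(vbox, prod(box))
    cpos <- frame_positions(traj, f)[cidx[ins], , drop = FALSE]
    n_center_obs <- n_center_obs + nrow(cpos)
    pos_all <- frame_positions(traj, f)
    for (ci in seq_along(contributors)) {
      qpos <- pos_all[traj$groups[[contributors[ci]]], , drop = FALSE]
      d <- pair_min_image_dist(cpos, qpos, box)
      h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE,
                          right = FALSE, include.lowest = FALSE)$counts
      counts[, ci] <- counts[, ci] + h
    }
  }
  if (used == 0L) stop("no frames with an inside center in the window")
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  vb <- mean(vbox)
  n_contrib <- lengths(traj$groups[contributors])
  g <- counts
  for (ci in seq_along(contributors))
    g[, ci] <- counts[, ci] / (n_center_obs * n_contrib[ci] * shell_vol / vb)
  structure(list(
    r = (edges[-1] + edges[-length(edges)]) / 2, g = g, edges = edges,
    meta = list(n_frames_used = used, n_center_obs = n_center_obs,
                n_contributors = n_contrib, shell_volumes = shell_vol,
                box_volume = vb, counts = counts, dr = dr)),
    class = "poredyn_rdf")
}

# all pairwise minimum-image distances between two point sets (rows)
pair_min_image_dist <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dd <- outer(a[, k], b[, k], "-")
    dd <- dd - round(dd / box[k]) * box[k]
    d2 <- d2 + dd * dd
  }
  sqrt(d2)
}

#' First coordination-shell radius from an RDF
#'
#' The first-shell radius is the location of the first local minimum of a
#' lightly smoothed g(r) after the first peak.  The first peak is the first
#' local maximum that exceeds 1 and reaches at least half the global
#' maximum of the smoothed curve — the prominence requirement discards
#' shot-noise spikes from single close approaches, whose g value is large
#' only because the normalizing shell volume is tiny.  Smoothing is a
#' centered moving average (default 3 points).
#'
#' @param profile a [rdf_decomposed()] result.
#' @param contributor contributor column name (or index).
#' @param smooth odd moving-average width in points (1 = no smoothing).
#' @return Radius in angstrom.
#' @export
first_shell_radius <- function(profile, contributor = 1, smooth = 3) {
  g <- profile$g[, contributor]
  r <- profile$r
  if (smooth > 1) g <- stats::filter(g, rep(1 / smooth, smooth), sides = 2)
  g <- as.numeric(g)
  n <- length(g)
  gmax <- max(g, na.rm = TRUE)
  in_peak <- FALSE
  for (i in 2:(n - 1)) {
    if (any(is.na(g[(i - 1):(i + 1)]))) next
    if (!in_peak && g[i] > 1 && g[i] >= 0.5 * gmax &&
        g[i] >= g[i - 1] && g[i] >= g[i + 1])
      in_peak <- TRUE
    else if (in_peak && g[i] <= g[i - 1] && g[i] <= g[i + 1])
      return(r[i])
  }
  stop("no first shell: g(r) has no local maximum above 1 followed by a minimum")
}

#' Coordination numbers by direct neighbor counting
#'
#' For every frame in the window and every inside center, counts the
#' contributors of each species within that species' first-shell radius
#' (minimum image).  Means and SDs are over all (frame, center)
#' observations.
#'
#' @param traj,res,centers,contributors,window_start as in
#'   [rdf_decomposed()].
#' @param shell_radius numeric vector of first-shell radii (angstrom), one
#'   per contributor (recycled if length 1).
#' @return A data frame: `contributor`, `shell_radius_A`, `mean`, `sd`,
#'   `n_obs`.
#' @export
coordination_numbers <- function(traj, res, centers, contributors,
                                 shell_radius, window_start = NULL) {
  shell_radius <- rep_len(shell_radius, length(contributors))
  if (any(shell_radius <= 0)) stop("shell radii must be > 0")
  times <- traj$times
  if (is.null(window_start)) window_start <- times[1] + 0.1 * diff(range(times))
  frames <- which(times >= window_start - 1e-9)
  cidx <- traj$groups[[centers]]
  obs <- lapply(contributors, function(x) numeric(0))
  names(obs) <- contributors
  for (f in frames) {
    ins <- res$flags[, f]
    if (!any(ins)) next
    box <- traj$box[f, ]
    cpos <- frame_positions(traj, f)[cidx[ins], , drop = FALSE]
    pos_all <- frame_positions(traj, f)
    for (ci in seq_along(contributors)) {
      qpos <- pos_all[traj$groups[[contributors[ci]]], , drop = FALSE]
      d <- pair_min_image_dist(cpos, qpos, box)
      obs[[ci]] <- c(obs[[ci]], rowSums(d <= shell_radius[ci]))
    }
  }
  if (!length(obs[[1]])) stop("no (frame, center) observations in the window")
  data.frame(contributor = contributors, shell_radius_A = shell_radius,
             mean = vapply(obs, mean, numeric(1)),
             sd = vapply(obs, stats::sd, numeric(1)),
             n_obs = lengths(obs), row.names = NULL)
}

#' Coordination number by RDF integration
#'
#' `N = 4 pi rho integral_0^rs g(r) r^2 dr`, with `rho` the contributor
#' number density and the integral taken as a midpoint sum over the RDF
#' shells up to the shell radius.  An independent cross-check of
#' [coordination_numbers()].
#'
#' @param profile a [rdf_decomposed()] result.
#' @param contributor contributor column name or index.
#' @param shell_radius integration limit (angstrom).
#' @return Estimated coordination number.
#' @export
coordination_from_rdf <- function(profile, contributor, shell_radius) {
  rho <- profile$meta$n_contributors[[contributor]] / profile$meta$box_volume
  keep <- profile$r <= shell_radius
  dr <- diff(profile$edges)[keep]
  sum(4 * pi * rho * profile$g[keep, contributor] * profile$r[keep]^2 * dr)
}

#' Geometric hydrogen-bond criteria
#'
#' @param dist_cutoff donor-acceptor distance cutoff in angstrom.
#' @param angle_cutoff minimum donor-hydrogen-acceptor angle in degrees
#'   (180 = perfectly linear).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(dist_cutoff = 3.5, angle_cutoff = 150) {
  stopifnot(dist_cutoff > 0, angle_cutoff > 0, angle_cutoff <= 180)
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Count geometric hydrogen bonds in one frame
#'
#' A donor-acceptor pair is bonded when the D...A distance is at most the
#' distance cutoff and the D-H...A angle is at least the angle cutoff.
#' Distances are minimum-image when a box is supplied.
#'
#' @param positions `n x 3` coordinate matrix (angstrom).
#' @param donors two-column integer matrix of (donor, hydrogen) index pairs.
#' @param acceptors integer vector of acceptor indices.
#' @param criteria an [hbond_criteria()].
#' @param box optional length-3 box for minimum-image distances.
#' @param labels optional character vector of per-donor classification
#'   labels (e.g. `"CP-CP"`, `"water-CO(Trp)"`), carried into the pair list.
#' @return List: `count`, and `pairs` (data frame `donor`, `hydrogen`,
#'   `acceptor`, `dist_A`, `angle_deg`, `label`).
#' @export
count_hbonds <- function(positions, donors, acceptors, criteria = hbond_criteria(),
                         box = NULL, labels = NULL) {
  if (!is.matrix(donors) || ncol(donors) != 2L)
    stop("donors must be a two-column (donor, hydrogen) index matrix")
  if (any(donors < 1L) || any(donors > nrow(positions)) ||
      any(acceptors < 1L) || any(acceptors > nrow(positions)))
    stop("donor/acceptor indices out of range")
  mi <- function(d) if (is.null(box)) d else d - round(sweep(d, 2, box, "/")) *
    matrix(box, nrow(d), 3, byrow = TRUE)
  rows <- list()
  for (i in seq_len(nrow(donors))) {
    D <- donors[i, 1]; H <- donors[i, 2]
    dh <- mi(matrix(positions[H, ] - positions[D, ], 1))[1, ]
    da <- mi(sweep(positions[acceptors, , drop = FALSE], 2, positions[D, ]))
    dist_da <- sqrt(rowSums(da^2))
    ha <- mi(sweep(positions[acceptors, , drop = FALSE], 2, positions[H, ]))
    # D-H...A angle at the hydrogen: vectors H->D and H->A
    hd <- -dh
    cosang <- (ha %*% hd) / (sqrt(rowSums(ha^2)) * sqrt(sum(hd^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    ok <- which(dist_da <= criteria$dist_cutoff &
                  ang >= criteria$angle_cutoff &
                  acceptors != D & acceptors != H)
    if (length(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        donor = D, hydrogen = H, acceptor = acceptors[ok],
        dist_A = dist_da[ok], angle_deg = ang[ok],
        label = if (is.null(labels)) NA_character_ else labels[i])
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               dist_A = numeric(), angle_deg = numeric(), label = character())
  list(count = nrow(pairs), pairs = pairs)
}

#' Per-frame hydrogen-bond counts along a trajectory
#'
#' @param traj a [trajectory()].
#' @param donors,acceptors,criteria,labels as in [count_hbonds()].
#' @return Data frame: `time_ps`, `count`.
#' @export
hbond_series <- function(traj, donors, acceptors, criteria = hbond_criteria(),
                         labels = NULL) {
  counts <- vapply(seq_len(traj$n_frames), function(f)
    count_hbonds(frame_positions(traj, f), donors, acceptors, criteria,
                 box = traj$box[f, ], labels = labels)$count, numeric(1))
  data.frame(time_ps = traj$times, count = counts)
}

#' Theoretical maximum number of inter-ring backbone hydrogen bonds
#'
#' A nanotube of `n_rings` stacked cyclic peptides has `n_rings - 1` ring
#' interfaces; with `bonds_per_interface` backbone hydrogen bonds possible
#' at each interface the theoretical maximum is
#' `(n_rings - 1) * bonds_per_interface`.  For an eight-ring tube with 12
#' bonds per CP pair this gives 84.
#'
#' @param n_rings number of stacked rings (>= 1).
#' @param bonds_per_interface H-bonds formable per adjacent ring pair (>= 0).
#' @return Integer count.
#' @export
theoretical_max_hbonds <- function(n_rings, bonds_per_interface) {
  stopifnot(n_rings >= 1, bonds_per_interface >= 0)
  as.integer(round((n_rings - 1) * bonds_per_interface))
}
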