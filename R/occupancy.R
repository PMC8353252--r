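#' Classify tracked particles as inside or outside the pore
#'
#' A particle is inside at frame f iff its radial distance from the channel
#' axis satisfies `R <= pore_radius` and its axial projection lies within
#' `[z_lo, z_hi]` for that frame.  For water only the oxygen site should be
#' tracked; for ions the ion site itself.
#'
#' @param traj a [trajectory()].
#' @param geom a [fit_channel_axis()] result covering all frames.
#' @param tracked_group name of the group to classify.
#' @return A `poredyn_residency`: logical matrix `flags` of dim
#'   `(n_tracked, n_frames)`, with `particle_ids` (1-based trajectory
#'   indices) and `times` (ps).
#' @export
classify_inside <- function(traj, geom, tracked_group) {
  if (!tracked_group %in% names(traj$groups))
    stop(sprintf("group '%s' is not defined on the trajectory", tracked_group))
  idx <- traj$groups[[tracked_group]]
  if (length(idx) == 0L) stop(sprintf("group '%s' is empty", tracked_group))
  if (geom$n_frames != traj$n_frames)
    stop("geometry does not cover all trajectory frames")
  nf <- traj$n_frames
  flags <- matrix(FALSE, length(idx), nf)
  for (f in seq_len(nf)) {
    d <- sweep(frame_positions(traj, f)[idx, , drop = FALSE], 2, geom$origin[f, ])
    zax <- as.numeric(d %*% geom$axis[f, ])
    R2 <- rowSums(d^2) - zax^2
    flags[, f] <- (R2 <= geom$pore_radius^2 + 1e-12) &
      (zax >= geom$z_lo[f]) & (zax <= geom$z_hi[f])
  }
  residency(flags, particle_ids = idx, times = traj$times)
}

#' Construct a residency matrix
#'
#' @param flags logical matrix, one row per tracked particle, one column per
#'   frame; `TRUE` means inside the pore.
#' @param particle_ids particle identifiers (defaults to row numbers).
#' @param times frame times in ps (defaults to 0, 1, ...).
#' @return A `poredyn_residency` object.
#' @export
residency <- function(flags, particle_ids = NULL, times = NULL) {
  stopifnot(is.matrix(flags), is.logical(flags))
  if (is.null(particle_ids)) particle_ids <- seq_len(nrow(flags))
  if (is.null(times)) times <- seq_len(ncol(flags)) - 1
  stopifnot(length(particle_ids) == nrow(flags), length(times) == ncol(flags))
  structure(list(flags = flags, particle_ids = particle_ids,
                 times = as.numeric(times)),
            class = "poredyn_residency")
}

#' @export
print.poredyn_residency <- function(x, ...) {
  cat(sprintf("<poredyn_residency> %d particles x %d frames, %.1f%% inside\n",
              nrow(x$flags), ncol(x$flags), 100 * mean(x$flags)))
  invisible(x)
}

#' Occupancy counts and window statistics
#'
#' Per-frame occupancy is the number of tracked particles inside the pore;
#' the mean and SD are computed over frames whose time lies in
#' `[window_start, window_end]`.  The default window discards the first 10%
#' of the trajectory, mirroring production-run practice of dropping the
#' initial transient.
#'
#' @param res a [residency()].
#' @param window_start,window_end analysis window (ps).  Defaults: the last
#'   90% of the time span.
#' @return List with `counts` (per frame), `times`, `window`, `mean`, `sd`,
#'   `n_frames_used`.
#' @export
occupancy_stats <- function(res, window_start = NULL, window_end = NULL) {
  times <- res$times
  if (is.null(window_start)) window_start <- times[1] + 0.1 * diff(range(times))
  if (is.null(window_end)) window_end <- times[length(times)]
  counts <- colSums(res$flags)
  keep <- times >= window_start & times <= window_end
  if (!any(keep)) stop("empty analysis window")
  list(counts = counts, times = times,
       window = c(window_start, window_end),
       mean = mean(counts[keep]),
       sd = stats::sd(counts[keep]),
       n_frames_used = sum(keep))
}

#' Axial traces and z-presence histogram of inside particles
#'
#' For each tracked particle, emits its (time, z) sequence restricted to
#' frames where it is inside the pore; additionally counts, per axial bin,
#' the number of frames in which at least one inside particle occupies that
#' bin.
#'
#' @param res a [residency()] aligned with `traj`.
#' @param traj the [trajectory()].
#' @param geom the channel geometry.
#' @param z_bin_width axial bin width in angstrom (> 0).
#' @return List with `traces` (data frame: `particle_id`, `time_ps`, `z_A`)
#'   and `histogram` (data frame: `z_bin_center`, `frames_with_presence`).
#' @export
z_traces <- function(res, traj, geom, z_bin_width = 1) {
  if (z_bin_width <= 0) stop("z bin width must be > 0")
  if (ncol(res$flags) != traj$n_frames)
    stop("residency and trajectory are not frame-aligned")
  nf <- traj$n_frames
  zmat <- matrix(NA_real_, nrow(res$flags), nf)
  for (f in seq_len(nf)) {
    pos <- frame_positions(traj, f)[res$particle_ids, , drop = FALSE]
    zmat[, f] <- to_cylindrical(pos, geom, f)$z
  }
  inside <- res$flags
  tr <- data.frame(
    particle_id = rep(res$particle_ids, times = rowSums(inside)),
    time_ps = unlist(lapply(seq_len(nrow(inside)), function(i)
      res$times[inside[i, ]]), use.names = FALSE),
    z_A = unlist(lapply(seq_len(nrow(inside)), function(i)
      zmat[i, inside[i, ]]), use.names = FALSE))
  z_min <- min(geom$z_lo - geom$z_mid); z_max <- max(geom$z_hi - geom$z_mid)
  edges <- seq(floor(z_min / z_bin_width) * z_bin_width,
               ceiling(z_max / z_bin_width) * z_bin_width + z_bin_width / 2,
               by = z_bin_width)
  nb <- length(edges) - 1L
  present <- integer(nb)
  for (f in seq_len(nf)) {
    zin <- zmat[inside[, f], f]
    if (!length(zin)) next
    b <- findInterval(zin, edges, rightmost.closed = TRUE)
    b <- b[b >= 1L & b <= nb]
    present[unique(b)] <- present[unique(b)] + 1L
  }
  list(traces = tr,
       histogram = data.frame(z_bin_center = (edges[-1] + edges[-length(edges)]) / 2,
                              frames_with_presence = present))
}
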