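#' Construct a trajectory object
#'
#' A `poredyn_traj` holds an ordered set of frames of particle positions
#' (angstrom), the stored-frame times (ps), per-frame orthorhombic box
#' lengths, and named particle groups (1-based index vectors).
#'
#' @param coords numeric array with dim `(n_particles, 3, n_frames)`, in
#'   angstrom.
#' @param times numeric vector of frame times in ps; must be strictly
#'   increasing with constant spacing.
#' @param box per-frame box lengths: either a length-3 vector (constant box)
#'   or an `n_frames x 3` matrix, in angstrom.
#' @param groups named list of 1-based particle index vectors.
#'
#' @return An object of class `poredyn_traj` with fields `coords`, `times`,
#'   `box`, `groups`, `n_frames`, `n_particles`, `dt_saved`.
#' @export
trajectory <- function(coords, times, box, groups = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_particles <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (length(times) != n_frames)
    stop("times must have one entry per frame")
  if (n_frames > 1) {
    dts <- diff(times)
    if (any(dts <= 0))
      stop("frame times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts))
      stop("non-constant frame spacing: trajectory must be saved on a uniform time grid")
    dt_saved <- mean(dts)
  } else {
    dt_saved <- NA_real_
  }
  if (is.null(dim(box))) {
    if (length(box) != 3L) stop("box must be a length-3 vector or an n_frames x 3 matrix")
    box <- matrix(rep(box, each = n_frames), nrow = n_frames)
  }
  if (!all(dim(box) == c(n_frames, 3L)))
    stop("box must be a length-3 vector or an n_frames x 3 matrix")
  if (any(box <= 0)) stop("box lengths must be > 0")
  if (length(groups)) {
    if (is.null(names(groups)) || any(!nzchar(names(groups))))
      stop("groups must be a named list")
    for (g in names(groups)) {
      idx <- groups[[g]]
      if (length(idx) == 0L)
        stop(sprintf("group '%s' selects zero particles", g))
      if (any(idx < 1L) || any(idx > n_particles))
        stop(sprintf("group '%s' contains indices outside 1..%d", g, n_particles))
      groups[[g]] <- as.integer(idx)
    }
  }
  structure(
    list(coords = coords, times = as.numeric(times), box = box,
         groups = groups, n_frames = n_frames, n_particles = n_particles,
         dt_saved = dt_saved),
    class = "poredyn_traj")
}

#' @export
print.poredyn_traj <- function(x, ...) {
  cat(sprintf("<poredyn_traj> %d particles x %d frames, dt = %s ps\n",
              x$n_particles, x$n_frames, format(x$dt_saved)))
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s[%d]", names(x$groups),
                                   lengths(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Positions of one frame
#'
#' @param traj a `poredyn_traj`.
#' @param frame frame index (1-based).
#' @return `n_particles x 3` matrix of coordinates (angstrom).
#' @export
frame_positions <- function(traj, frame) {
  stopifnot(frame >= 1L, frame <= traj$n_frames)
  traj$coords[, , frame, drop = FALSE][, , 1]
}

# ---- fixture trajectory dialect -------------------------------------------
# Whitespace-delimited text: one header line
#   n_frames n_particles dt_saved box_x box_y box_z
# followed by n_frames blocks of n_particles "x y z" lines (angstrom, ps).

#' Write a trajectory in the plain-text fixture dialect
#'
#' The dialect is a whitespace-delimited text format: a single header line
#' `n_frames n_particles dt_saved box_x box_y box_z`, then one block of
#' `n_particles` lines `x y z` per frame.  The box is constant across frames
#' in this dialect.  Coordinates in angstrom, times in ps.
#'
#' @param traj a `poredyn_traj`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fixture_trajectory <- function(traj, path) {
  box <- traj$box[1, ]
  header <- paste(c(traj$n_frames, traj$n_particles,
                    format(if (is.na(traj$dt_saved)) 1 else traj$dt_saved, digits = 17),
                    format(box, digits = 17)), collapse = " ")
  blocks <- vapply(seq_len(traj$n_frames), function(f) {
    m <- frame_positions(traj, f)
    paste(apply(format(m, digits = 17, trim = TRUE, scientific = FALSE), 1L,
                paste, collapse = " "), collapse = "\n")
  }, character(1))
  writeLines(c(header, blocks), path)
  invisible(path)
}

read_fixture_trajectory <- function(path) {
  if (!file.exists(path))
    stop(sprintf("trajectory file not found: %s", path))
  con <- file(path, "r"); on.exit(close(con))
  header <- scan(con, what = numeric(), nlines = 1, quiet = TRUE)
  if (length(header) != 6L)
    stop(sprintf("malformed fixture header in %s (expected 6 fields)", path))
  n_frames <- as.integer(header[1]); n_particles <- as.integer(header[2])
  dt_saved <- header[3]; box <- header[4:6]
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != 3L * n_particles * n_frames)
    stop(sprintf("fixture %s: expected %d coordinates, found %d",
                 path, 3L * n_particles * n_frames, length(vals)))
  # values are row-major per frame block: particle fastest over x y z
  coords <- array(NA_real_, dim = c(n_particles, 3L, n_frames))
  per_frame <- 3L * n_particles
  for (f in seq_len(n_frames)) {
    block <- matrix(vals[((f - 1L) * per_frame + 1L):(f * per_frame)],
                    ncol = 3L, byrow = TRUE)
    coords[, , f] <- block
  }
  trajectory(coords, times = (seq_len(n_frames) - 1) * dt_saved, box = box)
}

# ---- GRO / PDB topologies --------------------------------------------------

read_gro_topology <- function(path) {
  if (!file.exists(path)) stop(sprintf("topology file not found: %s", path))
  lines <- readLines(path)
  n_atoms <- as.integer(trimws(lines[2]))
  at <- lines[3:(2 + n_atoms)]
  # fixed-width: resid(5) resname(5) name(5) serial(5) x(8) y(8) z(8) [nm]
  resid <- as.integer(substr(at, 1, 5))
  resname <- trimws(substr(at, 6, 10))
  name <- trimws(substr(at, 11, 15))
  x <- as.numeric(substr(at, 21, 28))
  y <- as.numeric(substr(at, 29, 36))
  z <- as.numeric(substr(at, 37, 44))
  boxline <- as.numeric(strsplit(trimws(lines[3 + n_atoms]), "\\s+")[[1]])
  list(atoms = data.frame(resid = resid, resname = resname, name = name,
                          stringsAsFactors = FALSE),
       coords = cbind(x, y, z) * 10,          # nm -> angstrom
       box = boxline[1:3] * 10)
}

read_pdb_topology <- function(path) {
  if (!file.exists(path)) stop(sprintf("topology file not found: %s", path))
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB topologies requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  list(atoms = data.frame(resid = a$resno, resname = a$resid, name = a$elety,
                          stringsAsFactors = FALSE),
       coords = cbind(a$x, a$y, a$z),        # already angstrom
       box = NULL)
}

resolve_group <- function(sel, group_name, atoms, n_particles) {
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
  } else if (is.character(sel) && length(sel) >= 1L) {
    # mini selection language: "name OW HW1", "resname TRP", "index 1 4 9"
    toks <- strsplit(paste(sel, collapse = " "), "\\s+")[[1]]
    key <- toks[1]; vals <- toks[-1]
    if (is.null(atoms) && key != "index")
      stop(sprintf("group '%s': name-based selection requires a topology", group_name))
    idx <- switch(key,
      name    = which(atoms$name %in% vals),
      resname = which(atoms$resname %in% vals),
      index   = as.integer(vals),
      stop(sprintf("group '%s': unknown selection keyword '%s'", group_name, key)))
  } else stop(sprintf("group '%s': selection must be indices or a selection string",
                      group_name))
  if (length(idx) == 0L)
    stop(sprintf("group '%s' matches zero particles", group_name))
  if (any(idx < 1L) || any(idx > n_particles))
    stop(sprintf("group '%s' selects particle indices outside 1..%d",
                 group_name, n_particles))
  idx
}

#' Load a trajectory with named particle groups
#'
#' Supported inputs: the plain-text fixture dialect (pass its path as
#' `trajectory_path`, `topology_path = NULL`); a GRO or PDB topology alone
#' (single-frame trajectory); or a GRO/PDB topology plus a DCD trajectory
#' (read via \pkg{bio3d}).  GRO coordinates (nm) are converted to angstrom on
#' load; everything downstream is angstrom/ps.
#'
#' @param topology_path GRO/PDB file, or `NULL` for the fixture dialect.
#' @param trajectory_path fixture-dialect text file or DCD file; `NULL` to
#'   use the topology's single frame.
#' @param group_defs named list; each element is a 1-based integer index
#'   vector or a selection string (`"name OW"`, `"resname TRP"`,
#'   `"index 1 2 3"`).
#' @param dt_saved frame spacing in ps for formats that do not store times
#'   (DCD, single-frame topologies).
#' @return A [trajectory()] object with the requested groups resolved.
#' @export
load_trajectory <- function(topology_path = NULL, trajectory_path = NULL,
                            group_defs = list(), dt_saved = 1) {
  atoms <- NULL
  if (is.null(topology_path)) {
    if (is.null(trajectory_path)) stop("either a topology or a trajectory path is required")
    traj <- read_fixture_trajectory(trajectory_path)
  } else {
    ext <- tolower(tools::file_ext(topology_path))
    top <- switch(ext,
                  gro = read_gro_topology(topology_path),
                  pdb = read_pdb_topology(topology_path),
                  stop(sprintf("unsupported topology format '.%s' (use GRO or PDB)", ext)))
    atoms <- top$atoms
    if (is.null(trajectory_path)) {
      n <- nrow(top$coords)
      box <- if (is.null(top$box)) apply(top$coords, 2, function(v) diff(range(v)) + 20) else top$box
      traj <- trajectory(array(top$coords, dim = c(n, 3L, 1L)), times = 0, box = box)
    } else {
      text <- tolower(tools::file_ext(trajectory_path))
      if (text == "dcd") {
        if (!file.exists(trajectory_path))
          stop(sprintf("trajectory file not found: %s", trajectory_path))
        if (!requireNamespace("bio3d", quietly = TRUE))
          stop("reading DCD trajectories requires the 'bio3d' package")
        xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
        n_frames <- nrow(xyz); n <- ncol(xyz) / 3L
        coords <- array(NA_real_, dim = c(n, 3L, n_frames))
        for (f in seq_len(n_frames))
          coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
        box <- if (is.null(top$box)) apply(coords, 2, max) - apply(coords, 2, min) + 20 else top$box
        traj <- trajectory(coords, times = (seq_len(n_frames) - 1) * dt_saved, box = box)
      } else {
        traj <- read_fixture_trajectory(trajectory_path)
      }
    }
  }
  groups <- lapply(names(group_defs), function(g)
    resolve_group(group_defs[[g]], g, atoms, traj$n_particles))
  names(groups) <- names(group_defs)
  traj$groups <- groups
  traj$atoms <- atoms
  traj
}

#' Wrap all coordinates into the primary cell
#'
#' Maps every coordinate into `[0, L)` per dimension using the per-frame
#' orthorhombic box.  Idempotent; particle identities are untouched.
#'
#' @param traj a `poredyn_traj`.
#' @return The wrapped trajectory.
#' @export
wrap_into_cell <- function(traj) {
  if (any(traj$box <= 0)) stop("zero or negative box length")
  for (f in seq_len(traj$n_frames)) {
    b <- traj$box[f, ]
    m <- traj$coords[, , f, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    for (d in 1:3) m[, d] <- m[, d] - floor(m[, d] / b[d]) * b[d]
    traj$coords[, , f] <- m
  }
  traj
}

# minimum-image displacement a -> b under orthorhombic box (vector of 3 lengths)
min_image <- function(d, box) {
  d - round(sweep_div(d, box)) * rep_box(d, box)
}

# helpers keeping min_image shape-agnostic (vector or matrix rows = points)
sweep_div <- function(d, box) {
  if (is.matrix(d)) sweep(d, 2, box, "/") else d / box
}
rep_box <- function(d, box) {
  if (is.matrix(d)) matrix(box, nrow = nrow(d), ncol = 3, byrow = TRUE) else box
}
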