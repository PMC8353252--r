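#' Validate an analysis configuration
#'
#' A configuration is a named list (or a YAML file path) with exactly one
#' of `input` (paths + group definitions for a stored trajectory) or
#' `synthetic` (a generator block: `kind = "brownian"` with
#' [pore_model_params()] fields, or `kind = "dwell"` with
#' [dwell_process_params()] fields); a `geometry` block (`backbone_group`,
#' `pore_radius`, `z_pad`, optional `theta_ref_group`, `mode`); a
#' `tracked_group`; a `stages` character vector among `"occupancy"`,
#' `"survival"`, `"velocity"`, `"maps"`, `"coordination"`, `"hbonds"`; an
#' `outdir`; a `seed`; and optional per-stage parameter blocks.
#' All violations are collected and reported together.
#'
#' @param config named list or YAML path.
#' @return The normalized config list, invisibly; errors list every
#'   violation.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  problems <- character(0)
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth)
    problems <- c(problems,
                  "exactly one of 'input' or 'synthetic' must be present")
  if (is.null(config$outdir)) problems <- c(problems, "'outdir' is required")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$stages))
    config$stages <- c("occupancy", "survival")
  known <- c("occupancy", "survival", "velocity", "maps", "coordination",
             "hbonds")
  bad <- setdiff(config$stages, known)
  if (length(bad))
    problems <- c(problems, sprintf("unknown stage(s): %s",
                                    paste(bad, collapse = ", ")))
  if (has_synth) {
    kind <- config$synthetic$kind
    if (is.null(kind) || !kind %in% c("brownian", "dwell"))
      problems <- c(problems, "synthetic$kind must be 'brownian' or 'dwell'")
  }
  if (has_input && is.null(config$input$trajectory) && is.null(config$input$topology))
    problems <- c(problems, "input block needs 'trajectory' and/or 'topology' paths")
  # groups referenced anywhere must be defined (input groups are resolved at
  # load time; synthetic trajectories define 'tracked'/'backbone')
  defined <- if (has_input) names(config$input$groups) else
    c(if (identical(config$synthetic$kind, "brownian")) c("tracked", "backbone"))
  referenced <- c(config$tracked_group, config$geometry$backbone_group,
                  config$geometry$theta_ref_group,
                  config$coordination$centers,
                  unlist(config$coordination$contributors))
  if (!identical(config$synthetic$kind, "dwell")) {
    for (g in referenced)
      if (!is.null(g) && !g %in% defined)
        problems <- c(problems, sprintf("referenced group '%s' is not defined", g))
  }
  if (length(problems))
    stop(paste(c("invalid configuration:",
                 paste0("  - ", problems)), collapse = "\n"))
  invisible(config)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tf))
}

write_num_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  path
}

#' Run the configured analysis pipeline
#'
#' Executes the requested stages in dependency order (load or simulate,
#' then geometry and residency, then the independent analyses), writing
#' per-stage CSV outputs and a machine-readable JSON report into
#' `config$outdir`.  Every output carries the config hash and seed, and a
#' failing stage is recorded in the report without corrupting the outputs
#' of stages that already completed.
#'
#' @param config a config list or YAML path (see [validate_config()]).
#' @return The report list, invisibly.
#' @export
run_full_analysis <- function(config) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  hash <- config_hash(config)
  report <- list(config_hash = hash, seed = seed, stages = list(),
                 files = character(0))
  add_file <- function(path) report$files <<- c(report$files, basename(path))
  res <- NULL; traj <- NULL; geom <- NULL
  # ---- input stage ----
  if (!is.null(config$synthetic) && config$synthetic$kind == "dwell") {
    pars <- config$synthetic[setdiff(names(config$synthetic), "kind")]
    pars$seed <- seed
    sim <- do.call(dwell_process_params, pars)
    out <- simulate_dwell_process(sim)
    res <- out$res
    report$stages$input <- list(kind = "synthetic_dwell",
                                n_events = out$truth$n_events)
  } else {
    if (!is.null(config$synthetic)) {
      pars <- config$synthetic[setdiff(names(config$synthetic),
                                       c("kind", "n_particles", "duration"))]
      pars$seed <- seed
      pm <- do.call(pore_model_params, pars)
      sim <- simulate_confined_brownian(
        pm, n_particles = config$synthetic$n_particles %||% 50,
        duration = config$synthetic$duration %||% 200)
      traj <- sim$traj
      report$stages$input <- list(kind = "synthetic_brownian",
                                  n_frames = traj$n_frames)
    } else {
      traj <- load_trajectory(config$input$topology,
                              config$input$trajectory,
                              group_defs = config$input$groups %||% list(),
                              dt_saved = config$input$dt_saved %||% 1)
      report$stages$input <- list(kind = "loaded", n_frames = traj$n_frames)
    }
    geo <- config$geometry %||% list()
    geom <- fit_channel_axis(
      traj,
      backbone_group = geo$backbone_group %||% "backbone",
      pore_radius = geo$pore_radius %||% 9,
      z_pad = geo$z_pad %||% 2,
      theta_ref_group = geo$theta_ref_group,
      mode = geo$mode %||% "fitted")
    res <- classify_inside(traj, geom, config$tracked_group %||% "tracked")
  }
  window_start <- config$window_start %||%
    (res$times[1] + 0.1 * diff(range(res$times)))
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    r <- tryCatch(fun(), error = function(e)
      list(error = conditionMessage(e)))
    report$stages[[name]] <<- r
  }
  run_stage("occupancy", function() {
    occ <- occupancy_stats(res, window_start = window_start)
    f1 <- file.path(outdir, "occupancy.csv")
    write_num_csv(data.frame(time_ps = occ$times, count = occ$counts), f1)
    add_file(f1)
    out <- list(mean = occ$mean, sd = occ$sd, n_frames_used = occ$n_frames_used)
    if (!is.null(traj)) {
      zt <- z_traces(res, traj, geom,
                     z_bin_width = config$occupancy$z_bin_width %||% 1)
      f2 <- file.path(outdir, "z_traces.csv")
      write_num_csv(zt$traces, f2); add_file(f2)
      f3 <- file.path(outdir, "z_histogram.csv")
      write_num_csv(zt$histogram, f3); add_file(f3)
    }
    out
  })
  run_stage("survival", function() {
    sv <- survival_probability(
      res, tau_max = config$survival$tau_max %||% NULL,
      convention = config$survival$convention %||% "continuous",
      origins = config$survival$origins %||% "fixed")
    f <- file.path(outdir, "survival.csv")
    write_num_csv(data.frame(tau_ps = sv$tau, P = sv$P), f); add_file(f)
    list(tau_half_ps = sv$tau_half, convention = sv$convention)
  })
  run_stage("velocity", function() {
    if (is.null(traj)) stop("velocity stage requires a positional trajectory")
    vel <- windowed_velocities(traj, res, geom,
                               window = config$velocity$window %||% 10,
                               discard = config$velocity$discard %||% 0)
    f <- file.path(outdir, "velocities.csv")
    write_num_csv(vel, f); add_file(f)
    sh <- speed_distribution(vel)
    f2 <- file.path(outdir, "speed_histogram.csv")
    write_num_csv(data.frame(edge_lo = sh$edges[-length(sh$edges)],
                             edge_hi = sh$edges[-1], prob = sh$prob), f2)
    add_file(f2)
    list(n_samples = nrow(vel), mean_speed = mean(vel$speed),
         fd_binwidth = sh$binwidth)
  })
  run_stage("maps", function() {
    if (is.null(traj)) stop("maps stage requires a positional trajectory")
    out <- list()
    for (pl in c("XY", "XZ", "YZ")) {
      m <- planar_heatmap(traj, res, geom, plane = pl,
                          bin_width = config$maps$bin_width %||% 0.25,
                          window_start = window_start)
      f <- file.path(outdir, sprintf("heatmap_%s.csv", pl))
      write_num_csv(map_to_long(m), f); add_file(f)
      out[[pl]] <- list(n_counts = m$n_counts)
    }
    cm <- cylindrical_heatmap(traj, res, geom,
                              r_bins = config$maps$r_bins %||% 20,
                              theta_bins = config$maps$theta_bins %||% 24,
                              window_start = window_start)
    f <- file.path(outdir, "heatmap_Rtheta.csv")
    write_num_csv(map_to_long(cm), f); add_file(f)
    out$Rtheta <- list(n_counts = cm$n_counts)
    out
  })
  run_stage("coordination", function() {
    if (is.null(traj)) stop("coordination stage requires a positional trajectory")
    cc <- config$coordination
    if (is.null(cc$centers) || is.null(cc$contributors))
      stop("coordination stage needs 'centers' and 'contributors' groups")
    prof <- rdf_decomposed(traj, res, cc$centers, unlist(cc$contributors),
                           r_max = cc$r_max %||% 8, dr = cc$dr %||% 0.1,
                           window_start = window_start)
    f <- file.path(outdir, "rdf.csv")
    write_num_csv(data.frame(r_A = prof$r, prof$g, check.names = FALSE), f)
    add_file(f)
    radii <- vapply(unlist(cc$contributors), function(ct)
      tryCatch(first_shell_radius(prof, ct), error = function(e) NA_real_),
      numeric(1))
    ok <- !is.na(radii)
    out <- list(first_shell_radii = as.list(radii))
    if (any(ok)) {
      tab <- coordination_numbers(traj, res, cc$centers,
                                  unlist(cc$contributors)[ok], radii[ok],
                                  window_start = window_start)
      f2 <- file.path(outdir, "coordination.csv")
      write_num_csv(tab, f2); add_file(f2)
      out$table <- tab
    }
    out
  })
  run_stage("hbonds", function() {
    if (is.null(traj)) stop("hbonds stage requires a positional trajectory")
    hb <- config$hbonds
    if (is.null(hb$donors) || is.null(hb$acceptors))
      stop("hbonds stage needs 'donors' (D,H pairs) and 'acceptors' indices")
    donors <- matrix(as.integer(unlist(hb$donors)), ncol = 2, byrow = TRUE)
    crit <- hbond_criteria(hb$dist_cutoff %||% 3.5, hb$angle_cutoff %||% 150)
    series <- hbond_series(traj, donors, as.integer(unlist(hb$acceptors)), crit)
    f <- file.path(outdir, "hbonds.csv")
    write_num_csv(series, f); add_file(f)
    list(mean_count = mean(series$count),
         theoretical_max = theoretical_max_hbonds(hb$n_rings %||% 8,
                                                  hb$bonds_per_interface %||% 12))
  })
  write_report(report, file.path(outdir, "report.json"))
  invisible(report)
}

map_to_long <- function(m) {
  xc <- (m$x_edges[-1] + m$x_edges[-length(m$x_edges)]) / 2
  yc <- (m$y_edges[-1] + m$y_edges[-length(m$y_edges)]) / 2
  data.frame(bin_x = rep(xc, times = length(yc)),
             bin_y = rep(yc, each = length(xc)),
             probability = as.vector(m$prob))
}

#' Write the structured analysis report
#'
#' @param report a report list from [run_full_analysis()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
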