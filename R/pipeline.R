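# End-to-end analysis runs: a validated configuration drives one
# tessellation pass shared by all requested analyses, with CSV outputs
# and a JSON manifest for provenance.

#' Build and validate a pipeline run configuration
#'
#' @param trajectory Path to the trajectory file.
#' @param topology Path to the topology YAML.
#' @param format Trajectory format (see [read_trajectory()]).
#' @param output_dir Output directory (created if missing).
#' @param analyses Character vector from `"shells"`, `"rdf"`, `"thermo"`,
#'   `"residence"`, `"energy"`, `"hbonds"` (or `"all"`).
#' @param bin_width,r_max RDF binning parameters (Angstrom).
#' @param R_override Manual first-shell radius (Angstrom) for the
#'   Kirkwood-Buff summary; `NULL` uses the first minimum.
#' @param max_shell Largest shell resolved in the census.
#' @param cutoff Pair-energy cutoff (Angstrom).
#' @param temperature Temperature (K) for solvation free energies.
#' @param d_max,angle_min Hydrogen-bond criterion.
#' @param max_lag Residence correlation maximum lag (ps).
#' @param min_face_area Tessellation face filter (Angstrom^2).
#' @param seed Integer seed recorded in the manifest.
#' @return A validated `run_config` list.
#' @export
run_config <- function(trajectory, topology, format = "auto",
                       output_dir = "voroshell_out",
                       analyses = "all", bin_width = 0.1, r_max = NULL,
                       R_override = NULL, max_shell = 3, cutoff = 14,
                       temperature = 300, d_max = 2.4, angle_min = 135,
                       max_lag = NULL, min_face_area = 1e-6, seed = 1) {
  all_analyses <- c("shells", "rdf", "thermo", "residence", "energy",
                    "hbonds")
  if (identical(analyses, "all")) analyses <- all_analyses
  bad <- setdiff(analyses, all_analyses)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  if (!file.exists(trajectory)) stop("trajectory file not found: ", trajectory)
  if (!file.exists(topology)) stop("topology file not found: ", topology)
  if (bin_width <= 0) stop("bin_width must be positive")
  if (max_shell < 1) stop("max_shell must be >= 1")
  if (temperature <= 0) stop("temperature must be positive")
  hbond_criterion(d_max, angle_min)  # validates
  structure(list(trajectory = trajectory, topology = topology,
                 format = format, output_dir = output_dir,
                 analyses = analyses, bin_width = bin_width, r_max = r_max,
                 R_override = R_override, max_shell = max_shell,
                 cutoff = cutoff, temperature = temperature, d_max = d_max,
                 angle_min = angle_min, max_lag = max_lag,
                 min_face_area = min_face_area, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Reads trajectory and topology, validates parameters against the box
#' (e.g. `r_max` within minimum-image range) before any heavy compute,
#' performs a single tessellation pass, then executes the requested
#' analyses and writes one CSV per analysis plus a JSON manifest.  Any
#' stage failure aborts the run with the stage name and removes the
#' partial outputs of this run.
#'
#' @param config A [run_config()] (or a YAML file path holding its
#'   fields).
#' @return Invisibly, a list of the result objects keyed by analysis.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg <- yaml::read_yaml(config)
    config <- do.call(run_config, cfg)
  }
  if (!inherits(config, "run_config")) stop("config must be a run_config")

  top <- read_topology(config$topology)
  traj <- read_trajectory(config$trajectory, config$format, top)
  box <- as.numeric(traj$frames[[1]]$box)
  if (!is.null(config$r_max) && config$r_max > 0.5 * min(box))
    stop("validation: r_max exceeds half the smallest box edge")

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, df) {
    path <- file.path(config$output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
    path
  }
  t0 <- Sys.time()
  results <- list()
  stage <- "tessellation"
  ok <- FALSE
  on.exit(if (!ok) {
    unlink(written)
    message("pipeline aborted during stage '", stage, "'; partial outputs removed")
  })

  shell_map <- map_shells(traj, top, min_face_area = config$min_face_area)
  census <- shell_census(shell_map, max_shell = config$max_shell)
  results$shells <- census
  if ("shells" %in% config$analyses) emit("shells.csv", as.data.frame(census))

  solvent_species <- setdiff(unique(top$molecules$species),
                             top$molecules$species[
                               top$molecules$molecule_id == top$solute_id])

  if ("rdf" %in% config$analyses) {
    stage <- "rdf"
    results$rdf <- list()
    for (sp in solvent_species) {
      curve <- com_rdf(traj, top, sp, bin_width = config$bin_width,
                       r_max = config$r_max, shell_map = shell_map)
      kb <- tryCatch(kb_analysis(curve, R = config$R_override),
                     error = function(e) NULL)
      df <- data.frame(r = curve$r, g_total = curve$g)
      for (cn in colnames(curve$shell_g))
        df[[paste0("g_shell", cn)]] <- curve$shell_g[, cn]
      if (!is.null(kb)) {
        df$cn <- kb$cn_curve$cn
        df$delta_g <- kb$running$delta_g
      }
      emit(paste0("rdf_", sp, ".csv"), df)
      results$rdf[[sp]] <- list(curve = curve, kb = kb)
    }
  }

  if ("thermo" %in% config$analyses) {
    stage <- "thermo"
    thermo <- solvation_free_energy(census, T = config$temperature)
    results$thermo <- thermo
    emit("thermo.csv", as.data.frame(thermo))
  }

  if ("residence" %in% config$analyses) {
    stage <- "residence"
    res_rows <- list()
    results$residence <- list()
    for (sp in solvent_species) {
      series <- residence_series(shell_map, sp)
      curve <- residence_autocorrelation(series, max_lag = config$max_lag)
      fit <- tryCatch(fit_biexponential(curve), error = function(e) NULL)
      emit(paste0("residence_", sp, ".csv"), as.data.frame(curve))
      results$residence[[sp]] <- list(curve = curve, fit = fit)
      res_rows[[sp]] <- data.frame(
        species = sp, CN0 = attr(curve, "CN0"),
        mean_tau = if (is.null(fit)) NA_real_ else fit$mean_tau)
    }
    emit("residence_summary.csv", do.call(rbind, res_rows))
  }

  if ("energy" %in% config$analyses) {
    stage <- "energy"
    prof <- first_shell_energy_profile(traj, top, shell_map,
                                       cutoff = config$cutoff)
    results$energy <- prof
    emit("energy.csv", as.data.frame(prof))
  }

  if ("hbonds" %in% config$analyses) {
    stage <- "hbonds"
    hb <- hbond_profile(traj, top,
                        hbond_criterion(config$d_max, config$angle_min))
    results$hbonds <- hb
    emit("hbonds.csv", hb$per_frame)
    emit("hbonds_summary.csv", hb$summary)
  }

  stage <- "manifest"
  manifest <- list(
    inputs = list(trajectory = config$trajectory, topology = config$topology),
    parameters = config[setdiff(names(config),
                                c("trajectory", "topology", "output_dir"))],
    software = paste("voroshell",
                     as.character(utils::packageVersion("voroshell"))),
    n_frames = n_frames(traj), n_molecules = n_molecules(top),
    outputs = basename(written),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  ok <- TRUE
  invisible(results)
}
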