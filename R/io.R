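#' Read a labeled raster
#'
#' Two formats: the package's plain-text raster (header lines `shape nx ny
#' nz`, `spacing dx dy dz`, optional `labels code=NAME ...` remapping, then
#' whitespace-separated integer codes in x-fastest order) or a NIfTI
#' integer label volume (`.nii`/`.nii.gz`, requires the RNifti package;
#' spacing taken from the header, assumed millimeters and converted to
#' meters). The organ outline is whatever is not `background_label`:
#' background voxels become EXTERIOR.
#'
#' @param path input file.
#' @param background_label integer code in the file marking voxels outside
#'   the organ outline (mapped to EXTERIOR).
#' @return a `voxel_grid`.
#' @export
read_label_raster <- function(path, background_label = MATERIALS[["EXTERIOR"]]) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI rasters requires the RNifti package")
    img <- RNifti::readNifti(path)
    labs <- array(as.integer(img), dim(img))
    if (length(dim(labs)) == 2L) dim(labs) <- c(dim(labs), 1L)
    spacing <- RNifti::pixdim(img)[1:3] * 1e-3
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    hdr <- strsplit(trimws(lines[1:2]), "\\s+")
    if (hdr[[1]][1] != "shape" || hdr[[2]][1] != "spacing")
      stop("raster header must start with 'shape' and 'spacing' lines")
    shape <- as.integer(hdr[[1]][2:4])
    spacing <- as.numeric(hdr[[2]][2:4])
    body_start <- 3
    remap <- NULL
    if (grepl("^labels\\b", lines[3])) {
      pairs <- strsplit(strsplit(trimws(lines[3]), "\\s+")[[1]][-1], "=")
      remap <- stats::setNames(vapply(pairs, `[[`, "", 2),
                               vapply(pairs, `[[`, "", 1))
      body_start <- 4
    }
    vals <- as.integer(unlist(strsplit(trimws(lines[body_start:length(lines)]), "\\s+")))
    if (length(vals) != prod(shape))
      stop(sprintf("raster body has %d values, expected %d", length(vals), prod(shape)))
    if (!is.null(remap)) {
      mapped <- vals
      for (code in names(remap)) mapped[vals == as.integer(code)] <- MATERIALS[[remap[[code]]]]
      vals <- mapped
    }
    labs <- array(vals, shape)
  }
  labs[labs == background_label] <- MATERIALS[["EXTERIOR"]]
  voxel_grid(labs, spacing)
}

#' Write a labeled raster in the package text format
#' @param grid a `voxel_grid`.
#' @param path output file.
#' @export
write_label_raster <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# hemotherm label raster (codes: %s)",
                       paste(sprintf("%d=%s", MATERIALS, names(MATERIALS)), collapse = " ")),
               sprintf("shape %d %d %d", grid$shape[1], grid$shape[2], grid$shape[3]),
               sprintf("spacing %.9g %.9g %.9g", grid$spacing[1], grid$spacing[2],
                       grid$spacing[3])), con)
  writeLines(paste(as.integer(grid$labels), collapse = " "), con)
  invisible(path)
}

#' Run configuration
#'
#' All file paths, physical parameters and solver settings of a simulation,
#' round-trippable through YAML. Parameter keys mirror the reference
#' parameter table (`k_a`, `k_v`, `alpha`, `mu`, `gamma_a`, `gamma_v`,
#' `P_in`, `P_out`, `epsilon`, thermal keys, `tol`). `mode` presets the
#' blood-tissue convection coefficient (`pbm`: h_b = 0.001, `wjm`: h_b =
#' 10, `custom`: as given).
#'
#' @param raster,arterial_tree,venous_tree,output_dir file paths.
#' @param epsilon sphere-of-influence radius (m).
#' @param flow list of \code{\link{flow_params}} overrides.
#' @param thermal list of \code{\link{thermal_params}} overrides.
#' @param mode `"custom"`, `"pbm"` or `"wjm"`.
#' @param tol linear-solver tolerance.
#' @param method solver method (see \code{\link{solve_linear}}).
#' @param preconditioner `"ilu"` or `"none"`.
#' @param direct_threshold size cutoff for the auto method.
#' @param background_label raster background code.
#' @param seed integer seed recorded in the manifest.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(raster = NULL, arterial_tree = NULL, venous_tree = NULL,
                       output_dir = "hemotherm-out", epsilon = 10e-3,
                       flow = list(), thermal = list(),
                       mode = c("custom", "pbm", "wjm"),
                       tol = 1e-8, method = "auto",
                       preconditioner = "ilu", direct_threshold = 50000L,
                       background_label = 0L, seed = 1L,
                       log_level = c("info", "quiet")) {
  mode <- match.arg(mode)
  log_level <- match.arg(log_level)
  fp <- do.call(flow_params, flow)
  tp <- do.call(thermal_params, c(thermal, list(mode = mode)))
  structure(list(raster = raster, arterial_tree = arterial_tree,
                 venous_tree = venous_tree, output_dir = output_dir,
                 epsilon = epsilon, flow = unclass(fp), thermal = unclass(tp),
                 mode = mode, tol = tol, method = method,
                 preconditioner = preconditioner,
                 direct_threshold = direct_threshold,
                 background_label = background_label,
                 seed = seed, log_level = log_level),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$flow <- y$flow[!vapply(y$flow, is.null, logical(1))]
  th <- y$thermal
  th$mode <- NULL
  run_config(raster = y$raster, arterial_tree = y$arterial_tree,
             venous_tree = y$venous_tree,
             output_dir = if (is.null(y$output_dir)) "hemotherm-out" else y$output_dir,
             epsilon = y$epsilon, flow = y$flow, thermal = th,
             mode = if (is.null(y$mode)) "custom" else y$mode,
             tol = if (is.null(y$tol)) 1e-8 else y$tol,
             method = if (is.null(y$method)) "auto" else y$method,
             preconditioner = if (is.null(y$preconditioner)) "ilu" else y$preconditioner,
             direct_threshold = if (is.null(y$direct_threshold)) 50000L else y$direct_threshold,
             background_label = if (is.null(y$background_label)) 0L else y$background_label,
             seed = if (is.null(y$seed)) 1L else y$seed,
             log_level = if (is.null(y$log_level)) "info" else y$log_level)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load and validate a simulation problem from a configuration
#'
#' Reads the raster and both tree files, applies the parameter sets, and
#' validates everything together; all validation failures are collected and
#' reported in one error.
#'
#' @param config a `run_config`.
#' @return a `hemo_problem`.
#' @export
load_problem <- function(config) {
  stopifnot(inherits(config, "run_config"))
  errs <- character(0)
  note <- function(e, what) errs <<- c(errs, paste0(what, ": ", conditionMessage(e)))
  grid <- tryCatch(read_label_raster(config$raster, config$background_label),
                   error = function(e) { note(e, config$raster); NULL })
  art <- tryCatch(read_vessel_tree(config$arterial_tree),
                  error = function(e) { note(e, config$arterial_tree); NULL })
  ven <- tryCatch(read_vessel_tree(config$venous_tree),
                  error = function(e) { note(e, config$venous_tree); NULL })
  if (!is.null(art) && art$kind != "artery")
    errs <- c(errs, paste0(config$arterial_tree, ": kind is not 'artery'"))
  if (!is.null(ven) && ven$kind != "vein")
    errs <- c(errs, paste0(config$venous_tree, ": kind is not 'vein'"))
  if (length(errs)) stop("problem validation failed:\n  ", paste(errs, collapse = "\n  "))
  hemo_problem(grid, art, ven, epsilon = config$epsilon,
               flow = do.call(flow_params, config$flow),
               thermal = do.call(thermal_params, config$thermal))
}

#' Run the full pipeline and write artifacts
#'
#' Solves flow then heat and writes: VTK volumes of the pressure, source
#' and temperature fields, CSVs of nodal pressures, element flows and
#' element temperatures, JSON mass/energy balance reports, and a
#' machine-readable run manifest (configuration, residuals, iteration
#' counts, package version).
#'
#' @param config a `run_config`, or a `hemo_problem` (then `output_dir` and
#'   solver settings come from the remaining arguments).
#' @param output_dir overrides the configured output directory.
#' @param ... passed to \code{\link{run_simulation}} when `config` is a
#'   problem.
#' @return invisibly, the `hemo_run`.
#' @export
run_pipeline <- function(config, output_dir = NULL, ...) {
  if (inherits(config, "run_config")) {
    problem <- load_problem(config)
    out <- if (is.null(output_dir)) config$output_dir else output_dir
    run <- run_simulation(problem, method = config$method, tol = config$tol,
                          quiet = config$log_level == "quiet")
    cfg <- unclass(config)
  } else if (inherits(config, "hemo_problem")) {
    problem <- config
    out <- if (is.null(output_dir)) "hemotherm-out" else output_dir
    run <- run_simulation(problem, ...)
    cfg <- list(epsilon = problem$epsilon, flow = unclass(problem$flow),
                thermal = unclass(problem$thermal))
  } else stop("config must be a run_config or hemo_problem")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  grid <- problem$grid
  full <- function(v) { a <- array(NA_real_, grid$shape); a[run$flow_system$tissue] <- v; a }
  write_vtk_structured_points(
    file.path(out, "fields.vtk"), grid,
    list(P_a_Pa = full(run$flow$P_a), P_v_Pa = full(run$flow$P_v),
         Q_a_m3s = full(run$flow$Q_a), Q_v_m3s = full(run$flow$Q_v),
         u_perf_per_s = full(run$flow$u_perf),
         T_degC = temperature_field(run$heat),
         material = array(as.numeric(grid$labels), grid$shape)))

  np <- rbind(data.frame(tree = "artery", node = names(run$flow$p_arterial),
                         pressure_Pa = as.numeric(run$flow$p_arterial)),
              data.frame(tree = "vein", node = names(run$flow$p_venous),
                         pressure_Pa = as.numeric(run$flow$p_venous)))
  utils::write.csv(np, file.path(out, "nodal_pressures.csv"), row.names = FALSE)
  eq <- rbind(data.frame(tree = "artery", element = names(run$flow$q_arterial),
                         flow_m3s = as.numeric(run$flow$q_arterial)),
              data.frame(tree = "vein", element = names(run$flow$q_venous),
                         flow_m3s = as.numeric(run$flow$q_venous)))
  utils::write.csv(eq, file.path(out, "element_flows.csv"), row.names = FALSE)
  et <- data.frame(element = names(run$heat$T_elem),
                   temperature_degC = as.numeric(run$heat$T_elem))
  utils::write.csv(et, file.path(out, "element_temperatures.csv"), row.names = FALSE)

  mb <- mass_balance_report(run$flow)
  eb <- energy_balance_report(run$heat)
  jsonlite::write_json(
    list(mass = list(global = mb$global,
                     worst_terminal_imbalance = max(mb$terminal$imbalance),
                     worst_voxel_divergence = max(abs(mb$voxel_divergence))),
         energy = eb),
    file.path(out, "balance.json"), auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package = "hemotherm",
    version = as.character(utils::packageVersion("hemotherm")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    flow_solver = run$flow$solver,
    flow_residual = run$flow$residual_norm,
    heat_solver = run$heat$solver,
    heat_residual = run$heat$residual_norm,
    energy_residual_W = run$heat$energy_residual,
    n_flow_unknowns = nrow(run$flow_system$A),
    n_heat_unknowns = nrow(run$heat_system$A))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}
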