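#' Bundle a simulation problem
#'
#' A validated, simulation-ready problem: labeled grid, both vessel trees,
#' the sphere-of-influence radius and the parameter sets. The coupling map
#' is built lazily on first use and cached.
#'
#' @param grid a `voxel_grid`.
#' @param arterial_tree,venous_tree `vessel_tree` objects.
#' @param epsilon sphere-of-influence radius (m).
#' @param flow a `flow_params`.
#' @param thermal a `thermal_params`.
#' @param extra optional list of fixture metadata (e.g. closed-form
#'   oracles).
#' @return object of class `hemo_problem`.
#' @export
hemo_problem <- function(grid, arterial_tree, venous_tree, epsilon,
                         flow = flow_params(), thermal = thermal_params(),
                         extra = list()) {
  stopifnot(inherits(grid, "voxel_grid"),
            inherits(arterial_tree, "vessel_tree"),
            inherits(venous_tree, "vessel_tree"),
            epsilon > 0)
  structure(c(list(grid = grid, arterial_tree = arterial_tree,
                   venous_tree = venous_tree, epsilon = epsilon,
                   flow = flow, thermal = thermal), extra),
            class = "hemo_problem")
}

#' @export
print.hemo_problem <- function(x, ...) {
  cat("hemo_problem\n")
  print(x$grid)
  print(x$arterial_tree)
  print(x$venous_tree)
  cat(sprintf("  epsilon = %g m, P_in = %g Pa, P_out = %g Pa, h_b = %g W m^-2 degC^-1\n",
              x$epsilon, x$flow$P_in, x$flow$P_out, x$thermal$h_b))
  invisible(x)
}

#' Run the coupled flow + heat simulation
#'
#' Builds (or reuses) the coupling map, assembles and solves the flow
#' system, derives the advection graph, then assembles and solves the
#' thermal system.
#'
#' @param problem a `hemo_problem`.
#' @param coupling optional precomputed `coupling_map` to reuse.
#' @param flow optional precomputed `flow_solution` to reuse (parameters
#'   must match; used by the sensitivity driver for heat-only
#'   perturbations).
#' @param method,tol passed to the linear solver.
#' @param quiet suppress coupling-coverage warnings.
#' @return object of class `hemo_run` with `coupling`, `flow_system`,
#'   `flow`, `graph`, `heat_system`, `heat`, and the `problem`.
#' @export
run_simulation <- function(problem, coupling = NULL, flow = NULL,
                           method = "auto", tol = 1e-8, quiet = FALSE) {
  stopifnot(inherits(problem, "hemo_problem"))
  if (is.null(coupling)) {
    build <- function() build_coupling_map(problem$grid, problem$arterial_tree,
                                           problem$venous_tree, problem$epsilon)
    coupling <- if (quiet) suppressWarnings(build()) else build()
  }
  if (is.null(flow)) {
    fsys <- assemble_flow_system(problem$grid, problem$arterial_tree,
                                 problem$venous_tree, coupling, problem$flow)
    flow <- solve_flow(fsys, method = method, tol = tol)
  }
  graph <- build_advection_graph(flow)
  hsys <- assemble_heat_system(problem$grid, flow, graph, problem$thermal)
  heat <- solve_heat(hsys, method = method, tol = tol)
  structure(list(problem = problem, coupling = coupling,
                 flow_system = flow$system, flow = flow,
                 graph = graph, heat_system = hsys, heat = heat),
            class = "hemo_run")
}

#' @export
print.hemo_run <- function(x, ...) {
  print(x$flow)
  print(x$heat)
  invisible(x)
}

#' @export
summary.hemo_run <- function(object, ...) {
  print(object)
  eb <- energy_balance_report(object$heat)
  cat(sprintf("  energy: in %.4g W + wall %.4g W + metabolic %.4g W = out %.4g W + ambient %.4g W (rel. closure %.2e)\n",
              eb$advective_in, eb$root_convection, eb$metabolic,
              eb$advective_out, eb$ambient_loss, eb$rel_closure))
  invisible(eb)
}

#' Mid-layer image of a solved field
#'
#' Quick-look base-graphics image of the arterial pressure (flow) or
#' temperature (heat) field in a given z layer.
#'
#' @param x a `flow_solution` or `thermal_solution`.
#' @param layer z index (default: middle layer).
#' @param ... passed to \code{\link[graphics]{image}}.
#' @export
plot.flow_solution <- function(x, layer = NULL, ...) {
  sys <- x$system
  arr <- array(NA_real_, sys$grid$shape)
  arr[sys$tissue] <- x$P_a
  if (is.null(layer)) layer <- ceiling(sys$grid$shape[3] / 2)
  graphics::image(arr[, , layer], main = sprintf("P_a (Pa), layer %d", layer),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' @rdname plot.flow_solution
#' @export
plot.thermal_solution <- function(x, layer = NULL, ...) {
  arr <- temperature_field(x)
  if (is.null(layer)) layer <- ceiling(dim(arr)[3] / 2)
  graphics::image(arr[, , layer], main = sprintf("T (degC), layer %d", layer),
                  useRaster = TRUE, ...)
  invisible(x)
}
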