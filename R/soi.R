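#' Compact-support mollifier approximating a Dirac point source
#'
#' The smooth bump eta(x) = C exp(1/(|x|^2 - 1)) for |x| < 1 and 0 otherwise,
#' scaled to characteristic radius epsilon by
#' eta_eps(x) = eta(x/epsilon) / epsilon^n. It is radially symmetric,
#' strictly decreasing in |x|, and vanishes continuously at the support
#' boundary |x| = epsilon. The normalization constant C is chosen so the
#' integral of eta_eps over the domain is one; on a voxel mesh the package
#' calibrates C against the discrete voxel-center quadrature (see
#' \code{\link{calibrate_constant}}) so mass is conserved exactly even when
#' the sphere of influence is clipped by the domain boundary.
#'
#' @param epsilon characteristic (sphere-of-influence) radius (m).
#' @param n spatial dimension of the domain (default 3). Because C is
#'   re-calibrated discretely, n only rescales C and never changes the
#'   normalized weights.
#' @param C normalization constant; `NA` until calibrated.
#' @return object of class `mollifier`.
#' @export
mollifier <- function(epsilon, n = 3L, C = NA_real_) {
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be positive")
  if (!is.na(C) && C <= 0) stop("C must be positive")
  structure(list(epsilon = epsilon, n = as.integer(n), C = C),
            class = "mollifier")
}

# unnormalized radial profile at scaled radius u = |x|/epsilon (C = 1)
mollifier_profile <- function(u) {
  out <- numeric(length(u))
  inside <- u < 1
  out[inside] <- exp(1 / (u[inside]^2 - 1))
  out
}

#' Evaluate the mollifier density
#'
#' @param r displacement(s) from the terminal: numeric vector (single
#'   displacement) or matrix with columns x, y, z (m).
#' @param m a \code{\link{mollifier}} with calibrated constant `C`.
#' @return density value(s) (m^-n); exactly 0 at and beyond |r| = epsilon.
#' @export
mollifier_value <- function(r, m) {
  stopifnot(inherits(m, "mollifier"))
  if (is.na(m$C)) stop("mollifier constant C not calibrated")
  if (is.matrix(r)) d <- sqrt(rowSums(r^2)) else d <- sqrt(sum(r^2))
  (m$C / m$epsilon^m$n) * mollifier_profile(d / m$epsilon)
}

#' Calibrate the mollifier constant against the voxel quadrature
#'
#' Chooses C so that the discrete voxel-center quadrature
#' sum_i eta_eps(x_i - x_k) V_i over eligible tissue voxels equals 1
#' exactly, which is the discrete statement of unit mass for the virtual
#' unresolved vessel network. Calibrating per terminal (rather than using
#' the continuous-space constant) keeps the quadrature exact on coarse
#' meshes and where the sphere of influence is clipped at the boundary.
#'
#' @param grid a `voxel_grid`.
#' @param terminal_position numeric length-3, terminal node coordinate (m).
#' @param epsilon sphere-of-influence radius (m).
#' @param tissue_idx linear indices of eligible voxels (default: all
#'   tissue-labeled voxels; vessel and air voxels are never eligible).
#' @return list with `C`, the calibrated \code{\link{mollifier}} `m`, and the
#'   in-SoI voxel table `voxels` (columns `voxel`, `w` with sum(w) = 1).
#' @export
calibrate_constant <- function(grid, terminal_position, epsilon,
                               tissue_idx = which(grid$labels == MATERIALS[["TISSUE"]])) {
  stopifnot(inherits(grid, "voxel_grid"))
  ctr <- voxel_centers(grid, tissue_idx)
  d2 <- (ctr[, 1] - terminal_position[1])^2 + (ctr[, 2] - terminal_position[2])^2 +
    (ctr[, 3] - terminal_position[3])^2
  sel <- d2 < epsilon^2
  if (!any(sel))
    stop(sprintf(paste0("empty sphere of influence for terminal at (%g, %g, %g):",
                        " epsilon = %g m is too small for this grid"),
                 terminal_position[1], terminal_position[2], terminal_position[3],
                 epsilon))
  u <- sqrt(d2[sel]) / epsilon
  raw <- mollifier_profile(u) / epsilon^3  # C = 1 density at eligible voxels
  s <- sum(raw) * grid$voxel_volume
  if (s <= 0)
    stop("degenerate sphere of influence: all in-SoI voxels sit on the support boundary")
  C <- 1 / s
  w <- raw * grid$voxel_volume * C
  list(C = C,
       m = mollifier(epsilon, n = 3L, C = C),
       voxels = data.frame(voxel = tissue_idx[sel], w = w))
}

#' Build the terminal-to-voxel coupling map
#'
#' For every terminal of the arterial and venous trees, computes the set of
#' tissue voxels inside its sphere of influence together with normalized
#' mollifier weights w_ki = eta_eps(x_i - x_k) V_i (sum_i w_ki = 1). The
#' weights define how the terminal's flow is distributed into (arterial) or
#' collected from (venous) the tissue continuum, standing in for the
#' unresolved microvascular network. A reverse voxel-to-terminal index and
#' coverage statistics are attached.
#'
#' @param grid a `voxel_grid`.
#' @param arterial_tree,venous_tree `vessel_tree` objects.
#' @param epsilon sphere-of-influence radius (m), shared by all terminals.
#' @param warn_coverage warn when some tissue voxel has no direct arterial
#'   source or no direct venous sink (it then relies solely on cross-voxel
#'   Darcy flow).
#' @return object of class `coupling_map`: `terminals` (data frame with
#'   `tree`, `node`, `element`, position, `C`, `n_voxels`), `weights` (list
#'   of data frames `voxel`, `w`), `coverage` (fractions of tissue voxels
#'   with at least one source / sink), `epsilon`.
#' @export
build_coupling_map <- function(grid, arterial_tree, venous_tree, epsilon,
                               warn_coverage = TRUE) {
  stopifnot(inherits(arterial_tree, "vessel_tree"),
            inherits(venous_tree, "vessel_tree"),
            arterial_tree$kind == "artery", venous_tree$kind == "vein")
  tissue_idx <- which(grid$labels == MATERIALS[["TISSUE"]])
  if (!length(tissue_idx)) stop("grid has no tissue voxels")

  one_tree <- function(tree) {
    tidx <- match(tree$terminals, tree$nodes$id)
    eidx <- terminal_elements(tree)
    if (!length(tidx)) stop(tree$kind, " tree has no terminals")
    res <- lapply(seq_along(tidx), function(s) {
      pos <- unlist(tree$nodes[tidx[s], c("x", "y", "z")], use.names = FALSE)
      calibrate_constant(grid, pos, epsilon, tissue_idx)
    })
    data.frame(tree = tree$kind,
               node = tree$terminals,
               element = tree$elements$id[eidx],
               x = tree$nodes$x[tidx], y = tree$nodes$y[tidx], z = tree$nodes$z[tidx],
               C = vapply(res, `[[`, numeric(1), "C"),
               n_voxels = vapply(res, function(r) nrow(r$voxels), integer(1))) ->
      term
    list(term = term, weights = lapply(res, `[[`, "voxels"))
  }

  a <- one_tree(arterial_tree); v <- one_tree(venous_tree)
  terminals <- rbind(a$term, v$term)
  weights <- c(a$weights, v$weights)

  is_art <- terminals$tree == "artery"
  cov_src <- unique(unlist(lapply(weights[is_art], `[[`, "voxel")))
  cov_snk <- unique(unlist(lapply(weights[!is_art], `[[`, "voxel")))
  coverage <- c(source = length(intersect(tissue_idx, cov_src)) / length(tissue_idx),
                sink = length(intersect(tissue_idx, cov_snk)) / length(tissue_idx))
  if (warn_coverage && any(coverage < 1))
    warning(sprintf(paste0("incomplete sphere-of-influence coverage: %.1f%% of tissue",
                           " voxels have a direct source, %.1f%% a direct sink"),
                    100 * coverage[["source"]], 100 * coverage[["sink"]]))

  structure(list(terminals = terminals, weights = weights,
                 coverage = coverage, epsilon = epsilon,
                 n_tissue = length(tissue_idx)),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  cat(sprintf("coupling_map: %d terminals (%d arterial, %d venous), epsilon = %g m\n",
              nrow(x$terminals), sum(x$terminals$tree == "artery"),
              sum(x$terminals$tree == "vein"), x$epsilon))
  cat(sprintf("  tissue coverage: %.1f%% with a source, %.1f%% with a sink\n",
              100 * x$coverage[["source"]], 100 * x$coverage[["sink"]]))
  invisible(x)
}

#' Export / import a coupling map as JSON
#'
#' Round-trips the per-terminal weight lists for reproducibility.
#' @param map a `coupling_map`.
#' @param path file path.
#' @export
write_coupling_map <- function(map, path) {
  obj <- list(schema = 1, epsilon = map$epsilon, n_tissue = map$n_tissue,
              coverage = as.list(map$coverage),
              terminals = map$terminals,
              weights = lapply(map$weights, function(w)
                list(voxel = w$voxel, w = w$w)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coupling_map
#' @export
read_coupling_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  structure(list(terminals = obj$terminals,
                 weights = lapply(seq_len(nrow(obj$terminals)), function(s)
                   data.frame(voxel = as.integer(obj$weights$voxel[[s]]),
                              w = obj$weights$w[[s]])),
                 coverage = unlist(obj$coverage), epsilon = obj$epsilon,
                 n_tissue = obj$n_tissue),
            class = "coupling_map")
}
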