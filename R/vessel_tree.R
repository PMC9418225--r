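#' Hagen-Poiseuille conductance of a cylindrical vessel element
#'
#' Laminar flow in a vessel element obeys q = kappa * (p_inlet - p_outlet)
#' with kappa = pi R^4 / (8 mu L). The reciprocal of the conductance is the
#' element's hydraulic resistance.
#'
#' @param radius element radius R (m).
#' @param length element length L (m).
#' @param mu dynamic viscosity of blood (Pa s).
#' @return conductance (m^3 Pa^-1 s^-1). Vectorized over its arguments.
#' @examples
#' element_conductance(1e-3, 1e-2, 3e-3)
#' @export
element_conductance <- function(radius, length, mu) {
  if (any(radius <= 0) || any(length <= 0) || any(mu <= 0))
    stop("radius, length and mu must be positive")
  pi * radius^4 / (8 * mu * length)
}

#' Construct a 1-D vessel tree
#'
#' A directed graph of pressure nodes and cylindrical elements representing
#' the resolved part of an arterial or venous tree. Root nodes carry
#' Dirichlet pressure boundary conditions; terminal (degree-1, non-root)
#' nodes are where the tree couples to the tissue continuum through the
#' sphere-of-influence mollifier. Element flow direction is determined by
#' the solved pressure field, not by node order, so element flows may be
#' negative.
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z` (m), `root`
#'   (logical).
#' @param elements data frame with columns `id`, `node_j` (inlet-side node
#'   id), `node_i` (outlet-side node id), `radius` (m); optional `length`
#'   (m; defaults to the Euclidean node distance) and `member_voxels`
#'   (list column of linear voxel indices covered by the element).
#' @param kind `"artery"` or `"vein"`.
#' @param length_tol relative tolerance for checking a supplied `length`
#'   against the node distance; lengths farther off are kept (explicit
#'   override) but flagged with a warning.
#' @return object of class `vessel_tree` with fields `kind`, `nodes`,
#'   `elements`, `roots`, `terminals` (node ids).
#' @export
vessel_tree <- function(nodes, elements, kind = c("artery", "vein"),
                        length_tol = 1e-6) {
  kind <- match.arg(kind)
  nodes <- as.data.frame(nodes)
  elements <- as.data.frame(elements)
  need_n <- c("id", "x", "y", "z", "root")
  if (!all(need_n %in% names(nodes))) stop("nodes needs columns ", paste(need_n, collapse = ", "))
  need_e <- c("id", "node_j", "node_i", "radius")
  if (!all(need_e %in% names(elements))) stop("elements needs columns ", paste(need_e, collapse = ", "))
  nodes$id <- as.character(nodes$id)
  elements$id <- as.character(elements$id)
  elements$node_j <- as.character(elements$node_j)
  elements$node_i <- as.character(elements$node_i)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (anyDuplicated(elements$id)) stop("duplicate element ids")
  bad <- setdiff(c(elements$node_j, elements$node_i), nodes$id)
  if (length(bad)) stop("elements reference unknown nodes: ", paste(bad, collapse = ", "))
  if (any(elements$radius <= 0))
    stop("non-positive radius on element(s) ",
         paste(elements$id[elements$radius <= 0], collapse = ", "))
  ji <- match(elements$node_j, nodes$id); ii <- match(elements$node_i, nodes$id)
  dist <- sqrt((nodes$x[ji] - nodes$x[ii])^2 + (nodes$y[ji] - nodes$y[ii])^2 +
                 (nodes$z[ji] - nodes$z[ii])^2)
  if (is.null(elements$length)) {
    elements$length <- dist
  } else {
    off <- abs(elements$length - dist) > length_tol * pmax(dist, .Machine$double.eps)
    if (any(off))
      warning("element length overrides node distance for: ",
              paste(elements$id[off], collapse = ", "))
  }
  if (any(elements$length <= 0)) stop("non-positive element length")
  if (!any(nodes$root)) stop(kind, " tree has no root node")

  deg <- tabulate(c(ji, ii), nbins = nrow(nodes))
  if (any(deg == 0))
    stop("isolated node(s): ", paste(nodes$id[deg == 0], collapse = ", "))
  # connectivity: every node reachable from a root (undirected)
  adj <- split(c(ii, ji), c(ji, ii))
  seen <- logical(nrow(nodes)); queue <- which(nodes$root); seen[queue] <- TRUE
  while (length(queue)) {
    nb <- unlist(adj[as.character(queue)], use.names = FALSE)
    queue <- unique(nb[!seen[nb]]); seen[queue] <- TRUE
  }
  if (!all(seen))
    stop("node(s) unreachable from any root: ", paste(nodes$id[!seen], collapse = ", "))

  structure(list(kind = kind, nodes = nodes, elements = elements,
                 roots = nodes$id[nodes$root],
                 terminals = nodes$id[deg == 1L & !nodes$root]),
            class = "vessel_tree")
}

#' Terminal nodes of a vessel tree
#'
#' Terminals are the degree-1 non-root nodes: arterial terminals are the
#' outflow points into tissue and venous terminals the inflow points back
#' from tissue.
#'
#' @param tree a `vessel_tree`.
#' @return character vector of node ids.
#' @export
find_terminals <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  tree$terminals
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("vessel_tree (%s): %d nodes, %d elements, %d root(s), %d terminal(s)\n",
              x$kind, nrow(x$nodes), nrow(x$elements),
              length(x$roots), length(x$terminals)))
  cat(sprintf("  radius range %.3g .. %.3g m\n",
              min(x$elements$radius), max(x$elements$radius)))
  invisible(x)
}

#' Read a vessel tree from JSON
#'
#' Schema (units meters, `schema` version 1):
#' \preformatted{
#' {"schema": 1, "kind": "artery"|"vein",
#'  "nodes": [{"id", "x", "y", "z", "root"}],
#'  "elements": [{"id", "node_j", "node_i", "radius", "length"?, "member_voxels"?}]}
#' }
#'
#' @param path JSON file path.
#' @return a `vessel_tree`.
#' @export
read_vessel_tree <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.null(obj$schema) && obj$schema != 1)
    stop("unsupported vessel tree schema version: ", obj$schema)
  nodes <- obj$nodes
  if (is.null(nodes$root)) nodes$root <- FALSE
  nodes$root[is.na(nodes$root)] <- FALSE
  el <- obj$elements
  if (!is.null(el$member_voxels)) el$member_voxels <- I(lapply(el$member_voxels, as.integer))
  vessel_tree(nodes, el, kind = obj$kind)
}

#' Write a vessel tree to JSON
#' @param tree a `vessel_tree`.
#' @param path output file path.
#' @export
write_vessel_tree <- function(tree, path) {
  el <- tree$elements
  mv <- el$member_voxels
  el$member_voxels <- NULL
  obj <- list(schema = 1, kind = tree$kind,
              nodes = tree$nodes, elements = el)
  if (!is.null(mv)) obj$elements$member_voxels <- lapply(mv, as.integer)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# index helpers used by the solvers ---------------------------------------

# integer node indices (into tree$nodes) of element endpoints
element_endpoints <- function(tree) {
  cbind(j = match(tree$elements$node_j, tree$nodes$id),
        i = match(tree$elements$node_i, tree$nodes$id))
}

# for each terminal node id, the id/index of its single incident element
terminal_elements <- function(tree) {
  ep <- element_endpoints(tree)
  tidx <- match(tree$terminals, tree$nodes$id)
  vapply(tidx, function(t) {
    e <- which(ep[, "j"] == t | ep[, "i"] == t)
    if (length(e) != 1L) stop("terminal node with degree != 1")
    e
  }, integer(1))
}
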