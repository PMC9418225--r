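# Desk-scale synthetic domains with known behavior. Fixture defaults use
# the reference parameter set of flow_params()/thermal_params() (frog-tongue
# magnitudes: kPa pressures, degC fields, 64 x 64 x 333 um voxels) so all
# quantities come out at realistic scales; tree geometry is axis-aligned so
# member-voxel assignment is unambiguous.

DEFAULT_SPACING <- c(64e-6, 64e-6, 333e-6)

#' Darcy slab fixture with closed-form solution
#'
#' A 1 x 1 x n tissue slab with pressures fixed in the two end voxels. The
#' two-point flux discretization reproduces the continuum solution exactly:
#' cell-center pressures interpolate linearly between the fixed ends, and
#' every face carries the same flux k A (P_left - P_right) / (mu L) where L
#' is the distance between the fixed cell centers.
#'
#' @param n_voxels slab length in voxels (>= 2).
#' @param k permeability (m^2).
#' @param mu viscosity (Pa s).
#' @param P_left,P_right fixed pressures in the first/last voxel (Pa).
#' @param spacing voxel spacing (m).
#' @return list with `grid`, `fixed` (for \code{\link{solve_darcy}}), and
#'   `exact` (`P` per tissue voxel, `flux` in m^3/s).
#' @export
make_darcy_slab <- function(n_voxels, k = 1e-12, mu = 3e-3,
                            P_left = 10600, P_right = 1600,
                            spacing = DEFAULT_SPACING) {
  stopifnot(n_voxels >= 2)
  grid <- voxel_grid(array(MATERIALS[["TISSUE"]], c(1, 1, n_voxels)), spacing)
  fixed <- data.frame(voxel = c(1L, n_voxels), value = c(P_left, P_right))
  i <- seq_len(n_voxels)
  P <- P_left + (P_right - P_left) * (i - 1) / (n_voxels - 1)
  area <- spacing[1] * spacing[2]
  flux <- k * area * (P_left - P_right) / (mu * spacing[3] * (n_voxels - 1))
  list(grid = grid, fixed = fixed, exact = list(P = P, flux = flux))
}

# straight run of axis-aligned vessel elements through a row of voxels
straight_tree <- function(kind, voxels, grid, n_elem, radius, root_first = TRUE,
                          id_prefix = kind) {
  nv <- length(voxels)
  stopifnot(n_elem >= 1, nv >= n_elem)
  ctr <- voxel_centers(grid, voxels)
  dirx <- if (nv > 1) sign(ctr[nv, 1] - ctr[1, 1]) else 1
  # nodes at the outer edges and at member-run boundaries
  breaks <- round(seq(0, nv, length.out = n_elem + 1))
  pos <- matrix(0, n_elem + 1, 3)
  pos[1, ] <- ctr[1, ] - c(dirx * grid$spacing[1] / 2, 0, 0)
  for (b in 2:(n_elem + 1)) {
    v <- breaks[b]
    pos[b, ] <- ctr[v, ] + c(dirx * grid$spacing[1] / 2, 0, 0)
  }
  nodes <- data.frame(id = paste0(id_prefix, "_n", seq_len(n_elem + 1)),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      root = c(root_first, rep(FALSE, n_elem)))
  members <- lapply(seq_len(n_elem), function(e)
    voxels[(breaks[e] + 1):breaks[e + 1]])
  elements <- data.frame(id = paste0(id_prefix, "_e", seq_len(n_elem)),
                         node_j = nodes$id[seq_len(n_elem)],
                         node_i = nodes$id[seq_len(n_elem) + 1L],
                         radius = radius)
  elements$member_voxels <- I(members)
  vessel_tree(nodes, elements, kind = kind)
}

#' Straight artery / tissue / vein slab fixture
#'
#' A `(nx, 1, 3)` grid: layer 1 is a straight artery (one or more elements
#' in series), layer 2 tissue, layer 3 a straight vein running the opposite
#' way (counter-current). With `nx = 1` the fixture degenerates to the
#' single artery-voxel-vein chain whose total flow has the closed series
#' form `(P_in - P_out) / (1/kappa_a + mu/gamma_a + 1/(alpha V) +
#' mu/gamma_v + 1/kappa_v)`, attached as `exact_flow`.
#'
#' @param nx slab length in voxels.
#' @param n_elem number of vessel elements per tree.
#' @param radius vessel radius (m).
#' @param epsilon sphere-of-influence radius (m); default covers the whole
#'   slab from every terminal.
#' @param params a \code{\link{flow_params}}.
#' @param spacing voxel spacing (m).
#' @return object of class `hemo_problem` (see
#'   \code{\link{run_simulation}}) with `exact_flow` attached (or NULL).
#' @export
make_single_vessel_slab <- function(nx = 6, n_elem = 1, radius = 1e-4,
                                    epsilon = NULL, params = flow_params(),
                                    spacing = DEFAULT_SPACING) {
  stopifnot(nx >= 1, n_elem <= nx)
  labs <- array(MATERIALS[["TISSUE"]], c(nx, 1, 3))
  labs[, 1, 1] <- MATERIALS[["ARTERY"]]
  labs[, 1, 3] <- MATERIALS[["VEIN"]]
  grid <- voxel_grid(labs, spacing)
  lin <- array(seq_len(prod(grid$shape)), grid$shape)
  artery <- straight_tree("artery", lin[, 1, 1], grid, n_elem, radius,
                          root_first = TRUE)
  # vein runs right-to-left: root at the far end of the slab
  vein <- straight_tree("vein", rev(lin[, 1, 3]), grid, n_elem, radius,
                        root_first = TRUE, id_prefix = "vein")
  # vein voxel order was reversed; fix node x positions sign convention is
  # already handled by voxel_centers, nothing to adjust.
  exact_flow <- NULL
  if (nx == 1 && n_elem == 1) {
    kap <- element_conductance(radius, artery$elements$length[1], params$mu)
    kap_v <- element_conductance(radius, vein$elements$length[1], params$mu)
    V <- grid$voxel_volume
    R <- 1 / kap + params$mu / params$gamma_a + 1 / (params$alpha * V) +
      params$mu / params$gamma_v + 1 / kap_v
    exact_flow <- (params$P_in - params$P_out) / R
  }
  if (is.null(epsilon)) {
    tis <- which(grid$labels == MATERIALS[["TISSUE"]])
    ctr <- voxel_centers(grid, tis)
    tpos <- rbind(
      as.matrix(artery$nodes[match(artery$terminals, artery$nodes$id), c("x", "y", "z")]),
      as.matrix(vein$nodes[match(vein$terminals, vein$nodes$id), c("x", "y", "z")]))
    dmax <- max(apply(tpos, 1, function(p)
      max(sqrt(colSums((t(ctr) - p)^2)))))
    epsilon <- 1.05 * dmax
  }
  hemo_problem(grid, artery, vein, epsilon = epsilon, flow = params,
               thermal = thermal_params(), extra = list(exact_flow = exact_flow))
}

#' Miniature three-layer organ analogue
#'
#' A desk-scale analogue of a planar organ slice split into three layers:
#' layer 1 carries an axis-aligned arterial binary tree rooted at the left
#' edge, layer 2 is pure tissue, layer 3 a mirrored venous tree rooted at
#' the right edge. Radii follow a cube-root halving per generation
#' (Murray-type branching); `seed` jitters radii by +-10% for randomized
#' variants and the construction is bit-identical for identical arguments.
#' The default sphere-of-influence radius is calibrated to the generated
#' geometry: 1.05 times the largest nearest-terminal distance over tissue
#' voxels, which guarantees every tissue voxel at least one direct source
#' and one direct sink (the reference configuration's stated property).
#'
#' @param nx,ny slice dimensions in voxels (>= 8).
#' @param tree_levels number of bifurcation generations (>= 1).
#' @param seed integer; jitters radii reproducibly.
#' @param epsilon sphere-of-influence radius (m) or NULL for the
#'   geometry-calibrated default.
#' @param params a \code{\link{flow_params}}.
#' @param thermal a \code{\link{thermal_params}}.
#' @param root_radius trunk radius (m).
#' @param spacing voxel spacing (m).
#' @return object of class `hemo_problem`.
#' @export
make_three_layer_toy <- function(nx = 16, ny = 16, tree_levels = 2, seed = 1,
                                 epsilon = NULL, params = flow_params(),
                                 thermal = thermal_params(),
                                 root_radius = 1.2e-4,
                                 spacing = DEFAULT_SPACING) {
  stopifnot(nx >= 8, ny >= 8, tree_levels >= 1)
  rng <- local({ set.seed(seed); function(n) stats::runif(n, 0.9, 1.1) })

  # comb-style binary tree on an (nx, ny) raster: from each branch tip,
  # a vertical split segment then a horizontal advance, per generation
  build_tree_2d <- function() {
    L <- tree_levels
    xs <- round(seq(2, nx - 2, length.out = L + 2))  # column of each generation
    nodes <- list(); elements <- list(); members <- list()
    nid <- 0; eid <- 0
    new_node <- function(x, y) {
      nid <<- nid + 1
      nodes[[nid]] <<- c(x = x, y = y)
      nid
    }
    seg <- function(n_from, n_to, radius, vox) {
      eid <<- eid + 1
      elements[[eid]] <<- list(j = n_from, i = n_to, radius = radius)
      members[[eid]] <<- vox
      eid
    }
    cy <- round(ny / 2)
    root <- new_node(xs[1], cy)
    trunk_end <- new_node(xs[2], cy)
    seg(root, trunk_end, root_radius * rng(1), cbind(xs[1]:xs[2], cy))
    tips <- list(list(node = trunk_end, y = cy))
    span <- round(ny / 4)
    for (l in seq_len(L)) {
      radius_l <- root_radius * 2^(-l / 3)
      new_tips <- list()
      for (tip in tips) {
        x0 <- nodes[[tip$node]][["x"]]
        for (dirn in c(-1, 1)) {
          y1 <- max(1, min(ny, tip$y + dirn * span))
          if (y1 == tip$y) next   # no room on this side: prune the branch
          corner <- new_node(x0, y1)
          vseg <- cbind(x0, (tip$y + dirn):y1)
          seg(tip$node, corner, radius_l * rng(1), vseg)
          x1 <- xs[l + 2]
          endn <- new_node(x1, y1)
          seg(corner, endn, radius_l * rng(1), cbind((x0 + 1):x1, y1))
          new_tips[[length(new_tips) + 1]] <- list(node = endn, y = y1)
        }
      }
      tips <- new_tips
      span <- max(1, round(span / 2))
    }
    list(nodes = do.call(rbind, nodes), elements = elements,
         members = members, root = 1L)
  }

  art2d <- build_tree_2d()
  ven2d <- build_tree_2d()
  ven2d$nodes[, "x"] <- nx + 1 - ven2d$nodes[, "x"]           # mirror in x
  ven2d$members <- lapply(ven2d$members, function(m) {
    m[, 1] <- nx + 1 - m[, 1]; m
  })

  labs <- array(MATERIALS[["TISSUE"]], c(nx, ny, 3))
  mark <- function(t2d, layer, code) {
    for (m in t2d$members)
      labs[cbind(m[, 1], m[, 2], layer)] <<- code
  }
  mark(art2d, 1L, MATERIALS[["ARTERY"]])
  mark(ven2d, 3L, MATERIALS[["VEIN"]])
  grid <- voxel_grid(labs, spacing)
  lin <- array(seq_len(prod(grid$shape)), grid$shape)

  to_tree <- function(t2d, layer, kind) {
    z <- (layer - 0.5) * spacing[3]
    nodes <- data.frame(id = paste0(kind, "_n", seq_len(nrow(t2d$nodes))),
                        x = (t2d$nodes[, "x"] - 0.5) * spacing[1],
                        y = (t2d$nodes[, "y"] - 0.5) * spacing[2],
                        z = z,
                        root = seq_len(nrow(t2d$nodes)) == t2d$root)
    mem <- lapply(t2d$members, function(m) {
      v <- unique(lin[cbind(m[, 1], m[, 2], layer)])
      v
    })
    # de-duplicate voxels claimed by consecutive segments (corner voxels)
    seen <- integer(0)
    for (e in seq_along(mem)) {
      mem[[e]] <- setdiff(mem[[e]], seen)
      seen <- c(seen, mem[[e]])
    }
    el <- do.call(rbind, lapply(t2d$elements, function(e)
      data.frame(node_j = e$j, node_i = e$i, radius = e$radius)))
    elements <- data.frame(id = paste0(kind, "_e", seq_len(nrow(el))),
                           node_j = nodes$id[el$node_j],
                           node_i = nodes$id[el$node_i],
                           radius = el$radius)
    elements$member_voxels <- I(mem)
    vessel_tree(nodes, elements, kind = kind)
  }
  artery <- to_tree(art2d, 1L, "artery")
  vein <- to_tree(ven2d, 3L, "vein")

  if (is.null(epsilon)) {
    tis <- which(grid$labels == MATERIALS[["TISSUE"]])
    ctr <- voxel_centers(grid, tis)
    nearest <- function(tree) {
      tpos <- as.matrix(tree$nodes[match(tree$terminals, tree$nodes$id),
                                   c("x", "y", "z")])
      dm <- matrix(0, nrow(ctr), nrow(tpos))
      for (k in seq_len(nrow(tpos)))
        dm[, k] <- sqrt((ctr[, 1] - tpos[k, 1])^2 + (ctr[, 2] - tpos[k, 2])^2 +
                          (ctr[, 3] - tpos[k, 3])^2)
      apply(dm, 1, min)
    }
    epsilon <- 1.05 * max(pmax(nearest(artery), nearest(vein)))
  }
  hemo_problem(grid, artery, vein, epsilon = epsilon, flow = params,
               thermal = thermal, extra = list(seed = seed))
}
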