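#' Flow model parameters
#'
#' Proportionality coefficients of the coupled vascular/porous flow model.
#' `alpha` multiplies the compartment pressure difference to give the
#' intra-voxel perfusion rate density (Pa^-1 s^-1, printed elsewhere as the
#' equivalent m s kg^-1); `gamma_a`/`gamma_v` are the pressure-drop
#' parameters of the virtual unresolved network: a terminal's flow is
#' (gamma/mu) times the difference between its nodal pressure and the
#' mollifier-weighted tissue pressure, so gamma/mu is the virtual-network
#' conductance (with the default gamma = 1e14 m^3 that resistance is
#' negligible and the terminal pressure tracks the local tissue pressure).
#'
#' @param k_a,k_v arterial/venous compartment permeability (m^2).
#' @param alpha compartmental perfusion coefficient (Pa^-1 s^-1).
#' @param mu blood dynamic viscosity (Pa s).
#' @param gamma_a,gamma_v virtual-network pressure-drop parameter (m^3).
#' @param P_in,P_out Dirichlet pressures at arterial / venous roots (Pa).
#' @return object of class `flow_params`.
#' @export
flow_params <- function(k_a = 1e-12, k_v = 5e-10, alpha = 1e-6, mu = 3e-3,
                        gamma_a = 1e14, gamma_v = 1e14,
                        P_in = 10600, P_out = 1600) {
  stopifnot(k_a > 0, k_v > 0, alpha >= 0, mu > 0, gamma_a > 0, gamma_v > 0)
  if (P_in < P_out) stop("P_in must be >= P_out")
  structure(list(k_a = k_a, k_v = k_v, alpha = alpha, mu = mu,
                 gamma_a = gamma_a, gamma_v = gamma_v,
                 P_in = P_in, P_out = P_out),
            class = "flow_params")
}

#' Two-point flux approximation face transmissibility
#'
#' Finite-volume face conductance t = (A / (mu d)) * harmonic_mean(k_i, k_j),
#' symmetric in the two sides; a zero permeability on either side seals the
#' face (t = 0).
#'
#' @param area face area (m^2).
#' @param dist center-to-center distance across the face (m).
#' @param k_i,k_j permeabilities on the two sides (m^2).
#' @param mu viscosity (Pa s).
#' @return transmissibility (m^3 Pa^-1 s^-1). Vectorized.
#' @export
tpfa_transmissibility <- function(area, dist, k_i, k_j, mu) {
  stopifnot(all(area > 0), all(dist > 0), all(mu > 0),
            all(k_i >= 0), all(k_j >= 0))
  hm <- ifelse(k_i + k_j > 0, 2 * k_i * k_j / (k_i + k_j), 0)
  area * hm / (mu * dist)
}

#' Intra-voxel perfusion rate density
#'
#' Rate density of blood passing from the arterial to the venous
#' compartment of a voxel, u_perf = alpha * (P_a - P_v) (s^-1); multiply by
#' the voxel volume for the volumetric rate. Positive when P_a > P_v.
#'
#' @param P_a,P_v compartment pressures (Pa).
#' @param alpha perfusion coefficient (Pa^-1 s^-1).
#' @export
perfusion_flux <- function(P_a, P_v, alpha) alpha * (P_a - P_v)

#' Assemble the coupled flow system
#'
#' Builds the sparse linear system for the unknown vector
#' `[P_a (tissue voxels); P_v; p (arterial nodes); p (venous nodes);
#' q (terminal flows)]`. Rows are, in order: arterial compartment mass
#' conservation per tissue voxel (TPFA face fluxes + perfusion - mollifier
#' sources), venous compartment conservation, vessel-node rows (Dirichlet
#' at roots, Kirchhoff balances of Hagen-Poiseuille element flows at other
#' nodes, with the terminal flow entering its node balance), and one
#' pressure-continuity row per terminal linking the terminal flow to the
#' nodal and mollifier-averaged tissue pressures. The continuity rows are
#' scaled by mu/gamma and the terminal flows kept as explicit unknowns so
#' no coefficient exceeds order one there; vessel-labeled voxels carry no
#' porous unknowns (all resolved vessel flow is one-dimensional).
#'
#' @param grid a `voxel_grid`.
#' @param arterial_tree,venous_tree `vessel_tree` objects.
#' @param coupling a `coupling_map` covering all terminals of both trees.
#' @param params a `flow_params`.
#' @return object of class `flow_system` with the sparse matrix `A`, right
#'   hand side `b`, and index maps used by \code{\link{solve_flow}}.
#' @export
assemble_flow_system <- function(grid, arterial_tree, venous_tree, coupling, params) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(coupling, "coupling_map"),
            inherits(params, "flow_params"))
  tissue <- which(grid$labels == MATERIALS[["TISSUE"]])
  nt <- length(tissue)
  if (nt == 0) stop("no tissue voxels: nothing to assemble")
  tv <- integer(prod(grid$shape)); tv[tissue] <- seq_len(nt)

  # check the coupling map covers every terminal of both trees
  for (tr in list(arterial_tree, venous_tree)) {
    have <- coupling$terminals$node[coupling$terminals$tree == tr$kind]
    miss <- setdiff(tr$terminals, have)
    if (length(miss))
      stop("coupling map misses ", tr$kind, " terminal(s): ",
           paste(miss, collapse = ", "))
  }

  faces <- interior_faces(grid)
  fi <- faces$interior
  tt <- tv[fi$i] > 0 & tv[fi$j] > 0          # tissue-tissue faces only
  ftt <- fi[tt, , drop = FALSE]
  t_a <- tpfa_transmissibility(ftt$area, ftt$dist, params$k_a, params$k_a, params$mu)
  t_v <- tpfa_transmissibility(ftt$area, ftt$dist, params$k_v, params$k_v, params$mu)

  na <- nrow(arterial_tree$nodes); nv <- nrow(venous_tree$nodes)
  off_pv <- nt; off_na <- 2L * nt; off_nv <- 2L * nt + na
  off_s <- 2L * nt + na + nv
  nterm <- nrow(coupling$terminals)
  ndim <- off_s + nterm

  I <- integer(0); J <- integer(0); X <- numeric(0)
  add <- function(i, j, x) {
    I <<- c(I, i); J <<- c(J, j); X <<- c(X, x)
  }

  # TPFA face terms, both compartments
  ri <- tv[ftt$i]; rj <- tv[ftt$j]
  add(c(ri, ri, rj, rj), c(ri, rj, rj, ri), c(t_a, -t_a, t_a, -t_a))
  add(off_pv + c(ri, ri, rj, rj), off_pv + c(ri, rj, rj, ri), c(t_v, -t_v, t_v, -t_v))

  # perfusion coupling alpha * (P_a - P_v) * V
  aV <- params$alpha * grid$voxel_volume
  iv <- seq_len(nt)
  add(c(iv, iv), c(iv, off_pv + iv), c(rep(aV, nt), rep(-aV, nt)))
  add(off_pv + c(iv, iv), c(iv, off_pv + iv), c(rep(-aV, nt), rep(aV, nt)))

  b <- numeric(ndim)

  # vessel node rows per tree
  node_rows <- function(tree, off, P_root) {
    ep <- element_endpoints(tree)
    kap <- element_conductance(tree$elements$radius, tree$elements$length, params$mu)
    roots <- match(tree$roots, tree$nodes$id)
    is_root <- logical(nrow(tree$nodes)); is_root[roots] <- TRUE
    for (e in seq_len(nrow(ep))) {
      j <- ep[e, "j"]; i <- ep[e, "i"]; k <- kap[e]
      if (!is_root[j]) add(off + c(j, j), off + c(j, i), c(k, -k))
      if (!is_root[i]) add(off + c(i, i), off + c(i, j), c(k, -k))
    }
    for (r in roots) { add(off + r, off + r, 1) ; b[off + r] <<- P_root }
    kap
  }
  kap_a <- node_rows(arterial_tree, off_na, params$P_in)
  kap_v <- node_rows(venous_tree, off_nv, params$P_out)

  # terminal rows: node balance gets +q_k; continuity row defines q_k
  term <- coupling$terminals
  for (s in seq_len(nterm)) {
    art <- term$tree[s] == "artery"
    tree <- if (art) arterial_tree else venous_tree
    off <- if (art) off_na else off_nv
    gamma <- if (art) params$gamma_a else params$gamma_v
    node <- match(term$node[s], tree$nodes$id)
    add(off + node, off_s + s, 1)                       # terminal node balance
    w <- coupling$weights[[s]]
    rowp <- off_s + s
    add(rowp, off_s + s, params$mu / gamma)             # (mu/gamma) q_k
    add(rowp, off + node, -1)                           # - p_k
    cols <- (if (art) 0L else off_pv) + tv[w$voxel]
    if (any(cols == (if (art) 0L else off_pv)))
      stop("coupling map references non-tissue voxels")
    add(rep.int(rowp, nrow(w)), cols, w$w)              # + sum w_ki P_beta,i
    # mollifier source/sink in the compartment rows
    add((if (art) 0L else off_pv) + tv[w$voxel], rep.int(off_s + s, nrow(w)), -w$w)
  }

  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndim, ndim))

  structure(list(A = A, b = b, grid = grid,
                 arterial_tree = arterial_tree, venous_tree = venous_tree,
                 coupling = coupling, params = params,
                 tissue = tissue, tv = tv, n_tissue = nt,
                 off_pv = off_pv, off_na = off_na, off_nv = off_nv, off_s = off_s,
                 faces = ftt, t_a = t_a, t_v = t_v,
                 kappa_a = kap_a, kappa_v = kap_v),
            class = "flow_system")
}

#' @export
print.flow_system <- function(x, ...) {
  nnz <- length(x$A@x)
  n <- nrow(x$A)
  cat(sprintf("flow_system: n = %d unknowns (%d tissue voxels x 2 compartments, %d nodes, %d terminals)\n",
              n, x$n_tissue, x$off_s - 2L * x$n_tissue, n - x$off_s))
  cat(sprintf("  sparsity %.4f%%\n", 100 * (1 - nnz / (as.numeric(n)^2))))
  invisible(x)
}

#' Solve the coupled flow system
#'
#' Solves the assembled system (sparse direct LU by default at these sizes,
#' restarted GMRES with ILU(0) preconditioning on request or for large
#' systems, dense LAPACK as the small-system oracle) and derives element
#' flows, terminal flows, per-voxel source/sink rates and the perfusion
#' field.
#'
#' @param system a `flow_system`.
#' @param method,tol,preconditioner,... passed to \code{\link{solve_linear}}.
#' @return object of class `flow_solution`: tissue-voxel pressures `P_a`,
#'   `P_v` (Pa), nodal pressures `p_arterial`, `p_venous`, element flows
#'   `q_arterial`, `q_venous` (m^3/s, signed j -> i), terminal flows
#'   `s_terminal`, per-voxel absolute source/sink rates `Q_a`, `Q_v`
#'   (m^3/s), perfusion rate density `u_perf` (s^-1), and solver residuals.
#' @export
solve_flow <- function(system, method = "auto", tol = 1e-8,
                       preconditioner = "ilu", ...) {
  stopifnot(inherits(system, "flow_system"))
  sol <- solve_linear(system$A, system$b, method = method, tol = tol,
                      preconditioner = preconditioner, ...)
  x <- sol$x
  nt <- system$n_tissue
  P_a <- x[seq_len(nt)]
  P_v <- x[system$off_pv + seq_len(nt)]
  pa <- x[system$off_na + seq_len(nrow(system$arterial_tree$nodes))]
  pv <- x[system$off_nv + seq_len(nrow(system$venous_tree$nodes))]
  names(pa) <- system$arterial_tree$nodes$id
  names(pv) <- system$venous_tree$nodes$id
  s <- x[system$off_s + seq_len(nrow(system$coupling$terminals))]

  elem_q <- function(tree, p, kap) {
    ep <- element_endpoints(tree)
    q <- kap * (p[ep[, "j"]] - p[ep[, "i"]])
    names(q) <- tree$elements$id
    q
  }
  q_a <- elem_q(system$arterial_tree, pa, system$kappa_a)
  q_v <- elem_q(system$venous_tree, pv, system$kappa_v)

  Q_a <- numeric(nt); Q_v <- numeric(nt)
  term <- system$coupling$terminals
  for (k in seq_len(nrow(term))) {
    w <- system$coupling$weights[[k]]
    idx <- system$tv[w$voxel]
    if (term$tree[k] == "artery") Q_a[idx] <- Q_a[idx] + w$w * s[k]
    else Q_v[idx] <- Q_v[idx] - w$w * s[k]
  }

  structure(list(P_a = P_a, P_v = P_v,
                 p_arterial = pa, p_venous = pv,
                 q_arterial = q_a, q_venous = q_v,
                 s_terminal = s, Q_a = Q_a, Q_v = Q_v,
                 u_perf = perfusion_flux(P_a, P_v, system$params$alpha),
                 residual_norm = sol$relres,
                 max_abs_residual = sol$max_abs_residual,
                 solver = sol[c("method", "iterations", "converged")],
                 system = system),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("flow_solution (%s): %d tissue voxels\n",
              x$solver$method, length(x$P_a)))
  cat(sprintf("  P_a: %.4g .. %.4g Pa   P_v: %.4g .. %.4g Pa\n",
              min(x$P_a), max(x$P_a), min(x$P_v), max(x$P_v)))
  gb <- global_flow_balance(x)
  cat(sprintf("  root inflow %.4g m^3/s, outflow %.4g m^3/s (rel. mismatch %.2e)\n",
              gb$inflow, gb$outflow, gb$rel_mismatch))
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  rep <- mass_balance_report(object)
  print(object)
  cat(sprintf("  worst terminal imbalance %.3e m^3/s, worst voxel divergence %.3e m^3/s\n",
              max(rep$terminal$imbalance), max(abs(rep$voxel_divergence))))
  invisible(rep)
}

# signed flow out of root nodes into the tree (artery) / out of the tree (vein)
root_flows <- function(tree, p, kap) {
  ep <- element_endpoints(tree)
  roots <- match(tree$roots, tree$nodes$id)
  vapply(roots, function(r) {
    qs <- 0
    at_j <- which(ep[, "j"] == r); at_i <- which(ep[, "i"] == r)
    if (length(at_j)) qs <- qs + sum(kap[at_j] * (p[r] - p[ep[at_j, "i"]]))
    if (length(at_i)) qs <- qs + sum(kap[at_i] * (p[r] - p[ep[at_i, "j"]]))
    qs
  }, numeric(1))
}

global_flow_balance <- function(solution) {
  sys <- solution$system
  qin <- sum(root_flows(sys$arterial_tree, solution$p_arterial, sys$kappa_a))
  qout <- -sum(root_flows(sys$venous_tree, solution$p_venous, sys$kappa_v))
  list(inflow = qin, outflow = qout,
       rel_mismatch = abs(qin - qout) / max(abs(qin), .Machine$double.xmin))
}

#' Mass balance audit of a flow solution
#'
#' Reports, per terminal, the difference between the terminal element flow
#' and the total rate distributed over its sphere of influence; the net
#' divergence residual of every voxel-compartment equation; and the global
#' arterial-inflow / venous-outflow mismatch.
#'
#' @param solution a `flow_solution`.
#' @return list with `terminal` (data frame), `voxel_divergence` (residuals
#'   of the 2 x n_tissue compartment rows, m^3/s), and `global`.
#' @export
mass_balance_report <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  sys <- solution$system
  r <- as.numeric(sys$A %*% c(solution$P_a, solution$P_v,
                              solution$p_arterial, solution$p_venous,
                              solution$s_terminal) - sys$b)
  term <- sys$coupling$terminals
  # flow out of the terminal node through its element vs. flow distributed
  # over the sphere of influence (their sum is the node-row residual)
  imbalance <- vapply(seq_len(nrow(term)), function(k) {
    art <- term$tree[k] == "artery"
    tree <- if (art) sys$arterial_tree else sys$venous_tree
    p <- if (art) solution$p_arterial else solution$p_venous
    kap <- if (art) sys$kappa_a else sys$kappa_v
    e <- match(term$element[k], tree$elements$id)
    ep <- element_endpoints(tree)[e, ]
    node <- match(term$node[k], tree$nodes$id)
    other <- if (ep[["j"]] == node) ep[["i"]] else ep[["j"]]
    abs(kap[e] * (p[node] - p[other]) + solution$s_terminal[k])
  }, numeric(1))
  qelem <- ifelse(term$tree == "artery",
                  solution$q_arterial[term$element],
                  solution$q_venous[term$element])
  list(terminal = data.frame(term[, c("tree", "node", "element")],
                             q_terminal = solution$s_terminal,
                             element_flow = qelem,
                             imbalance = imbalance),
       voxel_divergence = r[seq_len(2L * sys$n_tissue)],
       global = global_flow_balance(solution))
}

#' Solve a single-compartment Darcy problem with fixed voxel pressures
#'
#' Pure porous-media solve on the tissue voxels of a grid (no vessels, one
#' compartment): TPFA face fluxes balance in every voxel except those with
#' prescribed pressures. Used to validate the face discretization against
#' the closed-form slab solution.
#'
#' @param grid a `voxel_grid` (tissue voxels carry unknowns).
#' @param k permeability (m^2).
#' @param mu viscosity (Pa s).
#' @param fixed data frame with columns `voxel` (linear index) and `value`
#'   (Pa); at least one required.
#' @param method passed to \code{\link{solve_linear}}.
#' @return list with `P` (Pa per tissue voxel), `tissue` (their linear
#'   indices), and `face_flux` (signed i -> j flux per tissue-tissue face,
#'   m^3/s).
#' @export
solve_darcy <- function(grid, k, mu, fixed, method = "auto") {
  tissue <- which(grid$labels == MATERIALS[["TISSUE"]])
  nt <- length(tissue)
  tv <- integer(prod(grid$shape)); tv[tissue] <- seq_len(nt)
  fixed <- as.data.frame(fixed)
  if (!nrow(fixed)) stop("at least one fixed pressure required")
  if (any(tv[fixed$voxel] == 0)) stop("fixed pressures must sit on tissue voxels")
  fx <- tv[fixed$voxel]
  ftt <- interior_faces(grid)$interior
  ftt <- ftt[tv[ftt$i] > 0 & tv[ftt$j] > 0, , drop = FALSE]
  t_f <- tpfa_transmissibility(ftt$area, ftt$dist, k, k, mu)
  free <- !(seq_len(nt) %in% fx)
  ri <- tv[ftt$i]; rj <- tv[ftt$j]
  I <- c(ri[free[ri]], ri[free[ri]], rj[free[rj]], rj[free[rj]], fx)
  J <- c(ri[free[ri]], rj[free[ri]], rj[free[rj]], ri[free[rj]], fx)
  X <- c(t_f[free[ri]], -t_f[free[ri]], t_f[free[rj]], -t_f[free[rj]], rep(1, length(fx)))
  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(nt, nt))
  b <- numeric(nt); b[fx] <- fixed$value
  P <- solve_linear(A, b, method = method)$x
  list(P = P, tissue = tissue,
       face_flux = data.frame(i = ftt$i, j = ftt$j,
                              flux = t_f * (P[ri] - P[rj])))
}
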