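#' Thermal model parameters
#'
#' Steady-state bioheat parameters. The blood-tissue convective coefficient
#' `h_b` switches the physical assumption: `mode = "pbm"` (h_b = 0.001
#' W m^-2 degC^-1, effectively no vessel-wall exchange, blood equilibrates
#' only on delivery to tissue) versus `mode = "wjm"` (h_b = 10, significant
#' counter-current vessel-tissue exchange). Blood thermal conductivity
#' `K_b` is accepted for completeness but enters no equation of the
#' element energy balance (which is advection plus wall convection); it is
#' stored and reported unused.
#'
#' @param K_t tissue thermal conductivity (W m^-1 degC^-1).
#' @param c_pt,c_pb tissue/blood specific heat (J kg^-1 degC^-1).
#' @param rho_t,rho_b tissue/blood density (kg m^-3).
#' @param qdot_m metabolic heat generation rate (W m^-3).
#' @param h_b blood-tissue convective coefficient (W m^-2 degC^-1).
#' @param h_inf ambient convective coefficient (W m^-2 degC^-1).
#' @param T_inf ambient temperature (degC).
#' @param T_in arterial inlet blood temperature (degC).
#' @param K_b blood thermal conductivity (W m^-1 degC^-1; parsed, unused).
#' @param mode `"custom"`, `"pbm"` or `"wjm"` (presets override `h_b`).
#' @return object of class `thermal_params`.
#' @export
thermal_params <- function(K_t = 0.49, c_pt = 3421, c_pb = 3617,
                           rho_t = 1090, rho_b = 1050, qdot_m = 0,
                           h_b = 0.001, h_inf = 20,
                           T_inf = 20, T_in = 35, K_b = 0.52,
                           mode = c("custom", "pbm", "wjm")) {
  mode <- match.arg(mode)
  if (mode == "pbm") h_b <- 0.001
  if (mode == "wjm") h_b <- 10
  stopifnot(K_t > 0, c_pt > 0, c_pb > 0, rho_t > 0, rho_b > 0,
            h_b >= 0, h_inf >= 0, qdot_m >= 0, K_b > 0)
  structure(list(K_t = K_t, c_pt = c_pt, c_pb = c_pb, rho_t = rho_t,
                 rho_b = rho_b, qdot_m = qdot_m, h_b = h_b, h_inf = h_inf,
                 T_inf = T_inf, T_in = T_in, K_b = K_b, mode = mode),
            class = "thermal_params")
}

#' Overall heat transfer coefficient of a voxel face
#'
#' Series thermal resistance across a face: between two tissue half-cells
#' U = K_t/ds; between a tissue half-cell and air U = [ds/2K_t + 1/h_inf]^-1;
#' between a tissue half-cell and a vessel wall U = [ds/2K_t + 1/h_b]^-1.
#' An h of zero makes the face adiabatic (U = 0). `ds` is the axis-aligned
#' center distance of the face (anisotropic grids use the spacing of the
#' face axis).
#'
#' @param neighbor_kind `"tissue"`, `"air"` or `"vessel"`.
#' @param ds center distance across the face (m).
#' @param K_t tissue conductivity (W m^-1 degC^-1).
#' @param h convective coefficient for air/vessel neighbours
#'   (W m^-2 degC^-1); ignored for tissue.
#' @return U (W m^-2 degC^-1). Vectorized over `ds` and `h`.
#' @export
overall_U <- function(neighbor_kind = c("tissue", "air", "vessel"),
                      ds, K_t, h = NULL) {
  neighbor_kind <- match.arg(neighbor_kind)
  stopifnot(all(ds > 0), K_t > 0)
  if (neighbor_kind == "tissue") return(K_t / ds)
  if (is.null(h)) stop("h required for air/vessel faces")
  ifelse(h > 0, 1 / (ds / (2 * K_t) + 1 / h), 0)
}

# ownership of vessel-labeled voxels: linear voxel index -> global element row
element_table <- function(arterial_tree, venous_tree, grid) {
  els <- rbind(
    data.frame(tree = "artery", id = arterial_tree$elements$id,
               local = seq_len(nrow(arterial_tree$elements))),
    data.frame(tree = "vein", id = venous_tree$elements$id,
               local = seq_len(nrow(venous_tree$elements))))
  els$global <- seq_len(nrow(els))
  owner <- integer(prod(grid$shape))
  assign_members <- function(tree, offset) {
    mv <- tree$elements$member_voxels
    if (is.null(mv)) return()
    for (e in seq_along(mv)) {
      v <- mv[[e]]
      if (is.null(v) || !length(v)) next
      clash <- owner[v] != 0L
      if (any(clash))
        stop("voxel(s) claimed by two vessel elements: ",
             paste(v[clash], collapse = ", "))
      owner[v] <<- offset + e
    }
  }
  assign_members(arterial_tree, 0L)
  assign_members(venous_tree, nrow(arterial_tree$elements))
  vess <- which(grid$labels == MATERIALS[["ARTERY"]] | grid$labels == MATERIALS[["VEIN"]])
  orphan <- vess[owner[vess] == 0L]
  if (length(orphan))
    stop("vessel-labeled voxel(s) not owned by any element: ",
         paste(utils::head(orphan, 10), collapse = ", "),
         if (length(orphan) > 10) " ..." else "")
  list(elements = els, owner = owner)
}

#' Build the blood advection graph from a flow solution
#'
#' Resolves flow directions into a donor-cell (upwind) advection structure:
#' inter-voxel mass rates (the signed sum of both compartments' face
#' flows, kept on the receiving side), per-voxel mollifier source rates
#' from arterial terminals (blood arrives at the supplying terminal
#' element's temperature), element-to-element transfers along each tree
#' (split proportionally at merging/dividing nodes), voxel-to-element
#' collection at venous terminals, and the tissue contact faces of every
#' element. Per-voxel mass closure (inflows + sources = outflows + sinks)
#' is checked against the flow residuals.
#'
#' @param flow a `flow_solution`.
#' @param closure_tol allowed voxel mass-closure violation relative to the
#'   gross arterial root inflow.
#' @param rate_tol volumetric rates with magnitude at or below this
#'   (m^3/s) are dropped; the default keeps everything but exact zeros.
#' @return object of class `advection_graph`.
#' @export
build_advection_graph <- function(flow, closure_tol = 1e-6, rate_tol = 0) {
  stopifnot(inherits(flow, "flow_solution"))
  sys <- flow$system
  grid <- sys$grid
  # all rates are volumetric (m^3/s); assembly multiplies by rho_b * c_pb
  # volumetric face flows i -> j, both compartments
  ftt <- sys$faces
  f <- sys$t_a * (flow$P_a[sys$tv[ftt$i]] - flow$P_a[sys$tv[ftt$j]]) +
    sys$t_v * (flow$P_v[sys$tv[ftt$i]] - flow$P_v[sys$tv[ftt$j]])
  recv <- ifelse(f > 0, sys$tv[ftt$j], sys$tv[ftt$i])
  src <- ifelse(f > 0, sys$tv[ftt$i], sys$tv[ftt$j])
  keep <- abs(f) > rate_tol
  voxel_inflows <- data.frame(receiver = recv[keep], source = src[keep],
                              rate = abs(f)[keep])

  et <- element_table(sys$arterial_tree, sys$venous_tree, grid)
  term <- sys$coupling$terminals
  s <- flow$s_terminal

  # per-voxel mollifier sources (arterial, s > 0) and sinks (venous, s < 0),
  # with sign-reversed terminals rerouted to the upwind side
  src_vox <- integer(0); src_el <- integer(0); src_rate <- numeric(0)
  col_el <- integer(0); col_vox <- integer(0); col_rate <- numeric(0)
  glob_of <- function(tr, eid) et$elements$global[et$elements$tree == tr][
    match(eid, et$elements$id[et$elements$tree == tr])]
  for (k in seq_len(nrow(term))) {
    if (s[k] == 0) next
    w <- sys$coupling$weights[[k]]
    ge <- glob_of(term$tree[k], term$element[k])
    if (s[k] > 0) {           # flow from terminal into tissue
      ok <- w$w * s[k] > rate_tol
      src_vox <- c(src_vox, sys$tv[w$voxel[ok]])
      src_el <- c(src_el, rep.int(ge, sum(ok)))
      src_rate <- c(src_rate, (w$w * s[k])[ok])
    } else {                  # flow from tissue into terminal
      ok <- w$w * (-s[k]) > rate_tol
      col_el <- c(col_el, rep.int(ge, sum(ok)))
      col_vox <- c(col_vox, sys$tv[w$voxel[ok]])
      col_rate <- c(col_rate, (w$w * (-s[k]))[ok])
    }
  }
  voxel_sources <- data.frame(voxel = src_vox, element = src_el, rate = src_rate)
  elem_voxel_inflows <- data.frame(element = col_el, voxel = col_vox, rate = col_rate)

  # element-to-element transfers at shared nodes, proportional split
  tr_recv <- integer(0); tr_src <- integer(0); tr_rate <- numeric(0)
  per_tree <- function(tree, q, goffset) {
    ep <- element_endpoints(tree)
    tidx <- match(tree$terminals, tree$nodes$id)
    tflow <- numeric(nrow(tree$nodes))    # flow node -> tissue at terminals
    sel <- term$tree == tree$kind
    tflow[match(term$node[sel], tree$nodes$id)] <- s[sel]
    for (n in seq_len(nrow(tree$nodes))) {
      into_e <- c(which(ep[, "i"] == n & q > 0), which(ep[, "j"] == n & q < 0))
      out_e <- c(which(ep[, "j"] == n & q > 0), which(ep[, "i"] == n & q < 0))
      m_in <- abs(q[into_e])
      m_out <- abs(q[out_e])
      total_out <- sum(m_out) + max(tflow[n], 0)
      if (total_out <= 0 || !length(out_e) || !length(into_e)) next
      for (oi in seq_along(out_e)) {
        share <- m_out[oi] / total_out
        rr <- m_in * share
        ok <- rr > rate_tol
        tr_recv <<- c(tr_recv, rep.int(goffset + out_e[oi], sum(ok)))
        tr_src <<- c(tr_src, goffset + into_e[ok])
        tr_rate <<- c(tr_rate, rr[ok])
      }
      # tissue inflow at a collecting terminal feeds the outflow elements
      if (tflow[n] < 0 && length(out_e)) {
        # rerouted via elem_voxel_inflows above (receiver = terminal element);
        # nothing further here: the terminal node has a single element.
      }
    }
  }
  na_el <- nrow(sys$arterial_tree$elements)
  per_tree(sys$arterial_tree, flow$q_arterial, 0L)
  per_tree(sys$venous_tree, flow$q_venous, na_el)
  elem_transfers <- data.frame(receiver = tr_recv, source = tr_src, rate = tr_rate)

  # contact faces between tissue voxels and vessel-owned voxels
  fi <- interior_faces(grid)
  intf <- fi$interior
  ti <- sys$tv[intf$i]; tj <- sys$tv[intf$j]
  vi <- et$owner[intf$i]; vj <- et$owner[intf$j]
  a_side <- ti > 0 & vj > 0
  b_side <- tj > 0 & vi > 0
  contact <- rbind(
    data.frame(voxel = ti[a_side], element = vj[a_side],
               area = intf$area[a_side], dist = intf$dist[a_side]),
    data.frame(voxel = tj[b_side], element = vi[b_side],
               area = intf$area[b_side], dist = intf$dist[b_side]))

  # ambient faces of tissue voxels (vessel voxels do not see ambient air:
  # element energy balance has advection and wall convection only)
  amb <- fi$ambient
  amb <- amb[sys$tv[amb$i] > 0, , drop = FALSE]
  ambient <- data.frame(voxel = sys$tv[amb$i], area = amb$area, dist = amb$dist)

  # pinned (Dirichlet) elements: arterial elements touching an arterial root
  ep_a <- element_endpoints(sys$arterial_tree)
  aroot <- match(sys$arterial_tree$roots, sys$arterial_tree$nodes$id)
  pinned <- which(ep_a[, "j"] %in% aroot | ep_a[, "i"] %in% aroot)

  # venous root outlets: per incident element, volumetric flow into the root
  ep_v <- element_endpoints(sys$venous_tree)
  vroot <- match(sys$venous_tree$roots, sys$venous_tree$nodes$id)
  out_el <- integer(0); out_q <- numeric(0)
  for (r in vroot) {
    at_j <- which(ep_v[, "j"] == r); at_i <- which(ep_v[, "i"] == r)
    if (length(at_j)) { out_el <- c(out_el, at_j); out_q <- c(out_q, -flow$q_venous[at_j]) }
    if (length(at_i)) { out_el <- c(out_el, at_i); out_q <- c(out_q, flow$q_venous[at_i]) }
  }
  outlets <- data.frame(element = na_el + out_el, q = out_q)

  # per-voxel volumetric mass closure from the flow residuals
  sysr <- as.numeric(sys$A %*% c(flow$P_a, flow$P_v, flow$p_arterial,
                                 flow$p_venous, flow$s_terminal) - sys$b)
  nt <- sys$n_tissue
  closure <- sysr[seq_len(nt)] + sysr[nt + seq_len(nt)]
  gross <- sum(abs(root_flows(sys$arterial_tree, flow$p_arterial, sys$kappa_a)))
  if (gross > 0 && max(abs(closure)) > closure_tol * gross)
    stop(sprintf("voxel mass closure violated (%.3e vs tolerance %.3e m^3/s): stale or inconsistent flow solution",
                 max(abs(closure)), closure_tol * gross))

  structure(list(voxel_inflows = voxel_inflows,
                 voxel_sources = voxel_sources,
                 elem_voxel_inflows = elem_voxel_inflows,
                 elem_transfers = elem_transfers,
                 contact = contact, ambient = ambient,
                 elements = et$elements, owner = et$owner,
                 pinned_arterial = pinned, outlets = outlets,
                 gross_inflow = gross, closure = closure,
                 flow = flow),
            class = "advection_graph")
}

#' @export
print.advection_graph <- function(x, ...) {
  cat(sprintf("advection_graph: %d voxel-voxel streams, %d source terms, %d sink terms, %d element transfers\n",
              nrow(x$voxel_inflows), nrow(x$voxel_sources),
              nrow(x$elem_voxel_inflows), nrow(x$elem_transfers)))
  cat(sprintf("  gross arterial inflow %.4g m^3/s; worst voxel closure %.3e m^3/s\n",
              x$gross_inflow, if (length(x$closure)) max(abs(x$closure)) else 0))
  invisible(x)
}

#' Assemble the steady-state thermal system
#'
#' Unknowns are one temperature per tissue voxel followed by one per vessel
#' element (all voxels of an element are isothermal with it). Voxel rows
#' balance face conduction/convection (overall-U coefficients over all six
#' faces), donor-cell advection from inflow neighbours, mollifier source
#' advection at the supplying element's temperature, ambient Robin
#' exchange, and metabolic generation. Element rows balance advection from
#' upstream elements (or collecting voxels at venous terminals) and wall
#' convection with adjacent tissue, with arterial root elements pinned to
#' the inlet temperature. The tissue-vessel wall coefficient of the face is
#' used on both sides of each contact face so the scheme conserves energy
#' exactly. Internally the system is assembled in ambient offsets
#' theta = T - T_inf (same matrix, homogeneous ambient right-hand side),
#' which makes the exact proportionality of the field to the inlet offset
#' explicit when metabolic generation is zero.
#'
#' @param grid a `voxel_grid`.
#' @param flow the `flow_solution` the graph was built from.
#' @param graph an `advection_graph`.
#' @param params a `thermal_params`.
#' @return object of class `heat_system`.
#' @export
assemble_heat_system <- function(grid, flow, graph, params) {
  stopifnot(inherits(graph, "advection_graph"), inherits(params, "thermal_params"))
  sys <- flow$system
  nt <- sys$n_tissue
  ne <- nrow(graph$elements)
  ndim <- nt + ne
  V <- grid$voxel_volume
  rho_b <- params$rho_b; c_pb <- params$c_pb

  I <- integer(0); J <- integer(0); X <- numeric(0)
  add <- function(i, j, x) { I <<- c(I, i); J <<- c(J, j); X <<- c(X, x) }
  b <- numeric(ndim)

  # conduction between tissue voxels
  fi <- interior_faces(grid)$interior
  ti <- sys$tv[fi$i]; tj <- sys$tv[fi$j]
  tt <- ti > 0 & tj > 0
  UA <- overall_U("tissue", fi$dist[tt], params$K_t) * fi$area[tt]
  add(c(ti[tt], ti[tt], tj[tt], tj[tt]), c(ti[tt], tj[tt], tj[tt], ti[tt]),
      c(UA, -UA, UA, -UA))

  # ambient Robin faces
  am <- graph$ambient
  if (nrow(am)) {
    # unknowns are offsets theta = T - T_inf, so the ambient rhs vanishes
    UAa <- overall_U("air", am$dist, params$K_t, params$h_inf) * am$area
    add(am$voxel, am$voxel, UAa)
  }

  # tissue-vessel contact faces, same coefficient both sides
  ct <- graph$contact
  pin <- logical(ne); pin[graph$pinned_arterial] <- TRUE
  if (nrow(ct)) {
    UAb <- overall_U("vessel", ct$dist, params$K_t, params$h_b) * ct$area
    add(ct$voxel, ct$voxel, UAb)
    add(ct$voxel, nt + ct$element, -UAb)
    unp <- !pin[ct$element]
    add(nt + ct$element[unp], nt + ct$element[unp], UAb[unp])
    add(nt + ct$element[unp], ct$voxel[unp], -UAb[unp])
  }

  # donor-cell advection: voxel <- voxel
  vin <- graph$voxel_inflows
  if (nrow(vin)) {
    mc <- rho_b * vin$rate * c_pb
    add(vin$receiver, vin$receiver, mc)
    add(vin$receiver, vin$source, -mc)
  }
  # voxel <- supplying terminal element
  vs <- graph$voxel_sources
  if (nrow(vs)) {
    mc <- rho_b * vs$rate * c_pb
    add(vs$voxel, vs$voxel, mc)
    add(vs$voxel, nt + vs$element, -mc)
  }
  # element <- element, element <- collecting voxels
  tr <- graph$elem_transfers
  if (nrow(tr)) {
    unp <- !pin[tr$receiver]
    mc <- rho_b * tr$rate[unp] * c_pb
    add(nt + tr$receiver[unp], nt + tr$receiver[unp], mc)
    add(nt + tr$receiver[unp], nt + tr$source[unp], -mc)
  }
  ei <- graph$elem_voxel_inflows
  if (nrow(ei)) {
    unp <- !pin[ei$element]
    mc <- rho_b * ei$rate[unp] * c_pb
    add(nt + ei$element[unp], nt + ei$element[unp], mc)
    add(nt + ei$element[unp], ei$voxel[unp], -mc)
  }

  # metabolic generation
  if (params$qdot_m > 0) b[seq_len(nt)] <- b[seq_len(nt)] + params$qdot_m * V

  # Dirichlet at arterial root elements (offset form)
  for (e in graph$pinned_arterial) {
    add(nt + e, nt + e, 1)
    b[nt + e] <- params$T_in - params$T_inf
  }

  A <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(ndim, ndim))
  dg <- Matrix::diag(A)
  if (any(dg == 0)) {
    bad <- which(dg == 0)
    lab <- ifelse(bad <= nt, paste0("tissue voxel ", bad),
                  paste0("element ", bad - nt))
    stop("isolated thermal unknown(s) (zero row): ", paste(lab, collapse = ", "))
  }
  structure(list(A = A, b = b, grid = grid, graph = graph, params = params,
                 n_tissue = nt, n_elements = ne, tissue = sys$tissue,
                 tv = sys$tv),
            class = "heat_system")
}

#' @export
print.heat_system <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf("heat_system: m = %d unknowns (%d tissue voxels + %d vessel elements)\n",
              n, x$n_tissue, x$n_elements))
  cat(sprintf("  sparsity %.4f%%\n", 100 * (1 - length(x$A@x) / (as.numeric(n)^2))))
  invisible(x)
}

#' Solve the thermal system
#'
#' @param system a `heat_system`.
#' @param method,tol,... passed to \code{\link{solve_linear}}.
#' @return object of class `thermal_solution`: `T_t` (degC per tissue
#'   voxel), `T_elem` (degC per vessel element, named by tree/element id),
#'   `energy_residual` (max |Ax - b| in watts: the discrepancy in energy
#'   conservation of the converged solution), and solver info.
#' @export
solve_heat <- function(system, method = "auto", tol = 1e-8, ...) {
  stopifnot(inherits(system, "heat_system"))
  sol <- solve_linear(system$A, system$b, method = method, tol = tol, ...)
  nt <- system$n_tissue
  # the system is assembled in offsets theta = T - T_inf
  T_t <- sol$x[seq_len(nt)] + system$params$T_inf
  T_elem <- sol$x[nt + seq_len(system$n_elements)] + system$params$T_inf
  names(T_elem) <- paste(system$graph$elements$tree, system$graph$elements$id,
                         sep = ":")
  structure(list(T_t = T_t, T_elem = T_elem,
                 energy_residual = sol$max_abs_residual,
                 residual_norm = sol$relres,
                 solver = sol[c("method", "iterations", "converged")],
                 system = system),
            class = "thermal_solution")
}

#' @export
print.thermal_solution <- function(x, ...) {
  cat(sprintf("thermal_solution (%s): %d tissue voxels + %d elements\n",
              x$solver$method, length(x$T_t), length(x$T_elem)))
  cat(sprintf("  tissue %.2f .. %.2f degC; elements %.2f .. %.2f degC\n",
              min(x$T_t), max(x$T_t), min(x$T_elem), max(x$T_elem)))
  cat(sprintf("  energy conservation residual %.3e W\n", x$energy_residual))
  invisible(x)
}

#' Full-grid temperature field
#'
#' Broadcasts element temperatures to their member voxels and fills tissue
#' voxel temperatures; exterior/air voxels are NA.
#'
#' @param solution a `thermal_solution`.
#' @return numeric 3-D array matching the grid shape (degC).
#' @export
temperature_field <- function(solution) {
  sys <- solution$system
  out <- array(NA_real_, sys$grid$shape)
  out[sys$tissue] <- solution$T_t
  own <- sys$graph$owner
  vess <- which(own != 0L)
  out[vess] <- solution$T_elem[own[vess]]
  out
}

#' Energy balance audit of a thermal solution
#'
#' Totals the advective enthalpy entering at arterial roots, leaving at
#' venous roots, wall convection from the pinned root elements, ambient
#' exchange and metabolic generation (enthalpies measured as offsets from
#' the ambient temperature) and reports the net closure.
#'
#' @param solution a `thermal_solution`.
#' @return list of totals (W) with `closure` and `rel_closure` (closure
#'   relative to gross input).
#' @export
energy_balance_report <- function(solution) {
  stopifnot(inherits(solution, "thermal_solution"))
  sys <- solution$system
  g <- sys$graph
  p <- sys$params
  flow <- g$flow
  fsys <- flow$system
  rho_b <- p$rho_b; c_pb <- p$c_pb
  m_in <- rho_b * sum(root_flows(fsys$arterial_tree, flow$p_arterial, fsys$kappa_a))
  adv_in <- m_in * c_pb * (p$T_in - p$T_inf)
  adv_out <- sum(rho_b * g$outlets$q * c_pb *
                   (solution$T_elem[g$outlets$element] - p$T_inf))
  am <- g$ambient
  amb_loss <- if (nrow(am))
    sum(overall_U("air", am$dist, p$K_t, p$h_inf) * am$area *
          (solution$T_t[am$voxel] - p$T_inf)) else 0
  ct <- g$contact
  pin <- ct$element %in% g$pinned_arterial
  root_conv <- if (any(pin))
    sum(overall_U("vessel", ct$dist[pin], p$K_t, p$h_b) * ct$area[pin] *
          (p$T_in - solution$T_t[ct$voxel[pin]])) else 0
  metabolic <- p$qdot_m * sys$grid$voxel_volume * sys$n_tissue
  closure <- adv_in + root_conv + metabolic - adv_out - amb_loss
  gross <- abs(adv_in) + abs(metabolic) + max(root_conv, 0)
  list(advective_in = adv_in, advective_out = adv_out,
       root_convection = root_conv, ambient_loss = amb_loss,
       metabolic = metabolic, closure = closure,
       rel_closure = if (gross > 0) abs(closure) / gross else abs(closure))
}
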