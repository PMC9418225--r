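test_that("TPFA transmissibility evaluates the harmonic-mean formula", {
  A <- 64e-6 * 333e-6; d <- 64e-6; mu <- 3e-3; k <- 1e-12
  expect_equal(tpfa_transmissibility(A, d, k, k, mu), k * A / (mu * d),
               tolerance = 1e-14)
  # unequal sides: harmonic mean, symmetric
  t12 <- tpfa_transmissibility(A, d, 1e-12, 5e-10, mu)
  hm <- 2 * 1e-12 * 5e-10 / (1e-12 + 5e-10)
  expect_equal(t12, A * hm / (mu * d))
  expect_equal(t12, tpfa_transmissibility(A, d, 5e-10, 1e-12, mu))
  # sealed limit
  expect_identical(tpfa_transmissibility(A, d, 0, 1e-12, mu), 0)
})

test_that("perfusion flux is signed and proportional", {
  expect_equal(perfusion_flux(9600, 1600, 1e-6), 8e-3)
  expect_identical(perfusion_flux(5000, 5000, 1e-6), 0)
  expect_equal(perfusion_flux(1600, 9600, 1e-6), -8e-3)
})

test_that("Darcy slab reproduces the linear profile and closed-form flux", {
  for (n in c(3, 7, 20)) {
    sl <- make_darcy_slab(n)
    sol <- solve_darcy(sl$grid, 1e-12, 3e-3, sl$fixed)
    expect_equal(sol$P, sl$exact$P, tolerance = 1e-12)
    expect_equal(sol$face_flux$flux, rep(sl$exact$flux, n - 1),
                 tolerance = 1e-12)
  }
  # zero pressure difference: zero flux
  sl0 <- make_darcy_slab(5, P_left = 5e3, P_right = 5e3)
  s0 <- solve_darcy(sl0$grid, 1e-12, 3e-3, sl0$fixed)
  expect_equal(max(abs(s0$face_flux$flux)), 0, tolerance = 1e-20)
})

test_that("assembled flow system is invariant to a uniform pressure shift", {
  run <- toy_run()
  sys <- run$flow_system
  n <- nrow(sys$A)
  shift <- numeric(n)
  shift[seq_len(sys$off_s)] <- 1   # all pressure unknowns; terminal flows 0
  r <- as.numeric(sys$A %*% shift)
  # Dirichlet rows see the shift; every conservation and continuity row is
  # exactly invariant (row coefficient sums over pressures are zero)
  art_roots <- sys$off_na + match(sys$arterial_tree$roots, sys$arterial_tree$nodes$id)
  ven_roots <- sys$off_nv + match(sys$venous_tree$roots, sys$venous_tree$nodes$id)
  dirichlet <- c(art_roots, ven_roots)
  expect_equal(r[dirichlet], rep(1, length(dirichlet)))
  expect_lt(max(abs(r[-dirichlet])), 1e-12)
})

test_that("the single artery-voxel-vein chain matches the series closed form", {
  pr <- chain_problem()
  run <- chain_run()
  expect_equal(run$flow$q_arterial[[1]], pr$exact_flow, tolerance = 1e-6)
  # one continuous stream: artery flow = perfusion rate = vein flow
  V <- pr$grid$voxel_volume
  expect_equal(run$flow$u_perf * V, unname(run$flow$q_arterial[1]),
               tolerance = 1e-6)
  expect_equal(abs(run$flow$q_venous[[1]]), run$flow$q_arterial[[1]],
               tolerance = 1e-9)
  # swapping the arterial and venous virtual/porous roles preserves the
  # total flow (the series formula is symmetric)
  pr2 <- make_single_vessel_slab(nx = 1,
                                 params = flow_params(k_a = 5e-10, k_v = 1e-12))
  run2 <- run_simulation(pr2, quiet = TRUE)
  expect_equal(run2$flow$q_arterial[[1]], run$flow$q_arterial[[1]],
               tolerance = 1e-6)
})

test_that("a hand-assembled dense oracle reproduces the 3-voxel chain", {
  # independent assembly of the same physics for nx = 3, n_elem = 1:
  # unknowns [Pa1 Pa2 Pa3 Pv1 Pv2 Pv3 pa_r pa_t pv_r pv_t qa qv]
  pr <- make_single_vessel_slab(nx = 3, n_elem = 1)
  p <- pr$flow
  g <- pr$grid
  cp <- suppressWarnings(build_coupling_map(g, pr$arterial_tree,
                                            pr$venous_tree, pr$epsilon))
  art_k <- which(cp$terminals$tree == "artery")
  ven_k <- which(cp$terminals$tree == "vein")
  tis <- which(g$labels == MATERIALS[["TISSUE"]])
  wa <- cp$weights[[art_k]]; wa <- wa$w[order(match(wa$voxel, tis))]
  wv <- cp$weights[[ven_k]]; wv <- wv$w[order(match(wv$voxel, tis))]
  V <- g$voxel_volume
  aV <- p$alpha * V
  # x-direction tissue faces (layer 2): area dy*dz, distance dx
  tface <- function(k) k * (g$spacing[2] * g$spacing[3]) / (p$mu * g$spacing[1])
  ta <- tface(p$k_a); tv <- tface(p$k_v)
  kap_a <- element_conductance(pr$arterial_tree$elements$radius,
                               pr$arterial_tree$elements$length, p$mu)
  kap_v <- element_conductance(pr$venous_tree$elements$radius,
                               pr$venous_tree$elements$length, p$mu)
  A <- matrix(0, 12, 12); b <- numeric(12)
  lap <- function(rows, t) {
    M <- matrix(0, 3, 3)
    M[1, 1:2] <- c(t, -t); M[3, 2:3] <- c(-t, t)
    M[2, ] <- c(-t, 2 * t, -t)
    M
  }
  A[1:3, 1:3] <- lap(1:3, ta) + diag(aV, 3)
  A[1:3, 4:6] <- -diag(aV, 3)
  A[1:3, 11] <- -wa
  A[4:6, 4:6] <- lap(1:3, tv) + diag(aV, 3)
  A[4:6, 1:3] <- -diag(aV, 3)
  A[4:6, 12] <- -wv
  A[7, 7] <- 1; b[7] <- p$P_in                  # arterial root Dirichlet
  A[8, 7:8] <- c(-kap_a, kap_a); A[8, 11] <- 1  # arterial terminal balance
  A[9, 9] <- 1; b[9] <- p$P_out                 # venous root Dirichlet
  A[10, 9:10] <- c(-kap_v, kap_v); A[10, 12] <- 1
  A[11, 11] <- p$mu / p$gamma_a; A[11, 8] <- -1; A[11, 1:3] <- wa
  A[12, 12] <- p$mu / p$gamma_v; A[12, 10] <- -1; A[12, 4:6] <- wv
  x <- solve(A, b)

  run <- run_simulation(pr, coupling = cp, quiet = TRUE)
  expect_equal(run$flow$P_a, x[1:3], tolerance = 1e-8)
  expect_equal(run$flow$P_v, x[4:6], tolerance = 1e-8)
  expect_equal(unname(run$flow$q_arterial[1]), kap_a * (x[7] - x[8]),
               tolerance = 1e-6)
})

test_that("equal boundary pressures give a quiescent equilibrium", {
  pr <- make_single_vessel_slab(nx = 4, n_elem = 2,
                                params = flow_params(P_in = 5000, P_out = 5000))
  run <- run_simulation(pr, quiet = TRUE)
  expect_equal(max(abs(c(run$flow$P_a, run$flow$P_v) - 5000)), 0,
               tolerance = 1e-9)
  expect_lt(max(abs(c(run$flow$q_arterial, run$flow$q_venous))), 1e-20)
})

test_that("raising the perfusion coefficient raises the total perfused flow", {
  pr <- toy_problem()
  base <- toy_run()
  pr2 <- pr; pr2$flow$alpha <- pr$flow$alpha * 1.5
  run2 <- run_simulation(pr2, coupling = base$coupling, quiet = TRUE)
  q1 <- sum(hemotherm:::root_flows(pr$arterial_tree, base$flow$p_arterial,
                                   base$flow_system$kappa_a))
  q2 <- sum(hemotherm:::root_flows(pr$arterial_tree, run2$flow$p_arterial,
                                   run2$flow_system$kappa_a))
  expect_gt(q2, q1)
})

test_that("mass balance closes per terminal, per voxel and globally", {
  run <- toy_run()
  rep <- mass_balance_report(run$flow)
  inflow <- rep$global$inflow
  expect_gt(inflow, 0)
  expect_lt(rep$global$rel_mismatch, 1e-6)
  expect_lt(max(rep$terminal$imbalance) / inflow, 1e-6)
  expect_lt(max(abs(rep$voxel_divergence)) / inflow, 1e-6)
  # source/sink fields integrate to the global inflow
  expect_equal(sum(run$flow$Q_a), inflow, tolerance = 1e-6)
  expect_equal(sum(run$flow$Q_v), inflow, tolerance = 1e-6)
})

test_that("coupling maps missing a terminal are rejected at assembly", {
  pr <- chain_problem()
  cp <- suppressWarnings(build_coupling_map(pr$grid, pr$arterial_tree,
                                            pr$venous_tree, pr$epsilon))
  cp_broken <- cp
  cp_broken$terminals <- cp$terminals[cp$terminals$tree == "artery", ]
  cp_broken$weights <- cp$weights[1]
  expect_error(assemble_flow_system(pr$grid, pr$arterial_tree, pr$venous_tree,
                                    cp_broken, pr$flow),
               "misses")
})
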