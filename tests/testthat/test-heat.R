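test_that("overall face coefficients follow the series-resistance forms", {
  expect_equal(overall_U("tissue", 64e-6, 0.49), 7656.25)
  expect_equal(overall_U("air", 64e-6, 0.49, 20),
               1 / (64e-6 / (2 * 0.49) + 1 / 20), tolerance = 1e-12)
  expect_equal(overall_U("air", 64e-6, 0.49, 20), 19.9739, tolerance = 1e-4)
  # infinite film coefficient recovers the half-cell conduction limit
  expect_equal(overall_U("vessel", 64e-6, 0.49, 1e14), 2 * 0.49 / 64e-6,
               tolerance = 1e-6)
  # h = 0 seals the face, not an error
  expect_identical(overall_U("air", 64e-6, 0.49, 0), 0)
  expect_error(overall_U("tissue", -1, 0.49), "ds")
})

test_that("1-D conduction coefficients solve a slab exactly (independent oracle)", {
  # tridiagonal conduction chain with Robin ends, assembled two ways:
  # from the package's face/U primitives and directly from the analytic
  # resistance network; both must give the same interior temperatures
  n <- 6; K <- 0.49; h <- 20; Tl <- 10; Tr <- 40
  g <- all_tissue_grid(c(1, 1, n))
  f <- interior_faces(g)
  ds <- g$spacing[3]; A_f <- g$spacing[1] * g$spacing[2]
  U_i <- overall_U("tissue", ds, K)
  U_r <- overall_U("air", ds, K, h)
  M <- matrix(0, n, n); b <- numeric(n)
  for (r in seq_len(nrow(f$interior))) {
    a <- arrayInd(f$interior$i[r], g$shape)[3]
    bb <- arrayInd(f$interior$j[r], g$shape)[3]
    M[a, a] <- M[a, a] + U_i * A_f; M[a, bb] <- M[a, bb] - U_i * A_f
    M[bb, bb] <- M[bb, bb] + U_i * A_f; M[bb, a] <- M[bb, a] - U_i * A_f
  }
  M[1, 1] <- M[1, 1] + U_r * A_f; b[1] <- U_r * A_f * Tl
  M[n, n] <- M[n, n] + U_r * A_f; b[n] <- U_r * A_f * Tr
  Tsol <- solve(M, b)
  # analytic series network: total resistance = 2/(h A) + ... per-cell,
  # temperature at cell centers linear between the wall temperatures
  Rh <- 1 / (U_r * A_f); Rc <- 1 / (U_i * A_f)
  q <- (Tr - Tl) / (2 * Rh + (n - 1) * Rc)
  T_exact <- Tl + q * (Rh + (seq_len(n) - 1) * Rc)
  expect_equal(Tsol, T_exact, tolerance = 1e-12)
  expect_true(all(diff(Tsol) > 0))
})

test_that("advection graph resolves donors and closes voxel mass budgets", {
  run <- toy_run()
  g <- build_advection_graph(run$flow)
  expect_true(all(g$voxel_inflows$rate >= 0))
  expect_true(all(g$voxel_sources$rate >= 0))
  expect_true(all(g$elem_voxel_inflows$rate >= 0))
  expect_true(all(g$elem_transfers$rate >= 0))
  # per-voxel closure against the flow residuals, relative to gross inflow
  expect_lt(max(abs(g$closure)) / g$gross_inflow, 1e-10)
  # inter-voxel rates equal the TPFA face flows of the solution
  sys <- run$flow_system
  f <- sys$t_a * (run$flow$P_a[sys$tv[sys$faces$i]] - run$flow$P_a[sys$tv[sys$faces$j]]) +
    sys$t_v * (run$flow$P_v[sys$tv[sys$faces$i]] - run$flow$P_v[sys$tv[sys$faces$j]])
  expect_equal(sort(g$voxel_inflows$rate), sort(abs(f[f != 0])))
})

test_that("a zero-flow solution yields an empty advection graph", {
  pr <- make_single_vessel_slab(nx = 2, params = flow_params(P_in = 0, P_out = 0))
  run <- run_simulation(pr, quiet = TRUE)
  g <- run$graph
  expect_identical(nrow(g$voxel_inflows), 0L)
  expect_identical(nrow(g$voxel_sources), 0L)
  expect_identical(nrow(g$elem_transfers), 0L)
})

test_that("element ownership of vessel voxels is validated", {
  pr <- chain_problem()
  bad <- pr
  bad$arterial_tree$elements$member_voxels[[1]] <- integer(0)
  expect_error(run_simulation(bad, quiet = TRUE), "not owned by any element")
})

test_that("equilibrium: inlet at ambient gives a uniform field", {
  pr <- toy_problem()
  pr$thermal$T_in <- pr$thermal$T_inf
  run <- run_simulation(pr, quiet = TRUE)
  expect_equal(max(abs(run$heat$T_t - pr$thermal$T_inf)), 0, tolerance = 1e-9)
  expect_equal(max(abs(run$heat$T_elem - pr$thermal$T_inf)), 0, tolerance = 1e-9)
})

test_that("temperature offsets scale exactly with the inlet offset", {
  pr <- toy_problem()
  base <- toy_run()
  pr2 <- pr
  pr2$thermal$T_in <- pr$thermal$T_inf + 2 * (pr$thermal$T_in - pr$thermal$T_inf)
  run2 <- run_simulation(pr2, coupling = base$coupling, flow = base$flow,
                         quiet = TRUE)
  th1 <- base$heat$T_t - pr$thermal$T_inf
  th2 <- run2$heat$T_t - pr$thermal$T_inf
  expect_equal(th2, 2 * th1, tolerance = 1e-10)
})

test_that("with negligible wall exchange the arterial tree is isothermal at T_in", {
  pr <- slab_problem()           # 4 arterial elements in series
  pr$thermal <- thermal_params(mode = "pbm")
  run <- run_simulation(pr, quiet = TRUE)
  art <- grepl("^artery", names(run$heat$T_elem))
  expect_lt(max(abs(run$heat$T_elem[art] - pr$thermal$T_in)), 0.01)
})

test_that("with significant wall exchange arterial temperature falls downstream", {
  pr <- slab_problem()
  pr$thermal <- thermal_params(mode = "wjm")
  run <- run_simulation(pr, quiet = TRUE)
  art <- run$heat$T_elem[grepl("^artery", names(run$heat$T_elem))]
  # elements are ordered root -> terminal in this fixture
  expect_true(all(diff(unname(art)) <= 1e-12))
  expect_lt(unname(art[length(art)]), pr$thermal$T_in)
})

test_that("raising the inlet temperature never lowers any temperature", {
  base <- toy_run()
  pr2 <- toy_problem()
  pr2$thermal$T_in <- pr2$thermal$T_in + 3
  run2 <- run_simulation(pr2, coupling = base$coupling, flow = base$flow,
                         quiet = TRUE)
  expect_true(all(run2$heat$T_t - base$heat$T_t >= -1e-10))
  expect_true(all(run2$heat$T_elem - base$heat$T_elem >= -1e-10))
})

test_that("temperatures respect the inlet/ambient bounds without generation", {
  run <- toy_run()
  p <- toy_problem()$thermal
  lo <- min(p$T_in, p$T_inf) - 1e-9
  hi <- max(p$T_in, p$T_inf) + 1e-9
  expect_true(all(run$heat$T_t >= lo & run$heat$T_t <= hi))
  expect_true(all(run$heat$T_elem >= lo & run$heat$T_elem <= hi))
})

test_that("steady-state energy budget closes", {
  run <- toy_run()
  eb <- energy_balance_report(run$heat)
  expect_lt(eb$rel_closure, 1e-6)
  expect_gt(eb$advective_in, 0)
  # the solver's conservation metric (max |residual| in watts) is tiny
  expect_lt(run$heat$energy_residual, 1e-10)
})

test_that("wall exchange warms the venous outlet relative to the no-exchange case", {
  # counter-current slab: tissue near the arterial inlet is warmest, so
  # finite wall convection returns warmer blood at the venous outlet
  pbm <- slab_problem(); pbm$thermal <- thermal_params(mode = "pbm")
  wjm <- slab_problem(); wjm$thermal <- thermal_params(mode = "wjm")
  r1 <- run_simulation(pbm, quiet = TRUE)
  r2 <- run_simulation(wjm, quiet = TRUE)
  out1 <- energy_balance_report(r1$heat)$advective_out
  out2 <- energy_balance_report(r2$heat)$advective_out
  expect_gte(out2, out1)
})

test_that("temperature_field broadcasts element temperatures to member voxels", {
  run <- chain_run()
  arr <- temperature_field(run$heat)
  pr <- chain_problem()
  expect_identical(dim(arr), pr$grid$shape)
  own <- run$graph$owner
  v <- which(own != 0L)
  expect_equal(arr[v], unname(run$heat$T_elem[own[v]]))
  expect_false(anyNA(arr[pr$grid$labels != MATERIALS[["EXTERIOR"]]]))
})

test_that("isolated thermal unknowns are reported at assembly", {
  # sealed walls and no flow leave the venous element with an empty row
  pr <- make_single_vessel_slab(nx = 2,
                                params = flow_params(P_in = 0, P_out = 0))
  pr$thermal <- thermal_params(h_b = 0, h_inf = 0)
  expect_error(run_simulation(pr, quiet = TRUE), "isolated thermal unknown")
})
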