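test_that("mollifier density has the compact-support bump shape", {
  m <- mollifier(epsilon = 1e-3, C = 2)
  # exactly zero at and beyond the support boundary
  expect_identical(mollifier_value(c(1e-3, 0, 0), m), 0)
  expect_identical(mollifier_value(c(2e-3, 0, 0), m), 0)
  # value at the center is (C / eps^n) * exp(-1)
  expect_equal(mollifier_value(c(0, 0, 0), m), 2 / (1e-3)^3 * exp(-1))
  # ratio at half radius: exp(1/(0.25 - 1) + 1) = exp(-1/3)
  r_half <- mollifier_value(c(0.5e-3, 0, 0), m) / mollifier_value(c(0, 0, 0), m)
  expect_equal(r_half, exp(-1 / 3), tolerance = 1e-14)
  # radially symmetric and strictly decreasing in |r|
  d <- seq(0, 0.999e-3, length.out = 50)
  vals <- mollifier_value(cbind(d, 0, 0), m)
  expect_true(all(diff(vals) < 0))
  expect_equal(vals, mollifier_value(cbind(0, d, 0), m))
})

test_that("calibration makes the discrete quadrature exactly one", {
  g <- all_tissue_grid(c(7, 7, 3))
  set.seed(7)
  for (i in 1:20) {
    pos <- c(runif(1, 0, 7 * 64e-6), runif(1, 0, 7 * 64e-6), runif(1, 0, 3 * 333e-6))
    eps <- runif(1, 120e-6, 800e-6)
    cal <- tryCatch(calibrate_constant(g, pos, eps), error = function(e) NULL)
    if (is.null(cal)) next  # empty SoI for a tiny radius: tested below
    expect_equal(sum(cal$voxels$w), 1, tolerance = 1e-12)
    expect_true(all(cal$voxels$w >= 0))
    # every in-SoI voxel lies within distance eps of the terminal
    ctr <- voxel_centers(g, cal$voxels$voxel)
    expect_true(all(sqrt(colSums((t(ctr) - pos)^2)) < eps))
  }
})

test_that("a SoI holding one voxel gives that voxel weight one", {
  g <- all_tissue_grid(c(3, 3, 1))
  pos <- voxel_centers(g, 5)  # center voxel
  cal <- calibrate_constant(g, pos, epsilon = 30e-6)  # under half a spacing
  expect_identical(cal$voxels$voxel, 5L)
  expect_identical(cal$voxels$w, 1)
})

test_that("an empty sphere of influence is a coupling error naming the spot", {
  g <- all_tissue_grid(c(3, 3, 1))
  expect_error(calibrate_constant(g, c(-1, -1, -1), epsilon = 1e-5),
               "empty sphere of influence")
})

test_that("halving voxel volume at fixed center distances doubles C", {
  # terminal at the center of voxel 1 of a 1x1xn slab: distances to the
  # other voxel centers depend only on the z spacing, so halving dx halves
  # the voxel volume without moving anything
  mk <- function(dx) all_tissue_grid(c(1, 1, 5), spacing = c(dx, 64e-6, 333e-6))
  g1 <- mk(64e-6); g2 <- mk(32e-6)
  c1 <- calibrate_constant(g1, voxel_centers(g1, 1), 1e-3)
  c2 <- calibrate_constant(g2, voxel_centers(g2, 1), 1e-3)
  expect_equal(c2$C / c1$C, 2, tolerance = 1e-12)
  expect_equal(c1$voxels$w, c2$voxels$w, tolerance = 1e-12)
})

test_that("translation invariance: shifting the terminal by whole voxels", {
  # SoI fully interior at both positions, so the relative geometry (and
  # hence the weights) is unchanged by a whole-voxel shift
  g <- all_tissue_grid(c(9, 9, 1))
  p1 <- voxel_centers(g, which(array(seq_len(81), c(9, 9, 1)) == 31))  # (4,4)
  p2 <- p1 + c(2 * 64e-6, 64e-6, 0)
  base <- calibrate_constant(g, p1, 150e-6)
  shifted <- calibrate_constant(g, p2, 150e-6)
  expect_equal(sort(base$voxels$w), sort(shifted$voxels$w), tolerance = 1e-12)
  expect_equal(base$C, shifted$C, tolerance = 1e-12)
})

test_that("coupling maps cover tissue, exclude vessels, and warn on gaps", {
  pr <- toy_problem()
  cp <- suppressWarnings(build_coupling_map(pr$grid, pr$arterial_tree,
                                            pr$venous_tree, pr$epsilon))
  expect_identical(unname(cp$coverage), c(1, 1))
  tissue <- which(pr$grid$labels == MATERIALS[["TISSUE"]])
  for (w in cp$weights) {
    expect_equal(sum(w$w), 1, tolerance = 1e-12)
    expect_true(all(w$voxel %in% tissue))   # never vessel or air voxels
  }
  # weight monotonicity: non-increasing with center distance
  for (k in seq_len(nrow(cp$terminals))) {
    w <- cp$weights[[k]]
    pos <- unlist(cp$terminals[k, c("x", "y", "z")])
    d <- sqrt(colSums((t(voxel_centers(pr$grid, w$voxel)) - pos)^2))
    o <- order(d)
    expect_true(all(diff(w$w[o]) <= 1e-15))
  }
  # a tiny epsilon yields incomplete coverage and a warning
  expect_warning(build_coupling_map(pr$grid, pr$arterial_tree, pr$venous_tree,
                                    epsilon = 1.01 * 64e-6),
                 "coverage")
})

test_that("1x1x3 grid with one distant terminal: weights decrease with distance", {
  g <- all_tissue_grid(c(1, 1, 3))
  # terminal at the center of the first voxel, SoI spanning the grid
  trees <- point_trees(voxel_centers(g, 1), voxel_centers(g, 3), reach = 1e-3)
  # vein terminal placed at the last voxel; only check the arterial weights
  cp <- suppressWarnings(build_coupling_map(g, trees$artery, trees$vein, 2e-3))
  wa <- cp$weights[[which(cp$terminals$tree == "artery")]]
  expect_identical(nrow(wa), 3L)
  expect_equal(sum(wa$w), 1, tolerance = 1e-12)
  expect_true(all(diff(wa$w[order(wa$voxel)]) < 0))  # decreasing away from voxel 1
})

test_that("coupling map JSON round-trips", {
  pr <- chain_problem()
  cp <- suppressWarnings(build_coupling_map(pr$grid, pr$arterial_tree,
                                            pr$venous_tree, pr$epsilon))
  f <- withr::local_tempfile(fileext = ".json")
  write_coupling_map(cp, f)
  cp2 <- read_coupling_map(f)
  expect_equal(cp2$epsilon, cp$epsilon)
  expect_equal(length(cp2$weights), length(cp$weights))
  for (k in seq_along(cp$weights))
    expect_equal(cp2$weights[[k]]$w, cp$weights[[k]]$w)
})
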