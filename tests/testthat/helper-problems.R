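# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(.cache[[key]])) .cache[[key]] <- build()
  .cache[[key]]
}

toy_problem <- function() cached("toy_problem", function()
  make_three_layer_toy(nx = 16, ny = 16, tree_levels = 2, seed = 1))

toy_run <- function() cached("toy_run", function()
  run_simulation(toy_problem(), quiet = TRUE))

chain_problem <- function() cached("chain", function()
  make_single_vessel_slab(nx = 1))

chain_run <- function() cached("chain_run", function()
  run_simulation(chain_problem(), quiet = TRUE))

# a straight multi-element artery/vein slab used for along-flow checks
slab_problem <- function() cached("slab", function()
  make_single_vessel_slab(nx = 8, n_elem = 4))

# minimal single-terminal trees for coupling tests: a one-element artery
# and vein whose terminals sit at given positions
point_trees <- function(a_pos, v_pos, radius = 1e-4, reach = 1e-3) {
  mk <- function(kind, pos) {
    nodes <- data.frame(id = c("r", "t"),
                        x = c(pos[1] - reach, pos[1]),
                        y = c(pos[2], pos[2]), z = c(pos[3], pos[3]),
                        root = c(TRUE, FALSE))
    elements <- data.frame(id = "e1", node_j = "r", node_i = "t",
                           radius = radius)
    vessel_tree(nodes, elements, kind = kind)
  }
  list(artery = mk("artery", a_pos), vein = mk("vein", v_pos))
}

all_tissue_grid <- function(shape, spacing = c(64e-6, 64e-6, 333e-6))
  voxel_grid(array(MATERIALS[["TISSUE"]], shape), spacing)
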