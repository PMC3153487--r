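# Shared fixtures: default parameters and small geometries for fast runs.

test_params <- function(...) kinetic_params(...)

small_clump <- function(n_cells = 30, nodes = 80, params = test_params()) {
  build_geometry("clump", n_cells = n_cells, params = params,
                 grid_nodes = nodes)
}

small_isolated <- function(nodes = 80, params = test_params()) {
  build_geometry("isolated", params = params, grid_nodes = nodes)
}

# conversion constant used in tests, derived independently of the package
MOLEC_PER_UM3_PER_MM <- 6.02214076e23 / 1e15 / 1e3

runif_seeded <- function(n, min = 0, max = 1, seed = 1) {
  set.seed(seed)
  runif(n, min, max)
}
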