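# Shared fixtures built in code.

pair_A <- training_pair("A")
class_A <- classify_pixels(pair_A)

# the training pair presented as its own test pair
self_test <- function(id = 1L) test_case(pair_A$grid_Z, pair_A$grid_H, id)

# an ad-hoc training pair from two grids (for classification edge cases)
custom_pair <- function(grid_Z, grid_H, variant = "A") {
  structure(list(variant = variant, positive_style = "Z",
                 grid_Z = as_pixel_grid(grid_Z),
                 grid_H = as_pixel_grid(grid_H)),
            class = "training_pair")
}

# small deterministic synthetic suite + per-test scores
small_sim <- function(seed = 11L, n_tests = 24L) {
  cfg <- sim_config(n_tests = n_tests, n_repeat_pairs = 4L,
                    n_triple_pairs = 1L, seed = seed)
  simulate_experiment(cfg)
}

# random grid with each location lit independently
random_grid <- function(p = 0.4) {
  pixel_grid(all_locations()[stats::runif(35) < p])
}
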