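## small seeded fixtures shared across test files

tiny_cluster <- function(m = 2, rho = 0.5, n = 120, sigma_e = 5, seed = 7) {
  sim_cluster(cluster_design(m = m, rho = rho, sigma_e = sigma_e, n = n, seed = seed))
}

## lean lasso controls so pipeline tests stay fast
fast_vim <- function(data, ...) {
  tmle_vim(data, folds = 3, nlambda = 20, lambda_min_ratio = 0.05, ...)
}

derive_seed_oracle <- function(...) tmlevim:::derive_seed(...)
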