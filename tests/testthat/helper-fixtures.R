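# shared fixtures: parameter records at the packaged reference estimates
# and small builders used across test files

ref_monod <- function() monod_params(mu_max = 0.0008 * 37328, K_H = 37328,
                                     Y = 0.0037, k_d = 0.087)
ref_first_order <- function() first_order_params(eta = 0.0008, Y = 0.0037,
                                                 k_d = 0.087)
ref_t1 <- function() t1_params(eta = 0.0008, Y = 0.0014, k_d = 0.014,
                               H_t = 86.2)
ref_t2 <- function() t2_params(eta = 0.0054, Y = 0.0017, k_d = 0.019,
                               A = 0.015, T = 336)
ref_t3 <- function() t3_params(mu_max_H = 0.451, mu_max_R = 0.002,
                               K_H = 295.8, K_R = 4.5, Y = 0.0018,
                               k_d = 0.022)

base_structures <- c("monod", "first_order", "t1", "t2", "t3")

ref_spec <- function(structure) {
  params <- switch(structure,
    monod = ref_monod(), first_order = ref_first_order(),
    t1 = ref_t1(), t2 = ref_t2(), t3 = ref_t3())
  model_spec(structure, params)
}

std_initial <- function() culture_state(H = 400, P = 0, X = 0.01)

# random-but-reproducible valid parameter draw for property tests:
# log-uniform within a decade around the reference estimates
random_spec <- function(structure, seed) {
  fl <- unlist(flatten_params(ref_spec(structure)))
  vals <- acetokin:::with_seed(seed,
    fl * exp(runif(length(fl), -log(3), log(3))))
  acetokin:::spec_from_flat(structure, as.list(vals))
}

# small noiseless dataset generated by a spec itself
noiseless_dataset <- function(spec, initial = std_initial(),
                              times = seq(0, 80, length.out = 8)) {
  scen <- scenario_config(spec, initial, times, noise_cv = 0,
                          n_replicates = 1L, seed = 1L)
  generate_dataset(scen)$dataset
}
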