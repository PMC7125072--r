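#' Synthetic batch-culture scenario configuration
#'
#' Describes how to generate a noisy batch time-course dataset from a
#' known model: the generating [model_spec()], initial state, sampling
#' grid, per-variable multiplicative noise level and replicate count.
#' Every generated dataset ships with its noise-free ground-truth
#' trajectory, enabling exact-recovery tests.
#'
#' @param spec generating [model_spec()]
#' @param initial initial [culture_state()]
#' @param sampling_times strictly increasing observation times, hours
#' @param noise_cv fractional coefficient of variation of the
#'   multiplicative observation noise; scalar or named per-variable
#'   (`H`, `P`, `X`, `E`); `>= 0`
#' @param n_replicates replicates per observation (>= 1)
#' @param seed integer seed
#' @return list of class `scenario_config`
#' @export
scenario_config <- function(spec, initial, sampling_times, noise_cv = 0.1,
                            n_replicates = 3L, seed = 1L) {
  if (!inherits(spec, "model_spec"))
    ak_stop("spec must be a model_spec", "invalid_input")
  if (any(noise_cv < 0))
    ak_stop("noise_cv must be non-negative", "invalid_input")
  if (n_replicates < 1)
    ak_stop("n_replicates must be >= 1", "invalid_input")
  if (length(sampling_times) < 2 || any(diff(sampling_times) <= 0))
    ak_stop("sampling_times must be strictly increasing", "invalid_input")
  structure(list(spec = spec, initial = initial,
                 sampling_times = sampling_times, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a noisy batch time-course dataset
#'
#' Simulates the scenario's ground-truth trajectory, then draws
#' `n_replicates` observations per (time, variable) as
#' `truth * (1 + eps)`, `eps ~ Normal(0, noise_cv)`, truncated at zero
#' (negative concentrations are unobservable).  The dataset rows carry
#' the replicate mean and standard deviation — the same structure as
#' published figure data with error bars from triplicate determinations.
#' Deterministic given the scenario seed.
#'
#' @param cfg a [scenario_config()]
#' @return list with `dataset` (a [ts_dataset()]) and `truth` (the
#'   noise-free trajectory)
#' @examples
#' gen <- generate_dataset(bernalier_like_scenario(seed = 7))
#' head(gen$dataset)
#' @export
generate_dataset <- function(cfg) {
  if (!inherits(cfg, "scenario_config"))
    ak_stop("cfg must be a scenario_config", "invalid_input")
  truth <- simulate_model(cfg$spec, cfg$initial, cfg$sampling_times)
  vars <- colnames(truth$states)
  cv <- cfg$noise_cv
  if (length(cv) == 1L) cv <- setNames(rep(cv, length(vars)), vars)
  rows <- with_seed(cfg$seed, {
    out <- list()
    for (v in vars) {
      for (i in seq_along(cfg$sampling_times)) {
        mu <- truth$states[i, v]
        reps <- pmax(mu * (1 + rnorm(cfg$n_replicates, 0, cv[[v]])), 0)
        out[[length(out) + 1L]] <- data.frame(
          time_h = cfg$sampling_times[i], variable = v,
          value = mean(reps),
          sd = if (cfg$n_replicates > 1L) sd(reps) else NA_real_,
          n = cfg$n_replicates)
      }
    }
    do.call(rbind, out)
  })
  rows <- rows[order(match(rows$variable, vars), rows$time_h), ]
  list(dataset = ts_dataset(rows), truth = truth)
}

#' Packaged calibration-style scenario
#'
#' A batch monoculture scenario with the structure of the classic
#' H2/CO2 serum-bottle experiments used for model calibration: hydrogen
#' starting at a few hundred mM and declining towards the uptake
#' threshold, stoichiometrically coupled acetate rise, and
#' sigmoid-then-declining biomass.  The generating kinetics are the
#' hard-threshold (T1) model at the packaged reference estimates
#' (`eta = 0.0008`, `Y = 0.0014`, `k_d = 0.014`, `H_t = 86.2`).  The
#' initial state (`H = 400` mM, `P = 0`, `X = 0.01` g/L), the 8-point
#' sampling grid over 0-80 h, the 10% noise CV and the 3 replicates are
#' invented defaults emulating the layout of such experiments — they are
#' not a reproduction of any measured dataset.
#'
#' @param seed integer seed for the generated noise
#' @return a [scenario_config()]
#' @export
bernalier_like_scenario <- function(seed = 1L) {
  scenario_config(
    spec = reference_params("t1"),
    initial = culture_state(H = 400, P = 0, X = 0.01),
    sampling_times = seq(0, 80, length.out = 8),
    noise_cv = 0.1, n_replicates = 3L, seed = seed)
}

#' Packaged validation-style scenario with yeast-extract metabolism
#'
#' A scenario emulating growth on a yeast-extract-rich medium (DSMZ
#' style): a T2 or T3 base model extended with the two-substrate
#' yeast-extract pathway at the packaged hypothetical extension values
#' ([dsmz_extension_params()]).  The initial hydrogen of 200 mM
#' corresponds to 0.02 mol H2 dissolved in a 0.1 L medium — the
#' headspace-limited supply of the serum-bottle experiments — so that
#' acetate beyond the 50 mM stoichiometric bound must come from yeast
#' extract.  `E(0)` is a nominal monomer concentration; all
#' non-parameter values are invented defaults.
#'
#' @param base `"t3"` or `"t2"` base structure
#' @param E0 initial yeast-extract concentration, mM
#' @param seed integer seed
#' @return a [scenario_config()]
#' @export
dsmz_like_scenario <- function(base = c("t3", "t2"), E0 = 200, seed = 1L) {
  base <- match.arg(base)
  ext <- dsmz_extension_params(base)
  ref <- reference_params(base)
  fl <- flatten_params(ref)
  fl$k_d <- ext$k_d
  spec <- model_spec(base, spec_from_flat(base, fl)$params,
                     extension = ext$extension)
  scenario_config(
    spec = spec,
    initial = culture_state(H = 200, P = 0, X = 0.01, E = E0),
    sampling_times = seq(0, 100, length.out = 10),
    noise_cv = 0.1, n_replicates = 3L, seed = seed)
}

#' Scenario JSON serialization
#'
#' @param cfg a [scenario_config()]
#' @param path file path
#' @return `read_scenario_json()` returns a [scenario_config()]
#' @export
write_scenario_json <- function(cfg, path) {
  obj <- list(structure = cfg$spec$structure,
              params = flatten_params(cfg$spec),
              initial = unclass(cfg$initial),
              sampling_times = cfg$sampling_times,
              noise_cv = cfg$noise_cv,
              n_replicates = cfg$n_replicates,
              seed = cfg$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- spec_from_flat(obj$structure, as.list(obj$params))
  ini <- obj$initial
  scenario_config(
    spec = spec,
    initial = culture_state(H = ini$H, P = ini$P, X = ini$X, E = ini$E),
    sampling_times = obj$sampling_times,
    noise_cv = if (!is.null(names(obj$noise_cv))) unlist(obj$noise_cv)
               else obj$noise_cv,
    n_replicates = obj$n_replicates, seed = obj$seed)
}
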