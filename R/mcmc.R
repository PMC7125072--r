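#' MCMC fitting configuration
#'
#' Settings for [mcmc_fit()].  Defaults follow common practice for
#' random-walk samplers: 4 chains, 20% burn-in, adaptive proposals frozen
#' at the end of burn-in, split-Rhat convergence threshold 1.05.  The
#' default iteration count (1e6 per chain) matches the full calibration
#' protocol; recovery studies in the test-suite scale this down.
#'
#' @param n_iterations iterations per chain (>= 1); the first sample of a
#'   chain is its starting point, so `n_iterations = 1` returns exactly
#'   the initial sample
#' @param n_chains number of independent chains
#' @param burn_in_fraction fraction of each chain discarded (and used for
#'   proposal adaptation), in `[0, 1)`
#' @param proposal_scale initial random-walk standard deviation on the
#'   log-parameter scale (scalar or per-parameter named vector)
#' @param prior_bounds optional named list of `c(lower, upper)` positive
#'   bounds per free parameter (natural scale); parameters without bounds
#'   default to +/- 3 decades around their starting value
#' @param seed integer seed; the fit is bit-reproducible given the seed
#' @return list of class `fit_config`
#' @export
fit_config <- function(n_iterations = 1e6, n_chains = 4,
                       burn_in_fraction = 0.2, proposal_scale = 0.1,
                       prior_bounds = NULL, seed = 1L) {
  if (n_iterations < 1) ak_stop("n_iterations must be >= 1", "invalid_input")
  if (n_chains < 1) ak_stop("n_chains must be >= 1", "invalid_input")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    ak_stop("burn_in_fraction must be in [0, 1)", "invalid_input")
  if (any(proposal_scale <= 0))
    ak_stop("proposal_scale must be positive", "invalid_input")
  if (!is.null(prior_bounds)) {
    ok <- vapply(prior_bounds, function(b)
      length(b) == 2 && all(is.finite(b)) && b[1] > 0 && b[1] < b[2],
      logical(1))
    if (!all(ok))
      ak_stop("prior_bounds entries must be positive ordered pairs",
              "invalid_input")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 n_chains = as.integer(n_chains),
                 burn_in_fraction = burn_in_fraction,
                 proposal_scale = proposal_scale,
                 prior_bounds = prior_bounds,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Calibrate a model to batch time-course data by MCMC
#'
#' Adaptive random-walk Metropolis sampling of the model parameters
#' against the normalised-least-squares objective of [fit_objective()].
#' Parameters are sampled on the log scale (all are strictly positive)
#' under flat log-priors truncated to `prior_bounds`.  The target density
#' is the Gaussian error model implied by the objective's per-point
#' normalisation with a global variance factor profiled out:
#' `log posterior = -(n_obs / 2) * log(objective)`.  Proposals use a
#' Haario-style running covariance estimate (scaled by `2.38^2 / d`),
#' adapted during burn-in only and frozen afterwards.
#'
#' Initial conditions are taken from the first observation of each
#' variable ([initial_from_data()]) — they are not free parameters.  The
#' point estimate reported as `best_fit` is the sampled parameter vector
#' with minimum objective; the posterior median is also reported
#' (`posterior_median`) since the two can differ and the mode may sit
#' outside the central interval.
#'
#' The non-linearised threshold structures (`"t1_nonlinear"`,
#' `"t2_nonlinear"`) are refused unless `allow_nonidentifiable = TRUE`:
#' their `mu_max`/`K_H` pair cannot be estimated reliably from
#' single-batch data.
#'
#' @param spec a [model_spec()] whose parameter values are the starting
#'   point (and centre of the default prior box)
#' @param data a [ts_dataset()]
#' @param config a [fit_config()]
#' @param initial optional [culture_state()] override for the initial
#'   condition
#' @param fixed character vector of parameter names held fixed at their
#'   `spec` values (e.g. base-model parameters when fitting only the
#'   yeast-extract extension)
#' @param allow_nonidentifiable permit fitting the non-linearised
#'   structures
#' @param rtol,atol integrator tolerances used inside the objective
#' @return object of class `fit_result`: `best_fit` (named vector),
#'   `best_spec`, `posterior_median`, `ci95` (2.5/97.5% central posterior
#'   interval per parameter), `chains` (post-burn-in samples, natural
#'   scale, one matrix per chain), `r_squared` (per variable at the best
#'   fit), `correlation` (Pearson, pooled samples), `rhat` and `converged`
#'   (split-Rhat per parameter), `objective_at_best`, `acceptance_rate`
#' @examples
#' \donttest{
#' scen <- bernalier_like_scenario(seed = 1)
#' gen <- generate_dataset(scen)
#' fit <- mcmc_fit(scen$spec, gen$dataset,
#'                 fit_config(n_iterations = 2000, n_chains = 2, seed = 1))
#' fit
#' }
#' @export
mcmc_fit <- function(spec, data, config = fit_config(), initial = NULL,
                     fixed = character(), allow_nonidentifiable = FALSE,
                     rtol = 1e-8, atol = 1e-10,
                     normalisation = c("sd", "mean", "value")) {
  normalisation <- match.arg(normalisation)
  if (!inherits(spec, "model_spec"))
    ak_stop("spec must be a model_spec", "invalid_input")
  if (!inherits(config, "fit_config"))
    ak_stop("config must be a fit_config", "invalid_input")
  if (spec$structure %in% c("t1_nonlinear", "t2_nonlinear") &&
      !allow_nonidentifiable)
    ak_stop(paste("the non-linearised threshold structures are not identifiable",
                  "from single-batch data; pass allow_nonidentifiable = TRUE",
                  "to fit them anyway"), "invalid_input")
  data <- ts_dataset(as.data.frame(data))
  if (is.null(initial))
    initial <- initial_from_data(data, extended = has_extension(spec))

  fl <- flatten_params(spec)
  free <- setdiff(names(fl), fixed)
  if (!length(free))
    ak_stop("no free parameters to fit", "invalid_input")
  d <- length(free)
  theta0 <- log(unlist(fl[free]))

  lb <- theta0 - log(1000); ub <- theta0 + log(1000)
  if (!is.null(config$prior_bounds)) {
    for (nm in intersect(names(config$prior_bounds), free)) {
      lb[nm] <- log(config$prior_bounds[[nm]][1])
      ub[nm] <- log(config$prior_bounds[[nm]][2])
    }
    theta0 <- pmin(pmax(theta0, lb), ub)
  }

  n_obs <- sum(!is.na(data$value))
  fast_obj <- make_fast_objective(spec, initial, data, free, rtol, atol,
                                  normalisation)
  log_post <- function(theta) {
    if (any(theta < lb | theta > ub)) return(list(lp = -Inf, obj = Inf))
    obj <- fast_obj(exp(theta))
    if (!is.finite(obj)) return(list(lp = -Inf, obj = Inf))
    list(lp = -0.5 * n_obs * log(max(obj, 1e-12)), obj = obj)
  }

  if (!is.finite(log_post(theta0)$lp))
    ak_stop("starting parameters have non-finite posterior density (check prior bounds and data)",
            "diagnostic_error")

  scale0 <- config$proposal_scale
  if (length(scale0) == 1L) scale0 <- setNames(rep(scale0, d), free)
  else {
    if (!all(free %in% names(scale0)))
      ak_stop("per-parameter proposal_scale must name every free parameter",
              "invalid_input")
    scale0 <- scale0[free]
  }

  n_iter <- config$n_iterations
  burn <- floor(config$burn_in_fraction * n_iter)
  chains <- vector("list", config$n_chains)
  objs <- vector("list", config$n_chains)
  best <- list(obj = Inf, theta = theta0)
  n_accept <- 0L; n_prop <- 0L

  for (k in seq_len(config$n_chains)) {
    res <- with_seed(config$seed + 1009L * (k - 1L), {
      start <- theta0
      if (k > 1L) {
        start <- theta0 + rnorm(d, 0, scale0)
        start <- pmin(pmax(start, lb), ub)
        if (!is.finite(log_post(start)$lp)) start <- theta0
      }
      run_metropolis_chain(log_post, start, n_iter, burn, scale0)
    })
    keep <- seq.int(burn + 1L, n_iter)
    samples <- exp(res$samples[keep, , drop = FALSE])
    colnames(samples) <- free
    chains[[k]] <- samples
    objs[[k]] <- res$objs[keep]
    n_accept <- n_accept + res$n_accept
    n_prop <- n_prop + res$n_prop
    if (res$best$obj < best$obj) best <- res$best
  }

  # zero acceptance signals a degenerate proposal scale — unless the chain
  # started at an essentially perfect fit, where rejection is expected
  if (n_prop > 0L && n_accept == 0L && best$obj > 1e-6)
    ak_stop("no MCMC proposal was accepted; the proposal scale or prior bounds are degenerate",
            "diagnostic_error")

  pooled <- do.call(rbind, chains)
  best_fit <- setNames(exp(best$theta), free)
  best_spec <- update_spec(spec, best_fit)
  ci95 <- t(apply(pooled, 2, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci95) <- c("lower", "upper")
  post_med <- apply(pooled, 2, stats::median)
  rhat <- tryCatch(convergence_diagnostic(chains)$rhat,
                   acetokin_insufficient_samples = function(e)
                     setNames(rep(NA_real_, d), free))
  corr <- if (nrow(pooled) >= 2) parameter_correlation(pooled)
          else matrix(NA_real_, d, d, dimnames = list(free, free))
  r2 <- r_squared_by_variable(best_spec, initial, data, rtol, atol)
  pred <- predict_dataset(best_spec, initial, data, rtol, atol)
  term_t <- max(pred$time_h)
  terminal <- setNames(pred$pred[pred$time_h == term_t],
                       pred$variable[pred$time_h == term_t])

  structure(list(best_fit = best_fit, best_spec = best_spec,
                 posterior_median = post_med, ci95 = ci95,
                 chains = chains, objectives = objs,
                 r_squared = r2, correlation = corr,
                 rhat = rhat, converged = !is.na(rhat) & rhat < 1.05,
                 objective_at_best = best$obj,
                 acceptance_rate = if (n_prop) n_accept / n_prop else NA_real_,
                 terminal_prediction = c(list(time_h = term_t),
                                         as.list(terminal)),
                 initial = initial, free = free, fixed = fixed,
                 n_obs = n_obs, config = config,
                 structure = spec$structure),
            class = "fit_result")
}

# slot index of each flat parameter name in the compiled parms vector
# (see pack_parms() and src/kinetics.c)
parm_slots <- function(structure) {
  base <- switch(structure,
    monod        = c(mu_max = 2, K_H = 3, Y = 4, k_d = 5),
    first_order  = c(eta = 2, Y = 3, k_d = 4),
    t1           = c(eta = 2, Y = 3, k_d = 4, H_t = 5),
    t2           = c(eta = 2, Y = 3, k_d = 4, A = 5, T = 6),
    t3           = c(mu_max_H = 2, mu_max_R = 3, K_H = 4, K_R = 5,
                     Y = 6, k_d = 7),
    t1_nonlinear = c(mu_max = 2, K_H = 3, Y = 4, k_d = 5, H_t = 6),
    t2_nonlinear = c(mu_max = 2, K_H = 3, Y = 4, k_d = 5, H_t = 6,
                     A = 7, T = 8))
  c(base, c(eta_E = 10, Y_E = 11, b_EP = 12))
}

# pre-compiled objective closure used inside the MCMC loop: identical in
# value to fit_objective() (see tests) but avoids per-iteration object
# construction by writing free parameters straight into the compiled
# parms vector and calling lsoda directly
make_fast_objective <- function(spec, initial, data, free,
                                rtol = 1e-8, atol = 1e-10,
                                normalisation = "sd") {
  parms <- pack_parms(spec)
  slots <- parm_slots(spec$structure)[free]
  times <- sort(unique(data$time_h))
  y0 <- as_state_vector(initial)
  col_of <- c(H = 2L, P = 3L, X = 4L, E = 5L)
  idx <- cbind(match(data$time_h, times), col_of[data$variable])
  obs <- data$value
  scale <- residual_scales(data, normalisation)
  function(values) {
    parms[slots] <- values
    out <- tryCatch(
      suppressWarnings(
        deSolve::lsoda(y0, times, func = "acetokin_derivs", parms = parms,
                       dllname = "acetokin", initfunc = "acetokin_init",
                       rtol = rtol, atol = atol)),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < length(times)) return(Inf)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1] < 0) return(Inf)
    pred <- pmax(out[idx], 0)
    sum(((pred - obs) / scale)^2, na.rm = TRUE)
  }
}

# one adaptive random-walk Metropolis chain on the log-parameter scale;
# RNG state is managed by the caller
run_metropolis_chain <- function(log_post, theta0, n_iter, burn, scale0) {
  d <- length(theta0)
  samples <- matrix(NA_real_, n_iter, d)
  objs <- numeric(n_iter)
  theta <- theta0
  cur <- log_post(theta)
  samples[1L, ] <- theta; objs[1L] <- cur$obj
  best <- list(obj = cur$obj, theta = theta)
  n_accept <- 0L; n_prop <- 0L

  # running moments for Haario covariance adaptation
  mean_t <- theta
  m2 <- diag(0, d)
  n_seen <- 1L
  sd_opt <- 2.38^2 / d
  prop_chol <- diag(scale0, d)
  adapt_start <- max(50L, 10L * d)

  for (i in seq_len(n_iter)[-1L]) {
    adapting <- i <= burn
    if (adapting && n_seen > adapt_start && i %% 25L == 0L) {
      cov_t <- m2 / (n_seen - 1L)
      prop <- sd_opt * cov_t + diag(1e-10, d)
      ch <- tryCatch(chol(prop), error = function(e) NULL)
      if (!is.null(ch)) prop_chol <- ch
    }
    cand <- theta + drop(rnorm(d) %*% prop_chol)
    n_prop <- n_prop + 1L
    prop_lp <- log_post(cand)
    if (is.finite(prop_lp$lp) &&
        log(runif(1)) < prop_lp$lp - cur$lp) {
      theta <- cand; cur <- prop_lp
      n_accept <- n_accept + 1L
    }
    samples[i, ] <- theta; objs[i] <- cur$obj
    if (cur$obj < best$obj) best <- list(obj = cur$obj, theta = theta)
    if (adapting) {
      n_seen <- n_seen + 1L
      delta <- theta - mean_t
      mean_t <- mean_t + delta / n_seen
      m2 <- m2 + tcrossprod(delta, theta - mean_t)
    }
  }
  list(samples = samples, objs = objs, best = best,
       n_accept = n_accept, n_prop = n_prop)
}

#' Split-Rhat convergence diagnostic
#'
#' Potential-scale-reduction statistic computed after splitting each chain
#' in half, so a single long chain can also be assessed.  A parameter is
#' flagged converged when `Rhat < threshold` (default 1.05).
#'
#' @param chains a `fit_result`, or a list of sample matrices (iterations
#'   x parameters, shared column names)
#' @param threshold convergence cutoff on Rhat
#' @return list with per-parameter `rhat` and logical `converged`
#' @export
convergence_diagnostic <- function(chains, threshold = 1.05) {
  if (inherits(chains, "fit_result")) chains <- chains$chains
  if (is.matrix(chains)) chains <- list(chains)
  n <- nrow(chains[[1]])
  if (n < 4L)
    ak_stop("split-Rhat needs chains of at least 4 samples",
            "insufficient_samples")
  half <- floor(n / 2)
  split_chains <- unlist(lapply(chains, function(m)
    list(m[seq_len(half), , drop = FALSE],
         m[seq.int(n - half + 1L, n), , drop = FALSE])), recursive = FALSE)
  params <- colnames(chains[[1]])
  rhat <- setNames(vapply(seq_along(params), function(j) {
    xs <- lapply(split_chains, function(m) m[, j])
    w <- mean(vapply(xs, var, numeric(1)))
    means <- vapply(xs, mean, numeric(1))
    b_over_n <- var(means)
    if (w == 0) return(if (b_over_n == 0) 1 else Inf)
    sqrt((half - 1) / half + b_over_n / w)
  }, numeric(1)), params)
  list(rhat = rhat, converged = rhat < threshold)
}

#' Posterior parameter correlations
#'
#' Pearson correlation of each parameter pair across (pooled) posterior
#' samples.  Constant chains produce `NA` entries.  The hallmark of
#' Monod non-identifiability on single-batch data is
#' `|corr(mu_max, K_H)|` close to 1.
#'
#' @param chains a `fit_result`, list of sample matrices, or one pooled
#'   matrix
#' @return correlation matrix
#' @export
parameter_correlation <- function(chains) {
  if (inherits(chains, "fit_result")) chains <- chains$chains
  if (is.list(chains) && !is.data.frame(chains))
    chains <- do.call(rbind, chains)
  if (nrow(chains) < 2L)
    ak_stop("correlation needs at least 2 samples", "insufficient_samples")
  suppressWarnings(cor(chains))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$structure, "model,",
      length(x$free), "free parameter(s),",
      x$n_obs, "observations\n")
  cat(sprintf("  objective at best fit: %.6g   acceptance rate: %.2f\n",
              x$objective_at_best, x$acceptance_rate))
  tab <- data.frame(
    `best fit` = signif(x$best_fit, 4),
    `95% interval` = sprintf("(%.4g-%.4g)", x$ci95[, "lower"],
                             x$ci95[, "upper"]),
    Rhat = round(x$rhat, 3),
    converged = x$converged,
    check.names = FALSE)
  print(tab)
  cat("  R^2:",
      paste(sprintf("%s = %.3f", names(x$r_squared), x$r_squared),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit result serialization
#'
#' `write_fit_json()` writes the summary (best fit, intervals, R^2, Rhat,
#' correlations, terminal predictions); `write_chains_csv()` dumps the
#' post-burn-in samples; `read_fit_json()` reads the summary back as a
#' plain list.
#'
#' @param fit a `fit_result`
#' @param path output path
#' @return input path, invisibly (`read_fit_json()`: a list)
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(
    structure = fit$structure,
    free_parameters = fit$free,
    fixed_parameters = fit$fixed,
    point_estimate = "minimum objective sample",
    best_fit = as.list(fit$best_fit),
    posterior_median = as.list(fit$posterior_median),
    ci95 = apply(fit$ci95, 1, function(r) list(lower = r[[1]],
                                               upper = r[[2]]),
                 simplify = FALSE),
    r_squared = as.list(fit$r_squared),
    rhat = as.list(fit$rhat),
    converged = as.list(fit$converged),
    correlation = fit$correlation,
    objective_at_best = fit$objective_at_best,
    acceptance_rate = fit$acceptance_rate,
    terminal_prediction = fit$terminal_prediction,
    n_obs = fit$n_obs,
    n_iterations = fit$config$n_iterations,
    n_chains = fit$config$n_chains,
    seed = fit$config$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname write_fit_json
#' @export
write_chains_csv <- function(fit, path) {
  dfs <- lapply(seq_along(fit$chains), function(k) {
    df <- as.data.frame(fit$chains[[k]])
    df$chain <- k
    df$iteration <- seq_len(nrow(df))
    df$objective <- fit$objectives[[k]]
    df
  })
  all <- do.call(rbind, dfs)
  write.csv(all, path, row.names = FALSE)
  invisible(path)
}
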