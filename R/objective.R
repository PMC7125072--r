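# model predictions at the observation times of a dataset; returns the
# dataset with a `pred` column appended
predict_dataset <- function(spec, initial, data, rtol = 1e-8, atol = 1e-10) {
  times <- sort(unique(data$time_h))
  traj <- simulate_model(spec, initial, times, rtol = rtol, atol = atol)
  idx <- match(data$time_h, times)
  vars <- colnames(traj$states)
  pred <- rep(NA_real_, nrow(data))
  for (v in unique(data$variable)) {
    if (!v %in% vars)
      ak_stop(sprintf("dataset observes %s but the model does not track it", v),
              "invalid_input")
    rows <- data$variable == v
    pred[rows] <- traj$states[idx[rows], v]
  }
  out <- as.data.frame(data)
  out$pred <- pred
  out
}

# per-row normalisation scale, by policy:
#   sd    — replicate SD where informative, else the mean absolute level
#           of the variable over the time course
#   mean  — the mean absolute level of the variable (ignores SDs)
#   value — the observation itself (relative residuals), floored at 10%
#           of the variable's mean level so near-zero observations keep
#           finite weight; matches multiplicative (constant-CV) error
residual_scales <- function(data,
                            normalisation = c("sd", "mean", "value")) {
  normalisation <- match.arg(normalisation)
  scale <- rep(NA_real_, nrow(data))
  for (v in unique(data$variable)) {
    rows <- data$variable == v
    mv <- mean(abs(data$value[rows]), na.rm = TRUE)
    scale[rows] <- switch(normalisation,
      sd = mv,
      mean = mv,
      value = pmax(abs(data$value[rows]), 0.1 * mv))
    if (normalisation == "sd") {
      use_sd <- rows & !is.na(data$sd) & data$sd > 0
      scale[use_sd] <- data$sd[use_sd]
    }
  }
  if (any(!is.na(data$value) & (!is.finite(scale) | scale <= 0)))
    ak_stop("cannot normalise residuals: a variable has zero mean level and no dispersion",
            "invalid_input")
  scale
}

#' Calibration objective: sum of normalised squared differences
#'
#' The fitting objective is `sum(((pred - obs) / scale)^2)` over all
#' non-missing observations.  The normalisation `scale` makes residuals
#' in mM (metabolites) and g L^-1 (biomass) commensurable and comes in
#' three flavours: `"sd"` (default) uses the observation's replicate
#' standard deviation when available, falling back to the mean observed
#' level of the variable; `"mean"` always uses the variable's mean
#' level; `"value"` uses the observation itself (relative residuals,
#' floored at 10% of the variable mean), which matches data whose error
#' bars scale with the signal — empirical SDs from as few as three
#' replicates are very noisy weights, so `"value"` typically yields
#' better-calibrated intervals in recovery studies (see the methods
#' vignette).  Integration failure yields `Inf` (a rejected proposal
#' during MCMC) rather than an error.
#'
#' @param spec a [model_spec()]
#' @param initial a [culture_state()] at the first observation time
#' @param data a [ts_dataset()]
#' @param rtol,atol integrator tolerances
#' @param normalisation residual scaling policy, see Details
#' @return non-negative scalar (possibly `Inf`)
#' @export
fit_objective <- function(spec, initial, data, rtol = 1e-8, atol = 1e-10,
                          normalisation = c("sd", "mean", "value")) {
  normalisation <- match.arg(normalisation)
  pred <- tryCatch(
    suppressWarnings(predict_dataset(spec, initial, data, rtol, atol)),
    acetokin_integration_error = function(e) NULL)
  if (is.null(pred)) return(Inf)
  scale <- residual_scales(data, normalisation)
  res <- (pred$pred - pred$value) / scale
  sum(res^2, na.rm = TRUE)
}

#' Coefficient of determination for one observed variable
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the observed
#' mean.  Used as the goodness-of-fit summary for each of hydrogen,
#' acetate and cell dry weight.  Can be negative when the model does worse
#' than the mean.
#'
#' @param predicted model values at the observation times
#' @param observed observed values (same length; `NA` pairs dropped)
#' @return scalar `<= 1`
#' @export
r_squared <- function(predicted, observed) {
  keep <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[keep]; observed <- observed[keep]
  if (length(observed) < 2)
    ak_stop("R^2 requires at least 2 observations", "invalid_input")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    ak_stop("R^2 undefined: observations have zero variance",
            "undefined_r_squared")
  1 - sum((observed - predicted)^2) / ss_tot
}

# per-variable R^2 for a spec against a dataset
r_squared_by_variable <- function(spec, initial, data,
                                  rtol = 1e-8, atol = 1e-10) {
  pred <- predict_dataset(spec, initial, data, rtol, atol)
  vars <- unique(pred$variable)
  out <- setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    rows <- pred$variable == v & !is.na(pred$value)
    if (sum(rows) >= 2 && var(pred$value[rows]) > 0)
      out[v] <- r_squared(pred$pred[rows], pred$value[rows])
  }
  out
}
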