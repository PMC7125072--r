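#' Integrate a kinetic model forward in time
#'
#' Solves the model ODE system from an initial [culture_state()] and
#' returns the solution at the requested times.  The first element of
#' `times` is the time of the initial state (usually 0).  Integration uses
#' `deSolve`'s stiff-capable adaptive `lsoda` with dense output at the
#' requested times; the hard T1 threshold kink and steep T2 gates can make
#' the system locally stiff, which lsoda handles by switching methods.
#'
#' Two backends are available: `"compiled"` (default; C derivatives, used
#' throughout calibration for speed) and `"R"` (the pure-R RHS functions
#' of [model_rhs()]).  Both produce identical trajectories to within
#' integrator tolerance.
#'
#' Cosmetic negative overshoot in the output (below the absolute
#' tolerance) is clipped to zero; the largest clipped magnitude is kept in
#' the trajectory's `clip_magnitude` field.
#'
#' @param spec a [model_spec()]
#' @param initial a [culture_state()]; must carry `E` iff `spec` has the
#'   yeast-extract extension
#' @param times numeric vector of output times in hours, strictly
#'   increasing, `times[1] >= 0`
#' @param rtol,atol relative/absolute integrator tolerances
#' @param engine `"compiled"` or `"R"`
#' @return an object of class `trajectory`: list with `times`, `states`
#'   (matrix with columns `H`, `P`, `X` and `E` when extended), `spec`,
#'   `initial`, `clip_magnitude`
#' @examples
#' tr <- simulate_model(reference_params("t1"),
#'                      culture_state(H = 400, P = 0, X = 0.01),
#'                      times = seq(0, 80, by = 5))
#' head(as.data.frame(tr))
#' @export
simulate_model <- function(spec, initial, times, rtol = 1e-8, atol = 1e-10,
                           engine = c("compiled", "R")) {
  engine <- match.arg(engine)
  if (!inherits(spec, "model_spec"))
    ak_stop("spec must be a model_spec", "invalid_input")
  if (!inherits(initial, "culture_state"))
    ak_stop("initial must be a culture_state", "invalid_input")
  if (has_extension(spec) && is.null(initial$E))
    ak_stop("extended model requires an initial state with E", "invalid_input")
  if (!has_extension(spec) && !is.null(initial$E))
    ak_stop("initial state has E but the model carries no extension",
            "invalid_input")
  if (length(times) < 1 || times[1] < 0 ||
      (length(times) > 1 && any(diff(times) <= 0)))
    ak_stop("times must be strictly increasing with times[1] >= 0",
            "invalid_input")

  vars <- c("H", "P", "X", if (has_extension(spec)) "E")
  y0 <- as_state_vector(initial)

  if (length(times) == 1L) {
    states <- matrix(y0[vars], nrow = 1, dimnames = list(NULL, vars))
    return(new_trajectory(times, states, spec, initial, 0))
  }

  if (engine == "compiled") {
    out <- deSolve::ode(y = y0, times = times, func = "acetokin_derivs",
                        parms = pack_parms(spec), dllname = "acetokin",
                        initfunc = "acetokin_init", method = "lsoda",
                        rtol = rtol, atol = atol)
  } else {
    rfun <- function(t, y, parms) {
      st <- list(H = y[[1]], P = y[[2]], X = y[[3]])
      if (has_extension(spec)) st$E <- y[[4]]
      st <- structure(st, class = "culture_state")
      d <- model_rhs(spec, st)
      list(c(d, if (length(d) == 3) 0))
    }
    out <- deSolve::ode(y = y0, times = times, func = rfun, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
  }

  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    ak_stop(sprintf("ODE integration failed near t = %.4g h (istate = %d)",
                    max(out[, "time"], na.rm = TRUE), istate[1]),
            "integration_error")
  if (nrow(out) < length(times))
    ak_stop("ODE integration terminated before the final requested time",
            "integration_error")

  states <- out[, c("H", "P", "X", "E")[seq_len(3 + has_extension(spec))],
                drop = FALSE]
  colnames(states) <- vars
  clip <- max(0, -min(states))
  states[states < 0] <- 0
  new_trajectory(times, states, spec, initial, clip)
}

new_trajectory <- function(times, states, spec, initial, clip) {
  structure(list(times = times, states = states, spec = spec,
                 initial = initial, clip_magnitude = clip),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", x$spec$structure, "model,", length(x$times),
      "time points over", diff(range(x$times)), "h\n")
  print(utils::head(as.data.frame(x), 4))
  if (length(x$times) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  df <- data.frame(time_h = x$times,
                   H_mM = x$states[, "H"],
                   P_mM = x$states[, "P"],
                   X_gL = x$states[, "X"])
  if ("E" %in% colnames(x$states)) df$E_mM <- x$states[, "E"]
  df
}

#' Stoichiometric conservation residual of a trajectory
#'
#' For every single-substrate structure the model implies the exact
#' conservation law `P(t) - P(0) = (H(0) - H(t)) / 4`.  This returns the
#' maximum absolute deviation (mM) from that law along a trajectory — a
#' direct check on integration quality.  Extended (two-substrate)
#' trajectories violate the law by construction and are rejected.
#'
#' @param traj a [simulate_model()] trajectory of a non-extended model
#' @return maximum absolute deviation, mM
#' @export
conservation_residual <- function(traj) {
  if (!inherits(traj, "trajectory"))
    ak_stop("traj must be a trajectory", "invalid_input")
  if ("E" %in% colnames(traj$states))
    ak_stop("conservation law does not apply to extended (two-substrate) trajectories",
            "unsupported_model")
  H <- traj$states[, "H"]; P <- traj$states[, "P"]
  max(abs((P - P[1]) - (H[1] - H) / 4))
}

#' Trajectory CSV I/O
#'
#' Writes/reads the wide tidy format `time_h, H_mM, P_mM, X_gL[, E_mM]`
#' at full precision.
#'
#' @param traj a trajectory
#' @param path file path
#' @return `read_trajectory_csv()` returns a data.frame
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- if (inherits(traj, "trajectory")) as.data.frame(traj) else traj
  write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
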