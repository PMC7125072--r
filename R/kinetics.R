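#' Model right-hand sides
#'
#' Pure derivative functions for each model structure, returning the
#' instantaneous rates `(dH/dt, dP/dt, dX/dt)` in mM h^-1 (X in
#' g L^-1 h^-1) at a given [culture_state()].  Every structure shares the
#' stoichiometric coupling `dP/dt = -(1/4) dH/dt` (four moles of hydrogen
#' per mole of acetate along the Wood-Ljungdahl pathway) and the biomass
#' balance `dX/dt = -Y dH/dt - k_d X`; they differ only in the hydrogen
#' uptake law:
#'
#' * `monod_rhs()`: `dH/dt = -(mu_max X / Y) H / (K_H + H)`
#' * `first_order_rhs()`: `dH/dt = -eta X H / Y`
#' * `t1_rhs()`: first-order in `H* = max(H - H_t, 0)` — uptake switches
#'   off below the threshold `H_t`
#' * `t2_rhs()`: `dH/dt = -eta X H F(H) / Y` with the sigmoid gate
#'   `F` of [t2_gate()]
#' * `t3_rhs()`: reversible Michaelis-Menten,
#'   `dH/dt = -(X/Y) (mu_max_H H/K_H - mu_max_R P/K_R) /
#'   (1 + H/K_H + P/K_R)` — net uptake reverses when acetate accumulates
#'   past the steady-state ratio (see [t3_steady_state_ratio()])
#' * `t1_nonlinear_rhs()`, `t2_nonlinear_rhs()`: the Monod-form threshold
#'   variants (hard cutoff inside a Monod term; the Ribes double-sigmoid
#'   construction with `f = 1/(1 + exp(A (H_t - H)))`)
#'
#' Infinitesimally negative state components (integrator overshoot) are
#' treated as zero.
#'
#' @param state a [culture_state()]
#' @param p the matching parameter record
#' @return named numeric vector `c(dH, dP, dX)` (plus `dE` from
#'   [extended_rhs()])
#' @examples
#' st <- culture_state(H = 100, P = 0, X = 0.1)
#' first_order_rhs(st, first_order_params(eta = 8e-4, Y = 0.0037, k_d = 0.087))
#' @name model_rhs_functions
NULL

# shared tail: product stoichiometry and biomass balance
assemble_rhs <- function(dH, Y, k_d, X) {
  dP <- -0.25 * dH
  dX <- -Y * dH - k_d * X
  c(dH = dH, dP = dP, dX = dX)
}

clipped <- function(state) {
  lapply(state, function(v) if (is.null(v)) NULL else max(v, 0))
}

check_rhs_inputs <- function(state, p) {
  if (!inherits(state, "culture_state"))
    ak_stop("state must be a culture_state", "invalid_input")
  if (!inherits(p, "kinetic_params"))
    ak_stop("p must be a kinetic parameter record", "invalid_input")
  # constructors validate at build time; re-check finiteness defensively
  if (!all(vapply(unclass(state), is.finite, logical(1))) ||
      !all(vapply(unclass(p), is.finite, logical(1))))
    ak_stop("non-finite state or parameter value", "invalid_input")
}

#' @rdname model_rhs_functions
#' @export
monod_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  dH <- -(p$mu_max * s$X / p$Y) * s$H / (p$K_H + s$H)
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' @rdname model_rhs_functions
#' @export
first_order_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  dH <- -p$eta * s$X * s$H / p$Y
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' @rdname model_rhs_functions
#' @export
t1_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  Hstar <- max(s$H - p$H_t, 0)
  dH <- -p$eta * Hstar * s$X / p$Y
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' Sigmoid uptake gate of the T2 model
#'
#' `F(H) = 1 / (1 + exp(A (T - H)))`, the empirical sigmoid (after Ribes
#' et al.) that shuts hydrogen uptake down smoothly as `H` falls towards
#' the threshold region.  Evaluated overflow-safely via [stats::plogis()];
#' the value lies in `(0, 1)` and reaches the bounds only in the limits
#' `H -> +/- Inf`.
#'
#' @param H hydrogen concentration, mM (finite)
#' @param p a [t2_params()] record (fields `A`, `T`)
#' @return gate value in `[0, 1]`
#' @examples
#' t2_gate(336, t2_params(eta = 0.0054, Y = 0.0017, k_d = 0.019,
#'                        A = 0.015, T = 336))  # 0.5 at the midpoint
#' @export
t2_gate <- function(H, p) {
  if (!is.numeric(H) || any(!is.finite(H)))
    ak_stop("H must be finite", "invalid_input")
  plogis(p$A * (H - p$T))
}

#' @rdname model_rhs_functions
#' @export
t2_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  dH <- -p$eta * s$X * s$H * t2_gate(s$H, p) / p$Y
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' @rdname model_rhs_functions
#' @export
t3_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  num <- p$mu_max_H * s$H / p$K_H - p$mu_max_R * s$P / p$K_R
  den <- 1 + s$H / p$K_H + s$P / p$K_R
  dH <- -(s$X / p$Y) * num / den
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' @rdname model_rhs_functions
#' @export
t1_nonlinear_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  Hstar <- max(s$H - p$H_t, 0)
  dH <- -(p$mu_max * s$X / p$Y) * Hstar / (p$K_H + Hstar)
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' @rdname model_rhs_functions
#' @export
t2_nonlinear_rhs <- function(state, p) {
  check_rhs_inputs(state, p)
  s <- clipped(state)
  f <- plogis(p$A * (s$H - p$H_t))
  F_ <- plogis(p$A * (s$H - p$T))
  Hf <- s$H - p$H_t * f
  dH <- -(p$mu_max * s$X / p$Y) * (Hf / (p$K_H + Hf)) * F_
  assemble_rhs(dH, p$Y, p$k_d, s$X)
}

#' Two-substrate (yeast-extract) derivative
#'
#' Augments any T2/T3 base model with first-order consumption of a pooled
#' yeast-extract substrate `E`: `dE/dt = -eta_E X E / Y_E`, with acetate
#' gaining `-b_EP dE/dt` and biomass gaining `-Y_E dE/dt`.  The hydrogen
#' equation is untouched.  With `E = 0` the result reduces exactly to the
#' base model's derivative.
#'
#' @param state a [culture_state()] carrying the `E` component
#' @param spec a [model_spec()] with an extension
#' @return named numeric vector `c(dH, dP, dX, dE)`
#' @export
extended_rhs <- function(state, spec) {
  if (!has_extension(spec))
    ak_stop("spec carries no yeast-extract extension", "invalid_input")
  if (is.null(state$E))
    ak_stop("state lacks the yeast-extract component E required by the extension",
            "invalid_input")
  base <- base_rhs(spec, state)
  ex <- spec$extension
  E <- max(state$E, 0)
  X <- max(state$X, 0)
  dE <- -ex$eta_E * X * E / ex$Y_E
  c(dH = unname(base["dH"]),
    dP = unname(base["dP"] - ex$b_EP * dE),
    dX = unname(base["dX"] - ex$Y_E * dE),
    dE = dE)
}

base_rhs <- function(spec, state) {
  switch(spec$structure,
    monod        = monod_rhs(state, spec$params),
    first_order  = first_order_rhs(state, spec$params),
    t1           = t1_rhs(state, spec$params),
    t2           = t2_rhs(state, spec$params),
    t3           = t3_rhs(state, spec$params),
    t1_nonlinear = t1_nonlinear_rhs(state, spec$params),
    t2_nonlinear = t2_nonlinear_rhs(state, spec$params))
}

#' Evaluate the derivative of any model specification
#'
#' Dispatches to the structure's RHS function, including the yeast-extract
#' extension when present.
#'
#' @inheritParams extended_rhs
#' @return named derivative vector (length 3, or 4 with extension)
#' @export
model_rhs <- function(spec, state) {
  if (has_extension(spec)) extended_rhs(state, spec)
  else base_rhs(spec, state)
}
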