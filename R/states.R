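#' Instantaneous state of a batch culture
#'
#' Bundles the concentrations tracked by every model structure: dissolved
#' hydrogen `H` (mM), acetate `P` (mM) and cell dry weight `X` (g L^-1).
#' The optional fourth component `E` (mM) is the pooled yeast-extract
#' substrate used by the two-substrate extension and must be present iff
#' the model carries an extension.
#'
#' @param H hydrogen concentration, mM (>= 0)
#' @param P acetate concentration, mM (>= 0)
#' @param X cell concentration, g L^-1 cell dry weight (>= 0)
#' @param E yeast-extract concentration, mM (>= 0), or `NULL` for the
#'   single-substrate models
#' @return an object of class `culture_state`
#' @examples
#' culture_state(H = 400, P = 0, X = 0.01)
#' @export
culture_state <- function(H, P, X, E = NULL) {
  vals <- list(H = H, P = P, X = X)
  if (!is.null(E)) vals$E <- E
  check_nonneg_finite(vals, "culture state")
  structure(vals, class = "culture_state")
}

#' @export
print.culture_state <- function(x, ...) {
  cat("<culture_state>  H =", x$H, "mM, P =", x$P, "mM, X =", x$X, "g/L")
  if (!is.null(x$E)) cat(", E =", x$E, "mM")
  cat("\n")
  invisible(x)
}

as_state_vector <- function(state) {
  c(H = state$H, P = state$P, X = state$X, E = state$E %||% 0)
}
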