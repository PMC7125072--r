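# internal helpers

ak_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("acetokin_", class),
                                     "acetokin_error", "error", "condition")))
}

# all finite, strictly positive scalars
check_positive <- function(x, what) {
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad))
    ak_stop(sprintf("parameter(s) %s must be finite and strictly positive",
                    paste(names(x)[bad], collapse = ", ")),
            "invalid_input")
  invisible(x)
}

check_nonneg_finite <- function(x, what) {
  bad <- vapply(x, function(v) !is.numeric(v) || length(v) != 1L ||
                  !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    ak_stop(sprintf("%s component(s) %s must be finite and non-negative",
                    what, paste(names(x)[bad], collapse = ", ")),
            "invalid_input")
  invisible(x)
}

# evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
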