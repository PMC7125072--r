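#' Observed batch time-course dataset
#'
#' Long-format container for batch-culture observations: one row per
#' (time, variable) pair with the replicate mean `value`, an optional
#' replicate standard deviation `sd` and an optional replicate count `n`.
#' Variables are `H` (hydrogen, mM), `P` (acetate, mM), `X` (cell dry
#' weight, g L^-1) and optionally `E` (yeast extract, mM).  Missing
#' observations are simply absent rows (or `NA` values, which the
#' objective skips).
#'
#' Validity: times strictly increasing within each variable, at least one
#' variable observed at three or more times, `sd >= 0` where present
#' (`sd = 0`, as produced by a noise-free synthetic scenario, is treated
#' as "no dispersion information" by the fitting objective).
#'
#' @param data data.frame with columns `time_h`, `variable`, `value` and
#'   optionally `sd`, `n`
#' @return an object of class `ts_dataset` (a data.frame)
#' @examples
#' ts_dataset(data.frame(time_h = rep(c(0, 24, 48), 2),
#'                       variable = rep(c("H", "P"), each = 3),
#'                       value = c(400, 250, 120, 0, 37, 70)))
#' @export
ts_dataset <- function(data) {
  need <- c("time_h", "variable", "value")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    ak_stop("dataset needs columns time_h, variable, value", "invalid_input")
  if (!"sd" %in% names(data)) data$sd <- NA_real_
  if (!"n" %in% names(data)) data$n <- NA_integer_
  data <- data[, c("time_h", "variable", "value", "sd", "n")]
  if (!all(data$variable %in% c("H", "P", "X", "E")))
    ak_stop("variable must be one of H, P, X, E", "invalid_input")
  if (any(!is.finite(data$time_h)) || any(data$time_h < 0))
    ak_stop("time_h must be finite and non-negative", "invalid_input")
  for (v in unique(data$variable)) {
    tv <- data$time_h[data$variable == v]
    if (any(diff(tv) <= 0))
      ak_stop(sprintf("times for variable %s must be strictly increasing", v),
              "invalid_input")
  }
  counts <- table(data$variable[!is.na(data$value)])
  if (!any(counts >= 3))
    ak_stop("at least one variable must be observed at 3 or more times",
            "invalid_input")
  if (any(data$sd < 0, na.rm = TRUE))
    ak_stop("sd must be non-negative where present", "invalid_input")
  class(data) <- c("ts_dataset", "data.frame")
  data
}

#' Dataset CSV I/O
#'
#' Tidy long format with columns `time_h, variable, value, sd, n` (the
#' last two optional).
#'
#' @param data a [ts_dataset()]
#' @param path file path
#' @return `read_dataset_csv()` returns a validated [ts_dataset()]
#' @export
write_dataset_csv <- function(data, path) {
  write.csv(format(as.data.frame(data), digits = 17, trim = TRUE,
                   scientific = NA),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path))
    ak_stop(sprintf("dataset file not found: %s", path), "invalid_input")
  ts_dataset(read.csv(path, stringsAsFactors = FALSE))
}

#' Initial culture state implied by a dataset
#'
#' Takes the earliest observation of each variable as the initial
#' condition; variables absent from the dataset fall back to the supplied
#' defaults.  Used by [mcmc_fit()], which does not treat initial states as
#' free parameters.
#'
#' @param data a [ts_dataset()]
#' @param defaults named list of fallback values (`H`, `P`, `X`, `E`)
#' @param extended should the state carry an `E` component?
#' @return a [culture_state()]
#' @export
initial_from_data <- function(data,
                              defaults = list(H = 0, P = 0, X = 0, E = 0),
                              extended = "E" %in% data$variable) {
  val0 <- function(v) {
    rows <- data[data$variable == v & !is.na(data$value), ]
    if (nrow(rows)) rows$value[which.min(rows$time_h)] else defaults[[v]]
  }
  culture_state(H = val0("H"), P = val0("P"), X = val0("X"),
                E = if (extended) val0("E"))
}
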