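#' Physical and conversion constants
#'
#' Constants used by the unit-conversion and stoichiometry helpers:
#' molar masses of H2 (2.016 g mol^-1) and acetate (59.044 g mol^-1),
#' the ideal gas constant (8.314 J mol^-1 K^-1), the optical-density to
#' cell-dry-weight factor for *B. hydrogenotrophica* (0.37 g L^-1 per OD
#' unit), and the literature hydrogen uptake threshold for this organism
#' (70 +/- 12.7 mM, reported from an 1100 +/- 200 ppm measurement; the
#' conversion basis is not published, so the value is stored as a
#' citation-level constant rather than computed).
#'
#' @format A named list.
#' @export
acetokin_constants <- list(
  molar_mass = c(hydrogen = 2.016, acetate = 59.044),  # g mol^-1
  gas_constant = 8.314,                                # J mol^-1 K^-1
  od_to_cdw_factor = 0.37,                             # g L^-1 per OD
  literature_h2_threshold = list(
    value_mM = 70, sd_mM = 12.7,
    source = "Leclerc et al., reported as 1100 +/- 200 ppm",
    note = "stored constant; ppm-to-mM conversion basis not published"))

#' Optical density to cell dry weight
#'
#' `CDW = 0.37 * OD` for *B. hydrogenotrophica*.
#'
#' @param od optical density (>= 0)
#' @return cell dry weight, g L^-1
#' @examples
#' od_to_cdw(1.0)   # 0.37
#' @export
od_to_cdw <- function(od) {
  if (any(!is.finite(od)) || any(od < 0))
    ak_stop("od must be finite and non-negative", "invalid_input")
  acetokin_constants$od_to_cdw_factor * od
}

#' Mass concentration to millimolar
#'
#' Divides g L^-1 by the species molar mass and scales to mM; the inverse
#' conversion is provided for round-tripping.
#'
#' @param value concentration in g L^-1 (or mM for the inverse)
#' @param species `"hydrogen"` or `"acetate"`
#' @return concentration in mM (or g L^-1)
#' @examples
#' gram_per_litre_to_mM(2.016, "hydrogen")  # 1000
#' @export
gram_per_litre_to_mM <- function(value, species = c("hydrogen", "acetate")) {
  species <- match.arg(species)
  if (any(!is.finite(value)) || any(value < 0))
    ak_stop("value must be finite and non-negative", "invalid_input")
  value / acetokin_constants$molar_mass[[species]] * 1000
}

#' @rdname gram_per_litre_to_mM
#' @export
mM_to_gram_per_litre <- function(value, species = c("hydrogen", "acetate")) {
  species <- match.arg(species)
  if (any(!is.finite(value)) || any(value < 0))
    ak_stop("value must be finite and non-negative", "invalid_input")
  value * acetokin_constants$molar_mass[[species]] / 1000
}

#' Serum-bottle headspace description
#'
#' Geometry and gas composition of a closed culture bottle, used for the
#' stoichiometric acetate bound.  Defaults describe the validation
#' experiments: 0.4 L headspace of H2:CO2 66:34 at 200 kPa over 0.1 L of
#' medium.  Temperature defaults to the 37 degree C culture temperature;
#' it is an explicit argument because the printed 0.02 mol figure rounds
#' identically anywhere between room and culture temperature.
#'
#' @param volume headspace volume, L
#' @param pressure total pressure, kPa
#' @param h2_fraction hydrogen mole fraction, in `(0, 1]`
#' @param temperature gas temperature, K
#' @param medium_volume liquid medium volume, L
#' @return list of class `headspace_spec`
#' @export
headspace_spec <- function(volume = 0.4, pressure = 200, h2_fraction = 0.66,
                           temperature = 310.15, medium_volume = 0.1) {
  vals <- list(volume = volume, pressure = pressure,
               h2_fraction = h2_fraction, temperature = temperature,
               medium_volume = medium_volume)
  check_nonneg_finite(vals, "headspace")
  if (h2_fraction > 1)
    ak_stop("h2_fraction must be <= 1", "invalid_input")
  structure(vals, class = "headspace_spec")
}

#' Moles of hydrogen in a bottle headspace
#'
#' Ideal-gas moles of the H2 partial pressure:
#' `n = x_H2 * p * V / (R * T)`; with pressure in kPa and volume in L the
#' product is already in joules.
#'
#' @param spec a [headspace_spec()]
#' @return mol H2
#' @examples
#' headspace_h2_moles(headspace_spec())  # ~0.0205 mol
#' @export
headspace_h2_moles <- function(spec = headspace_spec()) {
  if (!inherits(spec, "headspace_spec"))
    ak_stop("spec must be a headspace_spec", "invalid_input")
  spec$h2_fraction * spec$pressure * spec$volume /
    (acetokin_constants$gas_constant * spec$temperature)
}

#' Stoichiometric maximum acetate from a hydrogen supply
#'
#' Along the Wood-Ljungdahl pathway (4 H2 + 2 CO2 -> acetate + H+ +
#' 2 H2O) each mole of acetate costs four moles of hydrogen, so the most
#' acetate a finite hydrogen supply can yield in a liquid volume `V` is
#' `(n_H2 / 4) / V * 1000` mM.  Observed acetate beyond this bound must
#' come from other carbon sources.
#'
#' @param h2_moles available hydrogen, mol
#' @param medium_volume liquid volume, L
#' @return maximum acetate concentration, mM
#' @examples
#' max_acetate_mM(0.02, 0.1)  # 50 mM
#' @export
max_acetate_mM <- function(h2_moles, medium_volume) {
  if (any(!is.finite(c(h2_moles, medium_volume))) ||
      h2_moles < 0 || medium_volume <= 0)
    ak_stop("h2_moles must be >= 0 and medium_volume > 0", "invalid_input")
  (h2_moles / 4) / medium_volume * 1000
}

#' Steady-state metabolite ratio of the reversible (T3) model
#'
#' The net hydrogen flux of the reversible Michaelis-Menten model
#' vanishes when `mu_max_H * H / K_H = mu_max_R * P / K_R`, i.e. at the
#' acetate-to-hydrogen ratio `P/H = (mu_max_H * K_R) / (mu_max_R * K_H)`.
#' This is an attracting point: cultures above the ratio run the reverse
#' reaction, cultures below run the forward reaction.  At the packaged
#' reference estimates the ratio is about 3.43.
#'
#' @param p a [t3_params()] record
#' @return dimensionless P/H ratio
#' @examples
#' t3_steady_state_ratio(reference_params("t3")$params)
#' @export
t3_steady_state_ratio <- function(p) {
  if (!inherits(p, "t3_params"))
    ak_stop("p must be a t3_params record", "invalid_input")
  (p$mu_max_H * p$K_R) / (p$mu_max_R * p$K_H)
}

#' Default sigmoid tuning from a known threshold
#'
#' The default tuning suggested by Ribes et al. ties the T2 sigmoid parameters
#' to the substrate threshold: `A = 100 / H_t` and `T = 1.1 * H_t`.
#' These defaults give the parameters biological meaning but impose a
#' much steeper gate than fitted values typically support.
#'
#' @param H_t threshold hydrogen concentration, mM (> 0)
#' @return list with elements `A` (mM^-1) and `T` (mM)
#' @examples
#' ribes_default_tuning(86.2)  # A ~ 1.16, T = 94.82
#' @export
ribes_default_tuning <- function(H_t) {
  if (!is.finite(H_t) || H_t <= 0)
    ak_stop("H_t must be finite and positive", "invalid_input")
  list(A = 100 / H_t, T = 1.1 * H_t)
}

#' Compare two media fits against the stoichiometric acetate bound
#'
#' Side-by-side report for fits of the same organism on two growth media
#' (e.g. a minimal general-acetogen medium versus a yeast-extract-rich
#' medium): tabulates per-variable R^2 and flags any fit whose terminal
#' acetate exceeds the hydrogen-stoichiometry bound — the signature of
#' acetate production from alternative carbon sources.
#'
#' @param fit_a,fit_b `fit_result` objects (or lists read back by
#'   [read_fit_json()]) carrying terminal acetate predictions and R^2
#'   tables
#' @param bound_mM stoichiometric maximum acetate, mM (see
#'   [max_acetate_mM()])
#' @param labels length-2 character labels for the two fits
#' @return list of class `media_comparison`
#' @export
compare_media <- function(fit_a, fit_b, bound_mM,
                          labels = c("medium_a", "medium_b")) {
  one <- function(fit, label) {
    tp <- fit$terminal_prediction
    if (is.null(tp) || is.null(tp$P))
      ak_stop(sprintf("fit '%s' carries no terminal acetate prediction",
                      label), "invalid_input")
    acet <- tp$P
    list(label = label,
         terminal_acetate_mM = acet,
         exceeds_bound = acet > bound_mM,
         excess_mM = max(acet - bound_mM, 0),
         r_squared = fit$r_squared)
  }
  a <- one(fit_a, labels[1]); b <- one(fit_b, labels[2])
  structure(list(bound_mM = bound_mM, fits = list(a, b)),
            class = "media_comparison")
}

#' @export
print.media_comparison <- function(x, ...) {
  cat("<media_comparison>  stoichiometric acetate bound:",
      x$bound_mM, "mM\n")
  for (f in x$fits) {
    cat(sprintf("  %-12s terminal acetate %.1f mM %s",
                f$label, f$terminal_acetate_mM,
                if (f$exceeds_bound)
                  sprintf("EXCEEDS bound by %.1f mM", f$excess_mM)
                else "within bound"), "\n")
    r2 <- unlist(f$r_squared)
    cat("    R^2:", paste(sprintf("%s = %.3f", names(r2), r2),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname compare_media
#' @param comparison a `media_comparison`
#' @param path output path
#' @export
write_comparison_json <- function(comparison, path) {
  jsonlite::write_json(unclass(comparison), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
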