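# Reparametrized Arrhenius model: k(T) = k_ref * exp[(Ea/R)(1/T_ref - 1/T)].
# Estimating k_ref (the rate constant at T_ref) instead of the
# pre-exponential factor decorrelates the two parameters over a narrow
# temperature window; T_ref defaults to 393.15 K (120 degrees C), the
# midpoint of the study's range.

GAS_CONSTANT <- 8.314      # J mol^-1 K^-1
T_REF_DEFAULT <- 393.15    # K

celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15

#' Reparametrized Arrhenius parameter set
#'
#' Bundles per-step `(k_ref, Ea)` pairs with a shared reference
#' temperature. `k_ref` carries the units of the step's rate constant
#' (min^-1 or kg umol^-1 min^-1); `Ea` is in kJ/mol and is not sign
#' constrained.
#'
#' @param k_ref Non-negative numeric vector of rate constants at `T_ref_K`,
#'   one per step (optionally named `k1`, `k2`, ...).
#' @param Ea_kJ_mol Activation energies, same length.
#' @param step Step indices; defaults to `1:length(k_ref)`.
#' @param T_ref_K Shared reference temperature in kelvin.
#' @return An object of class `mr_arrhenius`: a tibble with columns `step`,
#'   `k_ref`, `Ea_kJ_mol` and attribute `T_ref_K`.
#' @examples
#' pars <- mr_arrhenius(k_ref = c(7.5e-9, 5.9e-3), Ea_kJ_mol = c(52.1, 64.1))
#' mr_arrhenius_rate(pars, temperature_C = 140)
#' @export
mr_arrhenius <- function(k_ref, Ea_kJ_mol, step = seq_along(k_ref),
                         T_ref_K = T_REF_DEFAULT) {
  if (length(k_ref) != length(Ea_kJ_mol)) {
    abort("`k_ref` and `Ea_kJ_mol` must have the same length")
  }
  if (any(k_ref < 0)) abort("`k_ref` must be non-negative")
  if (T_ref_K <= 0) abort("`T_ref_K` must be positive")
  out <- tibble::tibble(step = as.integer(step), k_ref = as.numeric(k_ref),
                        Ea_kJ_mol = as.numeric(Ea_kJ_mol))
  structure(out, T_ref_K = T_ref_K,
            class = c("mr_arrhenius", class(out)))
}

#' Evaluate the reparametrized Arrhenius equation
#'
#' `k(T) = k_ref * exp[(Ea/R) * (1/T_ref - 1/T)]` with `Ea` converted from
#' kJ/mol to J/mol and `R = 8.314` J mol^-1 K^-1. For `Ea > 0` the rate
#' constant increases with temperature; at `T = T_ref` it equals `k_ref`
#' exactly.
#'
#' @param params An [mr_arrhenius()] object.
#' @param temperature_C Heating temperature in degrees Celsius (converted to
#'   kelvin internally). Supply `temperature_K` instead to work in kelvin.
#' @param temperature_K Heating temperature in kelvin (overrides
#'   `temperature_C`).
#' @param step Optional step index; if given, returns the scalar rate
#'   constant for that step, otherwise a named vector over all steps.
#' @return Rate constant(s) at the requested temperature.
#' @export
mr_arrhenius_rate <- function(params, temperature_C = NULL,
                              temperature_K = NULL, step = NULL) {
  stopifnot(inherits(params, "mr_arrhenius"))
  if (is.null(temperature_K)) {
    if (is.null(temperature_C)) abort("supply `temperature_C` or `temperature_K`")
    temperature_K <- celsius_to_kelvin(temperature_C)
  }
  if (any(temperature_K <= 0)) abort("temperature must be positive (kelvin)")
  T_ref <- attr(params, "T_ref_K")
  k <- params$k_ref *
    exp((params$Ea_kJ_mol * 1000 / GAS_CONSTANT) * (1 / T_ref - 1 / temperature_K))
  names(k) <- paste0("k", params$step)
  if (!is.null(step)) {
    i <- match(as.integer(step), params$step)
    if (anyNA(i)) abort("step not present in the Arrhenius parameter set")
    k <- k[i]
  }
  k
}
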