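# ODE integration of the reaction network. The system is stiff (rate
# constants span ~1e-9 to ~1e2 min^-1), so lsoda with tight tolerances is
# the default. The right-hand side lives in compiled code; mr_ode_rhs() is
# the plain-R reference implementation of the same derivative.

# Precompute the integer encoding of a network for the compiled solver.
encode_network <- function(network) {
  sp <- network$species$name
  st <- network$steps
  r1 <- vapply(st$reactants, function(r) match(r[1], sp), integer(1))
  r2 <- vapply(st$reactants, function(r) {
    if (length(r) > 1L) match(r[2], sp) else 0L
  }, integer(1))
  list(species = sp, n_spec = length(sp), r1 = as.integer(r1),
       r2 = as.integer(r2), S = stoichiometry_matrix(network))
}

# Fast path: integrate and return the deSolve output matrix (time + one
# column per species), or NULL on solver failure. No clamping here.
sim_matrix <- function(enc, k, y0, times, rtol, atol, method = "lsoda") {
  .Call("mr_ode_setup", as.integer(enc$n_spec), as.numeric(k), enc$r1,
        enc$r2, as.numeric(enc$S), PACKAGE = "maillardkin")
  out <- try(suppressWarnings(
    deSolve::ode(y = y0, times = times, func = "mr_derivs", parms = NULL,
                 method = method, dllname = "maillardkin", initfunc = NULL,
                 rtol = rtol, atol = atol)
  ), silent = TRUE)
  if (inherits(out, "try-error") || nrow(out) < length(times) ||
      anyNA(out) || any(!is.finite(out))) {
    return(NULL)
  }
  out
}

# Clamp integration-noise negatives to zero; anything more negative than
# the absolute tolerance is a hard error.
clamp_negatives <- function(m, atol) {
  vals <- m[, -1, drop = FALSE]
  neg <- vals < 0
  if (any(neg)) {
    worst <- min(vals[neg])
    if (-worst >= atol) {
      abort(sprintf(
        "trajectory went negative beyond the absolute tolerance (min %.3g); the system may be ill-posed", worst))
    }
    vals[neg] <- 0
    m[, -1] <- vals
  }
  m
}

#' Integrate the network ODE system at one temperature
#'
#' Solves the isothermal mass-action system from `y0` over the requested
#' heating times with a stiff solver. Small negative excursions (below the
#' absolute tolerance in magnitude) are clamped to zero; larger ones raise
#' an error.
#'
#' @param network An [mr_network()].
#' @param k Rate constants at the heating temperature (named vector, step
#'   tibble, or vector in step order); see [mr_ode_rhs()].
#' @param y0 Initial state, umol/kg dry matter; defaults to
#'   [mr_initial_state()] for the network.
#' @param times Sorted vector of heating times in minutes, starting at 0.
#' @param temperature_C Heating temperature label attached to the result.
#' @param rtol,atol Relative and absolute solver tolerances. Defaults
#'   1e-8 and 1e-6 umol/kg.
#' @param method deSolve integration method (default `"lsoda"`).
#' @return A tibble of class `mr_sim` in tidy long form with columns
#'   `time_min`, `species`, `concentration` (plus `temperature_C` when
#'   given), and solver settings stored as attributes.
#' @examples
#' net <- mr_network()
#' sim <- mr_simulate(net, mr_rate_constants(110), times = 0:5,
#'                    temperature_C = 110)
#' head(sim)
#' @export
mr_simulate <- function(network, k, y0 = mr_initial_state(network),
                        times, temperature_C = NA_real_,
                        rtol = 1e-8, atol = 1e-6, method = "lsoda") {
  stopifnot(inherits(network, "mr_network"))
  kv <- rate_vector(network, k)
  y <- state_vector(network, y0)
  if (any(y < 0)) abort("initial concentrations must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) abort("`times` must be strictly increasing")
  if (times[1] != 0) abort("`times` must start at 0")
  enc <- encode_network(network)
  m <- sim_matrix(enc, kv, y, as.numeric(times), rtol, atol, method)
  if (is.null(m)) {
    abort("ODE integration failed (step-size collapse or non-finite state); try tighter tolerances or check the rate constants")
  }
  m <- clamp_negatives(m, atol)
  out <- as_tibble(as.data.frame(m))
  names(out) <- c("time_min", enc$species)
  out <- tidyr::pivot_longer(out, -"time_min", names_to = "species",
                             values_to = "concentration")
  if (!is.na(temperature_C)) {
    out <- dplyr::mutate(out, temperature_C = temperature_C, .before = 1)
  }
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  attr(out, "method") <- method
  class(out) <- c("mr_sim", class(out))
  out
}

# Resolve a per-temperature rate-constant map or Arrhenius parameter set to
# a rate vector at the given temperature.
rates_at <- function(network, params, temperature_C) {
  if (inherits(params, "mr_arrhenius")) {
    k <- mr_arrhenius_rate(params, temperature_C = temperature_C)
  } else if (is.list(params) && !is.data.frame(params)) {
    key <- as.character(temperature_C)
    if (is.null(params[[key]])) {
      abort(sprintf("no rate constants supplied for %s degrees C", key))
    }
    k <- params[[key]]
  } else {
    k <- params
  }
  rate_vector(network, k)
}

#' Simulate the full experimental design
#'
#' Integrates one trajectory per design temperature, evaluated at the
#' design's sampling times plus `t = 0`.
#'
#' @param network An [mr_network()].
#' @param params Either an [mr_arrhenius()] parameter set (rate constants
#'   derived per temperature) or a named list mapping temperature
#'   (as character, e.g. `"110"`) to a rate-constant vector.
#' @param design An [mr_design()] tibble (`temperature_C`, `time_min`,
#'   `replicates`).
#' @param y0 Initial state shared by all temperatures.
#' @inheritParams mr_simulate
#' @return An `mr_sim` tibble with a `temperature_C` column.
#' @export
mr_simulate_design <- function(network, params, design = mr_design(),
                               y0 = mr_initial_state(network),
                               rtol = 1e-8, atol = 1e-6, method = "lsoda") {
  temps <- sort(unique(design$temperature_C))
  sims <- purrr::map(temps, function(tc) {
    tt <- sort(unique(c(0, design$time_min[design$temperature_C == tc])))
    mr_simulate(network, rates_at(network, params, tc), y0 = y0, times = tt,
                temperature_C = tc, rtol = rtol, atol = atol, method = method)
  })
  out <- dplyr::bind_rows(sims)
  attr(out, "rtol") <- rtol
  attr(out, "atol") <- atol
  class(out) <- unique(c("mr_sim", class(out)))
  out
}
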