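# Synthetic-data module: encodes the heating design and pasteurized-milk
# initial state of the study, and generates replicate-level datasets with a
# configurable noise model so every downstream stage is testable without
# laboratory data.

#' Heating design of the UHT study
#'
#' The default design encodes the laboratory heating protocol: 110 and
#' 120 degrees C sampled at 1--5 min, 130 degrees C at 1--3 min in 0.5 min
#' steps, 140 degrees C at 0.5--2.5 min, all in triplicate.
#'
#' @param temperatures_C Temperatures to keep (subset of the default) or,
#'   with `times`, a custom design.
#' @param times Optional named list mapping temperature to sampling times
#'   (min), overriding the default grid.
#' @param replicates Number of replicates per condition (>= 1).
#' @return A tibble with columns `temperature_C`, `time_min`, `replicates`.
#' @export
mr_design <- function(temperatures_C = c(110, 120, 130, 140),
                      times = NULL, replicates = 3) {
  if (replicates < 1) abort("`replicates` must be >= 1")
  default_times <- list(
    `110` = c(1, 2, 3, 4, 5),
    `120` = c(1, 2, 3, 4, 5),
    `130` = c(1, 1.5, 2, 2.5, 3),
    `140` = c(0.5, 1, 1.5, 2, 2.5)
  )
  if (is.null(times)) {
    keys <- as.character(temperatures_C)
    unknown <- setdiff(keys, names(default_times))
    if (length(unknown) > 0) {
      abort(paste0("no default sampling times for ", paste(unknown, collapse = ", "),
                   " degrees C; supply `times`"))
    }
    times <- default_times[keys]
  }
  purrr::imap_dfr(times, function(tt, temp) {
    tibble(temperature_C = as.numeric(temp), time_min = as.numeric(tt),
           replicates = as.integer(replicates))
  })
}

#' Initial state of pasteurized milk
#'
#' Concentrations measured in pasteurized milk before UHT heating, in
#' umol/kg dry matter: lactose 939150, total lysine 194670, 3-DG 17.19,
#' 1-DG 2.43, CML 0.14, CEL 0.24. All other species (including the Amadori
#' compound LacLys, whose pasteurized-milk level cannot be converted to a
#' dry-matter molar basis without the unreported protein fraction) default
#' to zero and can be overridden.
#'
#' @param network Network whose species the state should cover.
#' @param ... Named overrides, e.g. `LacLys = 50`. Negative values error.
#' @return Named numeric state vector over the network's species.
#' @export
mr_initial_state <- function(network = mr_network(), ...) {
  defaults <- c(Lac = 939150, Lys = 194670, `3DG` = 17.19, `1DG` = 2.43,
                CML = 0.14, CEL = 0.24)
  y <- stats::setNames(numeric(nrow(network$species)), network$species$name)
  keep <- intersect(names(defaults), names(y))
  y[keep] <- defaults[keep]
  overrides <- c(...)
  if (length(overrides) > 0) {
    unknown <- setdiff(names(overrides), names(y))
    if (length(unknown) > 0) {
      abort(paste0("unknown species in overrides: ", paste(unknown, collapse = ", ")))
    }
    if (any(overrides < 0)) abort("initial concentrations must be non-negative")
    y[names(overrides)] <- overrides
  }
  y
}

#' Replicate noise model
#'
#' Proportional Gaussian noise with an absolute floor: an observation with
#' model value `mu` is drawn from `N(mu, sd)` with
#' `sd = max(cv * mu, floor_sd)`, resampled until non-negative. The 7%
#' default coefficient of variation reflects triplicate scatter typical of
#' the chromatographic assays across species spanning seven orders of
#' magnitude; the floor keeps near-zero trace species from becoming
#' noise-free.
#'
#' @param cv Coefficient of variation (>= 0), default 0.07.
#' @param floor_sd Absolute standard-deviation floor in umol/kg, default 0.05.
#' @return A list of class `mr_noise`.
#' @export
mr_noise_model <- function(cv = 0.07, floor_sd = 0.05) {
  if (cv < 0 || floor_sd < 0) abort("`cv` and `floor_sd` must be non-negative")
  structure(list(type = "proportional-gaussian", cv = cv, floor_sd = floor_sd),
            class = "mr_noise")
}

apply_noise <- function(mu, noise) {
  sd <- pmax(noise$cv * mu, noise$floor_sd)
  if (all(sd == 0)) return(mu)
  x <- stats::rnorm(length(mu), mu, sd)
  bad <- which(x < 0)
  tries <- 0L
  while (length(bad) > 0 && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sd[bad])
    bad <- bad[x[bad] < 0]
    tries <- tries + 1L
  }
  x[x < 0] <- 0 # pathological sd >> mu: truncate rather than loop forever
  x
}

#' Generate a replicate-level synthetic kinetic dataset
#'
#' Simulates the network over the design, evaluates the trajectories at the
#' sampling times, and adds independent replicate noise per
#' (temperature, time, replicate, species) cell. Only measured species are
#' reported. With `cv = 0` and `floor_sd = 0` the dataset equals the
#' noise-free model values exactly; for a fixed seed the dataset is
#' reproducible.
#'
#' @param design An [mr_design()] tibble.
#' @param params Per-temperature rate constants (named list) or an
#'   [mr_arrhenius()] set; see [mr_simulate_design()].
#' @param y0 Initial state.
#' @param noise An [mr_noise_model()].
#' @param seed Integer seed for the noise realization.
#' @param network The generating [mr_network()].
#' @param include_t0 Include `t = 0` baseline rows (noise-free initial
#'   state observed with the same noise model).
#' @param rtol,atol Solver tolerances passed to [mr_simulate_design()].
#' @return A tibble of class `mr_dataset` with columns `temperature_C`,
#'   `time_min`, `replicate`, `species`, `concentration`; the seed, noise
#'   model and generating parameters are stored as attributes.
#' @examples
#' ds <- mr_generate_dataset(mr_design(140), list(`140` = mr_rate_constants(140)),
#'                           seed = 1)
#' dplyr::count(ds, species)
#' @export
mr_generate_dataset <- function(design = mr_design(),
                                params,
                                y0 = mr_initial_state(network),
                                noise = mr_noise_model(),
                                seed = 1L,
                                network = mr_network(),
                                include_t0 = TRUE,
                                rtol = 1e-8, atol = 1e-6) {
  sim <- mr_simulate_design(network, params, design, y0 = y0,
                            rtol = rtol, atol = atol)
  measured <- network$species$name[network$species$measured]
  sim <- sim[sim$species %in% measured, ]
  keys <- dplyr::distinct(design, .data$temperature_C, .data$replicates)

  grid <- design |>
    dplyr::select("temperature_C", "time_min") |>
    dplyr::distinct()
  if (include_t0) {
    grid <- dplyr::bind_rows(
      tibble(temperature_C = unique(design$temperature_C), time_min = 0),
      grid
    ) |> dplyr::arrange(.data$temperature_C, .data$time_min)
  }
  obs <- grid |>
    dplyr::inner_join(sim, by = c("temperature_C", "time_min")) |>
    dplyr::inner_join(keys, by = "temperature_C") |>
    tidyr::uncount(.data$replicates, .id = "replicate") |>
    dplyr::select("temperature_C", "time_min", "replicate", "species",
                  mu = "concentration") |>
    dplyr::arrange(.data$temperature_C, .data$time_min, .data$replicate,
                   .data$species)

  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  obs$concentration <- apply_noise(obs$mu, noise)
  out <- dplyr::select(obs, -"mu")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "noise") <- noise
  attr(out, "params") <- params
  class(out) <- c("mr_dataset", class(out))
  out
}
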