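# CSV readers/writers for kinetic datasets and trajectories.
# Dialect: '.' decimal separator, no thousands separators, UTF-8, header
# row. Temperatures are degrees C in files (kelvin only ever appears
# internally). A sidecar JSON records the seed and noise settings of
# generated datasets.

DATASET_COLUMNS <- c("temperature_C", "time_min", "replicate", "species",
                     "concentration_umol_per_kg_dm")

#' Write a kinetic dataset to CSV
#'
#' @param dataset A dataset tibble (`temperature_C`, `time_min`,
#'   `replicate`, `species`, `concentration`), e.g. from
#'   [mr_generate_dataset()].
#' @param path Output CSV path.
#' @param metadata_path Sidecar JSON path for seed/noise metadata;
#'   `NULL` suppresses it. Defaults to `<path>.json` when the dataset
#'   carries generation metadata.
#' @return `path`, invisibly.
#' @export
mr_write_dataset <- function(dataset, path, metadata_path = NULL) {
  out <- dataset |>
    dplyr::select("temperature_C", "time_min", "replicate", "species",
                  concentration_umol_per_kg_dm = "concentration")
  readr::write_csv(out, path)
  seed <- attr(dataset, "seed")
  if (is.null(metadata_path) && !is.null(seed)) {
    metadata_path <- paste0(path, ".json")
  }
  if (!is.null(metadata_path) && !is.null(seed)) {
    noise <- attr(dataset, "noise")
    meta <- list(seed = seed,
                 noise = list(type = noise$type, cv = noise$cv,
                              floor_sd = noise$floor_sd),
                 n_rows = nrow(dataset),
                 package_version = as.character(utils::packageVersion("maillardkin")))
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a kinetic dataset CSV
#'
#' Checks the header, rejects unknown species (naming the allowed set),
#' negative concentrations (naming the offending row), and duplicate
#' (temperature, time, replicate, species) keys.
#'
#' @param path CSV path written by [mr_write_dataset()] or following the
#'   same layout.
#' @param network Network defining the allowed (measured) species names.
#' @return A validated tibble with columns `temperature_C`, `time_min`,
#'   `replicate`, `species`, `concentration`.
#' @export
mr_read_dataset <- function(path, network = mr_network()) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- raw |>
    dplyr::select(dplyr::all_of(DATASET_COLUMNS)) |>
    dplyr::rename(concentration = "concentration_umol_per_kg_dm")
  allowed <- network$species$name[network$species$measured]
  bad_species <- setdiff(unique(out$species), allowed)
  if (length(bad_species) > 0) {
    abort(paste0("unknown species: ", paste(bad_species, collapse = ", "),
                 "; allowed species are: ", paste(allowed, collapse = ", ")))
  }
  if (anyNA(out$concentration)) {
    abort(paste0("non-numeric or missing concentration at data row(s): ",
                 paste(which(is.na(out$concentration)), collapse = ", ")))
  }
  neg <- which(out$concentration < 0)
  if (length(neg) > 0) {
    abort(paste0("negative concentration at data row(s): ",
                 paste(neg, collapse = ", ")))
  }
  dup <- duplicated(out[, c("temperature_C", "time_min", "replicate", "species")])
  if (any(dup)) {
    abort(paste0("duplicate (temperature, time, replicate, species) key at row(s): ",
                 paste(which(dup), collapse = ", ")))
  }
  class(out) <- c("mr_dataset", class(out))
  out
}

#' Write simulated trajectories to tidy CSV
#'
#' @param sim An `mr_sim` tibble from [mr_simulate()] or
#'   [mr_simulate_design()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
mr_write_trajectories <- function(sim, path) {
  cols <- intersect(c("temperature_C", "time_min", "species"), names(sim))
  out <- sim |>
    dplyr::select(dplyr::all_of(cols),
                  concentration_umol_per_kg_dm = "concentration")
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a fit as a JSON report
#'
#' Serializes the estimates, HPD intervals, identifiability flags,
#' correlation matrix and convergence log of an [mr_fit_rates()] /
#' [mr_fit_arrhenius()] result.
#'
#' @param fit An `mr_fit` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
mr_write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mr_fit"))
  payload <- list(
    type = fit$type,
    temperature_C = fit$temperature_C,
    estimates = fit$estimates,
    objective = fit$objective,
    log_objective = fit$log_objective,
    correlation = fit$correlation,
    strong_pairs = fit$strong_pairs,
    convergence = fit$convergence[c("status", "iterations", "seed", "starts_used")],
    n_obs = fit$n_obs, n_responses = fit$n_responses
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Serialize a reaction network to YAML
#'
#' Writes the species (name, measured) and elementary steps (index,
#' reactants, products) of a network to a structured text file. Moiety
#' tags are not stored; they are recomputed from the steps on read.
#'
#' @param network An [mr_network()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
mr_write_network <- function(network, path) {
  stopifnot(inherits(network, "mr_network"))
  payload <- list(
    variant = network$variant,
    species = lapply(seq_len(nrow(network$species)), function(i) {
      list(name = network$species$name[i],
           measured = network$species$measured[i])
    }),
    steps = lapply(seq_len(nrow(network$steps)), function(i) {
      list(index = network$steps$index[i],
           reactants = as.list(network$steps$reactants[[i]]),
           products = as.list(network$steps$products[[i]]))
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' Read a reaction network from YAML
#'
#' @param path A YAML file written by [mr_write_network()] (the packaged
#'   proposed-model file lives at
#'   `system.file("extdata", "proposed_network.yaml", package = "maillardkin")`).
#' @return A validated [mr_network()].
#' @export
mr_read_network <- function(path) {
  raw <- yaml::read_yaml(path)
  species <- tibble(
    name = vapply(raw$species, function(s) as.character(s$name), character(1)),
    measured = vapply(raw$species, function(s) isTRUE(s$measured), logical(1))
  )
  steps <- tibble(
    index = vapply(raw$steps, function(s) as.integer(s$index), integer(1)),
    reactants = lapply(raw$steps, function(s) as.character(unlist(s$reactants))),
    products = lapply(raw$steps, function(s) as.character(unlist(s$products)))
  )
  variant <- if (is.null(raw$variant)) "custom" else raw$variant
  validate_mr_network(new_mr_network(variant, species, steps))
}
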