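# Shared fixtures. Expensive fits are computed lazily and cached so that
# several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Single-step first-order decay network: Lac -> P1, only Lac measured.
decay_network <- function() {
  mr_network(
    "custom",
    species = tibble::tibble(name = c("Lac", "P1"),
                             measured = c(TRUE, FALSE)),
    steps = tibble::tibble(index = 1L, reactants = list("Lac"),
                           products = list("P1"))
  )
}

# Two independent decays (orthogonal parameters): Lac -> P1, Lys -> P10.
two_decay_network <- function() {
  mr_network(
    "custom",
    species = tibble::tibble(name = c("Lac", "Lys", "P1", "P10"),
                             measured = c(TRUE, TRUE, FALSE, FALSE)),
    steps = tibble::tibble(index = 1:2,
                           reactants = list("Lac", "Lys"),
                           products = list("P1", "P10"))
  )
}

# Reversible isomerization with an unmeasured intermediate plus a sink,
# mirroring the lactose <-> Int steps: parameters strongly correlated.
lac_int_network <- function() {
  mr_network(
    "custom",
    species = tibble::tibble(name = c("Lac", "Int", "P1"),
                             measured = c(TRUE, FALSE, FALSE)),
    steps = tibble::tibble(index = 1:3,
                           reactants = list("Lac", "Int", "Lac"),
                           products = list("Int", "Lac", "P1"))
  )
}

# Duplicated step: two identical Lac -> P1 reactions, exactly
# non-identifiable individually.
duplicated_step_network <- function() {
  mr_network(
    "custom",
    species = tibble::tibble(name = c("Lac", "P1"),
                             measured = c(TRUE, FALSE)),
    steps = tibble::tibble(index = 1:2,
                           reactants = list("Lac", "Lac"),
                           products = list("P1", "P1"))
  )
}

# A small design reused by the reduced-network fits.
small_design <- function(temperature_C = 140, times = c(1, 2, 3, 4, 5),
                         replicates = 3) {
  mr_design(temperature_C,
            times = stats::setNames(list(times), temperature_C),
            replicates = replicates)
}

# Noise-free dataset generated from the reference constants at one
# temperature.
reference_dataset <- function(temperature_C, seed = 1,
                              noise = mr_noise_model(cv = 0, floor_sd = 0)) {
  k <- mr_rate_constants(temperature_C)
  mr_generate_dataset(mr_design(temperature_C),
                      stats::setNames(list(k), temperature_C),
                      noise = noise, seed = seed)
}

# Noise-free per-temperature recovery fit from 3x-perturbed starts,
# cached per temperature (reused by several acceptance criteria).
reference_recovery_fit <- function(temperature_C, uncertainty = FALSE) {
  key <- paste0("fit", temperature_C, if (uncertainty) "_unc")
  cached(key, {
    k_true <- mr_rate_constants(temperature_C)
    ds <- reference_dataset(temperature_C)
    mr_fit_rates(ds, mr_network(), temperature_C, init = k_true * 3,
                 starts = 2, seed = 1, compute_uncertainty = uncertainty)
  })
}
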