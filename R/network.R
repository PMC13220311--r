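#' @useDynLib maillardkin, .registration = TRUE
#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Canonical species of the Maillard network in UHT-heated milk.
# The 11 measured species are the responses of the multiresponse fit;
# Int (the transient lactose isomerization intermediate) and the product
# sinks P1..P10 are simulated but never enter the residual matrix.
MEASURED_SPECIES <- c("Lac", "Lys", "LacLys", "3DG", "1DG", "G",
                      "DA", "MGO", "GO", "CML", "CEL")

core_step_table <- function() {
  tibble::tribble(
    ~index, ~r1,      ~r2,   ~product,
    1L,     "Lac",    "Lys", "LacLys",
    2L,     "LacLys", NA,    "3DG",
    3L,     "LacLys", NA,    "1DG",
    4L,     "LacLys", NA,    "G",
    5L,     "LacLys", NA,    "CML",
    6L,     "LacLys", NA,    "CEL",
    7L,     "LacLys", NA,    "GO",
    8L,     "1DG",    NA,    "DA",
    9L,     "1DG",    NA,    "MGO",
    10L,    "G",      NA,    "GO",
    11L,    "GO",     "Lys", "CML",
    12L,    "MGO",    "Lys", "CEL",
    13L,    "Lac",    NA,    "Int",
    14L,    "Int",    NA,    "Lac",
    15L,    "Lac",    NA,    "P1",
    16L,    "LacLys", NA,    "P2",
    17L,    "3DG",    NA,    "P3",
    18L,    "1DG",    NA,    "P4",
    19L,    "G",      NA,    "P5",
    20L,    "MGO",    NA,    "P6",
    21L,    "GO",     NA,    "P7",
    22L,    "CML",    NA,    "P8",
    23L,    "CEL",    NA,    "P9",
    24L,    "Lys",    NA,    "P10"
  )
}

# Candidate steps examined (and ultimately rejected) during model
# discrimination: lactulose enolization, the lactosone/1-deoxylactosone
# route, a free-glucose intermediate, an explicit Heyns intermediate, and
# diacetyl degradation.  Grouped into named hypothesis blocks.
optional_step_table <- function() {
  tibble::tribble(
    ~block,            ~index, ~r1,      ~r2,           ~product,
    "lactulose",       25L,    "Lac",    NA_character_, "Lu",
    "lactulose",       26L,    "Lu",     NA_character_, "Lac",
    "lactulose",       27L,    "Lu",     NA_character_, "P11",
    "lactosone",       28L,    "Lac",    NA_character_, "Lon",
    "lactosone",       29L,    "Lon",    NA_character_, "GO",
    "lactosone",       30L,    "Lac",    NA_character_, "dLon",
    "lactosone",       31L,    "dLon",   NA_character_, "DA",
    "glucose",         32L,    "Lac",    NA_character_, "Glc",
    "glucose",         33L,    "Glc",    NA_character_, "3DG",
    "heyns",           34L,    "LacLys", NA_character_, "Hey",
    "heyns",           35L,    "Hey",    NA_character_, "CEL",
    "da_degradation",  36L,    "DA",     NA_character_, "P12"
  )
}

#' Build a Maillard reaction network
#'
#' Constructs the mass-action reaction network used throughout the package:
#' species, elementary reaction steps (all with unit stoichiometry), and the
#' conserved-moiety tags derived from them. The `"proposed"` variant is the
#' 24-step network retained after model discrimination (lactose + lysine
#' condensation to lactulosyllysine, Amadori degradation to the
#' alpha-dicarbonyls 3-DG, 1-DG, G, DA, MGO and GO, AGE formation to CML and
#' CEL, the reversible lactose isomerization through an unmeasured
#' intermediate, and first-order elimination of each species to product
#' sinks P1--P10). The `"comprehensive"` variant adds the candidate hypothesis
#' blocks that discrimination examined: a lactulose enolization route, the
#' lactosone/1-deoxylactosone route, a free-glucose intermediate, an explicit
#' Heyns intermediate, and diacetyl degradation.
#'
#' @param variant `"proposed"`, `"comprehensive"`, or `"custom"`.
#' @param include Character vector of optional hypothesis blocks to add to the
#'   proposed network: any of `"lactulose"`, `"lactosone"`, `"glucose"`,
#'   `"heyns"`, `"da_degradation"`.
#' @param exclude Integer vector of step indices to remove.
#' @param regenerate_lysine If `TRUE`, the Amadori degradation steps to the
#'   dicarbonyls (LacLys to 3-DG/1-DG/G/GO) release free lysine as a second
#'   product, mirroring the amino-acid regeneration chemistry of Amadori
#'   breakdown. The default network does not regenerate lysine, consistent
#'   with the observed net lysine loss.
#' @param species,steps For `variant = "custom"`: a species tibble
#'   (`name`, `measured`) and a step tibble (`index`, `reactants` list-column,
#'   `products` list-column).
#' @return An object of class `mr_network`: a list with tibbles `species`
#'   (name, measured, sugar/lysine moiety tags) and `steps` (index, reactants,
#'   products, order, rate_symbol), plus the variant label.
#' @examples
#' net <- mr_network()
#' net$steps
#' mr_network("proposed", exclude = 14) # drop the Int -> Lac back-reaction
#' @export
mr_network <- function(variant = c("proposed", "comprehensive", "custom"),
                       include = character(), exclude = integer(),
                       regenerate_lysine = FALSE,
                       species = NULL, steps = NULL) {
  variant <- match.arg(variant)

  if (variant == "custom") {
    if (is.null(species) || is.null(steps)) {
      abort("variant = \"custom\" requires both `species` and `steps`")
    }
    net <- new_mr_network("custom", as_tibble(species), as_tibble(steps))
    return(validate_mr_network(net, drop_orphans = FALSE))
  }

  opt <- optional_step_table()
  if (variant == "comprehensive") include <- unique(opt$block)
  bad_block <- setdiff(include, unique(opt$block))
  if (length(bad_block) > 0) {
    abort(paste0("unknown optional step block(s): ",
                 paste(bad_block, collapse = ", ")))
  }

  raw <- dplyr::bind_rows(
    core_step_table(),
    opt[opt$block %in% include, c("index", "r1", "r2", "product")]
  )
  if (length(exclude) > 0) {
    missing_idx <- setdiff(as.integer(exclude), raw$index)
    if (length(missing_idx) > 0) {
      abort(paste0("cannot exclude nonexistent step(s): ",
                   paste(missing_idx, collapse = ", ")))
    }
    raw <- raw[!raw$index %in% as.integer(exclude), ]
  }

  steps_tbl <- tibble(
    index = raw$index,
    reactants = purrr::map2(raw$r1, raw$r2, function(a, b) {
      if (is.na(b)) a else c(a, b)
    }),
    products = as.list(raw$product)
  )
  if (regenerate_lysine) {
    # Amadori breakdown to a dicarbonyl releases the amino acid; the AGE
    # routes (LacLys -> CML/CEL) retain the lysine in the product.
    regen <- raw$r1 == "LacLys" &
      vapply(steps_tbl$products, function(p) {
        p[1] %in% c("3DG", "1DG", "G", "GO")
      }, logical(1))
    steps_tbl$products[regen] <-
      lapply(steps_tbl$products[regen], function(p) c(p, "Lys"))
  }
  steps_tbl$order <- lengths(steps_tbl$reactants)
  steps_tbl$rate_symbol <- paste0("k", steps_tbl$index)

  used <- unique(c(unlist(steps_tbl$reactants), unlist(steps_tbl$products)))
  species_tbl <- tibble(
    name = used[order(match(used, MEASURED_SPECIES), used)],
    measured = used[order(match(used, MEASURED_SPECIES), used)] %in% MEASURED_SPECIES
  )

  net <- new_mr_network(variant, species_tbl, steps_tbl)
  validate_mr_network(net, drop_orphans = FALSE)
}

new_mr_network <- function(variant, species, steps) {
  if (!all(c("index", "reactants", "products") %in% names(steps))) {
    abort("`steps` must have columns index, reactants, products")
  }
  if (!"order" %in% names(steps)) steps$order <- lengths(steps$reactants)
  if (!"rate_symbol" %in% names(steps)) steps$rate_symbol <- paste0("k", steps$index)
  if (!"measured" %in% names(species)) species$measured <- species$name %in% MEASURED_SPECIES
  unknown <- setdiff(unique(c(unlist(steps$reactants), unlist(steps$products))),
                     species$name)
  if (length(unknown) > 0) {
    abort(paste0("steps reference unknown species: ",
                 paste(unknown, collapse = ", ")))
  }
  tags <- moiety_closure(species$name, steps)
  species$sugar <- tags$sugar
  species$lysine <- tags$lysine
  structure(
    list(variant = variant, species = species, steps = steps),
    class = "mr_network"
  )
}

# Propagate moiety tags to a fixed point: Lac seeds the sugar pool, Lys the
# lysine pool. For each step and moiety, if a reactant carries the moiety
# and no product does yet, the primary (first-listed) product inherits it;
# a co-product that already carries the moiety (e.g. regenerated Lys)
# absorbs it instead. With unit stoichiometry every unimolecular step is
# then exactly moiety-conserving; bimolecular condensations conserve a tag
# only when a single reactant carries it (see the methods vignette).
moiety_closure <- function(names, steps) {
  tag <- list(sugar = names == "Lac", lysine = names == "Lys")
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(steps))) {
      r <- match(steps$reactants[[i]], names)
      p <- match(steps$products[[i]], names)
      for (m in c("sugar", "lysine")) {
        if (any(tag[[m]][r]) && !any(tag[[m]][p])) {
          tag[[m]][p[1]] <- TRUE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  tag
}

validate_mr_network <- function(net, drop_orphans = FALSE) {
  sp <- net$species
  st <- net$steps
  if (anyDuplicated(sp$name)) abort("species names must be unique")
  if (anyDuplicated(st$index)) abort("step indices must be unique")
  referenced <- unique(c(unlist(st$reactants), unlist(st$products)))
  unknown <- setdiff(referenced, sp$name)
  if (length(unknown) > 0) {
    abort(paste0("steps reference unknown species: ",
                 paste(unknown, collapse = ", ")))
  }
  orphan <- setdiff(sp$name, referenced)
  if (length(orphan) > 0) {
    abort(paste0("network has orphan species: ", paste(orphan, collapse = ", ")))
  }
  bad_order <- st$order != lengths(st$reactants) | !st$order %in% c(1L, 2L)
  if (any(bad_order)) {
    abort(paste0("reaction order must equal the number of reactants (1 or 2); ",
                 "offending step(s): ", paste(st$index[bad_order], collapse = ", ")))
  }
  net
}

#' @export
print.mr_network <- function(x, ...) {
  cat(sprintf("<mr_network: %s>\n", x$variant))
  cat(sprintf("  %d species (%d measured), %d reaction steps\n",
              nrow(x$species), sum(x$species$measured), nrow(x$steps)))
  eq <- vapply(seq_len(nrow(x$steps)), function(i) {
    paste0(paste(x$steps$reactants[[i]], collapse = " + "), " -> ",
           paste(x$steps$products[[i]], collapse = " + "))
  }, character(1))
  cat(paste0("  ", format(x$steps$rate_symbol), "  ", eq, collapse = "\n"), "\n")
  invisible(x)
}

# Stoichiometry matrix (species x steps): -1 per consumed reactant,
# +1 per produced species, net per step.
stoichiometry_matrix <- function(network) {
  sp <- network$species$name
  st <- network$steps
  S <- matrix(0, nrow = length(sp), ncol = nrow(st),
              dimnames = list(sp, st$rate_symbol))
  for (j in seq_len(nrow(st))) {
    for (r in st$reactants[[j]]) S[r, j] <- S[r, j] - 1
    for (p in st$products[[j]]) S[p, j] <- S[p, j] + 1
  }
  S
}

# Reaction description strings in step order, e.g. "Lac + Lys -> LacLys".
reaction_labels <- function(network) {
  st <- network$steps
  vapply(seq_len(nrow(st)), function(i) {
    paste0(paste(st$reactants[[i]], collapse = " + "), " -> ",
           paste(st$products[[i]], collapse = " + "))
  }, character(1))
}

# Coerce a rate-constant specification (named vector, step-indexed vector, or
# tibble with columns step/k) to a full numeric vector in network step order.
rate_vector <- function(network, k) {
  idx <- network$steps$index
  if (is.data.frame(k)) {
    if (!all(c("step", "k") %in% names(k))) {
      abort("a rate-constant data frame needs columns `step` and `k`")
    }
    v <- k$k[match(idx, k$step)]
  } else if (!is.null(names(k))) {
    nm <- names(k)
    nm <- sub("^k", "", nm)
    v <- unname(k[match(as.character(idx), nm)])
  } else if (length(k) == length(idx)) {
    v <- as.numeric(k)
  } else {
    v <- rep(NA_real_, length(idx))
  }
  if (anyNA(v)) {
    abort(paste0("missing rate constant for step(s): ",
                 paste(idx[is.na(v)], collapse = ", ")))
  }
  if (any(v < 0)) abort("rate constants must be non-negative")
  stats::setNames(as.numeric(v), paste0("k", idx))
}

state_vector <- function(network, state) {
  sp <- network$species$name
  if (is.null(names(state))) {
    if (length(state) != length(sp)) {
      abort("unnamed state must have one entry per network species")
    }
    return(stats::setNames(as.numeric(state), sp))
  }
  v <- stats::setNames(numeric(length(sp)), sp)
  unknown <- setdiff(names(state), sp)
  if (length(unknown) > 0) {
    abort(paste0("state names not in the network: ",
                 paste(unknown, collapse = ", ")))
  }
  v[names(state)] <- as.numeric(state)
  v
}

#' Mass-action derivative of a network state
#'
#' Evaluates the right-hand side of the network ODE system: each step
#' contributes a flux `k_i * [reactant]` (first order) or
#' `k_i * [reactant1] * [reactant2]` (second order), and every species'
#' derivative is the signed sum over the steps consuming or producing it.
#' This is the plain-R reference implementation; [mr_simulate()] integrates
#' the same system through a compiled equivalent.
#'
#' @param network An [mr_network()].
#' @param k Rate constants: named vector (`k1`, `k2`, ...), tibble with
#'   columns `step`/`k`, or an unnamed vector in step order. Units are
#'   min^-1 for first-order steps and kg umol^-1 min^-1 for second-order
#'   steps.
#' @param state Named non-negative concentration vector (umol/kg dry matter).
#' @return Named derivative vector, umol kg^-1 min^-1, one entry per species.
#' @examples
#' net <- mr_network()
#' y0 <- mr_initial_state(net)
#' mr_ode_rhs(net, mr_rate_constants(110), y0)
#' @export
mr_ode_rhs <- function(network, k, state) {
  stopifnot(inherits(network, "mr_network"))
  kv <- rate_vector(network, k)
  y <- state_vector(network, state)
  if (any(y < 0)) abort("state concentrations must be non-negative")
  st <- network$steps
  flux <- vapply(seq_len(nrow(st)), function(j) {
    r <- st$reactants[[j]]
    kv[j] * prod(y[r])
  }, numeric(1))
  drop(stoichiometry_matrix(network) %*% flux)
}

#' Conserved-moiety totals of a state or trajectory
#'
#' Sums concentrations over the sugar-tagged and lysine-tagged species
#' pools. Tags are the moiety closure of the network (every species
#' downstream of lactose carries the sugar tag, every species downstream of
#' lysine the lysine tag), so the sugar total is an exact invariant of the
#' proposed network and the lysine total is exact up to the bimolecular
#' AGE-condensation steps (GO + Lys and MGO + Lys), each of which retires
#' one extra lysine equivalent into the untracked pool.
#'
#' @param network An [mr_network()].
#' @param x A named state vector, or a long trajectory tibble as returned by
#'   [mr_simulate()] (columns `time_min`, `species`, `concentration`).
#' @return A tibble with columns `moiety` and `total` (and `time_min`,
#'   `temperature_C` when `x` is a trajectory).
#' @export
mr_moiety_totals <- function(network, x) {
  stopifnot(inherits(network, "mr_network"))
  sp <- network$species
  if (is.data.frame(x)) {
    grp <- intersect(c("temperature_C", "time_min"), names(x))
    x |>
      dplyr::left_join(sp[, c("name", "sugar", "lysine")],
                       by = c(species = "name")) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::summarise(
        sugar = sum(.data$concentration[.data$sugar]),
        lysine = sum(.data$concentration[.data$lysine]),
        .groups = "drop"
      ) |>
      tidyr::pivot_longer(c("sugar", "lysine"),
                          names_to = "moiety", values_to = "total")
  } else {
    y <- state_vector(network, x)
    tibble(
      moiety = c("sugar", "lysine"),
      total = c(sum(y[sp$name[sp$sugar]]), sum(y[sp$name[sp$lysine]]))
    )
  }
}
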