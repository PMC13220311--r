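# Multiresponse estimation by the Box-Draper determinant criterion.
#
# The residual matrix Z has one row per (temperature, time, replicate)
# observation vector and one column per measured response; the objective is
# det(Z'Z), which generalizes least squares to several responses and is
# invariant to per-response rescaling -- no weighting is needed even though
# the responses span seven orders of magnitude. Internally the fit works
# with log det(Z'Z) of a column-rescaled Z (a constant shift, same
# minimizer, better conditioning), and with log-transformed rate constants
# so positivity is structural. Uncertainty comes from a Laplace
# approximation of the Box-Draper posterior p(theta | Y) ~ |Z'Z|^(-n/2):
# cov = (2 / (n - p)) * H^-1 with H the Gauss-Newton Hessian of
# log det(Z'Z) at the optimum, which reduces to the classical t-based
# interval in the single-response linear case.

#' Box-Draper determinant objective
#'
#' Computes `det(Z'Z)` for a residual matrix `Z` (observations x
#' responses). For a single response this is the residual sum of squares;
#' the value is invariant under row permutation and scales as `c^2` when
#' one response column is multiplied by `c`.
#'
#' @param Z Numeric matrix of residuals (observed minus predicted), rows
#'   aligned across responses per observation vector. Needs at least as
#'   many rows as columns.
#' @return The determinant of the residual cross-product matrix (>= 0 up
#'   to rounding).
#' @examples
#' mr_determinant_objective(cbind(c(1, 0, 0), c(0, 1, 0)))
#' @export
mr_determinant_objective <- function(Z) {
  Z <- as.matrix(Z)
  if (!is.numeric(Z)) abort("`Z` must be numeric")
  if (nrow(Z) < ncol(Z)) {
    abort("need at least as many observation rows as responses")
  }
  zero_col <- colSums(abs(Z)) == 0
  if (any(zero_col) && any(!zero_col)) {
    warn(paste0("degenerate residual matrix: all-zero response column(s) ",
                paste(which(zero_col), collapse = ", "),
                "; the determinant objective is identically zero"))
  }
  det(crossprod(Z))
}

# ---- internal fitting machinery ------------------------------------------

# Per-response default parameter scales used for bounds and zero-handling
# when the initial value is zero.
default_k_scale <- function(order) ifelse(order == 2, 1e-9, 1e-3)

# Align the dataset into per-temperature observation blocks: a complete-case
# wide matrix of responses plus the solver time grid and row-to-time map.
prepare_blocks <- function(dataset, network, temperatures_C, use_t0 = TRUE,
                           responses = NULL) {
  measured <- network$species$name[network$species$measured]
  if (is.null(responses)) {
    responses <- intersect(measured, unique(dataset$species))
  } else {
    bad <- setdiff(responses, measured)
    if (length(bad) > 0) {
      abort(paste0("responses not measured in this network: ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (length(responses) == 0) abort("dataset contains no measured species")

  blocks <- list()
  dropped <- 0L
  for (tc in temperatures_C) {
    sub <- dataset[dataset$temperature_C == tc &
                     dataset$species %in% responses, ]
    if (!use_t0) sub <- sub[sub$time_min > 0, ]
    if (nrow(sub) == 0) {
      abort(sprintf("dataset has no observations at %s degrees C", tc))
    }
    wide <- tidyr::pivot_wider(sub[, c("time_min", "replicate", "species",
                                       "concentration")],
                               names_from = "species",
                               values_from = "concentration")
    cc <- stats::complete.cases(wide)
    dropped <- dropped + sum(!cc)
    wide <- wide[cc, ]
    times <- sort(unique(c(0, wide$time_min)))
    blocks[[as.character(tc)]] <- list(
      temperature_C = tc,
      times = times,
      time_idx = match(wide$time_min, times),
      obs = as.matrix(wide[, responses, drop = FALSE])
    )
  }
  if (dropped > 0) {
    rlang::inform(sprintf(
      "dropped %d observation row(s) with missing responses (complete-case)",
      dropped))
  }
  n_obs <- sum(vapply(blocks, function(b) nrow(b$obs), integer(1)))
  if (n_obs < length(responses)) {
    abort("fewer observation rows than responses; the determinant criterion is undefined")
  }
  all_obs <- do.call(rbind, lapply(blocks, `[[`, "obs"))
  col_scale <- 1 / pmax(colMeans(abs(all_obs)), 1e-12)
  list(blocks = blocks, responses = responses, col_scale = col_scale,
       n_obs = n_obs)
}

# Stacked predictions at the observation rows: list of matrices aligned
# with the blocks' obs, or NULL on solver failure.
stacked_pred <- function(prep, enc, y0, klist, rtol, atol) {
  col_idx <- match(prep$responses, enc$species)
  out <- vector("list", length(prep$blocks))
  for (i in seq_along(prep$blocks)) {
    b <- prep$blocks[[i]]
    m <- sim_matrix(enc, klist[[i]], y0, b$times, rtol, atol)
    if (is.null(m)) return(NULL)
    out[[i]] <- m[b$time_idx, col_idx + 1L, drop = FALSE]
  }
  out
}

# log det(Z'Z) of the column-rescaled stacked residual matrix; +Inf on
# solver failure so the optimizer backs away.
stacked_logdet <- function(prep, enc, y0, klist, rtol, atol,
                           return_Z = FALSE) {
  preds <- stacked_pred(prep, enc, y0, klist, rtol, atol)
  if (is.null(preds)) return(if (return_Z) NULL else Inf)
  Z <- do.call(rbind, purrr::map2(prep$blocks, preds,
                                  function(b, p) b$obs - p))
  if (return_Z) return(Z)
  G <- crossprod(sweep(Z, 2, prep$col_scale, `*`))
  # Regularized log-determinant: sum log(eigenvalue + eps) with eps at the
  # squared relative-accuracy scale of the (unit-rescaled) responses. For
  # well-conditioned residual matrices this is log det(Z'Z) to rounding;
  # when Z is rank-deficient (noise-free replicates give fewer distinct
  # rows than responses, so det(Z'Z) is identically zero) it degrades
  # gracefully to a pseudo-determinant over the informative eigenvalues,
  # keeping the criterion smooth and minimized at the generating values.
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  eps_reg <- nrow(Z) * 1e-8
  sum(log(pmax(ev, 0) + eps_reg))
}

# Forward-difference gradient with a step (in log-parameter space) chosen
# well above the objective's numerical noise floor.
fd_gradient <- function(objective, h = 1e-4) {
  function(theta) {
    f0 <- objective(theta)
    vapply(seq_along(theta), function(i) {
      tp <- theta
      tp[i] <- tp[i] + h
      (objective(tp) - f0) / h
    }, numeric(1))
  }
}

with_preserved_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Multi-stage estimation engine shared by the per-temperature and global
# fits. The determinant-criterion surface of a sloppy reaction network is
# a narrow curved valley that defeats plain local optimization, so:
#   stage 1 - seeded multistart Levenberg-Marquardt, first on
#     log-concentration residuals (rates act nearly log-linearly, species
#     are equalized) and then on linearly rescaled residuals; for
#     noise-free data both surrogates share the determinant criterion's
#     global minimum at the generating parameters;
#   stage 2 - continuation along the sloppy valley: random long-range
#     probes in the subspace of the smallest singular vectors of the
#     residual Jacobian, each polished by LM, accepted when the deviance
#     improves;
#   stage 3 - a short quasi-Newton polish of the regularized
#     log-determinant itself, so the reported optimum is a stationary
#     point of the Box-Draper criterion proper (this is where the
#     estimator differs from least squares on noisy data).
engine_fit <- function(resid_fn, lresid_fn, logdet_fn, theta0, lower, upper,
                       starts, seed, perturb, control = list()) {
  opts <- utils::modifyList(
    list(lm_maxiter = 300, rounds = 15, probes = 300, subspace = 8,
         probe_radius = 8, fails_max = 3, dev_floor = 1e-9,
         polish_iter = 150),
    control
  )
  lm_ctrl <- minpack.lm::nls.lm.control(maxiter = opts$lm_maxiter,
                                        maxfev = 100 * opts$lm_maxiter)
  clamp <- function(th) pmin(pmax(th, lower), upper)
  lm_run <- function(th, fn) {
    tryCatch(minpack.lm::nls.lm(clamp(th), lower = lower, upper = upper,
                                fn = fn, control = lm_ctrl),
             error = function(e) NULL)
  }
  deviance_of <- function(th) sum(resid_fn(th)^2)
  jac_fd <- function(th, h = 1e-5) {
    r0 <- resid_fn(th)
    vapply(seq_along(th), function(i) {
      tp <- th
      tp[i] <- tp[i] + h
      (resid_fn(tp) - r0) / h
    }, r0)
  }

  with_preserved_seed(seed, {
    # stage 1: multistart LM
    start_log <- vector("list", starts)
    best <- NULL
    for (s in seq_len(starts)) {
      th <- if (s == 1) theta0 else {
        clamp(theta0 + stats::rnorm(length(theta0), 0, perturb))
      }
      r1 <- lm_run(th, lresid_fn)
      r2 <- lm_run(if (is.null(r1)) th else r1$par, resid_fn)
      if (is.null(r2)) {
        start_log[[s]] <- tibble(start = s, deviance = NA_real_,
                                 iterations = NA_integer_, message = "error")
        next
      }
      start_log[[s]] <- tibble(start = s, deviance = r2$deviance,
                               iterations = r2$niter,
                               message = r2$message)
      if (is.null(best) || r2$deviance < best$deviance) {
        best <- r2
        best$start <- s
      }
    }
    if (is.null(best)) abort("all optimization starts failed")

    # stage 2: sloppy-valley continuation
    iterations <- best$niter
    fails <- 0
    rounds_used <- 0
    p <- length(theta0)
    nsub <- min(opts$subspace, p)
    while (rounds_used < opts$rounds && best$deviance > opts$dev_floor &&
           fails < opts$fails_max) {
      rounds_used <- rounds_used + 1
      sv <- svd(jac_fd(best$par))
      V <- sv$v[, (p - nsub + 1):p, drop = FALSE]
      cand_th <- NULL
      cand_dev <- Inf
      for (i in seq_len(opts$probes)) {
        z <- stats::rnorm(nsub)
        z <- z / sqrt(sum(z^2)) * stats::runif(1, 0.5, opts$probe_radius)
        th <- clamp(best$par + drop(V %*% z))
        d <- deviance_of(th)
        if (d < cand_dev) {
          cand_dev <- d
          cand_th <- th
        }
      }
      improved <- FALSE
      if (is.finite(cand_dev) && cand_dev < best$deviance * 3) {
        pol <- lm_run(cand_th, resid_fn)
        if (!is.null(pol) && pol$deviance < best$deviance * 0.999) {
          pol$start <- best$start
          best <- pol
          improved <- TRUE
          iterations <- iterations + pol$niter
        }
      }
      fails <- if (improved) 0 else fails + 1
    }

    # stage 3: determinant-criterion polish
    polish <- NULL
    if (opts$polish_iter > 0) {
      polish <- tryCatch(
        stats::nlminb(best$par, logdet_fn, gradient = fd_gradient(logdet_fn),
                      lower = lower, upper = upper,
                      control = list(iter.max = opts$polish_iter,
                                     eval.max = 4 * opts$polish_iter)),
        error = function(e) NULL
      )
    }
    if (!is.null(polish) && is.finite(polish$objective) &&
        polish$objective <= logdet_fn(best$par)) {
      par <- polish$par
      iterations <- iterations + polish$iterations
      message <- polish$message
      converged <- TRUE
    } else {
      par <- best$par
      message <- best$message
      converged <- best$info %in% 1:4
    }

    list(
      par = par,
      objective = logdet_fn(par),
      deviance = deviance_of(par),
      convergence = if (converged) 0L else 1L,
      message = message,
      iterations = iterations,
      start = best$start,
      rounds = rounds_used,
      log = dplyr::bind_rows(start_log)
    )
  })
}

# Gauss-Newton Hessian of log det(Z'Z) at the optimum:
#   H_ij = 2 tr(G^-1 J_i' J_j),  G = Z'Z (+ regularization),
# with J_i = dZ/dtheta_i obtained by forward differences of the scaled
# residual matrix. Writing A_i = J_i G^(-1/2) gives H_ij = 2 <A_i, A_j>,
# so H is positive semidefinite by construction and exactly singular for
# exactly redundant parameters. For a single response it reduces to
# 2 J'J / SSE, i.e. the classical information matrix.
gn_logdet_hessian <- function(Zfun, par, rel_step = 1e-5) {
  Z0 <- Zfun(par)
  if (is.null(Z0)) return(NULL)
  G <- crossprod(Z0)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0) + nrow(Z0) * 1e-8
  Ghalf_inv <- ev$vectors %*% (t(ev$vectors) / sqrt(lam))
  p <- length(par)
  A <- vector("list", p)
  for (i in seq_len(p)) {
    h <- max(rel_step * abs(par[i]), 1e-14)
    xp <- par
    xp[i] <- par[i] + h
    Zi <- Zfun(xp)
    if (is.null(Zi)) return(NULL)
    A[[i]] <- ((Zi - Z0) / h) %*% Ghalf_inv
  }
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      H[i, j] <- H[j, i] <- 2 * sum(A[[i]] * A[[j]])
    }
  }
  H
}

# Column-scaled non-negative least squares with an active-set solver and a
# projected-gradient fallback.
nnls_scaled <- function(A, b) {
  cs <- apply(A, 2, function(x) max(sqrt(sum(x^2)), 1e-300))
  As <- sweep(A, 2, cs, `/`)
  z <- tryCatch(pracma::lsqnonneg(As, b)$x, error = function(e) NULL)
  if (is.null(z)) {
    f <- function(x) 0.5 * sum((As %*% x - b)^2)
    g <- function(x) drop(crossprod(As, As %*% x - b))
    z <- stats::optim(rep(0, ncol(A)), f, g, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = 2000, factr = 1e3))$par
  }
  z / cs
}

# Quasi-linearization warm start ("integral method"): mass-action dynamics
# are linear in the rate constants given the trajectories, so
#   y_s(t_j) - y_s(0) = sum_i k_i S[s,i] int_0^{t_j} prod[reactants_i] dt.
# Simulate at the current k on a fine grid, multiplicatively correct each
# measured species' trajectory by the interpolated observed/simulated
# ratio (so the integrals are nearly unbiased regardless of the current
# parameters), and solve the resulting non-negative linear system for k.
# Iterated to a fixed point this homes in on the data-consistent rate
# constants and crosses the curved, nearly-flat valleys in which local
# optimizers stall.
make_integral_refiners <- function(prep, enc, y0, network, rtol, atol,
                                   fine_n = 400) {
  S <- stoichiometry_matrix(network)
  st <- network$steps
  lapply(prep$blocks, function(b) {
    obs_t <- b$times
    counts <- as.vector(table(b$time_idx))
    obs_mean <- rowsum(b$obs, b$time_idx) / counts
    tf <- sort(unique(c(seq(0, max(obs_t), length.out = fine_n + 1), obs_t)))
    ti <- match(obs_t, tf)
    dt <- diff(tf)
    function(k) {
      m <- sim_matrix(enc, k, y0, tf, rtol, atol)
      if (is.null(m)) return(NULL)
      Y <- m[, -1, drop = FALSE]
      colnames(Y) <- enc$species
      for (s in prep$responses) {
        sim_at <- Y[ti, s]
        ratio <- ifelse(sim_at > 1e-12, obs_mean[, s] / sim_at, 1)
        ratio[!is.finite(ratio)] <- 1
        cf <- stats::approx(obs_t, ratio, xout = tf, rule = 2)$y
        Y[, s] <- Y[, s] * cf
      }
      basis <- vapply(seq_len(nrow(st)), function(j) {
        v <- Y[, st$reactants[[j]][1]]
        if (length(st$reactants[[j]]) > 1) v <- v * Y[, st$reactants[[j]][2]]
        v
      }, numeric(nrow(Y)))
      cum <- apply(basis, 2, function(x) {
        c(0, cumsum((x[-1] + x[-length(x)]) / 2 * dt))
      })
      C <- cum[ti, , drop = FALSE]
      A <- NULL
      rhs <- NULL
      for (s in prep$responses) {
        Aobs <- sweep(C, 2, S[s, ], `*`)[b$time_idx, , drop = FALSE]
        A <- rbind(A, Aobs * prep$col_scale[s])
        rhs <- c(rhs, (b$obs[, s] - y0[s]) * prep$col_scale[s])
      }
      nnls_scaled(A, rhs)
    }
  })
}

# Iterate one block's integral refiner from k_init, tracking the best
# deviance seen under `dev_fn` (which maps the block's k to a deviance).
iterate_refiner <- function(refiner, k_init, dev_fn, iters = 50,
                            rel_tol = 1e-5) {
  k <- k_init
  best_k <- k
  best_dev <- dev_fn(k)
  prev <- best_dev
  for (i in seq_len(iters)) {
    k2 <- refiner(k)
    if (is.null(k2)) break
    d <- dev_fn(k2)
    # strict relative improvement required: on exactly degenerate problems
    # (duplicated steps) the regression may redistribute rate between
    # equivalent parameters without fitting better, and the caller's init
    # should then stand
    if (is.finite(d) && d < best_dev * (1 - 1e-6)) {
      best_dev <- d
      best_k <- k2
    }
    if (is.finite(d) && is.finite(prev) && prev > 0 &&
        abs(prev - d) < rel_tol * prev) {
      k <- k2
      break
    }
    prev <- d
    k <- k2
  }
  best_k
}

# Residual / objective closures shared by both fit types. `klist_of` maps
# the optimizer's parameter vector to per-block rate-constant vectors.
make_objectives <- function(prep, enc, y0, klist_of, rtol, atol) {
  nresid <- prep$n_obs * length(prep$responses)
  # per-response offsets for the log-concentration surrogate
  eps <- pmax(1 / prep$col_scale, 1e-6) * 1e-3
  lobs <- lapply(prep$blocks, function(b) log(sweep(b$obs, 2, eps, `+`)))
  resid_fn <- function(theta) {
    preds <- stacked_pred(prep, enc, y0, klist_of(theta), rtol, atol)
    if (is.null(preds)) return(rep(1e6, nresid))
    unlist(purrr::map2(prep$blocks, preds, function(b, p) {
      as.vector(sweep(b$obs - p, 2, prep$col_scale, `*`))
    }), use.names = FALSE)
  }
  lresid_fn <- function(theta) {
    preds <- stacked_pred(prep, enc, y0, klist_of(theta), rtol, atol)
    if (is.null(preds)) return(rep(1e3, nresid))
    unlist(purrr::map2(lobs, preds, function(lo, p) {
      p[p < 0] <- 0
      as.vector(lo - log(sweep(p, 2, eps, `+`)))
    }), use.names = FALSE)
  }
  logdet_fn <- function(theta) {
    stacked_logdet(prep, enc, y0, klist_of(theta), rtol, atol)
  }
  list(resid = resid_fn, lresid = lresid_fn, logdet = logdet_fn)
}

COND_LIMIT <- 1e8       # information-matrix condition number for "ind"
HW_RATIO_LIMIT <- 10    # halfwidth > 10x |estimate| is "ind"

# Laplace uncertainty for free (non-pinned) natural-scale parameters from
# a precomputed (Gauss-Newton) Hessian of the log-determinant objective.
# Returns cov matrix, halfwidths, indeterminate flags and a caveat.
laplace_uncertainty <- function(H, par, df, level = 0.95) {
  p <- length(par)
  d <- pmax(abs(par), 1e-300)
  Hrel <- H * tcrossprod(d)        # curvature w.r.t. log-parameters
  ev <- eigen((Hrel + t(Hrel)) / 2, symmetric = TRUE)
  cond <- if (min(ev$values) <= 0) Inf else max(ev$values) / min(ev$values)
  singular <- !is.finite(cond) || cond > COND_LIMIT
  # invert on the relative scale (pseudo-inverse when ill-conditioned)
  lam <- ev$values
  tol <- max(lam) / COND_LIMIT
  inv_lam <- ifelse(lam > tol, 1 / lam, NA_real_)
  null_dir <- is.na(inv_lam)
  loadings <- abs(ev$vectors[, null_dir, drop = FALSE])
  affected <- if (any(null_dir)) {
    apply(loadings, 1, max) > 0.1
  } else rep(FALSE, p)
  inv_lam[is.na(inv_lam)] <- 1 / tol   # capped, flagged via `affected`
  Hrel_inv <- ev$vectors %*% (inv_lam * t(ev$vectors))
  cov_rel <- (2 / df) * Hrel_inv
  cov <- cov_rel * tcrossprod(d)       # back to natural scale
  hw <- stats::qt(1 - (1 - level) / 2, df) * sqrt(pmax(diag(cov), 0))
  indet <- affected | !is.finite(hw) | (hw > HW_RATIO_LIMIT * pmax(abs(par), 1e-300))
  corr <- suppressWarnings(stats::cov2cor(cov))
  corr[!is.finite(corr)] <- NA_real_
  diag(corr) <- 1
  list(cov = cov, halfwidth = hw, indeterminate = indet,
       correlation = corr, condition = cond, singular = singular, df = df,
       level = level)
}

strong_pairs <- function(correlation, labels, threshold = 0.95) {
  if (is.null(correlation)) return(tibble(par1 = character(), par2 = character(),
                                          r = numeric()))
  p <- nrow(correlation)
  out <- list()
  for (i in seq_len(max(p - 1, 0))) {
    for (j in (i + 1):p) {
      r <- correlation[i, j]
      if (is.finite(r) && abs(r) >= threshold) {
        out[[length(out) + 1]] <- tibble(par1 = labels[i], par2 = labels[j], r = r)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(par1 = character(), par2 = character(), r = numeric()))
  }
  dplyr::arrange(res, dplyr::desc(abs(.data$r)))
}

finish_status <- function(best) {
  if (best$convergence == 0) "converged" else "stalled"
}

# ---- per-temperature fit -------------------------------------------------

#' Fit rate constants at one temperature
#'
#' Estimates the network's rate constants from the replicate-level dataset
#' at one heating temperature by minimizing the determinant criterion
#' `det(Z'Z)` over non-negative rate constants, using seeded multistart
#' local optimization in log-parameter space. Parameters driven to the
#' lower boundary are profile-tested at exactly zero and, if the objective
#' does not degrade, pinned there and flagged `at_boundary`. 95% HPD
#' halfwidths, identifiability flags and the normalized parameter
#' covariance (correlation) matrix come from a Laplace approximation of the
#' Box-Draper posterior.
#'
#' @param dataset Kinetic dataset tibble (`temperature_C`, `time_min`,
#'   `replicate`, `species`, `concentration`).
#' @param network The [mr_network()] to fit.
#' @param temperature_C Heating temperature to fit (must be present in the
#'   dataset); each temperature is fitted separately.
#' @param init Initial rate-constant vector (named or in step order).
#'   Defaults to order-based scales (1e-3 min^-1, 1e-9 kg umol^-1 min^-1).
#' @param starts Number of multistart launches (first start is `init`
#'   itself, the rest are log-normal perturbations). Default 8.
#' @param seed Seed for the multistart perturbations.
#' @param perturb_sd Standard deviation of the log-scale start
#'   perturbations.
#' @param y0 Known initial state used by the forward model.
#' @param use_t0 Include `t = 0` baseline rows in the residual matrix.
#' @param responses Optional subset of measured species to fit against.
#' @param rtol,atol Solver tolerances for the forward model during
#'   fitting (tighter than the simulation defaults: the criterion
#'   differentiates the solution, so the model must be resolved below the
#'   residual scale).
#' @param compute_uncertainty Compute the Laplace Hessian (HPD intervals,
#'   correlation matrix). Disable for speed when only point estimates are
#'   needed.
#' @param level Credible level for the HPD halfwidths.
#' @param control Passed to [stats::nlminb()] control.
#' @return An object of class `mr_fit`; see [tidy()][generics::tidy] /
#'   [glance()][generics::glance] methods and [mr_parameter_correlation()].
#' @export
mr_fit_rates <- function(dataset, network = mr_network(), temperature_C,
                         init = NULL, starts = 8, seed = 1,
                         perturb_sd = log(2),
                         y0 = mr_initial_state(network),
                         use_t0 = TRUE, responses = NULL,
                         rtol = 1e-10, atol = 1e-8,
                         compute_uncertainty = TRUE, level = 0.95,
                         control = list()) {
  stopifnot(inherits(network, "mr_network"))
  if (!temperature_C %in% unique(dataset$temperature_C)) {
    abort(sprintf("dataset does not contain temperature %s degrees C",
                  temperature_C))
  }
  st <- network$steps
  n_par <- nrow(st)
  if (is.null(init)) {
    init <- default_k_scale(st$order)
  } else {
    init <- unname(rate_vector(network, init))
  }
  scale <- pmax(init, default_k_scale(st$order))
  lower <- log(scale * 1e-6)
  upper <- log(scale * 1e6)
  theta0 <- pmin(pmax(log(pmax(init, scale * 1e-6)), lower), upper)

  prep <- prepare_blocks(dataset, network, temperature_C, use_t0, responses)
  enc <- encode_network(network)
  y0v <- state_vector(network, y0)
  obj <- make_objectives(prep, enc, y0v, function(th) list(exp(th)),
                         rtol, atol)
  th_of_k <- function(k) {
    pmin(pmax(suppressWarnings(log(k)), lower), upper)
  }
  refiner <- make_integral_refiners(prep, enc, y0v, network, rtol, atol)[[1]]
  k_ws <- iterate_refiner(refiner, init,
                          function(k) sum(obj$resid(th_of_k(k))^2))
  theta0 <- th_of_k(k_ws)
  best <- engine_fit(obj$resid, obj$lresid, obj$logdet, theta0, lower, upper,
                     starts, seed, perturb_sd, control)
  k_hat <- exp(best$par)

  # explicit zero-boundary testing
  at_boundary <- rep(FALSE, n_par)
  obj_hat <- best$objective
  near_floor <- best$par < lower + 1e-3 | k_hat < scale * 1e-2
  for (i in which(near_floor)) {
    k_try <- k_hat
    k_try[i] <- 0
    o <- stacked_logdet(prep, enc, y0v, list(k_try), rtol, atol)
    if (is.finite(o) && o <= obj_hat + 0.02) {
      k_hat[i] <- 0
      at_boundary[i] <- TRUE
      obj_hat <- min(obj_hat, o)
    }
  }

  build_fit(
    type = "per-temperature", network = network, prep = prep, enc = enc,
    y0 = y0v, rtol = rtol, atol = atol,
    par_labels = st$rate_symbol, term = rep("k", n_par),
    step = st$index, estimate = k_hat, at_boundary = at_boundary,
    k_builder = function(est) list(est),
    best = best, obj_hat = obj_hat, seed = seed,
    temperature_C = temperature_C,
    compute_uncertainty = compute_uncertainty, level = level
  )
}

# Shared fit assembly: boundary bookkeeping, Laplace uncertainty over the
# free parameters, estimate table, correlation, diagnostics.
build_fit <- function(type, network, prep, enc, y0, rtol, atol,
                      par_labels, term, step, estimate, at_boundary,
                      k_builder, best, obj_hat, seed, temperature_C,
                      compute_uncertainty, level) {
  n_par <- length(estimate)
  free <- !at_boundary
  n_obs <- prep$n_obs
  df <- max(n_obs - sum(free), 1L)

  unc <- NULL
  if (compute_uncertainty && any(free)) {
    Zfun <- function(x) {
      est2 <- estimate
      est2[free] <- x
      Z <- stacked_logdet(prep, enc, y0, k_builder(est2), rtol, atol,
                          return_Z = TRUE)
      if (is.null(Z)) return(NULL)
      sweep(Z, 2, prep$col_scale, `*`)
    }
    H <- gn_logdet_hessian(Zfun, estimate[free])
    if (!is.null(H)) {
      unc <- laplace_uncertainty(H, estimate[free], df, level)
    }
  }

  hpd <- rep(NA_real_, n_par)
  flag <- rep(if (is.null(unc)) "unassessed" else "determinate", n_par)
  flag[at_boundary] <- "boundary"
  hpd[at_boundary] <- 0
  correlation <- NULL
  pairs <- NULL
  if (!is.null(unc)) {
    hpd[free] <- unc$halfwidth
    flag[free][unc$indeterminate] <- "indeterminate"
    hpd[free][unc$indeterminate] <- NA_real_
    correlation <- unc$correlation
    dimnames(correlation) <- list(par_labels[free], par_labels[free])
    pairs <- strong_pairs(correlation, par_labels[free])
  }

  # raw determinant objective (unscaled residuals) at the optimum
  Z <- stacked_logdet(prep, enc, y0, k_builder(estimate), rtol, atol,
                      return_Z = TRUE)
  objective_det <- if (is.null(Z)) NA_real_ else det(crossprod(Z))

  estimates <- tibble(
    step = step, term = term,
    label = par_labels,
    reaction = reaction_labels(network)[match(step, network$steps$index)],
    estimate = estimate, hpd = hpd, flag = flag, at_boundary = at_boundary
  )

  fitted <- NULL
  if (!is.null(Z)) {
    fitted <- purrr::map2_dfr(prep$blocks, k_builder(estimate), function(b, k) {
      m <- sim_matrix(enc, k, y0, b$times, rtol, atol)
      col_idx <- match(prep$responses, enc$species)
      tibble(
        temperature_C = b$temperature_C,
        time_min = rep(m[, 1], length(prep$responses)),
        species = rep(prep$responses, each = nrow(m)),
        fitted = as.vector(m[, col_idx + 1L])
      )
    })
  }

  structure(list(
    type = type,
    temperature_C = temperature_C,
    estimates = estimates,
    objective = objective_det,
    log_objective = obj_hat,
    correlation = correlation,
    strong_pairs = pairs,
    cov = if (is.null(unc)) NULL else unc$cov,
    free = free,
    df = df,
    level = level,
    condition = if (is.null(unc)) NA_real_ else unc$condition,
    singular_information = if (is.null(unc)) NA else unc$singular,
    convergence = list(
      status = finish_status(best),
      code = best$convergence,
      message = best$message,
      iterations = best$iterations,
      best_start = best$start,
      starts_used = nrow(best$log),
      seed = seed,
      log = best$log
    ),
    n_obs = n_obs,
    n_responses = length(prep$responses),
    responses = prep$responses,
    data = NULL,
    fitted = fitted,
    network = network
  ), class = "mr_fit")
}

# ---- global Arrhenius fit ------------------------------------------------

#' Fit reparametrized Arrhenius parameters globally
#'
#' Jointly estimates `(k_ref, Ea)` for every step by minimizing the pooled
#' determinant criterion over all temperatures in the dataset (residual
#' rows stacked across temperatures). `k_ref` is the rate constant at the
#' shared reference temperature (393.15 K by default) and is constrained
#' non-negative; `Ea` (kJ/mol) is unconstrained in sign. Requires at least
#' two temperatures, otherwise `Ea` is unidentifiable.
#'
#' @inheritParams mr_fit_rates
#' @param init An [mr_arrhenius()] parameter set used as the starting
#'   point; defaults to order-based `k_ref` scales with `Ea = 50` kJ/mol.
#' @param T_ref_K Reference temperature of the reparametrization.
#' @param Ea_perturb_sd Standard deviation (kJ/mol) of the multistart
#'   perturbations on the activation energies.
#' @return An `mr_fit` object whose estimate table has one `k_ref` and one
#'   `Ea` row per step; `Ea` rows of steps pinned at `k_ref = 0` are
#'   flagged indeterminate.
#' @export
mr_fit_arrhenius <- function(dataset, network = mr_network(), init = NULL,
                             starts = 8, seed = 1, perturb_sd = log(2),
                             Ea_perturb_sd = 10,
                             y0 = mr_initial_state(network),
                             use_t0 = TRUE, responses = NULL,
                             T_ref_K = T_REF_DEFAULT,
                             rtol = 1e-10, atol = 1e-8,
                             compute_uncertainty = TRUE, level = 0.95,
                             control = list()) {
  stopifnot(inherits(network, "mr_network"))
  temps <- sort(unique(dataset$temperature_C))
  if (length(temps) < 2) {
    abort("global Arrhenius fitting needs at least two temperatures (Ea is unidentifiable from one)")
  }
  st <- network$steps
  n_steps <- nrow(st)
  if (is.null(init)) {
    init <- mr_arrhenius(k_ref = default_k_scale(st$order),
                         Ea_kJ_mol = rep(50, n_steps), step = st$index,
                         T_ref_K = T_ref_K)
  }
  stopifnot(inherits(init, "mr_arrhenius"))
  k0 <- init$k_ref[match(st$index, init$step)]
  ea0 <- init$Ea_kJ_mol[match(st$index, init$step)]
  if (anyNA(k0) || anyNA(ea0)) abort("`init` must cover every network step")

  EA_SCALE <- 50 # kJ/mol per optimizer unit, balances the two blocks
  scale <- pmax(k0, default_k_scale(st$order))
  lower <- c(log(scale * 1e-6), rep(-500 / EA_SCALE, n_steps))
  upper <- c(log(scale * 1e6), rep(500 / EA_SCALE, n_steps))
  theta0 <- c(pmin(pmax(log(pmax(k0, scale * 1e-6)), lower[1:n_steps]),
                   upper[1:n_steps]),
              ea0 / EA_SCALE)

  prep <- prepare_blocks(dataset, network, temps, use_t0, responses)
  enc <- encode_network(network)
  y0v <- state_vector(network, y0)
  # per-temperature Arrhenius factors exp(C_T * Ea)
  C_T <- (1000 / GAS_CONSTANT) *
    (1 / T_ref_K - 1 / celsius_to_kelvin(temps))

  klist_from <- function(kref, ea) {
    lapply(C_T, function(ct) kref * exp(ct * ea))
  }
  klist_of <- function(theta) {
    klist_from(exp(theta[1:n_steps]),
               theta[(n_steps + 1):(2 * n_steps)] * EA_SCALE)
  }
  obj <- make_objectives(prep, enc, y0v, klist_of, rtol, atol)

  # warm start: per-temperature quasi-linearization, then a per-step
  # Arrhenius line fit of log k against (1/T_ref - 1/T)
  refiners <- make_integral_refiners(prep, enc, y0v, network, rtol, atol)
  k_init_T <- klist_from(k0, ea0)
  k_warm_T <- lapply(seq_along(temps), function(i) {
    prep_i <- prep
    prep_i$blocks <- prep$blocks[i]
    obj_i <- make_objectives(prep_i, enc, y0v, function(th) list(exp(th)),
                             rtol, atol)
    lower_i <- log(pmax(k_init_T[[i]], default_k_scale(st$order)) * 1e-8)
    dev_i <- function(k) {
      sum(obj_i$resid(pmin(pmax(suppressWarnings(log(k)), lower_i),
                           lower_i + 32))^2)
    }
    iterate_refiner(refiners[[i]], k_init_T[[i]], dev_i)
  })
  k0_ws <- k0
  ea0_ws <- ea0
  for (i in seq_len(n_steps)) {
    kv <- vapply(k_warm_T, `[`, numeric(1), i)
    pos <- kv > default_k_scale(st$order[i]) * 1e-4
    if (sum(pos) >= 2) {
      cf <- stats::lm.fit(cbind(1, C_T[pos]), log(kv[pos]))$coefficients
      k0_ws[i] <- exp(cf[1])
      ea0_ws[i] <- max(min(cf[2], 480), -480)
    } else if (all(kv <= default_k_scale(st$order[i]) * 1e-4)) {
      k0_ws[i] <- 0
    }
  }
  scale <- pmax(pmax(k0, k0_ws), default_k_scale(st$order))
  lower[1:n_steps] <- log(scale * 1e-6)
  upper[1:n_steps] <- log(scale * 1e6)
  theta0 <- c(pmin(pmax(log(pmax(k0_ws, scale * 1e-6)), lower[1:n_steps]),
                   upper[1:n_steps]),
              ea0_ws / EA_SCALE)

  # perturb Ea starts on their own scale
  perturb <- c(rep(perturb_sd, n_steps), rep(Ea_perturb_sd / EA_SCALE, n_steps))
  best <- engine_fit(obj$resid, obj$lresid, obj$logdet, theta0, lower, upper,
                     starts, seed, perturb, control)
  kref_hat <- exp(best$par[1:n_steps])
  ea_hat <- best$par[(n_steps + 1):(2 * n_steps)] * EA_SCALE

  # zero-boundary testing on k_ref only
  at_boundary_k <- rep(FALSE, n_steps)
  obj_hat <- best$objective
  near_floor <- best$par[1:n_steps] < lower[1:n_steps] + 1e-3 |
    kref_hat < scale * 1e-2
  for (i in which(near_floor)) {
    k_try <- kref_hat
    k_try[i] <- 0
    o <- stacked_logdet(prep, enc, y0v, klist_from(k_try, ea_hat), rtol, atol)
    if (is.finite(o) && o <= obj_hat + 0.02) {
      kref_hat[i] <- 0
      at_boundary_k[i] <- TRUE
      obj_hat <- min(obj_hat, o)
    }
  }

  estimate <- c(kref_hat, ea_hat)
  at_boundary <- c(at_boundary_k, rep(FALSE, n_steps))
  # Ea of a zeroed step is unidentifiable: exclude from the free set
  ea_dead <- c(rep(FALSE, n_steps), at_boundary_k)

  fit <- build_fit(
    type = "global-arrhenius", network = network, prep = prep, enc = enc,
    y0 = y0v, rtol = rtol, atol = atol,
    par_labels = c(paste0("k_ref", st$index), paste0("Ea", st$index)),
    term = rep(c("k_ref", "Ea"), each = n_steps),
    step = rep(st$index, 2),
    estimate = estimate,
    at_boundary = at_boundary | ea_dead,
    k_builder = function(est) {
      klist_from(est[1:n_steps], est[(n_steps + 1):(2 * n_steps)])
    },
    best = best, obj_hat = obj_hat, seed = seed, temperature_C = temps,
    compute_uncertainty = compute_uncertainty, level = level
  )
  # Ea rows of zeroed steps are indeterminate, not boundary-pinned
  idx_ea_dead <- which(ea_dead)
  fit$estimates$flag[idx_ea_dead] <- "indeterminate"
  fit$estimates$at_boundary[idx_ea_dead] <- FALSE
  fit$estimates$hpd[idx_ea_dead] <- NA_real_
  fit$T_ref_K <- T_ref_K
  fit
}

# ---- uncertainty accessors -----------------------------------------------

#' HPD halfwidths of a fit
#'
#' Recomputes the per-parameter highest-posterior-density halfwidths from
#' the fit's Laplace covariance at the requested credible level.
#' Boundary-pinned parameters report a degenerate `0 +/- 0` interval;
#' parameters whose interval cannot be trusted (ill-conditioned
#' information matrix or halfwidth above 10x the estimate) are flagged
#' indeterminate with `NA` halfwidth.
#'
#' @param fit An `mr_fit` with uncertainty computed.
#' @param level Credible level (default 0.95).
#' @return A tibble `step`, `term`, `estimate`, `hpd_halfwidth`, `flag`.
#' @export
mr_hpd_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mr_fit"))
  if (identical(fit$convergence$status, "failed")) {
    abort("cannot compute intervals for a failed fit")
  }
  if (is.null(fit$cov)) {
    abort("fit was run with compute_uncertainty = FALSE")
  }
  est <- fit$estimates
  hw <- rep(NA_real_, nrow(est))
  hw[est$at_boundary] <- 0
  free_idx <- which(fit$free)
  scale_t <- stats::qt(1 - (1 - level) / 2, fit$df) /
    stats::qt(1 - (1 - fit$level) / 2, fit$df)
  hw[free_idx] <- est$hpd[free_idx] * scale_t
  tibble(step = est$step, term = est$term, estimate = est$estimate,
         hpd_halfwidth = hw, flag = est$flag)
}

#' Normalized parameter covariance (correlation) matrix of a fit
#'
#' Returns the correlation matrix of the free parameters together with the
#' strongly correlated pairs (|r| above the threshold, sorted by |r|).
#' When the information matrix is singular or ill-conditioned the matrix
#' is computed from a pseudo-inverse and flagged with a caveat.
#'
#' @param fit An `mr_fit` with uncertainty computed.
#' @param threshold Absolute correlation defining a "strong" pair.
#' @return A list with elements `correlation` (matrix, unit diagonal),
#'   `pairs` (tibble `par1`, `par2`, `r`), and `caveat` (`TRUE` when a
#'   pseudo-inverse was needed).
#' @export
mr_parameter_correlation <- function(fit, threshold = 0.95) {
  stopifnot(inherits(fit, "mr_fit"))
  if (is.null(fit$correlation)) {
    abort("fit has no computable information matrix (compute_uncertainty = FALSE?)")
  }
  list(
    correlation = fit$correlation,
    pairs = strong_pairs(fit$correlation, rownames(fit$correlation), threshold),
    caveat = isTRUE(fit$singular_information)
  )
}
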