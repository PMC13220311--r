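# broom-style accessors and ggplot2 methods for fitted objects and
# simulations.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("<mr_fit: %s>\n", x$type))
  if (!is.null(x$temperature_C)) {
    cat("  temperature(s):", paste(x$temperature_C, collapse = ", "),
        "degrees C\n")
  }
  cat(sprintf("  %d observations x %d responses; det objective %.4g\n",
              x$n_obs, x$n_responses, x$objective))
  cat(sprintf("  status: %s (%d iterations, best start %d of %d)\n",
              x$convergence$status, x$convergence$iterations,
              x$convergence$best_start, x$convergence$starts_used))
  flags <- table(x$estimates$flag)
  cat("  parameters:", paste(sprintf("%s %d", names(flags), flags),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a kinetic fit
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return The estimate table: one row per parameter with `step`, `term`
#'   (`k`, `k_ref` or `Ea`), `reaction`, `estimate`, 95% HPD halfwidth
#'   `hpd`, identifiability `flag` and `at_boundary`.
#' @export
tidy.mr_fit <- function(x, ...) {
  x$estimates
}

#' One-row fit summary
#'
#' @param x An `mr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: objective values, dimensions, flag counts and
#'   convergence information.
#' @export
glance.mr_fit <- function(x, ...) {
  tibble(
    objective = x$objective,
    log_objective = x$log_objective,
    n_obs = x$n_obs,
    n_responses = x$n_responses,
    n_parameters = nrow(x$estimates),
    n_boundary = sum(x$estimates$at_boundary),
    n_indeterminate = sum(x$estimates$flag == "indeterminate"),
    status = x$convergence$status,
    iterations = x$convergence$iterations,
    seed = x$convergence$seed
  )
}

#' Plot simulated trajectories
#'
#' Concentration versus heating time, one facet per species (free y
#' scales; species span seven orders of magnitude), coloured by
#' temperature when several are present.
#'
#' @param object An `mr_sim` tibble.
#' @param species Optional subset of species to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_sim <- function(object, species = NULL, ...) {
  df <- object
  if (!is.null(species)) df <- df[df$species %in% species, ]
  has_temp <- "temperature_C" %in% names(df) && length(unique(df$temperature_C)) > 1
  p <- if (has_temp) {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$concentration,
                                     colour = factor(.data$temperature_C))) +
      ggplot2::labs(colour = "temperature (°C)")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$concentration))
  }
  p +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "heating time (min)",
                  y = "concentration (µmol/kg dm)")
}

#' Plot a fit against data
#'
#' Fitted trajectories (lines) with optional observed data (points),
#' faceted by species.
#'
#' @param object An `mr_fit`.
#' @param data Optional kinetic dataset tibble to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_fit <- function(object, data = NULL, ...) {
  fitted <- object$fitted
  if (is.null(fitted)) abort("fit carries no fitted trajectories")
  multi <- length(unique(fitted$temperature_C)) > 1
  aes_line <- if (multi) {
    ggplot2::aes(.data$time_min, .data$fitted,
                 colour = factor(.data$temperature_C))
  } else {
    ggplot2::aes(.data$time_min, .data$fitted)
  }
  p <- ggplot2::ggplot(fitted, aes_line) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "heating time (min)",
                  y = "concentration (µmol/kg dm)",
                  colour = if (multi) "temperature (°C)" else NULL)
  if (!is.null(data)) {
    data <- data[data$species %in% unique(fitted$species), ]
    aes_pt <- if (multi) {
      ggplot2::aes(.data$time_min, .data$concentration,
                   colour = factor(.data$temperature_C))
    } else {
      ggplot2::aes(.data$time_min, .data$concentration)
    }
    p <- p + ggplot2::geom_point(data = data, mapping = aes_pt, alpha = 0.6)
  }
  p
}

#' Heatmap of the parameter correlation matrix
#'
#' @param fit An `mr_fit` with uncertainty computed.
#' @return A ggplot tile plot of the normalized parameter covariance
#'   (correlation) matrix.
#' @export
plot_correlation <- function(fit) {
  corr <- mr_parameter_correlation(fit)$correlation
  df <- as_tibble(as.data.frame.table(corr, responseName = "r"))
  names(df)[1:2] <- c("par1", "par2")
  ggplot2::ggplot(df, ggplot2::aes(.data$par1, .data$par2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
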