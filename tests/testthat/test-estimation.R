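test_that("determinant objective reduces to SSE and obeys its invariances", {
  # all-zero residuals
  expect_equal(mr_determinant_objective(matrix(0, 4, 2)), 0)
  # single response: det(Z'Z) = residual sum of squares
  expect_equal(mr_determinant_objective(cbind(c(1, 2, 2))), 9)
  # hand-computed 2x2 determinant
  Z <- rbind(c(1, 0), c(0, 1), c(0, 0))
  expect_equal(mr_determinant_objective(Z), 1)
  # invariant under row permutation
  set.seed(1)
  Z2 <- matrix(rnorm(15), 5, 3)
  expect_equal(mr_determinant_objective(Z2),
               mr_determinant_objective(Z2[sample(5), ]))
  # scaling one response by c multiplies the objective by c^2
  Z3 <- Z2
  Z3[, 2] <- 7 * Z3[, 2]
  expect_equal(mr_determinant_objective(Z3),
               49 * mr_determinant_objective(Z2))
  # degenerate all-zero column warns
  expect_warning(mr_determinant_objective(cbind(c(1, 2, 3), 0)),
                 "degenerate")
  # preconditions
  expect_error(mr_determinant_objective(matrix(1, 2, 3)), "at least as many")
})

test_that("single-response determinant fit coincides with least squares", {
  net <- decay_network()
  d <- small_design(140, times = 1:5)
  k_true <- c(k1 = 0.3)
  ds <- mr_generate_dataset(d, list(`140` = k_true),
                            y0 = c(Lac = 1000, P1 = 0), network = net,
                            noise = mr_noise_model(cv = 0.05, floor_sd = 0),
                            seed = 11)
  # determinant objective over a k grid equals the SSE over the same grid
  grid <- seq(0.2, 0.4, by = 0.005)
  obs <- ds[ds$species == "Lac", ]
  vals <- vapply(grid, function(k) {
    pred <- 1000 * exp(-k * obs$time_min)
    c(det = mr_determinant_objective(cbind(obs$concentration - pred)),
      sse = sum((obs$concentration - pred)^2))
  }, numeric(2))
  expect_equal(vals["det", ], vals["sse", ])
  expect_equal(which.min(vals["det", ]), which.min(vals["sse", ]))

  # the full fit lands on the least-squares minimizer
  fit <- mr_fit_rates(ds, net, 140, init = c(k1 = 0.2), starts = 1, seed = 1,
                      y0 = c(Lac = 1000, P1 = 0))
  sse_fn <- function(k) sum((obs$concentration - 1000 * exp(-k * obs$time_min))^2)
  k_ls <- stats::optimize(sse_fn, c(0.1, 0.6))$minimum
  expect_equal(tidy(fit)$estimate, k_ls, tolerance = 1e-4)
})

test_that("HPD halfwidth matches the classical t interval on a decay fit", {
  net <- decay_network()
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.3)),
                            y0 = c(Lac = 1000, P1 = 0), network = net,
                            noise = mr_noise_model(cv = 0, floor_sd = 20),
                            seed = 4)
  fit <- mr_fit_rates(ds, net, 140, init = c(k1 = 0.3), starts = 1, seed = 1,
                      y0 = c(Lac = 1000, P1 = 0))
  obs <- ds[ds$species == "Lac", ]
  nls_fit <- stats::nls(concentration ~ 1000 * exp(-k * time_min),
                        data = obs, start = list(k = 0.3))
  se <- summary(nls_fit)$coefficients["k", "Std. Error"]
  hw_classical <- stats::qt(0.975, nrow(obs) - 1) * se
  expect_equal(tidy(fit)$hpd, hw_classical, tolerance = 0.05)
  expect_equal(tidy(fit)$estimate, coef(nls_fit)[["k"]], tolerance = 1e-3)

  # interval accessor rescales with the credible level
  hpd99 <- mr_hpd_intervals(fit, level = 0.99)
  expect_gt(hpd99$hpd_halfwidth[1], tidy(fit)$hpd[1])
})

test_that("an exactly duplicated step is flagged indeterminate", {
  net <- duplicated_step_network()
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.1, k2 = 0.1)),
                            y0 = c(Lac = 1000, P1 = 0), network = net,
                            noise = mr_noise_model(cv = 0, floor_sd = 0),
                            seed = 2)
  fit <- mr_fit_rates(ds, net, 140, init = c(k1 = 0.1, k2 = 0.1),
                      starts = 1, seed = 1, y0 = c(Lac = 1000, P1 = 0))
  labels <- mr_classify_identifiability(fit)
  expect_true(all(labels$label == "indeterminate"))
  # the identifiable sum is still recovered
  expect_equal(sum(tidy(fit)$estimate), 0.2, tolerance = 0.01)
})

test_that("a zero-rate step in the generating model is pinned at the boundary", {
  net <- two_decay_network()
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.2, k2 = 0)),
                            y0 = c(Lac = 1000, Lys = 500, P1 = 0, P10 = 0),
                            network = net,
                            noise = mr_noise_model(cv = 0, floor_sd = 0),
                            seed = 2)
  fit <- mr_fit_rates(ds, net, 140, init = c(k1 = 0.2, k2 = 0),
                      starts = 1, seed = 1,
                      y0 = c(Lac = 1000, Lys = 500, P1 = 0, P10 = 0))
  est <- tidy(fit)
  expect_equal(est$estimate[est$step == 2], 0)
  expect_true(est$at_boundary[est$step == 2])
  expect_equal(est$flag[est$step == 2], "boundary")
  expect_equal(est$hpd[est$step == 2], 0)
  expect_equal(est$estimate[est$step == 1], 0.2, tolerance = 1e-3)
})

test_that("parameter correlation separates orthogonal from coupled steps", {
  d <- small_design(140, times = 1:5)
  # orthogonal: two species decaying independently
  net_o <- two_decay_network()
  ds_o <- mr_generate_dataset(d, list(`140` = c(k1 = 0.2, k2 = 0.1)),
                              y0 = c(Lac = 1000, Lys = 500, P1 = 0, P10 = 0),
                              network = net_o,
                              noise = mr_noise_model(cv = 0.02, floor_sd = 0),
                              seed = 3)
  fit_o <- mr_fit_rates(ds_o, net_o, 140, init = c(k1 = 0.2, k2 = 0.1),
                        starts = 1, seed = 1,
                        y0 = c(Lac = 1000, Lys = 500, P1 = 0, P10 = 0))
  corr_o <- mr_parameter_correlation(fit_o)
  r_orth <- abs(corr_o$correlation[1, 2])

  # coupled: reversible isomerization through an unmeasured intermediate
  net_c <- lac_int_network()
  ds_c <- mr_generate_dataset(d, list(`140` = c(k1 = 0.8, k2 = 4.5, k3 = 0.05)),
                              y0 = c(Lac = 1000, Int = 0, P1 = 0),
                              network = net_c,
                              noise = mr_noise_model(cv = 0.02, floor_sd = 0),
                              seed = 3)
  fit_c <- mr_fit_rates(ds_c, net_c, 140, init = c(k1 = 0.8, k2 = 4.5, k3 = 0.05),
                        starts = 1, seed = 1,
                        y0 = c(Lac = 1000, Int = 0, P1 = 0))
  corr_c <- mr_parameter_correlation(fit_c)
  r_coupled <- abs(corr_c$correlation["k1", "k2"])

  expect_lt(r_orth, 0.5)
  expect_gt(r_coupled, r_orth)
  expect_gt(r_coupled, 0.8)
  # unit diagonal, symmetric, entries in [-1, 1]
  for (corr in list(corr_o$correlation, corr_c$correlation)) {
    expect_equal(unname(diag(corr)), rep(1, nrow(corr)))
    expect_equal(corr, t(corr))
    expect_true(all(abs(corr) <= 1 + 1e-8, na.rm = TRUE))
  }
})

test_that("estimation preconditions are enforced", {
  ds <- mr_generate_dataset(mr_design(140),
                            list(`140` = mr_rate_constants(140)), seed = 1)
  expect_error(mr_fit_rates(ds, mr_network(), 120), "does not contain")
  expect_error(mr_fit_arrhenius(ds, mr_network()), "at least two temperatures")
  fit_no_unc <- reference_recovery_fit(140, uncertainty = FALSE)
  expect_error(mr_parameter_correlation(fit_no_unc), "information matrix")
  expect_error(mr_hpd_intervals(fit_no_unc), "compute_uncertainty")
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- reference_recovery_fit(140, uncertainty = TRUE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "term", "label", "reaction", "estimate", "hpd",
                     "flag", "at_boundary"))
  expect_equal(nrow(td), 24)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("objective", "n_obs", "n_responses", "status",
                    "n_boundary", "n_indeterminate") %in% names(gl)))
  expect_equal(gl$n_obs, 18)
  expect_equal(gl$n_responses, 11)
})
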