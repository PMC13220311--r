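test_that("the default design encodes the heating protocol", {
  d <- mr_design()
  expect_equal(d$time_min[d$temperature_C == 110], c(1, 2, 3, 4, 5))
  expect_equal(d$time_min[d$temperature_C == 120], c(1, 2, 3, 4, 5))
  expect_equal(d$time_min[d$temperature_C == 130], c(1, 1.5, 2, 2.5, 3))
  expect_equal(d$time_min[d$temperature_C == 140], c(0.5, 1, 1.5, 2, 2.5))
  expect_true(all(d$replicates == 3))
  expect_error(mr_design(replicates = 0), ">= 1")
  expect_error(mr_design(125), "supply")
})

test_that("the default initial state matches pasteurized milk", {
  y0 <- mr_initial_state()
  expect_equal(unname(y0["Lac"]), 939150)
  expect_equal(unname(y0["Lys"]), 194670)
  expect_equal(unname(y0["3DG"]), 17.19)
  expect_equal(unname(y0["1DG"]), 2.43)
  expect_equal(unname(y0["CML"]), 0.14)
  expect_equal(unname(y0["CEL"]), 0.24)
  expect_equal(unname(y0["LacLys"]), 0)
  expect_equal(unname(y0["MGO"]), 0)

  y1 <- mr_initial_state(LacLys = 55)
  expect_equal(unname(y1["LacLys"]), 55)
  expect_error(mr_initial_state(Lys = -1), "non-negative")
  expect_error(mr_initial_state(Glucose = 3), "unknown species")
})

test_that("zero lysine shuts down the Amadori pathway entirely", {
  net <- mr_network()
  y0 <- mr_initial_state(net, Lys = 0)
  sim <- mr_simulate(net, mr_rate_constants(140), y0 = y0,
                     times = c(0, 1, 2))
  expect_true(all(sim$concentration[sim$species == "LacLys"] == 0))
})

test_that("generated datasets have the designed dimensions and seed contract", {
  params <- mr_reference_arrhenius_params()
  ds <- mr_generate_dataset(params = params, seed = 42)
  # 4 temperatures x 5 times x 3 replicates x 11 species, plus t0 baselines
  expect_equal(sum(ds$time_min > 0), 4 * 5 * 3 * 11)
  expect_equal(sum(ds$time_min == 0), 4 * 3 * 11)
  expect_true(all(ds$concentration >= 0))
  expect_setequal(unique(ds$species), maillardkin:::MEASURED_SPECIES)

  ds2 <- mr_generate_dataset(params = params, seed = 42)
  expect_identical(ds$concentration, ds2$concentration)
  ds3 <- mr_generate_dataset(params = params, seed = 43)
  expect_false(identical(ds$concentration, ds3$concentration))

  no_t0 <- mr_generate_dataset(params = params, seed = 1, include_t0 = FALSE)
  expect_equal(nrow(no_t0), 660)
})

test_that("degenerate noise returns exact model values", {
  net <- mr_network()
  k <- mr_rate_constants(110)
  ds <- mr_generate_dataset(mr_design(110), list(`110` = k),
                            noise = mr_noise_model(cv = 0, floor_sd = 0),
                            seed = 7)
  sim <- mr_simulate(net, k, times = c(0, 1, 2, 3, 4, 5), temperature_C = 110)
  joined <- dplyr::inner_join(
    ds, sim, by = c("temperature_C", "time_min", "species"),
    suffix = c("_obs", "_sim")
  )
  expect_equal(joined$concentration_obs, joined$concentration_sim)
})

test_that("replicate means converge to the noise-free values", {
  k <- mr_rate_constants(120)
  d <- mr_design(120, times = list(`120` = c(2, 5)), replicates = 1000)
  noisy <- mr_generate_dataset(d, list(`120` = k), seed = 3,
                               include_t0 = FALSE)
  clean <- mr_generate_dataset(d[1:2, ] |> dplyr::mutate(replicates = 1L),
                               list(`120` = k),
                               noise = mr_noise_model(cv = 0, floor_sd = 0),
                               seed = 3, include_t0 = FALSE)
  stats <- noisy |>
    dplyr::group_by(time_min, species) |>
    dplyr::summarise(m = mean(concentration),
                     se = stats::sd(concentration) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::inner_join(clean, by = c("time_min", "species"))
  # every replicate mean within 3 standard errors of the model value
  expect_true(all(abs(stats$m - stats$concentration) <=
                    3 * pmax(stats$se, 1e-12)))
})

test_that("the noise model validates its parameters", {
  expect_error(mr_noise_model(cv = -0.1), "non-negative")
  expect_error(mr_noise_model(floor_sd = -1), "non-negative")
  n <- mr_noise_model()
  expect_equal(n$cv, 0.07)
  expect_equal(n$floor_sd, 0.05)
})
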