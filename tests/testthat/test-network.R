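test_that("proposed network has the expected structure", {
  net <- mr_network("proposed")
  expect_equal(nrow(net$steps), 24)
  expect_equal(nrow(net$species), 22)
  expect_equal(sum(net$species$measured), 11)
  expect_false(any(net$species$measured[net$species$name %in%
                                          c("Int", paste0("P", 1:10))]))
  # second order exactly for the condensation steps
  expect_equal(net$steps$index[net$steps$order == 2], c(1L, 11L, 12L))
  # every measured intermediate has at least one formation step
  products <- unique(unlist(net$steps$products))
  measured_int <- setdiff(net$species$name[net$species$measured],
                          c("Lac", "Lys"))
  expect_true(all(measured_int %in% products))
})

test_that("step exclusion and the comprehensive variant behave as set operations", {
  no_back <- mr_network("proposed", exclude = 14)
  expect_equal(nrow(no_back$steps), 23)
  expect_false(14 %in% no_back$steps$index)
  # Int still present (still fed by step 13)
  expect_true("Int" %in% no_back$species$name)

  comp <- mr_network("comprehensive")
  expect_true(all(mr_network("proposed")$steps$index %in% comp$steps$index))
  expect_gt(nrow(comp$steps), 24)
  expect_error(mr_network("proposed", exclude = 99), "nonexistent")
  expect_error(mr_network("proposed", include = "nonsense"), "unknown optional")
})

test_that("custom networks are validated", {
  expect_error(
    mr_network("custom",
               species = tibble::tibble(name = c("Lac", "P1", "Ghost")),
               steps = tibble::tibble(index = 1L, reactants = list("Lac"),
                                      products = list("P1"))),
    "orphan"
  )
  expect_error(
    mr_network("custom",
               species = tibble::tibble(name = c("Lac", "P1")),
               steps = tibble::tibble(index = 1L, reactants = list("Missing"),
                                      products = list("P1"))),
    "unknown species"
  )
})

test_that("mass-action derivative matches hand-computed fluxes", {
  net <- mr_network()
  y0 <- mr_initial_state(net)

  # all rates zero -> zero derivative
  d0 <- mr_ode_rhs(net, rep(0, 24), y0)
  expect_equal(unname(d0), rep(0, 22))

  # isolated step 15 (Lac -> P1): dLac/dt = -k15 * Lac
  k <- rep(0, 24)
  k[15] <- 4.1e-6
  d <- mr_ode_rhs(net, k, y0)
  expect_equal(unname(d["Lac"]), -4.1e-6 * 939150, tolerance = 1e-12)
  expect_equal(unname(d["P1"]), 4.1e-6 * 939150, tolerance = 1e-12)

  # isolated step 1 (Lac + Lys -> LacLys), printed 110 C rate constant
  k <- rep(0, 24)
  k[1] <- 2.2e-9
  d <- mr_ode_rhs(net, k, y0)
  flux <- 2.2e-9 * 939150 * 194670
  expect_equal(unname(d["LacLys"]), flux, tolerance = 1e-12)
  expect_equal(unname(d["Lac"]), -flux, tolerance = 1e-12)
  expect_equal(unname(d["Lys"]), -flux, tolerance = 1e-12)

  expect_error(mr_ode_rhs(net, k[-1], y0), "missing rate constant")
  y_bad <- y0; y_bad["Lac"] <- -1
  expect_error(mr_ode_rhs(net, k, y_bad), "non-negative")
})

test_that("derivative is homogeneous of degree one in the rate constants", {
  net <- mr_network()
  y0 <- mr_initial_state(net, LacLys = 100, G = 5, MGO = 3, GO = 2, DA = 1)
  k <- mr_rate_constants(120)
  d1 <- mr_ode_rhs(net, k, y0)
  d2 <- mr_ode_rhs(net, 2 * k, y0)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
})

test_that("compiled solver derivative agrees with the plain-R reference", {
  net <- mr_network()
  y0 <- mr_initial_state(net, LacLys = 500, `3DG` = 30, G = 10, MGO = 4)
  k <- mr_rate_constants(130)
  enc <- maillardkin:::encode_network(net)
  # one tiny forward-Euler step through the compiled path vs analytic rhs
  m <- maillardkin:::sim_matrix(enc, k, y0, c(0, 1e-6), 1e-12, 1e-12)
  d_compiled <- (m[2, -1] - m[1, -1]) / 1e-6
  d_ref <- mr_ode_rhs(net, k, y0)
  expect_equal(unname(d_compiled), unname(d_ref[enc$species]),
               tolerance = 1e-4)
})

test_that("moiety closure tags conserve per-step flux where expected", {
  net <- mr_network()
  sp <- net$species
  # lysine never reaches the pure-lactose branch
  expect_false(sp$lysine[sp$name == "Lac"])
  expect_false(sp$lysine[sp$name == "Int"])
  expect_false(sp$lysine[sp$name == "P1"])
  # sugar never reaches the pure-lysine branch
  expect_false(sp$sugar[sp$name == "Lys"])
  expect_false(sp$sugar[sp$name == "P10"])
  # the Amadori compound carries both
  expect_true(sp$sugar[sp$name == "LacLys"] && sp$lysine[sp$name == "LacLys"])

  y <- mr_initial_state(net, Lac = 0, Lys = 100, `3DG` = 0, `1DG` = 0,
                        CML = 0, CEL = 0)
  tot <- mr_moiety_totals(net, y)
  expect_equal(tot$total[tot$moiety == "lysine"], 100)
  expect_equal(tot$total[tot$moiety == "sugar"], 0)

  # transferring mass from Lys to LacLys leaves the lysine total unchanged
  y2 <- mr_initial_state(net, Lac = 0, Lys = 90, LacLys = 10, `3DG` = 0,
                         `1DG` = 0, CML = 0, CEL = 0)
  tot2 <- mr_moiety_totals(net, y2)
  expect_equal(tot2$total[tot2$moiety == "lysine"], 100)
})

test_that("network round-trips through YAML and matches the packaged file", {
  net <- mr_network("proposed")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  mr_write_network(net, tmp)
  back <- mr_read_network(tmp)
  expect_equal(back$species, net$species)
  expect_equal(back$steps$reactants, net$steps$reactants)
  expect_equal(back$steps$products, net$steps$products)

  packaged <- system.file("extdata", "proposed_network.yaml",
                          package = "maillardkin")
  expect_true(nzchar(packaged))
  expect_equal(readLines(packaged), readLines(tmp))
})
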