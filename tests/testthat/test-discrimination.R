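test_that("the candidate library covers the discrimination history", {
  cand <- mr_candidates()
  expect_true(all(c("proposed", "lactulose", "lactosone", "glucose",
                    "heyns", "da_degradation", "no_age_degradation") %in%
                    cand$label))
  expect_false(anyDuplicated(cand$label) > 0)
  # every candidate is a valid network containing the Amadori step
  for (net in cand$network) {
    expect_s3_class(net, "mr_network")
    expect_true(1 %in% net$steps$index)
  }
})

test_that("a spurious zero-rate step loses to the true model by parsimony", {
  net_true <- decay_network()
  net_spur <- mr_network(
    "custom",
    species = tibble::tibble(name = c("Lac", "P1", "P2"),
                             measured = c(TRUE, FALSE, FALSE)),
    steps = tibble::tibble(index = 1:2, reactants = list("Lac", "Lac"),
                           products = list("P1", "P2"))
  )
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.25)),
                            y0 = c(Lac = 1000, P1 = 0), network = net_true,
                            noise = mr_noise_model(cv = 0.03, floor_sd = 0),
                            seed = 8)
  cand <- tibble::tibble(label = c("true", "spurious"),
                         network = list(net_true, net_spur))
  rep <- mr_compare_models(
    cand, ds, 140,
    inits = list(true = c(k1 = 0.25), spurious = c(k1 = 0.25, k2 = 1e-3)),
    y0 = c(Lac = 1000), starts = 1, seed = 1
  )
  # objectives tie (nested models, zero truth); fewer parameters wins
  expect_equal(attr(rep, "preferred"), "true")
  expect_equal(rep$rank[rep$label == "true"], 1L)
  expect_equal(rep$tie_group[rep$label == "true"],
               rep$tie_group[rep$label == "spurious"])
})

test_that("ranking is invariant to candidate order and response rescaling", {
  net_a <- decay_network()
  net_b <- lac_int_network()
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.6, k2 = 3, k3 = 0.05)),
                            y0 = c(Lac = 1000, Int = 0, P1 = 0),
                            network = net_b,
                            noise = mr_noise_model(cv = 0.03, floor_sd = 0),
                            seed = 9)
  inits <- list(decay = c(k1 = 0.3),
                isom = c(k1 = 0.6, k2 = 3, k3 = 0.05))
  cand_ab <- tibble::tibble(label = c("decay", "isom"),
                            network = list(net_a, net_b))
  cand_ba <- cand_ab[2:1, ]
  r1 <- mr_compare_models(cand_ab, ds, 140, inits = inits,
                          y0 = c(Lac = 1000), starts = 1, seed = 1)
  r2 <- mr_compare_models(cand_ba, ds, 140, inits = inits,
                          y0 = c(Lac = 1000), starts = 1, seed = 1)
  expect_equal(attr(r1, "preferred"), attr(r2, "preferred"))
  expect_equal(attr(r1, "preferred"), "isom")

  # uniform rescaling of the (single) response leaves the ranking unchanged
  ds_scaled <- ds
  ds_scaled$concentration <- ds_scaled$concentration * 1000
  inits_s <- inits
  r3 <- mr_compare_models(
    tibble::tibble(label = c("decay", "isom"), network = list(net_a, net_b)),
    ds_scaled, 140, inits = inits_s, y0 = c(Lac = 1e6), starts = 1, seed = 1
  )
  expect_equal(attr(r3, "preferred"), attr(r1, "preferred"))
})

test_that("single-candidate comparisons are rejected and failures reported", {
  d <- small_design(140, times = 1:5)
  ds <- mr_generate_dataset(d, list(`140` = c(k1 = 0.25)),
                            y0 = c(Lac = 1000, P1 = 0),
                            network = decay_network(),
                            noise = mr_noise_model(cv = 0, floor_sd = 0),
                            seed = 1)
  expect_error(
    mr_compare_models(tibble::tibble(label = "only",
                                     network = list(decay_network())),
                      ds, 140),
    "at least two"
  )
  # a candidate whose species don't cover the data fails but is reported
  net_wrong <- mr_network(
    "custom",
    species = tibble::tibble(name = c("CML", "P8"),
                             measured = c(TRUE, FALSE)),
    steps = tibble::tibble(index = 1L, reactants = list("CML"),
                           products = list("P8"))
  )
  rep <- mr_compare_models(
    tibble::tibble(label = c("ok", "wrong"),
                   network = list(decay_network(), net_wrong)),
    ds, 140, inits = list(ok = c(k1 = 0.25)), y0 = c(Lac = 1000),
    starts = 1, seed = 1
  )
  expect_equal(rep$status[rep$label == "wrong"], "failed")
  expect_true(is.na(rep$rank[rep$label == "wrong"]))
  expect_equal(attr(rep, "preferred"), "ok")
})

test_that("identifiability labels reproduce the published flag taxonomy", {
  fit <- reference_recovery_fit(140, uncertainty = TRUE)
  labels <- mr_classify_identifiability(fit)
  ref <- mr_reference_rates()
  r140 <- ref[ref$temperature_C == 140, ]
  # every boundary (0.0 +/- 0.0) entry is recovered as boundary
  for (s in r140$step[r140$flag == "boundary"]) {
    expect_equal(labels$label[labels$step == s], "boundary")
  }
  # published determinate entries come back determinate
  for (s in r140$step[r140$flag == "determinate" & r140$k > 0]) {
    expect_equal(labels$label[labels$step == s], "determinate")
  }
})
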