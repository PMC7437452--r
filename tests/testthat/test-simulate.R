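test_that("default calibration reproduces the closed-form plate statistics", {
  cal <- default_calibration()
  z1 <- compute_zprime(cal$IL1B$mu_hc, cal$IL1B$mu_lc,
                       cal$IL1B$sigma_hc, cal$IL1B$sigma_lc)
  expect_equal(z1, 1 - 3 * 610 / 7980)           # 0.7707...
  expect_equal(round(z1, 2), 0.77)
  expect_equal(compute_sb(cal$IL1B$mu_hc, cal$IL1B$mu_lc), 8.98)
  z6 <- compute_zprime(cal$IL6$mu_hc, cal$IL6$mu_lc,
                       cal$IL6$sigma_hc, cal$IL6$sigma_lc)
  expect_equal(z6, 1 - 3 * 580 / 3290)           # 0.4711...
  expect_equal(round(z6, 2), 0.47)
  expect_equal(compute_sb(cal$IL6$mu_hc, cal$IL6$mu_lc), 4.29)
})

test_that("simulation config validates mixture, capacity and class counts", {
  expect_error(simulation_config(effect_mix = c(inactive = 1.1,
                                                selective_inhibitor = 0.1,
                                                nonspecific_inhibitor = 0,
                                                enhancer = 0,
                                                cytotoxic = 0)),
               "sum to 1")
  expect_error(simulation_config(n_plates = 2, n_compounds = 1000),
               "capacity")
  expect_error(simulation_config(class_counts = c(bogus = 5)),
               "class_counts")
  cfg <- simulation_config(n_plates = 2, n_compounds = 700)
  expect_s3_class(cfg, "sim_config")
})

test_that("the same seed reproduces the screen bit for bit", {
  a <- small_sim(seed = 7)
  b <- small_sim(seed = 7)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth, b$truth)
  c <- small_sim(seed = 8)
  expect_false(identical(a$wells, c$wells))
})

test_that("the generated channels recover the target ratio exactly", {
  sim <- small_sim(seed = 13)
  ratio <- htrf_ratio(sim$wells$em665, sim$wells$em620)
  # noiseless inactive screen: every compound well must normalize to 0%
  cfg0 <- simulation_config(n_plates = 2, n_compounds = 100,
                            class_counts = c(inactive = 100),
                            noise_scale = 0)
  sim0 <- simulate_screen(cfg0, seed = 13)
  res0 <- normalize_screen(sim0$wells)
  expect_equal(res0$activity$percent_inhibition,
               rep(0, nrow(res0$activity)), tolerance = 1e-9)
  expect_true(all(is.finite(ratio)))
})

test_that("truth table conserves compound count and honors exact class counts", {
  sim <- small_sim(seed = 17, n_compounds = 200,
                   class_counts = c(selective_inhibitor = 10,
                                    cytotoxic = 5))
  expect_equal(nrow(sim$truth), 200L)
  tab <- table(sim$truth$effect_class)
  expect_equal(unname(tab["selective_inhibitor"]), 10L)
  expect_equal(unname(tab["cytotoxic"]), 5L)
  # selective inhibitors leave IL-6 untouched; inactives have no effect
  sel <- sim$truth[sim$truth$effect_class == "selective_inhibitor", ]
  expect_true(all(sel$true_inhibition_il6 == 0))
  expect_true(all(sel$true_inhibition_il1b > 0))
  ina <- sim$truth[sim$truth$effect_class == "inactive", ]
  expect_true(all(ina$true_inhibition_il1b == 0))
})

test_that("planted full-strength inhibitors are selected exactly under zero noise", {
  cfg <- simulation_config(n_plates = 2, n_compounds = 100,
                           class_counts = c(inactive = 90,
                                            selective_inhibitor = 10),
                           potency_range = c(1e-6, 1e-6),  # f ~ 1 at 1 uM
                           noise_scale = 0)
  sim <- simulate_screen(cfg, seed = 19)
  res <- run_screen(sim$wells, sim$map, sim$annotations)
  selected <- res$outcomes$compound_id[res$outcomes$stage ==
                                         "primary_selected"]
  planted <- sim$truth$compound_id[sim$truth$effect_class ==
                                     "selective_inhibitor"]
  expect_setequal(selected, planted)
})

test_that("dose-response simulation hits the Hill midpoint and conserves rows", {
  truth <- data.frame(compound_id = c("s1", "n1", "i1"),
                      effect_class = c("selective_inhibitor",
                                       "nonspecific_inhibitor", "inactive"),
                      true_ic50_il1b = c(2, 0.5, NA),
                      true_ic50_il6 = c(NA, 0.5, NA),
                      true_inhibition_il1b = c(33.3, 66.7, 0),
                      true_inhibition_il6 = c(0, 66.7, 0))
  dr <- simulate_dose_response(truth, doses = c(0.5, 2, 8),
                               replicates = 4, noise_sd = 0, seed = 3)
  expect_equal(nrow(dr), 3L * 2L * 3L * 4L)
  mid <- dr$percent_inhibition[dr$compound_id == "s1" &
                                 dr$analyte == "IL1B" &
                                 dr$concentration_uM == 2]
  expect_equal(mid, rep(50, 4))
  il6_sel <- dr$percent_inhibition[dr$compound_id == "s1" &
                                     dr$analyte == "IL6"]
  expect_true(all(il6_sel == 0))
  ina <- dr$percent_inhibition[dr$compound_id == "i1"]
  expect_true(all(ina == 0))
})

test_that("simulated plate statistics track the calibrated population values", {
  # full-size screen, fixed seed: 16-plate mean Z' within 0.03 and mean
  # S/B within 0.30 of the population values for each analyte
  sim <- simulate_screen(simulation_config(), seed = 2024)
  res <- normalize_screen(sim$wells)
  qc <- qc_plate(res$controls)
  cal <- default_calibration()
  for (an in c("IL1B", "IL6")) {
    p <- cal[[an]]
    zpop <- compute_zprime(p$mu_hc, p$mu_lc, p$sigma_hc, p$sigma_lc)
    sbpop <- compute_sb(p$mu_hc, p$mu_lc)
    zbar <- mean(qc$z_prime[qc$analyte == an])
    sbbar <- mean(qc$sb_ratio[qc$analyte == an])
    expect_lt(abs(zbar - zpop), 0.03)
    expect_lt(abs(sbbar - sbpop), 0.30)
  }
})
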