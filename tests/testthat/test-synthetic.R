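test_that("lognormal generator hits its median and validates input", {
  for (med in c(0.8, 9.3, 40)) {
    p <- lognormal_psd(med, 2)
    expect_equal(d50(p), med, tolerance = 0.01)
    expect_equal(sum(p$fraction), 1, tolerance = 1e-12)
  }
  expect_identical(lognormal_psd(5, 2), lognormal_psd(5, 2)) # deterministic
  expect_error(lognormal_psd(-1, 2), "positive")
  expect_error(lognormal_psd(5, 0.9), "> 1")
  expect_error(lognormal_psd(5, 2, n_bins = 4), "at least 10")
})

test_that("a vanishing spread collapses to the convention point value", {
  q <- material("quartz", 2.66)
  p <- lognormal_psd(3, 1.001)
  expect_equal(swerf_from_psd(p, q)$swerf,
               respirable_fraction(3 * sqrt(2.66)), tolerance = 1e-3)
})

test_that("generated SWeRF matches a Monte-Carlo draw from the lognormal", {
  set.seed(42)
  n_mc <- 1e5
  for (i in 1:8) {
    med <- stats::runif(1, 2, 25)
    gsd <- stats::runif(1, 1.5, 2.5)
    p <- lognormal_psd(med, gsd, diameter_basis = "aerodynamic")
    D <- stats::rlnorm(n_mc, log(med), log(gsd))
    R <- respirable_fraction(D)
    se <- stats::sd(R) / sqrt(n_mc)
    expect_lt(abs(swerf_from_psd(p)$swerf - mean(R)), 3 * se + 1e-4)
  }
})

test_that("spiked blends are component-level and exactly linear", {
  quartz <- list(psd = lognormal_psd(3, 2),
                 material = material("quartz flour", 2.66,
                                     cs_mass_fraction = 1))
  barite <- list(psd = lognormal_psd(40, 2),
                 material = material("barite", 4.48, cs_mass_fraction = 0))
  spike_swerf <- swerf_from_psd(quartz$psd, quartz$material)$swerf
  b0 <- spiked_blend(barite, quartz, 0)
  expect_equal(b0$blend$swerf, swerf_from_psd(barite$psd, barite$material)$swerf)
  expect_equal(b0$cs_mass_fraction, 0)
  b1 <- spiked_blend(barite, quartz, 1)
  expect_equal(b1$blend$swerf, spike_swerf)
  expect_equal(b1$cs_mass_fraction, 1)
  for (f in c(0.25, 0.5, 0.75)) {
    b <- spiked_blend(barite, quartz, f)
    expect_equal(b$blend$swerf_cs, f * spike_swerf, tolerance = 1e-12)
    expect_equal(b$cs_mass_fraction, f)
  }
  expect_error(spiked_blend(barite, quartz, 1.2), "\\[0, 1\\]")
})

test_that("noise-free virtual runs are deterministic and exact", {
  fx <- repeatability_fixture()
  aero <- to_aerodynamic(fx$psd, fx$material)
  plan <- sedimentation_plan(fx$material, extraction_height_m = 0.05,
                             column_height_m = 0.20)
  truth <- virtual_sedimentation(aero, plan)$swerf
  r1 <- noisy_sedimentation_run(aero, plan, noise = 0, seed = 1)
  r2 <- noisy_sedimentation_run(aero, plan, noise = 0, seed = 999)
  expect_identical(r1$m_mg, r2$m_mg)
  expect_equal(swerf_from_measurement(r1)$swerf, truth, tolerance = 1e-12)
  s1 <- noisy_sedimentation_run(aero, plan, noise = 0.09, n_replicates = 7,
                                seed = 7)
  s2 <- noisy_sedimentation_run(aero, plan, noise = 0.09, n_replicates = 7,
                                seed = 7)
  expect_identical(s1$m_mg, s2$m_mg)
  expect_error(noisy_sedimentation_run(aero, plan, noise = -0.1), ">= 0")
})

test_that("replicate scatter of the noisy runs emulates the repeatability study", {
  fx <- repeatability_fixture()
  aero <- to_aerodynamic(fx$psd, fx$material)
  plan <- sedimentation_plan(fx$material, extraction_height_m = 0.05,
                             column_height_m = 0.20)
  sds <- vapply(seq_len(200), function(s) {
    runs <- noisy_sedimentation_run(aero, plan, noise = 0.09,
                                    n_replicates = 7, seed = s)
    stats::sd(100 * swerf_from_measurement(runs)$swerf)
  }, numeric(1))
  med_sd <- stats::median(sds)
  expect_gt(med_sd, 0.5 * 1.41)
  expect_lt(med_sd, 2 * 1.41)
})
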