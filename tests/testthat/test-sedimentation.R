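quartz_plan <- function(...) {
  sedimentation_plan(material("quartz", 2.66), extraction_height_m = 0.05,
                     column_height_m = 0.20, ...)
}

test_that("survival probability follows the depletion geometry", {
  plan <- quartz_plan()
  Dc <- plan$cut_diameter_um
  expect_equal(survival_probability(0, plan), 1.0)
  expect_equal(survival_probability(Dc, plan), 0.0)
  expect_equal(survival_probability(Dc / sqrt(2), plan), 0.5)
  expect_equal(survival_probability(2 * Dc, plan), 0.0) # already settled
  D <- seq(0, 2 * Dc, length.out = 100)
  expect_true(all(diff(survival_probability(D, plan)) <= 0))
  expect_error(survival_probability(1, list()), "derived")
})

test_that("cut diameter equates the convention and survival integrals", {
  Dc <- cut_diameter()
  expect_equal(Dc, 1.5 * respirable_integral(), tolerance = 1e-9)
  expect_equal(Dc, 6.4215, tolerance = 1e-4)
  # numerical equating on a fine grid: integral of S equals integral of R
  plan <- quartz_plan()
  g <- seq(0, 50, by = 0.005)
  S <- survival_probability(g, plan)
  int_S <- sum((S[-1] + S[-length(S)]) / 2) * 0.005
  expect_equal(int_S, trapezoid_integral(), tolerance = 1e-4)
  # no inhalable decay: closed-form lognormal integral
  expect_equal(cut_diameter(convention_params(inhalable_decay = 0)),
               1.5 * 4.25 * exp(log(1.5)^2 / 2), tolerance = 1e-6)
  expect_lt(cut_diameter(convention_params(respirable_median = 1e-6)), 1e-3)
})

test_that("settling time matches a Stokes-law hand computation", {
  w <- liquid_properties("water", 1.00e-3, 1000)
  t <- settling_time(6.43, 2660, w, extraction_height_m = 0.05)
  # oracle: v = g (rho_p - rho_l) d^2 / (18 eta), d = D_c / sqrt(2.66)
  d <- 6.43e-6 / sqrt(2.66)
  v <- 9.81 * (2660 - 1000) * d^2 / (18 * 1.00e-3)
  expect_equal(t, 0.05 / v, tolerance = 1e-12)
  expect_equal(t, 3.56e3, tolerance = 2e-3)
  expect_equal(settling_time(6.43, 2660, w, 0.10), 2 * t)
  expect_equal(settling_time(2 * 6.43, 2660, w, 0.05), t / 4)
  expect_error(settling_time(6.43, 900, w, 0.05), "do not settle")
})

test_that("a derived plan carries consistent cut and time", {
  plan <- quartz_plan()
  expect_equal(plan$settling_time_s,
               settling_time(plan$cut_diameter_um, 2660, plan$liquid, 0.05))
  expect_gt(plan$settling_time_s, 0)
  expect_error(sedimentation_plan(material("q", 2.66),
                                  extraction_height_m = 0.3,
                                  column_height_m = 0.2), "height")
  expect_output(print(plan), "cut diameter")
})

test_that("gravimetric records evaluate to m H / (M h), clamped", {
  r <- swerf_from_measurement(
    data.frame(M_mg = 5000, m_mg = 100, H_mm = 200, h_mm = 40))
  expect_equal(r$swerf, 0.100)
  expect_equal(r$method, "sedimentation")
  expect_equal(swerf_from_measurement(
    data.frame(M_mg = 5000, m_mg = 0, H_mm = 200, h_mm = 40))$swerf, 0)
  # homogeneous extraction limit: nothing settled yet
  expect_equal(swerf_from_measurement(
    data.frame(M_mg = 5000, m_mg = 1000, H_mm = 200, h_mm = 40))$swerf, 1)
  expect_warning(
    c1 <- swerf_from_measurement(
      data.frame(M_mg = 5000, m_mg = 1050, H_mm = 200, h_mm = 40)),
    "clamped")
  expect_equal(c1$swerf, 1)
  expect_error(swerf_from_measurement(
    data.frame(M_mg = 100, m_mg = 200, H_mm = 200, h_mm = 40)), "m <= M")
  expect_error(swerf_from_measurement(
    data.frame(M_mg = 5000, m_mg = 10, H_mm = 100, h_mm = 200)), "h <= H")
})

test_that("measured SWeRF is invariant to common rescaling of masses or heights", {
  base <- data.frame(M_mg = 5000, m_mg = 130, H_mm = 200, h_mm = 40)
  s0 <- swerf_from_measurement(base)$swerf
  masses <- transform(base, M_mg = M_mg * 3.7, m_mg = m_mg * 3.7)
  heights <- transform(base, H_mm = H_mm * 0.5, h_mm = h_mm * 0.5)
  expect_equal(swerf_from_measurement(masses)$swerf, s0)
  expect_equal(swerf_from_measurement(heights)$swerf, s0)
})

test_that("constituent SWeRF is the residue-fraction product", {
  expect_equal(round(100 * swerf_cs_from_measurement(0.345, 0.283), 1), 9.8)
  expect_equal(round(100 * swerf_cs_from_measurement(0.408, 0.794), 1), 32.4)
  expect_equal(swerf_cs_from_measurement(0.5, 0), 0)
  expect_error(swerf_cs_from_measurement(1.2, 0.5), "\\[0, 1\\]")
  # batch route through the measurement table
  r <- swerf_from_measurement(
    data.frame(M_mg = 5000, m_mg = 345, H_mm = 200, h_mm = 40, f_cs = 0.283))
  expect_equal(r$swerf_cs, 0.345 * 0.283)
})

test_that("virtual sedimentation equals the calculated SWeRF on uniform mass", {
  plan <- quartz_plan()
  p <- uniform_psd(30, 3000)
  expect_equal(virtual_sedimentation(p, plan)$swerf, swerf_from_psd(p)$swerf,
               tolerance = 1e-3)
  expect_lt(virtual_sedimentation(dirac_psd(50), plan)$swerf, 1e-9)
  expect_gt(virtual_sedimentation(dirac_psd(0.01), plan)$swerf, 0.999)
  expect_error(virtual_sedimentation(lognormal_psd(5, 2), plan), "aerodynamic")
})

test_that("the two routes agree for realistic lognormal powders", {
  plan <- quartz_plan()
  for (med in c(2, 5, 10, 20, 30)) {
    for (gsd in c(1.5, 2.0, 2.5)) {
      p <- lognormal_psd(med, gsd, diameter_basis = "aerodynamic")
      expect_lt(abs(virtual_sedimentation(p, plan)$swerf -
                      swerf_from_psd(p)$swerf), 0.05)
    }
  }
})

test_that("the dilute-suspension rule warns above 1% v/v", {
  expect_silent(v <- check_solids_loading(5, 2660, 250))
  expect_lt(v, 0.01)
  expect_warning(check_solids_loading(10, 2660, 250), "hindered")
})
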