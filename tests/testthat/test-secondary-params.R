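# Non-compartmental summaries: trapezoid AUC, peak, terminal slope, Vss, ratios.

test_that("trapezoidal AUC handles constant, exponential and model curves", {
  expect_equal(auc_trapezoid(c(0, 6, 12, 24), rep(5, 4)), 24 * 5)
  tt <- seq(0, 72, 0.25)
  k <- 0.1
  expect_equal(auc_trapezoid(tt, 100 * exp(-k * tt), extrapolate = TRUE),
               100 / k, tolerance = 5e-3)
  cv <- solve_profile(pub_typ, regimen(1, "IV"), STUDY_TIMES[-1])
  auc <- auc_trapezoid(cv$times, cv$c_parent, extrapolate = TRUE)
  expect_equal(auc, IV_DOSE / pub_typ$Cl, tolerance = 0.01)
  expect_error(auc_trapezoid(c(0, 1), c(1, 1), t_end = 5), "within")
  # monotone in interval length; extrapolation only adds area
  a24 <- auc_trapezoid(cv$times, cv$c_parent, t_end = 24)
  a72 <- auc_trapezoid(cv$times, cv$c_parent, t_end = 72)
  expect_lt(a24, a72)
  expect_lt(a72, auc)
})

test_that("Cmax/Tmax break ties at the earliest time and order the formulations", {
  expect_equal(cmax_tmax(1:4, c(1, 7, 7, 2)), list(cmax = 7, tmax = 2))
  cv <- solve_profile(pub_typ, regimen(1, "IV"), STUDY_TIMES[-1])
  expect_equal(cmax_tmax(cv$times, cv$c_parent)$tmax, STUDY_TIMES[2])
  mic <- solve_profile(typical_params("micellar"),
                       regimen(10, "oral", "micellar"), STUDY_TIMES[-1])
  oil <- solve_profile(typical_params("oil"),
                       regimen(10, "oral", "oil"), STUDY_TIMES[-1])
  expect_lt(cmax_tmax(mic$times, mic$c_parent)$tmax,
            cmax_tmax(oil$times, oil$c_parent)$tmax)
})

test_that("log-linear terminal half-life recovers known slopes", {
  tt <- c(8, 12, 24, 36, 48, 72)
  th <- terminal_half_life(tt, 50 * exp(-0.0231 * tt))
  expect_equal(th$t_half, log(2) / 0.0231, tolerance = 1e-6)
  cv <- solve_profile(pub_typ, regimen(1, "IV"), STUDY_TIMES[-1])
  est <- terminal_half_life(cv$times, cv$c_parent)
  expect_equal(est$t_half, terminal_slope(pub_typ)$t_half, tolerance = 0.03)
  expect_error(terminal_half_life(c(1, 2, 3), c(3, 2, 1)), "3")  # 2 post-peak
  expect_error(terminal_half_life(c(1, 2), c(2, 1)), "3")
  expect_error(terminal_half_life(tt, 50 * exp(-0.0231 * tt), n_points = 10),
               "n_points")
})

test_that("Vss is the volume sum and its population mean sits near the reported value", {
  expect_equal(vss(pub_typ), 32.15 + 36.12)
  p0 <- structural_params(F = 0.5, ka = 1, beta = 1, Cl = 1, Vc = 3,
                          Q = 1, Vp = 1e-9, Fm = 0.5, Clm = 1, Vm = 1)
  expect_equal(vss(p0), 3, tolerance = 1e-6)
  smp <- sample_population(pub_pop, 4000, seed = 5)
  expect_equal(mean(smp$params$Vc + smp$params$Vp), 75.58, tolerance = 0.04)
})

test_that("metabolite/parent AUC ratio follows the molar closed form and scales", {
  tt <- seq(0.25, 72, 0.25)
  same <- concentration_curve(tt, exp(-0.05 * tt), exp(-0.05 * tt))
  expect_equal(auc_ratio(same), 1)
  half <- concentration_curve(tt, 2 * exp(-0.05 * tt), exp(-0.05 * tt))
  expect_equal(auc_ratio(half), 0.5)
  # typical IV ratio over the infinite interval: Fm*Cl/Clm = 78.28
  cv <- solve_profile(pub_typ, regimen(1, "IV"), c(seq(0.25, 72, 0.25),
                                                   seq(76, 400, 4)))
  r <- auc_ratio(cv, extrapolate = TRUE)
  expect_equal(r, pub_typ$Fm * pub_typ$Cl / pub_typ$Clm, tolerance = 0.02)
  zero <- concentration_curve(tt, rep(0, length(tt)), exp(-0.05 * tt))
  expect_error(auc_ratio(zero), "parent AUC")
})

test_that("exposure_summary assembles the secondary-parameter row", {
  cv <- solve_profile(pub_typ, regimen(1, "IV"), STUDY_TIMES[-1])
  es <- exposure_summary(cv, "parent", params = pub_typ)
  expect_equal(es$vss, 68.27)
  expect_lt(es$auc24, es$auc_inf)
  expect_equal(es$cmax, max(cv$c_parent))
  expect_equal(es$t_half, 28.42, tolerance = 0.05)
})
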