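# Random-effect layer: transforms, covariate mapping, sampling, residual error.

test_that("variability percentages convert by the CV convention (direct SD on the logit scale)", {
  expect_equal(percent_to_sd(0), 0)
  expect_equal(percent_to_sd(27.95), sqrt(log(1 + 0.2795^2)))
  expect_equal(percent_to_sd(27.95), 0.2743, tolerance = 1e-3)
  expect_equal(percent_to_sd(66.74), 0.6071, tolerance = 1e-3)
  expect_equal(percent_to_sd(25.52, transform = "logit"), 0.2552)
  expect_error(percent_to_sd(-5), "non-negative")
})

test_that("zero random effects reproduce the category-adjusted typical values", {
  mic <- realize_individual(pub_pop, "micellar")
  expect_equal(mic$ka, 0.99)
  expect_equal(mic$beta, 1.59)
  expect_equal(mic$F, 0.28)
  oil <- realize_individual(pub_pop, "oil")
  expect_equal(oil$ka, 0.31, tolerance = 1e-10)
  expect_equal(oil$beta, 0.70, tolerance = 1e-10)
  expect_equal(oil$Cl, mic$Cl)      # covariate touches absorption only
  expect_equal(oil$Fm, 0.75)        # metabolized fraction stays fixed
  expect_error(realize_individual(pub_pop, "sublingual"), "micellar")
})

test_that("log-normal random effects act multiplicatively on the typical value", {
  th <- realize_individual(pub_pop, "micellar", eta_iiv = c(Cl = 0.2743))
  expect_equal(th$Cl, 1.67 * exp(0.2743), tolerance = 1e-6)
  expect_equal(th$Cl, 2.198, tolerance = 1e-3)
  # IIV and IOV compose additively on the transformed scale
  th2 <- realize_individual(pub_pop, "micellar", eta_iiv = c(ka = 0.1),
                            eta_iov = c(ka = 0.2))
  expect_equal(th2$ka, 0.99 * exp(0.3), tolerance = 1e-10)
})

test_that("population sampling respects bounds, moments and determinism", {
  smp <- sample_population(pub_pop, 5000, seed = 11)
  F_draws <- smp$params$F
  expect_true(all(F_draws > 0 & F_draws < 1))      # logit bound
  om <- percent_to_sd(27.95)
  expect_equal(mean(smp$params$Cl), 1.67 * exp(om^2 / 2), tolerance = 0.02)
  expect_equal(median(smp$params$Cl), 1.67, tolerance = 0.02)
  # population mean Vss = mean(Vc) + mean(Vp), about 75.6 L/kg
  expect_equal(mean(smp$params$Vc + smp$params$Vp), 75.58, tolerance = 0.03)
  smp2 <- sample_population(pub_pop, 5000, seed = 11)
  expect_identical(smp$params, smp2$params)
  smp3 <- sample_population(pub_pop, 50, seed = 12)
  expect_false(identical(smp3$params$Cl[1], smp$params$Cl[1]))
})

test_that("removing IOV makes a subject's two oral occasions share absorption parameters", {
  pop_noiov <- population_model(typical = pub_pop$typical,
                                iiv_pct = pub_pop$iiv_pct,
                                iov_pct = c(F = 0, ka = 0, beta = 0),
                                cov_oil = pub_pop$cov_oil)
  des <- data.frame(occasion = c(2, 3), route = "oral",
                    formulation = "micellar")
  smp <- sample_population(pop_noiov, 10, design = des, seed = 3)
  for (i in 1:10) {
    two <- smp$params[smp$params$subject == i, ]
    expect_equal(two$F[1], two$F[2])
    expect_equal(two$ka[1], two$ka[2])
    expect_equal(two$beta[1], two$beta[2])
  }
})

test_that("the proportional residual error model behaves at its edges and at scale", {
  cv <- concentration_curve(times = 1:5, c_parent = c(10, 8, 0, 4, 2),
                            c_metabolite = rep(1, 5))
  ex <- apply_residual_error(cv, b1 = 0, b2 = 0, seed = 1)
  expect_equal(ex$obs_parent, cv$c_parent)        # b = 0: exact
  expect_equal(ex$obs_parent[3], 0)               # zero prediction stays zero
  n <- 1e5
  big <- concentration_curve(times = seq_len(n), c_parent = rep(100, n),
                             c_metabolite = rep(100, n))
  noisy <- apply_residual_error(big, b1 = 0.29, b2 = 0.41, seed = 2)
  expect_equal(sd(noisy$obs_parent / 100 - 1), 0.29, tolerance = 0.01)
  expect_error(apply_residual_error(cv, b1 = -0.1), ">= 0")
})

test_that("the population model serializes to and from the table-layout configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_population_model(pub_pop, path)
  back <- read_population_model(path)
  expect_equal(back$typical, pub_pop$typical)
  expect_equal(back$omega, pub_pop$omega)
  expect_equal(back$cov_oil, pub_pop$cov_oil, tolerance = 1e-10)
  expect_equal(back$b1, pub_pop$b1)
  expect_equal(back$Fm, pub_pop$Fm)
})
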