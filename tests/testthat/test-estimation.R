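# SAEM layer: contracts, self-consistency, EBEs, bootstrap, convergence runs.

test_that("fitting contracts are enforced", {
  st <- small_study(n = 2, seed = 13)
  expect_error(fit_nlme(st$data, free = "Fm"), "parameter is fixed")
  expect_error(fit_nlme(st$data, fixed = c()), "Fm")
  one <- st$data[st$data$ID == 1, ]
  expect_error(fit_nlme(as_pk_dataset(one)), "2 subjects")
  expect_error(convergence_assessment(st$data, n_runs = 1), "2 runs")
  expect_error(bootstrap(st$data, list(), n_replicates = 1), "2 bootstrap")
})

test_that("a noise-free zero-variability study started at truth is recovered", {
  pop0 <- noise_free_pop()
  st <- generate_study(pop0, study_design(n_subjects = 3), seed = 5)
  fit <- suppressWarnings(
    fit_nlme(st$data, init = pop0,
             settings = saem_settings(n_burn = 100, n_sa = 100,
                                      compute_ll = FALSE), seed = 1))
  rel <- fit$pop$typical / pub_pop$typical - 1
  # data-rich parameters pin down tightly; Q (no random effect) is loosest
  expect_lt(max(abs(rel[c("F", "ka", "beta", "Cl", "Vm", "Clm")])), 0.05)
  expect_lt(max(abs(rel[c("Vc", "Vp")])), 0.12)
  expect_lt(abs(rel[["Q"]]), 0.20)
  expect_equal(fit$pop$Fm, 0.75)                  # fixed stays fixed
  expect_equal(unname(fit$cov_oil[["ka"]]), log(0.31 / 0.99), tolerance = 0.1)
})

test_that("information criteria follow their definitions and fits are seed-reproducible", {
  st <- small_study(n = 4, seed = 19)
  sett <- saem_settings(n_burn = 40, n_sa = 30, ll_nsim = 40)
  fit <- fit_nlme(st$data, settings = sett, seed = 8)
  expect_equal(fit$aic, fit$minus2ll + 2 * fit$n_param)
  expect_equal(fit$bic, fit$minus2ll + fit$n_param * log(4))
  fit2 <- fit_nlme(st$data, settings = sett, seed = 8)
  expect_identical(fit$pop$typical, fit2$pop$typical)
  expect_identical(fit$minus2ll, fit2$minus2ll)
  # identical fits: no BIC difference, covariate not retained
  cmp <- compare_covariate_models(fit, fit2)
  expect_equal(cmp$delta_bic, 0)
  expect_false(cmp$retain)
  other <- small_study(n = 4, seed = 20)
  fit3 <- fit_nlme(other$data, settings = sett, seed = 8)
  expect_error(compare_covariate_models(fit, fit3), "same dataset")
})

test_that("empirical Bayes estimates shrink to the typical value without data", {
  st <- small_study(n = 3, seed = 23)
  ds <- as.data.frame(st$data)
  # subject 3 loses all observations to the LOQ flag
  ds$BLQ[ds$ID == 3 & ds$DVID != 0] <- 1L
  fit <- fit_nlme(as_pk_dataset(ds),
                  settings = saem_settings(n_burn = 40, n_sa = 30,
                                           compute_ll = FALSE), seed = 2)
  eb <- compute_ebes(fit)
  expect_equal(length(fit$subjects), 3)
  i3 <- which(vapply(fit$subjects, `[[`, numeric(1), "id") == 3)
  expect_equal(unname(eb$eta[i3, c("Cl", "Vc", "Vp", "Vm", "Clm")]),
               rep(0, 5))
  expect_true(is.na(eb$shrinkage_pct[["Q"]]))      # no random effect
  expect_true(all(is.finite(eb$shrinkage_pct[c("Cl", "Vc", "F")])))
})

test_that("bootstrap resampling is reproducible and brackets the estimate", {
  st <- small_study(n = 5, seed = 29)
  sett <- saem_settings(n_burn = 60, n_sa = 60, compute_ll = FALSE)
  fit <- fit_nlme(st$data, settings = sett, seed = 3)
  bs1 <- bootstrap(st$data, fit, n_replicates = 2, seed = 7)
  bs2 <- bootstrap(st$data, fit, n_replicates = 2, seed = 7)
  expect_identical(bs1$estimates, bs2$estimates)
  expect_equal(bs1$n_failed, 0)
  expect_true(all(bs1$ci$lower <= bs1$ci$upper))
})

test_that("perturbed starting points converge to consistent estimates", {
  st <- small_study(n = 4, seed = 31)
  ca <- convergence_assessment(st$data, n_runs = 2, perturbation = 0.2,
                               settings = saem_settings(n_burn = 60,
                                                        n_sa = 40,
                                                        compute_ll = FALSE),
                               seed = 5)
  expect_equal(nrow(ca$estimates), 2)
  # clearance is the best-identified parameter: runs agree closely
  expect_lt(ca$cv_pct[["Cl"]], 10)
})
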