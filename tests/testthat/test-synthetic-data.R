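# Study generator: reproducibility, design structure, noise-free limit, LOQ.

test_that("a fixed seed reproduces the dataset exactly", {
  a <- generate_study(design = study_design(n_subjects = 2), seed = 42)
  b <- generate_study(design = study_design(n_subjects = 2), seed = 42)
  expect_identical(a$data, b$data)
  expect_identical(a$truth$params, b$truth$params)
  c <- generate_study(design = study_design(n_subjects = 2), seed = 43)
  expect_false(identical(a$data$DV, c$data$DV))
})

test_that("the default design yields the expected row structure", {
  st <- small_study()
  ds <- st$data
  expect_equal(length(unique(ds$ID)), 8)
  expect_equal(sum(ds$DVID == 0), 8 * 3)                 # one dose row each
  # per occasion: 2 pre-dose + 15 post-dose rows per analyte
  expect_equal(sum(ds$DVID == 1), 8 * 3 * 16)
  expect_equal(sum(ds$DVID == 2), 8 * 3 * 16)
  # dose row precedes observations; occasions alternate oral formulations
  expect_true(all(tapply(seq_len(nrow(ds)), interaction(ds$ID, ds$OCC),
                         function(ix) which(ds$DVID[ix] == 0)[1] == 1)))
  expect_setequal(unique(ds$FORM[ds$OCC == 1]), "none")
  expect_setequal(unique(ds$FORM[ds$OCC %in% 2:3]), c("micellar", "oil"))
  # pre-dose observations are zero and flagged below the LOQ
  pre <- ds[ds$TIME == 0 & ds$DVID %in% 1:2, ]
  expect_true(all(pre$DV == 0))
  expect_true(all(pre$BLQ == 1))
})

test_that("with no variability and no noise the data equal the typical curves", {
  st <- generate_study(noise_free_pop(), study_design(n_subjects = 2),
                       seed = 1)
  ds <- st$data
  post <- STUDY_TIMES[STUDY_TIMES > 0]
  for (form in c("micellar", "oil")) {
    cv <- solve_profile(typical_params(form),
                        regimen(10, "oral", form), post)
    sub <- ds[ds$ID == 1 & ds$FORM == form & ds$DVID == 1 & ds$TIME > 0, ]
    expect_equal(sub$DV, cv$c_parent, tolerance = 1e-6)
    subm <- ds[ds$ID == 1 & ds$FORM == form & ds$DVID == 2 & ds$TIME > 0, ]
    expect_equal(subm$DV, cv$c_metabolite, tolerance = 1e-6)
  }
})

test_that("LOQ censoring flags exactly the sub-threshold tail", {
  st <- generate_study(noise_free_pop(), study_design(n_subjects = 1),
                       seed = 1)
  ds <- st$data
  # zero LOQ: nothing flagged
  none <- censor_loq(ds, 0, 0)
  expect_equal(sum(none$BLQ), 0)
  # choose a threshold crossing between 48 and 72 h on the IV parent curve
  iv <- ds[ds$FORM == "none" & ds$DVID == 1 & ds$TIME > 0, ]
  thr <- sqrt(iv$DV[iv$TIME == 48] * iv$DV[iv$TIME == 72])
  cut <- censor_loq(ds, loq_parent = thr, loq_metabolite = 0)
  iv_cut <- cut[cut$FORM == "none" & cut$DVID == 1 & cut$TIME > 0, ]
  expect_equal(iv_cut$TIME[iv_cut$BLQ == 1], 72)
  # everything censored: the fit refuses
  all_cut <- censor_loq(ds, 1e9, 1e9)
  expect_error(fit_nlme(all_cut), "quantifiable")
})

test_that("simulated between-subject spread of Cl reproduces the input IIV", {
  smp <- sample_population(pub_pop, 400,
                           design = data.frame(occasion = 1, route = "IV",
                                               formulation = "none"),
                           seed = 9)
  cv_pct <- 100 * sd(smp$params$Cl) / mean(smp$params$Cl)
  expect_equal(cv_pct, 27.95, tolerance = 0.12)
})
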