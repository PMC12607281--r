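# Multiple-dose Monte Carlo: steady-state identities, accumulation, summaries.

test_that("without variability every subject reproduces the typical steady-state exposure", {
  pop0 <- noise_free_pop()
  mm <- monte_carlo_regimen(pop0, regimen_spec(n_subjects = 5, seed = 1))
  target <- pub_typ$F * ORAL_DOSE / pub_typ$Cl    # 5297.8 nmol h/L
  expect_equal(unname(mm$auc_ss_parent), rep(target, 5), tolerance = 1e-3)
  expect_equal(sd(mm$auc24_parent), 0, tolerance = 1e-6)
})

test_that("accumulation is at least one, equal across analytes, and vanishes for long intervals", {
  mm <- monte_carlo_regimen(pub_pop, regimen_spec(n_subjects = 150, seed = 4))
  expect_true(all(mm$accumulation_parent >= 1))
  expect_true(all(mm$accumulation_metabolite >= 1))
  # formation-limited metabolite accumulates like the parent
  ratio <- mm$accumulation_metabolite / mm$accumulation_parent
  expect_lt(median(abs(ratio - 1)), 0.02)
  expect_lt(max(abs(ratio - 1)), 0.10)
  # last-interval AUC never exceeds the subject's single-dose AUC0-inf
  smp <- sample_population(pub_pop, 150, seed = 4)
  expect_true(all(mm$auc_ss_parent <=
                    smp$params$F * ORAL_DOSE / smp$params$Cl * (1 + 1e-6)))
  long <- monte_carlo_regimen(noise_free_pop(),
                              regimen_spec(interval = 2000, n_doses = 3,
                                           n_subjects = 2, seed = 1,
                                           grid_dt = 5))
  expect_equal(unname(long$accumulation_parent), c(1, 1), tolerance = 0.01)
})

test_that("metric summaries report the central statistic with CV and degenerate cases", {
  mm <- monte_carlo_regimen(pub_pop, regimen_spec(n_subjects = 40, seed = 2))
  sm <- summarize_metrics(mm)
  expect_equal(sm$estimate[sm$metric == "auc_ss_parent"],
               median(mm$auc_ss_parent))
  one <- mm[1, ]
  s1 <- summarize_metrics(one)
  expect_true(all(s1$cv_pct == 0))
  dup <- mm[rep(1, 6), ]
  sdup <- summarize_metrics(dup)
  expect_equal(sdup$estimate[sdup$metric == "auc24_parent"],
               mm$auc24_parent[1])
  expect_equal(max(sdup$cv_pct), 0, tolerance = 1e-10)
  # doubling the sample leaves the medians stable
  big <- monte_carlo_regimen(pub_pop, regimen_spec(n_subjects = 800, seed = 5))
  big2 <- monte_carlo_regimen(pub_pop, regimen_spec(n_subjects = 1600, seed = 6))
  expect_equal(median(big$auc_ss_parent), median(big2$auc_ss_parent),
               tolerance = 0.08)
})

test_that("time to steady state matches the one-compartment closed form and the drug's profile", {
  # one-compartment toy, t1/2 = 24 h, q24h: 1 - 2^-n >= 0.9 first at n = 4
  toy <- population_model(
    typical = c(F = 0.9, ka = 10, beta = 1, Cl = log(2) / 24, Vc = 1,
                Q = 1e-9, Vp = 1e-6, Vm = 1, Clm = 1),
    iiv_pct = numeric(), iov_pct = numeric(), b1 = 0, b2 = 0)
  tss <- time_to_steady_state(toy, regimen_spec(n_doses = 14), threshold = 0.9)
  expect_equal(tss$dose_index, 4)
  # a tiny threshold is met by the first dose
  t0 <- time_to_steady_state(toy, regimen_spec(n_doses = 14),
                             threshold = 1e-6)
  expect_equal(t0$dose_index, 1)
  expect_error(time_to_steady_state(toy, threshold = 1.2), "threshold")
  # typical micellar profile approaches steady state within the first week
  tss_cbg <- time_to_steady_state(pub_pop, regimen_spec(), threshold = 0.9)
  expect_gte(tss_cbg$time_days, 3)
  expect_lte(tss_cbg$time_days, 7)
})
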