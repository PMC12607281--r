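# Deterministic parent-metabolite kinetics: unit bridge, Weibull depot,
# terminal slope, and the compiled ODE kernel against independent oracles.

test_that("mass dose converts to the molar scale", {
  expect_equal(mg_per_kg_to_nmol_per_kg(1, 316.48), 1e6 / 316.48)
  expect_equal(mg_per_kg_to_nmol_per_kg(10, 316.48), 1e7 / 316.48)
  expect_equal(mg_per_kg_to_nmol_per_kg(0.31648, 316.48), 1000)
  expect_error(mg_per_kg_to_nmol_per_kg(-1), "positive")
  expect_error(mg_per_kg_to_nmol_per_kg(1, 0), "positive")
})

test_that("Weibull depot reduces to first order at shape 1 and empties at the survival half-point", {
  tt <- seq(0, 12, 0.5)
  expect_equal(weibull_depot(0.28, 0.99, 1, ORAL_DOSE, tt),
               0.28 * ORAL_DOSE * exp(-0.99 * tt))
  expect_equal(weibull_depot(0.28, 0.99, 1.59, ORAL_DOSE, 0),
               0.28 * ORAL_DOSE)
  t_half <- log(2)^(1 / 1.59) / 0.99
  expect_equal(weibull_depot(0.28, 0.99, 1.59, ORAL_DOSE, t_half),
               0.28 * ORAL_DOSE / 2)
  expect_error(weibull_depot(0.28, 0.99, 0, ORAL_DOSE, 1), "beta")
  expect_error(weibull_depot(0.28, 0.99, 1, ORAL_DOSE, -1), "non-negative")
})

test_that("terminal slope matches the 2x2 disposition eigenvalue oracle", {
  # oracle: smallest eigenvalue magnitude of the parent disposition matrix
  k10 <- pub_typ$Cl / pub_typ$Vc; k12 <- pub_typ$Q / pub_typ$Vc
  k21 <- pub_typ$Q / pub_typ$Vp
  lam <- eigen(matrix(c(-(k10 + k12), k21, k12, -k21), 2, byrow = TRUE))$values
  oracle <- min(abs(lam))
  ts <- terminal_slope(pub_typ)
  expect_equal(ts$lambda_z, oracle, tolerance = 1e-10)
  expect_equal(ts$t_half, 28.42, tolerance = 1e-3)

  # one-compartment limit Q -> 0
  p1 <- structural_params(F = 0.28, ka = 1, beta = 1, Cl = 1.67, Vc = 32.15,
                          Q = 1e-9, Vp = 36.12, Fm = 0.75, Clm = 0.016,
                          Vm = 0.0047)
  expect_equal(terminal_slope(p1)$lambda_z, 1.67 / 32.15, tolerance = 1e-4)

  # doubling both volumes halves the terminal eigenvalue
  p2 <- structural_params(F = 0.28, ka = 1, beta = 1, Cl = 1.67,
                          Vc = 2 * 32.15, Q = 154.5, Vp = 2 * 36.12,
                          Fm = 0.75, Clm = 0.016, Vm = 0.0047)
  expect_equal(terminal_slope(p2)$lambda_z, ts$lambda_z / 2,
               tolerance = 1e-6)
})

test_that("numerical IV solution matches the analytic eigen-decomposition solution", {
  tt <- seq(0.25, 72, 0.25)
  num <- solve_profile(pub_typ, regimen(1, "IV"), tt,
                       rtol = 1e-10, atol = 1e-10)
  ana <- iv_profile_analytic(pub_typ, IV_DOSE, 1 / 12, tt)
  for (comp in c("c_parent", "c_metabolite")) {
    rel <- abs(num[[comp]] - ana[[comp]]) /
      pmax(ana[[comp]], 1e-9 * max(ana[[comp]]))
    expect_lt(max(rel), 1e-6)
  }
})

test_that("oral solution matches an independent deSolve integration", {
  skip_if_not_installed("deSolve")
  for (form in c("micellar", "oil")) {
    p <- typical_params(form)
    rhs <- function(t, y, parms) {
      with(as.list(parms), {
        u <- t + t0
        rate <- FD * beta * ka * (ka * u)^(beta - 1) * exp(-(ka * u)^beta)
        list(c(rate + k21 * y[2] - (k10 + k12) * y[1],
               k12 * y[1] - k21 * y[2],
               kmf * y[1] - k30 * y[3]))
      })
    }
    t0 <- 1e-6
    parms <- c(FD = p$F * ORAL_DOSE, ka = p$ka, beta = p$beta,
               k10 = p$Cl / p$Vc, k12 = p$Q / p$Vc, k21 = p$Q / p$Vp,
               k30 = p$Clm / p$Vm, kmf = p$Fm * p$Cl / p$Vc, t0 = t0)
    tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 48, 72)
    y0 <- c(p$F * ORAL_DOSE * (1 - exp(-(p$ka * t0)^p$beta)), 0, 0)
    ode <- deSolve::lsoda(y0, c(0, tt), rhs, parms,
                          rtol = 1e-11, atol = 1e-8)
    ours <- solve_profile(p, regimen(10, "oral", form), tt,
                          rtol = 1e-10, atol = 1e-10)
    expect_equal(ours$c_parent, ode[-1, 2] / p$Vc, tolerance = 1e-6)
    expect_equal(ours$c_metabolite, ode[-1, 4] / p$Vm, tolerance = 1e-6)
  }
})

test_that("numerical AUC to infinity matches D/Cl (IV) and F*D/Cl (oral) closed forms", {
  horizon <- 2000
  iv <- solve_profile(pub_typ, regimen(1, "IV"), horizon,
                      rtol = 1e-10, atol = 1e-10)
  expect_equal(iv$auc_parent, IV_DOSE / pub_typ$Cl, tolerance = 1e-3)
  oral <- solve_profile(pub_typ, regimen(10, "oral", "micellar"), horizon,
                        rtol = 1e-10, atol = 1e-10)
  expect_equal(oral$auc_parent, pub_typ$F * ORAL_DOSE / pub_typ$Cl,
               tolerance = 1e-3)
  # metabolite in parent-molar equivalents: Fm * F * D / Clm = 414718.5
  expect_equal(oral$auc_metabolite,
               pub_typ$Fm * pub_typ$F * ORAL_DOSE / pub_typ$Clm,
               tolerance = 1e-3)
  expect_equal(oral$auc_metabolite, 414718.5, tolerance = 2e-3)
})

test_that("multiple doses superpose linearly, each with its own absorption clock", {
  tt <- c(12, 30, 50, 100, 200, 335)
  multi <- solve_profile(pub_typ, regimen(10, "oral", "micellar",
                                          n_doses = 14, interval = 24),
                         tt, rtol = 1e-10, atol = 1e-10)
  sup_p <- sup_m <- numeric(length(tt))
  for (k in 0:13) {
    u <- tt - 24 * k
    pos <- u > 0
    if (!any(pos)) next
    single <- solve_profile(pub_typ, regimen(10, "oral", "micellar"),
                            u[pos], rtol = 1e-10, atol = 1e-10)
    sup_p[pos] <- sup_p[pos] + single$c_parent
    sup_m[pos] <- sup_m[pos] + single$c_metabolite
  }
  expect_lt(max(abs(multi$c_parent - sup_p)) / max(sup_p), 1e-8)
  expect_lt(max(abs(multi$c_metabolite - sup_m)) / max(sup_m), 1e-8)
})

test_that("the system is dose-linear", {
  tt <- c(0.5, 2, 8, 24, 72)
  base <- solve_profile(pub_typ, regimen(10, "oral", "micellar"), tt,
                        rtol = 1e-10, atol = 1e-12)
  scaled <- solve_profile(pub_typ, regimen(30, "oral", "micellar"), tt,
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(scaled$c_parent / base$c_parent - 3)), 1e-8 * 3)
  expect_lt(max(abs(scaled$c_metabolite / base$c_metabolite - 3)), 1e-8 * 3)
})

test_that("moles are conserved between absorption, disposition and metabolite formation", {
  tt <- c(1, 6, 24, 96, 336)
  cv <- solve_profile(pub_typ, regimen(10, "oral", "micellar"), tt,
                      rtol = 1e-10, atol = 1e-10)
  absorbed <- pub_typ$F * ORAL_DOSE *
    (1 - exp(-(pub_typ$ka * tt)^pub_typ$beta))
  eliminated_parent <- pub_typ$Cl * cv$auc_parent
  balance <- cv$A1 + cv$A2 + eliminated_parent
  expect_equal(balance, absorbed, tolerance = 1e-6)
  # metabolite: formed = Fm * (parent eliminated); formed = A3 + Clm*AUC3
  formed <- pub_typ$Fm * eliminated_parent
  expect_equal(cv$A3 + pub_typ$Clm * cv$auc_metabolite, formed,
               tolerance = 1e-6)
  # as t -> infinity the formed/eliminated ratio converges to Fm exactly
  expect_equal(formed[length(tt)] / eliminated_parent[length(tt)],
               pub_typ$Fm, tolerance = 1e-9)
})

test_that("profiles are zero before the first dose and inputs validate", {
  cv <- solve_profile(pub_typ, data.frame(dose_event(10, "oral", ORAL_DOSE,
                                                     0, "micellar")),
                      c(1, 5, 9.9, 20))
  expect_equal(cv$c_parent[1:3], c(0, 0, 0))
  expect_gt(cv$c_parent[4], 0)
  expect_error(solve_profile(pub_typ, regimen(1, "IV"), c(2, 1)),
               "increasing")
  expect_error(dose_event(0, "IV", -1), "positive")
  expect_error(dose_event(0, "IV", 1, formulation = "oil"), "none")
  expect_error(dose_event(0, "oral", 1, formulation = "none"), "category")
  expect_error(structural_params(F = 0, ka = 1, beta = 1, Cl = 1, Vc = 1,
                                 Q = 1, Vp = 1, Fm = 0.5, Clm = 1, Vm = 1),
               "F must")
  expect_error(structural_params(F = 0.5, ka = 1, beta = 1, Cl = -1, Vc = 1,
                                 Q = 1, Vp = 1, Fm = 0.5, Clm = 1, Vm = 1),
               "positive")
})
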