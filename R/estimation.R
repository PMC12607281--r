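#' SAEM estimation settings
#'
#' @param n_burn exploration iterations (step size 1, variance annealing).
#' @param n_sa stochastic-approximation iterations (decreasing step).
#' @param mh_reps Metropolis-Hastings repetitions per block per iteration.
#' @param gamma_floor lower bound on the IOV standard deviations during
#'   sampling (keeps the occasion-level Gibbs step proper).
#' @param b_floor lower bound on the residual proportions.
#' @param ll_nsim importance-sampling draws per subject for the marginal
#'   log-likelihood.
#' @param compute_ll estimate the marginal likelihood after fitting? Turn
#'   off for throwaway replicate fits where only the estimates matter.
#' @param rtol,atol ODE tolerances used during fitting.
#' @param seed_offset added to the fit seed for the likelihood stage.
#' @return list of settings.
#' @export
saem_settings <- function(n_burn = 250, n_sa = 150, mh_reps = 2,
                          gamma_floor = 0.015, b_floor = 1e-3,
                          ll_nsim = 150, compute_ll = TRUE,
                          rtol = 1e-6, atol = 1e-6, seed_offset = 1000L) {
  list(n_burn = n_burn, n_sa = n_sa, mh_reps = mh_reps,
       gamma_floor = gamma_floor, b_floor = b_floor, ll_nsim = ll_nsim,
       compute_ll = compute_ll, rtol = rtol, atol = atol,
       seed_offset = seed_offset)
}

PK_PAR_NAMES <- c("F", "ka", "beta", "Cl", "Vc", "Q", "Vp", "Vm", "Clm")
ABS_PARS <- c("F", "ka", "beta")          # occasion-level (IOV) parameters
DISP_PARS <- c("Cl", "Vc", "Q", "Vp", "Vm", "Clm")
IIV_PARS <- setdiff(PK_PAR_NAMES, "Q")    # Q carries no random effect

# ---- data preparation --------------------------------------------------

# split a pk_dataset into per-subject, per-occasion fitting structures
prep_fit_data <- function(ds) {
  stopifnot(inherits(ds, "data.frame"))
  ids <- sort(unique(ds$ID))
  subjects <- lapply(ids, function(id) {
    sub <- ds[ds$ID == id, ]
    occs <- lapply(sort(unique(sub$OCC)), function(oc) {
      so <- sub[sub$OCC == oc, ]
      drow <- so[so$DVID == 0, ]
      oral <- drow$FORM != "none"
      obs <- so[so$DVID %in% c(1L, 2L) & so$BLQ == 0L & !is.na(so$DV) &
                  so$TIME > drow$TIME, ]
      if (nrow(obs) == 0) return(NULL)
      times <- sort(unique(obs$TIME))
      list(oral = oral, x_oil = as.numeric(drow$FORM == "oil"),
           formulation = drow$FORM,
           dose_mat = cbind(time = drow$TIME, amt = drow$AMT,
                            oral = as.numeric(oral),
                            tinf = ifelse(oral, 0,
                                          ifelse(is.na(drow$DUR), 0, drow$DUR))),
           times = times, t_idx = match(obs$TIME, times),
           dvid = obs$DVID, y = obs$DV)
    })
    occs <- Filter(Negate(is.null), occs)
    list(id = id, occs = occs,
         oral_idx = which(vapply(occs, `[[`, logical(1), "oral")))
  })
  has_both <- vapply(subjects, function(s) {
    dv <- unlist(lapply(s$occs, `[[`, "dvid"))
    all(c(1L, 2L) %in% dv)
  }, logical(1))
  if (length(subjects) == 0 || !any(vapply(subjects, function(s)
    length(s$occs) > 0, logical(1))))
    stop("no quantifiable data")
  if (sum(has_both) < 2)
    stop("need at least 2 subjects with quantifiable data on both analytes")
  subjects
}

# occasion log-likelihood under the proportional error model; returns the
# predictions too so the M-step can reuse them
occ_loglik <- function(occ, par10, b1, b2, Fm, rtol, atol) {
  m <- tryCatch(.cpp_pk_solve(par10, occ$dose_mat, occ$times, rtol, atol),
                error = function(e) NULL)
  if (is.null(m))   # pathological parameter proposal (extreme stiffness)
    return(list(ll = -1e10, pred = rep(1e-12, length(occ$y))))
  c1 <- m[, "A1"] / par10[5]
  c3 <- m[, "A3"] / par10[10]
  f <- ifelse(occ$dvid == 1L, c1[occ$t_idx], c3[occ$t_idx])
  f <- pmax(f, 1e-12)
  b <- ifelse(occ$dvid == 1L, b1, b2)
  ll <- sum(stats::dnorm(occ$y, f, b * f, log = TRUE))
  list(ll = ll, pred = f)
}

# natural-scale kernel parameter vector for one occasion
occ_par10 <- function(psi_row, phi_abs, oral, Fm) {
  d <- exp(psi_row[DISP_PARS])
  if (oral) {
    c(stats::plogis(phi_abs[["F"]]), exp(phi_abs[["ka"]]), exp(phi_abs[["beta"]]),
      d[["Cl"]], d[["Vc"]], d[["Q"]], d[["Vp"]], Fm, d[["Clm"]], d[["Vm"]])
  } else {
    c(1, 1, 1, d[["Cl"]], d[["Vc"]], d[["Q"]], d[["Vp"]], Fm, d[["Clm"]],
      d[["Vm"]])
  }
}

# ---- NCA-informed initial values ---------------------------------------

#' Heuristic initial population values from non-compartmental summaries
#'
#' Clearance from IV dose/AUC, volumes from the terminal phase, F from the
#' oral/IV dose-normalized AUC ratio, metabolite clearance from the IV
#' metabolite AUC with the fixed metabolized fraction.
#'
#' @param ds a `pk_dataset`.
#' @param Fm fixed metabolized fraction used in the heuristics.
#' @return A `population_model` suitable as `init` for [fit_nlme()].
#' @export
nca_initial_values <- function(ds, Fm = 0.75) {
  subjects <- prep_fit_data(ds)
  cl <- c(); fvals <- c(); vss_ <- c(); vc <- c(); clm <- c(); tmx <- c()
  for (s in subjects) {
    for (occ in s$occs) {
      tt <- occ$times
      selp <- occ$dvid == 1L
      tp <- tt[occ$t_idx[selp]]; yp <- occ$y[selp]
      o <- order(tp); tp <- tp[o]; yp <- yp[o]
      if (length(tp) < 4) next
      dose <- occ$dose_mat[1, "amt"]
      aucp <- tryCatch(auc_trapezoid(tp, yp, extrapolate = TRUE),
                       error = function(e) NA_real_)
      if (!occ$oral && is.finite(aucp)) {
        cl <- c(cl, dose / aucp)
        th <- tryCatch(terminal_half_life(tp, yp), error = function(e) NULL)
        if (!is.null(th)) vss_ <- c(vss_, dose / aucp / th$lambda_z)
        vc <- c(vc, dose / max(yp))
        selm <- occ$dvid == 2L
        tm <- tt[occ$t_idx[selm]]; ym <- occ$y[selm]
        o <- order(tm); tm <- tm[o]; ym <- ym[o]
        if (length(tm) >= 4) {
          aucm <- tryCatch(auc_trapezoid(tm, ym, extrapolate = TRUE),
                           error = function(e) NA_real_)
          if (is.finite(aucm)) clm <- c(clm, Fm * dose / aucm)
        }
      } else if (occ$oral && is.finite(aucp)) {
        fvals <- c(fvals, aucp / dose)
        tmx <- c(tmx, tp[which.max(yp)])
      }
    }
  }
  cl0 <- if (length(cl)) stats::median(cl) else 1
  vss0 <- if (length(vss_)) stats::median(vss_) else 50 * cl0
  vc0 <- max(if (length(vc)) stats::median(vc) else vss0 / 2, 0.05 * vss0)
  vp0 <- max(vss0 - vc0, 0.2 * vc0)
  f0 <- if (length(fvals) && length(cl))
    min(0.9, max(0.02, stats::median(fvals) * cl0)) else 0.3
  ka0 <- if (length(tmx)) 1 / stats::median(tmx) else 0.5
  clm0 <- if (length(clm)) stats::median(clm) else 0.02
  population_model(
    typical = c(F = f0, ka = ka0, beta = 1, Cl = cl0, Vc = vc0,
                Q = 30 * cl0, Vp = vp0, Vm = clm0 / 1.0, Clm = clm0),
    iiv_pct = stats::setNames(rep(30, length(IIV_PARS)), IIV_PARS),
    iov_pct = c(F = 15, ka = 15, beta = 15),
    cov_oil = c(ka = 0, beta = 0),
    b1 = 0.3, b2 = 0.3, Fm = Fm)
}

#' Naive-pooled typical-value pre-fit
#'
#' Refines initial typical values by least squares on the log scale against
#' the median observed concentration per administration stratum, nominal
#' time and analyte (under multiplicative noise the median curve tracks the
#' typical-subject curve). Fits all typical values including the
#' category-specific absorption parameters; variabilities are left at the
#' supplied init.
#'
#' @param ds a `pk_dataset`.
#' @param init starting `population_model` (e.g. [nca_initial_values()]).
#' @param Fm fixed metabolized fraction.
#' @param maxit Nelder-Mead iteration budget.
#' @return A `population_model` with refined typical values and oil
#'   covariate coefficients.
#' @export
pooled_prefit <- function(ds, init, Fm = 0.75, maxit = 1500) {
  subjects <- prep_fit_data(ds)
  # median observed concentration per stratum x time x analyte
  med <- list()
  for (s in subjects) for (occ in s$occs) {
    key <- occ$formulation
    tt <- occ$times[occ$t_idx]
    for (a in 1:2) {
      sel <- occ$dvid == a
      if (!any(sel)) next
      df <- data.frame(t = tt[sel], y = occ$y[sel], a = a)
      med[[key]] <- rbind(med[[key]], df)
    }
  }
  med <- lapply(med, function(df) {
    agg <- stats::aggregate(y ~ t + a, df, stats::median)
    agg[agg$y > 0, ]
  })
  # one representative dose schedule per stratum
  sched <- list()
  for (s in subjects) for (occ in s$occs)
    if (is.null(sched[[occ$formulation]])) sched[[occ$formulation]] <- occ$dose_mat
  typ <- init$typical
  x0 <- c(stats::qlogis(typ[["F"]]), log(typ[["ka"]]), log(typ[["beta"]]),
          log(typ[["ka"]] * exp(init$cov_oil[["ka"]])),
          log(typ[["beta"]] * exp(init$cov_oil[["beta"]])),
          log(typ[["Cl"]]), log(typ[["Vc"]]), log(typ[["Q"]]),
          log(typ[["Vp"]]), log(typ[["Vm"]]), log(typ[["Clm"]]))
  obj <- function(x) {
    Fv <- stats::plogis(x[1]); ab <- exp(x[2:5]); d <- exp(x[6:11])
    sse <- 0
    for (key in names(med)) {
      par10 <- switch(key,
        none = c(1, 1, 1, d[1], d[2], d[3], d[4], Fm, d[6], d[5]),
        micellar = c(Fv, ab[1], ab[2], d[1], d[2], d[3], d[4], Fm, d[6], d[5]),
        oil = c(Fv, ab[3], ab[4], d[1], d[2], d[3], d[4], Fm, d[6], d[5]))
      mm <- med[[key]]
      tt <- sort(unique(mm$t))
      sol <- .cpp_pk_solve(par10, sched[[key]], tt, 1e-6, 1e-6)
      c1 <- pmax(sol[, "A1"] / d[2], 1e-12)
      c3 <- pmax(sol[, "A3"] / d[5], 1e-12)
      pred <- ifelse(mm$a == 1, c1[match(mm$t, tt)], c3[match(mm$t, tt)])
      sse <- sse + sum((log(mm$y) - log(pred))^2)
    }
    sse
  }
  opt <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-9))
  x <- opt$par
  typ_new <- c(F = stats::plogis(x[1]), ka = exp(x[2]), beta = exp(x[3]),
               Cl = exp(x[6]), Vc = exp(x[7]), Q = exp(x[8]), Vp = exp(x[9]),
               Vm = exp(x[10]), Clm = exp(x[11]))
  population_model(typical = typ_new, iiv_pct = init$iiv_pct,
                   iov_pct = init$iov_pct,
                   cov_oil = c(ka = x[4] - x[2], beta = x[5] - x[3]),
                   b1 = init$b1, b2 = init$b2, Fm = Fm)
}

# ---- SAEM fit ----------------------------------------------------------

#' Fit the population model by SAEM
#'
#' Maximum marginal-likelihood estimation of the parent-metabolite
#' population model by stochastic approximation EM: the E-step samples the
#' subject-level random effects (random-walk Metropolis within Gibbs, with
#' an exact Gibbs update for the subject-level absorption latents), the
#' M-step is closed-form on the sampled sufficient statistics, and a
#' simulated-annealing floor keeps variances from collapsing during
#' exploration. Both analytes are fitted jointly; the metabolized fraction
#' is fixed. The marginal -2 log-likelihood is estimated by importance
#' sampling at the conditional distribution, and `AIC = -2LL + 2p`,
#' `BIC = -2LL + p log(N)` with `N` the number of subjects.
#'
#' @param ds a `pk_dataset`.
#' @param init a `population_model` of initial values, or `NULL` for
#'   [nca_initial_values()].
#' @param fixed named list/vector of fixed parameters; must contain `Fm`
#'   (default 0.75, as in the published analysis).
#' @param settings see [saem_settings()].
#' @param seed integer seed; fits are reproducible given the seed.
#' @param covariate include the categorical formulation covariate on `ka`
#'   and `beta` (oil vs the micellar reference)?
#' @param free character vector of parameters requested free; requesting a
#'   parameter listed in `fixed` is an error.
#' @return An object of class `cbg_fit`: the estimated `population_model`
#'   (`$pop`), `minus2ll`, `aic`, `bic`, `n_param`, `converged`, the
#'   iteration `trace`, and internal state consumed by [compute_ebes()],
#'   [vpc()] and [residual_table()].
#' @export
fit_nlme <- function(ds, init = NULL, fixed = c(Fm = 0.75),
                     settings = saem_settings(), seed = 1,
                     covariate = TRUE, free = NULL) {
  if (!is.null(free) && any(free %in% names(fixed)))
    stop("parameter is fixed: ", paste(intersect(free, names(fixed)),
                                       collapse = ", "))
  if (!"Fm" %in% names(fixed))
    stop("the metabolized fraction Fm must be fixed (unidentifiable without ",
         "IV metabolite dosing)")
  Fm <- as.numeric(fixed[["Fm"]])
  subjects <- prep_fit_data(ds)
  n <- length(subjects)
  if (is.null(init))
    init <- pooled_prefit(ds, nca_initial_values(ds, Fm = Fm), Fm = Fm)
  set.seed(seed)
  rtol <- settings$rtol; atol <- settings$atol
  n_iter <- settings$n_burn + settings$n_sa
  nm <- PK_PAR_NAMES

  # current population estimate (transformed scale)
  mu <- vapply(nm, function(p) transform_value(init$typical[[p]],
                                               param_transform(p)), numeric(1))
  omega2 <- vapply(nm, function(p) init$omega[[p]]^2, numeric(1))
  omega2[IIV_PARS] <- pmax(omega2[IIV_PARS], 0.05^2)
  gamma2 <- pmax(vapply(ABS_PARS, function(p) init$gamma[[p]]^2, numeric(1)),
                 settings$gamma_floor^2)
  cov_oil <- if (covariate)
    c(ka = unname(init$cov_oil[["ka"]]), beta = unname(init$cov_oil[["beta"]])) else
    c(ka = 0, beta = 0)
  b1 <- max(init$b1, 0.05); b2 <- max(init$b2, 0.05)

  # latent state: psi (subject level, transformed), phi (per oral occasion)
  psi <- matrix(rep(mu, each = n), n, length(nm), dimnames = list(NULL, nm))
  phi <- lapply(subjects, function(s) {
    no <- length(s$oral_idx)
    if (no == 0) return(NULL)
    matrix(rep(mu[ABS_PARS], each = no), no, 3,
           dimnames = list(NULL, ABS_PARS))
  })
  # proposal scalars and caches
  sD <- rep(0.4, n)
  sM <- rep(0.4, n)
  sQ <- rep(1.0, n)
  sO <- lapply(subjects, function(s) rep(0.4, length(s$oral_idx)))
  cache <- vector("list", n)
  subj_par10 <- function(i, j) {
    occ <- subjects[[i]]$occs[[j]]
    ph <- if (occ$oral)
      phi[[i]][match(j, subjects[[i]]$oral_idx), ] else NULL
    occ_par10(psi[i, ], ph, occ$oral, Fm)
  }
  refresh_cache <- function(i) {
    lapply(seq_along(subjects[[i]]$occs), function(j)
      occ_loglik(subjects[[i]]$occs[[j]], subj_par10(i, j), b1, b2, Fm,
                 rtol, atol))
  }
  for (i in seq_len(n)) cache[[i]] <- refresh_cache(i)

  trace <- matrix(NA_real_, n_iter, length(nm) + 7,
                  dimnames = list(NULL, c(nm, "cov_ka", "cov_beta", "b1", "b2",
                                          "om_Cl", "om_Vc", "om_F")))
  sa <- NULL  # sufficient-statistic accumulators
  latent_store <- lapply(seq_len(n), function(i) list())

  for (k in seq_len(n_iter)) {
    phase1 <- k <= settings$n_burn
    a_k <- if (phase1) 1 else 1 / (k - settings$n_burn)^0.65
    om_art <- if (phase1) 0.3 else 0.05
    adapt <- if (phase1) 0.4 else 0.05

    for (i in seq_len(n)) {
      s <- subjects[[i]]
      # subject-level MH sub-blocks over all occasions: parent disposition
      # (Cl, Vc, Vp), metabolite (Vm, Clm), and Q (no random effect; its
      # walker uses the artificial exploration prior)
      try_block <- function(pars, scales, prior_fun) {
        prop <- psi[i, ]
        prop[pars] <- prop[pars] + stats::rnorm(length(pars)) * scales
        new_cache <- lapply(seq_along(s$occs), function(j) {
          occ <- s$occs[[j]]
          ph <- if (occ$oral) phi[[i]][match(j, s$oral_idx), ] else NULL
          occ_loglik(occ, occ_par10(prop, ph, occ$oral, Fm), b1, b2, Fm,
                     rtol, atol)
        })
        ll_new <- sum(vapply(new_cache, `[[`, numeric(1), "ll")) +
          prior_fun(prop)
        ll_old <- sum(vapply(cache[[i]], `[[`, numeric(1), "ll")) +
          prior_fun(psi[i, ])
        if (log(stats::runif(1)) < ll_new - ll_old) {
          psi[i, ] <<- prop; cache[[i]] <<- new_cache
          TRUE
        } else FALSE
      }
      prior_sub <- function(pars) function(prow)
        sum(stats::dnorm(prow[pars], mu[pars],
                         pmax(sqrt(omega2[pars]), 1e-4), log = TRUE))
      blocks <- list(
        list(pars = c("Cl", "Vc", "Vp"), sv = quote(sD[i]),
             prior = prior_sub(c("Cl", "Vc", "Vp"))),
        list(pars = c("Vm", "Clm"), sv = quote(sM[i]),
             prior = prior_sub(c("Vm", "Clm"))),
        list(pars = "Q", sv = quote(sQ[i]),
             prior = function(prow) stats::dnorm(prow[["Q"]], mu[["Q"]],
                                                 om_art, log = TRUE)))
      for (bl in blocks) {
        acc <- 0
        sv <- eval(bl$sv)
        scales <- if (identical(bl$pars, "Q")) sv * om_art else
          sv * pmax(sqrt(omega2[bl$pars]), 0.05)
        for (rep in seq_len(settings$mh_reps))
          acc <- acc + try_block(bl$pars, scales, bl$prior)
        newsv <- sv * exp(adapt * (acc / settings$mh_reps - 0.3))
        eval(call("<-", bl$sv, newsv))
      }

      # --- block O: occasion-level absorption latents (oral occasions)
      for (jj in seq_along(s$oral_idx)) {
        j <- s$oral_idx[jj]
        occ <- s$occs[[j]]
        cvec <- c(F = 0, ka = unname(cov_oil[["ka"]]) * occ$x_oil,
                  beta = unname(cov_oil[["beta"]]) * occ$x_oil)
        acc <- 0
        for (rep in seq_len(settings$mh_reps)) {
          cur <- phi[[i]][jj, ]
          prop <- cur + stats::rnorm(3) * sO[[i]][jj] *
            pmax(sqrt(gamma2), 0.08)
          new1 <- occ_loglik(occ, occ_par10(psi[i, ], prop, TRUE, Fm),
                             b1, b2, Fm, rtol, atol)
          pr_new <- sum(stats::dnorm(prop, psi[i, ABS_PARS] + cvec,
                                     sqrt(gamma2), log = TRUE))
          pr_old <- sum(stats::dnorm(cur, psi[i, ABS_PARS] + cvec,
                                     sqrt(gamma2), log = TRUE))
          if (log(stats::runif(1)) <
              new1$ll + pr_new - (cache[[i]][[j]]$ll + pr_old)) {
            phi[[i]][jj, ] <- prop; cache[[i]][[j]] <- new1; acc <- acc + 1
          }
        }
        sO[[i]][jj] <- sO[[i]][jj] * exp(adapt * (acc / settings$mh_reps - 0.3))
      }

      # --- Gibbs: subject-level absorption latents given occasion latents
      if (length(s$oral_idx)) {
        for (p in ABS_PARS) {
          xs <- vapply(s$oral_idx, function(j) s$occs[[j]]$x_oil, numeric(1))
          cc <- if (p == "F") rep(0, length(xs)) else cov_oil[[p]] * xs
          om2 <- max(omega2[[p]], 1e-8)
          prec <- 1 / om2 + length(xs) / gamma2[[p]]
          mm <- (mu[[p]] / om2 +
                   sum(phi[[i]][, p] - cc) / gamma2[[p]]) / prec
          psi[i, p] <- stats::rnorm(1, mm, sqrt(1 / prec))
        }
      }
      if (!phase1) {
        latent_store[[i]][[length(latent_store[[i]]) + 1]] <-
          c(psi[i, c("Cl", "Vc", "Vp", "Vm", "Clm")],
            if (length(s$oral_idx)) as.vector(t(phi[[i]])) else numeric(0))
      }
    }

    # --- sufficient statistics of this sweep
    stat <- list(S1 = colMeans(psi), S2 = colMeans(psi^2))
    U0 <- U1 <- U0sq <- U1sq <- stats::setNames(numeric(3), ABS_PARS)
    n0 <- n1 <- 0
    res2 <- c(0, 0); nres <- c(0, 0)
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      for (jj in seq_along(s$oral_idx)) {
        j <- s$oral_idx[jj]
        d <- phi[[i]][jj, ] - psi[i, ABS_PARS]
        if (s$occs[[j]]$x_oil > 0.5) {
          U1 <- U1 + d; U1sq <- U1sq + d^2; n1 <- n1 + 1
        } else {
          U0 <- U0 + d; U0sq <- U0sq + d^2; n0 <- n0 + 1
        }
      }
      for (j in seq_along(s$occs)) {
        occ <- s$occs[[j]]
        r2 <- ((occ$y - cache[[i]][[j]]$pred) / cache[[i]][[j]]$pred)^2
        for (a in 1:2) {
          sel <- occ$dvid == a
          res2[a] <- res2[a] + sum(r2[sel]); nres[a] <- nres[a] + sum(sel)
        }
      }
    }
    stat$U0 <- U0; stat$U1 <- U1; stat$U0sq <- U0sq; stat$U1sq <- U1sq
    stat$n0 <- n0; stat$n1 <- n1
    stat$b2hat <- ifelse(nres > 0, res2 / pmax(nres, 1), c(b1^2, b2^2))

    if (is.null(sa)) sa <- stat else
      sa <- mapply(function(old, new) (1 - a_k) * old + a_k * new,
                   sa, stat, SIMPLIFY = FALSE)

    # --- M-step (closed form)
    mu_new <- sa$S1
    om2_new <- pmax(sa$S2 - sa$S1^2, 1e-8)
    mu <- mu_new
    if (phase1) {
      omega2[IIV_PARS] <- pmax(om2_new[IIV_PARS], 0.95 * omega2[IIV_PARS])
    } else omega2[IIV_PARS] <- om2_new[IIV_PARS]
    omega2["Q"] <- 0
    if (covariate && n1 > 0) {
      cov_oil <- c(ka = unname(sa$U1[["ka"]]) / sa$n1,
                   beta = unname(sa$U1[["beta"]]) / sa$n1)
    }
    cfull <- c(F = 0, cov_oil)
    g2_new <- vapply(ABS_PARS, function(p) {
      num <- sa$U0sq[[p]] + sa$U1sq[[p]] - 2 * cfull[[p]] * sa$U1[[p]] +
        sa$n1 * cfull[[p]]^2
      num / max(sa$n0 + sa$n1, 1)
    }, numeric(1))
    g2_new <- pmax(g2_new, settings$gamma_floor^2)
    gamma2 <- if (phase1) pmax(g2_new, 0.95 * gamma2) else g2_new
    bnew <- sqrt(pmax(sa$b2hat, settings$b_floor^2))
    if (phase1) bnew <- pmax(bnew, 0.95 * c(b1, b2))
    b1 <- bnew[1]; b2 <- bnew[2]

    trace[k, ] <- c(vapply(nm, function(p) inverse_transform(mu[[p]],
                      param_transform(p)), numeric(1)),
                    cov_oil[["ka"]], cov_oil[["beta"]], b1, b2,
                    sqrt(omega2[["Cl"]]), sqrt(omega2[["Vc"]]),
                    sqrt(omega2[["F"]]))
  }

  # --- assemble the estimated population model
  omega_fin <- sqrt(omega2)
  singular <- IIV_PARS[omega_fin[IIV_PARS] < 1e-3]
  if (length(singular)) {
    warning("random-effect variance collapsed to 0 for: ",
            paste(singular, collapse = ", "))
    omega_fin[singular] <- 0
  }
  typ <- vapply(nm, function(p) inverse_transform(mu[[p]], param_transform(p)),
                numeric(1))
  pop_hat <- population_model(
    typical = typ,
    iiv_pct = vapply(IIV_PARS, function(p)
      sd_to_percent(omega_fin[[p]], param_transform(p)), numeric(1)),
    iov_pct = vapply(ABS_PARS, function(p)
      sd_to_percent(sqrt(gamma2[[p]]), param_transform(p)), numeric(1)),
    cov_oil = cov_oil, b1 = b1, b2 = b2, Fm = Fm)

  # --- convergence heuristic: relative drift of typicals over the tail
  tail_n <- min(30, settings$n_sa)
  tail_tr <- trace[(n_iter - tail_n + 1):n_iter, nm, drop = FALSE]
  drift <- apply(tail_tr, 2, function(v) abs(log(v[length(v)] / v[1])))
  converged <- all(is.finite(drift)) && max(drift) < 0.10

  n_param <- length(nm) + (if (covariate) 2 else 0) + length(IIV_PARS) +
    length(ABS_PARS) + 2

  fit <- structure(list(pop = pop_hat, covariate = covariate, Fm = Fm,
                        mu = mu, omega2 = omega2, gamma2 = gamma2,
                        cov_oil = cov_oil, b1 = b1, b2 = b2,
                        subjects = subjects, psi = psi, phi = phi,
                        latent_store = latent_store,
                        trace = trace, converged = converged,
                        algorithm = "SAEM (MCMC E-step, closed-form M-step)",
                        bic_N = "subjects",
                        n_subjects = n, n_obs = sum(vapply(subjects, function(s)
                          sum(vapply(s$occs, function(o) length(o$y),
                                     numeric(1))), numeric(1))),
                        y_checksum = sum(unlist(lapply(subjects, function(s)
                          lapply(s$occs, `[[`, "y")))),
                        n_param = n_param, settings = settings, seed = seed),
                   class = "cbg_fit")
  if (isTRUE(settings$compute_ll)) {
    ll <- marginal_loglik(fit)
    fit$minus2ll <- -2 * ll
    fit$aic <- fit$minus2ll + 2 * n_param
    fit$bic <- fit$minus2ll + n_param * log(n)
  } else {
    fit$minus2ll <- fit$aic <- fit$bic <- NA_real_
  }
  fit
}

#' @export
print.cbg_fit <- function(x, ...) {
  cat("Population PK fit (", x$algorithm, ")\n", sep = "")
  cat(sprintf("subjects %d, observations %d; -2LL %.1f, AIC %.1f, BIC %.1f (N = %s)\n",
              x$n_subjects, x$n_obs, x$minus2ll, x$aic, x$bic, x$bic_N))
  cat("converged:", x$converged, "\n\n")
  print(x$pop)
  invisible(x)
}

# importance-sampling estimate of the marginal log-likelihood
marginal_loglik <- function(fit, nsim = fit$settings$ll_nsim) {
  set.seed(fit$seed + fit$settings$seed_offset)
  total <- 0
  for (i in seq_along(fit$subjects)) {
    s <- fit$subjects[[i]]
    Zs <- do.call(rbind, fit$latent_store[[i]])
    if (is.null(Zs)) {     # no SA phase stored; fall back to current state
      Zs <- matrix(c(fit$psi[i, c("Cl", "Vc", "Vp", "Vm", "Clm")],
                     if (length(s$oral_idx)) as.vector(t(fit$phi[[i]]))),
                   nrow = 1)
    }
    m <- colMeans(Zs)
    Cv <- stats::cov(Zs)
    if (nrow(Zs) < 5 || any(!is.finite(Cv))) Cv <- diag(length(m)) * 0.04
    Cv <- Cv + diag(length(m)) * 1e-4
    L <- chol(1.5 * Cv)
    d <- length(m)
    lw <- numeric(nsim)
    for (r in seq_len(nsim)) {
      z <- m + drop(stats::rnorm(d) %*% L)
      lw[r] <- subject_loglik_at(fit, i, z) - mvn_logpdf(z, m, 1.5 * Cv)
    }
    total <- total + (max(lw) + log(mean(exp(lw - max(lw)))))
  }
  total
}

mvn_logpdf <- function(z, m, S) {
  L <- chol(S)
  u <- backsolve(L, z - m, transpose = TRUE)
  -0.5 * sum(u^2) - sum(log(diag(L))) - 0.5 * length(z) * log(2 * pi)
}

# joint log density  log p(y_i, z) at latent vector z = (psi_d re-part,
# phi occasions); Q fixed at its typical value
subject_loglik_at <- function(fit, i, z) {
  s <- fit$subjects[[i]]
  dpar <- c("Cl", "Vc", "Vp", "Vm", "Clm")
  psi_row <- fit$mu
  psi_row[dpar] <- z[seq_along(dpar)]
  lp <- sum(stats::dnorm(z[seq_along(dpar)], fit$mu[dpar],
                         sqrt(pmax(fit$omega2[dpar], 1e-10)), log = TRUE))
  no <- length(s$oral_idx)
  phi_i <- NULL
  if (no) {
    phi_i <- matrix(z[(length(dpar) + 1):(length(dpar) + 3 * no)], no, 3,
                    byrow = TRUE, dimnames = list(NULL, ABS_PARS))
    xs <- vapply(s$oral_idx, function(j) s$occs[[j]]$x_oil, numeric(1))
    for (p in ABS_PARS) {
      cc <- if (p == "F") rep(0, no) else fit$cov_oil[[p]] * xs
      mean_p <- fit$mu[[p]] + cc
      S <- matrix(fit$omega2[[p]], no, no) + diag(no) * fit$gamma2[[p]]
      lp <- lp + mvn_logpdf(phi_i[, p], mean_p, S)
    }
  }
  ll <- 0
  for (j in seq_along(s$occs)) {
    occ <- s$occs[[j]]
    ph <- if (occ$oral) phi_i[match(j, s$oral_idx), ] else NULL
    ll <- ll + occ_loglik(occ, occ_par10(psi_row, ph, occ$oral, fit$Fm),
                          fit$b1, fit$b2, fit$Fm,
                          fit$settings$rtol, fit$settings$atol)$ll
  }
  ll + lp
}

#' Covariate model decision by BIC
#'
#' A covariate is retained when it lowers the BIC by at least 10
#' (`delta_bic = BIC_base - BIC_extended >= 10`). The likelihood-ratio
#' statistic is reported alongside for nested pairs.
#'
#' @param base,extended two `cbg_fit` objects on the same dataset.
#' @return List with `delta_bic`, `retain`, `lrt`.
#' @export
compare_covariate_models <- function(base, extended) {
  if (base$n_obs != extended$n_obs ||
      abs(base$y_checksum - extended$y_checksum) > 1e-6 * max(1, abs(base$y_checksum)))
    stop("fits are not on the same dataset; BIC not comparable")
  delta <- base$bic - extended$bic
  list(delta_bic = delta, retain = delta >= 10,
       lrt = base$minus2ll - extended$minus2ll,
       df = extended$n_param - base$n_param)
}

#' Empirical Bayes estimates and shrinkage
#'
#' Per-subject conditional modes of the random effects given the population
#' fit, and the shrinkage `1 - sd(EBE eta)/omega` per parameter (percent).
#' Parameters without a random effect are reported as `NA`.
#'
#' @param fit a converged `cbg_fit`.
#' @return List with `ebe` (tibble: subject x structural parameters at the
#'   conditional mode, per oral occasion for the absorption parameters),
#'   `eta` (subject-level random effects), and `shrinkage_pct`.
#' @export
compute_ebes <- function(fit) {
  n <- length(fit$subjects)
  dpar <- c("Cl", "Vc", "Vp", "Vm", "Clm")
  modes <- vector("list", n)
  for (i in seq_len(n)) {
    s <- fit$subjects[[i]]
    no <- length(s$oral_idx)
    Zs <- do.call(rbind, fit$latent_store[[i]])
    z0 <- if (!is.null(Zs) && nrow(Zs) >= 5) colMeans(Zs) else
      c(fit$psi[i, dpar],
        if (no) as.vector(t(fit$phi[[i]])) else numeric(0))
    if (!length(unlist(lapply(s$occs, `[[`, "y")))) {
      modes[[i]] <- c(fit$mu[dpar], rep(fit$mu[ABS_PARS], no))
      next
    }
    # the chain leaves z0 near the conditional mode; a short scaled BFGS
    # refines it (steps in units of the prior standard deviations)
    psc <- c(pmax(sqrt(fit$omega2[dpar]), 0.02),
             rep(pmax(sqrt(fit$omega2[ABS_PARS] + fit$gamma2), 0.02), no))
    opt <- stats::optim(z0, function(z) -subject_loglik_at(fit, i, z),
                        method = "BFGS",
                        control = list(maxit = 40, reltol = 1e-6,
                                       parscale = psc))
    modes[[i]] <- opt$par
  }
  eta <- t(vapply(seq_len(n), function(i) {
    z <- modes[[i]]
    out <- stats::setNames(rep(NA_real_, length(PK_PAR_NAMES)), PK_PAR_NAMES)
    out[dpar] <- z[seq_along(dpar)] - fit$mu[dpar]
    s <- fit$subjects[[i]]
    no <- length(s$oral_idx)
    if (no) {
      phi_i <- matrix(z[-seq_along(dpar)], no, 3, byrow = TRUE)
      colnames(phi_i) <- ABS_PARS
      xs <- vapply(s$oral_idx, function(j) s$occs[[j]]$x_oil, numeric(1))
      for (p in ABS_PARS) {
        cc <- if (p == "F") rep(0, no) else fit$cov_oil[[p]] * xs
        # subject-level posterior mean of eta_IIV given the occasion latents
        om2 <- max(fit$omega2[[p]], 1e-10)
        prec <- 1 / om2 + no / fit$gamma2[[p]]
        out[p] <- (sum(phi_i[, p] - cc - fit$mu[[p]]) / fit$gamma2[[p]]) / prec
      }
    }
    out
  }, stats::setNames(numeric(length(PK_PAR_NAMES)), PK_PAR_NAMES)))
  shrink <- vapply(PK_PAR_NAMES, function(p) {
    om <- sqrt(fit$omega2[[p]])
    if (om < 1e-6 || all(is.na(eta[, p]))) return(NA_real_)
    100 * (1 - stats::sd(eta[, p], na.rm = TRUE) / om)
  }, numeric(1))
  ebe_rows <- lapply(seq_len(n), function(i) {
    s <- fit$subjects[[i]]
    z <- modes[[i]]
    psi_row <- fit$mu
    psi_row[dpar] <- z[seq_along(dpar)]
    d <- exp(psi_row[dpar])
    base <- data.frame(subject = s$id, Cl = d[["Cl"]], Vc = d[["Vc"]],
                       Q = exp(fit$mu[["Q"]]), Vp = d[["Vp"]],
                       Vm = d[["Vm"]], Clm = d[["Clm"]])
    no <- length(s$oral_idx)
    if (no) {
      phi_i <- matrix(z[-seq_along(dpar)], no, 3, byrow = TRUE)
      occ_rows <- do.call(rbind, lapply(seq_len(no), function(jj) {
        j <- s$oral_idx[jj]
        cbind(base, occasion = j,
              formulation = s$occs[[j]]$formulation,
              F = stats::plogis(phi_i[jj, 1]), ka = exp(phi_i[jj, 2]),
              beta = exp(phi_i[jj, 3]))
      }))
      occ_rows
    } else cbind(base, occasion = NA, formulation = NA,
                 F = NA, ka = NA, beta = NA)
  })
  list(ebe = tibble::as_tibble(do.call(rbind, ebe_rows)),
       eta = eta, shrinkage_pct = shrink, modes = modes)
}

#' Non-parametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement, refits each replicate with the
#' original settings, and reports 2.5/97.5 percentile intervals for the
#' typical values, covariate coefficients and residual proportions.
#' Non-converged replicates are counted and excluded.
#'
#' @param ds the original `pk_dataset`.
#' @param fit the reference `cbg_fit` (provides init and settings).
#' @param n_replicates number of bootstrap datasets (>= 2).
#' @param seed integer seed (resampling indices are reproducible).
#' @return List with `ci` (tibble: parameter, lower, upper, estimate),
#'   `estimates` (replicate x parameter matrix), `n_failed`.
#' @export
bootstrap <- function(ds, fit, n_replicates = 200, seed = 1) {
  if (n_replicates < 2) stop("need >= 2 bootstrap replicates")
  ids <- unique(ds$ID)
  set.seed(seed)
  idx <- matrix(sample(ids, n_replicates * length(ids), replace = TRUE),
                n_replicates)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    parts <- lapply(seq_along(idx[r, ]), function(k) {
      sub <- ds[ds$ID == idx[r, k], ]
      sub$ID <- k
      sub
    })
    bds <- as_pk_dataset(do.call(rbind, parts))
    reps[[r]] <- tryCatch({
      f <- fit_nlme(bds, init = fit$pop, fixed = c(Fm = fit$Fm),
                    settings = fit$settings, seed = seed + r,
                    covariate = fit$covariate)
      if (!f$converged) NULL else
        c(f$pop$typical, cov_ka = unname(f$cov_oil[["ka"]]),
          cov_beta = unname(f$cov_oil[["beta"]]), b1 = f$b1, b2 = f$b2)
    }, error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed")
  est <- do.call(rbind, reps[ok])
  ci <- tibble::tibble(
    parameter = colnames(est),
    estimate = c(fit$pop$typical, unname(fit$cov_oil[["ka"]]),
                 unname(fit$cov_oil[["beta"]]), fit$b1, fit$b2),
    lower = apply(est, 2, stats::quantile, 0.025),
    upper = apply(est, 2, stats::quantile, 0.975))
  list(ci = ci, estimates = est, n_failed = sum(!ok))
}

#' Convergence assessment from perturbed initial values
#'
#' Refits the model `n_runs` times from randomly perturbed initial typical
#' values (multiplicative `exp(U(-perturbation, perturbation))`) and
#' summarizes the dispersion of the final estimates and -2LL.
#'
#' @param ds a `pk_dataset`.
#' @param init baseline initial `population_model` (`NULL` = NCA
#'   heuristics).
#' @param n_runs number of runs (>= 2; the full assessment used many more,
#'   see the methods vignette).
#' @param perturbation log-scale half-width of the initial-value jitter.
#' @param settings,seed,covariate passed to [fit_nlme()].
#' @return List with `estimates` (run x parameter), `minus2ll`, `cv_pct`
#'   per typical parameter.
#' @export
convergence_assessment <- function(ds, init = NULL, n_runs = 20,
                                   perturbation = 0.3,
                                   settings = saem_settings(), seed = 1,
                                   covariate = TRUE) {
  if (n_runs < 2) stop("need >= 2 runs")
  if (is.null(init)) init <- nca_initial_values(ds)
  set.seed(seed)
  runs <- vector("list", n_runs)
  lls <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    typ <- init$typical *
      exp(stats::runif(length(init$typical), -perturbation, perturbation))
    typ[["F"]] <- min(typ[["F"]], 0.95)
    ini <- population_model(typical = typ, iiv_pct = init$iiv_pct,
                            iov_pct = init$iov_pct, cov_oil = init$cov_oil,
                            b1 = init$b1, b2 = init$b2, Fm = init$Fm)
    f <- fit_nlme(ds, init = ini, fixed = c(Fm = init$Fm),
                  settings = settings, seed = seed + 100 * r,
                  covariate = covariate)
    runs[[r]] <- f$pop$typical
    lls[r] <- f$minus2ll
  }
  est <- do.call(rbind, runs)
  list(estimates = est, minus2ll = lls,
       cv_pct = apply(est, 2, function(v) 100 * stats::sd(v) / mean(v)))
}
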