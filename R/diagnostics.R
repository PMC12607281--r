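#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the study under the population model and
#' design actually present in `ds` (same subjects, occasions, sampling
#' times), and compares observed 10th/50th/90th percentiles per time bin
#' with the 90% prediction band (5th-95th percentile across replicates) of
#' each simulated percentile. One bin per nominal sampling time, stratified
#' by analyte and administration stratum (IV / micellar / oil).
#'
#' @param ds a `pk_dataset` of observations.
#' @param pop the `population_model` to simulate from.
#' @param n_sim number of simulated replicates (>= 100).
#' @param seed integer seed.
#' @return A `vpc_result` tibble: stratum, analyte, time, n observations,
#'   observed percentiles `obs_p10/p50/p90`, and band columns
#'   `sim_p{10,50,90}_{lo,md,hi}`.
#' @export
vpc <- function(ds, pop, n_sim = 500, seed = 1) {
  if (n_sim < 100) stop("n_sim must be >= 100")
  set.seed(seed)
  subjects <- prep_fit_data(ds)
  nm <- names(pop$typical)
  iovp <- c("F", "ka", "beta")
  # observed table
  obs <- ds[ds$DVID %in% 1:2 & ds$BLQ == 0L & !is.na(ds$DV) & ds$TIME > 0, ]
  obs$stratum <- obs$FORM
  # simulate
  sims <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    rows <- vector("list", 64); nr <- 0
    for (s in subjects) {
      eta_iiv <- stats::setNames(
        stats::rnorm(length(nm), 0, pop$omega[nm]), nm)
      for (occ in s$occs) {
        eta_iov <- if (occ$oral)
          stats::setNames(stats::rnorm(3, 0, pop$gamma[iovp]), iovp) else
          numeric()
        th <- realize_individual(pop, occ$formulation, eta_iiv, eta_iov)
        par10 <- unlist(th)[c("F", "ka", "beta", "Cl", "Vc", "Q", "Vp",
                              "Fm", "Clm", "Vm")]
        if (!occ$oral) { par10[1:3] <- c(1, 1, 1) }
        m <- .cpp_pk_solve(par10, occ$dose_mat, occ$times, 1e-6, 1e-6)
        f <- ifelse(occ$dvid == 1L, (m[, "A1"] / th$Vc)[occ$t_idx],
                    (m[, "A3"] / th$Vm)[occ$t_idx])
        b <- ifelse(occ$dvid == 1L, pop$b1, pop$b2)
        yv <- pmax(f * (1 + b * stats::rnorm(length(f))), 0)
        nr <- nr + 1
        rows[[nr]] <- data.frame(stratum = occ$formulation,
                                 TIME = occ$times[occ$t_idx],
                                 DVID = occ$dvid, DV = yv)
      }
    }
    sims[[r]] <- do.call(rbind, rows[seq_len(nr)])
  }
  qs <- c(0.1, 0.5, 0.9)
  strata <- unique(obs[, c("stratum", "DVID")])
  out <- list()
  for (k in seq_len(nrow(strata))) {
    st <- strata$stratum[k]; dv <- strata$DVID[k]
    ob <- obs[obs$stratum == st & obs$DVID == dv, ]
    for (tb in sort(unique(ob$TIME))) {
      yv <- ob$DV[ob$TIME == tb]
      if (!length(yv)) next
      simq <- vapply(sims, function(sm) {
        v <- sm$DV[sm$stratum == st & sm$DVID == dv & sm$TIME == tb]
        if (length(v) < 2) return(c(NA_real_, NA_real_, NA_real_))
        stats::quantile(v, qs, names = FALSE)
      }, numeric(3))
      if (all(is.na(simq))) {
        warning("empty bin dropped: ", st, " DVID ", dv, " t=", tb)
        next
      }
      band <- apply(simq, 1, stats::quantile, c(0.05, 0.5, 0.95), na.rm = TRUE)
      oq <- stats::quantile(yv, qs, names = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        stratum = st, analyte = ifelse(dv == 1L, "parent", "metabolite"),
        time = tb, n = length(yv),
        obs_p10 = oq[1], obs_p50 = oq[2], obs_p90 = oq[3],
        sim_p10_lo = band[1, 1], sim_p10_md = band[2, 1], sim_p10_hi = band[3, 1],
        sim_p50_lo = band[1, 2], sim_p50_md = band[2, 2], sim_p50_hi = band[3, 2],
        sim_p90_lo = band[1, 3], sim_p90_md = band[2, 3], sim_p90_hi = band[3, 3])
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("vpc_result", class(res))
  res
}

#' Plot a visual predictive check
#'
#' @param x a `vpc_result`.
#' @param log_y log-scale concentration axis?
#' @return A ggplot object (observed percentiles as lines, simulated median
#'   band as ribbons), faceted by stratum and analyte.
#' @export
vpc_plot <- function(x, log_y = TRUE) {
  gg <- ggplot2::ggplot(as.data.frame(x), ggplot2::aes(x = time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p10_lo,
                                      ymax = sim_p10_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p90_lo,
                                      ymax = sim_p90_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_p50_lo,
                                      ymax = sim_p50_hi),
                         fill = "pink", alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p50), linewidth = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p10), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = obs_p90), linetype = 2) +
    ggplot2::facet_wrap(~ stratum + analyte, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration (nmol/L)")
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}

#' Population and individual weighted residuals
#'
#' `IWRES = (obs - ipred) / (b * ipred)` with individual predictions at the
#' empirical Bayes modes; `PWRES = (obs - E[Y]) / sd(Y)` with the marginal
#' mean and standard deviation estimated by simulating `n_sim` population
#' replicates at each design point. Observations with zero individual
#' prediction are excluded (count reported).
#'
#' @param ds the fitted `pk_dataset`.
#' @param fit a converged `cbg_fit`.
#' @param ebes optional result of [compute_ebes()] (recomputed otherwise).
#' @param n_sim simulation replicates for the marginal moments.
#' @param seed integer seed.
#' @return Tibble with ID, OCC, TIME, analyte, obs, ipred, iwres, pwres;
#'   attributes `frac_iwres_gt2` (fraction with |IWRES| > 2),
#'   `frac_pwres_gt2` and `n_excluded`.
#' @export
residual_table <- function(ds, fit, ebes = NULL, n_sim = 200, seed = 1) {
  obs <- ds$DV[ds$DVID %in% 1:2 & ds$BLQ == 0L & !is.na(ds$DV) & ds$TIME > 0]
  if (abs(sum(obs) - fit$y_checksum) >
      1e-6 * max(1, abs(fit$y_checksum)))
    stop("dataset does not match the one the model was fitted to")
  if (is.null(ebes)) ebes <- compute_ebes(fit)
  set.seed(seed)
  dpar <- c("Cl", "Vc", "Vp", "Vm", "Clm")
  nm <- names(fit$pop$typical)
  iovp <- c("F", "ka", "beta")
  rows <- list()
  n_excluded <- 0
  for (i in seq_along(fit$subjects)) {
    s <- fit$subjects[[i]]
    z <- ebes$modes[[i]]
    psi_row <- fit$mu
    psi_row[dpar] <- z[seq_along(dpar)]
    no <- length(s$oral_idx)
    phi_i <- if (no) matrix(z[-seq_along(dpar)], no, 3, byrow = TRUE,
                            dimnames = list(NULL, ABS_PARS)) else NULL
    for (j in seq_along(s$occs)) {
      occ <- s$occs[[j]]
      ph <- if (occ$oral) phi_i[match(j, s$oral_idx), ] else NULL
      par10 <- occ_par10(psi_row, ph, occ$oral, fit$Fm)
      m <- .cpp_pk_solve(par10, occ$dose_mat, occ$times,
                         fit$settings$rtol, fit$settings$atol)
      ipred <- ifelse(occ$dvid == 1L, (m[, "A1"] / par10[5])[occ$t_idx],
                      (m[, "A3"] / par10[10])[occ$t_idx])
      b <- ifelse(occ$dvid == 1L, fit$b1, fit$b2)
      # marginal moments by simulation from the fitted population model
      K <- n_sim
      sim <- matrix(NA_real_, K, length(occ$y))
      for (r in seq_len(K)) {
        eta_iiv <- stats::setNames(stats::rnorm(length(nm), 0,
                                                fit$pop$omega[nm]), nm)
        eta_iov <- if (occ$oral)
          stats::setNames(stats::rnorm(3, 0, fit$pop$gamma[iovp]), iovp) else
          numeric()
        th <- realize_individual(fit$pop, occ$formulation, eta_iiv, eta_iov)
        p10 <- unlist(th)[c("F", "ka", "beta", "Cl", "Vc", "Q", "Vp",
                            "Fm", "Clm", "Vm")]
        if (!occ$oral) p10[1:3] <- c(1, 1, 1)
        ms <- .cpp_pk_solve(p10, occ$dose_mat, occ$times, 1e-6, 1e-6)
        f <- ifelse(occ$dvid == 1L, (ms[, "A1"] / th$Vc)[occ$t_idx],
                    (ms[, "A3"] / th$Vm)[occ$t_idx])
        sim[r, ] <- f * (1 + b * stats::rnorm(length(f)))
      }
      mmean <- colMeans(sim)
      msd <- apply(sim, 2, stats::sd)
      keep <- ipred > 0
      n_excluded <- n_excluded + sum(!keep)
      rows[[length(rows) + 1]] <- tibble::tibble(
        ID = s$id, OCC = j, TIME = occ$times[occ$t_idx][keep],
        analyte = ifelse(occ$dvid[keep] == 1L, "parent", "metabolite"),
        obs = occ$y[keep], ipred = ipred[keep],
        iwres = (occ$y[keep] - ipred[keep]) / (b[keep] * ipred[keep]),
        pwres = (occ$y[keep] - mmean[keep]) / msd[keep])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "frac_iwres_gt2") <- mean(abs(out$iwres) > 2)
  attr(out, "frac_pwres_gt2") <- mean(abs(out$pwres) > 2)
  attr(out, "n_excluded") <- n_excluded
  out
}
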