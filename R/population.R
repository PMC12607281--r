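#' Population pharmacokinetic model
#'
#' Bundles the typical structural values, the random-effect standard
#' deviations (inter-individual, IIV, and inter-occasion, IOV, both on the
#' transformed scale), the categorical formulation covariate coefficients on
#' `ka` and `beta` (log scale, micellar = reference), the proportional
#' residual-error components, and the fixed metabolized fraction.
#'
#' All parameters are log-normally distributed between subjects except the
#' oral bioavailability `F`, which is logit-normal so every draw stays in
#' (0, 1). IOV applies to the absorption-side parameters `F`, `ka`, `beta`
#' only, and only across oral occasions (the IV occasion bypasses the depot).
#'
#' @param typical named numeric vector of typical values for `F, ka, beta,
#'   Cl, Vc, Q, Vp, Vm, Clm` (`ka`/`beta` at the reference micellar category).
#' @param iiv_pct named IIV percentages (parameters absent have no IIV).
#' @param iov_pct named IOV percentages (subset of `F`, `ka`, `beta`).
#' @param cov_oil named log-scale covariate coefficients added for the oil
#'   category (on `ka` and `beta`).
#' @param b1,b2 proportional residual-error components, parent / metabolite.
#' @param Fm fixed metabolized fraction (not estimated).
#' @return An object of class `population_model`.
#' @examples
#' pop <- published_population_model()
#' pop$omega[["Cl"]]   # 27.95% CV -> 0.274 on the log scale
#' @export
population_model <- function(typical, iiv_pct = numeric(), iov_pct = numeric(),
                             cov_oil = c(ka = 0, beta = 0),
                             b1 = 0.29, b2 = 0.41, Fm = 0.75) {
  need <- c("F", "ka", "beta", "Cl", "Vc", "Q", "Vp", "Vm", "Clm")
  if (!all(need %in% names(typical)))
    stop("typical values missing for: ",
         paste(setdiff(need, names(typical)), collapse = ", "))
  typical <- typical[need]
  if (any(c(b1, b2) < 0)) stop("residual-error proportions must be >= 0")
  if (any(iiv_pct < 0) || any(iov_pct < 0))
    stop("variability percentages must be >= 0")
  if (!all(names(iov_pct) %in% c("F", "ka", "beta")))
    stop("IOV is defined for F, ka and beta only")
  omega <- vapply(need, function(p) {
    pct <- if (p %in% names(iiv_pct)) iiv_pct[[p]] else 0
    percent_to_sd(pct, transform = param_transform(p))
  }, numeric(1))
  gamma <- vapply(c("F", "ka", "beta"), function(p) {
    pct <- if (p %in% names(iov_pct)) iov_pct[[p]] else 0
    percent_to_sd(pct, transform = param_transform(p))
  }, numeric(1))
  structure(list(typical = typical, iiv_pct = iiv_pct, iov_pct = iov_pct,
                 omega = omega, gamma = gamma,
                 cov_oil = cov_oil[c("ka", "beta")],
                 b1 = b1, b2 = b2, Fm = Fm),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (typical values; IIV/IOV on transformed scale)\n")
  df <- data.frame(typical = x$typical, omega = x$omega,
                   gamma = x$gamma[match(names(x$typical), names(x$gamma))])
  df$gamma[is.na(df$gamma)] <- 0
  print(round(df, 4))
  cat(sprintf("oil covariate: ka %+0.4f, beta %+0.4f (log scale)\n",
              x$cov_oil[["ka"]], x$cov_oil[["beta"]]))
  cat(sprintf("residual error b1 = %.3g (parent), b2 = %.3g (metabolite); Fm fixed = %.3g\n",
              x$b1, x$b2, x$Fm))
  invisible(x)
}

#' The published final model
#'
#' Typical values, IIV/IOV percentages, formulation covariate and residual
#' proportions of the final horse CBG/CBG-G population model.
#'
#' @return A `population_model`.
#' @export
published_population_model <- function() {
  population_model(
    typical = c(F = 0.28, ka = 0.99, beta = 1.59, Cl = 1.67, Vc = 32.15,
                Q = 154.5, Vp = 36.12, Vm = 0.0047, Clm = 0.016),
    iiv_pct = c(F = 25.52, ka = 46.64, beta = 26.01, Cl = 27.95, Vc = 66.74,
                Vp = 21.22, Vm = 53.58, Clm = 32.23),
    iov_pct = c(F = 13.93, ka = 37.99, beta = 12.8),
    cov_oil = c(ka = log(0.31 / 0.99), beta = log(0.70 / 1.59)),
    b1 = 0.29, b2 = 0.41, Fm = 0.75)
}

# transform per parameter: logit keeps bioavailability inside (0, 1)
param_transform <- function(name) ifelse(name == "F", "logit", "log")

transform_value <- function(x, transform) {
  switch(transform, log = log(x), logit = stats::qlogis(x),
         stop("unknown transform"))
}
inverse_transform <- function(x, transform) {
  switch(transform, log = exp(x), logit = stats::plogis(x),
         stop("unknown transform"))
}

#' Variability percentage to transformed-scale standard deviation
#'
#' Tabulated variabilities are percentages. For log-normal parameters they
#' are read as coefficients of variation, `omega = sqrt(log(1 + (pct/100)^2))`;
#' for the logit-normal bioavailability the percentage is taken directly as
#' the standard deviation of the logit-scale random effect (/100).
#'
#' @param pct percentage (>= 0).
#' @param transform `"log"` or `"logit"`.
#' @return Standard deviation on the transformed scale.
#' @examples
#' percent_to_sd(27.95)  # 0.2743
#' @export
percent_to_sd <- function(pct, transform = "log") {
  if (any(pct < 0)) stop("percentage must be non-negative")
  if (transform == "logit") pct / 100 else sqrt(log(1 + (pct / 100)^2))
}

# inverse, for reporting estimates on the printed percent scale
sd_to_percent <- function(sd, transform = "log") {
  if (transform == "logit") sd * 100 else 100 * sqrt(exp(sd^2) - 1)
}

#' Map population parameters and random effects to one individual
#'
#' `theta_i = inverse_transform(transform(theta_typical) + cov + eta_IIV +
#' eta_IOV)`: multiplicative log-normal effects, logit-additive for `F`.
#' The metabolized fraction stays fixed.
#'
#' @param pop a `population_model`.
#' @param formulation `"micellar"` (reference), `"oil"` (covariate applied),
#'   or `"none"` (IV occasion; absorption parameters at reference, unused).
#' @param eta_iiv,eta_iov named numeric vectors of random effects on the
#'   transformed scale; missing names are taken as zero.
#' @return A `structural_params` object.
#' @examples
#' realize_individual(published_population_model(), "oil")  # ka 0.31, beta 0.70
#' @export
realize_individual <- function(pop, formulation = "micellar",
                               eta_iiv = numeric(), eta_iov = numeric()) {
  known <- c("micellar", "oil", "none")
  if (!formulation %in% known)
    stop("unknown formulation category '", formulation,
         "'; known categories: ", paste(known, collapse = ", "))
  nm <- names(pop$typical)
  get_eta <- function(eta, p) if (p %in% names(eta)) eta[[p]] else 0
  vals <- vapply(nm, function(p) {
    tr <- param_transform(p)
    phi <- transform_value(pop$typical[[p]], tr)
    if (formulation == "oil" && p %in% names(pop$cov_oil))
      phi <- phi + pop$cov_oil[[p]]
    phi <- phi + get_eta(eta_iiv, p) + get_eta(eta_iov, p)
    inverse_transform(phi, tr)
  }, numeric(1))
  structural_params(F = vals[["F"]], ka = vals[["ka"]], beta = vals[["beta"]],
                    Cl = vals[["Cl"]], Vc = vals[["Vc"]], Q = vals[["Q"]],
                    Vp = vals[["Vp"]], Fm = pop$Fm, Clm = vals[["Clm"]],
                    Vm = vals[["Vm"]])
}

#' Sample individual realizations from the population
#'
#' Draws `eta_IIV` once per subject and `eta_IOV` independently per occasion
#' (oral occasions only), then maps them through [realize_individual()].
#'
#' @param pop a `population_model`.
#' @param n number of subjects (>= 1).
#' @param design data frame with columns `occasion`, `route`, `formulation`;
#'   defaults to a single micellar oral occasion.
#' @param seed integer seed (required for reproducibility).
#' @return A list with `params`: data frame of one row per
#'   subject-occasion holding the realized structural parameters, and
#'   `eta_iiv` (n x parameter matrix of subject-level effects).
#' @export
sample_population <- function(pop, n,
                              design = data.frame(occasion = 1, route = "oral",
                                                  formulation = "micellar"),
                              seed = 1) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  nm <- names(pop$typical)
  iovp <- c("F", "ka", "beta")
  eta_iiv <- vapply(nm, function(p) stats::rnorm(n, 0, pop$omega[[p]]),
                    numeric(n))
  eta_iiv <- matrix(eta_iiv, nrow = n, dimnames = list(NULL, nm))
  rows <- vector("list", n * nrow(design))
  k <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(design))) {
      occ_oral <- design$route[j] == "oral"
      eta_iov <- if (occ_oral) {
        stats::setNames(stats::rnorm(3, 0, pop$gamma[iovp]), iovp)
      } else numeric()
      th <- realize_individual(pop, design$formulation[j],
                               eta_iiv = stats::setNames(eta_iiv[i, ], nm),
                               eta_iov = eta_iov)
      k <- k + 1
      rows[[k]] <- data.frame(subject = i, occasion = design$occasion[j],
                              route = design$route[j],
                              formulation = design$formulation[j],
                              as.data.frame(unclass(th)))
    }
  }
  list(params = do.call(rbind, rows), eta_iiv = eta_iiv)
}

#' Apply the proportional residual-error model
#'
#' Observation model `C_obs = C_pred (1 + b eps)` with standard-normal
#' `eps`, per analyte, truncated at zero (a zero prediction stays zero).
#'
#' @param curve a `concentration_curve`.
#' @param b1,b2 proportional error components for parent and metabolite.
#' @param seed optional integer seed.
#' @return List with `obs_parent` and `obs_metabolite` (nmol/L).
#' @export
apply_residual_error <- function(curve, b1 = 0.29, b2 = 0.41, seed = NULL) {
  if (b1 < 0 || b2 < 0) stop("error proportions must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(curve$times)
  obs_p <- curve$c_parent * (1 + b1 * stats::rnorm(n))
  obs_m <- curve$c_metabolite * (1 + b2 * stats::rnorm(n))
  list(obs_parent = pmax(obs_p, 0), obs_metabolite = pmax(obs_m, 0))
}
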