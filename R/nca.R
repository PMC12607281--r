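#' Linear-up/log-down trapezoidal AUC
#'
#' Numerical area under a sampled concentration-time curve: linear trapezoid
#' on rising or zero segments, log trapezoid on declining positive segments.
#' With `extrapolate = TRUE` the tail `C_last / lambda_z` is added,
#' `lambda_z` taken from [terminal_half_life()] unless supplied.
#'
#' @param times sampling times (h), strictly increasing.
#' @param conc concentrations (nmol/L), same length.
#' @param t_start,t_end integration window (defaults: full curve). Window
#'   ends interior to the grid are linearly interpolated.
#' @param extrapolate add the `C_last/lambda_z` tail beyond `t_end`?
#' @param lambda_z optional terminal slope (1/h) for the tail.
#' @return AUC in nmol h/L.
#' @examples
#' tt <- seq(0, 72, 0.25)
#' auc_trapezoid(tt, 100 * exp(-0.1 * tt), extrapolate = TRUE)  # ~ 1000
#' @export
auc_trapezoid <- function(times, conc, t_start = min(times),
                          t_end = max(times), extrapolate = FALSE,
                          lambda_z = NULL) {
  if (inherits(times, "concentration_curve"))
    stop("pass numeric vectors: auc_trapezoid(curve$times, curve$c_parent, ...)")
  stopifnot(length(times) == length(conc))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (t_start < min(times) || t_end > max(times))
    stop("integration window must lie within the sampled curve")
  if (t_end <= t_start) stop("t_end must exceed t_start")
  keep <- times >= t_start & times <= t_end
  tt <- times[keep]; cc <- conc[keep]
  if (!length(tt) || tt[1] > t_start) {
    tt <- c(t_start, tt); cc <- c(stats::approx(times, conc, t_start)$y, cc)
  }
  if (tt[length(tt)] < t_end) {
    tt <- c(tt, t_end); cc <- c(cc, stats::approx(times, conc, t_end)$y)
  }
  dt <- diff(tt); c1 <- cc[-length(cc)]; c2 <- cc[-1]
  logdown <- c2 < c1 & c2 > 0 & c1 > 0
  seg <- ifelse(logdown, (c1 - c2) / log(c1 / c2), (c1 + c2) / 2) * dt
  auc <- sum(seg)
  if (extrapolate) {
    if (is.null(lambda_z)) {
      lz <- tryCatch(terminal_half_life(times, conc)$lambda_z,
                     error = function(e) NULL)
      if (is.null(lz)) stop("terminal slope unavailable; cannot extrapolate")
      lambda_z <- lz
    }
    auc <- auc + cc[length(cc)] / lambda_z
  }
  auc
}

#' Maximum concentration and its time
#'
#' Ties are broken by the earliest time.
#'
#' @param times,conc sampled curve.
#' @return List with `cmax` and `tmax`.
#' @export
cmax_tmax <- function(times, conc) {
  stopifnot(length(times) == length(conc), length(times) > 0)
  i <- which(conc == max(conc))[1]
  list(cmax = conc[i], tmax = times[i])
}

#' Terminal half-life by log-linear regression
#'
#' Ordinary least squares of `log(C)` on time over the last `n_points`
#' strictly positive concentrations after the peak. When `n_points` is
#' `NULL`, the best adjusted R-squared over 3..6 terminal points is used
#' (the common NCA convention).
#'
#' @param times,conc sampled curve.
#' @param n_points number of terminal points, or `NULL` for automatic
#'   selection.
#' @return List with `t_half` (h), `lambda_z` (1/h), `n_points`, `adj_r2`.
#' @examples
#' tt <- c(8, 12, 24, 36, 48, 72)
#' terminal_half_life(tt, 50 * exp(-0.0231 * tt))$t_half  # 30 h
#' @export
terminal_half_life <- function(times, conc, n_points = NULL) {
  stopifnot(length(times) == length(conc))
  ipk <- which.max(conc)
  idx <- seq_along(times) > ipk & conc > 0
  tt <- times[idx]; cc <- conc[idx]
  if (length(tt) < 3)
    stop("need at least 3 strictly positive post-peak concentrations")
  fit_tail <- function(k) {
    sel <- seq(length(tt) - k + 1, length(tt))
    x <- tt[sel]; y <- log(cc[sel])
    slope <- stats::cov(x, y) / stats::var(x)
    resid <- y - mean(y) - slope * (x - mean(x))
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(resid^2) / sst else 1
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    list(lambda_z = -slope, adj_r2 = adj, n_points = k)
  }
  if (!is.null(n_points)) {
    if (n_points < 3 || n_points > length(tt))
      stop("n_points must be between 3 and the number of usable points")
    best <- fit_tail(n_points)
  } else {
    cand <- lapply(3:min(6, length(tt)), fit_tail)
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "adj_r2"))]]
  }
  if (best$lambda_z <= 0) stop("non-negative terminal slope; no decline phase")
  c(best, list(t_half = log(2) / best$lambda_z))
}

#' Steady-state volume of distribution
#'
#' Sum of the central and peripheral volumes.
#'
#' @param params a `structural_params` object.
#' @return Vss in L/kg.
#' @export
vss <- function(params) params$Vc + params$Vp

#' Metabolite-to-parent AUC ratio
#'
#' Ratio of the metabolite to parent AUC over a common interval, on the
#' molar (parent-equivalent) concentration scale.
#'
#' @param curve a `concentration_curve` holding both analytes.
#' @param t_start,t_end common integration window.
#' @param extrapolate extrapolate both AUCs to infinity?
#' @return Unitless ratio.
#' @export
auc_ratio <- function(curve, t_start = min(curve$times),
                      t_end = max(curve$times), extrapolate = FALSE) {
  ap <- auc_trapezoid(curve$times, curve$c_parent, t_start, t_end, extrapolate)
  am <- auc_trapezoid(curve$times, curve$c_metabolite, t_start, t_end, extrapolate)
  if (ap <= 0) stop("parent AUC is zero; ratio undefined")
  am / ap
}

#' Per-curve exposure summary
#'
#' The study's secondary parameters for one analyte of a sampled curve:
#' AUC0-24, AUC0-inf (trapezoid + tail), Cmax, Tmax and terminal half-life;
#' Vss and the metabolite/parent AUC ratio are added when the structural
#' parameters / the second analyte are available.
#'
#' @param curve a `concentration_curve`.
#' @param analyte `"parent"` or `"metabolite"`.
#' @param params optional `structural_params` for Vss.
#' @return One-row tibble.
#' @export
exposure_summary <- function(curve, analyte = c("parent", "metabolite"),
                             params = NULL) {
  analyte <- match.arg(analyte)
  cc <- if (analyte == "parent") curve$c_parent else curve$c_metabolite
  pk <- cmax_tmax(curve$times, cc)
  th <- tryCatch(terminal_half_life(curve$times, cc), error = function(e) NULL)
  # concentration is zero at the dose time for both routes (IV is infused)
  tt <- curve$times
  if (min(tt) > 0) { tt <- c(0, tt); cc <- c(0, cc) }
  auc24 <- if (max(tt) >= 24) auc_trapezoid(tt, cc, 0, 24) else NA_real_
  aucinf <- if (!is.null(th))
    auc_trapezoid(tt, cc, extrapolate = TRUE,
                  lambda_z = th$lambda_z) else NA_real_
  tibble::tibble(analyte = analyte, auc24 = auc24, auc_inf = aucinf,
                 cmax = pk$cmax, tmax = pk$tmax,
                 t_half = if (is.null(th)) NA_real_ else th$t_half,
                 vss = if (is.null(params)) NA_real_ else vss(params),
                 auc_ratio_met_parent = tryCatch(
                   auc_ratio(curve), error = function(e) NA_real_))
}
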