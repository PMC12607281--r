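#' Crossover study design
#'
#' The design the synthetic generator emulates: healthy adult horses in a
#' three-occasion crossover (IV 1 mg/kg infused over 5 min; oral micellar
#' 10 mg/kg; oral oil 10 mg/kg, oral order alternating across subjects as a
#' 2x2 Latin square), body weight normal with mean 451 kg and SD 49.4 kg
#' (truncated positive), rich sampling at 0 (pre-dose), 5, 10, 15, 30,
#' 45 min and 1, 2, 4, 6, 8, 12, 24, 36, 48, 72 h, complete washout between
#' occasions.
#'
#' @param n_subjects number of subjects (study: 8).
#' @param bw_mean,bw_sd body-weight distribution (kg).
#' @param sampling_times post-dose sampling grid (h), strictly increasing,
#'   starting at the pre-dose 0.
#' @param iv_dose,oral_dose doses in mg/kg.
#' @param infusion_duration IV infusion length (h).
#' @param loq_parent,loq_metabolite limits of quantification (nmol/L).
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_subjects = 8, bw_mean = 451, bw_sd = 49.4,
                         sampling_times = c(0, 5/60, 10/60, 15/60, 0.5, 0.75,
                                            1, 2, 4, 6, 8, 12, 24, 36, 48, 72),
                         iv_dose = 1, oral_dose = 10,
                         infusion_duration = 1 / 12,
                         loq_parent = 0.0004, loq_metabolite = 0.0008) {
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("sampling times must be strictly increasing")
  if (loq_parent < 0 || loq_metabolite < 0) stop("LOQs must be >= 0")
  structure(list(n_subjects = n_subjects, bw_mean = bw_mean, bw_sd = bw_sd,
                 sampling_times = sampling_times, iv_dose = iv_dose,
                 oral_dose = oral_dose, infusion_duration = infusion_duration,
                 loq_parent = loq_parent, loq_metabolite = loq_metabolite),
            class = "study_design")
}

#' Generate a synthetic crossover study
#'
#' Draws subject-level IIV and occasion-level IOV random effects from `pop`,
#' solves each subject-occasion profile, perturbs it with the proportional
#' residual-error model, censors at the LOQ, and assembles the long-format
#' dataset the estimation step consumes. The generating ("truth") individual
#' parameters are returned alongside, never inside the fitting table.
#'
#' @param pop a `population_model` (defaults to the published model).
#' @param design a `study_design`.
#' @param seed integer seed; fixed seed gives a byte-identical dataset.
#' @return List with `data` (a `pk_dataset` tibble: ID, OCC, TIME, DVID,
#'   DV, AMT, DUR, FORM, BW, BLQ) and `truth` (generating parameters per
#'   subject-occasion plus the random-effect draws).
#' @examples
#' st <- generate_study(design = study_design(n_subjects = 2), seed = 1)
#' head(st$data)
#' @export
generate_study <- function(pop = published_population_model(),
                           design = study_design(), seed = 1) {
  set.seed(seed)
  n <- design$n_subjects
  bw <- numeric(n)
  for (i in seq_len(n)) {
    repeat { bw[i] <- stats::rnorm(1, design$bw_mean, design$bw_sd)
             if (bw[i] > 0) break }
  }
  nm <- names(pop$typical)
  iovp <- c("F", "ka", "beta")
  eta_iiv <- vapply(nm, function(p) stats::rnorm(n, 0, pop$omega[[p]]),
                    numeric(n))
  eta_iiv <- matrix(eta_iiv, nrow = n, dimnames = list(NULL, nm))
  st <- design$sampling_times
  post <- st[st > 0]
  iv_amt <- mg_per_kg_to_nmol_per_kg(design$iv_dose)
  or_amt <- mg_per_kg_to_nmol_per_kg(design$oral_dose)
  rows <- list(); truth_rows <- list(); eta_iov_rows <- list()
  for (i in seq_len(n)) {
    # 2x2 Latin square for the oral order: odd subjects micellar first
    oral_order <- if (i %% 2 == 1) c("micellar", "oil") else c("oil", "micellar")
    occs <- data.frame(occasion = 1:3, route = c("IV", "oral", "oral"),
                       formulation = c("none", oral_order))
    for (j in seq_len(3)) {
      occ_oral <- occs$route[j] == "oral"
      eta_iov <- if (occ_oral)
        stats::setNames(stats::rnorm(3, 0, pop$gamma[iovp]), iovp) else
        stats::setNames(numeric(3), iovp)
      th <- realize_individual(pop, occs$formulation[j],
                               eta_iiv = stats::setNames(eta_iiv[i, ], nm),
                               eta_iov = eta_iov)
      reg <- if (occ_oral) {
        dose_event(0, "oral", or_amt, 0, occs$formulation[j])
      } else {
        dose_event(0, "IV", iv_amt, design$infusion_duration, "none")
      }
      cv <- solve_profile(th, reg, post)
      obs <- apply_residual_error(cv, pop$b1, pop$b2)
      form <- occs$formulation[j]
      dose_row <- data.frame(ID = i, OCC = j, TIME = 0, DVID = 0, DV = NA_real_,
                             AMT = reg$amount, DUR = reg$infusion_duration,
                             FORM = form, BW = bw[i], BLQ = 0L)
      pre <- data.frame(ID = i, OCC = j, TIME = 0, DVID = c(1L, 2L), DV = 0,
                        AMT = NA_real_, DUR = NA_real_, FORM = form,
                        BW = bw[i], BLQ = 0L)
      obs_rows <- rbind(
        data.frame(ID = i, OCC = j, TIME = post, DVID = 1L,
                   DV = obs$obs_parent, AMT = NA_real_, DUR = NA_real_,
                   FORM = form, BW = bw[i], BLQ = 0L),
        data.frame(ID = i, OCC = j, TIME = post, DVID = 2L,
                   DV = obs$obs_metabolite, AMT = NA_real_, DUR = NA_real_,
                   FORM = form, BW = bw[i], BLQ = 0L))
      obs_rows <- obs_rows[order(obs_rows$TIME, obs_rows$DVID), ]
      rows[[length(rows) + 1]] <- rbind(dose_row, pre, obs_rows)
      truth_rows[[length(truth_rows) + 1]] <-
        data.frame(subject = i, occasion = j, formulation = form,
                   as.data.frame(unclass(th)))
      eta_iov_rows[[length(eta_iov_rows) + 1]] <-
        data.frame(subject = i, occasion = j, t(eta_iov))
    }
  }
  ds <- tibble::as_tibble(do.call(rbind, rows))
  ds <- censor_loq(ds, design$loq_parent, design$loq_metabolite)
  ds <- as_pk_dataset(ds)
  list(data = ds,
       truth = list(pop = pop, design = design, seed = seed,
                    params = do.call(rbind, truth_rows),
                    eta_iiv = eta_iiv,
                    eta_iov = do.call(rbind, eta_iov_rows)))
}

#' Censor observations below the limit of quantification
#'
#' Flags observation rows whose `DV` falls strictly below the analyte's LOQ
#' (`BLQ = 1`). Flagged rows are excluded from fitting; the printed study
#' LOQs (0.0004 / 0.0008 nmol/L) are kept as defaults.
#'
#' @param ds a `pk_dataset` (or compatible data frame).
#' @param loq_parent,loq_metabolite LOQs in nmol/L (>= 0).
#' @return The dataset with the `BLQ` column updated.
#' @export
censor_loq <- function(ds, loq_parent = 0.0004, loq_metabolite = 0.0008) {
  if (loq_parent < 0 || loq_metabolite < 0) stop("LOQs must be >= 0")
  obs <- ds$DVID %in% c(1L, 2L)
  loq <- ifelse(ds$DVID == 1L, loq_parent, loq_metabolite)
  ds$BLQ <- ifelse(obs & !is.na(ds$DV) & ds$DV < loq, 1L, 0L)
  ds
}
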