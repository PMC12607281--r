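#' Long-format dataset dialect
#'
#' The analysis exchanges data as a NONMEM-like long-format CSV with the
#' exact header `ID, OCC, TIME, DVID, DV, AMT, DUR, FORM, BW, BLQ`:
#' subject id, occasion id, time (h), analyte code (1 parent, 2 metabolite,
#' 0 dose row), observed concentration (nmol/L; empty on dose rows), dose
#' amount (nmol/kg; dose rows only), infusion duration (h), formulation
#' category (`micellar`/`oil`/`none`), body weight (kg) and a below-LOQ
#' flag. Decimal point, UTF-8, one dose row per subject-occasion preceding
#' its observations.
#'
#' @param ds a data frame in the dialect above.
#' @return A validated `pk_dataset` tibble.
#' @export
as_pk_dataset <- function(ds) {
  cols <- c("ID", "OCC", "TIME", "DVID", "DV", "AMT", "DUR", "FORM", "BW", "BLQ")
  missing_cols <- setdiff(cols, names(ds))
  if (length(missing_cols))
    stop("dataset is missing columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(ds), cols)
  if (length(extra))
    stop("unknown dataset columns: ", paste(extra, collapse = ", "))
  ds <- tibble::as_tibble(ds)[, cols]
  if (any(ds$TIME < 0))
    stop("negative time at row ", which(ds$TIME < 0)[1])
  if (!all(ds$DVID %in% 0:2))
    stop("DVID must be 0 (dose), 1 (parent) or 2 (metabolite); bad row ",
         which(!ds$DVID %in% 0:2)[1])
  bad_dose_dv <- which(ds$DVID == 0 & !is.na(ds$DV))
  if (length(bad_dose_dv))
    stop("DV present on a dose row at row ", bad_dose_dv[1])
  bad_obs <- which(ds$DVID != 0 & (is.na(ds$DV) | ds$DV < 0))
  if (length(bad_obs))
    stop("missing or negative observation at row ", bad_obs[1])
  key <- interaction(ds$ID, ds$OCC, drop = TRUE)
  for (k in levels(key)) {
    sub <- ds[key == k, ]
    ndose <- sum(sub$DVID == 0)
    if (ndose != 1)
      stop("subject-occasion ", k, " has ", ndose, " dose rows (need exactly 1)")
    if (any(sub$TIME[sub$DVID != 0] < sub$TIME[sub$DVID == 0]))
      stop("observations precede the dose in subject-occasion ", k)
  }
  class(ds) <- c("pk_dataset", class(ds))
  ds
}

#' Read / write the dataset dialect
#'
#' @param path CSV file path.
#' @return `read_pk_dataset`: a validated `pk_dataset`.
#' @seealso [as_pk_dataset()] for the column contract.
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ds <- utils::read.csv(path, stringsAsFactors = FALSE)
  ds <- as_pk_dataset(ds)
  if (!any(ds$DVID != 0 & ds$BLQ == 0))
    stop("no quantifiable data in ", path)
  ds
}

#' @rdname read_pk_dataset
#' @param ds a `pk_dataset`.
#' @export
write_pk_dataset <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a population model to a structured text configuration
#'
#' Keys mirror the published parameter table: typical values, IIV/IOV
#' percentages, category-specific absorption values, residual proportions
#' and the fixed metabolized fraction.
#'
#' @param pop a `population_model`.
#' @param path YAML file path.
#' @export
write_population_model <- function(pop, path) {
  cfg <- list(
    typical = as.list(pop$typical),
    iiv_pct = as.list(pop$iiv_pct),
    iov_pct = as.list(pop$iov_pct),
    category = list(micellar = list(ka = pop$typical[["ka"]],
                                    beta = pop$typical[["beta"]]),
                    oil = list(ka = pop$typical[["ka"]] * exp(pop$cov_oil[["ka"]]),
                               beta = pop$typical[["beta"]] * exp(pop$cov_oil[["beta"]]))),
    residual_error = list(b1 = pop$b1, b2 = pop$b2),
    fixed = list(Fm = pop$Fm))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_population_model
#' @return `read_population_model`: a `population_model`.
#' @export
read_population_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  typ <- unlist(cfg$typical)
  population_model(
    typical = typ,
    iiv_pct = unlist(cfg$iiv_pct),
    iov_pct = unlist(cfg$iov_pct),
    cov_oil = c(ka = log(cfg$category$oil$ka / typ[["ka"]]),
                beta = log(cfg$category$oil$beta / typ[["beta"]])),
    b1 = cfg$residual_error$b1, b2 = cfg$residual_error$b2,
    Fm = cfg$fixed$Fm)
}

#' Write the generating ("truth") parameters of a synthetic study
#'
#' Sidecar file for parameter-recovery checks; never part of the fitting
#' table.
#'
#' @param truth the `truth` element returned by [generate_study()].
#' @param path YAML file path.
#' @export
write_truth_sidecar <- function(truth, path) {
  yaml::write_yaml(list(seed = truth$seed,
                        typical = as.list(truth$pop$typical),
                        params = lapply(split(truth$params,
                                              seq_len(nrow(truth$params))),
                                        as.list)),
                   path)
  invisible(path)
}
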