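#!/usr/bin/env Rscript
# Step 3 — non-compartmental exposure summaries per subject and occasion.
#
# AUC0-24, AUC0-inf (trapezoid + lambda-z tail), Cmax, Tmax, terminal
# half-life and metabolite/parent AUC ratio from each observed profile,
# plus the model-typical closed forms for reference.

library(cbgpk)

ds <- read_pk_dataset("results/study_dataset.csv")
obs <- ds[ds$DVID != 0 & ds$BLQ == 0, ]

rows <- list()
for (id in unique(obs$ID)) for (oc in unique(obs$OCC[obs$ID == id])) {
  sub <- obs[obs$ID == id & obs$OCC == oc, ]
  tt <- sort(unique(sub$TIME))
  getc <- function(a) vapply(tt, function(t) {
    v <- sub$DV[sub$DVID == a & sub$TIME == t]
    if (length(v)) v[1] else 0
  }, numeric(1))
  cv <- concentration_curve(tt, getc(1), getc(2))
  for (an in c("parent", "metabolite")) {
    es <- exposure_summary(cv, an)
    rows[[length(rows) + 1]] <-
      cbind(data.frame(subject = id, occasion = oc,
                       formulation = sub$FORM[1]), es)
  }
}
nca <- do.call(rbind, rows)
write.csv(nca, "results/nca_summary.csv", row.names = FALSE)

typ <- typical_params()
cf_iv <- auc_inf_closed_form(typ, mg_per_kg_to_nmol_per_kg(1), "IV")
cf_or <- auc_inf_closed_form(typ, mg_per_kg_to_nmol_per_kg(10), "oral")
message(sprintf("Typical closed forms: IV AUC %.1f, oral AUC %.1f, oral metabolite AUC %.0f nmol.h/L.",
                cf_iv$auc_parent, cf_or$auc_parent, cf_or$auc_metabolite))
message(sprintf("Median observed IV parent half-life: %.1f h (eigenvalue value %.1f h).",
                median(nca$t_half[nca$formulation == "none" &
                                    nca$analyte == "parent"], na.rm = TRUE),
                terminal_slope(typ)$t_half))
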