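#!/usr/bin/env Rscript
# Step 1 — simulate the crossover study the analysis runs on.
#
# Eight horses, three occasions each (IV 1 mg/kg over 5 min; oral micellar
# and oral oil 10 mg/kg in alternating order), the study sampling schedule,
# log-normal IIV, IOV on the absorption side, logit-normal bioavailability,
# proportional residual error (29% parent, 41% metabolite), LOQ censoring.
# Writes the long-format dataset, the generating-parameter sidecar and the
# population-model configuration under results/.

library(cbgpk)

dir.create("results", showWarnings = FALSE)
seed <- 20250925

pop <- published_population_model()
st <- generate_study(pop, study_design(), seed = seed)

write_pk_dataset(st$data, "results/study_dataset.csv")
write_truth_sidecar(st$truth, "results/study_truth.yaml")
write_population_model(pop, "results/population_model.yaml")

obs <- st$data[st$data$DVID != 0 & st$data$BLQ == 0, ]
message(sprintf("Simulated %d subjects, %d quantifiable observations (seed %d).",
                length(unique(st$data$ID)), nrow(obs), seed))
message(sprintf("Parent concentrations span %.3g-%.3g nmol/L.",
                min(obs$DV[obs$DVID == 1 & obs$DV > 0]),
                max(obs$DV[obs$DVID == 1])))
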