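#!/usr/bin/env Rscript
# Step 4 — Monte Carlo simulation of 14-day multiple-dose regimens.
#
# 10 mg/kg orally every 24 h for 14 days, 5000 simulated subjects per
# formulation arm drawn from the published population distribution.
# Summaries (median + CV%) of first-interval and steady-state AUCs,
# accumulation indices and Cmax/Tmax per arm, and the time to reach 90%
# of steady state for the typical subject.

library(cbgpk)

pop <- published_population_model()
out <- list()
for (form in c("micellar", "oil")) {
  message("Simulating ", form, " arm (n = 5000) ...")
  mm <- monte_carlo_regimen(pop, regimen_spec(formulation = form,
                                              n_subjects = 5000,
                                              seed = match(form,
                                                           c("micellar",
                                                             "oil"))))
  sm <- summarize_metrics(mm, statistic = "median")
  sm$formulation <- form
  out[[form]] <- sm
  message(sprintf("  median AUC24 %.0f, AUCss %.0f nmol.h/L, accumulation %.2f (parent)",
                  sm$estimate[sm$metric == "auc24_parent"],
                  sm$estimate[sm$metric == "auc_ss_parent"],
                  sm$estimate[sm$metric == "accumulation_parent"]))
}
write.csv(do.call(rbind, out), "results/regimen_summary.csv",
          row.names = FALSE)

tss <- time_to_steady_state(pop, regimen_spec(), threshold = 0.9)
message(sprintf("Typical subject reaches 90%% of steady state by dose %d (day %.0f).",
                tss$dose_index, tss$time_days))
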