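# shared fixtures: published constants and small generated studies

pub_pop <- published_population_model()
pub_typ <- typical_params()

IV_DOSE <- mg_per_kg_to_nmol_per_kg(1)     # 3159.76 nmol/kg
ORAL_DOSE <- mg_per_kg_to_nmol_per_kg(10)  # 31597.6 nmol/kg

STUDY_TIMES <- c(0, 5/60, 10/60, 15/60, 0.5, 0.75, 1, 2, 4, 6, 8, 12,
                 24, 36, 48, 72)

# a zero-variability, zero-noise population (deterministic typical curves)
noise_free_pop <- function() {
  population_model(typical = pub_pop$typical, iiv_pct = numeric(),
                   iov_pct = numeric(), cov_oil = pub_pop$cov_oil,
                   b1 = 0, b2 = 0)
}

# small cached studies (generated once per test file)
small_study <- local({
  cache <- new.env()
  function(n = 8, seed = 7, pop = pub_pop) {
    key <- paste0("s", n, "_", seed, "_", substr(digest_pop(pop), 1, 8))
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_study(pop, study_design(n_subjects = n), seed)
    cache[[key]]
  }
})

digest_pop <- function(pop) {
  paste0(format(sum(pop$typical) + sum(pop$omega) + pop$b1 + pop$b2,
                digits = 12))
}

fast_settings <- function(...) {
  saem_settings(n_burn = 100, n_sa = 80, ll_nsim = 80, ...)
}
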