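# Shared fixtures: small record tables built in code, and a cache so the
# expensive Gibbs fits are computed once per test run.

make_record <- function(study_id = "S1", substance = "subA",
                        formulation_type = "EC",
                        target_concentration = 100,
                        is_undiluted_product = TRUE,
                        exposure_hours = 8,
                        replicate_id = "r1",
                        receptor = 0.02, wash = 0.005, skin = 0.01,
                        strips = c(0.003, 0.002, 0.005, 0.004, 0.001),
                        recovery = 100, half_duration = 50) {
  rec <- data.frame(
    study_id = study_id, substance = substance,
    formulation_type = formulation_type,
    target_concentration = target_concentration,
    is_undiluted_product = is_undiluted_product,
    exposure_hours = exposure_hours, replicate_id = replicate_id,
    receptor_fluid_fraction = receptor, chamber_wash_fraction = wash,
    skin_fraction = skin, mean_recovery_percent = recovery,
    absorbed_at_half_duration_percent = half_duration,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(strips)) {
    rec[[paste0("tape_strip_", i)]] <- strips[i]
  }
  rec
}

make_records <- function(n = 6, ...) {
  rows <- lapply(seq_len(n), function(i) {
    make_record(replicate_id = paste0("r", i), ...)
  })
  do.call(rbind, rows)
}

# one small synthetic truth used across model tests
small_truth <- function() {
  synthetic_truth(n_substances = 25, studies_per_substance_mean = 1.2,
                  groups_per_study_mean = 1.2, replicates_min = 3,
                  replicates_mean = 6)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a moderate posterior shared by prediction/monotonicity tests
shared_small_fit <- function() {
  cached("small_fit", {
    sim <- generate_logit_dataset(small_truth(), seed = 9101)
    fit_absorption_model(sim$data, iterations = 700, burnin = 200,
                         seed = 9102)
  })
}
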