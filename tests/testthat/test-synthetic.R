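test_that("degenerate truth with all variances zero gives identical fractions per cell", {
  truth <- synthetic_truth(
    params = list(
      alpha = -2.34, beta_concentrate = -2.37, beta_other = -0.24,
      beta_solid = -0.94, beta_water_based = -0.67,
      var_substance_dilution = 1e-12, var_substance_concentrate = 1e-12,
      var_study = 0, var_within = 0, rho = 0, var_resid = 0
    ),
    n_substances = 10
  )
  sim <- generate_logit_dataset(truth, seed = 1)
  cell <- paste(sim$data$formulation_category, sim$data$status)
  for (cl in unique(cell)) {
    f <- sim$data$fraction_absorbed[cell == cl]
    expect_lt(diff(range(f)), 1e-5)
  }
  ref <- sim$data[cell == "organic_solvent dilution", ]
  if (nrow(ref) > 0) {
    expect_equal(ref$fraction_absorbed[1], inv_logit(-2.34),
                 tolerance = 1e-4)
  }
})

test_that("substance effect pairs reproduce the truth covariance and correlation", {
  truth <- synthetic_truth(n_substances = 2000)
  sim_eff <- generate_logit_dataset(
    synthetic_truth(n_substances = 400), seed = 21
  )$effects$substance
  emp <- cov(sim_eff)
  expect_lt(norm(emp - truth$G, "F") / norm(truth$G, "F"), 0.2)
  high_rho <- synthetic_truth(params = utils::modifyList(
    reference_posterior_means(), list(rho = 0.99)
  ), n_substances = 300)
  eff <- generate_logit_dataset(high_rho, seed = 22)$effects$substance
  expect_gt(cor(eff[, 1], eff[, 2]), 0.9)
})

test_that("generation is deterministic given truth and seed", {
  truth <- small_truth()
  a <- generate_logit_dataset(truth, seed = 99)
  b <- generate_logit_dataset(truth, seed = 99)
  expect_identical(a, b)
  r1 <- generate_raw_records(truth, seed = 99)
  r2 <- generate_raw_records(truth, seed = 99)
  expect_identical(r1, r2)
})

test_that("planted recovery violations are exactly the experiments the filter removes", {
  sim <- generate_raw_records(small_truth(), seed = 12,
                              frac_low_recovery = 0.1,
                              frac_high_recovery = 0.05)
  kept <- suppressWarnings(recovery_filter(sim$records))
  expect_setequal(kept$replicate_id,
                  sim$planted$replicate_id[sim$planted$recovery_retained])
  expect_gt(sum(!sim$planted$recovery_retained), 0)
})

test_that("raw-record decomposition round trips through preprocessing exactly", {
  sim <- generate_raw_records(small_truth(), seed = 13)
  prep <- prepare_dataset(sim$records)
  planted <- sim$planted[sim$planted$recovery_retained, ]
  idx <- match(planted$group_id, prep$group_id)
  expect_false(anyNA(idx))
  # compare per replicate via ordering within groups
  prep_key <- paste(prep$group_id, round(prep$fraction_absorbed, 14))
  plant_key <- paste(planted$group_id, round(planted$fraction, 14))
  expect_setequal(prep_key, plant_key)
  expect_equal(sort(prep$fraction_absorbed), sort(planted$fraction),
               tolerance = 1e-12)
})

test_that("the complete-absorption branch keeps strip mass out of the fraction", {
  sim <- generate_raw_records(small_truth(), seed = 14,
                              frac_complete = 1,
                              frac_low_recovery = 0,
                              frac_high_recovery = 0)
  prep <- prepare_dataset(sim$records)
  # no recovery exclusions, so rows correspond in order
  expect_identical(nrow(prep), nrow(sim$records))
  rec <- sim$records
  expect_true(all(rec$tape_strip_1 > 0))
  base <- rec$receptor_fluid_fraction + rec$chamber_wash_fraction +
    rec$skin_fraction
  expect_equal(prep$fraction_absorbed, base, tolerance = 1e-12)
})

test_that("default truth mirrors the source dataset scale", {
  truth <- synthetic_truth()
  sim <- generate_logit_dataset(truth, seed = 3)
  expect_equal(length(unique(sim$data$substance)), 155)
  n_studies <- length(unique(sim$data$study_id))
  expect_gt(n_studies, 280)
  expect_lt(n_studies, 440)
  expect_gt(nrow(sim$data), 4500)
  expect_lt(nrow(sim$data), 8500)
  # all eight cells populated at default scale
  expect_identical(
    length(unique(paste(sim$data$formulation_category, sim$data$status))),
    8L
  )
  # concentrations straddle the 50 g/L cut-off in both commercial classes
  counts <- reclassification_counts(
    data.frame(target_concentration = sim$data$target_concentration,
               is_undiluted_product = sim$data$status == "concentrate")
  )
  expect_gt(counts$dilution_to_concentrate, 0)
  expect_gt(counts$concentrate_to_dilution, 0)
})
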