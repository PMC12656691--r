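test_that("formulation codes map to their categories and unknown codes are rejected", {
  expect_identical(categorize_formulation("EC"), "organic_solvent")
  expect_identical(categorize_formulation("WP"), "solid")
  expect_identical(categorize_formulation("CS"), "other")
  expect_identical(categorize_formulation("SL"), "water_based")
  # mapping is total over the 20 supported codes
  map <- formulation_categories()
  expect_length(map, 20L)
  expect_setequal(unique(unname(map)),
                  c("organic_solvent", "water_based", "solid", "other"))
  expect_error(categorize_formulation("XX"), "XX")
  expect_error(categorize_formulation(c("EC", "QQ")), "QQ")
})

test_that("commercial definition classifies by the undiluted-product flag", {
  rec <- rbind(make_record(is_undiluted_product = TRUE),
               make_record(is_undiluted_product = FALSE,
                           replicate_id = "r2"))
  expect_identical(classify_status(rec, concentrate_definition()),
                   c("concentrate", "dilution"))
  rec$is_undiluted_product <- NA
  expect_error(classify_status(rec, concentrate_definition()),
               "is_undiluted_product")
})

test_that("cut-off definition is strict: above 50 g/L concentrate, at 50 dilution", {
  rec <- make_records(3)
  rec$target_concentration <- c(116, 50, 50.0001)
  status <- classify_status(rec, concentrate_definition("scopaff"))
  expect_identical(status, c("concentrate", "dilution", "concentrate"))
})

test_that("both definitions jointly realise all eight category cells", {
  cats <- c("EC", "CS", "SC", "WG")
  grid <- expand.grid(code = cats, undiluted = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  rec <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    make_record(formulation_type = grid$code[i],
                is_undiluted_product = grid$undiluted[i],
                target_concentration = if (grid$undiluted[i]) 300 else 5,
                replicate_id = paste0("r", i))
  }))
  for (mode in c("commercial", "scopaff")) {
    key <- paste(categorize_formulation(rec$formulation_type),
                 classify_status(rec, concentrate_definition(mode)))
    expect_length(unique(key), 8L)
  }
})

test_that("reclassification counts equal the definition disagreements", {
  rec <- make_records(10)
  rec$target_concentration <- c(300, 300, 60, 5, 5, 40, 700, 55, 2, 45)
  rec$is_undiluted_product <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE,
                                TRUE, FALSE, FALSE, TRUE)
  counts <- reclassification_counts(rec)
  # commercial-dilutions above the cut-off and commercial-concentrates at
  # or below it are exactly the records whose cell changes
  expect_identical(counts$dilution_to_concentrate, 2L)  # rows 3, 8
  expect_identical(counts$concentrate_to_dilution, 2L)  # rows 6, 10
  expect_identical(counts$total, 4L)
  commercial <- classify_status(rec, concentrate_definition())
  scopaff <- classify_status(rec, concentrate_definition("scopaff"))
  expect_identical(counts$total, sum(commercial != scopaff))
})

test_that("plausibility checks flag dose inconsistencies but never drop records", {
  rec <- make_records(3)
  rec$skin_area_cm2 <- c(1, 2, NA)
  rec$area_dose_ug_cm2 <- c(1160, 10, 50)
  rec$total_dose_ug <- c(1160, 30, 100)
  flags <- validate_plausibility(rec)
  expect_identical(flags$flag[flags$replicate_id == "r2"],
                   "dose_inconsistency")
  expect_false("r1" %in% flags$replicate_id)  # 1160 = 1160 x 1
  expect_false("r3" %in% flags$replicate_id)  # missing field: skipped
})

test_that("plausibility checks flag implausible concentration/status pairs", {
  rec <- make_records(2)
  rec$is_undiluted_product <- c(TRUE, FALSE)
  rec$target_concentration <- c(0.01, 900)
  flags <- validate_plausibility(rec)
  expect_setequal(flags$flag, c("concentrate_low_concentration",
                                "dilution_high_concentration"))
  # nothing checkable -> empty flag table
  clean <- make_records(2)
  clean$target_concentration <- c(300, 200)
  expect_identical(nrow(validate_plausibility(clean)), 0L)
})

test_that("record validation enforces fraction bounds and strip contiguity", {
  rec <- make_records(2)
  expect_silent(validate_records(rec))
  bad <- rec
  bad$receptor_fluid_fraction[1] <- 1.2
  expect_error(validate_records(bad), "receptor_fluid_fraction")
  gap <- rec[setdiff(names(rec), "tape_strip_2")]
  expect_error(validate_records(gap), "contiguous")
})

test_that("record CSV round trip preserves values", {
  rec <- make_records(4)
  rec$target_concentration <- c(0.003, 2.5, 116, 960)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dermal_records(rec, path)
  back <- read_dermal_records(path)
  expect_equal(back$target_concentration, rec$target_concentration)
  expect_identical(back$is_undiluted_product, rec$is_undiluted_product)
  expect_equal(back$tape_strip_3, rec$tape_strip_3)
})
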