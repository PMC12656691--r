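# Record schema, formulation categorisation, concentrate/dilution
# classification, and plausibility checks.

#' Formulation type categories
#'
#' Mapping from the 20 supported product formulation type codes to the four
#' formulation type categories used in default-value derivation. Codes follow
#' the international coding system for agrochemical formulations (EC =
#' emulsifiable concentrate, SC = suspension concentrate, WG = water
#' dispersible granule, ...).
#'
#' @return Named character vector: names are formulation codes, values are
#'   categories (`"organic_solvent"`, `"water_based"`, `"solid"`, `"other"`).
#' @export
#' @examples
#' formulation_categories()[["EC"]]
formulation_categories <- function() {
  c(
    EC = "organic_solvent", EW = "organic_solvent", DC = "organic_solvent",
    ME = "organic_solvent", OD = "organic_solvent", OL = "organic_solvent",
    SE = "organic_solvent",
    GD = "other", CS = "other", ZC = "other",
    FS = "water_based", SC = "water_based", SD = "water_based",
    SL = "water_based",
    AP = "solid", DP = "solid", GR = "solid", SG = "solid", WG = "solid",
    WP = "solid"
  )
}

#' All eight category cells
#'
#' The cross of the four formulation type categories with the two
#' concentration statuses, in the fixed order used by report tables.
#'
#' @return Data frame with columns `formulation_category` and `status`
#'   (8 rows).
#' @export
category_cells <- function() {
  cells <- expand.grid(
    status = c("concentrate", "dilution"),
    formulation_category = c(
      "organic_solvent", "other", "water_based", "solid"
    ),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  cells[, c("formulation_category", "status")]
}

#' Categorise a formulation type code
#'
#' @param formulation_type Character vector of formulation type codes
#'   (e.g. `"EC"`, `"SC"`, `"WG"`).
#' @return Character vector of formulation categories.
#' @export
#' @examples
#' categorize_formulation(c("EC", "WP", "CS"))
categorize_formulation <- function(formulation_type) {
  map <- formulation_categories()
  unknown <- setdiff(unique(formulation_type), names(map))
  if (length(unknown) > 0L) {
    stop(
      "unknown formulation type code(s): ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  unname(map[formulation_type])
}

#' Concentrate definition
#'
#' Constructs the rule that decides whether a tested product concentration is
#' a concentrate or a dilution. Under the `"commercial"` definition the
#' undiluted commercial product is the concentrate (taken from the
#' `is_undiluted_product` flag of each record). Under the `"scopaff"`
#' definition, concentrates are target concentrations strictly above the
#' cut-off of 50 g/L (g/kg for solids); 50 g/L itself is a dilution.
#'
#' @param mode `"commercial"` or `"scopaff"`.
#' @param cutoff Cut-off in g/L, used only in `"scopaff"` mode. Default 50.
#' @return Object of class `concentrate_definition`.
#' @export
concentrate_definition <- function(mode = c("commercial", "scopaff"),
                                   cutoff = 50) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  structure(list(mode = mode, cutoff = cutoff),
            class = "concentrate_definition")
}

#' @exportS3Method base::print
print.concentrate_definition <- function(x, ...) {
  if (x$mode == "commercial") {
    cat("Concentrate definition: commercially undiluted product\n")
  } else {
    cat(sprintf(
      "Concentrate definition: target concentration > %g g/L (g/kg)\n",
      x$cutoff
    ))
  }
  invisible(x)
}

#' Classify records as concentrate or dilution
#'
#' @param records Data frame of absorption records (see
#'   [read_dermal_records()]); needs `target_concentration` and, in
#'   commercial mode, `is_undiluted_product`.
#' @param definition A [concentrate_definition()].
#' @return Character vector (`"concentrate"`/`"dilution"`), one per row.
#' @export
classify_status <- function(records,
                            definition = concentrate_definition()) {
  stopifnot(inherits(definition, "concentrate_definition"))
  conc <- records$target_concentration
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("target_concentration must be positive and finite", call. = FALSE)
  }
  if (definition$mode == "commercial") {
    flag <- records$is_undiluted_product
    if (is.null(flag) || anyNA(flag)) {
      stop(
        "is_undiluted_product flag required for the commercial definition",
        call. = FALSE
      )
    }
    ifelse(as.logical(flag), "concentrate", "dilution")
  } else {
    # strict inequality: exactly the cut-off is a dilution
    ifelse(conc > definition$cutoff, "concentrate", "dilution")
  }
}

#' Count records reclassified between concentrate definitions
#'
#' @param records Data frame of absorption records.
#' @param cutoff SCoPAFF cut-off in g/L.
#' @return List with `dilution_to_concentrate`, `concentrate_to_dilution`
#'   and `total` counts.
#' @export
reclassification_counts <- function(records, cutoff = 50) {
  commercial <- classify_status(records, concentrate_definition("commercial"))
  scopaff <- classify_status(
    records, concentrate_definition("scopaff", cutoff)
  )
  list(
    dilution_to_concentrate = sum(
      commercial == "dilution" & scopaff == "concentrate"
    ),
    concentrate_to_dilution = sum(
      commercial == "concentrate" & scopaff == "dilution"
    ),
    total = sum(commercial != scopaff)
  )
}

#' Validate the structural invariants of absorption records
#'
#' Checks the record table for the invariants the downstream stages rely on:
#' compartment fractions in \[0, 1\], positive target concentrations and
#' exposure durations, contiguous tape-strip columns starting at strip 1.
#'
#' @param records Data frame of absorption records.
#' @return The records, invisibly; stops with an informative message on the
#'   first violated invariant.
#' @export
validate_records <- function(records) {
  required <- c(
    "study_id", "substance", "formulation_type", "target_concentration",
    "exposure_hours", "replicate_id", "receptor_fluid_fraction",
    "chamber_wash_fraction", "skin_fraction", "mean_recovery_percent"
  )
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  frac_cols <- c(
    "receptor_fluid_fraction", "chamber_wash_fraction", "skin_fraction",
    tape_strip_columns(records)
  )
  for (col in frac_cols) {
    v <- records[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) {
      stop(sprintf("column %s outside [0, 1] in %d row(s)", col, sum(bad)),
           call. = FALSE)
    }
  }
  if (any(records$target_concentration <= 0, na.rm = TRUE)) {
    stop("target_concentration must be > 0", call. = FALSE)
  }
  if (any(records$exposure_hours <= 0, na.rm = TRUE)) {
    stop("exposure_hours must be > 0", call. = FALSE)
  }
  strips <- tape_strip_columns(records)
  if (length(strips) > 0L) {
    idx <- sort(as.integer(sub("^tape_strip_", "", strips)))
    if (!identical(idx, seq_along(idx))) {
      stop("tape_strip_* columns must be contiguous starting at 1",
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Tape-strip column names of a record table
#'
#' @param records Data frame of absorption records.
#' @return Character vector `tape_strip_1`, `tape_strip_2`, ... in strip
#'   order (outermost first); empty if the table has no strip columns.
#' @export
tape_strip_columns <- function(records) {
  cols <- grep("^tape_strip_[0-9]+$", names(records), value = TRUE)
  cols[order(as.integer(sub("^tape_strip_", "", cols)))]
}

#' Plausibility checks on dose bookkeeping
#'
#' Advisory consistency checks mirroring manual data curation: whether the
#' recorded total dose agrees with area dose times exposed skin area, and
#' whether concentrates/dilutions carry implausible target concentrations.
#' Flags are advisory; no record is ever dropped here.
#'
#' @param records Data frame of absorption records. The optional columns
#'   `skin_area_cm2`, `area_dose_ug_cm2`, `total_dose_ug` enable the dose
#'   consistency check; rows lacking them are skipped.
#' @param definition A [concentrate_definition()] used to interpret the
#'   concentration-range flags.
#' @param rel_tol Relative tolerance for the dose consistency check.
#' @param low_concentrate g/L below which a concentrate is flagged as
#'   implausibly dilute.
#' @param high_dilution g/L above which a dilution is flagged as implausibly
#'   concentrated.
#' @return Data frame with columns `row`, `replicate_id`, `flag`,
#'   `detail`; zero rows when nothing is flagged.
#' @export
validate_plausibility <- function(records,
                                  definition = concentrate_definition(),
                                  rel_tol = 0.05,
                                  low_concentrate = 1,
                                  high_dilution = 500) {
  flags <- list()
  add <- function(row, flag, detail) {
    flags[[length(flags) + 1L]] <<- data.frame(
      row = row,
      replicate_id = as.character(records$replicate_id[row]),
      flag = flag, detail = detail, stringsAsFactors = FALSE
    )
  }
  dose_cols <- c("skin_area_cm2", "area_dose_ug_cm2", "total_dose_ug")
  if (all(dose_cols %in% names(records))) {
    for (i in seq_len(nrow(records))) {
      a <- records$area_dose_ug_cm2[i]
      s <- records$skin_area_cm2[i]
      tot <- records$total_dose_ug[i]
      if (anyNA(c(a, s, tot))) next
      expected <- a * s
      if (abs(tot - expected) > rel_tol * max(abs(expected), abs(tot))) {
        add(i, "dose_inconsistency", sprintf(
          "total_dose %g != area_dose %g x skin_area %g", tot, a, s
        ))
      }
    }
  }
  status <- tryCatch(classify_status(records, definition),
                     error = function(e) NULL)
  if (!is.null(status)) {
    conc <- records$target_concentration
    low <- which(status == "concentrate" & conc < low_concentrate)
    for (i in low) {
      add(i, "concentrate_low_concentration",
          sprintf("concentrate at %g g/L", conc[i]))
    }
    high <- which(status == "dilution" & conc > high_dilution)
    for (i in high) {
      add(i, "dilution_high_concentration",
          sprintf("dilution at %g g/L", conc[i]))
    }
  }
  if (length(flags) == 0L) {
    return(data.frame(
      row = integer(), replicate_id = character(), flag = character(),
      detail = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Read absorption records from CSV
#'
#' Reads the flat per-replicate CSV dialect used throughout the package:
#' one row per experimental replicate, UTF-8, fractions as decimals in
#' \[0, 1\], concentrations in g/L (g/kg for solids), tape strips in columns
#' `tape_strip_1`, `tape_strip_2`, ... with strip 1 outermost.
#'
#' @param path Path to a CSV file.
#' @param validate Run [validate_records()] after reading (default `TRUE`).
#' @return Data frame of absorption records.
#' @export
read_dermal_records <- function(path, validate = TRUE) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  if ("is_undiluted_product" %in% names(records)) {
    records$is_undiluted_product <- as.logical(records$is_undiluted_product)
  }
  if (validate) validate_records(records)
  records
}

#' Write absorption records to CSV
#'
#' @param records Data frame of absorption records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dermal_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
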