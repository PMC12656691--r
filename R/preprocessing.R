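# Recovery filter, tape-strip rule, potential absorption, and the
# logit-scale modelling table.

#' Logit and inverse-logit transforms
#'
#' `logit(f) = log(f / (1 - f))`; `inv_logit` is its exact inverse.
#' Fractions of exactly 0 or 1 are rejected rather than epsilon-clipped:
#' observed potential-absorption fractions lie strictly inside (0, 1) and a
#' boundary value indicates a data error upstream.
#'
#' @param f Numeric vector of fractions in (0, 1).
#' @param y Numeric vector on the real line.
#' @return Numeric vector.
#' @export
#' @examples
#' logit(0.5)
#' inv_logit(logit(0.07))
logit <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1)) {
    stop("logit requires fractions strictly inside (0, 1)", call. = FALSE)
  }
  log(f / (1 - f))
}

#' @rdname logit
#' @export
inv_logit <- function(y) {
  stats::plogis(y)
}

#' Mass-balance recovery filter
#'
#' Removes whole experiments whose mean mass-balance recovery falls outside
#' the retention window \[90, 110\]% (strict: exactly 90 and exactly 110 are
#' retained). The mean recovery is an experiment-level quantity shared by all
#' replicates of a tested concentration within a study, so the filter acts on
#' every replicate carrying that mean. Records with a missing recovery are
#' excluded with a warning rather than silently kept.
#'
#' @param records Data frame of absorption records with
#'   `mean_recovery_percent`.
#' @param lower,upper Retention window in percent.
#' @return The retained records; attribute `"recovery_report"` carries counts
#'   of rows in/out and rows dropped for missing recovery.
#' @export
recovery_filter <- function(records, lower = 90, upper = 110) {
  rec <- records$mean_recovery_percent
  missing <- is.na(rec)
  if (any(missing)) {
    warning(sum(missing), " record(s) without mean recovery excluded",
            call. = FALSE)
  }
  keep <- !missing & rec >= lower & rec <= upper
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "recovery_report") <- list(
    n_in = nrow(records),
    n_retained = sum(keep),
    n_excluded_recovery = sum(!missing & (rec < lower | rec > upper)),
    n_excluded_low = sum(!missing & rec < lower),
    n_excluded_high = sum(!missing & rec > upper),
    n_missing_recovery = sum(missing)
  )
  out
}

#' Tape strips retained for absorption
#'
#' Decides which tape strips count towards potential absorption. If
#' absorption was essentially complete -- at least 75% of the material
#' absorbed on average after half the sampling duration -- all strips are
#' excluded (the substance left in the stratum corneum would largely have
#' desorbed, not absorbed). Otherwise only the two outermost strips are
#' excluded and strips 3 and deeper are retained.
#'
#' @param absorbed_at_half_duration_percent Experiment-level mean percent
#'   absorbed at half the sampling duration; may be `NA`.
#' @param n_strips Number of tape strips taken for the replicate.
#' @param threshold Completeness threshold in percent (default 75; equality
#'   counts as complete).
#' @param missing_policy What to do when the half-duration value is missing:
#'   `"incomplete"` (default, the conservative branch: keep strips 3+) or
#'   `"complete"` (exclude all strips).
#' @return Integer vector of retained strip indices (possibly empty).
#' @export
select_tape_strips <- function(absorbed_at_half_duration_percent,
                               n_strips,
                               threshold = 75,
                               missing_policy = c("incomplete", "complete")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(absorbed_at_half_duration_percent) == 1L,
            n_strips >= 0)
  half <- absorbed_at_half_duration_percent
  complete <- if (is.na(half)) {
    missing_policy == "complete"
  } else {
    half >= threshold
  }
  if (complete || n_strips <= 2L) {
    integer(0)
  } else {
    seq.int(3L, n_strips)
  }
}

#' Potential absorption of one replicate
#'
#' Sums the compartments counted as absorbable: receptor fluid, chamber
#' wash, whole skin (excluding tape strips), and the retained tape strips.
#' The result must lie strictly inside (0, 1); values at or beyond the
#' boundaries are rejected, naming the replicate, because a full or empty
#' mass balance in the absorbable compartments indicates a recording error.
#'
#' @param record One-row data frame (or list) with the compartment fraction
#'   fields and any `tape_strip_*` columns.
#' @param included_strips Integer vector of retained strip indices, normally
#'   from [select_tape_strips()].
#' @return Fraction absorbed in (0, 1).
#' @export
potential_absorption <- function(record, included_strips = integer(0)) {
  total <- record$receptor_fluid_fraction +
    record$chamber_wash_fraction +
    record$skin_fraction
  for (i in included_strips) {
    col <- paste0("tape_strip_", i)
    v <- record[[col]]
    if (is.null(v) || is.na(v)) {
      stop("retained tape strip ", i, " missing for replicate ",
           record$replicate_id, call. = FALSE)
    }
    total <- total + v
  }
  if (!is.finite(total) || total <= 0 || total >= 1) {
    stop(sprintf(
      "potential absorption %g outside (0, 1) for replicate %s",
      total, as.character(record$replicate_id)
    ), call. = FALSE)
  }
  total
}

#' Build the logit-scale modelling table
#'
#' Runs the full preprocessing chain: record validation, the mass-balance
#' recovery filter, the tape-strip rule, potential absorption per replicate,
#' concentrate/dilution classification and formulation categorisation, and
#' the logit transform. Rows are keyed by the within-study experiment group
#' (study x substance x formulation type x target concentration), the
#' grouping used as the innermost random effect of the mixed model.
#'
#' @param records Data frame of absorption records.
#' @param definition A [concentrate_definition()].
#' @param strip_threshold Completeness threshold for [select_tape_strips()].
#' @param missing_policy Missing-value policy for [select_tape_strips()].
#' @return Data frame of class `da_prepared` with columns `substance`,
#'   `study_id`, `formulation_type`, `target_concentration`,
#'   `formulation_category`, `status`, `group_id`, `fraction_absorbed`, `y`
#'   (= logit fraction). Attribute `"preprocessing_report"` records counts
#'   per rule.
#' @export
prepare_dataset <- function(records,
                            definition = concentrate_definition(),
                            strip_threshold = 75,
                            missing_policy = "incomplete") {
  validate_records(records)
  n_raw <- nrow(records)
  filtered <- recovery_filter(records)
  recovery_report <- attr(filtered, "recovery_report")
  if (nrow(filtered) == 0L) {
    stop("no records retained after the recovery filter", call. = FALSE)
  }
  # vectorised equivalent of select_tape_strips() + potential_absorption()
  strip_cols <- tape_strip_columns(filtered)
  half <- filtered$absorbed_at_half_duration_percent
  if (is.null(half)) half <- rep(NA_real_, nrow(filtered))
  complete <- ifelse(is.na(half), missing_policy == "complete",
                     half >= strip_threshold)
  base <- filtered$receptor_fluid_fraction +
    filtered$chamber_wash_fraction + filtered$skin_fraction
  retained_strip_mass <- 0
  if (length(strip_cols) > 2L) {
    deep <- as.matrix(filtered[strip_cols[-(1:2)]])
    retained_strip_mass <- ifelse(
      complete, 0, rowSums(deep, na.rm = TRUE)
    )
  }
  fractions <- base + retained_strip_mass
  bad <- !is.finite(fractions) | fractions <= 0 | fractions >= 1
  if (any(bad)) {
    stop("potential absorption outside (0, 1) for replicate(s): ",
         paste(utils::head(filtered$replicate_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  n_all_strips_excluded <- if (length(strip_cols) > 0L) {
    sum(complete)
  } else 0L
  status <- classify_status(filtered, definition)
  category <- categorize_formulation(filtered$formulation_type)
  group_id <- paste(
    filtered$study_id, filtered$substance, filtered$formulation_type,
    sprintf("%.15g", filtered$target_concentration),
    sep = "|"
  )
  out <- data.frame(
    substance = as.character(filtered$substance),
    study_id = as.character(filtered$study_id),
    formulation_type = filtered$formulation_type,
    target_concentration = filtered$target_concentration,
    formulation_category = category,
    status = status,
    group_id = group_id,
    fraction_absorbed = fractions,
    y = logit(fractions),
    stringsAsFactors = FALSE
  )
  attr(out, "preprocessing_report") <- list(
    n_records_in = n_raw,
    n_retained = nrow(out),
    recovery = recovery_report,
    n_replicates_all_strips_excluded = n_all_strips_excluded,
    definition_mode = definition$mode,
    n_substances = length(unique(out$substance)),
    n_studies = length(unique(out$study_id)),
    n_groups = length(unique(out$group_id))
  )
  class(out) <- c("da_prepared", "data.frame")
  out
}

#' Write a prepared dataset with its preprocessing report
#'
#' @param prepared A `da_prepared` table from [prepare_dataset()].
#' @param path CSV output path; the JSON report is written next to it with
#'   suffix `_report.json`.
#' @return `path`, invisibly.
#' @export
write_prepared_dataset <- function(prepared, path) {
  utils::write.csv(as.data.frame(prepared), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  report <- attr(prepared, "preprocessing_report")
  if (!is.null(report)) {
    jsonlite::write_json(
      report, sub("\\.csv$", "_report.json", path),
      auto_unbox = TRUE, pretty = TRUE
    )
  }
  invisible(path)
}
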