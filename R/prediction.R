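# Posterior predictions and upper limits of 90% prediction intervals at
# three levels of random-effect variation.

#' z-score for the upper limit of a two-sided 90% prediction interval
#'
#' The upper limit of a two-sided 90% interval is the 95% quantile, so the
#' multiplier is the standard-normal 95% quantile, kept at full double
#' precision (never the rounded 1.645).
#'
#' @return Scalar, `qnorm(0.95)`.
#' @export
pi_z_score <- function() stats::qnorm(0.95)

#' The three prediction-interval variance levels
#'
#' @return Character vector naming the nested variance levels, in
#'   increasing order: between-substance only; plus between-study; plus
#'   within-study.
#' @export
variance_levels <- function() {
  c("substance", "substance_study", "substance_study_within")
}

cell_linear_predictor <- function(draws, status, category) {
  status <- match.arg(status, c("dilution", "concentrate"))
  category <- match.arg(
    category, c("organic_solvent", "other", "solid", "water_based")
  )
  lp <- draws$alpha
  if (status == "concentrate") lp <- lp + draws$beta_concentrate
  if (category != "organic_solvent") {
    lp <- lp + draws[[paste0("beta_", category)]]
  }
  lp
}

#' Posterior draws of mean percent absorbed for a cell
#'
#' Inverse-logit of the cell's linear predictor, per posterior draw, in
#' percent. Predictions for a concentration status keep the formulation
#' category at its reference (organic solvent); predictions for a category
#' keep the status at its reference (dilution). Passing both non-reference
#' levels gives the corresponding interaction-free cell mean.
#'
#' @param posterior A `da_posterior` object (a single pseudo-draw built
#'   with [posterior_from_means()] works too).
#' @param status `"dilution"` or `"concentrate"`.
#' @param category Formulation category.
#' @return Numeric vector of draws, percent absorbed in (0, 100).
#' @export
mean_prediction <- function(posterior, status = "dilution",
                            category = "organic_solvent") {
  stopifnot(inherits(posterior, "da_posterior"))
  100 * inv_logit(cell_linear_predictor(posterior$draws, status, category))
}

#' Posterior draws of the upper 90% prediction-interval limit for a cell
#'
#' Per draw, adds `z * sqrt(V)` to the cell's linear predictor and back-
#' transforms to percent, where `z` is the 95% standard-normal quantile and
#' `V` is the total random-effect variance at the requested level: the
#' status-specific between-substance variance (dilution or concentrate
#' column of the substance covariance), optionally plus the between-study
#' variance, optionally plus the within-study variance. The residual
#' variance is never part of `V`: the interval describes mean absorption of
#' new substances/studies/concentrations, not single replicates.
#'
#' @inheritParams mean_prediction
#' @param level One of [variance_levels()].
#' @return Numeric vector of draws, percent in (0, 100).
#' @export
pi_upper <- function(posterior, status = "dilution",
                     category = "organic_solvent",
                     level = "substance_study_within") {
  stopifnot(inherits(posterior, "da_posterior"))
  level <- match.arg(level, variance_levels())
  status <- match.arg(status, c("dilution", "concentrate"))
  draws <- posterior$draws
  V <- if (status == "dilution") {
    draws$var_substance_dilution
  } else {
    draws$var_substance_concentrate
  }
  if (level %in% c("substance_study", "substance_study_within")) {
    V <- V + draws$var_study
  }
  if (level == "substance_study_within") {
    V <- V + draws$var_within
  }
  if (anyNA(V)) {
    stop("posterior lacks the random-effect variances needed for level ",
         level, call. = FALSE)
  }
  if (any(V < 0)) {
    stop("negative total variance draw encountered", call. = FALSE)
  }
  lp <- cell_linear_predictor(draws, status, category)
  100 * inv_logit(lp + pi_z_score() * sqrt(V))
}

#' Summarise prediction draws
#'
#' Median, 95th percentile and 95% highest-density interval of a vector of
#' posterior prediction draws. The 95th percentile of the posterior is the
#' most conservative summary used for default values. With fewer than 20
#' draws the HPDI is replaced by the range.
#'
#' @param draws Numeric vector of prediction draws (percent).
#' @param quantile_type Quantile convention for the 95th percentile.
#' @return List with `median`, `p95`, `hpdi`, `n_draws`.
#' @export
summarize_prediction <- function(draws, quantile_type = 7) {
  if (length(draws) == 0L) {
    stop("no prediction draws to summarise", call. = FALSE)
  }
  hp <- if (length(draws) >= 20L) hpdi(draws) else range(draws)
  list(
    median = unname(stats::median(draws)),
    p95 = unname(stats::quantile(draws, 0.95, type = quantile_type)),
    hpdi = hp,
    n_draws = length(draws)
  )
}

#' Model-derived default-value table
#'
#' Upper 90% prediction-interval limits for every formulation-category by
#' status cell at each of the three variance levels, summarised by the
#' posterior median and 95th percentile (plus the 95% HPDI bounds). Values
#' are full precision; report-style rounding to integer percent is left to
#' the caller or to [run_pipeline()].
#'
#' @param posterior A `da_posterior` object.
#' @param quantile_type Quantile convention for the 95th percentile.
#' @return Data frame, 8 cells x 3 levels rows.
#' @export
prediction_table <- function(posterior, quantile_type = 7) {
  cells <- category_cells()
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    for (level in variance_levels()) {
      draws <- pi_upper(posterior, status = cells$status[i],
                        category = cells$formulation_category[i],
                        level = level)
      s <- summarize_prediction(draws, quantile_type = quantile_type)
      rows[[length(rows) + 1L]] <- data.frame(
        formulation_category = cells$formulation_category[i],
        status = cells$status[i],
        variance_level = level,
        posterior_median = s$median,
        posterior_p95 = s$p95,
        hpdi_lower = s$hpdi[1],
        hpdi_upper = s$hpdi[2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare default values between concentrate definitions
#'
#' Per cell and variance level, the difference of the rounded default
#' values (alternative minus commercial) for both the posterior median and
#' the 95th percentile summaries.
#'
#' @param pred_commercial,pred_alternative Prediction tables from
#'   [prediction_table()] computed under the two concentrate definitions;
#'   must cover identical cells and levels.
#' @param digits Rounding applied before differencing (default 0: integer
#'   percent, as in report tables).
#' @return Data frame with the cell key, both rounded summaries under each
#'   definition, and `diff_median` / `diff_p95`.
#' @export
compare_definitions <- function(pred_commercial, pred_alternative,
                                digits = 0) {
  key <- c("formulation_category", "status", "variance_level")
  a <- pred_commercial[do.call(order, pred_commercial[key]), ]
  b <- pred_alternative[do.call(order, pred_alternative[key]), ]
  same <- nrow(a) == nrow(b) &&
    all(vapply(key, function(k) all(a[[k]] == b[[k]]), logical(1)))
  if (!same) {
    stop("prediction tables cover different cells or variance levels",
         call. = FALSE)
  }
  out <- a[key]
  out$median_commercial <- round(a$posterior_median, digits)
  out$median_alternative <- round(b$posterior_median, digits)
  out$p95_commercial <- round(a$posterior_p95, digits)
  out$p95_alternative <- round(b$posterior_p95, digits)
  out$diff_median <- out$median_alternative - out$median_commercial
  out$diff_p95 <- out$p95_alternative - out$p95_commercial
  rownames(out) <- NULL
  out
}

#' Reference posterior means for plug-in reconstruction
#'
#' The posterior-mean parameter set from the published mixed-model analysis
#' of the harmonised 2024 regulatory dermal-absorption dataset (155
#' substances, 356 studies, 6340 replicates). Used to reconstruct the
#' reported default values by plug-in evaluation without refitting, and as
#' the default ground truth of the synthetic-data generator.
#'
#' @return Named list: fixed effects (`alpha`, `beta_concentrate`,
#'   `beta_other`, `beta_solid`, `beta_water_based`), variance components
#'   (`var_substance_dilution`, `var_substance_concentrate`, `var_study`,
#'   `var_within`) and the substance-effect correlation `rho`.
#' @export
reference_posterior_means <- function() {
  list(
    alpha = -2.34,
    beta_concentrate = -2.37,
    beta_other = -0.24,
    beta_solid = -0.94,
    beta_water_based = -0.67,
    var_substance_dilution = 0.64,
    var_substance_concentrate = 0.52,
    var_study = 0.67,
    var_within = 0.59,
    rho = 0.20
  )
}

#' Build a degenerate posterior from point parameter values
#'
#' Wraps a single parameter set (e.g. published posterior means) as a
#' one-draw `da_posterior` so that [mean_prediction()] and [pi_upper()]
#' can be evaluated as plug-in formulas.
#'
#' @param means Named list or vector with the parameters of
#'   [reference_posterior_means()]; `var_resid` optional.
#' @return A `da_posterior` with a single draw.
#' @export
posterior_from_means <- function(means = reference_posterior_means()) {
  means <- as.list(means)
  required <- c(
    FIXED_EFFECT_NAMES,
    "var_substance_dilution", "var_substance_concentrate",
    "var_study", "var_within", "rho"
  )
  missing <- setdiff(required, names(means))
  if (length(missing) > 0L) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cov_sub <- means$rho *
    sqrt(means$var_substance_dilution * means$var_substance_concentrate)
  draws <- data.frame(
    alpha = means$alpha,
    beta_concentrate = means$beta_concentrate,
    beta_other = means$beta_other,
    beta_solid = means$beta_solid,
    beta_water_based = means$beta_water_based,
    var_substance_dilution = means$var_substance_dilution,
    var_substance_concentrate = means$var_substance_concentrate,
    cov_substance = cov_sub,
    rho = means$rho,
    var_study = means$var_study,
    var_within = means$var_within,
    var_resid = if (is.null(means$var_resid)) NA_real_ else means$var_resid
  )
  structure(
    list(
      draws = draws,
      ess = stats::setNames(rep(1, ncol(draws)), names(draws)),
      settings = list(iterations = 1, burnin = 0, thin = 1, seed = NA,
                      n_retained = 1, include = c("substance", "study",
                                                  "group")),
      substances = character(0), studies = character(0),
      groups = character(0), n_obs = 0L
    ),
    class = "da_posterior"
  )
}
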