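# Hierarchical synthetic-data generator with known ground truth, at logit
# scale (for model testing) and raw-record scale (for preprocessing
# testing).

#' Ground truth for the synthetic-data generator
#'
#' Defines the parameter set and design shape of a simulated absorption
#' dataset: the mixed-model parameters (defaults: the reference posterior
#' means, with a residual variance of 0.25 on the logit scale), the number
#' of substances, and the Poisson-shifted count distributions for studies
#' per substance, concentration groups per study and replicates per group.
#' The default scale mirrors the source dataset (155 substances, about 356
#' studies and 6300 replicates). Category weights over the eight
#' formulation-category by status cells default to the observed replicate
#' shares of that dataset.
#'
#' @param params Named list of model parameters as in
#'   [reference_posterior_means()]; `var_resid` is added if absent.
#' @param var_resid Residual variance on the logit scale.
#' @param n_substances Number of substances.
#' @param studies_per_substance_mean,groups_per_study_mean Means of the
#'   Poisson part of `1 + rpois(.)` counts.
#' @param replicates_min,replicates_mean Replicates per group are
#'   `replicates_min + rpois(replicates_mean - replicates_min)`.
#' @param cell_weights Numeric vector of 8 non-negative weights over the
#'   rows of [category_cells()]; normalised internally.
#' @param concentration_range Range (g/L) of the log-uniform target
#'   concentrations, straddling the 50 g/L cut-off.
#' @return Object of class `da_truth`.
#' @export
synthetic_truth <- function(params = reference_posterior_means(),
                            var_resid = 0.25,
                            n_substances = 155,
                            studies_per_substance_mean = 1.3,
                            groups_per_study_mean = 1.5,
                            replicates_min = 3,
                            replicates_mean = 7,
                            cell_weights = NULL,
                            concentration_range = c(0.003, 960)) {
  params <- as.list(params)
  if (is.null(params$var_resid)) params$var_resid <- var_resid
  G <- matrix(c(
    params$var_substance_dilution,
    params$rho * sqrt(params$var_substance_dilution *
                        params$var_substance_concentrate),
    params$rho * sqrt(params$var_substance_dilution *
                        params$var_substance_concentrate),
    params$var_substance_concentrate
  ), 2, 2)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("substance covariance implied by the truth is not positive ",
         "definite", call. = FALSE)
  }
  if (is.null(cell_weights)) {
    # replicate shares of the eight cells in the source dataset overview
    cell_weights <- c(847, 1490, 83, 103, 1268, 1771, 351, 427)
  }
  stopifnot(length(cell_weights) == 8L, all(cell_weights >= 0),
            sum(cell_weights) > 0)
  stopifnot(n_substances >= 1, replicates_min >= 1,
            concentration_range[1] > 0,
            concentration_range[2] > concentration_range[1])
  structure(
    list(
      params = params, G = G,
      n_substances = n_substances,
      studies_per_substance_mean = studies_per_substance_mean,
      groups_per_study_mean = groups_per_study_mean,
      replicates_min = replicates_min,
      replicates_mean = replicates_mean,
      cell_weights = cell_weights / sum(cell_weights),
      concentration_range = concentration_range
    ),
    class = "da_truth"
  )
}

#' @exportS3Method base::print
print.da_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic ground truth: %d substances, ~%.0f studies expected\n",
    x$n_substances,
    x$n_substances * (1 + x$studies_per_substance_mean)
  ))
  cat("model parameters:\n")
  print(unlist(x$params), digits = 3)
  invisible(x)
}

category_codes <- c(
  organic_solvent = "EC", other = "CS", water_based = "SC", solid = "WG"
)

#' Generate a logit-scale dataset from known ground truth
#'
#' Draws the full hierarchy the mixed model assumes: one substance-effect
#' pair per substance from the bivariate normal with the truth covariance,
#' one intercept per study and per within-study concentration group from
#' their variances, and i.i.d. residuals per replicate. Each study is
#' assigned a formulation category by largest-remainder allocation over the
#' marginal cell weights (every category populated, substances with several
#' studies may span categories); each group is a concentrate with the
#' category-conditional probability implied by the cell weights, and
#' carries a log-uniform target concentration drawn from a
#' status-dependent sub-range so that both concentrate definitions
#' disagree on some groups.
#'
#' @param truth A `da_truth` object.
#' @param seed Integer seed; identical truth and seed give identical data.
#' @return List with `data` (a `da_prepared`-shaped table) and `effects`
#'   (the ground-truth draws: `substance` as an n x 2 matrix with columns
#'   dilution/concentrate, `study`, `group`).
#' @export
generate_logit_dataset <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "da_truth"))
  set.seed(as.integer(seed))
  p <- truth$params
  cells <- category_cells()
  categories <- unique(cells$formulation_category)
  w8 <- truth$cell_weights
  cat_weight <- vapply(categories, function(cat) {
    sum(w8[cells$formulation_category == cat])
  }, numeric(1))
  conc_prob <- vapply(categories, function(cat) {
    i_c <- which(cells$formulation_category == cat &
                   cells$status == "concentrate")
    i_all <- which(cells$formulation_category == cat)
    if (sum(w8[i_all]) == 0) 0.5 else w8[i_c] / sum(w8[i_all])
  }, numeric(1))

  L <- chol(truth$G)
  n_sub <- truth$n_substances
  sub_eff <- matrix(stats::rnorm(2L * n_sub), ncol = 2) %*% L
  colnames(sub_eff) <- c("dilution", "concentrate")
  # study counts first, so categories can be allocated over all studies by
  # largest remainder (at least one study per category): every cell of the
  # analysis design is populated, and substances with several studies can
  # span formulation categories, as in the real dataset
  n_studies_per_sub <- 1L +
    stats::rpois(n_sub, truth$studies_per_substance_mean)
  n_studies_total <- sum(n_studies_per_sub)
  target <- cat_weight / sum(cat_weight) * n_studies_total
  counts <- pmax(1L, floor(target))
  while (sum(counts) < n_studies_total) {
    i <- which.max(target - counts)
    counts[i] <- counts[i] + 1L
  }
  while (sum(counts) > n_studies_total) {
    over <- which(counts > 1L)
    i <- over[which.min((target - counts)[over])]
    counts[i] <- counts[i] - 1L
  }
  study_cat <- sample(rep(categories, counts))

  beta <- c(
    other = p$beta_other, solid = p$beta_solid,
    water_based = p$beta_water_based, organic_solvent = 0
  )
  lcr <- log(truth$concentration_range)
  # dilutions draw from the lower part of the range, concentrates from the
  # upper part; the sub-ranges overlap around the 50 g/L cut-off
  conc_draw <- function(status) {
    if (status == "concentrate") {
      exp(stats::runif(1, log(10), lcr[2]))
    } else {
      exp(stats::runif(1, lcr[1], log(100)))
    }
  }

  rows <- vector("list", 4L * n_sub)
  study_eff <- numeric(0)
  group_eff <- numeric(0)
  study_counter <- 0L
  nrows <- 0L
  for (s in seq_len(n_sub)) {
    for (st in seq_len(n_studies_per_sub[s])) {
      study_counter <- study_counter + 1L
      cat_s <- study_cat[study_counter]
      study_id <- sprintf("ST%04d", study_counter)
      v <- stats::rnorm(1, 0, sqrt(p$var_study))
      study_eff[study_id] <- v
      n_groups <- 1L + stats::rpois(1, truth$groups_per_study_mean)
      for (g in seq_len(n_groups)) {
        status <- if (stats::runif(1) < conc_prob[cat_s]) {
          "concentrate"
        } else "dilution"
        conc <- conc_draw(status)
        w <- stats::rnorm(1, 0, sqrt(p$var_within))
        n_rep <- truth$replicates_min +
          stats::rpois(1, truth$replicates_mean - truth$replicates_min)
        lp <- p$alpha +
          (status == "concentrate") * p$beta_concentrate +
          beta[[cat_s]] + sub_eff[s, status] + v + w
        y <- lp + stats::rnorm(n_rep, 0, sqrt(p$var_resid))
        group_id <- paste(study_id, sprintf("SUB%03d", s),
                          category_codes[[cat_s]],
                          sprintf("%.15g", conc),
                          sep = "|")
        group_eff[group_id] <- w
        nrows <- nrows + 1L
        rows[[nrows]] <- data.frame(
          substance = sprintf("SUB%03d", s),
          study_id = study_id,
          formulation_type = category_codes[[cat_s]],
          target_concentration = conc,
          formulation_category = cat_s,
          status = status,
          group_id = group_id,
          fraction_absorbed = inv_logit(y),
          y = y,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  data <- do.call(rbind, rows[seq_len(nrows)])
  rownames(data) <- NULL
  class(data) <- c("da_prepared", "data.frame")
  list(
    data = data,
    effects = list(
      substance = sub_eff,
      study_category = study_cat,
      study = study_eff,
      group = group_eff
    )
  )
}

#' Generate raw per-replicate records exercising the preprocessing rules
#'
#' Builds a raw-record table whose preprocessing reproduces a known
#' logit-scale dataset exactly. Each replicate's generated absorption
#' fraction is decomposed into receptor fluid, chamber wash, skin and tape
#' strips so that summing the compartments retained under the applicable
#' tape-strip branch recovers the fraction; strips that the rule excludes
#' carry extra mass that must not leak into the result. A configurable
#' share of experiments is planted with out-of-window mass-balance recovery
#' and is expected to be removed by the recovery filter.
#'
#' @param truth A `da_truth` object.
#' @param seed Integer seed.
#' @param frac_low_recovery,frac_high_recovery Shares of experiments
#'   planted below / above the retention window (recoveries 85% and 115%).
#' @param frac_complete Share of experiments planted on the
#'   absorption-essentially-complete branch (half-duration absorption 80%,
#'   all strips excluded); the rest are planted at 50% (strips 3+ kept).
#' @param n_strips Tape strips per replicate.
#' @param excluded_strip_mass Fraction planted on each excluded strip.
#' @return List with `records` (raw table for [prepare_dataset()]),
#'   `planted` (per-replicate truth: fraction, recovery retention flag,
#'   branch), and `generated` (the underlying logit-scale dataset and
#'   effects).
#' @export
generate_raw_records <- function(truth, seed = 1,
                                 frac_low_recovery = 0.05,
                                 frac_high_recovery = 0.05,
                                 frac_complete = 0.3,
                                 n_strips = 5,
                                 excluded_strip_mass = 0.003) {
  stopifnot(frac_low_recovery + frac_high_recovery < 1,
            frac_complete >= 0, frac_complete <= 1, n_strips >= 2)
  generated <- generate_logit_dataset(truth, seed = seed)
  data <- generated$data
  # experiment-level plants (experiment == within-study group)
  groups <- unique(data$group_id)
  n_g <- length(groups)
  u <- stats::runif(n_g)
  recovery <- ifelse(
    u < frac_low_recovery, 85,
    ifelse(u < frac_low_recovery + frac_high_recovery, 115,
           round(stats::runif(n_g, 92, 108), 1))
  )
  complete <- stats::runif(n_g) < frac_complete
  half_duration <- ifelse(complete, 80, 50)
  names(recovery) <- names(half_duration) <- groups
  complete <- stats::setNames(complete, groups)

  n <- nrow(data)
  f <- data$fraction_absorbed
  if (any(f >= 1)) {
    stop("generated fraction >= 1 cannot be decomposed", call. = FALSE)
  }
  g_of_row <- data$group_id
  row_complete <- complete[g_of_row]
  receptor <- ifelse(row_complete, 0.60 * f, 0.55 * f)
  wash <- 0.10 * f
  skin <- ifelse(row_complete, 0.30 * f, 0.25 * f)
  strip_cols <- matrix(0, nrow = n, ncol = n_strips,
                       dimnames = list(NULL, paste0("tape_strip_",
                                                    seq_len(n_strips))))
  # excluded mass on strips 1 and 2 always; on 3+ only when all strips are
  # excluded anyway
  strip_cols[, 1:2] <- excluded_strip_mass
  n_kept_strips <- n_strips - 2L
  for (j in 3:n_strips) {
    strip_cols[, j] <- ifelse(row_complete, excluded_strip_mass,
                              (0.10 * f) / n_kept_strips)
  }
  records <- data.frame(
    study_id = data$study_id,
    substance = data$substance,
    formulation_type = data$formulation_type,
    target_concentration = data$target_concentration,
    is_undiluted_product = data$status == "concentrate",
    exposure_hours = ifelse(
      as.integer(factor(data$study_id)) %% 3L == 0L, 6, 8
    ),
    replicate_id = sprintf("R%05d", seq_len(n)),
    receptor_fluid_fraction = receptor,
    chamber_wash_fraction = wash,
    skin_fraction = skin,
    mean_recovery_percent = unname(recovery[g_of_row]),
    absorbed_at_half_duration_percent = unname(half_duration[g_of_row]),
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(strip_cols))
  planted <- data.frame(
    replicate_id = records$replicate_id,
    group_id = data$group_id,
    fraction = f,
    recovery_retained = records$mean_recovery_percent >= 90 &
      records$mean_recovery_percent <= 110,
    complete_branch = unname(row_complete),
    stringsAsFactors = FALSE
  )
  list(records = records, planted = planted, generated = generated)
}
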