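# Bayesian Gaussian linear mixed model on the logit fraction absorbed,
# fitted by a blocked Gibbs sampler with conjugate updates.
#
# Model, for replicate i in group g within study j, substance s with
# concentration status c(i):
#   y_i = x_i' beta + u_{s, c(i)} + v_j + w_g + e_i
#   (u_{s,D}, u_{s,C})' ~ N(0, G)        2x2, correlation rho
#   v_j ~ N(0, s2_study),  w_g ~ N(0, s2_within),  e_i ~ N(0, s2_resid)
# Fixed effects: intercept (reference cell dilution / organic solvent) and
# indicators for concentrate, other, solid, water-based.

FIXED_EFFECT_NAMES <- c(
  "alpha", "beta_concentrate", "beta_other", "beta_solid", "beta_water_based"
)

#' Design structures for the absorption mixed model
#'
#' Builds the fixed-effect matrix and the sparse random-effect incidence
#' matrices from a prepared dataset. The fixed-effect row for a replicate is
#' `[1, I(concentrate), I(other), I(solid), I(water_based)]`, so the
#' intercept is the dilution / organic-solvent reference cell. Substance
#' effects are indexed by (substance, status) pairs, dilution column first
#' within each substance.
#'
#' @param prepared A `da_prepared` table from [prepare_dataset()] (or any
#'   data frame with `y`, `status`, `formulation_category`, `substance`,
#'   `study_id`, `group_id`).
#' @return List with the response `y`, dense `X`, sparse `Z_substance`,
#'   `Z_study`, `Z_group`, the level vectors, and the per-row status.
#' @export
build_design <- function(prepared) {
  required <- c("y", "status", "formulation_category", "substance",
                "study_id", "group_id")
  missing <- setdiff(required, names(prepared))
  if (length(missing) > 0L) {
    stop("prepared dataset lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_status <- setdiff(unique(prepared$status),
                        c("dilution", "concentrate"))
  if (length(bad_status) > 0L) {
    stop("unknown concentration status label(s): ",
         paste(bad_status, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(
    unique(prepared$formulation_category),
    c("organic_solvent", "other", "solid", "water_based")
  )
  if (length(bad_cat) > 0L) {
    stop("unknown formulation category label(s): ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  n <- nrow(prepared)
  X <- cbind(
    1,
    as.numeric(prepared$status == "concentrate"),
    as.numeric(prepared$formulation_category == "other"),
    as.numeric(prepared$formulation_category == "solid"),
    as.numeric(prepared$formulation_category == "water_based")
  )
  colnames(X) <- FIXED_EFFECT_NAMES
  substances <- sort(unique(prepared$substance))
  studies <- sort(unique(prepared$study_id))
  groups <- sort(unique(prepared$group_id))
  s_idx <- match(prepared$substance, substances)
  status_offset <- ifelse(prepared$status == "concentrate", 2L, 1L)
  Z_substance <- Matrix::sparseMatrix(
    i = seq_len(n), j = 2L * (s_idx - 1L) + status_offset, x = 1,
    dims = c(n, 2L * length(substances))
  )
  Z_study <- Matrix::sparseMatrix(
    i = seq_len(n), j = match(prepared$study_id, studies), x = 1,
    dims = c(n, length(studies))
  )
  Z_group <- Matrix::sparseMatrix(
    i = seq_len(n), j = match(prepared$group_id, groups), x = 1,
    dims = c(n, length(groups))
  )
  list(
    y = prepared$y, X = X,
    Z_substance = Z_substance, Z_study = Z_study, Z_group = Z_group,
    substances = substances, studies = studies, groups = groups,
    status = prepared$status
  )
}

#' Default priors for the absorption mixed model
#'
#' Weakly informative proper priors: a large-variance Gaussian on the fixed
#' effects, scaled inverse-chi-squared priors (unit scale, low degrees of
#' freedom) on the scalar variance components and the residual variance, and
#' an inverse-Wishart with near-minimal degrees of freedom on the 2x2
#' substance covariance. All are overridable.
#'
#' @param beta_var Prior variance of each fixed effect.
#' @param var_df,var_scale Degrees of freedom and scale of the scaled
#'   inverse-chi-squared priors on the scalar variances.
#' @param G_df,G_scale Degrees of freedom and 2x2 scale matrix of the
#'   inverse-Wishart prior on the substance covariance.
#' @return List of prior settings.
#' @export
default_priors <- function(beta_var = 1e8, var_df = 1, var_scale = 1,
                           G_df = 3, G_scale = diag(2)) {
  stopifnot(beta_var > 0, var_df > 0, var_scale > 0, G_df > 1,
            all(dim(G_scale) == c(2, 2)))
  list(beta_var = beta_var, var_df = var_df, var_scale = var_scale,
       G_df = G_df, G_scale = G_scale)
}

rinvwishart <- function(df, scale) {
  W <- stats::rWishart(1, df = df, Sigma = solve(scale))[, , 1]
  out <- solve(W)
  (out + t(out)) / 2
}

rscaled_invchisq <- function(df, scale_sum) {
  scale_sum / stats::rchisq(1, df = df)
}

#' Fit the absorption mixed model by blocked Gibbs sampling
#'
#' Samples the joint posterior of the fixed effects, the 2x2 substance
#' covariance (between-substance variances for dilutions and concentrates
#' plus their correlation), the study and within-study variances, and the
#' residual variance. Each sweep draws all location effects jointly from
#' their Gaussian full conditional (sparse Cholesky), then each variance
#' component from its conjugate full conditional (scaled inverse-chi-squared
#' for scalars, inverse-Wishart for the substance covariance). Every
#' covariance draw is checked for positive definiteness. Given a seed the
#' draw sequence is fully deterministic.
#'
#' @param prepared A `da_prepared` table from [prepare_dataset()].
#' @param priors Prior settings from [default_priors()].
#' @param iterations Total Gibbs sweeps including burn-in.
#' @param burnin Sweeps discarded from the start.
#' @param thin Keep every `thin`-th sweep after burn-in.
#' @param seed Integer seed controlling the whole chain.
#' @param include Random-effect terms to keep in the model; subset of
#'   `c("substance", "study", "group")`. Dropping terms is mainly useful for
#'   sampler validation against closed-form posteriors.
#' @param verbose Print progress every 500 sweeps.
#' @return Object of class `da_posterior`: a list with `draws` (data frame,
#'   one row per retained draw), `ess` (effective sample sizes), `settings`,
#'   and the design level vectors.
#' @export
fit_absorption_model <- function(prepared,
                                 priors = default_priors(),
                                 iterations = 2500,
                                 burnin = 500,
                                 thin = 1,
                                 seed = 1,
                                 include = c("substance", "study", "group"),
                                 verbose = FALSE) {
  stopifnot(iterations > burnin, thin >= 1)
  bad_terms <- setdiff(include, c("substance", "study", "group"))
  if (length(bad_terms) > 0L) {
    stop("unknown random-effect term(s): ",
         paste(bad_terms, collapse = ", "), call. = FALSE)
  }
  if (nrow(prepared) == 0L) stop("empty dataset", call. = FALSE)
  if (any(!is.finite(prepared$y))) {
    stop("non-finite response values in dataset", call. = FALSE)
  }
  design <- build_design(prepared)
  y <- design$y
  n <- length(y)
  use_sub <- "substance" %in% include
  use_study <- "study" %in% include
  use_group <- "group" %in% include

  blocks <- list(Matrix::Matrix(design$X, sparse = TRUE))
  if (use_sub) blocks <- c(blocks, list(design$Z_substance))
  if (use_study) blocks <- c(blocks, list(design$Z_study))
  if (use_group) blocks <- c(blocks, list(design$Z_group))
  W <- do.call(cbind, blocks)
  q <- ncol(W)
  p <- ncol(design$X)
  n_sub <- length(design$substances)
  n_study <- length(design$studies)
  n_group <- length(design$groups)
  # column index ranges of each block within theta
  idx_sub <- if (use_sub) p + seq_len(2L * n_sub) else integer(0)
  off <- p + length(idx_sub)
  idx_study <- if (use_study) off + seq_len(n_study) else integer(0)
  off <- off + length(idx_study)
  idx_group <- if (use_group) off + seq_len(n_group) else integer(0)

  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))

  set.seed(as.integer(seed))
  G <- diag(2)
  s2_study <- 1
  s2_group <- 1
  s2_e <- 1
  n_keep <- floor((iterations - burnin) / thin)
  par_names <- c(
    FIXED_EFFECT_NAMES,
    "var_substance_dilution", "var_substance_concentrate", "cov_substance",
    "rho", "var_study", "var_within", "var_resid"
  )
  draws <- matrix(NA_real_, nrow = n_keep, ncol = length(par_names),
                  dimnames = list(NULL, par_names))
  kept <- 0L
  for (iter in seq_len(iterations)) {
    # --- joint location update ---------------------------------------
    k_blocks <- list(Matrix::Diagonal(p, 1 / priors$beta_var))
    if (use_sub) {
      Ginv <- solve(G)
      k_blocks <- c(k_blocks, list(
        Matrix::kronecker(Matrix::Diagonal(n_sub), Ginv)
      ))
    }
    if (use_study) {
      k_blocks <- c(k_blocks, list(Matrix::Diagonal(n_study, 1 / s2_study)))
    }
    if (use_group) {
      k_blocks <- c(k_blocks, list(Matrix::Diagonal(n_group, 1 / s2_group)))
    }
    K <- Matrix::bdiag(k_blocks)
    C <- Matrix::forceSymmetric(WtW / s2_e + K)
    ch <- Matrix::Cholesky(C, LDL = FALSE, perm = TRUE)
    mu <- as.numeric(Matrix::solve(ch, Wty / s2_e, system = "A"))
    z <- stats::rnorm(q)
    pert <- Matrix::solve(
      ch, Matrix::solve(ch, z, system = "Lt"), system = "Pt"
    )
    theta <- mu + as.numeric(pert)

    # --- variance updates --------------------------------------------
    r <- y - as.numeric(W %*% theta)
    s2_e <- rscaled_invchisq(
      priors$var_df + n,
      priors$var_df * priors$var_scale + sum(r^2)
    )
    if (use_sub) {
      U <- matrix(theta[idx_sub], ncol = 2, byrow = TRUE)
      S <- crossprod(U)
      G <- rinvwishart(priors$G_df + n_sub, priors$G_scale + S)
      ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev <= 0)) {
        stop("non-positive-definite substance covariance draw at sweep ",
             iter, call. = FALSE)
      }
    }
    if (use_study) {
      v <- theta[idx_study]
      s2_study <- rscaled_invchisq(
        priors$var_df + n_study,
        priors$var_df * priors$var_scale + sum(v^2)
      )
    }
    if (use_group) {
      w_eff <- theta[idx_group]
      s2_group <- rscaled_invchisq(
        priors$var_df + n_group,
        priors$var_df * priors$var_scale + sum(w_eff^2)
      )
    }

    if (iter > burnin && (iter - burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(
        theta[seq_len(p)],
        if (use_sub) G[1, 1] else NA_real_,
        if (use_sub) G[2, 2] else NA_real_,
        if (use_sub) G[1, 2] else NA_real_,
        if (use_sub) G[1, 2] / sqrt(G[1, 1] * G[2, 2]) else NA_real_,
        if (use_study) s2_study else NA_real_,
        if (use_group) s2_group else NA_real_,
        s2_e
      )
    }
    if (verbose && iter %% 500L == 0L) {
      message("sweep ", iter, "/", iterations)
    }
  }
  draws <- as.data.frame(draws[seq_len(kept), , drop = FALSE])
  active <- par_names[colSums(!is.na(draws)) > 0L]
  ess <- vapply(draws[active], function(col) {
    suppressWarnings(effective_sample_size(col))
  }, numeric(1))
  structure(
    list(
      draws = draws,
      ess = ess,
      settings = list(iterations = iterations, burnin = burnin,
                      thin = thin, seed = seed, n_retained = kept,
                      include = include),
      substances = design$substances,
      studies = design$studies,
      groups = design$groups,
      n_obs = n
    ),
    class = "da_posterior"
  )
}

#' @exportS3Method base::print
print.da_posterior <- function(x, ...) {
  cat(sprintf(
    "Absorption mixed-model posterior: %d draws (seed %s), %d observations\n",
    x$settings$n_retained, format(x$settings$seed), x$n_obs
  ))
  cat(sprintf("%d substances, %d studies, %d within-study groups\n",
              length(x$substances), length(x$studies), length(x$groups)))
  print(posterior_summary(x), digits = 3)
  invisible(x)
}

#' Posterior summary table
#'
#' Posterior means, 95% highest-density intervals and effective sample
#' sizes for the reported model parameters: the five fixed effects, the two
#' substance variances, their correlation, and the study and within-study
#' variances (plus the residual variance, which is fitted but not part of
#' any prediction interval).
#'
#' @param posterior A `da_posterior` object.
#' @return Data frame with columns `parameter`, `mean`, `lower`, `upper`,
#'   `ess`.
#' @export
posterior_summary <- function(posterior) {
  stopifnot(inherits(posterior, "da_posterior"))
  draws <- posterior$draws
  keep <- names(draws)[colSums(!is.na(draws)) > 0L]
  keep <- setdiff(keep, "cov_substance")
  rows <- lapply(keep, function(p) {
    x <- draws[[p]]
    ci <- if (length(x) >= 20) hpdi(x) else range(x)
    data.frame(
      parameter = p, mean = mean(x), lower = ci[1], upper = ci[2],
      ess = unname(posterior$ess[p]), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-based effective sample size using the initial positive
#' sequence estimator: autocorrelations are summed over consecutive lag
#' pairs until a pair sum turns non-positive. A constant chain has no
#' information about mixing; it is reported as the draw count with a
#' warning.
#'
#' @param x Numeric vector of draws (>= 10).
#' @return Effective sample size (scalar).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10L) stop("need at least 10 draws", call. = FALSE)
  if (stats::var(x) == 0) {
    warning("constant chain; effective sample size undefined",
            call. = FALSE)
    return(n)
  }
  max_lag <- min(n - 1L, 10L * floor(sqrt(n)))
  rho <- as.numeric(stats::acf(x, lag.max = max_lag,
                               plot = FALSE)$acf)[-1]
  tau <- 1
  m <- 0L
  while (2L * m + 2L <= length(rho)) {
    pair <- rho[2L * m + 1L] + rho[2L * m + 2L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 1L
  }
  n / tau
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing the requested posterior mass of
#' a set of draws.
#'
#' @param x Numeric vector of draws (>= 20).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, mass = 0.95) {
  if (mass <= 0 || mass >= 1) {
    stop("mass must lie in (0, 1)", call. = FALSE)
  }
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 20L) stop("need at least 20 draws for an HPDI", call. = FALSE)
  m <- max(1L, ceiling(mass * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- starts[which.min(widths)]
  c(x[i], x[i + m])
}
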