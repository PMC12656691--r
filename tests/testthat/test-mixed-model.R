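test_that("fixed-effect coding uses dilution / organic solvent as reference", {
  d <- data.frame(
    y = c(0, 0, 0),
    status = c("dilution", "concentrate", "concentrate"),
    formulation_category = c("organic_solvent", "solid", "water_based"),
    substance = "s", study_id = "st", group_id = "g",
    stringsAsFactors = FALSE
  )
  X <- build_design(d)$X
  expect_equal(unname(X[1, ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(X[2, ]), c(1, 1, 0, 1, 0))
  expect_equal(unname(X[3, ]), c(1, 1, 0, 0, 1))
  d$formulation_category[1] <- "mystery"
  expect_error(build_design(d), "mystery")
})

test_that("substance incidence columns are status specific", {
  d <- data.frame(
    y = 1:4 / 10,
    status = c("dilution", "concentrate", "dilution", "concentrate"),
    formulation_category = "organic_solvent",
    substance = c("a", "a", "b", "b"),
    study_id = "st", group_id = "g", stringsAsFactors = FALSE
  )
  Z <- as.matrix(build_design(d)$Z_substance)
  expect_equal(dim(Z), c(4L, 4L))
  expect_equal(which(Z[1, ] == 1), 1L)  # a, dilution
  expect_equal(which(Z[2, ] == 1), 2L)  # a, concentrate
  expect_equal(which(Z[4, ] == 1), 4L)  # b, concentrate
})

test_that("identical seeds give bit-identical chains", {
  sim <- generate_logit_dataset(
    synthetic_truth(n_substances = 8), seed = 5
  )
  a <- fit_absorption_model(sim$data, iterations = 60, burnin = 10,
                            seed = 123)
  b <- fit_absorption_model(sim$data, iterations = 60, burnin = 10,
                            seed = 123)
  expect_identical(a$draws, b$draws)
  c <- fit_absorption_model(sim$data, iterations = 60, burnin = 10,
                            seed = 124)
  expect_false(identical(a$draws$alpha, c$draws$alpha))
})

test_that("with only the residual term the posterior matches the closed-form linear-regression posterior", {
  set.seed(3)
  n <- 200
  status <- rep(c("dilution", "concentrate"), each = n / 2)
  category <- rep(c("organic_solvent", "solid"), n / 2)
  Xs <- cbind(1, as.numeric(status == "concentrate"),
              as.numeric(category == "solid"))
  beta_true <- c(-2.3, -2.4, -0.9)
  y <- as.numeric(Xs %*% beta_true + stats::rnorm(n, 0, 0.5))
  d <- data.frame(substance = "s1", study_id = "st1", group_id = "g1",
                  status = status, formulation_category = category,
                  y = y, stringsAsFactors = FALSE)
  post <- fit_absorption_model(d, iterations = 2500, burnin = 500,
                               seed = 5, include = character(0))
  bhat <- solve(crossprod(Xs), crossprod(Xs, y))
  s2 <- sum((y - Xs %*% bhat)^2) / (n - 3)
  se <- sqrt(s2 * diag(solve(crossprod(Xs))))
  nm <- c("alpha", "beta_concentrate", "beta_solid")
  for (j in seq_along(nm)) {
    z <- (post$draws[[nm[j]]] - bhat[j]) / se[j]
    ks <- suppressWarnings(
      stats::ks.test(z, function(q) stats::pt(q, df = n - 3))
    )
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("posterior agrees with REML estimates from an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  sim <- cached("lme4_sim", generate_logit_dataset(
    synthetic_truth(n_substances = 40, studies_per_substance_mean = 1.5),
    seed = 31
  ))
  d <- sim$data
  reml <- lme4::lmer(
    y ~ status + formulation_category + (0 + status | substance) +
      (1 | study_id) + (1 | group_id),
    data = d
  )
  post <- cached("lme4_post", fit_absorption_model(
    d, iterations = 1500, burnin = 300, seed = 32
  ))
  pm <- colMeans(post$draws)
  fe <- lme4::fixef(reml)
  # lme4 picks concentrate as the status reference; translate
  expect_equal(unname(pm["alpha"]),
               unname(fe["(Intercept)"] + fe["statusdilution"]),
               tolerance = 0.1)
  expect_equal(unname(pm["beta_concentrate"]),
               unname(-fe["statusdilution"]), tolerance = 0.1)
  expect_equal(unname(pm["beta_solid"]),
               unname(fe["formulation_categorysolid"]), tolerance = 0.25)
  vc <- as.data.frame(lme4::VarCorr(reml))
  v_study <- vc$vcov[vc$grp == "study_id" & vc$var1 == "(Intercept)"]
  v_group <- vc$vcov[vc$grp == "group_id" & vc$var1 == "(Intercept)"]
  v_resid <- vc$vcov[vc$grp == "Residual"]
  expect_equal(unname(pm["var_study"]), v_study, tolerance = 0.25)
  expect_equal(unname(pm["var_within"]), v_group, tolerance = 0.2)
  expect_equal(unname(pm["var_resid"]), v_resid, tolerance = 0.1)
})

test_that("posterior summaries are invariant to substance relabelling", {
  truth <- synthetic_truth(n_substances = 15)
  sim <- generate_logit_dataset(truth, seed = 88)
  d <- sim$data
  relabelled <- d
  relabelled$substance <- chartr("0123456789", "9876543210", d$substance)
  a <- fit_absorption_model(d, iterations = 700, burnin = 200, seed = 55)
  b <- fit_absorption_model(relabelled, iterations = 700, burnin = 200,
                            seed = 55)
  # same posterior up to Monte-Carlo error (different column ordering
  # changes the draw stream, so only summaries can agree)
  for (p in c("alpha", "beta_concentrate", "var_study", "var_within")) {
    mc <- stats::sd(a$draws[[p]]) / sqrt(unname(a$ess[p])) +
      stats::sd(b$draws[[p]]) / sqrt(unname(b$ess[p]))
    expect_lt(abs(mean(a$draws[[p]]) - mean(b$draws[[p]])), 6 * mc + 0.02)
  }
})

test_that("effective sample size matches white-noise and AR(1) references", {
  set.seed(1)
  w <- stats::rnorm(2000)
  expect_equal(effective_sample_size(w), 2000, tolerance = 0.1)
  set.seed(2)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 2000))
  # closed form n(1-phi)/(1+phi) ~ 105
  expect_equal(effective_sample_size(ar), 105, tolerance = 0.25)
  expect_warning(ess <- effective_sample_size(rep(1, 100)), "constant")
  expect_equal(ess, 100)
  expect_error(effective_sample_size(1:5), "at least 10")
})

test_that("HPDI is the shortest interval and matches Gaussian and uniform references", {
  set.seed(4)
  g <- stats::rnorm(1e5)
  expect_equal(hpdi(g), c(-1.96, 1.96), tolerance = 0.05)
  u <- stats::runif(1e5)
  expect_equal(diff(hpdi(u, mass = 0.5)), 0.5, tolerance = 0.02)
  # symmetric unimodal: close to the equal-tailed interval
  expect_equal(hpdi(g), unname(stats::quantile(g, c(0.025, 0.975))),
               tolerance = 0.05)
  expect_error(hpdi(g, mass = 1.2), "mass")
  expect_error(hpdi(stats::rnorm(5)), "at least 20")
})
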