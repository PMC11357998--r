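# Spline basis contracts and model-fitting oracles.

test_that("centered P-spline basis has the promised dimensions and penalty", {
  x <- seq(0, 1, length.out = 300)
  b <- build_spline_basis(x, k = 10)
  expect_identical(ncol(b$X), 9L)                      # k - 1 after centering
  expect_lt(max(abs(colSums(b$X))), 1e-8)              # sum-to-zero columns
  expect_identical(qr(b$S)$rank, 8L)                   # penalty rank k - 2
  ev <- eigen(b$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))                        # positive semidefinite

  # second-difference penalty annihilates constant and linear coefficients
  for (v in list(rep(1, 10), seq_len(10))) {
    expect_lt(abs(t(v) %*% b$S_raw %*% v), 1e-10)
  }

  expect_error(build_spline_basis(x, k = 3), "k must be")
  expect_error(build_spline_basis(rep(1:5, 10), k = 10), "distinct")
})

test_that("basis evaluation is consistent and zero coefficients give zero", {
  x <- runif(100, 20, 80)
  b <- build_spline_basis(x, k = 8)
  expect_equal(eval_spline_basis(b, x), b$X, tolerance = 1e-12)
  expect_equal(drop(b$X %*% rep(0, ncol(b$X))), rep(0, 100))
  expect_error(eval_spline_basis(b, 100), "outside")
})

test_that("unpenalized gaussian fit equals ordinary least squares", {
  set.seed(5)
  n <- 400
  d <- data.frame(age = runif(n, 20, 80),
                  sex = factor(sample(c("M", "F"), n, TRUE),
                               levels = c("M", "F")))
  d$y <- 1 + 0.02 * d$age + 0.4 * (d$sex == "F") + sin(d$age / 8) +
    rnorm(n, 0, 0.5)
  fit <- suppressWarnings(
    fit_gam(gam_spec("y", k = 6), d, engine = "gam", sp = c(0, 0)))
  X <- model.matrix(fit$model)
  ols_fitted <- qr.fitted(qr(X), fit$model$y)
  expect_lt(max(abs(fitted(fit$model) - ols_fitted)), 1e-8)
})

test_that("penalty null space and exact parametric recovery", {
  # noiseless linear data: exact interpolation
  d <- data.frame(age = seq(20, 80, length.out = 300))
  d$y <- 3 + 2 * d$age
  fit <- suppressWarnings(
    fit_gam(gam_spec("y", sex = FALSE, interaction = FALSE), d,
            engine = "gam"))
  expect_lt(max(abs(fitted(fit$model) - d$y)), 1e-8)

  # forcing lambda -> infinity collapses the smooth onto its null space
  d$y2 <- 3 + 2 * d$age + rnorm(300, 0, 0.1)
  fit_inf <- fit_gam(gam_spec("y2", sex = FALSE, interaction = FALSE), d,
                     engine = "gam", sp = 1e10)
  expect_lt(abs(smooth_term_edf(fit_inf, "age") - 1), 1e-3)

  # pure sex offset, zero noise: parametric coefficient exact
  spec <- trajectory_spec("x", sex_offset = 1, noise_sd = 0)
  co <- generate_cohort(cohort_config(300, list(spec), seed = 2))
  fit_sex <- fit_gam(gam_spec("x", interaction = FALSE), co$data,
                     engine = "gam")
  expect_lt(abs(coef(fit_sex$model)["sexF"] - 1), 1e-8)
})

test_that("binomial fit recovers a constant probability", {
  set.seed(10)
  d <- data.frame(age = runif(800, 20, 80),
                  sex = factor(sample(c("M", "F"), 800, TRUE),
                               levels = c("M", "F")),
                  y = rbinom(800, 1, 0.5))
  fit <- fit_gam(gam_spec("y", family = "binomial"), d, engine = "gam")
  expect_lt(abs(coef(fit$model)["(Intercept)"] - qlogis(0.5)), 0.3)
  expect_lt(smooth_term_edf(fit, "age"), 1.6)
})

test_that("predictions reproduce fitted values and closed-form SEs", {
  set.seed(3)
  d <- null_table(300, seed = 12)
  fit <- fit_gam(gam_spec("null01"), d, engine = "gam")
  pr <- predict_gam(fit, d)
  expect_equal(pr$fit, unname(fitted(fit$model)), tolerance = 1e-10)
  expect_error(predict_gam(fit, d[, "null01", drop = FALSE]), "lacks")

  # intercept-only model: prediction = mean, se = sd/sqrt(n) (OLS sigma-hat)
  d2 <- data.frame(y = rnorm(50))
  fit2 <- fit_gam(gam_spec("y", sex = FALSE, age_smooth = FALSE,
                           interaction = FALSE), d2, engine = "gam")
  pr2 <- predict_gam(fit2, data.frame(y = 0))
  expect_equal(pr2$fit, mean(d2$y), tolerance = 1e-10)
  expect_equal(pr2$se, sd(d2$y) / sqrt(50), tolerance = 1e-8)

  # doubling the data halves the squared standard error
  d4 <- rbind(d2, d2)
  fit4 <- fit_gam(gam_spec("y", sex = FALSE, age_smooth = FALSE,
                           interaction = FALSE), d4, engine = "gam")
  pr4 <- predict_gam(fit4, data.frame(y = 0))
  expect_lt(pr4$se, pr2$se)
})

test_that("explained_r2 respects limits and nesting", {
  d <- data.frame(age = seq(20, 80, length.out = 200))
  d$y <- 1 + 0.1 * d$age
  fit <- suppressWarnings(
    fit_gam(gam_spec("y", sex = FALSE, interaction = FALSE), d,
            engine = "gam"))
  expect_equal(explained_r2(fit), 1, tolerance = 1e-8)

  d2 <- data.frame(y = rnorm(100))
  fit0 <- fit_gam(gam_spec("y", sex = FALSE, age_smooth = FALSE,
                           interaction = FALSE), d2, engine = "gam")
  expect_equal(explained_r2(fit0), 0, tolerance = 1e-10)

  set.seed(33)
  d3 <- null_table(400, seed = 44)
  full <- fit_gam(gam_spec("null01"), d3, engine = "gam")
  sub <- fit_gam(gam_spec("null01", interaction = FALSE), d3, engine = "gam")
  expect_gte(explained_r2(full), explained_r2(sub) - 1e-6)
})

test_that("sex-label symmetry leaves fitted values unchanged", {
  # the model space is symmetric in the sex labels; with penalties off the
  # fit is the projection onto that span, so swapping labels is exact
  co <- cohort_scenario("crossover", n = 1500, seed = 17)
  d <- co$data
  fit <- fit_gam(gam_spec("crossover", k = 8), d, engine = "gam",
                 sp = c(0, 0))
  d_swap <- d
  d_swap$sex <- factor(ifelse(d$sex == "F", "M", "F"), levels = c("M", "F"))
  fit_swap <- fit_gam(gam_spec("crossover", k = 8), d_swap, engine = "gam",
                      sp = c(0, 0))
  expect_equal(unname(fitted(fit$model)), unname(fitted(fit_swap$model)),
               tolerance = 1e-8)

  # with REML smoothing the two fits agree closely but not identically
  fit_r <- fit_gam(gam_spec("crossover"), d, engine = "gam")
  fit_rs <- fit_gam(gam_spec("crossover"), d_swap, engine = "gam")
  expect_lt(mean(abs(fitted(fit_r$model) - fitted(fit_rs$model))), 0.05)
})

test_that("cross-validated MSE comparison is seeded and discriminates", {
  d <- cohort_scenario("crossover", n = 1200, seed = 31, slope = 0.04)$data
  spec_full <- gam_spec("crossover")
  spec_red <- gam_spec("crossover", interaction = FALSE)
  m1 <- cv_mse_compare(spec_full, spec_full, d, folds = 5, seed = 9)
  expect_equal(unname(m1["mse_a"]), unname(m1["mse_b"]), tolerance = 1e-12)
  expect_error(cv_mse_compare(spec_full, spec_red, d[1:4, ], folds = 10),
               "folds")

  # with a true interaction the interaction spec wins in most replicates
  wins <- 0
  for (i in 1:8) {
    di <- cohort_scenario("crossover", n = 1200, seed = 600 + i,
                          slope = 0.04)$data
    m <- cv_mse_compare(spec_full, spec_red, di, folds = 5, seed = i)
    wins <- wins + as.integer(m["mse_a"] < m["mse_b"])
  }
  expect_gte(wins, 7)

  # on pure noise the extra term cannot help on average (overfit penalty)
  diffs <- numeric(8)
  for (i in 1:8) {
    dn <- cohort_scenario("null_panel", n = 800, seed = 700 + i,
                          n_phenotypes = 1)$data
    spec_f0 <- gam_spec("null01")
    spec_r0 <- gam_spec("null01", interaction = FALSE)
    m <- cv_mse_compare(spec_f0, spec_r0, dn, folds = 5, seed = i)
    diffs[i] <- m["mse_a"] - m["mse_b"]
  }
  expect_gte(mean(diffs), -1e-4)
})
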