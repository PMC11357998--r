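# Variance decomposition, PERMANOVA, trajectory matrices and UPGMA.

test_that("variance decomposition hits limit cases", {
  # deterministic f(age), zero noise: age increment ~ 1, interaction ~ 0
  spec <- trajectory_spec("det", base_fn = function(a) sin(a / 10),
                          noise_sd = 0)
  co <- generate_cohort(cohort_config(800, list(spec), seed = 71))
  vd <- variance_decomposition(co$data, "det", folds = 5, repeats = 2,
                               seed = 5)
  expect_gt(vd$increments[["age"]], 0.95)
  expect_lt(vd$increments[["interaction"]], 0.02)

  # pure noise: every increment small
  co2 <- cohort_scenario("null_panel", n = 800, seed = 73, n_phenotypes = 1)
  vd2 <- variance_decomposition(co2$data, "null01", folds = 5, repeats = 2,
                                seed = 5)
  expect_true(all(vd2$increments <= 0.01 + 1e-9))
})

test_that("decomposition increments are deterministic given the seed", {
  co <- cohort_scenario("variance_shares", n = 600, seed = 79)
  a <- variance_decomposition(co$data, "feature", folds = 5, repeats = 2,
                              seed = 11)
  b <- variance_decomposition(co$data, "feature", folds = 5, repeats = 2,
                              seed = 11)
  expect_identical(a$increments, b$increments)
})

test_that("in-sample sequential increments sum to the full model R2", {
  co <- cohort_scenario("variance_shares", n = 1200, seed = 83)
  d <- co$data
  fits <- list(
    fit_gam(gam_spec("feature", sex = FALSE, age_smooth = FALSE,
                     interaction = FALSE), d, engine = "gam"),
    fit_gam(gam_spec("feature", age_smooth = FALSE, interaction = FALSE), d,
            engine = "gam"),
    fit_gam(gam_spec("feature", interaction = FALSE), d, engine = "gam"),
    fit_gam(gam_spec("feature"), d, engine = "gam"))
  r2 <- vapply(fits, explained_r2, 0)
  increments <- c(r2[1], diff(r2))
  expect_equal(sum(increments), r2[4], tolerance = 1e-6)
})

test_that("univariate PERMANOVA pseudo-F equals classical ANOVA F", {
  x <- c(1.2, 0.8, 1.1, 3.4, 3.9, 3.1)
  g <- factor(rep(c("a", "b"), each = 3))
  pm <- permanova(matrix(x, ncol = 1), data.frame(g = g), n_perm = 99,
                  seed = 1)
  f_aov <- summary(aov(x ~ g))[[1]]$`F value`[1]
  expect_equal(pm$F[1], f_aov, tolerance = 1e-10)
})

test_that("PERMANOVA matches vegan::adonis2 on a multivariate design", {
  skip_if_not_installed("vegan")
  set.seed(91)
  X <- matrix(rnorm(40 * 4), 40, 4)
  des <- data.frame(g = factor(rep(c("a", "b"), 20)), z = rnorm(40))
  pm <- permanova(X, des, terms = c("g", "z"), n_perm = 199, seed = 2)
  ref <- vegan::adonis2(X ~ g + z, data = des, method = "euclidean",
                        permutations = 199, by = "terms")
  expect_equal(pm$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(pm$F[1:2], ref$F[1:2], tolerance = 1e-8)
})

test_that("PERMANOVA p-values: permutation floor and exchange invariance", {
  set.seed(97)
  X <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 8), 20, 3))
  des <- data.frame(g = factor(rep(c("a", "b"), each = 20)))
  pm <- permanova(X, des, n_perm = 1000, seed = 3)
  expect_equal(pm$p[1], 1 / 1001, tolerance = 1e-12)

  # permuting samples together with labels leaves F unchanged
  idx <- sample(40)
  pm2 <- permanova(X[idx, ], data.frame(g = des$g[idx]), n_perm = 99,
                   seed = 4)
  expect_equal(pm2$F[1], pm$F[1], tolerance = 1e-10)

  expect_error(permanova(matrix(1, 10, 2),
                         data.frame(g = factor(rep(c("a", "b"), 5)))),
               "constant")
  expect_error(permanova(X, data.frame(g = factor(rep("a", 40)))),
               "single level")
})

test_that("trajectory matrices have the contracted layout", {
  co <- cohort_scenario("demo", n = 1500, seed = 101)
  tr <- fit_trajectories(co$data, c("lipid", "static"), grid_points = 300)
  expect_identical(dim(tr$matrix), c(2L, 600L))
  expect_identical(rownames(tr$matrix), c("lipid", "static"))
  expect_identical(length(tr$grid), 300L)

  # noiseless linear feature: trajectory exactly linear on the grid
  spec <- trajectory_spec("lin", base_fn = function(a) 2 + 0.1 * a,
                          noise_sd = 0)
  co2 <- generate_cohort(cohort_config(500, list(spec), seed = 103))
  tr2 <- suppressWarnings(fit_trajectories(co2$data, "lin", grid_points = 50))
  male <- tr2$matrix[1, 1:50]
  expect_lt(max(abs(male - (2 + 0.1 * tr2$grid))), 1e-6)

  # a failing feature is dropped with a warning, scan continues
  co$data$bad <- 1
  expect_warning(tr3 <- fit_trajectories(co$data, c("lipid", "bad"),
                                         grid_points = 20),
                 "dropping")
  expect_identical(rownames(tr3$matrix), "lipid")
})

test_that("crossover trajectories intersect near the true crossing age", {
  co <- cohort_scenario("crossover", n = 8000, seed = 107, sex_offset = 0)
  tr <- fit_trajectories(co$data, "crossover", grid_points = 300)
  male <- tr$matrix[1, 1:300]
  female <- tr$matrix[1, 301:600]
  gap <- female - male
  cross_idx <- which.min(abs(gap))
  # true interaction 0.02*(age-50) with zero offset crosses at age 50
  expect_lt(abs(tr$grid[cross_idx] - 50), 3)
})

test_that("UPGMA merges match the hand-computed toy and stay monotone", {
  # coordinates realizing d(A,B) = 1, d(A,C) = d(B,C) = 4 exactly
  toy <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, sqrt(16 - 0.25)))
  hc <- upgma_cluster(toy)
  expect_equal(hc$height, c(1, 4), tolerance = 1e-12)
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))

  mat <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  hc2 <- upgma_cluster(mat)
  expect_equal(hc2$height[1], 0)
  expect_true(all(diff(hc2$height) >= 0))

  expect_error(upgma_cluster(mat[1, , drop = FALSE]), "at least 2")
  mat[1, 1] <- NA
  expect_error(upgma_cluster(mat), "non-finite")
})

test_that("Newick export round-trips through ape", {
  mat <- rbind(a = c(0, 0), b = c(1, 0), c = c(5, 5), d = c(5.2, 5))
  hc <- upgma_cluster(mat)
  nwk <- export_newick(hc)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))

  tab <- cluster_summary_table(hc, k = 2)
  expect_identical(sort(unique(tab$cluster)), c(1L, 2L))
})
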