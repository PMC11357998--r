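# Per-phenotype sex-difference profiling.
#
# Two complementary views per phenotype: a whole-age-range linear sex
# difference (OLS, covariate-adjusted), and a nonlinear age-by-sex
# interaction from the penalized-spline model. Interactions pass the gate
# only when both Bonferroni-significant and carrying Cohen's f^2 >= 0.01 --
# in very large cohorts even negligible interactions are significant, so the
# effect-size gate keeps the list interpretable.

#' Cohen's f-squared from nested-model explained variances
#'
#' `f2 = (R2_full - R2_sub) / (1 - R2_full)`, the effect size of the terms
#' present in the full but not the nested sub-model.
#'
#' @param r2_full,r2_sub Explained-variance proportions of the full and
#'   nested models, `0 <= r2_sub <= r2_full < 1`.
#' @return Non-negative effect size.
#' @export
cohens_f2 <- function(r2_full, r2_sub) {
  if (any(r2_full >= 1)) stop("f^2 undefined for R2_full = 1")
  if (any(r2_sub < 0) || any(r2_full < 0)) stop("R2 must be non-negative")
  if (any(r2_sub > r2_full)) {
    stop("R2_sub exceeds R2_full; models are not nested")
  }
  (r2_full - r2_sub) / (1 - r2_full)
}

# Variant for fitted-model pairs: nested penalized fits select their
# smoothing parameters independently, so the richer model's in-sample R2 can
# land slightly below the nested one; an effect size indistinguishable from
# zero is reported as zero.
cohens_f2_fitted <- function(r2_full, r2_sub) {
  if (r2_full >= 1) return(Inf)
  max(0, (r2_full - r2_sub) / (1 - r2_full))
}

#' Whole-age-range linear sex difference
#'
#' Ordinary least squares fit of the phenotype on sex plus linear covariates;
#' the effect size is Cohen's f^2 from the R-squared of the fits with and
#' without sex.
#'
#' @param table Phenotype table.
#' @param phenotype Phenotype column name.
#' @param covariates Optional covariate column names (entered linearly).
#' @return List: `estimate` (female minus male), `se`, `p`, `f2_sex`, `n`.
#' @export
linear_sex_difference <- function(table, phenotype, covariates = character(0)) {
  vars <- c(phenotype, "sex", covariates)
  df <- table[stats::complete.cases(table[, vars, drop = FALSE]), vars,
              drop = FALSE]
  if (!is.factor(df$sex)) df$sex <- factor(df$sex, levels = c("M", "F"))
  if (length(unique(df$sex)) < 2) stop("table contains a single sex")
  full <- stats::lm(stats::reformulate(c("sex", covariates),
                                       response = phenotype), data = df)
  sub <- stats::lm(stats::reformulate(if (length(covariates)) covariates else "1",
                                      response = phenotype), data = df)
  co <- summary(full)$coefficients["sexF", ]
  r2f <- summary(full)$r.squared
  r2s <- summary(sub)$r.squared
  f2 <- if (r2f >= 1 - 1e-12) Inf else cohens_f2_fitted(r2f, r2s)
  list(estimate = unname(co["Estimate"]), se = unname(co["Std. Error"]),
       p = unname(co["Pr(>|t|)"]),
       f2_sex = f2,
       n = nrow(df))
}

#' Scan a phenotype panel for age-dependent sex differences
#'
#' For each phenotype, fits the full model
#' `phenotype ~ sex + s(age) + s(age, by = sex) + covariates`, the nested
#' model without the deviation smooth, and the model additionally without
#' sex. The age-by-sex interaction p-value comes from the deviation smooth;
#' its effect size is Cohen's f^2 between the first two fits, and the
#' whole-range sex effect size between the last two. Bonferroni adjustment
#' uses the panel as the family. Categories:
#' `age_dependent_sex_difference` when the adjusted interaction p is below
#' `alpha` and its f^2 at least `f2_threshold`;
#' otherwise `static_sex_difference` when the adjusted sex p is below `alpha`
#' with sex f^2 at least `f2_threshold`; otherwise `none`.
#'
#' @param table Phenotype table.
#' @param phenotypes Character vector of phenotype columns (the Bonferroni
#'   family).
#' @param covariates Linear covariate names.
#' @param smooth_covariates Covariates adjusted through their own smooth.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param f2_threshold Effect-size gate (default 0.01).
#' @param k Spline basis dimension.
#' @param binary Character vector naming phenotypes modeled with the
#'   binomial family (deviance-explained analogues are used for f^2).
#' @param engine Passed to [fit_gam()].
#' @return data.frame of class `sexdiff_scan`, one row per phenotype; fit
#'   failures are recorded in the `error` column and do not stop the scan.
#' @export
interaction_scan <- function(table, phenotypes, covariates = character(0),
                             smooth_covariates = character(0),
                             alpha = 0.05, f2_threshold = 0.01, k = 10,
                             binary = character(0),
                             engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  rows <- lapply(phenotypes, function(ph) {
    out <- data.frame(phenotype = ph, n = NA_integer_,
                      linear_estimate = NA_real_, linear_p = NA_real_,
                      p_sex = NA_real_, f2_sex = NA_real_,
                      p_interaction = NA_real_, f2_interaction = NA_real_,
                      edf_interaction = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    tryCatch({
      fam <- if (ph %in% binary) "binomial" else "gaussian"
      full <- fit_gam(gam_spec(ph, family = fam, covariates = covariates,
                               smooth_covariates = smooth_covariates, k = k),
                      table, engine = engine)
      nointer <- fit_gam(gam_spec(ph, family = fam, interaction = FALSE,
                                  covariates = covariates,
                                  smooth_covariates = smooth_covariates,
                                  k = k),
                         table, engine = engine)
      nosex <- fit_gam(gam_spec(ph, family = fam, sex = FALSE,
                                interaction = FALSE, covariates = covariates,
                                smooth_covariates = smooth_covariates, k = k),
                       table, engine = engine)
      out$n <- full$n
      out$p_interaction <- smooth_term_pvalue(full, "interaction")
      out$f2_interaction <- cohens_f2_fitted(explained_r2(full),
                                             explained_r2(nointer))
      out$edf_interaction <- smooth_term_edf(full, "interaction")
      pt <- summary(nointer$model)$p.table
      out$p_sex <- pt["sexF", ncol(pt)]
      out$f2_sex <- cohens_f2_fitted(explained_r2(nointer),
                                     explained_r2(nosex))
      if (fam == "gaussian") {
        lin <- linear_sex_difference(table, ph, c(covariates,
                                                  smooth_covariates))
        out$linear_estimate <- lin$estimate
        out$linear_p <- lin$p
      }
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  m <- length(phenotypes)
  res$p_interaction_adj <- pmin(res$p_interaction * m, 1)
  res$p_sex_adj <- pmin(res$p_sex * m, 1)
  res$category <- ifelse(
    !is.na(res$p_interaction_adj) & res$p_interaction_adj < alpha &
      res$f2_interaction >= f2_threshold,
    "age_dependent_sex_difference",
    ifelse(!is.na(res$p_sex_adj) & res$p_sex_adj < alpha &
             res$f2_sex >= f2_threshold,
           "static_sex_difference", "none"))
  res$category[!is.na(res$error)] <- NA_character_
  attr(res, "alpha") <- alpha
  attr(res, "f2_threshold") <- f2_threshold
  class(res) <- c("sexdiff_scan", "data.frame")
  res
}

#' Localize the turning-point age with a sliding-window t-test
#'
#' Within one sex, compares phenotype values in the 5-year window before each
#' integer age against the 5-year window after it (Welch t-test; windows
#' `[a - w, a)` vs `[a, a + w]`), and reports the age with the smallest
#' p-value. Ages where either window has fewer than `min_n` observations are
#' dropped; zero-variance windows give p = 1 by convention.
#'
#' @param table Phenotype table.
#' @param phenotype Phenotype column.
#' @param sex `"F"` or `"M"`: the stratum scanned.
#' @param half_window Window half-width in years (default 5).
#' @param grid Integer ages to scan; default every integer age in the data
#'   range.
#' @param min_n Minimum observations per window (default 30).
#' @return Object of class `changepoint_trace`: `trace` (data.frame with
#'   `age`, `n_before`, `n_after`, `t`, `p`, `neglog10_p`), `changepoint_age`
#'   (argmin-p age, ties toward the smallest age; `NA` if no age qualifies)
#'   and `min_p`.
#' @export
sliding_changepoint <- function(table, phenotype, sex = "F",
                                half_window = 5, grid = NULL, min_n = 30) {
  df <- table[!is.na(table[[phenotype]]) & !is.na(table$age) &
                as.character(table$sex) == sex, c("age", phenotype)]
  if (!nrow(df)) stop("no observations for sex '", sex, "'")
  if (is.null(grid)) {
    grid <- seq(ceiling(min(df$age)), floor(max(df$age)))
  }
  rows <- lapply(grid, function(a) {
    before <- df[[phenotype]][df$age >= a - half_window & df$age < a]
    after <- df[[phenotype]][df$age >= a & df$age <= a + half_window]
    if (length(before) < min_n || length(after) < min_n) return(NULL)
    if (stats::var(before) == 0 && stats::var(after) == 0) {
      # both windows constant: identical means are uninformative (p = 1);
      # different constant means are a perfect separation
      tt <- if (mean(before) == mean(after)) {
        list(statistic = 0, p.value = 1)
      } else {
        list(statistic = Inf, p.value = .Machine$double.xmin)
      }
    } else {
      tt <- tryCatch(stats::t.test(before, after),
                     error = function(e) list(statistic = 0, p.value = 1))
    }
    data.frame(age = a, n_before = length(before), n_after = length(after),
               t = unname(tt$statistic), p = tt$p.value)
  })
  trace <- do.call(rbind, rows)
  if (is.null(trace) || !nrow(trace)) {
    warning("no age with both windows >= ", min_n, " observations")
    trace <- data.frame(age = numeric(0), n_before = integer(0),
                        n_after = integer(0), t = numeric(0), p = numeric(0))
  }
  trace$neglog10_p <- -log10(pmax(trace$p, .Machine$double.xmin))
  cp <- if (nrow(trace)) trace$age[which.min(trace$p)] else NA_real_
  structure(list(phenotype = phenotype, sex = sex, trace = trace,
                 changepoint_age = cp,
                 min_p = if (nrow(trace)) min(trace$p) else NA_real_),
            class = "changepoint_trace")
}

#' @export
print.changepoint_trace <- function(x, ...) {
  cat("Sliding-window t-test:", x$phenotype, "(", x$sex, ")\n")
  cat("  strongest change at age", x$changepoint_age,
      " (p =", format(x$min_p, digits = 3), ")\n")
  invisible(x)
}

#' Menopause leave-out comparison
#'
#' Re-runs the interaction scan separately on the pre-menopause (ages 20-45)
#' and post-menopause (ages 55-80) windows, excluding the 45-55 transition,
#' each with its own Bonferroni family; then compares the whole-range sex
#' effect sizes (f^2 of the sex term in the no-interaction model) between the
#' windows with a paired two-sided Wilcoxon signed-rank test across
#' phenotypes.
#'
#' @inheritParams interaction_scan
#' @param pre,post Closed age windows, default `c(20, 45)` and `c(55, 80)`.
#' @return List of class `leaveout_result`: `pre` and `post` scans,
#'   `wilcoxon_p`, and the windows used.
#' @export
menopause_leaveout <- function(table, phenotypes, covariates = character(0),
                               smooth_covariates = character(0),
                               pre = c(20, 45), post = c(55, 80),
                               alpha = 0.05, f2_threshold = 0.01, k = 10,
                               engine = c("auto", "gam", "bam")) {
  if (pre[2] > post[1]) stop("windows must be disjoint")
  tab_pre <- filter_age_range(table, pre[1], pre[2])
  tab_post <- filter_age_range(table, post[1], post[2])
  if (!nrow(tab_pre) || !nrow(tab_post)) stop("empty age window")
  scan_pre <- interaction_scan(tab_pre, phenotypes, covariates,
                               smooth_covariates, alpha, f2_threshold, k,
                               engine = engine)
  scan_post <- interaction_scan(tab_post, phenotypes, covariates,
                                smooth_covariates, alpha, f2_threshold, k,
                                engine = engine)
  d <- scan_pre$f2_sex - scan_post$f2_sex
  d <- d[!is.na(d)]
  wp <- if (!length(d) || all(d == 0)) 1 else {
    suppressWarnings(stats::wilcox.test(scan_pre$f2_sex, scan_post$f2_sex,
                                        paired = TRUE)$p.value)
  }
  structure(list(pre = scan_pre, post = scan_post, wilcoxon_p = wp,
                 windows = list(pre = pre, post = post)),
            class = "leaveout_result")
}

#' @export
print.leaveout_result <- function(x, ...) {
  cat("Menopause leave-out: ages", paste(x$windows$pre, collapse = "-"),
      "vs", paste(x$windows$post, collapse = "-"), "\n")
  cat("  age-dependent pre:",
      sum(x$pre$category == "age_dependent_sex_difference", na.rm = TRUE),
      " post:",
      sum(x$post$category == "age_dependent_sex_difference", na.rm = TRUE),
      "\n  paired Wilcoxon on sex f^2: p =",
      format(x$wilcoxon_p, digits = 3), "\n")
  invisible(x)
}

#' Refit trajectories separately within strata
#'
#' Fits the full interaction model independently in each stratum (for
#' example medication users vs nonusers) and returns per-stratum fitted
#' sex-specific trajectories for overlay comparison. Strata with fewer than
#' `min_n` rows are skipped with a warning.
#'
#' @param table Phenotype table.
#' @param phenotype Phenotype column.
#' @param strata Name of a factor/logical column defining the strata.
#' @param covariates,smooth_covariates,k,engine As in [interaction_scan()].
#' @param min_n Minimum stratum size (default 50).
#' @param grid_points Ages per trajectory (default 100).
#' @return Named list per retained stratum: `fit`, `trajectory` (data.frame
#'   `age`, `sex`, `fit`, `se`, `lwr`, `upr`) and `n`.
#' @export
stratified_refit <- function(table, phenotype, strata,
                             covariates = character(0),
                             smooth_covariates = character(0),
                             min_n = 50, grid_points = 100, k = 10,
                             engine = c("auto", "gam", "bam")) {
  if (!strata %in% names(table)) stop("stratum column '", strata, "' not found")
  levels_found <- unique(stats::na.omit(table[[strata]]))
  out <- list()
  for (lev in levels_found) {
    sub <- table[!is.na(table[[strata]]) & table[[strata]] == lev, ,
                 drop = FALSE]
    if (nrow(sub) < min_n) {
      warning("stratum '", lev, "' has ", nrow(sub), " rows (< ", min_n,
              "); skipped")
      next
    }
    fit <- fit_gam(gam_spec(phenotype, covariates = covariates,
                            smooth_covariates = smooth_covariates, k = k),
                   sub, engine = engine)
    ages <- seq(min(sub$age, na.rm = TRUE), max(sub$age, na.rm = TRUE),
                length.out = grid_points)
    nd <- reference_newdata(fit, sub, ages)
    pred <- predict_gam(fit, nd)
    out[[as.character(lev)]] <- list(
      fit = fit,
      trajectory = cbind(nd[, c("age", "sex")], pred),
      n = nrow(sub))
  }
  out
}

# Prediction frame over an age grid for both sexes, with covariates held at
# the median (continuous) or reference/modal level (factors, logicals).
reference_newdata <- function(fit, table, ages) {
  nd <- expand.grid(age = ages, sex = factor(c("M", "F"), levels = c("M", "F")),
                    KEEP.OUT.ATTRS = FALSE)
  covs <- setdiff(setdiff(all.vars(fit$spec$formula)[-1], ".sexo"),
                  c("age", "sex"))
  for (cv in covs) {
    x <- table[[cv]]
    nd[[cv]] <- if (is.numeric(x)) {
      stats::median(x, na.rm = TRUE)
    } else if (is.logical(x)) {
      FALSE
    } else {
      fx <- factor(x)
      factor(levels(fx)[1], levels = levels(fx))
    }
  }
  nd
}
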