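# Penalized-spline additive models for age-by-sex trajectory analysis.
#
# Model structure, following the ordered-factor coding convention for
# factor-smooth interactions:
#
#   phenotype ~ sex + s(age) + s(age, by = sex_ordered) + covariates
#
# where s(age) is the age smooth shared by both sexes and the by-smooth is
# the female deviation from it (male is the reference level), whose
# significance tests the age-by-sex interaction. Smooths are cubic P-splines
# with a second-order difference penalty; smoothing parameters are selected
# by (f)REML. Large fits are routed through mgcv::bam with discretized
# covariates, which is numerically equivalent at these problem sizes but much
# faster.

#' Build a centered cubic P-spline basis
#'
#' Cubic B-splines on `k` equally spaced knots spanning the data range, with
#' a second-order difference penalty on the coefficients, reparameterized to
#' absorb the sum-to-zero identifiability constraint (columns of the
#' constrained basis sum to zero; `k - 1` columns remain).
#'
#' @param x Numeric vector with at least `k` distinct values.
#' @param k Number of unconstrained basis functions (>= 4).
#' @return An object of class `spline_basis` with elements `X` (constrained
#'   basis at `x`), `S` (constrained penalty, rank `k - 2`), `knots`, `k`,
#'   `Z` (constraint null-space basis), `S_raw` and a closure-free evaluator
#'   via [eval_spline_basis()].
#' @export
build_spline_basis <- function(x, k = 10) {
  if (k < 4) stop("k must be >= 4 for a cubic spline basis")
  ux <- unique(x[!is.na(x)])
  if (length(ux) < k) stop("need at least k distinct x values")
  rng <- range(ux)
  dx <- diff(rng) / (k - 3)
  knots <- rng[1] + (-3:k) * dx
  X_raw <- splines::splineDesign(knots, x, ord = 4)
  D <- diff(diag(k), differences = 2)
  S_raw <- crossprod(D)
  cons <- colSums(X_raw)
  Z <- qr.Q(qr(matrix(cons, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  structure(
    list(X = X_raw %*% Z, S = t(Z) %*% S_raw %*% Z, knots = knots, k = k,
         Z = Z, S_raw = S_raw, range = rng),
    class = "spline_basis"
  )
}

#' Evaluate a spline basis at new points
#'
#' @param basis A [build_spline_basis()] object.
#' @param x Points inside the basis range.
#' @return Constrained basis matrix (`length(x)` by `k - 1`).
#' @export
eval_spline_basis <- function(basis, x) {
  if (any(x < basis$range[1] | x > basis$range[2])) {
    stop("x outside the basis range")
  }
  splines::splineDesign(basis$knots, x, ord = 4) %*% basis$Z
}

#' Specify a penalized-spline additive model
#'
#' @param response Name of the response column.
#' @param family `"gaussian"` or `"binomial"` (logit link).
#' @param sex Include the parametric sex level shift (reference male).
#' @param age_smooth Include the shared age smooth `s(age)`.
#' @param interaction Include the female deviation smooth
#'   `s(age, by = ordered(sex))`, testing the age-by-sex interaction.
#'   Requires `age_smooth`.
#' @param covariates Parametric (linear) covariate names.
#' @param smooth_covariates Covariates entering through their own P-spline
#'   smooth (for example a nonlinear BMI adjustment).
#' @param k Basis dimension per smooth (default 10; reported in summaries).
#' @param extra_terms Additional raw formula terms (character), appended
#'   verbatim; used by the lifestyle and event-scan models.
#' @return An object of class `gam_spec`.
#' @export
gam_spec <- function(response, family = c("gaussian", "binomial"),
                     sex = TRUE, age_smooth = TRUE, interaction = TRUE,
                     covariates = character(0),
                     smooth_covariates = character(0),
                     k = 10, extra_terms = character(0)) {
  family <- match.arg(family)
  if (interaction && !age_smooth) {
    stop("a by-sex deviation smooth requires the shared age smooth")
  }
  if (k < 4) stop("k must be >= 4")
  terms <- character(0)
  if (sex) terms <- c(terms, "sex")
  terms <- c(terms, covariates)
  if (age_smooth) terms <- c(terms, sprintf('s(age, bs = "ps", k = %d)', k))
  if (interaction) {
    terms <- c(terms, sprintf('s(age, by = .sexo, bs = "ps", k = %d)', k))
  }
  terms <- c(terms,
             sprintf('s(%s, bs = "ps", k = %d)', smooth_covariates, k),
             extra_terms)
  if (!length(terms)) terms <- "1"
  fml <- stats::reformulate(terms, response = response)
  structure(list(response = response, family = family, sex = sex,
                 age_smooth = age_smooth, interaction = interaction,
                 covariates = covariates,
                 smooth_covariates = smooth_covariates, k = k,
                 extra_terms = extra_terms, formula = fml),
            class = "gam_spec")
}

#' @export
print.gam_spec <- function(x, ...) {
  cat("gam_spec [", x$family, "]: ", deparse(x$formula), "\n", sep = "")
  invisible(x)
}

# Prepare the model frame: coerce sex to factor with male reference, add the
# ordered-sex helper column for by-smooths, keep complete cases on the
# variables the spec uses.
prepare_model_frame <- function(spec, table) {
  vars <- intersect(all.vars(spec$formula), names(table))
  missing_vars <- setdiff(setdiff(all.vars(spec$formula), ".sexo"),
                          names(table))
  if (length(missing_vars)) {
    stop("missing column(s): ", paste(missing_vars, collapse = ", "))
  }
  df <- table[, vars, drop = FALSE]
  if ("sex" %in% names(df)) {
    if (!is.factor(df$sex)) df$sex <- factor(df$sex, levels = c("M", "F"))
    df$sex <- droplevels(df$sex)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if ("sex" %in% names(df)) {
    df$.sexo <- ordered(as.character(df$sex), levels = c("M", "F"))
  }
  df
}

#' Fit a penalized-spline additive model
#'
#' Gaussian models use restricted maximum likelihood for smoothness
#' selection; binomial models use penalized IRLS with (f)REML. Fits on more
#' than `bam_threshold` rows use `mgcv::bam` with covariate discretization.
#'
#' @param spec A [gam_spec()].
#' @param table Phenotype table (see [read_phenotype_table()]).
#' @param select Add a shrinkage penalty on each smooth's null space so whole
#'   terms can be penalized out (used by the lifestyle and event models).
#' @param engine `"auto"`, `"gam"` or `"bam"`.
#' @param bam_threshold Row count above which `"auto"` picks `bam`.
#' @param sp Optional fixed smoothing-parameter vector (one per penalty);
#'   `sp = 0` turns a smooth's penalty off (used by equivalence oracles).
#' @return An object of class `gam_fit` wrapping the mgcv fit.
#' @export
fit_gam <- function(spec, table, select = FALSE,
                    engine = c("auto", "gam", "bam"), bam_threshold = 3000,
                    sp = NULL) {
  stopifnot(inherits(spec, "gam_spec"))
  engine <- match.arg(engine)
  df <- prepare_model_frame(spec, table)
  if (!nrow(df)) stop("no complete cases for model variables")
  if (spec$sex && length(unique(df$sex)) < 2) {
    stop("sex term requested but the table contains a single sex")
  }
  fam <- if (spec$family == "binomial") stats::binomial() else stats::gaussian()
  use_bam <- engine == "bam" || (engine == "auto" && nrow(df) > bam_threshold)
  model <- if (use_bam) {
    mgcv::bam(spec$formula, data = df, family = fam, method = "fREML",
              discrete = TRUE, select = select, sp = sp)
  } else {
    mgcv::gam(spec$formula, data = df, family = fam, method = "REML",
              select = select, sp = sp)
  }
  if (!model$converged) {
    stop("penalized likelihood fit did not converge for ", spec$response)
  }
  structure(list(model = model, spec = spec, n = nrow(df),
                 engine = if (use_bam) "bam" else "gam"),
            class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("gam_fit [", x$spec$family, ", ", x$engine, "]: ",
      deparse(x$spec$formula), "\n  n = ", x$n,
      ", R2 = ", signif(explained_r2(x), 4), "\n", sep = "")
  invisible(x)
}

#' Predict from a fitted model with pointwise standard errors
#'
#' @param fit A [fit_gam()] result.
#' @param newdata Data frame of covariate values; `sex` must use the training
#'   coding. Ages beyond the training range are allowed but flagged with a
#'   warning (spline extrapolation).
#' @param type `"response"` (default) or `"link"`.
#' @param level Confidence level for the pointwise interval (default 0.95,
#'   i.e. +/- 1.96 standard errors).
#' @param warn_extrapolation Warn when `newdata` ages fall outside the
#'   training range (default `TRUE`; cross-validation internals disable it).
#' @return data.frame with columns `fit`, `se`, `lwr`, `upr`.
#' @export
predict_gam <- function(fit, newdata, type = c("response", "link"),
                        level = 0.95, warn_extrapolation = TRUE) {
  stopifnot(inherits(fit, "gam_fit"))
  type <- match.arg(type)
  needed <- setdiff(all.vars(fit$spec$formula)[-1], ".sexo")
  missing_vars <- setdiff(needed, names(newdata))
  missing_vars <- setdiff(missing_vars, fit$spec$response)
  if (length(missing_vars)) {
    stop("newdata lacks covariate(s): ", paste(missing_vars, collapse = ", "))
  }
  if ("sex" %in% names(newdata)) {
    if (!is.factor(newdata$sex)) {
      newdata$sex <- factor(newdata$sex, levels = c("M", "F"))
    }
    newdata$.sexo <- ordered(as.character(newdata$sex), levels = c("M", "F"))
  }
  if (warn_extrapolation && "age" %in% names(newdata)) {
    tr <- range(fit$model$model$age %||% newdata$age)
    if (any(newdata$age < tr[1] | newdata$age > tr[2])) {
      warning("predicting beyond the training age range")
    }
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (type == "response" && fit$spec$family == "binomial") {
    # compute on link scale, back-transform the interval
    pr <- stats::predict(fit$model, newdata = newdata, type = "link",
                         se.fit = TRUE, newdata.guaranteed = FALSE)
    eta <- as.numeric(pr$fit); se_eta <- as.numeric(pr$se.fit)
    mu <- stats::plogis(eta)
    data.frame(fit = mu,
               se = se_eta * mu * (1 - mu),
               lwr = stats::plogis(eta - z * se_eta),
               upr = stats::plogis(eta + z * se_eta))
  } else {
    pr <- stats::predict(fit$model, newdata = newdata, type = type,
                         se.fit = TRUE)
    f <- as.numeric(pr$fit); s <- as.numeric(pr$se.fit)
    data.frame(fit = f, se = s, lwr = f - z * s, upr = f + z * s)
  }
}

#' P-value of a smooth term
#'
#' Wald-type test of the penalized coefficients of a smooth (mgcv's
#' `summary.gam` test, using the Bayesian posterior covariance at the
#' estimated effective degrees of freedom).
#'
#' @param fit A [fit_gam()] result.
#' @param term Either the mgcv smooth label (e.g. `"s(age)"`,
#'   `"s(age):.sexoF"`) or one of the shorthands `"age"` (shared age smooth)
#'   and `"interaction"` (female deviation smooth).
#' @return p-value in (0, 1]; a smooth penalized to effectively zero degrees
#'   of freedom returns 1 with a warning.
#' @export
smooth_term_pvalue <- function(fit, term = "interaction") {
  stopifnot(inherits(fit, "gam_fit"))
  st <- summary(fit$model)$s.table
  if (is.null(st) || !nrow(st)) stop("model has no smooth terms")
  label <- switch(term,
                  age = "s(age)",
                  interaction = "s(age):.sexoF",
                  term)
  row <- match(label, rownames(st))
  if (is.na(row)) {
    stop("smooth term '", term, "' not found; available: ",
         paste(rownames(st), collapse = ", "))
  }
  edf <- st[row, "edf"]
  p <- st[row, ncol(st)]
  if (is.na(p) || edf < 1e-3) {
    warning("smooth '", label, "' penalized to ~0 edf; returning p = 1")
    return(1)
  }
  max(min(p, 1), .Machine$double.xmin)
}

#' Effective degrees of freedom of a smooth term
#' @inheritParams smooth_term_pvalue
#' @return Effective degrees of freedom.
#' @export
smooth_term_edf <- function(fit, term = "interaction") {
  st <- summary(fit$model)$s.table
  label <- switch(term, age = "s(age)", interaction = "s(age):.sexoF", term)
  row <- match(label, rownames(st))
  if (is.na(row)) stop("smooth term '", term, "' not found")
  unname(st[row, "edf"])
}

#' Proportion of variance (or deviance) explained
#'
#' Gaussian models: `1 - RSS/TSS` on the response scale. Binomial models: the
#' deviance-explained analogue `1 - D/D0`.
#'
#' @param fit A [fit_gam()] result.
#' @return Value in `[0, 1]` (clamped at 0 against numeric noise).
#' @export
explained_r2 <- function(fit) {
  stopifnot(inherits(fit, "gam_fit"))
  m <- fit$model
  if (fit$spec$family == "gaussian") {
    y <- m$y
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) stop("response has zero variance")
    max(0, 1 - sum(stats::residuals(m, type = "response")^2) / tss)
  } else {
    d0 <- m$null.deviance
    if (d0 <= 0) stop("null deviance is zero")
    max(0, 1 - stats::deviance(m) / d0)
  }
}

#' Compare two model specifications by cross-validated MSE
#'
#' Both specifications are fitted on the same seeded fold assignment
#' (stratified by sex so every training fold contains both sexes) and scored
#' by mean squared error on the held-out rows.
#'
#' @param spec_a,spec_b Two [gam_spec()]s for the same response.
#' @param table Phenotype table.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Named numeric vector `c(mse_a = , mse_b = )`.
#' @export
cv_mse_compare <- function(spec_a, spec_b, table, folds = 10, seed = 1L) {
  stopifnot(inherits(spec_a, "gam_spec"), inherits(spec_b, "gam_spec"),
            spec_a$response == spec_b$response)
  vars <- union(setdiff(all.vars(spec_a$formula), ".sexo"),
                setdiff(all.vars(spec_b$formula), ".sexo"))
  df <- table[stats::complete.cases(table[, vars, drop = FALSE]), ,
              drop = FALSE]
  n <- nrow(df)
  if (folds > n) stop("more folds than rows")
  fold <- make_cv_folds(df$sex %||% rep("M", n), folds, seed)
  score <- function(spec) {
    sq <- numeric(0)
    for (f in seq_len(folds)) {
      fit <- fit_gam(spec, df[fold != f, , drop = FALSE])
      pred <- predict_gam(fit, df[fold == f, , drop = FALSE],
                          type = "response", warn_extrapolation = FALSE)
      sq <- c(sq, (df[[spec$response]][fold == f] - pred$fit)^2)
    }
    mean(sq)
  }
  c(mse_a = score(spec_a), mse_b = score(spec_b))
}

# Sex-stratified fold assignment: within each sex, cycle fold labels over a
# random permutation, so each fold has both sexes in near-equal proportion.
make_cv_folds <- function(sex, folds, seed) {
  set.seed(seed)
  fold <- integer(length(sex))
  for (lev in unique(sex)) {
    idx <- which(sex == lev)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold
}

#' Serialize a fit to a JSON-ready summary list
#'
#' @param fit A [fit_gam()] result.
#' @return List with family, formula, n, coefficients, smoothing parameters,
#'   per-smooth edf and p-values, and explained variance.
#' @export
gam_fit_summary <- function(fit) {
  s <- summary(fit$model)
  list(family = fit$spec$family, formula = deparse(fit$spec$formula),
       n = fit$n, k = fit$spec$k,
       coefficients = as.list(stats::coef(fit$model)[
         seq_len(nrow(s$p.table))]),
       smoothing_parameters = as.list(fit$model$sp),
       smooth_terms = if (!is.null(s$s.table)) {
         stats::setNames(
           lapply(seq_len(nrow(s$s.table)), function(i) {
             list(edf = s$s.table[i, "edf"], p = s$s.table[i, ncol(s$s.table)])
           }), rownames(s$s.table))
       },
       r2 = explained_r2(fit))
}
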