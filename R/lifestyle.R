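# Lifestyle-by-age-by-sex interaction modeling and the longitudinal
# new-onset event scan.
#
# Continuous lifestyle factors enter through six smooth terms each: a shared
# factor smooth, a shared factor-by-age interaction smooth, per-sex factor
# deviation smooths (2) and per-sex factor-by-age deviation smooths (2);
# binary factors enter parametrically with a sex interaction and an
# age-smooth per level. Whole-term selection uses the double-penalty
# shrinkage approach (an extra penalty on each smooth's null space), with a
# term counted as selected when its Wald p-value is below 0.05.

#' Fit the lifestyle interaction model for one phenotype
#'
#' `phenotype ~ sex + s(age) + s(age, by = sex) + lifestyle terms`, with the
#' six-term structure per continuous factor (see the module description) and
#' null-space shrinkage (`select = TRUE`) so that irrelevant terms can be
#' penalized out entirely.
#'
#' @param table Phenotype table.
#' @param phenotype Response column.
#' @param continuous_factors Continuous lifestyle factor columns (e.g. diet
#'   quality, stress, physical activity, alcohol, sleep duration scores).
#' @param binary_factors Binary factor columns (e.g. current smoking,
#'   medication usage).
#' @param k Basis dimension for univariate smooths (default 10); tensor
#'   interaction smooths use 5 basis functions per margin.
#' @param engine Passed to [fit_gam()].
#' @return List of class `lifestyle_fit`: `fit` (the [fit_gam()] result) and
#'   `selection` (data.frame: `term`, `type`, `edf` (smooths), `p`,
#'   `selected`).
#' @export
fit_lifestyle_model <- function(table, phenotype,
                                continuous_factors = character(0),
                                binary_factors = character(0),
                                k = 10,
                                engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  for (f in c(continuous_factors, binary_factors)) {
    if (!f %in% names(table)) stop("factor column '", f, "' not found")
  }
  table <- table
  extra <- character(0)
  for (f in continuous_factors) {
    extra <- c(extra,
               sprintf('s(%s, bs = "ps", k = %d)', f, k),
               sprintf('ti(%s, age, bs = "ps", k = c(5, 5))', f),
               sprintf('s(%s, by = sex, bs = "ps", k = %d)', f, k),
               sprintf('ti(%s, age, by = sex, bs = "ps", k = c(5, 5))', f))
  }
  covars <- character(0)
  for (f in binary_factors) {
    if (!is.factor(table[[f]])) table[[f]] <- factor(table[[f]])
    covars <- c(covars, f, paste0(f, ":sex"))
    extra <- c(extra, sprintf('s(age, by = %s, bs = "ps", k = %d)', f, k))
  }
  spec <- gam_spec(phenotype, covariates = covars, k = k,
                   extra_terms = extra)
  fit <- fit_gam(spec, table, select = TRUE, engine = engine)
  structure(list(fit = fit, selection = selection_table(fit)),
            class = "lifestyle_fit")
}

#' Term-level p-values and selection flags of a penalized fit
#'
#' @param fit A [fit_gam()] result (typically fitted with `select = TRUE`).
#' @param threshold Selection threshold on the per-term p-value (default
#'   0.05).
#' @return data.frame: `term`, `type` (`"parametric"` or `"smooth"`), `edf`
#'   (`NA` for parametric terms), `p`, `selected`.
#' @export
selection_table <- function(fit, threshold = 0.05) {
  s <- summary(fit$model)
  rows <- list()
  pt <- s$p.table
  keep <- rownames(pt) != "(Intercept)"
  if (any(keep)) {
    rows$param <- data.frame(term = rownames(pt)[keep], type = "parametric",
                             edf = NA_real_, p = pt[keep, ncol(pt)],
                             stringsAsFactors = FALSE)
  }
  if (!is.null(s$s.table) && nrow(s$s.table)) {
    st <- s$s.table
    rows$smooth <- data.frame(term = rownames(st), type = "smooth",
                              edf = st[, "edf"], p = st[, ncol(st)],
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$selected <- !is.na(out$p) & out$p < threshold
  rownames(out) <- NULL
  out
}

#' @export
print.lifestyle_fit <- function(x, ...) {
  cat("Lifestyle interaction model:", x$fit$spec$response, "\n")
  sel <- x$selection[x$selection$selected, "term"]
  cat("  selected terms (p < 0.05):",
      if (length(sel)) paste(sel, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Bootstrap stability of lifestyle term selection
#'
#' Refits the lifestyle model on `B` bootstrap resamples (rows drawn with
#' replacement, resample size n) and reports, per term, the fraction of
#' resamples in which it was selected (p < 0.05 under the penalization
#' approach).
#'
#' @inheritParams fit_lifestyle_model
#' @param B Number of bootstrap resamples (default 50).
#' @param seed Integer seed; resamples use named substreams so results are
#'   reproducible.
#' @return data.frame: `term`, `frequency`, `B_effective` (resamples whose
#'   fit succeeded).
#' @export
bootstrap_stability <- function(table, phenotype,
                                continuous_factors = character(0),
                                binary_factors = character(0),
                                B = 50, seed = 1L, k = 10,
                                engine = c("auto", "gam", "bam")) {
  if (B < 1) stop("B must be >= 1")
  engine <- match.arg(engine)
  counts <- NULL
  ok <- 0L
  for (b in seq_len(B)) {
    set.seed(substream_seed(seed, paste0("bootstrap", b)))
    idx <- sample.int(nrow(table), replace = TRUE)
    res <- tryCatch(
      fit_lifestyle_model(table[idx, , drop = FALSE], phenotype,
                          continuous_factors, binary_factors, k = k,
                          engine = engine)$selection,
      error = function(e) NULL)
    if (is.null(res)) {
      warning("bootstrap resample ", b, " failed; skipped")
      next
    }
    ok <- ok + 1L
    sel <- stats::setNames(as.integer(res$selected), res$term)
    counts <- if (is.null(counts)) sel else counts + sel[names(counts)]
  }
  if (ok == 0L) stop("all bootstrap fits failed")
  data.frame(term = names(counts), frequency = unname(counts) / ok,
             B_effective = ok, stringsAsFactors = FALSE)
}

#' Scan baseline phenotypes for association with new-onset events
#'
#' After excluding prevalent cases, users of the named medication classes and
#' rows with missing outcome, fits per phenotype a penalized logistic model
#'
#' `event ~ sex + phenotype + phenotype:sex + s(age) + s(age, by = sex) +
#'  s(age, by = phenotype) + s(age, by = phenotype x female)`
#'
#' testing the phenotype main effect and its two- and three-way interactions
#' with age and sex. P-values are Bonferroni-adjusted across the scanned
#' panel, per term.
#'
#' @param table Baseline phenotype table with an event column.
#' @param phenotypes Phenotype columns to scan (the Bonferroni family).
#' @param event Event column name (0/1 or logical), default `"event"`.
#' @param prevalent Optional logical column flagging prevalent cases at
#'   baseline (excluded).
#' @param medication Optional character vector of logical medication-flag
#'   columns; flagged users are excluded.
#' @param k Spline basis dimension (default 10).
#' @param engine Passed to [fit_gam()]; defaults to `bam` above the usual
#'   threshold.
#' @return data.frame of class `cvd_scan`, one row per phenotype with raw and
#'   adjusted p-values for the main effect, phenotype-by-age,
#'   phenotype-by-sex and phenotype-by-age-by-sex terms, a `separation` flag,
#'   and exclusion counts in `attr(, "exclusions")`.
#' @export
cvd_onset_scan <- function(table, phenotypes, event = "event",
                           prevalent = NULL, medication = character(0),
                           k = 10, engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  if (!event %in% names(table)) stop("event column '", event, "' not found")
  n_input <- nrow(table)
  n_prev <- 0L
  if (!is.null(prevalent)) {
    flag <- isTRUE_vec(table[[prevalent]])
    n_prev <- sum(flag)
    table <- table[!flag, , drop = FALSE]
  }
  n_med <- 0L
  if (length(medication)) {
    flag <- Reduce(`|`, lapply(medication, function(m) isTRUE_vec(table[[m]])))
    n_med <- sum(flag)
    table <- table[!flag, , drop = FALSE]
  }
  miss <- is.na(table[[event]])
  n_missing <- sum(miss)
  table <- table[!miss, , drop = FALSE]
  exclusions <- list(n_input = n_input, n_prevalent = n_prev,
                     n_medication = n_med, n_missing_outcome = n_missing,
                     n_baseline = nrow(table))
  ev <- as.integer(table[[event]])
  if (sum(ev) == 0L) stop("zero events after exclusion")
  if (all(ev == 1L)) stop("no event-free participants after exclusion")

  extra <- c(sprintf('s(age, by = .ph, bs = "ps", k = %d)', k),
             sprintf('s(age, by = .phF, bs = "ps", k = %d)', k))
  rows <- lapply(phenotypes, function(ph) {
    out <- data.frame(phenotype = ph, n = NA_integer_, n_events = NA_integer_,
                      p_main = NA_real_, p_age = NA_real_, p_sex = NA_real_,
                      p_age_sex = NA_real_, separation = FALSE,
                      error = NA_character_, stringsAsFactors = FALSE)
    tryCatch({
      df <- table[!is.na(table[[ph]]), , drop = FALSE]
      df$.event <- as.integer(df[[event]])
      df$.ph <- df[[ph]]
      df$.phF <- df[[ph]] * (df$sex == "F")
      spec <- gam_spec(".event", family = "binomial",
                       covariates = c(".ph", ".ph:sex"),
                       k = k, extra_terms = extra)
      sep_flag <- FALSE
      fit <- withCallingHandlers(
        fit_gam(spec, df, select = TRUE, engine = engine),
        warning = function(w) {
          if (grepl("fitted (probabilities|rates)", conditionMessage(w))) {
            sep_flag <<- TRUE
            invokeRestart("muffleWarning")
          }
        })
      s <- summary(fit$model)
      pt <- s$p.table; st <- s$s.table
      out$n <- fit$n
      out$n_events <- sum(df$.event)
      out$p_main <- row_p(pt, ".ph")
      out$p_sex <- row_p(pt, c(".ph:sexF", "sexF:.ph"))
      out$p_age <- row_p(st, "s(age):.ph")
      out$p_age_sex <- row_p(st, "s(age):.phF")
      out$separation <- sep_flag
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  m <- length(phenotypes)
  for (col in c("p_main", "p_age", "p_sex", "p_age_sex")) {
    res[[paste0(col, "_adj")]] <- pmin(res[[col]] * m, 1)
  }
  attr(res, "exclusions") <- exclusions
  class(res) <- c("cvd_scan", "data.frame")
  res
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

# first matching row's p-value (last column), NA if none present
row_p <- function(tab, candidates) {
  for (nm in candidates) {
    if (!is.null(tab) && nm %in% rownames(tab)) return(tab[nm, ncol(tab)])
  }
  NA_real_
}
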