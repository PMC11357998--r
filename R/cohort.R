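# Synthetic cohort generation with known ground truth.
#
# Every downstream analysis in the package (interaction gating, changepoint
# localization, leave-out comparison, variance decomposition, lifestyle
# selection, event scan) is validated against cohorts generated here, where
# the true sex offsets, age-by-sex interactions, changepoints and
# lifestyle/event effects are known exactly.

#' Describe the ground-truth trajectory of one synthetic phenotype
#'
#' A trajectory is built from a male baseline mean function of age, a static
#' female offset, an optional female age-dependent deviation (the age-by-sex
#' interaction), and an optional sigmoidal changepoint (a smooth step such as
#' the menopause-window jump seen in clinical blood markers). Gaussian
#' phenotypes add homoscedastic or age-dependent noise; Bernoulli phenotypes
#' interpret the assembled trajectory as a log-odds surface and draw through
#' the logistic link, so means always lie in (0, 1).
#'
#' @param name Column name of the phenotype in the generated table.
#' @param family `"gaussian"` or `"bernoulli"`.
#' @param base_fn Function of age giving the male mean (gaussian) or male
#'   log-odds (bernoulli).
#' @param sex_offset Constant added for females.
#' @param interaction_fn Function of age added for females, or `NULL` for no
#'   age-by-sex interaction.
#' @param changepoint Optional list with elements `center_age`, `half_width`
#'   (> 0, years), `jump` (phenotype units) and `sex` (`"female"`, `"male"` or
#'   `"both"`). The jump enters as `jump * plogis((age - center)/half_width)`,
#'   a smooth sigmoidal step, for the targeted sex.
#' @param noise_sd Gaussian noise standard deviation (>= 0); either a single
#'   number or a function of age (heteroscedastic noise). Ignored for
#'   Bernoulli phenotypes.
#' @param lifestyle_effects Optional named list mapping lifestyle factor names
#'   to functions `f(age, sex, level)` returning the additive contribution of
#'   that factor to the trajectory (log-odds scale for Bernoulli phenotypes).
#'
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(name,
                            family = c("gaussian", "bernoulli"),
                            base_fn = function(age) rep(0, length(age)),
                            sex_offset = 0,
                            interaction_fn = NULL,
                            changepoint = NULL,
                            noise_sd = 1,
                            lifestyle_effects = NULL) {
  family <- match.arg(family)
  stopifnot(is.character(name), length(name) == 1L, is.function(base_fn))
  if (!is.null(changepoint)) {
    needed <- c("center_age", "half_width", "jump")
    if (!all(needed %in% names(changepoint))) {
      stop("changepoint must provide center_age, half_width and jump")
    }
    if (changepoint$half_width <= 0) stop("changepoint half_width must be > 0")
    changepoint$sex <- match.arg(changepoint$sex %||% "female",
                                 c("female", "male", "both"))
  }
  if (is.numeric(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(name = name, family = family, base_fn = base_fn,
         sex_offset = sex_offset, interaction_fn = interaction_fn,
         changepoint = changepoint, noise_sd = noise_sd,
         lifestyle_effects = lifestyle_effects),
    class = "trajectory_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground-truth mean of a synthetic phenotype at given ages
#'
#' Evaluates the noiseless trajectory: `base_fn(age)` for males, plus
#' `sex_offset + interaction_fn(age)` for females, plus the sigmoidal
#' changepoint step for the targeted sex. For Bernoulli phenotypes the result
#' is mapped through the logistic link and is the event probability.
#'
#' @param spec A [trajectory_spec()].
#' @param age Numeric vector of ages (years).
#' @param sex Character/factor vector (`"F"`/`"M"`), recycled against `age`.
#' @param age_range Allowed closed age interval; ages outside it are an error.
#'
#' @return Numeric vector of means (probabilities for Bernoulli).
#' @export
trajectory_mean <- function(spec, age, sex, age_range = c(20, 80)) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (any(age < age_range[1] | age > age_range[2])) {
    stop("age outside the configured range [", age_range[1], ", ",
         age_range[2], "]")
  }
  lp <- trajectory_linpred(spec, age, sex)
  if (spec$family == "bernoulli") stats::plogis(lp) else lp
}

# Linear-predictor-scale trajectory (identity scale for gaussian, log-odds
# for bernoulli), without lifestyle contributions.
trajectory_linpred <- function(spec, age, sex) {
  n <- max(length(age), length(sex))
  age <- rep_len(age, n)
  female <- rep_len(as.character(sex), n) %in% c("F", "f", "female", "Female")
  lp <- spec$base_fn(age)
  lp <- rep_len(lp, n)
  if (any(female)) {
    lp[female] <- lp[female] + spec$sex_offset
    if (!is.null(spec$interaction_fn)) {
      lp[female] <- lp[female] + spec$interaction_fn(age[female])
    }
  }
  cp <- spec$changepoint
  if (!is.null(cp)) {
    hit <- switch(cp$sex, female = female, male = !female,
                  both = rep(TRUE, n))
    step <- cp$jump * stats::plogis((age - cp$center_age) / cp$half_width)
    lp[hit] <- lp[hit] + step[hit]
  }
  lp
}

#' Describe a synthetic cohort
#'
#' @param n Number of participants.
#' @param trajectories List of [trajectory_spec()] objects (at least one).
#' @param female_fraction Proportion of women, in (0, 1). Default 0.58,
#'   a typical female share in volunteer population cohorts.
#' @param age_range Closed age interval sampled, default 20--80 years.
#' @param age_distribution `"uniform"` over the range, or `"thinned_tails"`,
#'   a piecewise-linear density with lower mass below 30 and above 70,
#'   resembling the age pyramid of adult population biobanks.
#' @param lifestyle_factors Optional named list of sampler functions
#'   `f(n, age, sex)` returning a numeric or logical column per factor.
#' @param medication_flags Optional named list of functions `f(age, sex)`
#'   returning per-row probabilities of carrying the (boolean) flag.
#' @param seed Integer root seed; together with the configuration it fully
#'   determines the generated cohort. Per-column substreams are derived from
#'   the root seed and the column name, so adding a phenotype does not
#'   perturb the draws of existing columns.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, trajectories, female_fraction = 0.58,
                          age_range = c(20, 80),
                          age_distribution = c("uniform", "thinned_tails"),
                          lifestyle_factors = NULL,
                          medication_flags = NULL,
                          seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  if (length(trajectories) == 0L) stop("at least one trajectory is required")
  if (inherits(trajectories, "trajectory_spec")) trajectories <- list(trajectories)
  stopifnot(n >= 1, female_fraction > 0, female_fraction < 1,
            length(age_range) == 2L, age_range[1] < age_range[2])
  ok <- vapply(trajectories, inherits, logical(1), "trajectory_spec")
  if (!all(ok)) stop("trajectories must be a list of trajectory_spec objects")
  names(trajectories) <- vapply(trajectories, `[[`, character(1), "name")
  if (anyDuplicated(names(trajectories))) stop("duplicated phenotype names")
  structure(
    list(n = as.integer(n), female_fraction = female_fraction,
         age_range = age_range, age_distribution = age_distribution,
         trajectories = trajectories,
         lifestyle_factors = lifestyle_factors,
         medication_flags = medication_flags, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Deterministic 31-bit hash of a string, used to derive independent
# per-column seeds from the root seed.
string_hash <- function(x) {
  h <- 0
  for (code in utf8ToInt(x)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

substream_seed <- function(root, name) {
  as.integer((as.double(root) * 48271 + string_hash(name)) %% 2147483647)
}

#' Generate a synthetic cohort
#'
#' Draws sex, age, lifestyle factors, medication flags and every phenotype
#' described in the configuration, and returns both the participant table and
#' a ground-truth manifest recording every effect that was planted.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `data` (a
#'   data.frame: `id`, `sex` (factor, reference `"M"`), `age`, then lifestyle,
#'   medication and phenotype columns) and `truth` (the manifest).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n

  withr_seed <- function(name, expr) {
    set.seed(substream_seed(config$seed, name))
    expr
  }

  sex <- withr_seed("sex", factor(
    ifelse(stats::runif(n) < config$female_fraction, "F", "M"),
    levels = c("M", "F")
  ))
  age <- withr_seed("age", sample_ages(n, config$age_range,
                                       config$age_distribution))
  tab <- data.frame(id = sprintf("P%06d", seq_len(n)), sex = sex, age = age,
                    stringsAsFactors = FALSE)

  lifestyle <- list()
  for (nm in names(config$lifestyle_factors)) {
    tab[[nm]] <- withr_seed(paste0("lifestyle.", nm),
                            config$lifestyle_factors[[nm]](n, age, sex))
    lifestyle[[nm]] <- "sampled"
  }
  for (nm in names(config$medication_flags)) {
    p <- config$medication_flags[[nm]](age, sex)
    tab[[nm]] <- withr_seed(paste0("medication.", nm),
                            stats::runif(n) < rep_len(p, n))
  }

  truth <- list(seed = config$seed, n = n,
                female_fraction = config$female_fraction,
                age_range = config$age_range, phenotypes = list())
  for (spec in config$trajectories) {
    lp <- trajectory_linpred(spec, age, sex)
    for (fac in names(spec$lifestyle_effects)) {
      if (is.null(tab[[fac]])) {
        stop("lifestyle effect refers to unknown factor '", fac, "'")
      }
      lp <- lp + spec$lifestyle_effects[[fac]](age, sex, tab[[fac]])
    }
    tab[[spec$name]] <- withr_seed(paste0("phenotype.", spec$name), {
      if (spec$family == "gaussian") {
        sd_vec <- if (is.function(spec$noise_sd)) spec$noise_sd(age) else spec$noise_sd
        lp + stats::rnorm(n, sd = rep_len(sd_vec, n))
      } else {
        as.integer(stats::runif(n) < stats::plogis(lp))
      }
    })
    truth$phenotypes[[spec$name]] <- list(
      family = spec$family,
      sex_offset = spec$sex_offset,
      has_interaction = !is.null(spec$interaction_fn),
      changepoint = spec$changepoint,
      noise_sd = if (is.function(spec$noise_sd)) "age-dependent" else spec$noise_sd,
      lifestyle_effects = names(spec$lifestyle_effects)
    )
  }

  structure(list(data = tab, truth = truth), class = "synthetic_cohort")
}

sample_ages <- function(n, range, distribution) {
  if (distribution == "uniform") {
    return(stats::runif(n, range[1], range[2]))
  }
  # thinned tails: trapezoid density, half weight below (min + 10) and above
  # (max - 10) relative to the middle plateau
  lo <- range[1]; hi <- range[2]
  mid_lo <- min(lo + 10, hi); mid_hi <- max(hi - 10, lo)
  u <- stats::runif(n)
  ages <- numeric(n)
  # piecewise-constant density with weights 0.5 / 1 / 0.5 on the three pieces
  w <- c(0.5 * (mid_lo - lo), 1 * (mid_hi - mid_lo), 0.5 * (hi - mid_hi))
  w <- w / sum(w)
  cw <- cumsum(w)
  piece <- findInterval(u, c(0, cw[1], cw[2]))
  frac <- (u - c(0, cw)[piece]) / w[piece]
  lows <- c(lo, mid_lo, mid_hi)[piece]
  highs <- c(mid_lo, mid_hi, hi)[piece]
  ages <- lows + frac * (highs - lows)
  ages
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$data), "participants,",
      length(x$truth$phenotypes), "phenotypes\n")
  cat("  female fraction:", round(mean(x$data$sex == "F"), 3),
      " age range:", paste(round(range(x$data$age), 1), collapse = "-"), "\n")
  invisible(x)
}

#' Describe a follow-up event process
#'
#' Participants experience a single binary event over a fixed horizon with
#' probability `plogis(intercept + sum of effects)`, where effects are linear
#' in named baseline phenotype columns, optionally in age and sex, and in
#' named interaction products.
#'
#' @param intercept Baseline log-odds of an event over the horizon.
#' @param effects Named numeric vector of per-unit log-odds coefficients for
#'   baseline phenotype columns.
#' @param age_coef,sex_coef Optional log-odds coefficients for age (per year)
#'   and female sex.
#' @param horizon Follow-up horizon in years (metadata only), default 10.
#' @return An object of class `followup_spec`.
#' @export
followup_spec <- function(intercept = -4, effects = numeric(0),
                          age_coef = 0, sex_coef = 0, horizon = 10) {
  structure(list(intercept = intercept, effects = effects,
                 age_coef = age_coef, sex_coef = sex_coef, horizon = horizon),
            class = "followup_spec")
}

#' Draw follow-up events for a cohort table
#'
#' @param table A participant data.frame with `age`, `sex` and the phenotype
#'   columns named in the spec.
#' @param spec A [followup_spec()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return A list with `event` (integer 0/1 vector, one per row) and `truth`
#'   (the coefficients used).
#' @export
generate_followup <- function(table, spec, seed = 1L) {
  stopifnot(inherits(spec, "followup_spec"))
  missing_cols <- setdiff(names(spec$effects), names(table))
  if (length(missing_cols)) {
    stop("unknown phenotype(s) in followup spec: ",
         paste(missing_cols, collapse = ", "))
  }
  lp <- rep(spec$intercept, nrow(table))
  for (nm in names(spec$effects)) lp <- lp + spec$effects[[nm]] * table[[nm]]
  lp <- lp + spec$age_coef * table$age + spec$sex_coef * (table$sex == "F")
  p <- pmin(pmax(stats::plogis(lp), 0), 1)
  set.seed(substream_seed(seed, "followup"))
  event <- as.integer(stats::runif(nrow(table)) < p)
  list(event = event,
       truth = list(intercept = spec$intercept, effects = spec$effects,
                    age_coef = spec$age_coef, sex_coef = spec$sex_coef,
                    horizon = spec$horizon))
}

#' Write a synthetic cohort to disk
#'
#' Writes the participant table as TSV and the ground-truth manifest as JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "cohort.tsv")
  json <- file.path(dir, "truth.json")
  utils::write.table(cohort$data, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(table = tsv, manifest = json))
}
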