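# Canned simulation scenarios.
#
# Each scenario encodes one data-generating condition exercised by the
# validation suite: fully null panels for calibration, linear crossover
# interactions sized by their population Cohen's f^2, a menopause-window
# sigmoidal step in women only, features with analytic variance shares,
# a male-only diet-by-age lifestyle effect, and a phenotype-driven 10-year
# event process. Effect sizes are fixed here, once, so that every test and
# the validation script run under identical conditions.
#
# Sizing notes (age uniform on 20-80, so var(age) = 300; female fraction p):
# * a linear female deviation b*(age-50) adds residual variance
#   p*(1-p)*b^2*300 beyond the sex + shared-smooth model, so its population
#   Cohen's f^2 against unit noise is ~73*b^2 at p = 0.58; b = 0.02 gives
#   f^2 ~ 0.03.
# * orthogonalized components a*(F-p), c*(age-50), b*(age-50)*(F-p) have
#   variances 0.2436*a^2, 300*c^2 and 73.1*b^2, giving exact population
#   explained-variance shares when total variance is normalized to 1.

#' Build a predefined synthetic scenario
#'
#' @param name One of `"null_panel"`, `"gate_panel"`, `"crossover"`,
#'   `"menopause_step"`, `"variance_shares"`, `"lifestyle_interaction"`,
#'   `"event_followup"`, `"demo"`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param ... Scenario-specific overrides, see Details.
#'
#' @details
#' * `null_panel`: `n_phenotypes` (default 20) independent unit-noise
#'   phenotypes with no sex, age or interaction effect.
#' * `gate_panel`: `n_null` (20) null phenotypes plus `n_signal` (5)
#'   crossover phenotypes with female deviation `slope*(age-50)`
#'   (`slope = 0.02`, population interaction f^2 of about 0.03 at unit
#'   noise), each also carrying a static female offset of 0.3.
#' * `crossover`: a single crossover phenotype (same parameterization).
#' * `menopause_step`: one phenotype with a male linear age trend and, in
#'   women only, a sigmoidal step of height `jump` (default 0.8 noise SDs)
#'   centered at `center` (50 y) with half-width 2.5 y, plus one null
#'   phenotype; mimics the clinical blood markers that shift across the
#'   menopause window.
#' * `variance_shares`: one feature with exact population variance shares
#'   `sex_share` (0.20), `age_share` (0.10), `interaction_share` (0.03),
#'   remainder noise; plus one pure-noise feature.
#' * `lifestyle_interaction`: phenotype with a diet-by-age effect in men
#'   only (`b = 0.3` per diet SD per 30 y of age), with null lifestyle
#'   factors `stress` and `activity` alongside `diet`.
#' * `event_followup`: `n_phenotypes` (default 1) standard-normal baseline
#'   phenotypes; a binary 10-year event with log-odds
#'   `intercept + coef * phenotype1` (`intercept = -4`, about 2% events;
#'   `coef = 0.8`; `coef = 0` gives a fully null event panel).
#' * `demo`: a small mixed cohort used by the package documentation: one
#'   crossover lipid-like phenotype, one menopause-step electrolyte-like
#'   phenotype, one static-offset phenotype, one null phenotype, a diet
#'   score with a male-only age-modified effect, a medication flag and a
#'   follow-up event.
#'
#' @return A `synthetic_cohort`; for event scenarios the data contains an
#'   `event` column and the manifest a `followup` entry.
#' @export
cohort_scenario <- function(name, n, seed = 1L, ...) {
  opts <- list(...)
  switch(
    name,
    null_panel = {
      k <- opts$n_phenotypes %||% 20L
      specs <- lapply(seq_len(k), function(i) {
        trajectory_spec(sprintf("null%02d", i))
      })
      generate_cohort(cohort_config(n, specs, seed = seed))
    },
    gate_panel = {
      n_null <- opts$n_null %||% 20L
      n_signal <- opts$n_signal %||% 5L
      slope <- opts$slope %||% 0.02
      specs <- c(
        lapply(seq_len(n_null), function(i) {
          trajectory_spec(sprintf("null%02d", i))
        }),
        lapply(seq_len(n_signal), function(i) {
          trajectory_spec(sprintf("cross%02d", i), sex_offset = 0.3,
                          interaction_fn = function(a) slope * (a - 50))
        })
      )
      generate_cohort(cohort_config(n, specs, seed = seed))
    },
    crossover = {
      slope <- opts$slope %||% 0.02
      spec <- trajectory_spec("crossover", sex_offset = opts$sex_offset %||% 0.3,
                              interaction_fn = function(a) slope * (a - 50))
      generate_cohort(cohort_config(n, list(spec), seed = seed))
    },
    menopause_step = {
      jump <- opts$jump %||% 0.8
      center <- opts$center %||% 50
      specs <- list(
        trajectory_spec("marker",
                        base_fn = function(a) 0.01 * (a - 50),
                        changepoint = list(center_age = center,
                                           half_width = 2.5, jump = jump,
                                           sex = "female")),
        trajectory_spec("null01")
      )
      generate_cohort(cohort_config(n, specs, seed = seed))
    },
    variance_shares = {
      shares <- list(sex = opts$sex_share %||% 0.20,
                     age = opts$age_share %||% 0.10,
                     inter = opts$interaction_share %||% 0.03)
      p <- 0.58
      a <- sqrt(shares$sex / (p * (1 - p)))
      cc <- sqrt(shares$age / 300)
      b <- sqrt(shares$inter / (300 * p * (1 - p)))
      noise <- sqrt(1 - shares$sex - shares$age - shares$inter)
      spec <- trajectory_spec(
        "feature",
        base_fn = function(age) -a * p + (cc - b * p) * (age - 50),
        sex_offset = a,
        interaction_fn = function(age) b * (age - 50),
        noise_sd = noise
      )
      generate_cohort(cohort_config(
        n, list(spec, trajectory_spec("noisefeat")), seed = seed))
    },
    lifestyle_interaction = {
      b <- opts$effect %||% 0.3
      null_sampler <- function(n, age, sex) stats::rnorm(n)
      spec <- trajectory_spec(
        "phenotype",
        base_fn = function(a) 0.01 * (a - 50),
        sex_offset = 0.2,
        lifestyle_effects = list(
          diet = function(age, sex, level) {
            ifelse(sex == "M", b * level * (age - 50) / 30, 0)
          }
        )
      )
      generate_cohort(cohort_config(
        n, list(spec),
        lifestyle_factors = list(diet = null_sampler, stress = null_sampler,
                                 activity = null_sampler),
        seed = seed))
    },
    event_followup = {
      coef <- opts$coef %||% 0.8
      k <- opts$n_phenotypes %||% 1L
      intercept <- opts$intercept %||% -4
      specs <- lapply(seq_len(k), function(i) {
        trajectory_spec(sprintf("pheno%02d", i))
      })
      cohort <- generate_cohort(cohort_config(n, specs, seed = seed))
      fs <- followup_spec(intercept = intercept,
                          effects = if (coef != 0) c(pheno01 = coef) else numeric(0))
      fu <- generate_followup(cohort$data, fs, seed = seed)
      cohort$data$event <- fu$event
      cohort$truth$followup <- fu$truth
      cohort
    },
    demo = {
      specs <- list(
        trajectory_spec("lipid", base_fn = function(a) 0.015 * (a - 50),
                        sex_offset = -0.4,
                        interaction_fn = function(a) 0.025 * (a - 50),
                        noise_sd = 1,
                        lifestyle_effects = list(
                          diet = function(age, sex, level) {
                            ifelse(sex == "M", 0.25 * level * (age - 50) / 30, 0)
                          })),
        trajectory_spec("electrolyte",
                        base_fn = function(a) 0.005 * (a - 50),
                        changepoint = list(center_age = 50, half_width = 2.5,
                                           jump = 0.8, sex = "female")),
        trajectory_spec("static", sex_offset = 0.6),
        trajectory_spec("null01")
      )
      cohort <- generate_cohort(cohort_config(
        n, specs,
        lifestyle_factors = list(diet = function(n, age, sex) stats::rnorm(n)),
        medication_flags = list(
          lipid_med = function(age, sex) stats::plogis((age - 65) / 5) * 0.4),
        seed = seed))
      fu <- generate_followup(cohort$data,
                              followup_spec(intercept = -4.2,
                                            effects = c(lipid = 0.6),
                                            age_coef = 0.02),
                              seed = seed)
      cohort$data$event <- fu$event
      cohort$truth$followup <- fu$truth
      cohort
    },
    stop("unknown scenario '", name, "'")
  )
}
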