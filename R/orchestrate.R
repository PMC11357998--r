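# Config-driven end-to-end runs.
#
# A run configuration (R list or YAML file) names the input (a table on disk
# or a simulation scenario), the preprocessing lists, the phenotype panels
# (each its own Bonferroni family) and the stages to execute. Results are
# written as tidy TSVs plus a JSON manifest; re-running an identical config
# reproduces identical tables.

#' Load a run configuration from YAML
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Validate a run configuration
#'
#' Checks the configuration against the input table without mutating either,
#' collecting every problem found rather than stopping at the first.
#'
#' @param config Configuration list (see [run_full_analysis()]).
#' @param table Optional pre-loaded table; otherwise the configured input is
#'   read / simulated for column checks.
#' @return Character vector of problems; empty when runnable.
#' @export
validate_config <- function(config, table = NULL) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$input) && is.null(config$simulate)) {
    add("config needs either 'input' (a table path) or 'simulate'")
  }
  if (!is.null(config$input) && !file.exists(config$input)) {
    add(paste0("input file not found: ", config$input))
  }
  ar <- config$age_range %||% c(20, 80)
  if (length(ar) != 2 || ar[1] >= ar[2]) add("age_range must be [lo, hi] with lo < hi")
  if (is.null(config$panels) || !length(config$panels)) {
    add("at least one phenotype panel is required")
  } else {
    for (nm in names(config$panels)) {
      if (!length(config$panels[[nm]])) {
        add(paste0("panel '", nm, "' is empty (Bonferroni family size 0)"))
      }
    }
  }
  if (is.null(table)) {
    table <- tryCatch(load_input(config), error = function(e) NULL)
  }
  if (!is.null(table)) {
    referenced <- unique(c(unlist(config$panels), config$covariates,
                           config$smooth_covariates,
                           config$lifestyle$continuous_factors,
                           config$lifestyle$binary_factors,
                           config$cvd$phenotypes, config$cvd$event,
                           config$preprocess$log_phenotypes))
    missing_cols <- setdiff(referenced, names(table))
    for (col in missing_cols) {
      add(paste0("referenced column not in table: ", col))
    }
  } else if (is.null(config$input) || file.exists(config$input %||% "")) {
    add("input table could not be loaded for column validation")
  }
  problems
}

load_input <- function(config) {
  if (!is.null(config$input)) {
    read_phenotype_table(config$input,
                         sex_col = config$schema$sex_col %||% "sex",
                         age_col = config$schema$age_col %||% "age")
  } else {
    sim <- config$simulate
    do.call(cohort_scenario,
            c(list(name = sim$scenario, n = sim$n,
                   seed = sim$seed %||% config$seed %||% 1L),
              sim$args %||% list()))$data
  }
}

#' Run the full analysis pipeline
#'
#' Executes, as toggled in `config$stages` (default all applicable):
#' preprocessing, the per-panel interaction scan, changepoint localization,
#' the menopause leave-out, variance decomposition + trajectory clustering,
#' the lifestyle interaction model and the new-onset event scan. Fails fast
#' on configuration errors; per-phenotype fit failures are recorded in the
#' stage tables and do not abort the run.
#'
#' @param config Configuration list or YAML path. Recognized entries:
#'   `input` / `simulate`, `schema`, `preprocess` (`phenotypes`,
#'   `log_phenotypes`, `z_features`), `age_range`, `panels`, `covariates`,
#'   `smooth_covariates`, `stages`, `changepoint`, `leaveout`, `variance`
#'   (`features`, `folds`, `repeats`, `n_clusters`), `lifestyle`
#'   (`phenotype`, `continuous_factors`, `binary_factors`, `B`), `cvd`
#'   (`event`, `phenotypes`, `prevalent`, `medication`), `seed`, `k`.
#' @param out_dir Output directory for the report bundle.
#' @return List of class `report_bundle`: per-stage results and the paths of
#'   the files written.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    writeLines(msg, log_con)
    message(msg)
  }
  seed <- config$seed %||% 1L
  k <- config$k %||% 10
  stages <- config$stages %||% c("preprocess", "sexdiff", "changepoint",
                                 "leaveout", "variance", "cluster")
  ar <- config$age_range %||% c(20, 80)
  covs <- config$covariates %||% character(0)
  scovs <- config$smooth_covariates %||% character(0)

  results <- list()
  paths <- character(0)
  emit <- function(name, df) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }

  say("loading input")
  table <- load_input(config)
  all_phenos <- unique(unlist(config$panels))

  if ("preprocess" %in% stages) {
    say("preprocessing ", length(all_phenos), " phenotypes")
    pp <- preprocess_phenotypes(
      table, all_phenos,
      log_phenotypes = config$preprocess$log_phenotypes %||% character(0),
      age_lo = ar[1], age_hi = ar[2],
      z_features = config$preprocess$z_features %||% character(0))
    table <- pp$table
    results$preprocess <- pp$report
    emit("preprocess_report", pp$report)
  }

  if ("sexdiff" %in% stages) {
    scans <- list()
    for (panel in names(config$panels)) {
      say("interaction scan: panel '", panel, "' (",
          length(config$panels[[panel]]), " phenotypes)")
      sc <- interaction_scan(table, config$panels[[panel]], covs, scovs,
                             k = k)
      sc$panel <- panel
      scans[[panel]] <- sc
    }
    results$sexdiff <- do.call(rbind, scans)
    emit("sexdiff_scan", results$sexdiff)
  }

  if ("changepoint" %in% stages) {
    cp_phenos <- config$changepoint$phenotypes %||% all_phenos
    say("sliding-window changepoint scan: ", length(cp_phenos), " phenotypes")
    traces <- list()
    for (ph in cp_phenos) {
      for (sx in c("F", "M")) {
        tr <- tryCatch(
          sliding_changepoint(table, ph, sx,
                              half_window = config$changepoint$half_window %||% 5,
                              min_n = config$changepoint$min_n %||% 30),
          error = function(e) NULL)
        if (!is.null(tr) && nrow(tr$trace)) {
          traces[[paste(ph, sx)]] <- cbind(phenotype = ph, sex = sx, tr$trace)
        }
      }
    }
    results$changepoint <- do.call(rbind, traces)
    if (!is.null(results$changepoint)) emit("changepoint_trace", results$changepoint)
  }

  if ("leaveout" %in% stages) {
    say("menopause leave-out")
    lo <- menopause_leaveout(table, all_phenos, covs, scovs, k = k)
    results$leaveout <- lo
    pre <- lo$pre; pre$window <- "pre"
    post <- lo$post; post$window <- "post"
    emit("leaveout_scan", rbind(pre, post))
  }

  if ("variance" %in% stages || "cluster" %in% stages) {
    feats <- config$variance$features %||% all_phenos
    if ("variance" %in% stages) {
      say("variance decomposition: ", length(feats), " features")
      decs <- lapply(feats, function(ft) {
        tryCatch(variance_decomposition(
          table, ft, covs, scovs,
          folds = config$variance$folds %||% 5,
          repeats = config$variance$repeats %||% 10,
          seed = seed, k = k), error = function(e) NULL)
      })
      names(decs) <- feats
      results$variance <- decs
    }
    say("fitting trajectories for clustering")
    traj <- fit_trajectories(table, feats, covs, scovs, k = k)
    hc <- upgma_cluster(traj)
    results$trajectories <- traj
    results$cluster <- hc
    export_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    paths <- c(paths, file.path(out_dir, "dendrogram.nwk"))
    emit("cluster_summary",
         cluster_summary_table(hc, config$variance$n_clusters %||%
                                 min(4, nrow(traj$matrix)),
                               results$variance))
  }

  if ("lifestyle" %in% stages) {
    lf <- config$lifestyle
    say("lifestyle interaction model: ", lf$phenotype)
    lfit <- fit_lifestyle_model(table, lf$phenotype,
                                lf$continuous_factors %||% character(0),
                                lf$binary_factors %||% character(0), k = k)
    results$lifestyle <- lfit
    emit("lifestyle_selection", lfit$selection)
    if (!is.null(lf$B) && lf$B > 0) {
      say("bootstrap stability (B = ", lf$B, ")")
      bs <- bootstrap_stability(table, lf$phenotype,
                                lf$continuous_factors %||% character(0),
                                lf$binary_factors %||% character(0),
                                B = lf$B, seed = seed, k = k)
      results$bootstrap <- bs
      emit("lifestyle_bootstrap", bs)
    }
  }

  if ("cvd_onset" %in% stages) {
    cv <- config$cvd
    say("new-onset event scan: ", length(cv$phenotypes), " phenotypes")
    sc <- cvd_onset_scan(table, cv$phenotypes, event = cv$event %||% "event",
                         prevalent = cv$prevalent,
                         medication = cv$medication %||% character(0), k = k)
    results$cvd <- sc
    emit("cvd_onset_scan", sc)
  }

  manifest <- list(seed = seed, k = k, stages = stages,
                   panels = config$panels,
                   package_version = as.character(utils::packageVersion("sexspan")),
                   config_hash = config_digest(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(out_dir, "manifest.json"), log_path)
  say("done: ", length(paths), " files in ", out_dir)
  structure(list(results = results, paths = paths, manifest = manifest),
            class = "report_bundle")
}

# stable hash of the configuration (order-normalized serialization)
config_digest <- function(config) {
  ser <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          force = TRUE)
  h <- 0
  for (code in utf8ToInt(as.character(ser))) h <- (h * 131 + code) %% 2147483647
  sprintf("%010d", h)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Report bundle:", length(x$paths), "files\n")
  cat(paste(" ", x$paths, collapse = "\n"), "\n")
  invisible(x)
}
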