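# Reading and preprocessing of phenotype tables.
#
# Preprocessing order is fixed: selective log-transform first, then 3-IQR
# outlier removal on the whole (sex- and age-pooled) distribution, then the
# age-range filter. z-scaling is applied only to omics-style panels, after
# the steps above.

#' Read a tidy phenotype table
#'
#' @param path TSV or CSV file (separator chosen from the extension, override
#'   with `sep`).
#' @param sex_col,age_col,id_col Column names for sex, age and participant id.
#' @param phenotypes Optional character vector of phenotype columns to type as
#'   numeric; unknown names are an error.
#' @param sex_levels Two-level coding of the sex column, reference level
#'   first. Default `c("M", "F")` (male reference).
#' @param sep Field separator, default inferred from the file extension.
#' @return A data.frame with `sex` as a factor (reference level first) and
#'   numeric `age`; all other columns preserved in their original order.
#' @export
read_phenotype_table <- function(path, sex_col = "sex", age_col = "age",
                                 id_col = "id", phenotypes = NULL,
                                 sex_levels = c("M", "F"), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(sex_col, age_col)) {
    if (!col %in% names(tab)) stop("required column '", col, "' not found")
  }
  sex_raw <- tab[[sex_col]]
  # a column containing only "F" (or "T") parses as logical; undo that
  if (is.logical(sex_raw)) sex_raw <- ifelse(sex_raw, "T", "F")
  sex_raw <- as.character(sex_raw)
  bad <- !is.na(sex_raw) & !sex_raw %in% sex_levels
  if (any(bad)) {
    stop("sex values outside {", paste(sex_levels, collapse = ", "),
         "}: ", paste(utils::head(unique(sex_raw[bad]), 3), collapse = ", "))
  }
  tab[[sex_col]] <- factor(sex_raw, levels = sex_levels)
  age <- suppressWarnings(as.numeric(tab[[age_col]]))
  if (any(is.na(age) & !is.na(tab[[age_col]]))) {
    stop("non-numeric values in age column '", age_col, "'")
  }
  tab[[age_col]] <- age
  keep <- !is.na(tab[[sex_col]]) & !is.na(tab[[age_col]])
  if (!all(keep)) {
    message("dropping ", sum(!keep), " rows with missing sex or age")
    tab <- tab[keep, , drop = FALSE]
  }
  for (ph in phenotypes) {
    if (!ph %in% names(tab)) stop("phenotype column '", ph, "' not found")
    tab[[ph]] <- suppressWarnings(as.numeric(tab[[ph]]))
  }
  rownames(tab) <- NULL
  tab
}

#' Write a phenotype table as TSV
#' @param table data.frame to write.
#' @param path Output path.
#' @export
write_phenotype_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Natural-log transform selected phenotype columns
#'
#' Right-skewed phenotypes are log-transformed before any outlier handling.
#' Listed columns must be strictly positive on their non-missing values.
#'
#' @param table Phenotype table.
#' @param phenotypes Character vector of columns to transform (may be empty).
#' @return The table with listed columns replaced by their natural log.
#' @export
apply_log_transform <- function(table, phenotypes) {
  for (ph in phenotypes) {
    if (!ph %in% names(table)) stop("column '", ph, "' not found")
    x <- table[[ph]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive value in '", ph, "' at row ", bad[1],
           "; log transform undefined")
    }
    table[[ph]] <- log(x)
  }
  table
}

#' Keep-mask under the 3-IQR extreme-outlier rule
#'
#' Values more than three interquartile ranges below the first quartile or
#' above the third quartile are flagged as extreme outliers. Quartiles are
#' computed on the whole vector, pooling sexes and ages, with the
#' linear-interpolation convention (`stats::quantile` type 7). Missing values
#' get `FALSE` in the mask but are not counted as outliers.
#'
#' @param values Numeric vector with at least 4 non-missing values.
#' @return Logical keep-mask, same length as `values`, with attribute
#'   `n_outliers`.
#' @export
outlier_mask <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values missing")
  if (sum(ok) < 4) stop("need at least 4 non-missing values")
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - 3 * iqr
  hi <- q[2] + 3 * iqr
  keep <- ok & values >= lo & values <= hi
  keep[is.na(keep)] <- FALSE
  attr(keep, "n_outliers") <- sum(ok) - sum(keep)
  keep
}

#' Filter a table to a closed age interval
#'
#' @param table Phenotype table with an age column.
#' @param lo,hi Closed interval bounds (defaults 20 and 80 years, the range
#'   where adult population cohorts have adequate sample size).
#' @param age_col Age column name.
#' @return The filtered table; a warning is raised if no rows remain.
#' @export
filter_age_range <- function(table, lo = 20, hi = 80, age_col = "age") {
  if (lo >= hi) stop("lo must be < hi")
  out <- table[!is.na(table[[age_col]]) &
                 table[[age_col]] >= lo & table[[age_col]] <= hi, ,
               drop = FALSE]
  if (nrow(out) == 0L) warning("age filter removed all rows")
  rownames(out) <- NULL
  out
}

#' z-scale feature columns to mean 0, SD 1
#'
#' Used for omics panels so that features on different scales contribute
#' comparably to distances and variance summaries.
#'
#' @param table Phenotype table.
#' @param features Columns to scale.
#' @return The table with listed columns standardized (sample SD, computed on
#'   non-missing rows).
#' @export
z_scale <- function(table, features) {
  for (ft in features) {
    if (!ft %in% names(table)) stop("column '", ft, "' not found")
    x <- table[[ft]]
    s <- stats::sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("zero-variance feature '", ft, "'")
    table[[ft]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

#' Run the full preprocessing pipeline
#'
#' Applies, in order: natural-log transform of the listed right-skewed
#' phenotypes, 3-IQR extreme-outlier removal per phenotype (outlying values
#' are set to missing so that each downstream model uses its own complete
#' cases), and the closed age-range filter. Returns the table together with a
#' reconciliation report.
#'
#' @param table Phenotype table (see [read_phenotype_table()]).
#' @param phenotypes Phenotype columns to preprocess.
#' @param log_phenotypes Subset of `phenotypes` to log-transform first.
#' @param age_lo,age_hi Age filter bounds (closed interval).
#' @param z_features Optional columns to z-scale after filtering (omics
#'   panels).
#' @return A list of class `preprocess_result`: `table` and `report` (one row
#'   per phenotype: `n_input`, `log_transformed`, `n_missing`, `n_outliers`,
#'   `n_retained`), plus `n_age_filtered`.
#' @export
preprocess_phenotypes <- function(table, phenotypes,
                                  log_phenotypes = character(0),
                                  age_lo = 20, age_hi = 80,
                                  z_features = character(0)) {
  stopifnot(all(log_phenotypes %in% phenotypes))
  table <- apply_log_transform(table, log_phenotypes)
  rep_rows <- vector("list", length(phenotypes))
  for (i in seq_along(phenotypes)) {
    ph <- phenotypes[i]
    x <- table[[ph]]
    if (is.null(x)) stop("phenotype column '", ph, "' not found")
    n_missing <- sum(is.na(x))
    n_out <- 0L
    if (sum(!is.na(x)) >= 4 && !all(x == x[!is.na(x)][1], na.rm = TRUE)) {
      keep <- outlier_mask(x)
      n_out <- attr(keep, "n_outliers")
      x[!keep] <- NA
      table[[ph]] <- x
    }
    rep_rows[[i]] <- data.frame(
      phenotype = ph, n_input = length(x),
      log_transformed = ph %in% log_phenotypes,
      n_missing = n_missing, n_outliers = n_out,
      n_retained = length(x) - n_missing - n_out)
  }
  report <- do.call(rbind, rep_rows)
  n_before <- nrow(table)
  table <- filter_age_range(table, age_lo, age_hi)
  if (length(z_features)) table <- z_scale(table, z_features)
  structure(list(table = table, report = report,
                 n_age_filtered = n_before - nrow(table)),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("Preprocessing:", nrow(x$table), "rows retained (",
      x$n_age_filtered, "removed by age filter)\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
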