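# Omics-panel analyses: cross-validated nested-model variance attribution,
# PERMANOVA on the Euclidean distance matrix, trajectory prediction on a
# fixed age grid, and UPGMA clustering of sex-specific trajectories.

#' Cross-validated variance decomposition over nested models
#'
#' Fits four nested penalized-spline models -- covariates only, plus sex,
#' plus the shared age smooth, plus the by-sex deviation smooth -- and
#' attributes variance sequentially. Each model's explained fraction is the
#' squared Pearson correlation between held-out observations and predictions,
#' averaged over `folds` x `repeats` cross-validation (folds stratified by
#' sex). Small negative increments, possible under CV noise, are clipped to
#' zero and flagged.
#'
#' @param table Phenotype table.
#' @param feature Continuous feature column (z-scaled upstream for omics
#'   panels).
#' @param covariates,smooth_covariates Covariates of the base model.
#' @param folds,repeats CV scheme (defaults 5 and 10).
#' @param seed Integer seed for fold assignment.
#' @param k Spline basis dimension.
#' @param engine Passed to [fit_gam()].
#' @return List of class `variance_decomposition`: `explained` (per-model CV
#'   explained fractions), `increments` (named: `covariates`, `sex`, `age`,
#'   `interaction`), `clipped` (which increments were negative before
#'   clipping), and the CV scheme.
#' @export
variance_decomposition <- function(table, feature,
                                   covariates = character(0),
                                   smooth_covariates = character(0),
                                   folds = 5, repeats = 10, seed = 1L,
                                   k = 10,
                                   engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  has_cov <- length(covariates) || length(smooth_covariates)
  specs <- list(
    covariates = gam_spec(feature, sex = FALSE, age_smooth = FALSE,
                          interaction = FALSE, covariates = covariates,
                          smooth_covariates = smooth_covariates, k = k),
    sex = gam_spec(feature, sex = TRUE, age_smooth = FALSE,
                   interaction = FALSE, covariates = covariates,
                   smooth_covariates = smooth_covariates, k = k),
    age = gam_spec(feature, sex = TRUE, age_smooth = TRUE,
                   interaction = FALSE, covariates = covariates,
                   smooth_covariates = smooth_covariates, k = k),
    interaction = gam_spec(feature, sex = TRUE, age_smooth = TRUE,
                           interaction = TRUE, covariates = covariates,
                           smooth_covariates = smooth_covariates, k = k)
  )
  vars <- unique(unlist(lapply(specs, function(s) {
    setdiff(all.vars(s$formula), ".sexo")
  })))
  df <- table[stats::complete.cases(table[, vars, drop = FALSE]), ,
              drop = FALSE]
  if (nrow(df) < folds) stop("fewer rows than folds")
  scores <- matrix(NA_real_, nrow = folds * repeats, ncol = length(specs),
                   dimnames = list(NULL, names(specs)))
  row <- 0L
  for (r in seq_len(repeats)) {
    fold <- make_cv_folds(as.character(df$sex), folds,
                          substream_seed(seed, paste0("cvrep", r)))
    for (f in seq_len(folds)) {
      row <- row + 1L
      train <- df[fold != f, , drop = FALSE]
      test <- df[fold == f, , drop = FALSE]
      if (length(unique(train$sex)) < 2 || length(unique(test$sex)) < 2) {
        stop("cross-validation fold with a single sex; increase n")
      }
      for (m in names(specs)) {
        fit <- fit_gam(specs[[m]], train, engine = engine)
        pred <- predict_gam(fit, test, type = "response",
                            warn_extrapolation = FALSE)$fit
        obs <- test[[feature]]
        scores[row, m] <- if (stats::sd(pred) < 1e-12) 0 else
          stats::cor(obs, pred)^2
      }
    }
  }
  explained <- colMeans(scores)
  if (!has_cov) explained["covariates"] <- 0  # intercept-only base model
  inc <- c(covariates = unname(explained["covariates"]),
           diff(explained))
  clipped <- names(inc)[inc < 0]
  inc[inc < 0] <- 0
  structure(list(feature = feature, explained = explained,
                 increments = inc, clipped = clipped,
                 scheme = list(folds = folds, repeats = repeats, seed = seed)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition for", x$feature, "(", x$scheme$folds,
      "-fold CV x", x$scheme$repeats, ")\n")
  print(round(x$increments, 4))
  if (length(x$clipped)) {
    cat("  clipped negative increments:", paste(x$clipped, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' PERMANOVA on the Euclidean distance matrix
#'
#' Permutational multivariate analysis of variance with sequential
#' (terms-in-order) sum-of-squares decomposition of the Gower-centered
#' squared-distance matrix, pseudo-F statistics, and p-values from free
#' permutation of rows: `p = (1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param X Numeric samples-by-features matrix (or vector), no missing cells.
#' @param design data.frame of explanatory factors/covariates (one row per
#'   sample).
#' @param terms Term order (character); defaults to `names(design)`.
#'   Interactions may be given in formula notation, e.g. `"age:sex"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return data.frame of class `permanova_result` with one row per term plus
#'   `Residual` and `Total`: `df`, `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(X, design, terms = NULL, n_perm = 1000, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing cells")
  n <- nrow(X)
  if (is.null(terms)) terms <- names(design)
  stopifnot(nrow(design) == n, length(terms) >= 1)
  for (tm in terms) {
    for (v in all.vars(stats::as.formula(paste("~", tm)))) {
      x <- design[[v]]
      if (is.factor(x) || is.character(x) || is.logical(x)) {
        if (length(unique(x)) < 2) stop("term '", v, "' has a single level")
        if (min(table(x)) < 2) stop("term '", v, "' has a level with < 2 samples")
      }
    }
  }
  # Gower centering: G = C A C with A = -(1/2) d^2 and C = I - 11'/n
  d2 <- as.matrix(stats::dist(X))^2
  A <- -0.5 * d2
  rm_ <- rowMeans(A); cm_ <- colMeans(A); gm <- mean(A)
  G <- A - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12) stop("constant X: total sum of squares is zero")

  # sequential hat matrices
  hats <- vector("list", length(terms))
  dfs <- integer(length(terms))
  prev_rank <- 1L
  for (j in seq_along(terms)) {
    fml <- stats::as.formula(paste("~", paste(terms[seq_len(j)],
                                              collapse = " + ")))
    M <- stats::model.matrix(fml, data = design)
    qrM <- qr(M)
    Q <- qr.Q(qrM)[, seq_len(qrM$rank), drop = FALSE]
    hats[[j]] <- tcrossprod(Q)
    dfs[j] <- qrM$rank - prev_rank
    prev_rank <- qrM$rank
  }
  df_res <- n - prev_rank
  if (df_res < 1) stop("no residual degrees of freedom")

  decompose <- function(Gm) {
    tr_prev <- 0
    ss <- numeric(length(terms))
    for (j in seq_along(terms)) {
      tr_j <- sum(hats[[j]] * Gm)
      ss[j] <- tr_j - tr_prev
      tr_prev <- tr_j
    }
    ss_res <- sum(diag(Gm)) - tr_prev
    f <- (ss / dfs) / (ss_res / df_res)
    list(ss = ss, ss_res = ss_res, f = f)
  }

  obs <- decompose(G)
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (p in seq_len(n_perm)) {
    idx <- sample.int(n)
    fp <- decompose(G[idx, idx])$f
    exceed <- exceed + (fp >= obs$f - 1e-12)
  }
  pvals <- (1 + exceed) / (1 + n_perm)

  res <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(dfs, df_res, n - 1),
    SS = c(obs$ss, obs$ss_res, ss_total),
    R2 = c(obs$ss, obs$ss_res, ss_total) / ss_total,
    F = c(obs$f, NA, NA),
    p = c(pvals, NA, NA)
  )
  attr(res, "n_perm") <- n_perm
  class(res) <- c("permanova_result", "data.frame")
  res
}

#' Fitted sex-specific trajectories on a fixed age grid
#'
#' Fits the covariate-adjusted interaction model per feature and predicts at
#' `grid_points` ages for each sex, covariates held at the median (continuous)
#' or reference level (categorical). Features whose fit fails are dropped
#' with a warning.
#'
#' @param table Phenotype table.
#' @param features Feature columns (typically z-scaled).
#' @param covariates,smooth_covariates,k,engine As in [interaction_scan()].
#' @param grid_points Ages per sex (default 300).
#' @return Object of class `trajectory_matrix`: `matrix` (features x
#'   `2 * grid_points` fitted values, male block then female block), `grid`
#'   (the ages) and `sexes`.
#' @export
fit_trajectories <- function(table, features, covariates = character(0),
                             smooth_covariates = character(0),
                             grid_points = 300, k = 10,
                             engine = c("auto", "gam", "bam")) {
  engine <- match.arg(engine)
  ages <- seq(min(table$age, na.rm = TRUE), max(table$age, na.rm = TRUE),
              length.out = grid_points)
  rows <- list()
  for (ft in features) {
    row <- tryCatch({
      fit <- fit_gam(gam_spec(ft, covariates = covariates,
                              smooth_covariates = smooth_covariates, k = k),
                     table, engine = engine)
      nd <- reference_newdata(fit, table, ages)
      pred <- predict_gam(fit, nd)$fit
      # expand.grid cycles age fastest: rows 1..G are male, G+1..2G female
      pred
    }, error = function(e) {
      warning("dropping feature '", ft, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(row)) rows[[ft]] <- row
  }
  if (!length(rows)) stop("no feature could be fitted")
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(paste0("M_", signif(ages, 6)),
                     paste0("F_", signif(ages, 6)))
  structure(list(matrix = mat, grid = ages, sexes = c("M", "F")),
            class = "trajectory_matrix")
}

#' UPGMA clustering of trajectories
#'
#' Average-linkage agglomerative clustering of the Euclidean distances
#' between feature trajectories (or the rows of any numeric matrix).
#'
#' @param x A [fit_trajectories()] result, or a numeric matrix with one row
#'   per feature.
#' @return An `hclust` object (method `"average"`).
#' @export
upgma_cluster <- function(x) {
  mat <- if (inherits(x, "trajectory_matrix")) x$matrix else as.matrix(x)
  if (nrow(mat) < 2) stop("need at least 2 feature rows")
  bad <- rownames(mat)[!apply(is.finite(mat), 1, all)]
  if (length(bad)) {
    stop("non-finite trajectory values for: ", paste(bad, collapse = ", "))
  }
  stats::hclust(stats::dist(mat), method = "average")
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` object (e.g. from [upgma_cluster()]).
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
export_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Per-feature cluster and variance summary table
#'
#' Combines cluster assignments (tree cut at `k` groups) with per-feature
#' variance fractions, in a tidy table suitable for circular bar-plot tools.
#'
#' @param hc An `hclust` from [upgma_cluster()].
#' @param k Number of cluster groups.
#' @param decompositions Optional named list of [variance_decomposition()]
#'   results (names matching features).
#' @return data.frame: `feature`, `cluster`, and increment columns if
#'   decompositions are supplied.
#' @export
cluster_summary_table <- function(hc, k, decompositions = NULL) {
  cl <- stats::cutree(hc, k = k)
  out <- data.frame(feature = names(cl), cluster = unname(cl),
                    stringsAsFactors = FALSE)
  if (!is.null(decompositions)) {
    inc <- t(vapply(out$feature, function(ft) {
      d <- decompositions[[ft]]
      if (is.null(d)) rep(NA_real_, 4) else d$increments
    }, numeric(4)))
    colnames(inc) <- c("covariates", "sex", "age", "interaction")
    out <- cbind(out, inc)
  }
  rownames(out) <- NULL
  out
}
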