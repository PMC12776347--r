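#' Mean squared error against the true mixed effects
#'
#' Mean over (selected samples) x outcomes of `(theta_hat - theta)^2`.
#' Available in simulation only, where the true mixed effect is known.
#'
#' @param pred a `cmmp_predictions` object or a prediction matrix.
#' @param truth matrix of true mixed effects with matching dimensions.
#' @param subset optional logical/integer subset of samples (rows); default
#'   all.
#' @return scalar MSE.
#' @export
mse_vs_truth <- function(pred, truth, subset = NULL) {
  th <- if (inherits(pred, "cmmp_predictions")) pred$theta_hat else as.matrix(pred)
  truth <- as.matrix(truth)
  if (!all(dim(th) == dim(truth)))
    stop("prediction and truth dimensions differ", call. = FALSE)
  if (!is.null(subset)) {
    th <- th[subset, , drop = FALSE]
    truth <- truth[subset, , drop = FALSE]
  }
  if (nrow(th) == 0L) stop("empty sample subset", call. = FALSE)
  mean((th - truth)^2)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same samples,
#' corrected for chance; 1 for identical partitions (up to label
#' permutation).
#'
#' @param labels_a,labels_b label vectors of equal length (>= 2).
#' @return the ARI (scalar, at most 1).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length", call. = FALSE)
  if (length(labels_a) < 2L)
    stop("need at least two samples", call. = FALSE)
  mclust::adjustedRandIndex(labels_a, labels_b)
}

#' Test covariates for association with cluster membership
#'
#' One-way ANOVA F-test for numeric covariates and Pearson chi-squared for
#' categorical covariates, against the cluster labels; p-values are
#' Bonferroni-adjusted by the number of covariates tested (capped at 1).
#' Covariates constant in the data are flagged with `p = NA`.
#'
#' @param labels cluster label per sample (>= 2 distinct clusters).
#' @param covariates covariate data.frame (a `sample_id` column is ignored).
#' @return data.frame with columns `covariate`, `test`, `p_raw`, `p_adj`.
#' @export
cluster_covariate_tests <- function(labels, covariates) {
  stopifnot(is.data.frame(covariates))
  if (length(unique(labels)) < 2L)
    stop("need at least two clusters", call. = FALSE)
  cov <- covariates[setdiff(names(covariates), "sample_id")]
  if (nrow(cov) != length(labels))
    stop("labels and covariates differ in length", call. = FALSE)
  cl <- factor(labels)
  res <- lapply(names(cov), function(nm) {
    x <- cov[[nm]]
    if (is.numeric(x)) {
      if (stats::var(x) == 0)
        return(data.frame(covariate = nm, test = "anova_f", p_raw = NA_real_))
      p <- summary(stats::aov(x ~ cl))[[1]][["Pr(>F)"]][1]
      data.frame(covariate = nm, test = "anova_f", p_raw = p)
    } else {
      x <- factor(x)
      if (nlevels(droplevels(x)) < 2L)
        return(data.frame(covariate = nm, test = "chisq", p_raw = NA_real_))
      p <- suppressWarnings(stats::chisq.test(table(x, cl))$p.value)
      data.frame(covariate = nm, test = "chisq", p_raw = p)
    }
  })
  out <- do.call(rbind, res)
  n_tests <- sum(!is.na(out$p_raw))
  out$p_adj <- pmin(out$p_raw * n_tests, 1)
  out
}

#' Run one simulation replicate comparing the four predictors
#'
#' Generates a dataset, clusters the training methylation profiles with
#' k-means, fits the per-outcome mixed models under both the k-means labels
#' and the true labels (oracle), fits the OLS regression baseline, predicts
#' the test-set mixed effects under all four methods, and returns test MSE,
#' minority-restricted MSE (race != White), and train/test ARI against the
#' true clusters.
#'
#' @param config a [simulation_config()].
#' @param k number of clusters given to k-means (default `config$n_clusters`).
#' @param seed integer seed for this replicate.
#' @param n_init k-means restarts.
#' @return data.frame with one row per method: `method`, `mse`,
#'   `mse_minority`, `ari_train`, `ari_test`.
#' @export
run_replicate <- function(config, k = config$n_clusters, seed = 1L,
                          n_init = 10L) {
  ds <- generate_dataset(config, seed)
  tr <- ds$train; te <- !tr
  if (!any(te)) stop("empty test set", call. = FALSE)
  X <- ds$design$X
  Xtr <- X[tr, , drop = FALSE]
  design_tr <- structure(list(X = Xtr, encoding = ds$design$encoding),
                         class = "cmmp_design")
  design_te <- structure(list(X = X[te, , drop = FALSE],
                              encoding = ds$design$encoding),
                         class = "cmmp_design")
  Ytr <- ds$outcomes[tr, , drop = FALSE]
  Yte <- ds$outcomes[te, , drop = FALSE]
  theta_te <- ds$theta[te, , drop = FALSE]
  truth_tr <- ds$clusters[tr]
  truth_te <- ds$clusters[te]
  minority <- ds$covariates$race[te] != "White"

  km <- fit_kmeans(Ytr, k, seed = child_seed(seed, 1L), n_init = n_init)
  fits_km <- fit_all_outcomes(Ytr, design_tr, km$labels)
  fits_or <- fit_all_outcomes(Ytr, design_tr, truth_tr)
  fits_ols <- fit_ols(Ytr, design_tr)

  preds <- list(
    naive = predict_all(Yte, design_te, NULL, mode = "naive"),
    regression = predict_all(Yte, design_te, fits_ols, mode = "regression"),
    cmmp = predict_all(Yte, design_te, fits_km, mode = "cmmp"),
    oracle = predict_all(Yte, design_te, fits_or, mode = "oracle")
  )

  row <- function(method, pred, ari_train, ari_test) {
    data.frame(method = method,
               mse = mse_vs_truth(pred, theta_te),
               mse_minority = if (any(minority))
                 mse_vs_truth(pred, theta_te, minority) else NA_real_,
               ari_train = ari_train, ari_test = ari_test,
               stringsAsFactors = FALSE)
  }
  ari_or_test <- adjusted_rand_index(preds$oracle$consensus, truth_te)
  ari_km_test <- adjusted_rand_index(preds$cmmp$consensus, truth_te)
  ari_km_train <- adjusted_rand_index(km$labels, truth_tr)
  out <- rbind(
    row("naive", preds$naive, NA_real_, NA_real_),
    row("regression", preds$regression, NA_real_, NA_real_),
    row("cmmp", preds$cmmp, ari_km_train, ari_km_test),
    row("oracle", preds$oracle,
        adjusted_rand_index(truth_tr, truth_tr), ari_or_test)
  )
  rownames(out) <- NULL
  out
}

#' Run a one-parameter simulation grid
#'
#' Varies exactly one parameter (`b` the White fraction, `c` the true number
#' of clusters, `sigma` the random-intercept SD, or `k` the number of
#' clusters given to k-means) while holding the rest of `base_config` fixed,
#' running `n_replicates` seeded replicates per value and collecting the
#' per-method metrics of [run_replicate()] in tidy long format.
#'
#' @param vary one of `"b"`, `"c"`, `"sigma"`, `"k"`.
#' @param values values of the varied parameter.
#' @param base_config base [simulation_config()].
#' @param k number of k-means clusters when `vary != "k"` (default 6).
#' @param n_replicates replicates per grid value (default 30).
#' @param seed master seed; replicate r of value v uses
#'   `child_seed(seed, (v - 1) * n_replicates + r)`.
#' @return data.frame with columns `parameter`, `value`, `replicate`,
#'   `method`, `mse`, `mse_minority`, `ari_train`, `ari_test`.  Failed
#'   replicates are excluded; their count is in `attr(, "n_failed")`.
#' @export
run_grid <- function(vary = c("b", "c", "sigma", "k"), values,
                     base_config = simulation_config(),
                     k = 6L, n_replicates = 30L, seed = 1L) {
  vary <- match.arg(vary)
  rows <- vector("list", length(values) * n_replicates)
  n_failed <- 0L
  i <- 0L
  for (vi in seq_along(values)) {
    v <- values[vi]
    cfg <- base_config
    kk <- k
    switch(vary,
           b = { cfg$bias <- v },
           c = { cfg$n_clusters <- as.integer(v) },
           sigma = { cfg$sigma_alpha <- v },
           k = { kk <- as.integer(v) })
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      s <- child_seed(seed, (vi - 1L) * n_replicates + r)
      res <- tryCatch(
        suppressWarnings(run_replicate(cfg, k = kk, seed = s)),
        error = function(e) {
          message(sprintf("replicate failed (%s = %s, rep %d): %s",
                          vary, format(v), r, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      res$parameter <- vary; res$value <- v; res$replicate <- r
      rows[[i]] <- res[, c("parameter", "value", "replicate", "method",
                           "mse", "mse_minority", "ari_train", "ari_test")]
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
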