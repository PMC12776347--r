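#' Read a delimited sample-by-feature matrix
#'
#' Reads a CSV/TSV file with a header row and IDs in the first column,
#' oriented internally to samples-as-rows.  Empty cells and `"NA"` become
#' missing.
#'
#' @param path file path (`.csv` or `.tsv`; delimiter inferred from the
#'   extension).
#' @param orientation `"samples_rows"` (default) or `"features_rows"` when
#'   the file stores features as rows.
#' @return numeric matrix, samples x features, with dimnames.
#' @export
read_matrix <- function(path, orientation = c("samples_rows", "features_rows")) {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        na.strings = c("NA", ""), stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate IDs in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "features_rows") m <- t(m)
  m
}

#' Write a matrix as CSV with IDs in the first column
#'
#' @param m samples x features matrix with row names.
#' @param path output file path.
#' @param id_name header for the ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_name = "sample_id") {
  m <- as.matrix(m)
  ids <- rownames(m); if (is.null(ids)) ids <- seq_len(nrow(m))
  df <- data.frame(ids, m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' CSV with a header and `sample_id` first column; character columns become
#' factors with alphabetically sorted levels (the reference-cell coding of
#' [build_design()] then uses the alphabetically first level as reference).
#'
#' @param path file path.
#' @return data.frame of covariates.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("NA", ""), stringsAsFactors = FALSE)
  names(df)[1] <- "sample_id"
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in covariate table", call. = FALSE)
  for (nm in names(df)[-1]) {
    if (is.character(df[[nm]]))
      df[[nm]] <- factor(df[[nm]], levels = sort(unique(df[[nm]])))
  }
  rownames(df) <- df$sample_id
  df
}

#' Run the full k-means + CMMP pipeline on one dataset
#'
#' Executes the end-to-end analysis on a `cmmp_dataset` (or an equivalent
#' list with `outcomes`, `covariates`, `train`, and optionally `theta` /
#' `clusters` truth): optional gap-statistic selection of k, k-means on the
#' training methylation, per-outcome mixed-model fits, predictions under the
#' requested methods, optional parametric bootstrap, and evaluation metrics
#' when the truth is available.  With `out_dir` set, all artifacts plus a
#' manifest (seeds, parameters, chosen k) are written as plain CSV/JSON so a
#' run can be reproduced exactly.
#'
#' @param dataset a `cmmp_dataset` or compatible list.
#' @param k number of clusters; `NULL` selects k by [gap_statistic()].
#' @param modes prediction methods to run (subset of
#'   `c("cmmp", "regression", "naive", "oracle")`).
#' @param seed master seed; stage seeds are derived with [child_seed()].
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap).
#' @param bootstrap_outcomes outcome indices passed to [bootstrap_mse()].
#' @param gap_k_grid,gap_B gap-statistic settings when `k` is `NULL`.
#' @param out_dir optional output directory.
#' @return list with `k`, `kmeans`, `gap` (or NULL), `fits`, `predictions`
#'   (named by mode), `bootstrap` (or NULL) and `metrics` (or NULL).
#' @export
run_pipeline <- function(dataset, k = NULL,
                         modes = c("cmmp", "regression", "naive"),
                         seed = 1L, bootstrap_B = 0L,
                         bootstrap_outcomes = NULL,
                         gap_k_grid = 2:15, gap_B = 50L,
                         out_dir = NULL) {
  modes <- match.arg(modes, c("cmmp", "regression", "naive", "oracle"),
                     several.ok = TRUE)
  tr <- dataset$train
  if (is.null(tr)) stop("dataset must carry a `train` mask", call. = FALSE)
  if (!any(!tr)) stop("empty test set", call. = FALSE)
  if ("oracle" %in% modes && is.null(dataset$clusters))
    stop("oracle mode requires true cluster labels", call. = FALSE)

  design <- if (!is.null(dataset$design)) dataset$design
            else build_design(dataset$covariates)
  sub_design <- function(rows)
    structure(list(X = design$X[rows, , drop = FALSE],
                   encoding = design$encoding), class = "cmmp_design")
  Ytr <- dataset$outcomes[tr, , drop = FALSE]
  Yte <- dataset$outcomes[!tr, , drop = FALSE]

  gap <- NULL
  if (is.null(k)) {
    gap <- gap_statistic(Ytr, k_grid = gap_k_grid, n_reference = gap_B,
                         seed = child_seed(seed, 1L))
    k <- gap$chosen_k
  }
  km <- fit_kmeans(Ytr, k, seed = child_seed(seed, 2L))
  fits <- fit_all_outcomes(Ytr, sub_design(tr), km$labels)
  preds <- list()
  for (mode in modes) {
    f <- switch(mode,
      cmmp = fits,
      regression = fit_ols(Ytr, sub_design(tr)),
      naive = NULL,
      oracle = fit_all_outcomes(Ytr, sub_design(tr), dataset$clusters[tr]))
    preds[[mode]] <- predict_all(Yte, sub_design(!tr), f, mode = mode)
  }

  boot <- NULL
  if (bootstrap_B > 0L && "cmmp" %in% modes) {
    boot <- bootstrap_mse(fits, preds$cmmp, sub_design(tr), km$labels,
                          sub_design(!tr), B = bootstrap_B,
                          seed = child_seed(seed, 3L),
                          outcomes = bootstrap_outcomes)
  }

  metrics <- NULL
  if (!is.null(dataset$theta)) {
    theta_te <- dataset$theta[!tr, , drop = FALSE]
    metrics <- do.call(rbind, lapply(names(preds), function(mode) {
      data.frame(method = mode,
                 mse = mse_vs_truth(preds[[mode]], theta_te),
                 stringsAsFactors = FALSE)
    }))
  }

  result <- list(k = k, kmeans = km, gap = gap, fits = fits,
                 predictions = preds, bootstrap = boot, metrics = metrics,
                 seed = seed)
  if (!is.null(out_dir)) write_pipeline(result, dataset, out_dir)
  result
}

write_pipeline <- function(result, dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(result$kmeans$centroids, file.path(out_dir, "centroids.csv"),
               id_name = "cluster")
  fits <- result$fits
  fit_tab <- data.frame(outcome = colnames(fits$beta),
                        G_hat = fits$G, R_hat = fits$R,
                        converged = fits$converged,
                        t(fits$beta), t(fits$alpha), check.names = FALSE)
  utils::write.csv(fit_tab, file.path(out_dir, "fits.csv"), row.names = FALSE)
  pred_long <- do.call(rbind, lapply(result$predictions, predictions_long))
  utils::write.csv(pred_long, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  if (!is.null(result$metrics))
    utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  if (!is.null(result$bootstrap))
    write_matrix(result$bootstrap$mse, file.path(out_dir, "bootstrap_mse.csv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cmmp")),
    seed = result$seed, k = result$k,
    gap_chosen = !is.null(result$gap),
    kmeans_seed = result$kmeans$seed,
    n_train = sum(dataset$train), n_test = sum(!dataset$train),
    n_outcomes = ncol(dataset$outcomes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
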