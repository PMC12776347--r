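#' k-means clustering of training methylation profiles
#'
#' Runs `stats::kmeans` on the training outcome matrix with `n_init` random
#' restarts, keeping the solution with the lowest total within-cluster sum of
#' squares; deterministic given `seed`.
#'
#' @param train_outcomes training samples x M numeric matrix (no missing
#'   values).
#' @param k number of clusters (`k <= n_train`).
#' @param seed integer seed.
#' @param n_init number of random restarts (default 10).
#' @param iter_max maximum iterations per restart (default 300).
#' @return object of class `cmmp_clusters`: list with `k`, `centroids`
#'   (k x M), `labels` (per training sample), `tot_withinss`, `seed`,
#'   `n_init`.
#' @export
fit_kmeans <- function(train_outcomes, k, seed = 1L, n_init = 10L,
                       iter_max = 300L) {
  x <- as.matrix(train_outcomes)
  assert_matrix_like(x, "train_outcomes")
  if (anyNA(x)) stop("training outcomes contain missing values", call. = FALSE)
  if (k > nrow(x)) stop("k cannot exceed the number of training samples",
                        call. = FALSE)
  if (k == 1L) {
    centroids <- matrix(colMeans(x), 1, ncol(x),
                        dimnames = list(NULL, colnames(x)))
    labels <- rep(1L, nrow(x))
    wss <- sum(sweep(x, 2L, centroids[1, ])^2)
  } else if (k == nrow(x)) {
    # each point its own cluster: the exact optimum with zero dispersion
    centroids <- x
    labels <- seq_len(nrow(x))
    wss <- 0
  } else {
    km <- with_fixed_seed(seed,
      stats::kmeans(x, centers = k, nstart = n_init, iter.max = iter_max))
    centroids <- km$centers
    labels <- as.integer(km$cluster)
    wss <- km$tot.withinss
  }
  structure(list(k = as.integer(k), centroids = centroids, labels = labels,
                 tot_withinss = wss,
                 seed = seed, n_init = as.integer(n_init)),
            class = "cmmp_clusters")
}

#' @export
print.cmmp_clusters <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, %d training samples, W_k = %.4g\n",
              x$k, length(x$labels), x$tot_withinss))
  cat("  cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Gap-statistic selection of the number of clusters
#'
#' Computes Tibshirani's gap statistic
#' `Gap(k) = E*[log W*_k] - log W_k` with `B` reference datasets drawn
#' uniformly over each feature's observed range (via
#' `cluster::clusGap(spaceH0 = "original")`), the `sqrt(1 + 1/B)` standard
#' error, and chooses k by the `firstSEmax` rule: the smallest k whose gap is
#' within one standard error of the first local maximum
#' (`cluster::maxSE`), balancing a high gap against parsimony.
#'
#' @param train_outcomes training samples x M matrix.
#' @param k_grid candidate cluster counts (default `2:15`; `k = 1` is always
#'   computed internally as the reference point).
#' @param n_reference number of reference datasets B (default 50).
#' @param seed integer seed.
#' @param n_init k-means restarts per k (default 10).
#' @param select `"firstSEmax"` (default) or `"globalmax"`.
#' @return object of class `cmmp_gap`: list with `k_grid`, `gap`, `se`,
#'   `chosen_k`, `n_reference` and the full `table` over `1..max(k_grid)`.
#' @export
gap_statistic <- function(train_outcomes, k_grid = 2:15, n_reference = 50L,
                          seed = 1L, n_init = 10L,
                          select = c("firstSEmax", "globalmax")) {
  select <- match.arg(select)
  x <- as.matrix(train_outcomes)
  if (anyNA(x)) stop("training outcomes contain missing values", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (min(k_grid) < 1L || max(k_grid) > nrow(x))
    stop("`k_grid` must lie within [1, n_train]", call. = FALSE)
  gap_obj <- with_fixed_seed(seed,
    cluster::clusGap(x,
      FUNcluster = function(xx, k)
        stats::kmeans(xx, centers = k, nstart = n_init, iter.max = 300L),
      K.max = max(k_grid), B = n_reference, spaceH0 = "original",
      verbose = FALSE))
  tab <- gap_obj$Tab
  if (any(!is.finite(tab[, "logW"])))
    stop("within-cluster dispersion of 0 for some k; reduce `k_grid`",
         call. = FALSE)
  gap <- tab[k_grid, "gap"]
  se <- tab[k_grid, "SE.sim"]
  se[!is.finite(se)] <- 0   # B = 1 has no simulation spread
  chosen <- if (select == "globalmax") {
    k_grid[which.max(gap)]
  } else {
    k_grid[cluster::maxSE(gap, se, method = "firstSEmax")]
  }
  structure(list(k_grid = k_grid, gap = unname(gap), se = unname(se),
                 chosen_k = chosen, n_reference = as.integer(n_reference),
                 table = tab),
            class = "cmmp_gap")
}

#' @export
print.cmmp_gap <- function(x, ...) {
  cat(sprintf("Gap statistic over k in {%s} (B = %d references)\n",
              paste(range(x$k_grid), collapse = ".."), x$n_reference))
  cat(sprintf("  chosen k = %d\n", x$chosen_k))
  invisible(x)
}

#' Assign new samples to their nearest centroid
#'
#' Diagnostic Euclidean nearest-centroid assignment (the main pipeline
#' assigns test clusters through CMMP, not centroids).  Ties go to the
#' lowest cluster index.
#'
#' @param model a `cmmp_clusters` object.
#' @param new_outcomes samples x M matrix on the same features.
#' @return integer vector of cluster labels.
#' @export
assign_by_centroid <- function(model, new_outcomes) {
  stopifnot(inherits(model, "cmmp_clusters"))
  x <- as.matrix(new_outcomes)
  if (ncol(x) != ncol(model$centroids))
    stop("feature dimension does not match the centroids", call. = FALSE)
  cc <- model$centroids
  # squared distances via the expansion ||x||^2 - 2 x.c + ||c||^2
  d2 <- outer(rowSums(x^2), rep(1, nrow(cc))) - 2 * x %*% t(cc) +
    outer(rep(1, nrow(x)), rowSums(cc^2))
  max.col(-d2, ties.method = "first")
}
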