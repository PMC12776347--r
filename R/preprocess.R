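#' Mark boundary methylation beta values as missing
#'
#' Beta values of exactly 0 or 1 have an undefined M-value, so they are
#' treated as missing before any transformation; all interior values pass
#' through unchanged (the rule is strict equality, so `1 - 1e-9` is kept).
#'
#' @param beta_matrix samples x features matrix of beta values in `[0, 1]`
#'   (missing allowed).
#' @return the matrix with exact 0/1 entries replaced by `NA`.
#' @export
mark_boundary_missing <- function(beta_matrix) {
  x <- as.matrix(beta_matrix)
  rng <- range(x, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("beta values must lie in [0, 1]", call. = FALSE)
  x[x == 0 | x == 1] <- NA_real_
  x
}

#' Drop features that are missing anywhere or unshared between two cohorts
#'
#' Keeps only the features present in both matrices and complete (zero
#' missing cells) in both; feature order follows the first matrix.
#'
#' @param a,b samples x features matrices with feature names as column
#'   names.
#' @return list with the two filtered matrices (`a`, `b`) and a `report`
#'   list recording the dropped feature IDs.
#' @export
drop_missing_or_unshared <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(colnames(a)) || is.null(colnames(b)))
    stop("both matrices need feature names as column names", call. = FALSE)
  shared <- intersect(colnames(a), colnames(b))
  has_na <- shared[colSums(is.na(a[, shared, drop = FALSE])) > 0 |
                   colSums(is.na(b[, shared, drop = FALSE])) > 0]
  keep <- setdiff(shared, has_na)
  keep <- colnames(a)[colnames(a) %in% keep]   # preserve a's order
  if (length(keep) == 0L)
    stop("no complete shared features remain", call. = FALSE)
  # unshared features are reported per cohort so that
  # n_output = n_input(a) - dropped_unshared(a) - dropped_missing
  list(a = a[, keep, drop = FALSE], b = b[, keep, drop = FALSE],
       report = list(dropped_unshared = setdiff(colnames(a), shared),
                     dropped_unshared_other = setdiff(colnames(b), shared),
                     dropped_missing = has_na,
                     n_output = length(keep)))
}

#' Filter methylation features by standard deviation
#'
#' Keeps features whose sample standard deviation (denominator n - 1) over
#' the reference samples is at least `threshold`; the threshold is closed
#' (SD exactly at the threshold is kept).  Filtering on a reference cohort
#' (e.g. CESC only) mirrors filtering rules defined on one cancer type.
#'
#' @param m samples x features matrix.
#' @param threshold minimum SD (default 0.2).
#' @param reference_samples row names (or indices) of the reference samples;
#'   default all rows.
#' @return the filtered matrix, with the dropped feature IDs in
#'   `attr(, "dropped")`.
#' @export
filter_methyl_by_sd <- function(m, threshold = 0.2, reference_samples = NULL) {
  m <- as.matrix(m)
  ref <- if (is.null(reference_samples)) m
         else m[reference_samples, , drop = FALSE]
  if (nrow(ref) < 2L)
    stop("need at least two reference samples to compute an SD", call. = FALSE)
  sds <- apply(ref, 2L, stats::sd)
  keep <- sds >= threshold
  out <- m[, keep, drop = FALSE]
  attr(out, "dropped") <- colnames(m)[!keep]
  out
}

# Exact maximum independent set by branch and bound; `adj` is a small
# logical adjacency matrix.  Among maximum sets, the lexicographically
# smallest index set is returned (deterministic, favors input order).
mis_exact <- function(adj) {
  p <- nrow(adj)
  best <- integer(0)
  nbrs <- lapply(seq_len(p), function(i) which(adj[i, ]))
  rec <- function(cand, chosen) {
    if (length(chosen) + length(cand) <= length(best)) return()
    if (length(cand) == 0L) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    v <- cand[1L]
    rec(setdiff(cand[-1L], nbrs[[v]]), c(chosen, v))  # include v first
    rec(cand[-1L], chosen)                            # then exclude v
  }
  rec(seq_len(p), integer(0))
  sort(best)
}

# Greedy pruning: iteratively remove the feature with the most
# |r| > threshold partners (ties: larger mean |r|, then later input
# position).  Used for conflict components too large for exact search.
prune_greedy <- function(r, threshold) {
  keep <- rep(TRUE, ncol(r))
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    deg <- rowSums(sub > threshold)
    if (all(deg == 0)) break
    mean_r <- rowMeans(sub)
    ord <- order(-deg, -mean_r, -seq_along(deg))
    victim <- which(keep)[ord[1]]
    keep[victim] <- FALSE
  }
  keep
}

# Retain a maximum (or near-maximum) subset with all pairwise
# |r| <= threshold.  Features with no conflicts are always kept; each
# connected conflict component is solved exactly when small enough,
# otherwise by the greedy heuristic.
prune_correlated <- function(r, threshold, exact_limit = 30L) {
  p <- ncol(r)
  diag(r) <- 0
  r <- abs(r)
  adj <- r > threshold
  keep <- rep(TRUE, p)
  active <- which(rowSums(adj) > 0)
  if (length(active) == 0L) return(keep)
  # connected components of the conflict subgraph
  comp <- rep(NA_integer_, p); cid <- 0L
  for (v in active) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, setdiff(which(adj[u, ]), which(!is.na(comp))))
    }
  }
  for (g in seq_len(cid)) {
    members <- which(comp == g)
    if (length(members) <= exact_limit) {
      kept <- members[mis_exact(adj[members, members, drop = FALSE])]
    } else {
      kept <- members[prune_greedy(r[members, members, drop = FALSE],
                                   threshold)]
    }
    keep[setdiff(members, kept)] <- FALSE
  }
  keep
}

#' Variance and correlation filtering of CNA covariates
#'
#' Two-stage filter on the reference samples: (1) keep features whose
#' variance reaches the `variance_quantile` quantile of all feature
#' variances (default the 85th percentile, i.e. the top 15%); (2) from the
#' survivors, retain a subset with all pairwise
#' `|Pearson r| <= corr_threshold`, chosen to keep as many features as
#' possible: conflict-free features are always kept, each connected
#' component of the conflict graph with at most 30 features is solved as an
#' exact maximum independent set (lexicographically smallest maximum set,
#' so input order breaks ties), and larger components fall back to a
#' deterministic greedy heuristic (remove the feature with the most
#' above-threshold partners; ties broken by larger mean absolute
#' correlation, then by later input position).
#'
#' @param cna samples x features matrix of CNA values.
#' @param variance_quantile quantile defining the variance cut (default .85).
#' @param corr_threshold maximum allowed absolute pairwise correlation
#'   (default .7).
#' @param reference_samples rows used to compute variances/correlations
#'   (default all).
#' @return the filtered matrix; `attr(, "report")` records
#'   `dropped_low_variance` and `dropped_correlated`.
#' @export
filter_cna <- function(cna, variance_quantile = 0.85, corr_threshold = 0.7,
                       reference_samples = NULL) {
  cna <- as.matrix(cna)
  ref <- if (is.null(reference_samples)) cna
         else cna[reference_samples, , drop = FALSE]
  if (nrow(ref) < 2L) stop("need at least two reference samples", call. = FALSE)
  v <- apply(ref, 2L, stats::var)
  if (all(v == 0)) stop("all CNA features are constant", call. = FALSE)
  cut <- stats::quantile(v, variance_quantile, type = 7)
  stage1 <- v >= cut
  surv <- which(stage1)
  r <- suppressWarnings(stats::cor(ref[, surv, drop = FALSE]))
  r[is.na(r)] <- 0
  keep2 <- prune_correlated(r, corr_threshold)
  kept <- surv[keep2]
  out <- cna[, kept, drop = FALSE]
  attr(out, "report") <- list(
    dropped_low_variance = colnames(cna)[!stage1],
    dropped_correlated = colnames(cna)[surv[!keep2]],
    n_output = length(kept))
  out
}

#' M-value transform of methylation beta values
#'
#' `M = log2(beta / (1 - beta))`, the logit-2 transform that maps the (0,1)
#' beta scale to an approximately Gaussian scale; missing values propagate.
#' Boundary values must already have been marked missing.
#'
#' @param beta_matrix matrix with values strictly in (0, 1) or `NA`.
#' @return the transformed matrix.
#' @export
m_value_transform <- function(beta_matrix) {
  x <- as.matrix(beta_matrix)
  obs <- x[!is.na(x)]
  if (any(obs <= 0 | obs >= 1))
    stop(paste0("values at 0 or 1 reached the M-value transform; run ",
                "mark_boundary_missing() first"), call. = FALSE)
  log2(x / (1 - x))
}

#' Standardize features within sample groups
#'
#' Per feature and per group (e.g. cancer type): subtract the group mean and
#' divide by the group SD, so every feature has mean 0 and SD 1 within each
#' group.  Idempotent up to floating-point error.
#'
#' @param m samples x features matrix.
#' @param group per-sample group label.
#' @return the standardized matrix.
#' @export
standardize_within_group <- function(m, group) {
  m <- as.matrix(m)
  if (length(group) != nrow(m))
    stop("`group` must have one label per sample", call. = FALSE)
  g <- factor(group)
  if (any(tabulate(g) < 2L))
    stop("every group needs at least two samples", call. = FALSE)
  out <- m
  for (lev in levels(g)) {
    rows <- which(g == lev)
    mu <- colMeans(m[rows, , drop = FALSE])
    sdv <- apply(m[rows, , drop = FALSE], 2L, stats::sd)
    if (any(sdv == 0, na.rm = TRUE)) {
      bad <- colnames(m)[which(sdv == 0)]
      stop(sprintf("zero within-group SD for feature %s in group %s",
                   bad[1], lev), call. = FALSE)
    }
    out[rows, ] <- sweep(sweep(m[rows, , drop = FALSE], 2L, mu), 2L, sdv, "/")
  }
  out
}

#' Full preprocessing pipeline for paired methylation/CNA cohorts
#'
#' Applies the fixed filter order: boundary values to missing; drop features
#' missing anywhere or unshared between the two cohorts; SD filter on the
#' reference cohort's methylation; variance + correlation filter on the
#' reference cohort's CNA; M-value transform; within-cancer
#' standardization.  Every dropped feature is accounted for exactly once in
#' the report.
#'
#' @param methyl_a,methyl_b beta-value matrices for the two cohorts (samples
#'   x features; cohort a is the reference, e.g. CESC).
#' @param cna_a,cna_b CNA matrices for the two cohorts.
#' @param sd_threshold methylation SD cut (default .2).
#' @param variance_quantile,corr_threshold CNA filter settings.
#' @return list with `methyl` and `cna` (row-bound processed matrices over
#'   both cohorts), `cancer_type` (the group label used for
#'   standardization), and `report` (a `FeatureFilterReport`-style list).
#' @export
preprocess_pipeline <- function(methyl_a, methyl_b, cna_a, cna_b,
                                sd_threshold = 0.2,
                                variance_quantile = 0.85,
                                corr_threshold = 0.7) {
  n_in_methyl <- ncol(as.matrix(methyl_a))
  n_in_cna <- ncol(as.matrix(cna_a))
  ma <- mark_boundary_missing(methyl_a)
  mb <- mark_boundary_missing(methyl_b)
  sh <- drop_missing_or_unshared(ma, mb)
  fa <- filter_methyl_by_sd(sh$a, sd_threshold)
  kept <- colnames(fa)
  fb <- sh$b[, kept, drop = FALSE]

  csh <- drop_missing_or_unshared(as.matrix(cna_a), as.matrix(cna_b))
  ca <- filter_cna(csh$a, variance_quantile, corr_threshold)
  cb <- csh$b[, colnames(ca), drop = FALSE]

  m_all <- rbind(m_value_transform(fa), m_value_transform(fb))
  grp <- c(rep("a", nrow(fa)), rep("b", nrow(fb)))
  m_all <- standardize_within_group(m_all, grp)

  report <- list(
    n_input_methyl = n_in_methyl, n_input_cna = n_in_cna,
    dropped_missing = sh$report$dropped_missing,
    dropped_unshared = sh$report$dropped_unshared,
    dropped_low_sd = attr(fa, "dropped"),
    dropped_unshared_cna = csh$report$dropped_unshared,
    dropped_missing_cna = csh$report$dropped_missing,
    dropped_low_variance_cna = attr(ca, "report")$dropped_low_variance,
    dropped_correlated_cna = attr(ca, "report")$dropped_correlated,
    n_output_methyl = ncol(m_all), n_output_cna = ncol(ca)
  )
  list(methyl = m_all, cna = rbind(ca, cb), cancer_type = grp,
       report = report)
}
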