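#' Build the fixed-effect design matrix
#'
#' Encodes a covariate table into the design used by every per-outcome model:
#' an intercept, the numeric CNA columns, age in decades (`age / 10`, which
#' keeps its coefficient on a scale comparable to the categorical contrasts),
#' and reference-cell (treatment) coding for each categorical covariate with
#' the alphabetically first level as reference.  The encoding (column order
#' and factor levels) is stored so the identical design can be rebuilt for
#' test samples; an unseen categorical level at prediction time is an error.
#'
#' @param covariates data.frame of covariates; a `sample_id` column, if
#'   present, is used for row names only.  Factor columns contribute
#'   indicator columns for every declared level beyond the reference, so a
#'   declared-but-unobserved level yields a rank-deficiency error.
#' @param encoding optional encoding from a previous call (fit-time reuse);
#'   when supplied, no rank check is performed.
#' @return an object of class `cmmp_design`: list with the numeric matrix `X`
#'   (samples x p, including the intercept) and the `encoding` map.
#' @export
build_design <- function(covariates, encoding = NULL) {
  stopifnot(is.data.frame(covariates))
  ids <- if ("sample_id" %in% names(covariates)) {
    as.character(covariates$sample_id)
  } else rownames(covariates)
  cov <- covariates[setdiff(names(covariates), "sample_id")]

  if (is.null(encoding)) {
    is_cat <- vapply(cov, function(x) is.factor(x) || is.character(x), TRUE)
    encoding <- list(
      columns = names(cov),
      categorical = names(cov)[is_cat],
      levels = lapply(cov[is_cat], function(x)
        if (is.factor(x)) levels(x) else sort(unique(as.character(x))))
    )
    check_rank <- TRUE
  } else {
    missing_cols <- setdiff(encoding$columns, names(cov))
    if (length(missing_cols))
      stop("covariate table lacks columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    check_rank <- FALSE
  }

  n <- nrow(cov)
  blocks <- list(`(Intercept)` = matrix(1, n, 1,
                                        dimnames = list(NULL, "(Intercept)")))
  for (col in encoding$columns) {
    x <- cov[[col]]
    if (col %in% encoding$categorical) {
      lev <- encoding$levels[[col]]
      vals <- as.character(x)
      bad <- setdiff(unique(vals), lev)
      if (length(bad))
        stop(sprintf("column `%s` has level(s) not in the encoding: %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      if (length(lev) > 1L) {
        m <- vapply(lev[-1L], function(l) as.numeric(vals == l),
                    numeric(n))
        m <- matrix(m, nrow = n,
                    dimnames = list(NULL, paste0(col, lev[-1L])))
        blocks[[col]] <- m
      }
    } else {
      v <- as.numeric(x)
      if (identical(col, "age")) {
        blocks[[col]] <- matrix(v / 10, n, 1,
                                dimnames = list(NULL, "age_decades"))
      } else {
        blocks[[col]] <- matrix(v, n, 1, dimnames = list(NULL, col))
      }
    }
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- ids

  if (check_rank) {
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
      stop("design matrix is rank deficient; aliased columns: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(X = X, encoding = encoding), class = "cmmp_design")
}

# Precompute the label-dependent pieces of the profiled REML criterion.
reml_prep <- function(X, labels) {
  assert_matrix_like(X, "X")
  n <- nrow(X); p <- ncol(X)
  if (length(labels) != n)
    stop("`labels` must have one entry per row of `X`", call. = FALSE)
  f <- factor(labels)
  idx <- as.integer(f)
  k <- nlevels(f)
  nj <- tabulate(idx, k)
  if (any(nj == 0L)) stop("every cluster must be nonempty", call. = FALSE)
  if (n <= p)
    stop(sprintf("need n > p for REML (n = %d, p = %d)", n, p), call. = FALSE)
  list(X = X, idx = idx, k = k, nj = nj, n = n, p = p,
       XtX = crossprod(X),
       S = t(rowsum(X, idx)),           # p x k cluster sums of X
       cluster_levels = levels(f))
}

# -2 * profiled restricted log-likelihood (up to a constant) at variance
# ratio gamma = G / R, using the Woodbury identity per cluster:
#   V0^-1 = I - sum_j gamma/(1 + n_j gamma) J_j.
# Returns the criterion together with the GLS solution so the optimum can be
# reused without recomputation.
reml_eval <- function(gamma, prep, Xty, Tj, yy) {
  w <- gamma / (1 + prep$nj * gamma)
  A <- prep$XtX - prep$S %*% (w * t(prep$S))
  b <- Xty - prep$S %*% (w * Tj)
  q <- yy - sum(w * Tj^2)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(list(crit = Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  rss <- q - sum(b * beta)
  if (!is.finite(rss) || rss <= 0) return(list(crit = Inf))
  crit <- (prep$n - prep$p) * log(rss) +
    sum(log1p(prep$nj * gamma)) + 2 * sum(log(diag(ch)))
  list(crit = crit, beta = drop(beta), rss = rss)
}

fit_outcome_stats <- function(prep, Xty, Tj, yy, lg_bounds = c(-12, 12),
                              tol = 1e-8) {
  ols <- reml_eval(0, prep, Xty, Tj, yy)
  if (prep$k == 1L) {
    # a single cluster is confounded with the intercept: G fixed at 0
    opt_gamma <- 0; best <- ols
  } else {
    obj <- function(lg) reml_eval(exp(lg), prep, Xty, Tj, yy)$crit
    opt <- stats::optimize(obj, lg_bounds, tol = tol)
    cand <- reml_eval(exp(opt$minimum), prep, Xty, Tj, yy)
    if (is.finite(ols$crit) && ols$crit <= cand$crit) {
      opt_gamma <- 0; best <- ols
    } else {
      opt_gamma <- exp(opt$minimum); best <- cand
    }
  }
  if (!is.finite(best$crit)) {
    return(list(converged = FALSE, gamma = NA_real_,
                beta = rep(NA_real_, prep$p), G = NA_real_, R = NA_real_,
                alpha = rep(NA_real_, prep$k), objective = NA_real_))
  }
  R <- best$rss / (prep$n - prep$p)
  G <- opt_gamma * R
  resid_sums <- drop(Tj - crossprod(prep$S, best$beta))
  alpha <- (opt_gamma / (1 + prep$nj * opt_gamma)) * resid_sums
  list(converged = TRUE, gamma = opt_gamma, beta = best$beta, G = G, R = R,
       alpha = alpha, objective = -best$crit / 2)
}

#' Fit the cluster random-intercept model for every methylation outcome
#'
#' For each outcome m fits `y_im = x_i beta_m + alpha_{j_i, m} + eps_im` with
#' `alpha_jm ~ N(0, G_m)` and `eps_im ~ N(0, R_m)` by REML: the restricted
#' likelihood is profiled down to a bounded 1-D optimization over
#' `log(gamma)`, `gamma = G/R`, with GLS `beta_hat` at the optimum and BLUPs
#' `alpha_hat_j = n_j gamma / (1 + n_j gamma) * (mean residual of cluster j)`.
#' The boundary estimate `G_hat = 0` (plain OLS) is permitted and is forced
#' when there is a single cluster.  Outcomes are fitted independently, so
#' results do not depend on column order.
#'
#' @param outcomes numeric matrix, samples x M.
#' @param design a `cmmp_design` (or bare design matrix with intercept).
#' @param labels cluster label per sample (training clusters).
#' @param lg_bounds search interval for `log(gamma)` (default `c(-12, 12)`).
#' @param tol optimizer tolerance on `log(gamma)`.
#' @return an object of class `cmmp_fits`: list with `beta` (p x M), `G`,
#'   `R`, `gamma` (length M), `alpha` (k x M BLUPs), `converged`,
#'   `objective` (restricted log-likelihood up to a constant), `nj`, `k`,
#'   `labels`, and the design `encoding`.
#' @export
fit_all_outcomes <- function(outcomes, design, labels,
                             lg_bounds = c(-12, 12), tol = 1e-8) {
  if (is.matrix(outcomes) || is.numeric(outcomes)) {
    Y <- as.matrix(outcomes)
  } else stop("`outcomes` must be a numeric matrix", call. = FALSE)
  if (anyNA(Y)) stop("`outcomes` must not contain missing values", call. = FALSE)
  encoding <- NULL
  X <- if (inherits(design, "cmmp_design")) {
    encoding <- design$encoding; design$X
  } else as.matrix(design)
  prep <- reml_prep(X, labels)
  M <- ncol(Y)
  XtY <- crossprod(X, Y)
  TjY <- rowsum(Y, prep$idx)
  yy <- colSums(Y^2)

  beta <- matrix(NA_real_, prep$p, M, dimnames = list(colnames(X), colnames(Y)))
  alpha <- matrix(NA_real_, prep$k, M,
                  dimnames = list(prep$cluster_levels, colnames(Y)))
  G <- R <- gamma <- objective <- rep(NA_real_, M)
  converged <- logical(M)
  for (m in seq_len(M)) {
    fm <- fit_outcome_stats(prep, XtY[, m], TjY[, m], yy[m], lg_bounds, tol)
    converged[m] <- fm$converged
    if (fm$converged) {
      beta[, m] <- fm$beta; alpha[, m] <- fm$alpha
      G[m] <- fm$G; R[m] <- fm$R; gamma[m] <- fm$gamma
      objective[m] <- fm$objective
    }
  }
  structure(list(beta = beta, G = G, R = R, gamma = gamma, alpha = alpha,
                 converged = converged, objective = objective,
                 k = prep$k, nj = prep$nj, labels = prep$idx,
                 cluster_levels = prep$cluster_levels,
                 encoding = encoding),
            class = "cmmp_fits")
}

#' Fit a single outcome
#'
#' Convenience wrapper around [fit_all_outcomes()] for one outcome vector.
#'
#' @param y numeric outcome vector.
#' @param design design matrix or `cmmp_design`.
#' @param labels cluster label per sample.
#' @param ... passed to [fit_all_outcomes()].
#' @return list with `beta`, `G`, `R`, `gamma`, `alpha`, `converged`,
#'   `objective`.
#' @export
fit_outcome <- function(y, design, labels, ...) {
  fits <- fit_all_outcomes(matrix(as.numeric(y), ncol = 1), design, labels, ...)
  list(beta = fits$beta[, 1], G = fits$G[1], R = fits$R[1],
       gamma = fits$gamma[1], alpha = fits$alpha[, 1],
       converged = fits$converged[1], objective = fits$objective[1],
       k = fits$k, nj = fits$nj)
}

#' @export
print.cmmp_fits <- function(x, ...) {
  M <- ncol(x$beta)
  cat(sprintf("Per-outcome mixed-model fits: M = %d outcomes, k = %d clusters\n",
              M, x$k))
  cat(sprintf("  converged: %d/%d; median G_hat = %.4g, median R_hat = %.4g\n",
              sum(x$converged), M,
              stats::median(x$G, na.rm = TRUE),
              stats::median(x$R, na.rm = TRUE)))
  invisible(x)
}

#' Ordinary least squares fits for the regression-prediction baseline
#'
#' Fits each outcome on the same fixed-effect design by OLS; used for the
#' "regression prediction" competitor of CMMP.
#'
#' @param outcomes samples x M numeric matrix.
#' @param design a `cmmp_design` or design matrix.
#' @return object of class `cmmp_ols` with `beta` (p x M) and the design
#'   `encoding`.
#' @export
fit_ols <- function(outcomes, design) {
  Y <- as.matrix(outcomes)
  encoding <- NULL
  X <- if (inherits(design, "cmmp_design")) {
    encoding <- design$encoding; design$X
  } else as.matrix(design)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qx, Y)
  structure(list(beta = beta, encoding = encoding), class = "cmmp_ols")
}
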