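#' Parametric bootstrap MSE of CMMP mixed-effect predictions
#'
#' Estimates, for real data where the true mixed effect is unobservable, the
#' MSE of the CMMP prediction `theta_hat_nm` by parametric bootstrap.  For
#' each outcome m and replicate b:
#' \enumerate{
#'   \item draw k random intercepts `alpha_b ~ N(0, G_hat_m)`;
#'   \item regenerate training outcomes
#'     `y_ib = x_i beta_hat_m + alpha_b[j_i] + eps`, `eps ~ N(0, R_hat_m)`;
#'   \item regenerate each test outcome with the intercept of its original
#'     CMMP cluster `I_hat_nm`;
#'   \item refit the mixed model on the replicate training data (same
#'     training cluster labels; k is not re-selected) and rerun CMMP on the
#'     replicate test data to obtain `theta_hat_nmb`.
#' }
#' The estimate is the mean over replicates of
#' `(theta_hat_nmb - target)^2`, where the target is the original prediction
#' `theta_hat_nm` (`variant = "as_written"`, measuring predictor
#' variability) or the replicate's own true mixed effect
#' `x_n beta_hat_m + alpha_b[I_hat_nm]` (`variant = "bootstrap_truth"`,
#' measuring error against the bootstrap truth).
#'
#' @param fits `cmmp_fits` from the original training fit.
#' @param pred `cmmp_predictions` from the original CMMP run on the test set
#'   (provides `theta_hat` and the assignments `I_hat`).
#' @param train_design training `cmmp_design` (or design matrix).
#' @param labels training cluster labels used in `fits`.
#' @param test_design test `cmmp_design` (or design matrix).
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param variant `"as_written"` (default) or `"bootstrap_truth"`.
#' @param outcomes which outcome columns to bootstrap (default all).
#' @return object of class `cmmp_bootstrap`: list with `mse`
#'   (test x outcomes matrix), `B`, `variant`, `n_dropped` (replicate fits
#'   that failed to converge, per outcome).
#' @export
bootstrap_mse <- function(fits, pred, train_design, labels, test_design,
                          B = 100L, seed = 1L,
                          variant = c("as_written", "bootstrap_truth"),
                          outcomes = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(fits, "cmmp_fits"), inherits(pred, "cmmp_predictions"))
  if (B < 1L) stop("B must be at least 1", call. = FALSE)
  if (is.null(pred$assigned))
    stop("`pred` must carry CMMP cluster assignments", call. = FALSE)
  Xtr <- if (inherits(train_design, "cmmp_design")) train_design$X
         else as.matrix(train_design)
  Xte <- if (inherits(test_design, "cmmp_design")) test_design$X
         else as.matrix(test_design)
  prep <- reml_prep(Xtr, labels)
  k <- prep$k
  if (is.null(outcomes)) outcomes <- seq_len(ncol(fits$beta))
  n_te <- nrow(Xte)

  mse <- matrix(NA_real_, n_te, length(outcomes),
                dimnames = list(rownames(Xte),
                                colnames(fits$beta)[outcomes]))
  n_dropped <- integer(length(outcomes))

  with_fixed_seed(seed, {
    for (oi in seq_along(outcomes)) {
      m <- outcomes[oi]
      if (!fits$converged[m]) next
      beta <- fits$beta[, m]; G <- fits$G[m]; R <- fits$R[m]
      I_hat <- pred$assigned[, m]
      lp_tr <- drop(Xtr %*% beta)
      lp_te <- drop(Xte %*% beta)
      target0 <- pred$theta_hat[, m]
      acc <- numeric(n_te)
      used <- 0L
      for (b in seq_len(B)) {
        alpha_b <- stats::rnorm(k, sd = sqrt(max(G, 0)))
        y_tr <- lp_tr + alpha_b[prep$idx] +
          stats::rnorm(prep$n, sd = sqrt(R))
        y_te <- lp_te + alpha_b[I_hat] + stats::rnorm(n_te, sd = sqrt(R))
        fm <- fit_outcome_stats(prep, crossprod(Xtr, y_tr)[, 1],
                                rowsum(y_tr, prep$idx)[, 1], sum(y_tr^2))
        if (!fm$converged) { n_dropped[oi] <- n_dropped[oi] + 1L; next }
        r_te <- y_te - drop(Xte %*% fm$beta)
        d <- outer(r_te, fm$alpha, "-")
        idx <- max.col(-(d * d), ties.method = "first")
        theta_b <- y_te - r_te + fm$alpha[idx]
        target <- if (variant == "as_written") target0
                  else lp_te + alpha_b[I_hat]
        acc <- acc + (theta_b - target)^2
        used <- used + 1L
      }
      if (used > 0L) mse[, oi] <- acc / used
    }
  })
  if (sum(n_dropped) > 0.1 * B * length(outcomes))
    warning("more than 10% of bootstrap replicates were dropped",
            call. = FALSE)
  structure(list(mse = mse, B = as.integer(B), variant = variant,
                 n_dropped = n_dropped, seed = seed),
            class = "cmmp_bootstrap")
}

#' @export
print.cmmp_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap MSE (B = %d, variant = %s)\n",
              x$B, x$variant))
  cat(sprintf("  %d test samples x %d outcomes; median MSE = %.4g\n",
              nrow(x$mse), ncol(x$mse), stats::median(x$mse, na.rm = TRUE)))
  invisible(x)
}
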