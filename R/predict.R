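#' Classify a test observation to a training cluster (matched CMMP)
#'
#' With each test observation forming its own group of size one, the CMMP
#' classification criterion reduces to nearest-residual matching: the chosen
#' cluster minimizes `(y_nm - x_n beta_hat_m - alpha_hat_jm)^2` over the
#' training clusters j.  Ties go to the lowest cluster index.
#'
#' @param y_nm observed outcome value for the test observation (required:
#'   matched CMMP classifies on the observed outcome).
#' @param x_n encoded design row for the observation.
#' @param fit single-outcome fit from [fit_outcome()] (or a list with `beta`
#'   and `alpha`).
#' @return integer cluster index.
#' @export
classify_observation <- function(y_nm, x_n, fit) {
  if (is.na(y_nm))
    stop("matched CMMP requires the observed outcome y_nm", call. = FALSE)
  r <- y_nm - sum(as.numeric(x_n) * fit$beta)
  which.min((r - fit$alpha)^2)
}

#' Predict the mixed effect for a classified observation
#'
#' `theta_hat = x_n beta_hat_m + alpha_hat_{I, m}` for the assigned cluster I.
#'
#' @param x_n encoded design row.
#' @param fit single-outcome fit.
#' @param assigned cluster index in `1..k`.
#' @return predicted mixed effect (scalar).
#' @export
predict_theta <- function(x_n, fit, assigned) {
  stopifnot(assigned >= 1L, assigned <= length(fit$alpha))
  sum(as.numeric(x_n) * fit$beta) + fit$alpha[assigned]
}

#' Most common per-outcome cluster assignment
#'
#' The consensus cluster of a test observation is the modal label over its
#' per-outcome CMMP assignments; ties go to the lowest label.
#'
#' @param labels vector of positive integer labels (one per outcome).
#' @return the modal label.
#' @export
consensus_cluster <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) < 1L || anyNA(labels) || any(labels < 1L))
    stop("`labels` must be positive integers with at least one entry",
         call. = FALSE)
  which.max(tabulate(labels))
}

#' Predict test-set mixed effects under a chosen method
#'
#' Produces the full test x outcome prediction table for one of the four
#' predictors compared in the simulation study:
#' \describe{
#'   \item{`cmmp`}{per-outcome matched CMMP with k-means training clusters:
#'     classify by nearest residual, predict `x beta_hat + alpha_hat_I`.}
#'   \item{`oracle`}{identical mechanics, but `fits` must come from the true
#'     training cluster labels (simulation only).}
#'   \item{`regression`}{OLS fixed-effect prediction `x beta_ols` (pass a
#'     `cmmp_ols` object as `fits`).}
#'   \item{`naive`}{the observed outcome itself.}
#' }
#' For `cmmp`/`oracle` the per-outcome assignments and the per-sample
#' consensus (modal) cluster are recorded; the consensus is reporting-only
#' and never feeds back into the predictions.
#'
#' @param test_outcomes test samples x M observed outcome matrix.
#' @param test_covariates covariate table for the test samples (or a prebuilt
#'   `cmmp_design`); ignored for `naive`.
#' @param fits `cmmp_fits` (cmmp/oracle) or `cmmp_ols` (regression); ignored
#'   for `naive`.
#' @param mode one of `"cmmp"`, `"regression"`, `"naive"`, `"oracle"`.
#' @return object of class `cmmp_predictions`: list with `theta_hat`
#'   (test x M), `assigned` (test x M integer, cmmp/oracle only),
#'   `consensus` (per-sample label, cmmp/oracle only) and `method`.
#' @export
predict_all <- function(test_outcomes, test_covariates, fits,
                        mode = c("cmmp", "regression", "naive", "oracle")) {
  mode <- match.arg(mode)
  Y <- as.matrix(test_outcomes)

  if (mode == "naive") {
    return(structure(list(theta_hat = Y, assigned = NULL, consensus = NULL,
                          method = "naive"), class = "cmmp_predictions"))
  }

  X <- if (inherits(test_covariates, "cmmp_design")) test_covariates$X
       else build_design(test_covariates, encoding = fits$encoding)$X

  if (mode == "regression") {
    if (!inherits(fits, "cmmp_ols"))
      stop("regression mode requires OLS fits from `fit_ols()`", call. = FALSE)
    theta <- X %*% fits$beta
    dimnames(theta) <- dimnames(Y)
    return(structure(list(theta_hat = theta, assigned = NULL,
                          consensus = NULL, method = "regression"),
                     class = "cmmp_predictions"))
  }

  if (!inherits(fits, "cmmp_fits"))
    stop("cmmp/oracle mode requires mixed-model fits from `fit_all_outcomes()`",
         call. = FALSE)
  if (anyNA(Y))
    stop("matched CMMP requires observed test outcomes without missing values",
         call. = FALSE)
  M <- ncol(Y)
  if (M != ncol(fits$beta))
    stop("test outcomes and fits disagree on the number of outcomes",
         call. = FALSE)
  lp <- X %*% fits$beta                      # fixed-effect predictions
  theta <- matrix(NA_real_, nrow(Y), M, dimnames = dimnames(Y))
  assigned <- matrix(NA_integer_, nrow(Y), M, dimnames = dimnames(Y))
  for (m in seq_len(M)) {
    if (!fits$converged[m]) next
    r <- Y[, m] - lp[, m]
    d <- outer(r, fits$alpha[, m], "-")
    idx <- max.col(-(d * d), ties.method = "first")
    assigned[, m] <- idx
    theta[, m] <- lp[, m] + fits$alpha[idx, m]
  }
  consensus <- apply(assigned, 1L, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0L) NA_integer_ else consensus_cluster(z)
  })
  structure(list(theta_hat = theta, assigned = assigned,
                 consensus = consensus, method = mode),
            class = "cmmp_predictions")
}

#' @export
print.cmmp_predictions <- function(x, ...) {
  cat(sprintf("CMMP predictions (method = %s): %d test samples x %d outcomes\n",
              x$method, nrow(x$theta_hat), ncol(x$theta_hat)))
  invisible(x)
}

#' Convert a prediction set to a long-format data frame
#'
#' One row per (sample, outcome): sample, outcome, method, assigned cluster
#' (NA for methods without classification) and predicted mixed effect.
#'
#' @param pred a `cmmp_predictions` object.
#' @return a data.frame in long format.
#' @export
predictions_long <- function(pred) {
  stopifnot(inherits(pred, "cmmp_predictions"))
  th <- pred$theta_hat
  samples <- rownames(th); if (is.null(samples)) samples <- seq_len(nrow(th))
  outcomes <- colnames(th); if (is.null(outcomes)) outcomes <- seq_len(ncol(th))
  data.frame(
    sample = rep(samples, times = ncol(th)),
    outcome = rep(outcomes, each = nrow(th)),
    method = pred$method,
    assigned_cluster = if (is.null(pred$assigned)) NA_integer_
                       else as.vector(pred$assigned),
    theta_hat = as.vector(th),
    stringsAsFactors = FALSE
  )
}
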