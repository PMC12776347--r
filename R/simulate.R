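#' Default covariate sampling distributions for the synthetic cohort
#'
#' Parametric stand-ins for the empirical covariate marginals of a pan-cancer
#' (cervical + lung adenocarcinoma) cohort: per-gene copy-number alteration
#' (CNA) calls on the usual 5-level scale, cancer type with P(CESC) = 254/655,
#' consolidated stage I-IV, age as a truncated normal on [20, 90] years, sex
#' sampled conditionally on cancer type (CESC is always female), and a race
#' table for the non-White categories (renormalized after the White fraction
#' `bias` is fixed).  All tables can be overridden through
#' [simulation_config()].
#'
#' @return a named list of distribution tables.
#' @export
default_covariate_distributions <- function() {
  list(
    cna_levels = c(-2L, -1L, 0L, 1L, 2L),
    cna_probs  = c(0.05, 0.15, 0.60, 0.15, 0.05),
    race_nonwhite = c("AI/AN" = 0.09, Asian = 0.53, Black = 0.32, NHPI = 0.06),
    stage_probs = c(I = 0.45, II = 0.25, III = 0.20, IV = 0.10),
    p_cesc = 254 / 655,
    p_female_luad = 0.55,
    age_mean = 57, age_sd = 13, age_range = c(20, 90)
  )
}

#' Configuration of the synthetic methylation cohort
#'
#' Defines the data-generating process used throughout the simulation study:
#' `n_samples` patients with CNA and clinical covariates, a White fraction
#' `bias`, `n_clusters` latent methylation clusters with random intercepts of
#' standard deviation `sigma_alpha`, per-outcome fixed effects drawn
#' `N(0, beta_variance)`, independent errors `N(0, error_variance)`, and
#' "clumpy dependence" across outcomes: two blocks of `block_size` outcomes in
#' which every pair of random intercepts shares covariance `block_covariance`
#' (outcomes outside the blocks are uncorrelated).
#'
#' When `block_covariance` exceeds `sigma_alpha^2` the requested covariance
#' matrix is not positive semidefinite; by default it is clamped to
#' `0.99 * sigma_alpha^2` with a warning (`strict_psd = TRUE` raises instead),
#' and `block_cov_interpretation = "correlation"` reads the value as a
#' correlation instead of a covariance.
#'
#' @param n_samples cohort size (default 655).
#' @param n_outcomes number of methylation outcomes M (default 2275; reduce
#'   for desk-scale work).
#' @param n_cna number of CNA covariates (default 65).
#' @param bias White fraction b, strictly in (0, 1); exactly
#'   `round(bias * n_samples)` samples are assigned race White
#'   (round-half-even).
#' @param n_clusters true number of latent clusters c.
#' @param sigma_alpha standard deviation of the cluster random intercepts.
#' @param error_variance variance of the measurement error (default .9).
#' @param beta_variance variance of each fixed-effect coefficient (default .03).
#' @param block_covariance within-block covariance of random intercepts across
#'   outcomes (default .07).
#' @param n_blocks number of correlated outcome blocks (default 2).
#' @param block_size outcomes per block; defaults to `n_outcomes %/% 4`.
#' @param block_cov_interpretation `"covariance"` (default) or `"correlation"`.
#' @param strict_psd error instead of clamping a non-PSD block covariance.
#' @param train_fraction_cesc fraction of CESC samples assigned to training
#'   (all LUAD samples always train).
#' @param stratify_split stratify the CESC train/test split by race (default
#'   TRUE; FALSE gives a plain random split).
#' @param covariate_distributions see [default_covariate_distributions()].
#' @return an object of class `cmmp_config`.
#' @export
simulation_config <- function(n_samples = 655L,
                              n_outcomes = 2275L,
                              n_cna = 65L,
                              bias = 0.78,
                              n_clusters = 6L,
                              sigma_alpha = 0.2,
                              error_variance = 0.9,
                              beta_variance = 0.03,
                              block_covariance = 0.07,
                              n_blocks = 2L,
                              block_size = NULL,
                              block_cov_interpretation = c("covariance", "correlation"),
                              strict_psd = FALSE,
                              train_fraction_cesc = 0.7,
                              stratify_split = TRUE,
                              covariate_distributions = default_covariate_distributions()) {
  block_cov_interpretation <- match.arg(block_cov_interpretation)
  if (is.null(block_size)) block_size <- n_outcomes %/% 4L
  if (!is.numeric(bias) || length(bias) != 1L || bias <= 0 || bias >= 1)
    stop("`bias` must lie strictly in (0, 1)", call. = FALSE)
  stopifnot(n_samples >= 2L, n_outcomes >= 1L, n_cna >= 0L, n_clusters >= 1L,
            sigma_alpha >= 0, beta_variance >= 0,
            n_blocks >= 0L, block_size >= 0L,
            train_fraction_cesc > 0, train_fraction_cesc <= 1)
  if (error_variance <= 0)
    stop("`error_variance` must be positive", call. = FALSE)
  if (n_blocks * block_size > n_outcomes)
    stop("`n_blocks * block_size` cannot exceed `n_outcomes`", call. = FALSE)
  cd <- covariate_distributions
  assert_prob_table(cd$cna_probs, "cna_probs")
  assert_prob_table(cd$race_nonwhite, "race_nonwhite")
  assert_prob_table(cd$stage_probs, "stage_probs")
  if (bias < 1 && length(cd$race_nonwhite) == 0L)
    stop("non-White race table is empty but bias < 1", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), n_outcomes = as.integer(n_outcomes),
    n_cna = as.integer(n_cna), bias = bias,
    n_clusters = as.integer(n_clusters), sigma_alpha = sigma_alpha,
    error_variance = error_variance, beta_variance = beta_variance,
    block_covariance = block_covariance, n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size),
    block_cov_interpretation = block_cov_interpretation,
    strict_psd = strict_psd,
    train_fraction_cesc = train_fraction_cesc,
    stratify_split = stratify_split,
    covariate_distributions = cd
  ), class = "cmmp_config")
}

#' @export
print.cmmp_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d samples, M = %d outcomes, %d CNA covariates\n",
              x$n_samples, x$n_outcomes, x$n_cna))
  cat(sprintf("  White fraction b = %.3f, clusters c = %d, sigma_alpha = %.2f\n",
              x$bias, x$n_clusters, x$sigma_alpha))
  cat(sprintf("  error variance = %.2f, beta variance = %.3f\n",
              x$error_variance, x$beta_variance))
  cat(sprintf("  %d outcome blocks of %d, block covariance %.3f (%s)\n",
              x$n_blocks, x$block_size, x$block_covariance,
              x$block_cov_interpretation))
  invisible(x)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample a synthetic covariate table
#'
#' Draws `n_samples` rows of covariates using the current RNG state: exactly
#' `round(bias * n)` rows (round-half-even) are assigned race White at random
#' positions; the remaining rows draw race from the renormalized non-White
#' table.  CNA covariates are sampled independently; sex is sampled
#' conditionally on cancer type with CESC forced female.
#'
#' @param config a [simulation_config()].
#' @return a data.frame with columns `sample_id`, `cna_1..cna_p`,
#'   `cancer_type`, `stage`, `age`, `sex`, `race`.  Categorical columns are
#'   factors with only the levels realized in the table.
#' @export
sample_covariates <- function(config) {
  stopifnot(inherits(config, "cmmp_config"))
  n <- config$n_samples
  cd <- config$covariate_distributions
  b <- config$bias
  if (b <= 0 || b >= 1) stop("`bias` must lie strictly in (0, 1)", call. = FALSE)

  n_white <- round(b * n)  # round-half-even
  race <- character(n)
  white_rows <- sample.int(n, n_white)
  race[white_rows] <- "White"
  if (n_white < n) {
    nw <- cd$race_nonwhite / sum(cd$race_nonwhite)
    race[-white_rows] <- sample(names(nw), n - n_white, replace = TRUE, prob = nw)
  }

  cna <- matrix(sample(cd$cna_levels, n * config$n_cna, replace = TRUE,
                       prob = cd$cna_probs),
                nrow = n, ncol = config$n_cna)
  colnames(cna) <- sprintf("cna_%d", seq_len(config$n_cna))

  cancer <- ifelse(stats::runif(n) < cd$p_cesc, "CESC", "LUAD")
  stage <- sample(names(cd$stage_probs), n, replace = TRUE, prob = cd$stage_probs)
  age <- rtruncnorm1(n, cd$age_mean, cd$age_sd, cd$age_range[1], cd$age_range[2])
  sex <- ifelse(cancer == "CESC", "female",
                ifelse(stats::runif(n) < cd$p_female_luad, "female", "male"))

  out <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    cna,
    cancer_type = factor(cancer),
    stage = factor(stage, levels = sort(unique(stage))),
    age = age,
    sex = factor(sex),
    race = factor(race, levels = sort(unique(race))),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- out$sample_id
  out
}

# Resolve the effective within-block covariance, clamping (or refusing) a
# non-PSD request: marginal variance sigma^2 with common block covariance tau
# is PSD only when tau <= sigma^2.
effective_block_cov <- function(config) {
  s2 <- config$sigma_alpha^2
  tau <- switch(config$block_cov_interpretation,
                covariance = config$block_covariance,
                correlation = config$block_covariance * s2)
  if (tau < 0) stop("block covariance must be non-negative", call. = FALSE)
  if (tau > s2) {
    if (config$strict_psd)
      stop(sprintf(paste0("block covariance %.4f exceeds sigma_alpha^2 = %.4f: ",
                          "requested intercept covariance is not positive ",
                          "semidefinite"), tau, s2), call. = FALSE)
    tau_new <- 0.99 * s2
    warning(sprintf(paste0("block covariance %.4f exceeds sigma_alpha^2 = %.4f; ",
                           "clamped to 0.99 * sigma_alpha^2 = %.4f"),
                    tau, s2, tau_new), call. = FALSE)
    tau <- tau_new
  }
  tau
}

# 0/1 membership of each outcome in a correlated block (blocks occupy the
# first n_blocks * block_size outcome indices, deterministically).
block_index <- function(config) {
  blk <- integer(config$n_outcomes)
  if (config$n_blocks > 0L && config$block_size > 0L) {
    for (j in seq_len(config$n_blocks)) {
      idx <- ((j - 1L) * config$block_size + 1L):(j * config$block_size)
      blk[idx] <- j
    }
  }
  blk
}

#' Sample cluster random intercepts with clumpy dependence
#'
#' Each cluster's intercept vector over the M outcomes is multivariate normal
#' with marginal variance `sigma_alpha^2`, common covariance
#' (the effective block covariance, see [simulation_config()]) within each
#' block, and zero covariance elsewhere.  Sampling uses the exchangeable-block
#' factorization: intercept = sqrt(tau) * shared block factor +
#' sqrt(sigma^2 - tau) * idiosyncratic normal, so no M x M Cholesky is formed.
#'
#' @param config a [simulation_config()].
#' @param n_draws number of independent cluster vectors (default
#'   `config$n_clusters`).
#' @return an `n_draws x n_outcomes` matrix.
#' @export
sample_random_intercepts <- function(config, n_draws = config$n_clusters) {
  stopifnot(inherits(config, "cmmp_config"), n_draws >= 1L)
  M <- config$n_outcomes
  s2 <- config$sigma_alpha^2
  if (s2 == 0) return(matrix(0, n_draws, M))
  tau <- effective_block_cov(config)
  blk <- block_index(config)
  sd_idio <- ifelse(blk > 0L, sqrt(s2 - tau), sqrt(s2))
  a <- matrix(stats::rnorm(n_draws * M), n_draws, M) *
    rep(sd_idio, each = n_draws)
  if (config$n_blocks > 0L && tau > 0) {
    u <- matrix(stats::rnorm(n_draws * config$n_blocks), n_draws,
                config$n_blocks) * sqrt(tau)
    for (j in seq_len(config$n_blocks)) {
      cols <- which(blk == j)
      a[, cols] <- a[, cols] + u[, j]
    }
  }
  a
}

split_train_test <- function(covariates, train_fraction_cesc, stratify) {
  is_cesc <- covariates$cancer_type == "CESC"
  train <- !is_cesc  # all LUAD samples train
  cesc_idx <- which(is_cesc)
  if (length(cesc_idx) == 0L) return(train)
  pick <- function(idx) {
    n_tr <- round(train_fraction_cesc * length(idx))
    if (n_tr >= length(idx)) idx else sample(idx, n_tr)
  }
  if (stratify) {
    for (r in unique(covariates$race[cesc_idx])) {
      idx <- cesc_idx[covariates$race[cesc_idx] == r]
      train[pick(idx)] <- TRUE
    }
  } else {
    train[pick(cesc_idx)] <- TRUE
  }
  train
}

#' Generate a complete synthetic dataset
#'
#' Assembles covariates, per-outcome fixed effects `beta_m ~ N(0, beta_variance)`
#' over the encoded design, uniform cluster labels, clumpy-dependent random
#' intercepts, and independent errors `N(0, error_variance)`; the observed
#' outcome is `y = theta + eps` with true mixed effect
#' `theta_im = x_i beta_m + alpha_{j_i, m}`.  Identical `config` + `seed`
#' give an identical dataset on any platform.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed for this dataset.
#' @return an object of class `cmmp_dataset`: a list with `covariates`,
#'   `design` (the encoded design, see [build_design()]), `outcomes` (n x M),
#'   `theta` (n x M true mixed effects), `clusters` (true labels),
#'   `betas` (p x M), `alphas` (c x M), `train` (logical mask) and `config`.
#' @export
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "cmmp_config"))
  with_fixed_seed(seed, {
    covariates <- sample_covariates(config)
    train <- split_train_test(covariates, config$train_fraction_cesc,
                              config$stratify_split)
    design <- build_design(covariates)
    X <- design$X
    n <- config$n_samples; M <- config$n_outcomes; p <- ncol(X)
    betas <- matrix(stats::rnorm(p * M, sd = sqrt(config$beta_variance)), p, M,
                    dimnames = list(colnames(X), NULL))
    clusters <- sample.int(config$n_clusters, n, replace = TRUE)
    alphas <- sample_random_intercepts(config)
    theta <- X %*% betas + alphas[clusters, , drop = FALSE]
    eps <- matrix(stats::rnorm(n * M, sd = sqrt(config$error_variance)), n, M)
    outcomes <- theta + eps
    out_names <- sprintf("m%04d", seq_len(M))
    dimnames(outcomes) <- dimnames(theta) <-
      list(covariates$sample_id, out_names)
    colnames(betas) <- out_names
    colnames(alphas) <- out_names
    structure(list(covariates = covariates, design = design,
                   outcomes = outcomes, theta = theta,
                   clusters = clusters, betas = betas, alphas = alphas,
                   train = train, seed = seed, config = config),
              class = "cmmp_dataset")
  })
}

#' @export
print.cmmp_dataset <- function(x, ...) {
  cat(sprintf("Synthetic methylation dataset: %d samples x %d outcomes\n",
              nrow(x$outcomes), ncol(x$outcomes)))
  cat(sprintf("  %d training / %d test samples; %d true clusters; seed %s\n",
              sum(x$train), sum(!x$train), x$config$n_clusters,
              format(x$seed)))
  invisible(x)
}

#' Empirical signal-to-noise ratio of fitted outcome models
#'
#' SNR = Var(X beta_hat) / R_hat per outcome: the sample variance of the
#' fitted fixed-effect linear predictor over the supplied samples, divided by
#' the estimated error variance.
#'
#' @param covariates covariate table (or a prebuilt `cmmp_design`).
#' @param fit a `cmmp_fits` object from [fit_all_outcomes()].
#' @return numeric vector of per-outcome SNR values.
#' @export
empirical_snr <- function(covariates, fit) {
  stopifnot(inherits(fit, "cmmp_fits"))
  X <- if (inherits(covariates, "cmmp_design")) covariates$X
       else build_design(covariates, encoding = fit$encoding)$X
  if (any(fit$R <= 0)) stop("zero or negative error-variance estimate",
                            call. = FALSE)
  lp <- X %*% fit$beta
  apply(lp, 2L, stats::var) / fit$R
}

#' Write a simulated dataset to a directory of CSV files
#'
#' Writes `covariates.csv`, `outcomes.csv`, `truth_theta.csv`,
#' `truth_clusters.csv` (all samples-as-rows with the sample ID in the first
#' column) and `meta.yaml` holding the generating configuration and seed.
#'
#' @param dataset a `cmmp_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cmmp_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  write_matrix(dataset$outcomes, file.path(dir, "outcomes.csv"))
  write_matrix(dataset$theta, file.path(dir, "truth_theta.csv"))
  utils::write.csv(data.frame(sample_id = dataset$covariates$sample_id,
                              cluster = dataset$clusters,
                              train = dataset$train),
                   file.path(dir, "truth_clusters.csv"), row.names = FALSE)
  cfg <- dataset$config
  cfg$covariate_distributions <- lapply(cfg$covariate_distributions, as.vector)
  yaml::write_yaml(c(unclass(cfg), list(seed = dataset$seed)),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}
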