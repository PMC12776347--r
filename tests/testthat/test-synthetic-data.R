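test_that("configuration rejects invalid bias and degenerate tables", {
  expect_error(simulation_config(bias = 1.0), "strictly in")
  expect_error(simulation_config(bias = 0), "strictly in")
  expect_error(simulation_config(error_variance = 0), "positive")
  bad <- default_covariate_distributions()
  bad$stage_probs <- c(I = 0.5, II = 0.6)
  expect_error(simulation_config(covariate_distributions = bad), "sum to 1")
})

test_that("White fraction is exactly round(b * n) / n", {
  cfg <- desk_config(M = 5, n_samples = 100L, bias = 0.9)
  cov <- withr::with_seed(1, sample_covariates(cfg))
  expect_identical(sum(cov$race == "White"), 90L)
  cfg2 <- desk_config(M = 5, bias = 0.78)  # n = 655
  cov2 <- withr::with_seed(2, sample_covariates(cfg2))
  expect_identical(sum(cov2$race == "White"), as.integer(round(0.78 * 655)))
})

test_that("CESC samples are always recorded female", {
  cd <- default_covariate_distributions()
  cd$p_cesc <- 1
  cfg <- desk_config(M = 5, n_samples = 200L, covariate_distributions = cd)
  cov <- withr::with_seed(3, sample_covariates(cfg))
  expect_true(all(cov$cancer_type == "CESC"))
  expect_true(all(cov$sex == "female"))
  # and in a mixed cohort the rule holds conditionally
  ds <- quiet_dataset(desk_config(M = 5), 4)
  cesc <- ds$covariates$cancer_type == "CESC"
  expect_true(all(ds$covariates$sex[cesc] == "female"))
})

test_that("non-White race draws follow the renormalized table", {
  cd <- default_covariate_distributions()
  cd$race_nonwhite <- c(Black = 0.5, Asian = 0.5)
  cfg <- desk_config(M = 5, n_samples = 10000L, bias = 0.5,
                     covariate_distributions = cd)
  cov <- withr::with_seed(5, sample_covariates(cfg))
  n_black <- sum(cov$race == "Black")
  # 5000 non-White draws, binomial(5000, .5): 3 s.e. ~ 106
  expect_lt(abs(n_black - 2500), 3 * sqrt(5000 * 0.25) + 1)
})

test_that("clumpy dependence gives the stated block covariance", {
  # sigma = 1 so tau = .07 needs no clamping; Monte-Carlo check of the
  # within-block covariance over many cluster draws
  cfg <- desk_config(M = 8, sigma_alpha = 1, block_size = 2L, n_blocks = 2L)
  a <- withr::with_seed(6, sample_random_intercepts(cfg, n_draws = 20000L))
  cv <- cov(a)
  se3 <- 3 / sqrt(20000)  # crude s.e. scale for covariance of unit normals
  expect_lt(abs(cv[1, 2] - 0.07), 3 * se3)
  expect_lt(abs(cv[3, 4] - 0.07), 3 * se3)
  expect_lt(abs(cv[1, 3]), 3 * se3)      # across blocks: independent
  expect_lt(abs(cv[5, 6]), 3 * se3)      # outside blocks: independent
  expect_lt(max(abs(diag(cv) - 1)), 0.05)
})

test_that("non-PSD block covariance is clamped with a warning, or errors in strict mode", {
  cfg <- desk_config(M = 8, sigma_alpha = 0.2, block_size = 2L)
  expect_warning(a <- withr::with_seed(7, sample_random_intercepts(cfg)),
                 "clamped")
  expect_equal(dim(a), c(6L, 8L))
  strict <- desk_config(M = 8, sigma_alpha = 0.2, block_size = 2L,
                        strict_psd = TRUE)
  expect_error(sample_random_intercepts(strict), "not positive semidefinite")
  # correlation interpretation never needs clamping for rho < 1
  corr <- desk_config(M = 8, sigma_alpha = 0.2, block_size = 2L,
                      block_cov_interpretation = "correlation")
  expect_silent(withr::with_seed(8, sample_random_intercepts(corr)))
})

test_that("degenerate intercept structures behave as defined", {
  cfg0 <- desk_config(M = 6, sigma_alpha = 0)
  expect_true(all(sample_random_intercepts(cfg0) == 0))
  # blocks of size 1 have no pairs: diagonal covariance
  cfg1 <- desk_config(M = 4, sigma_alpha = 1, block_size = 1L, n_blocks = 2L)
  a <- withr::with_seed(9, sample_random_intercepts(cfg1, n_draws = 20000L))
  off <- cov(a)[upper.tri(diag(4))]
  expect_lt(max(abs(off)), 3 * 3 / sqrt(20000))
})

test_that("observed outcomes decompose exactly as theta + error", {
  ds <- quiet_dataset(desk_config(M = 30), 11)
  eps <- ds$outcomes - ds$theta
  theta_rebuilt <- ds$design$X %*% ds$betas +
    ds$alphas[ds$clusters, , drop = FALSE]
  expect_equal(max(abs(ds$theta - theta_rebuilt)), 0)
  expect_equal(ds$theta + eps, ds$outcomes)
})

test_that("marginal moments match the generating parameters", {
  cfg <- desk_config(M = 200)
  ds <- quiet_dataset(cfg, 12)
  eps <- as.vector(ds$outcomes - ds$theta)
  n <- length(eps)  # 131000 draws
  expect_lt(abs(var(eps) - 0.9), 3 * 0.9 * sqrt(2 / n))
  b <- as.vector(ds$betas)
  expect_lt(abs(var(b) - 0.03), 3 * 0.03 * sqrt(2 / length(b)))
  a <- as.vector(ds$alphas)
  expect_lt(abs(var(a) - 0.04), 3 * 0.04 * sqrt(2 / length(a)) + 0.005)
})

test_that("same config and seed reproduce the dataset exactly", {
  cfg <- desk_config(M = 20)
  d1 <- quiet_dataset(cfg, 99)
  d2 <- quiet_dataset(cfg, 99)
  expect_identical(d1$outcomes, d2$outcomes)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$clusters, d2$clusters)
  expect_identical(d1$train, d2$train)
  d3 <- quiet_dataset(cfg, 100)
  expect_false(identical(d1$outcomes, d3$outcomes))
})

test_that("single-cluster data has one shared intercept per outcome", {
  ds <- quiet_dataset(desk_config(M = 10, n_clusters = 1L), 13)
  expect_true(all(ds$clusters == 1L))
  expect_equal(nrow(ds$alphas), 1L)
})

test_that("train/test split keeps all LUAD in training and ~70% of CESC", {
  ds <- quiet_dataset(desk_config(M = 5), 14)
  luad <- ds$covariates$cancer_type == "LUAD"
  expect_true(all(ds$train[luad]))
  cesc_train <- sum(ds$train & !luad)
  n_cesc <- sum(!luad)
  expect_lt(abs(cesc_train - 0.7 * n_cesc), 0.03 * n_cesc)
  expect_true(any(!ds$train))
})

test_that("empirical SNR matches closed forms and the design value", {
  # single covariate, variance 4, beta = 1, R = 2 -> SNR = 2
  X <- cbind(`(Intercept)` = rep(1, 4), x = c(-3, -1, 1, 3))
  fit <- structure(list(beta = matrix(c(0, 1), 2),
                        R = 2, encoding = NULL), class = "cmmp_fits")
  d <- structure(list(X = X, encoding = NULL), class = "cmmp_design")
  expect_equal(unname(empirical_snr(d, fit)), var(c(-3, -1, 1, 3)) / 2)
  fit0 <- structure(list(beta = matrix(c(0, 0), 2), R = 2, encoding = NULL),
                    class = "cmmp_fits")
  expect_equal(unname(empirical_snr(d, fit0)), 0)
  fit_bad <- structure(list(beta = matrix(c(0, 1), 2), R = 0,
                            encoding = NULL), class = "cmmp_fits")
  expect_error(empirical_snr(d, fit_bad), "error-variance")
  # on simulated data the SNR recomputed from the truth is recovered
  ds <- quiet_dataset(desk_config(M = 20), 15)
  lp <- ds$design$X %*% ds$betas
  snr_true <- apply(lp, 2, var) / 0.9
  tr <- ds$train
  fits <- fit_all_outcomes(ds$outcomes[tr, ], structure(
    list(X = ds$design$X[tr, ], encoding = ds$design$encoding),
    class = "cmmp_design"), ds$clusters[tr])
  snr_hat <- empirical_snr(ds$covariates[tr, ], fits)
  expect_equal(median(snr_hat), median(snr_true), tolerance = 0.25)
})

test_that("a dataset round-trips through its CSV directory format", {
  ds <- quiet_dataset(desk_config(M = 6, n_samples = 40L, n_cna = 5L,
                                  covariate_distributions = {
                                    cd <- default_covariate_distributions()
                                    cd$p_cesc <- 0.5
                                    cd
                                  }), 16)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("covariates.csv", "outcomes.csv", "truth_theta.csv",
      "truth_clusters.csv", "meta.yaml")))))
  y <- read_matrix(file.path(dir, "outcomes.csv"))
  expect_equal(y, ds$outcomes, tolerance = 1e-12)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  expect_equal(meta$seed, 16)
})
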