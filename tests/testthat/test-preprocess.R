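test_that("boundary beta values become missing, interior values survive", {
  m <- matrix(c(0, 0.5, 1, 1 - 1e-9, 0.2, 0.8), 2, 3,
              dimnames = list(NULL, c("p", "q", "r")))
  out <- mark_boundary_missing(m)
  expect_true(is.na(out[1, 1]) && is.na(out[1, 2]))
  expect_equal(unname(out[2, 2]), 1 - 1e-9)   # strict equality rule
  expect_equal(out[c(2, 4, 5, 6)], m[c(2, 4, 5, 6)])
  interior <- matrix(runif(10, 0.1, 0.9), 2, 5)
  expect_equal(mark_boundary_missing(interior), interior)
  expect_error(mark_boundary_missing(matrix(c(-0.1, 0.5), 1)), "\\[0, 1\\]")
})

test_that("missing or unshared features are dropped from both cohorts", {
  a <- matrix(runif(9, .2, .8), 3, 3, dimnames = list(NULL, c("p", "q", "r")))
  b <- matrix(runif(9, .2, .8), 3, 3, dimnames = list(NULL, c("q", "r", "s")))
  out <- drop_missing_or_unshared(a, b)
  expect_identical(colnames(out$a), c("q", "r"))
  expect_identical(colnames(out$b), c("q", "r"))
  expect_identical(out$report$dropped_unshared, "p")
  expect_identical(out$report$dropped_unshared_other, "s")
  b2 <- b; b2[1, "q"] <- NA
  out2 <- drop_missing_or_unshared(a, b2)
  expect_identical(colnames(out2$a), "r")
  expect_identical(out2$report$dropped_missing, "q")
  out3 <- drop_missing_or_unshared(a, a)
  expect_identical(out3$a, a)
  expect_error(drop_missing_or_unshared(
    a, matrix(1, 1, 1, dimnames = list(NULL, "z"))), "shared")
})

test_that("SD filter keeps features at or above the threshold", {
  m <- cbind(const = rep(0.5, 4), alt = c(0.1, 0.9, 0.1, 0.9),
             low = c(0.50, 0.50, 0.50, 0.88), hi = c(0.5, 0.5, 0.5, 0.92))
  # hand-computed reference SDs
  expect_equal(sd(m[, "low"]), 0.19, tolerance = 1e-10)
  expect_equal(sd(m[, "hi"]), 0.21, tolerance = 1e-10)
  out <- filter_methyl_by_sd(m, threshold = 0.2)
  expect_identical(colnames(out), c("alt", "hi"))
  expect_setequal(attr(out, "dropped"), c("const", "low"))
  expect_error(filter_methyl_by_sd(m[1, , drop = FALSE]), "two reference")
})

test_that("correlation pruning removes redundant CNA features deterministically", {
  withr::with_seed(21, {
    n <- 200
    base <- rnorm(n)
    cna <- cbind(f1 = base, f2 = base + rnorm(n, sd = 1e-3),
                 f3 = rnorm(n), f4 = rnorm(n))
    out <- filter_cna(cna, variance_quantile = 0, corr_threshold = 0.7)
    # perfectly correlated pair: exactly one survives
    expect_identical(sum(c("f1", "f2") %in% colnames(out)), 1L)
    expect_true(all(c("f3", "f4") %in% colnames(out)))
    # pairwise-uncorrelated features: stage 2 is the identity
    ind <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
    out2 <- filter_cna(ind, variance_quantile = 0)
    expect_identical(ncol(out2), 4L)
  })
  expect_error(filter_cna(matrix(1, 5, 2)), "constant")
})

test_that("variance stage keeps the top share by the quantile rule", {
  withr::with_seed(22, {
    sds <- seq(0.1, 2, length.out = 20)
    cna <- sapply(sds, function(s) rnorm(100, sd = s))
    colnames(cna) <- paste0("v", 1:20)
    out <- filter_cna(cna, variance_quantile = 0.85, corr_threshold = 0.99)
    v <- apply(cna, 2, var)
    expect_setequal(colnames(out), names(v)[v >= quantile(v, 0.85)])
  })
})

test_that("pruning retains a maximum independent set on a path graph", {
  # 5 features chained at rho ~ .8 (next-nearest ~ .64 < .7): the adjacency
  # at |r| > .7 is a path graph whose maximum independent set has size 3;
  # verified against exhaustive search
  withr::with_seed(23, {
    n <- 5000
    z <- matrix(rnorm(n * 5), n, 5)
    x1 <- z[, 1]
    x2 <- 0.8 * scale(x1)[, 1] + sqrt(1 - 0.64) * z[, 2]
    x3 <- 0.8 * scale(x2)[, 1] + sqrt(1 - 0.64) * z[, 3]
    x4 <- 0.8 * scale(x3)[, 1] + sqrt(1 - 0.64) * z[, 4]
    x5 <- 0.8 * scale(x4)[, 1] + sqrt(1 - 0.64) * z[, 5]
    cna <- cbind(a = x1, b = x2, c = x3, d = x4, e = x5)
    r <- cor(cna)
    adj <- abs(r) > 0.7; diag(adj) <- FALSE
    expect_identical(unname(rowSums(adj)), c(1, 2, 2, 2, 1))  # a path
    out <- filter_cna(cna, variance_quantile = 0, corr_threshold = 0.7)
    expect_identical(ncol(out), max_independent_set_size(adj))
  })
})

test_that("M-value transform matches closed forms and is strictly increasing", {
  expect_equal(m_value_transform(matrix(0.5)), matrix(0))
  expect_equal(m_value_transform(matrix(0.8)), matrix(2))
  expect_equal(m_value_transform(matrix(0.2)), matrix(-2))
  x <- matrix(seq(0.01, 0.99, by = 0.01), 1)
  expect_true(all(diff(drop(m_value_transform(x))) > 0))
  # antisymmetry M(x) = -M(1 - x)
  expect_equal(m_value_transform(x), -m_value_transform(1 - x))
  # missing propagates; boundary values are a pipeline-order violation
  xm <- matrix(c(NA, 0.5), 1); expect_true(is.na(m_value_transform(xm)[1]))
  expect_error(m_value_transform(matrix(c(0, 0.5), 1)), "boundary")
})

test_that("within-group standardization zeroes group means and is idempotent", {
  withr::with_seed(24, {
    m <- matrix(rnorm(60, mean = rep(c(0, 5), each = 30)), 60, 4)
    g <- rep(c("a", "b"), each = 30)
    s <- standardize_within_group(m, g)
    for (lev in c("a", "b")) {
      expect_lt(max(abs(colMeans(s[g == lev, ]))), 1e-12)
      expect_equal(unname(apply(s[g == lev, ], 2, sd)), rep(1, 4))
    }
    expect_equal(standardize_within_group(s, g), s, tolerance = 1e-10)
    # single group reduces to ordinary z-scoring
    z <- standardize_within_group(m, rep("a", 60))
    expect_equal(z, scale(m)[, ], tolerance = 1e-12, ignore_attr = TRUE)
  })
  # hand-computed two-group, three-sample toy
  toy <- matrix(c(1, 2, 3, 10, 12, 14), 6, 1)
  g <- rep(c("a", "b"), each = 3)
  s <- standardize_within_group(toy, g)
  expect_equal(drop(s), c(-1, 0, 1, -1, 0, 1))
  const <- matrix(c(1, 1, 1, 2, 3, 4), 6, 1,
                  dimnames = list(NULL, "f1"))
  expect_error(standardize_within_group(const, g), "zero within-group SD")
})

test_that("the full preprocessing pipeline accounts for every dropped feature", {
  withr::with_seed(25, {
    n_a <- 30; n_b <- 40
    feats <- paste0("cg", 1:12)
    ma <- matrix(runif(n_a * 12, 0.05, 0.95), n_a, 12,
                 dimnames = list(NULL, feats))
    mb <- matrix(runif(n_b * 12, 0.05, 0.95), n_b, 12,
                 dimnames = list(NULL, feats))
    # engineer one boundary-missing feature, one unshared, one low-SD
    ma[1, "cg1"] <- 0
    colnames(mb)[12] <- "cgX"
    ma[, "cg2"] <- 0.5 + seq(-0.01, 0.01, length.out = n_a)
    cna_a <- matrix(rnorm(n_a * 6), n_a, 6,
                    dimnames = list(NULL, paste0("g", 1:6)))
    cna_b <- matrix(rnorm(n_b * 6), n_b, 6,
                    dimnames = list(NULL, paste0("g", 1:6)))
    out <- preprocess_pipeline(ma, mb, cna_a, cna_b, sd_threshold = 0.05)
    rep <- out$report
    accounted <- length(rep$dropped_missing) + length(rep$dropped_unshared) +
      length(rep$dropped_low_sd)
    expect_identical(rep$n_input_methyl - accounted, rep$n_output_methyl)
    expect_true("cg1" %in% rep$dropped_missing)
    expect_identical(rep$dropped_unshared, "cg12")
    expect_true("cg2" %in% rep$dropped_low_sd)
    # outputs are standardized within cohort
    expect_lt(max(abs(colMeans(out$methyl[out$cancer_type == "a", ]))), 1e-12)
  })
})
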