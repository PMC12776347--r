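# Shared fixtures: all synthetic, built in code at test time.

# Desk-scale configuration; the default (sigma = .2) block covariance is
# clamped with a warning, which callers silence explicitly.
desk_config <- function(M = 50L, ...) {
  simulation_config(n_outcomes = as.integer(M), ...)
}

quiet_dataset <- function(config, seed) {
  suppressWarnings(generate_dataset(config, seed))
}

# Small regression-style design for mixed-model unit tests.
toy_design <- function(n, p = 3L, seed = 1L) {
  withr::with_seed(seed, {
    X <- cbind(1, matrix(rnorm(n * (p - 1L)), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1L)))
    X
  })
}

toy_mixed_data <- function(n = 90L, k = 3L, G = 0.5, R = 1, seed = 1L,
                           balanced = FALSE, p = 3L) {
  X <- toy_design(n, p, seed)
  withr::with_seed(seed + 1L, {
    lab <- if (balanced) rep(seq_len(k), each = n %/% k)
           else sample.int(k, n, replace = TRUE)
    beta <- rnorm(ncol(X), sd = 0.5)
    y <- drop(X %*% beta) + rnorm(k, sd = sqrt(G))[lab] +
      rnorm(n, sd = sqrt(R))
    list(X = X, labels = lab, y = y, beta = beta)
  })
}

# Dense-matrix REML oracle: direct grid search over gamma with explicit
# covariance matrices (independent of the Woodbury/profiled implementation).
dense_reml_oracle <- function(y, X, labels,
                              gamma_grid = exp(seq(log(1e-4), log(50),
                                                   length.out = 2000))) {
  n <- nrow(X); p <- ncol(X)
  Z <- outer(labels, sort(unique(labels)), "==") * 1
  crit <- function(gamma) {
    V0 <- diag(n) + gamma * tcrossprod(Z)
    Vi <- solve(V0)
    A <- t(X) %*% Vi %*% X
    beta <- solve(A, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    (n - p) * log(rss) + determinant(V0)$modulus + determinant(A)$modulus
  }
  vals <- vapply(gamma_grid, crit, numeric(1))
  i <- which.min(vals)
  # refine around the coarse optimum for ~1e-6 relative resolution
  lo <- gamma_grid[max(1, i - 2)]; hi <- gamma_grid[min(length(vals), i + 2)]
  fine <- exp(seq(log(lo), log(hi), length.out = 2001))
  vals_f <- vapply(fine, crit, numeric(1))
  g <- fine[which.min(vals_f)]
  V0 <- diag(n) + g * tcrossprod(Z)
  Vi <- solve(V0)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  R <- drop(t(r) %*% Vi %*% r) / (n - p)
  list(gamma = g, beta = drop(beta), G = g * R, R = R)
}

# Exhaustive pair-counting ARI (independent of mclust).
ari_brute <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- 0
  pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    s_a <- s_a + sa; s_b <- s_b + sb; s_ab <- s_ab + (sa && sb)
  }
  exp_idx <- s_a * s_b / pairs
  max_idx <- (s_a + s_b) / 2
  if (max_idx == exp_idx) return(1)
  (s_ab - exp_idx) / (max_idx - exp_idx)
}

# Exhaustive maximum independent set size for the correlation-filter oracle.
max_independent_set_size <- function(adj) {
  p <- nrow(adj)
  best <- 0
  for (mask in 0:(2^p - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) > 1) {
      for (i in seq_along(members)[-1]) {
        if (any(adj[members[i], members[seq_len(i - 1)]])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- length(members)
  }
  best
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(n_per, centers, sd_within = 1, seed = 1L) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    x <- centers[rep(seq_len(k), each = n_per), ] +
      matrix(rnorm(n_per * k * ncol(centers), sd = sd_within),
             n_per * k, ncol(centers))
    list(x = x, labels = rep(seq_len(k), each = n_per))
  })
}
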