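#' Derive a child seed from a master seed
#'
#' Counter-based stream splitting: every randomized stage of a pipeline draws
#' its own seed as `child_seed(master, index)` with a fixed stage index, so
#' adding a stage never perturbs the draws of earlier stages.  The map is a
#' Lehmer-style mix modulo 2^31 - 1; all arithmetic is exact in doubles.
#'
#' @param seed master seed (integer-valued).
#' @param index non-negative stage counter.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647
  x <- (abs(as.double(seed)) %% m) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.double(index) %% m) * 2654435) %% m
  x <- (x * 16807) %% m
  as.integer(x %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG state (Mersenne-Twister / Inversion /
# Rejection) and restore the caller's state afterwards.  Pinning the kinds
# makes dataset generation reproducible across sessions and platforms.
with_fixed_seed <- function(seed, code) {
  withr::with_seed(seed, code,
    .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion",
    .rng_sample_kind = "Rejection")
}

# shared argument checks ------------------------------------------------------

assert_matrix_like <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

assert_prob_table <- function(p, name, tol = 1e-12) {
  if (length(p) == 0L || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("probability table `%s` must be non-negative and finite", name),
         call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probability table `%s` must sum to 1 (got %.15f)", name, sum(p)),
         call. = FALSE)
  invisible(p)
}
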