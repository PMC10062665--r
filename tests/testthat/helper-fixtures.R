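# Shared fixtures: all built in code, seeded where random.

reduced_labels <- c("GL", "GH", "BL", "BH")

# A tiny two-participant diary with a gap and an incomplete day.
tiny_diary <- function() {
  tibble::tibble(
    participant_id = c("a", "a", "a", "a", "b", "b", "b"),
    day = c(1L, 2L, 5L, 6L, 1L, 2L, 3L),
    mood = c(4L, 4L, 1L, NA, 2L, 2L, 5L),
    pain = c(1L, 1L, 5L, 3L, 4L, 4L, 1L)
  )
}

# Random strictly-positive (hence regular) row-stochastic matrix.
random_regular_matrix <- function(n = 4) {
  M <- matrix(stats::rexp(n * n) + 0.01, n, n)
  M <- M / rowSums(M)
  dimnames(M) <- if (n == 4) list(reduced_labels, reduced_labels) else NULL
  M
}

# Brute-force stationary distribution by power iteration.
power_iteration_stationary <- function(M, iters = 200) {
  P <- M
  for (i in seq_len(iters)) P <- P %*% M
  P[1, ]
}

# Two well-separated sticky chains, the recovery workhorse.
two_cluster_spec <- function(S, mean_length = 40, seed = 1) {
  cohort_spec(
    S = S, K = 2, weights = c(0.5, 0.5),
    matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
    mean_length = mean_length, seed = seed
  )
}

# Four-regime spec mirroring the qualitative cluster descriptions.
four_regime_matrices <- function() {
  list(
    attractor_matrix(c(0.05, 0.05, 0.10, 0.80)), # -> BH
    attractor_matrix(c(0.80, 0.10, 0.05, 0.05)), # -> GL
    attractor_matrix(c(0.10, 0.75, 0.05, 0.10)), # -> GH
    sticky_matrix(4, 0.85)
  )
}
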