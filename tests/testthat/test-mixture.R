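test_that("component log-likelihood handles zeros in counts and matrix", {
  M <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  C1 <- rbind(c(0, 1), c(0, 0))
  expect_equal(component_loglik(C1, M), log(0.1))
  expect_equal(component_loglik(matrix(0, 2, 2), M), 0)
  expect_equal(component_loglik(rbind(c(2, 0), c(0, 0)), M), 2 * log(0.9))
  # zero count on a zero-probability cell contributes nothing
  M0 <- rbind(c(1, 0), c(0.5, 0.5))
  expect_equal(component_loglik(rbind(c(3, 0), c(0, 0)), M0), 0)
  # positive count on a zero-probability cell is impossible, not an error
  expect_equal(component_loglik(rbind(c(0, 2), c(0, 0)), M0), -Inf)
})

test_that("E-step responsibilities match the closed-form two-component ratio", {
  C <- matrix(0, 4, 4)
  C[1, 1] <- 10 # ten self-transitions in one state
  model <- list(weights = c(0.5, 0.5),
                matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)))
  es <- e_step(model, list(C))
  expect_equal(es$gamma[1, 1], 0.9^10 / (0.9^10 + 0.5^10), tolerance = 1e-12)
  expect_equal(es$loglik, log(0.5 * 0.9^10 + 0.5 * 0.5^10), tolerance = 1e-12)
  # identical components: responsibilities equal the weights
  model2 <- list(weights = c(0.3, 0.7),
                 matrices = list(sticky_matrix(4, 0.7), sticky_matrix(4, 0.7)))
  es2 <- e_step(model2, list(C))
  expect_equal(unname(es2$gamma[1, ]), c(0.3, 0.7), tolerance = 1e-12)
  # zero-count participant: responsibilities equal the weights
  es3 <- e_step(model2, list(matrix(0, 4, 4)))
  expect_equal(unname(es3$gamma[1, ]), c(0.3, 0.7), tolerance = 1e-12)
})

test_that("impossible-under-all-components participants get uniform gamma", {
  M0 <- rbind(c(1, 0), c(0.5, 0.5))
  C <- rbind(c(0, 5), c(0, 0))
  model <- list(weights = c(0.5, 0.5), matrices = list(M0, M0))
  expect_warning(es <- e_step(model, list(C)), "impossible")
  expect_equal(unname(es$gamma[1, ]), c(0.5, 0.5))
})

test_that("M-step recovers per-group MLEs under hard responsibilities", {
  set.seed(5)
  counts <- replicate(6, matrix(rpois(16, 3), 4, 4), simplify = FALSE)
  # hard split: first three vs last three
  gamma <- rbind(matrix(rep(c(1, 0), each = 3), 3),
                 matrix(rep(c(0, 1), each = 3), 3))
  m <- m_step(gamma, counts, epsilon = 0)
  pooled1 <- Reduce(`+`, counts[1:3])
  expect_equal(unname(m$matrices[[1]]), unname(pooled1 / rowSums(pooled1)),
               tolerance = 1e-12)
  expect_equal(m$weights, c(0.5, 0.5))
  # symmetric responsibilities: both components equal the blended MLE
  g2 <- matrix(0.5, 1, 2)
  m2 <- m_step(g2, counts[1], epsilon = 0)
  C1 <- counts[[1]]
  expect_equal(unname(m2$matrices[[1]]), unname(C1 / rowSums(C1)))
  expect_equal(m2$matrices[[1]], m2$matrices[[2]])
  # epsilon smoothing keeps every entry strictly positive
  m3 <- m_step(gamma, counts, epsilon = 1e-6)
  expect_true(all(vapply(m3$matrices, function(M) all(M > 0), logical(1))))
})

test_that("K = 1 fit reduces to the pooled row-normalised MLE", {
  sp <- two_cluster_spec(S = 30, mean_length = 15, seed = 3)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  fit <- fit_markov_mixture(cnt, K = 1, n_restarts = 2, seed = 1)
  pooled <- pool_counts(cnt)
  expect_equal(unname(fit$matrices[[1]]),
               unname(pooled / rowSums(pooled)), tolerance = 1e-4)
  expect_equal(fit$weights, 1)
  expect_true(all(fit$gamma == 1))
})

test_that("EM log-likelihood trace is monotone nondecreasing", {
  sp <- two_cluster_spec(S = 60, mean_length = 20, seed = 4)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  for (K in 1:3) {
    fit <- fit_markov_mixture(cnt, K, n_restarts = 3, seed = K)
    diffs <- diff(fit$trace)
    expect_true(all(diffs >= -1e-10 * abs(fit$trace[-length(fit$trace)])),
                label = paste("monotone trace at K =", K))
  }
})

test_that("fits are reproducible given a seed and invariant to relabelling", {
  sp <- two_cluster_spec(S = 40, mean_length = 15, seed = 6)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  f1 <- fit_markov_mixture(cnt, 2, n_restarts = 3, seed = 9)
  f2 <- fit_markov_mixture(cnt, 2, n_restarts = 3, seed = 9)
  expect_equal(f1$log_likelihood, f2$log_likelihood)
  expect_equal(f1$matrices, f2$matrices)
  # permuting components leaves the observed-data likelihood unchanged
  model_perm <- list(weights = rev(f1$weights),
                     matrices = rev(f1$matrices))
  es <- e_step(list(weights = f1$weights, matrices = f1$matrices), cnt)
  es_perm <- e_step(model_perm, cnt)
  expect_equal(es$loglik, es_perm$loglik, tolerance = 1e-12)
})

test_that("EM optimum dominates brute-force hard-assignment likelihood", {
  # tiny cohort: enumerate all 2^S hard assignments, fit per-group MLEs
  # with the same smoothing, and score the complete-data likelihood.
  sp <- two_cluster_spec(S = 6, mean_length = 10, seed = 8)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  counts <- cnt$counts
  eps <- 1e-6
  S <- length(counts)
  best_hard <- -Inf
  for (code in 0:(2^S - 1)) {
    z <- as.integer(intToBits(code))[1:S] + 1L
    if (length(unique(z)) < 2) next
    ll <- 0
    lam <- tabulate(z, 2) / S
    for (g in 1:2) {
      pooled <- Reduce(`+`, counts[z == g])
      M <- (pooled + eps) / (rowSums(pooled) + 4 * eps)
      ll <- ll + sum(vapply(which(z == g), function(s) {
        component_loglik(counts[[s]], M)
      }, numeric(1))) + sum(z == g) * log(lam[g])
    }
    best_hard <- max(best_hard, ll)
  }
  fit <- fit_markov_mixture(counts, 2, n_restarts = 20, seed = 2)
  expect_gte(fit$log_likelihood, best_hard - 1e-8)
})

test_that("cluster assignment is argmax with lowest-index tie-breaking", {
  g <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(0, 0, 1))
  expect_message(z <- assign_clusters(g), "tie")
  expect_equal(unname(z), c(2L, 1L, 3L))
  # hard responsibilities assign identically
  hard <- diag(3)
  expect_equal(unname(assign_clusters(hard)), 1:3)
})

test_that("zero-transition participants are excluded with a warning", {
  counts <- list(a = matrix(c(2, 1, 1, 3), 2), b = matrix(0, 2, 2))
  expect_warning(fit <- fit_markov_mixture(counts, 1, n_restarts = 1, seed = 1),
                 "zero transitions")
  expect_equal(fit$excluded_ids, "b")
  expect_equal(fit$n_participants, 1)
  expect_error(
    suppressWarnings(fit_markov_mixture(counts, 2, n_restarts = 1, seed = 1)),
    "exceeds"
  )
})

test_that("model selection table has nested-model and BIC structure", {
  sp <- two_cluster_spec(S = 80, mean_length = 20, seed = 12)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  scan <- model_selection_scan(cnt, 1:3, n_restarts = 8, seed = 5)
  expect_equal(scan$K, 1:3)
  # a larger model contains the smaller: best-of-restarts negLL nonincreasing
  expect_true(all(diff(scan$neg_loglik) <= 1e-6))
  expect_equal(scan$delta_neg_loglik[-1], -diff(scan$neg_loglik))
  expect_true(is.na(scan$delta_neg_loglik[1]))
  # parameter count (K-1) + K n (n-1) and the BIC identity
  T_ <- sum(cnt$n_transitions)
  expect_equal(scan$n_params, (1:3 - 1) + (1:3) * 4 * 3)
  expect_equal(scan$bic, 2 * scan$neg_loglik + scan$n_params * log(T_))
  # single-K scan
  one <- model_selection_scan(cnt, 1, n_restarts = 2, seed = 5)
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$delta_neg_loglik))
})

test_that("tidy and glance expose the fitted mixture coherently", {
  sp <- two_cluster_spec(S = 30, mean_length = 12, seed = 13)
  cnt <- transition_counts(simulate_cohort(sp)$diary)
  fit <- fit_markov_mixture(cnt, 2, n_restarts = 3, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 16)
  sums <- tapply(td$probability, list(td$cluster, td$from), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  gl <- glance(fit)
  expect_equal(gl$bic, BIC(fit))
  expect_equal(gl$n_params, 1 + 2 * 4 * 3)
  ca <- cluster_assignments(fit)
  expect_equal(names(ca), c("participant_id", "cluster", "gamma_1", "gamma_2"))
  expect_equal(rowSums(as.matrix(ca[, 3:4])), rep(1, nrow(ca)),
               ignore_attr = TRUE, tolerance = 1e-9)
})
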