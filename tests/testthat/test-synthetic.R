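test_that("cohort specs validate their invariants and list all violations", {
  err <- tryCatch(
    cohort_spec(S = 10, K = 2, weights = c(0.7, 0.7),
                matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
                mean_length = 1),
    error = conditionMessage
  )
  expect_match(err, "simplex")
  expect_match(err, "mean_length")
  bad_mat <- matrix(1, 4, 4)
  expect_error(
    cohort_spec(S = 10, K = 1, weights = 1, matrices = list(bad_mat)),
    "row-stochastic"
  )
})

test_that("identical spec and seed give byte-identical cohorts", {
  sp <- two_cluster_spec(S = 25, mean_length = 12, seed = 50)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$diary, c2$diary)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(sp, seed = 51)
  expect_false(identical(c1$diary, c3$diary))
})

test_that("degenerate chains and gap-free settings behave as specified", {
  # stay probability 1: every trajectory is constant
  sp <- cohort_spec(S = 10, K = 1, weights = 1,
                    matrices = list(sticky_matrix(4, 1)),
                    mean_length = 8, gap_prob = 0, seed = 1)
  co <- simulate_cohort(sp)
  per <- split(co$diary$state, co$diary$participant_id)
  expect_true(all(vapply(per, function(s) length(unique(s)) == 1, logical(1))))
  # no gaps: day indices are consecutive
  days <- split(co$diary$day, co$diary$participant_id)
  expect_true(all(vapply(days, function(d) all(diff(d) == 1), logical(1))))
  # with gaps, some day increments exceed one
  sp_gap <- cohort_spec(S = 40, K = 1, weights = 1,
                        matrices = list(sticky_matrix(4, 0.5)),
                        mean_length = 20, gap_prob = 0.3, seed = 2)
  co_gap <- simulate_cohort(sp_gap)
  gaps <- unlist(lapply(split(co_gap$diary$day, co_gap$diary$participant_id),
                        diff))
  expect_gt(max(gaps), 1)
})

test_that("empirical transition frequencies converge to the chain", {
  M <- rbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.2, 0.5, 0.2, 0.1),
             c(0.1, 0.2, 0.6, 0.1),
             c(0.3, 0.3, 0.2, 0.2))
  dimnames(M) <- list(reduced_labels, reduced_labels)
  sp <- cohort_spec(S = 2000, K = 1, weights = 1, matrices = list(M),
                    mean_length = 51, length_dispersion = 1e6,
                    gap_prob = 0, seed = 3)
  co <- simulate_cohort(sp)
  pooled <- pool_counts(transition_counts(co$diary))
  expect_gt(sum(pooled), 9e4)
  P_hat <- pooled / rowSums(pooled)
  expect_lt(max(abs(P_hat - M)), 0.01)
})

test_that("full-scale refinement round-trips through the reduced grouping", {
  R <- uniform_refinement()
  expect_equal(rowSums(R), rep(1, 4), ignore_attr = TRUE)
  # block sizes follow the 2/3 mood and 2/3 pain splits
  expect_equal(unname(rowSums(R > 0)), c(4, 6, 6, 9))
  sp <- two_cluster_spec(S = 30, mean_length = 15, seed = 60)
  co <- simulate_cohort(sp)
  full <- simulate_full_scale_states(co, seed = 61)
  ok <- !is.na(full$diary$mood) & !is.na(full$diary$pain)
  expect_equal(recode_reduced(full$diary$mood[ok], full$diary$pain[ok]),
               co$diary$state[ok])
  # single-score missingness blanks roughly the configured share of days
  q_hat <- mean(!ok)
  expect_gt(q_hat, 0.01)
  expect_lt(q_hat, 0.12)
  # degenerate refinement: one full cell per reduced state inverts exactly
  Rdeg <- matrix(0, 4, 25)
  picks <- c(recode_full(4, 1), recode_full(4, 3),
             recode_full(1, 1), recode_full(1, 3))
  for (r in 1:4) Rdeg[r, picks[r]] <- 1
  co_nomiss <- simulate_cohort(
    cohort_spec(S = 10, K = 1, weights = 1,
                matrices = list(sticky_matrix(4, 0.5)),
                mean_length = 10, single_score_missing = 0, seed = 5))
  full_deg <- simulate_full_scale_states(co_nomiss, Rdeg, seed = 6)
  expect_equal(recode_reduced(full_deg$diary$mood, full_deg$diary$pain),
               co_nomiss$diary$state)
  # refinement mass outside a reduced state's cells is rejected
  Rbad <- uniform_refinement()
  Rbad[1, recode_full(1, 5)] <- 0.5 # a BH cell in the GL row
  Rbad <- Rbad / rowSums(Rbad)
  expect_error(simulate_full_scale_states(co, Rbad), "outside")
})

test_that("pooled synthetic counts approach the weight-averaged chain", {
  sp <- cohort_spec(
    S = 2000, K = 2, weights = c(0.4, 0.6),
    matrices = list(sticky_matrix(4, 0.8), sticky_matrix(4, 0.4)),
    mean_length = 50, gap_prob = 0, seed = 8
  )
  co <- simulate_cohort(sp)
  pooled <- pool_counts(transition_counts(co$diary))
  P_hat <- pooled / rowSums(pooled)
  # rows mix the two chains in proportion to time spent by each cluster;
  # with uniform stationary chains that is the mixing weight
  M_bar <- 0.4 * sp$matrices[[1]] + 0.6 * sp$matrices[[2]]
  expect_lt(max(abs(P_hat - M_bar)), 0.02)
})

test_that("recovery harness separates well-separated components", {
  rep_ <- recovery_harness(two_cluster_spec(S = 150, mean_length = 30,
                                            seed = 70),
                           n_restarts = 5, seed = 70)
  expect_gte(rep_$accuracy, 0.95)
  expect_gt(rep_$ari, 0.8)
  expect_lt(rep_$max_matrix_error, 0.1)
  # identical components are unidentifiable: accuracy near chance
  same <- cohort_spec(S = 120, K = 2, weights = c(0.5, 0.5),
                      matrices = list(sticky_matrix(4, 0.6),
                                      sticky_matrix(4, 0.6)),
                      mean_length = 20, seed = 71)
  rep_same <- recovery_harness(same, n_restarts = 3, seed = 71)
  expect_lt(rep_same$ari, 0.2)
  # errors shrink as the cohort grows
  errs <- vapply(c(100, 400), function(S) {
    recovery_harness(two_cluster_spec(S = S, mean_length = 30, seed = 72),
                     n_restarts = 4, seed = 72)$max_matrix_error
  }, numeric(1))
  expect_lt(errs[2], errs[1])
})

test_that("covariate prevalences follow the cluster-linked model", {
  sp <- cohort_spec(
    S = 1500, K = 2, weights = c(0.5, 0.5),
    matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
    mean_length = 10,
    covariate_model = list(flag = c(0.8, 0.1)),
    covariate_missing = 0.2, seed = 80
  )
  co <- simulate_cohort(sp)
  merged <- dplyr::inner_join(co$covariates, co$truth, by = "participant_id")
  prev <- as.numeric(tapply(merged$flag, merged$cluster, mean, na.rm = TRUE))
  expect_lt(max(abs(prev - c(0.8, 0.1))), 0.06)
  expect_lt(abs(mean(is.na(merged$flag)) - 0.2), 0.05)
})
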