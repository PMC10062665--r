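uniform4 <- function() {
  matrix(0.25, 4, 4, dimnames = list(reduced_labels, reduced_labels))
}

test_that("mood transform boosts good-mood destinations in bad-mood rows", {
  M <- uniform4()
  Mp <- apply_mood_intervention(M, 0.1, split = 0.8)
  for (i in c("BL", "BH")) {
    expect_equal(unname(Mp[i, ]), c(0.35, 0.35, 0.24, 0.06))
  }
  # good-mood rows untouched, bit-identical
  expect_identical(Mp["GL", ], M["GL", ])
  expect_identical(Mp["GH", ], M["GH", ])
  expect_equal(rowSums(Mp), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("pain transform mirrors the mood arm on high-pain rows", {
  M <- uniform4()
  Mp <- apply_pain_intervention(M, 0.1, split = 0.8)
  for (i in c("GH", "BH")) {
    expect_equal(unname(Mp[i, ]), c(0.35, 0.24, 0.35, 0.06))
  }
  expect_identical(Mp["GL", ], M["GL", ])
  expect_identical(Mp["BL", ], M["BL", ])
  expect_equal(rowSums(Mp), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("zero boost with the matching split is the identity", {
  M <- uniform4()
  # uniform rows put equal mass on both non-improved destinations
  expect_equal(apply_mood_intervention(M, 0, split = 0.5), M)
  expect_equal(apply_pain_intervention(M, 0, split = 0.5), M)
  # general matrix: identity when split equals the rows' conditional share
  set.seed(31)
  M2 <- random_regular_matrix(4)
  s <- 0.7
  for (i in c("BL", "BH")) {
    ti <- M2[i, "BL"] + M2[i, "BH"]
    M2[i, "BL"] <- s * ti
    M2[i, "BH"] <- (1 - s) * ti
  }
  expect_equal(apply_mood_intervention(M2, 0, split = s), M2, tolerance = 1e-12)
})

test_that("row-stochasticity is preserved across random matrices and betas", {
  set.seed(32)
  for (i in 1:25) {
    M <- random_regular_matrix(4)
    for (target in c("mood", "pain")) {
      bmax <- max_feasible_beta(M, target)
      b <- runif(1, 0, bmax)
      spec <- intervention_spec(target, b, split = runif(1))
      Mp <- apply_intervention(M, spec)
      expect_equal(rowSums(Mp), rep(1, 4), ignore_attr = TRUE,
                   tolerance = 1e-12)
      expect_true(all(Mp >= 0 & Mp <= 1))
    }
  }
})

test_that("feasibility bound is exact and violations are named", {
  expect_equal(max_feasible_beta(uniform4(), "mood"), 0.25)
  expect_equal(max_feasible_beta(uniform4(), "pain"), 0.25)
  # a treated row already at (1,0,0,0): no headroom on the boosted entry
  M <- uniform4()
  M["BH", ] <- c(1, 0, 0, 0)
  expect_equal(max_feasible_beta(M, "mood"), 0)
  # just above the bound errors with the offending row
  expect_error(apply_mood_intervention(uniform4(), 0.26), "infeasible")
  expect_error(apply_mood_intervention(M, 0.01), "infeasible")
  # the bound itself is feasible
  expect_silent(apply_mood_intervention(uniform4(), 0.25))
})

test_that("per-cluster report balances deltas and flags infeasible beta", {
  model <- list(weights = c(0.5, 0.5),
                matrices = list(sticky_matrix(4, 0.6), uniform4()))
  rep_ <- intervention_report(model, intervention_spec("mood", 0.05))
  expect_equal(nrow(rep_), 8)
  deltas <- as.numeric(tapply(rep_$delta, rep_$cluster, sum))
  expect_equal(deltas, c(0, 0), tolerance = 1e-9)
  # before/after columns are stationary distributions
  expect_equal(as.numeric(tapply(rep_$x_after, rep_$cluster, sum)), c(1, 1),
               tolerance = 1e-9)
  # zero boost with matching split: delta identically zero
  rep0 <- intervention_report(list(weights = 1, matrices = list(uniform4())),
                              intervention_spec("mood", 0, split = 0.5))
  expect_equal(max(abs(rep0$delta)), 0)
  expect_error(
    intervention_report(model, intervention_spec("mood", 0.3)),
    "infeasible for cluster"
  )
})

test_that("good-mood stationary mass is nondecreasing in the mood boost", {
  set.seed(33)
  for (i in 1:10) {
    M <- random_regular_matrix(4)
    bmax <- max_feasible_beta(M, "mood")
    masses <- vapply(seq(0, bmax, length.out = 8), function(b) {
      x <- stationary(apply_mood_intervention(M, b, split = 0.8))
      x["GL"] + x["GH"]
    }, numeric(1))
    expect_true(all(diff(masses) >= -1e-9))
  }
})
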