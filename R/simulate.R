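# Synthetic-cohort generator. Emulates the structure the analysis assumes:
# latent clusters with cluster-specific transition matrices, variable
# trajectory lengths around a mean of 44 reporting days, calendar gaps
# between reports, and cluster-linked binary covariate prevalences.
#
# The latent chain advances one step per *reporting occasion*: the gap
# model shapes day indices only, so generated transition counts follow the
# mixture model exactly, matching the next-reporting-day transition
# convention used throughout the analysis.

#' Sticky transition matrix
#'
#' Diagonal `stay`, uniform off-diagonal mass.
#'
#' @param n Number of states.
#' @param stay Probability of remaining in the current state.
#' @param labels Optional state labels (defaults: reduced labels for n = 4).
#' @return An `n x n` row-stochastic matrix.
#' @export
sticky_matrix <- function(n, stay, labels = NULL) {
  stopifnot(n >= 2, stay >= 0, stay <= 1)
  M <- matrix((1 - stay) / (n - 1), n, n)
  diag(M) <- stay
  labels <- labels %||% if (n == 4) c("GL", "GH", "BL", "BH") else
    paste0("S", seq_len(n))
  dimnames(M) <- list(labels, labels)
  M
}

#' Attractor transition matrix
#'
#' Every row is a blend of a common destination profile and the identity:
#' `M = (1 - stickiness) * rep(profile) + stickiness * I`. With most mass
#' on one state of the profile this yields a chain attracted to that state.
#'
#' @param profile A probability vector over destinations.
#' @param stickiness Weight on staying put (default 0.15).
#' @param labels Optional state labels.
#' @return A row-stochastic matrix.
#' @export
attractor_matrix <- function(profile, stickiness = 0.15, labels = NULL) {
  stopifnot(abs(sum(profile) - 1) < 1e-9, all(profile >= 0),
            stickiness >= 0, stickiness <= 1)
  n <- length(profile)
  M <- (1 - stickiness) * matrix(profile, n, n, byrow = TRUE) +
    stickiness * diag(n)
  labels <- labels %||% names(profile) %||%
    if (n == 4) c("GL", "GH", "BL", "BH") else paste0("S", seq_len(n))
  dimnames(M) <- list(labels, labels)
  M
}

#' Specify a synthetic cohort
#'
#' Collects and validates everything the generator needs: the mixture
#' (weights and per-cluster transition matrices), initial-state
#' distributions, a trajectory-length model (negative binomial around a
#' mean of 44 reporting days, reflecting typical app diary adherence), a
#' reporting-gap model (geometric gaps between reporting days), the chance
#' a day carries only one of the two scores (relevant once trajectories are
#' refined to the full Likert grid), and optional per-cluster covariate
#' prevalences.
#'
#' @param S Number of participants.
#' @param K Number of latent clusters.
#' @param weights Mixing proportions (length K, simplex).
#' @param matrices List of K row-stochastic transition matrices (equal
#'   dimension).
#' @param initial_dists Optional list of K initial-state distributions;
#'   default uniform.
#' @param mean_length Mean number of reporting days per participant
#'   (default 44).
#' @param length_dispersion Negative-binomial size parameter of the length
#'   model (default 8; smaller = more overdispersed).
#' @param gap_prob Probability a calendar day between reports is skipped
#'   (default 0.15); shapes day indices only.
#' @param single_score_missing Probability a refined full-scale day records
#'   only one of mood/pain (default 0.05).
#' @param covariate_model Optional named list: per flag, a length-K vector
#'   of within-cluster prevalences.
#' @param covariate_missing Probability a participant reports no covariates
#'   at all (default 0.14, roughly the study's nonresponse).
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated `cohort_spec` object.
#' @export
cohort_spec <- function(S, K, weights, matrices, initial_dists = NULL,
                        mean_length = 44, length_dispersion = 8,
                        gap_prob = 0.15, single_score_missing = 0.05,
                        covariate_model = NULL, covariate_missing = 0.14,
                        seed = NULL) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (S < 1) note("S must be >= 1")
  if (K < 1) note("K must be >= 1")
  if (length(weights) != K) note("weights must have length K")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    note("weights must be a probability simplex")
  }
  if (length(matrices) != K) note("matrices must have length K")
  # accept row-lists (JSON) or column-major flat vectors (YAML) for matrices
  matrices <- lapply(matrices, function(M) {
    if (is.matrix(M)) return(M)
    if (is.list(M)) return(do.call(rbind, lapply(M, unlist)))
    matrix(M, nrow = as.integer(sqrt(length(M))))
  })
  n <- nrow(matrices[[1]])
  for (c in seq_along(matrices)) {
    M <- matrices[[c]]
    if (nrow(M) != n || ncol(M) != n) note(paste0("matrix ", c, " has wrong dimension"))
    else if (any(M < 0) || max(abs(rowSums(M) - 1)) > 1e-9) {
      note(paste0("matrix ", c, " is not row-stochastic"))
    }
  }
  if (is.null(initial_dists)) {
    initial_dists <- rep(list(rep(1 / n, n)), K)
  }
  if (length(initial_dists) != K ||
      any(vapply(initial_dists, function(p) {
        length(p) != n || any(p < 0) || abs(sum(p) - 1) > 1e-9
      }, logical(1)))) {
    note("initial_dists must be K probability vectors of length n")
  }
  if (mean_length < 2) note("mean_length must be >= 2")
  if (length_dispersion <= 0) note("length_dispersion must be > 0")
  for (p in c(gap_prob, single_score_missing, covariate_missing)) {
    if (p < 0 || p >= 1) note("probabilities must lie in [0, 1)")
  }
  if (!is.null(covariate_model)) {
    if (is.null(names(covariate_model)) ||
        any(vapply(covariate_model, function(v) {
          length(v) != K || any(v < 0) || any(v > 1)
        }, logical(1)))) {
      note("covariate_model must be a named list of length-K prevalence vectors in [0, 1]")
    }
  }
  if (length(problems) > 0) {
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  labels <- rownames(matrices[[1]]) %||%
    if (n == 4) c("GL", "GH", "BL", "BH") else paste0("S", seq_len(n))
  matrices <- lapply(matrices, function(M) {
    dimnames(M) <- list(labels, labels); M
  })
  structure(
    list(S = as.integer(S), K = as.integer(K), weights = weights,
         matrices = matrices, initial_dists = initial_dists,
         n_states = n, state_labels = labels,
         mean_length = mean_length, length_dispersion = length_dispersion,
         gap_prob = gap_prob, single_score_missing = single_score_missing,
         covariate_model = covariate_model,
         covariate_missing = covariate_missing, seed = seed),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> S =", x$S, ", K =", x$K, "on", x$n_states, "states\n")
  cat("  weights:", paste(format(x$weights), collapse = " "), "\n")
  cat("  mean length", x$mean_length, "; gap prob", x$gap_prob, "\n")
  invisible(x)
}

# State space matching a label set / dimension.
as_space <- function(n, labels = NULL) {
  if (n == 4 && (is.null(labels) || identical(labels, c("GL", "GH", "BL", "BH")))) {
    return(state_space("reduced"))
  }
  if (n == 25 && is.null(labels)) return(state_space("full"))
  structure(list(kind = "custom", n = n,
                 labels = labels %||% paste0("S", seq_len(n))),
            class = "state_space")
}

#' Simulate a synthetic cohort
#'
#' For each participant: draw a latent cluster from the mixing weights, a
#' trajectory length from the negative-binomial length model (minimum 2),
#' an initial state, then evolve the cluster's Markov chain one step per
#' reporting day; reporting days are spaced by geometric calendar gaps.
#' Covariate flags, if modelled, are drawn per cluster and blanked for a
#' `covariate_missing` fraction of participants.
#'
#' @param spec A [cohort_spec()].
#' @param seed Overrides `spec$seed`.
#' @return A `synthetic_cohort`: list with `diary` (tibble
#'   `participant_id`, `day`, `state`, `state_label`), `truth`
#'   (`participant_id`, `cluster`), `covariates` (tibble or `NULL`) and
#'   `spec`.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  S <- spec$S; K <- spec$K; n <- spec$n_states
  z <- sample.int(K, S, replace = TRUE, prob = spec$weights)
  len <- 2L + stats::rnbinom(S, size = spec$length_dispersion,
                             mu = spec$mean_length - 2)
  ids <- sprintf("P%05d", seq_len(S))

  states <- vector("list", S)
  for (c in seq_len(K)) {
    idx <- which(z == c)
    if (length(idx) == 0) next
    cumM <- t(apply(spec$matrices[[c]], 1, cumsum))
    cumM[, n] <- 1 # guard against cumsum rounding below 1
    cum0 <- cumsum(spec$initial_dists[[c]])
    cum0[n] <- 1
    Smat <- matrix(NA_integer_, length(idx), max(len[idx]))
    Smat[, 1] <- rowSums(stats::runif(length(idx)) > matrix(
      cum0, length(idx), n, byrow = TRUE)) + 1L
    for (t in 2:ncol(Smat)) {
      act <- which(len[idx] >= t)
      if (length(act) == 0) break
      u <- stats::runif(length(act))
      Smat[act, t] <- rowSums(u > cumM[Smat[act, t - 1L], , drop = FALSE]) + 1L
    }
    for (j in seq_along(idx)) states[[idx[j]]] <- Smat[j, seq_len(len[idx[j]])]
  }

  # geometric calendar gaps between consecutive reporting days
  gaps <- stats::rgeom(sum(len) - S, prob = 1 - spec$gap_prob)
  diary <- tibble::tibble(
    participant_id = rep(ids, len),
    state = unlist(states)
  )
  incr <- rep(1L, nrow(diary))
  first <- !duplicated(diary$participant_id)
  incr[!first] <- 1L + gaps
  day <- stats::ave(incr, diary$participant_id, FUN = cumsum)
  diary$day <- as.integer(day)
  diary$state_label <- spec$state_labels[diary$state]
  diary <- diary[, c("participant_id", "day", "state", "state_label")]

  covariates <- NULL
  if (!is.null(spec$covariate_model)) {
    covariates <- tibble::tibble(participant_id = ids)
    for (v in names(spec$covariate_model)) {
      prev <- spec$covariate_model[[v]][z]
      covariates[[v]] <- as.integer(stats::runif(S) < prev)
    }
    miss <- stats::runif(S) < spec$covariate_missing
    for (v in names(spec$covariate_model)) covariates[[v]][miss] <- NA_integer_
  }

  structure(
    list(diary = diary,
         truth = tibble::tibble(participant_id = ids, cluster = z),
         covariates = covariates, spec = spec),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", x$spec$S, "participants,", nrow(x$diary),
      "diary rows,", x$spec$K, "latent clusters\n")
  invisible(x)
}

#' Uniform refinement of reduced states to the full Likert grid
#'
#' Each reduced state's mass is spread uniformly over the full-grid cells
#' it groups: GL has 4 (2 good-mood x 2 low-pain levels), GH 6, BL 6, BH 9.
#'
#' @return A 4 x 25 row-stochastic matrix.
#' @export
uniform_refinement <- function() {
  grid <- expand.grid(pain = 1:5, mood = 1:5)
  reduced <- recode_reduced(grid$mood, grid$pain)
  full <- recode_full(grid$mood, grid$pain)
  R <- matrix(0, 4, 25,
              dimnames = list(c("GL", "GH", "BL", "BH"),
                              state_space("full")$labels))
  for (k in seq_len(25)) R[reduced[k], full[k]] <- 1
  R / rowSums(R)
}

#' Refine a reduced-state cohort to full-scale Likert pairs
#'
#' Draws, for each observation, a (mood, pain) Likert pair from the
#' refinement distribution of its reduced state, then blanks one of the two
#' scores on a `single_score_missing` fraction of days (those days are
#' dropped again when trajectories are rebuilt, emulating incomplete
#' reports). Recoding the refined diary through the reduced grouping
#' reproduces the reduced trajectories wherever both scores survive.
#'
#' @param cohort A reduced-space (4-state) [simulate_cohort()] result.
#' @param refinement A 4 x 25 row-stochastic matrix whose rows are
#'   supported only on the full-grid cells of the corresponding reduced
#'   state; default [uniform_refinement()].
#' @param seed Optional seed.
#' @return A `synthetic_cohort` whose diary has `participant_id`, `day`,
#'   `mood`, `pain`.
#' @export
simulate_full_scale_states <- function(cohort, refinement = uniform_refinement(),
                                       seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            cohort$spec$n_states == 4)
  refinement <- as.matrix(refinement)
  if (!all(dim(refinement) == c(4, 25)) ||
      max(abs(rowSums(refinement) - 1)) > 1e-9 || any(refinement < 0)) {
    stop("refinement must be a 4 x 25 row-stochastic matrix", call. = FALSE)
  }
  grid <- expand.grid(pain = 1:5, mood = 1:5)
  block <- recode_reduced(grid$mood, grid$pain)[order(recode_full(grid$mood, grid$pain))]
  for (r in 1:4) {
    if (any(refinement[r, block != r] > 0)) {
      stop("refinement row ", r, " puts mass outside its reduced state's cells",
           call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  red <- cohort$diary$state
  cumR <- t(apply(refinement, 1, cumsum))
  cumR[, ncol(cumR)] <- 1
  u <- stats::runif(length(red))
  full <- as.integer(rowSums(u > cumR[red, , drop = FALSE]) + 1L)
  mood <- (full - 1L) %/% 5L + 1L
  pain <- (full - 1L) %% 5L + 1L
  q <- cohort$spec$single_score_missing
  if (q > 0) {
    blank <- stats::runif(length(full)) < q
    which_score <- stats::runif(length(full)) < 0.5
    mood[blank & which_score] <- NA_integer_
    pain[blank & !which_score] <- NA_integer_
  }
  out <- cohort
  out$reduced_diary <- cohort$diary
  out$diary <- tibble::tibble(
    participant_id = cohort$diary$participant_id,
    day = cohort$diary$day,
    mood = mood, pain = pain
  )
  out
}

#' Synthetic preset emulating a large mobile-health chronic-pain cohort
#'
#' A four-cluster cohort shaped like the four qualitative regimes the
#' analysis is designed to find — a chain attracted to BH (bad mood, high
#' pain), one attracted to GL, one attracted to GH, and a sticky chain
#' that mostly stays put — with the motivating cohort's size and cluster
#' shares (9990 participants; 18%, 16%, 20%, 46%) and a handful of
#' cluster-linked condition flags. The matrices are illustrative
#' stand-ins, not fitted values from any real cohort.
#'
#' @param S Number of participants (default 9990).
#' @param seed Default simulation seed.
#' @return A [cohort_spec()].
#' @export
mhealth_preset <- function(S = 9990, seed = 1) {
  cohort_spec(
    S = S, K = 4,
    weights = c(0.18, 0.16, 0.20, 0.46),
    matrices = list(
      attractor_matrix(c(0.05, 0.05, 0.10, 0.80)), # -> BH
      attractor_matrix(c(0.80, 0.10, 0.05, 0.05)), # -> GL
      attractor_matrix(c(0.10, 0.75, 0.05, 0.10)), # -> GH
      sticky_matrix(4, 0.85)                       # stay put
    ),
    covariate_model = list(
      fibromyalgia = c(0.25, 0.35, 0.15, 0.12),
      osteoarthritis = c(0.30, 0.20, 0.35, 0.28),
      gout = c(0.05, 0.05, 0.05, 0.05),
      back_pain = c(0.45, 0.30, 0.35, 0.33),
      stomach_pain = c(0.10, 0.22, 0.08, 0.07)
    ),
    seed = seed
  )
}

# All permutations of 1..k (k small).
permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in permutations(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# Align fitted components to truth: permutation sigma minimising the total
# L1 distance between fitted matrix sigma(c) and true matrix c.
align_components <- function(fitted_mats, true_mats) {
  K <- length(true_mats)
  best <- NULL
  for (sigma in permutations(K)) {
    cost <- sum(vapply(seq_len(K), function(c) {
      sum(abs(fitted_mats[[sigma[c]]] - true_mats[[c]]))
    }, numeric(1)))
    if (is.null(best) || cost < best$cost) best <- list(sigma = sigma, cost = cost)
  }
  best$sigma
}

#' Simulate-fit-score parameter recovery harness
#'
#' Simulates a cohort with known truth, fits the mixture by EM, aligns the
#' fitted components to the truth by exhaustive best-permutation matching
#' on L1 matrix distance, and scores the fit: largest mixing-weight error,
#' largest absolute transition-probability error, hard-assignment accuracy,
#' and the adjusted Rand index.
#'
#' @param spec A [cohort_spec()] (the truth).
#' @param K Components to fit (default the spec's K).
#' @param n_restarts,max_iter,tol Passed to [fit_markov_mixture()].
#' @param seed Seed for both simulation and fitting.
#' @return A one-row tibble: `S`, `K`, `weight_error`, `max_matrix_error`,
#'   `accuracy`, `ari`; the fit and permutation are kept as attributes
#'   `"fit"` and `"permutation"`.
#' @export
recovery_harness <- function(spec, K = spec$K, n_restarts = 10,
                             max_iter = 500, tol = 1e-8, seed = 1) {
  cohort <- simulate_cohort(spec, seed = seed)
  space <- as_space(spec$n_states, spec$state_labels)
  counts <- transition_counts(cohort$diary, space)
  fit <- fit_markov_mixture(counts, K, n_restarts = n_restarts,
                            max_iter = max_iter, tol = tol,
                            seed = seed + 1000L)
  sigma <- align_components(fit$matrices, spec$matrices)
  weight_error <- max(abs(fit$weights[sigma] - spec$weights))
  max_matrix_error <- max(vapply(seq_len(K), function(c) {
    max(abs(fit$matrices[[sigma[c]]] - spec$matrices[[c]]))
  }, numeric(1)))
  inv <- integer(K)
  inv[sigma] <- seq_len(K)
  assigned <- unname(assign_clusters(fit))
  truth <- cohort$truth$cluster[match(fit$ids, cohort$truth$participant_id)]
  accuracy <- mean(inv[assigned] == truth)
  ari <- mclust::adjustedRandIndex(assigned, truth)
  out <- tibble::tibble(
    S = spec$S, K = K, weight_error = weight_error,
    max_matrix_error = max_matrix_error, accuracy = accuracy, ari = ari
  )
  attr(out, "fit") <- fit
  attr(out, "permutation") <- sigma
  out
}
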