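# Mixture of Markov chains fitted by EM.
#
# Internally the S per-participant count matrices are flattened row-major
# into an S x n^2 matrix so the E-step is a single matrix product and the
# M-step a single crossproduct; this keeps full-cohort fits (S ~ 10^4)
# fast in plain R.

# Sentinel for log(0) inside the vectorised E-step: far below any
# attainable log-likelihood but safe against overflow when multiplied by
# counts. Rows whose best component falls below IMPOSSIBLE are treated as
# -Inf under every component.
LOGZERO <- -1e12
IMPOSSIBLE <- -1e10

flatten_counts <- function(counts) {
  counts <- counts_list(counts)
  n <- nrow(counts[[1]])
  Cmat <- t(vapply(counts, function(m) as.numeric(t(m)), numeric(n * n)))
  if (length(counts) == 1) Cmat <- matrix(Cmat, nrow = 1)
  list(Cmat = Cmat, n = n,
       labels = rownames(counts[[1]]) %||% paste0("S", seq_len(n)),
       ids = names(counts) %||% as.character(seq_along(counts)))
}

#' Log-likelihood of one participant's counts under one chain
#'
#' `sum_ij C[i,j] * log(M[i,j])`, the log-likelihood of a trajectory's
#' transition counts conditional on its first observed state. Zero counts
#' contribute nothing even where `M` is zero; a positive count on a
#' zero-probability transition yields `-Inf`.
#'
#' @param C A square matrix of transition counts.
#' @param M A row-stochastic transition matrix of the same dimension.
#' @return A single number, possibly `-Inf`.
#' @examples
#' component_loglik(rbind(c(2, 0), c(0, 0)), rbind(c(0.9, 0.1), c(0.5, 0.5)))
#' @export
component_loglik <- function(C, M) {
  C <- as.matrix(C); M <- as.matrix(M)
  if (!all(dim(C) == dim(M))) stop("dimension mismatch", call. = FALSE)
  pos <- C > 0
  if (!any(pos)) return(0)
  if (any(M[pos] == 0)) return(-Inf)
  sum(C[pos] * log(M[pos]))
}

# S x K matrix of component log-likelihoods, vectorised with the LOGZERO
# sentinel standing in for log(0).
loglik_matrix <- function(Cmat, matrices) {
  logM <- vapply(matrices, function(M) {
    lm <- as.vector(t(M))
    lm <- ifelse(lm > 0, log(lm), LOGZERO)
    lm
  }, numeric(ncol(Cmat)))
  Cmat %*% logM
}

#' E-step: posterior cluster responsibilities
#'
#' Computes the responsibility matrix Gamma whose (s, c) entry is the
#' posterior probability that participant s was generated by component c,
#' normalised per participant via log-sum-exp, together with the total
#' observed-data log-likelihood `sum_s log sum_c lambda_c L_sc`.
#'
#' Participants whose counts are impossible under every component get
#' uniform responsibilities with a warning; zero-count participants get the
#' mixing weights.
#'
#' @param model A list with `weights` (K-vector) and `matrices` (list of K
#'   row-stochastic matrices), e.g. the `model` element of a fit.
#' @param counts List of per-participant count matrices or a
#'   [transition_counts()] tibble.
#' @return List with `gamma` (S x K matrix) and `loglik`.
#' @export
e_step <- function(model, counts) {
  fc <- flatten_counts(counts)
  ll <- loglik_matrix(fc$Cmat, model$matrices)
  estep_from_loglik(ll, model$weights)
}

estep_from_loglik <- function(ll, weights) {
  K <- length(weights)
  logw <- ifelse(weights > 0, log(weights), LOGZERO)
  a <- sweep(ll, 2, logw, `+`)
  dead <- apply(ll, 1, max) < IMPOSSIBLE
  m <- apply(a, 1, max)
  g <- exp(a - m)
  rs <- rowSums(g)
  gamma <- g / rs
  loglik <- sum(m + log(rs))
  if (any(dead)) {
    warning(sum(dead), " participant(s) impossible under every component; ",
            "responsibilities set uniform", call. = FALSE)
    gamma[dead, ] <- 1 / K
    loglik <- -Inf
  }
  list(gamma = gamma, loglik = loglik)
}

#' M-step: re-estimate mixing weights and transition matrices
#'
#' Weights become the mean responsibility per component; each component's
#' transition matrix is the responsibility-weighted pooled count matrix,
#' row-normalised with a smoothing pseudocount `epsilon` that keeps every
#' entry strictly positive (rows with no weighted mass become uniform).
#'
#' @param gamma S x K responsibility matrix, rows summing to 1.
#' @param counts As in [e_step()].
#' @param epsilon Smoothing pseudocount (default `1e-6`).
#' @return A list with `weights` and `matrices` (length-K list).
#' @export
m_step <- function(gamma, counts, epsilon = 1e-6) {
  fc <- flatten_counts(counts)
  mstep_flat(gamma, fc$Cmat, fc$n, fc$labels, epsilon)
}

mstep_flat <- function(gamma, Cmat, n, labels, epsilon) {
  gamma <- as.matrix(gamma)
  weights <- colMeans(gamma)
  W <- crossprod(gamma, Cmat) # K x n^2, row-major blocks
  matrices <- lapply(seq_len(nrow(W)), function(c) {
    M <- matrix(W[c, ], n, n, byrow = TRUE)
    M <- (M + epsilon) / (rowSums(M) + n * epsilon)
    dimnames(M) <- list(labels, labels)
    M
  })
  list(weights = weights, matrices = matrices)
}

# Dirichlet(1) rows: independent Exp(1) draws, row-normalised.
init_gamma_dirichlet <- function(S, K) {
  g <- matrix(stats::rexp(S * K), S, K)
  g / rowSums(g)
}

# Perturbed pooled-MLE initialiser: each component is the pooled
# row-normalised count matrix jittered multiplicatively, then one E-step
# provides the starting responsibilities.
init_gamma_pooled <- function(Cmat, n, labels, K, weights0, epsilon) {
  pooled <- matrix(colSums(Cmat), n, n, byrow = TRUE)
  pooled <- (pooled + epsilon) / (rowSums(pooled) + n * epsilon)
  mats <- lapply(seq_len(K), function(c) {
    M <- pooled * exp(matrix(stats::rnorm(n * n, sd = 0.3), n, n))
    M <- M / rowSums(M)
    dimnames(M) <- list(labels, labels)
    M
  })
  ll <- loglik_matrix(Cmat, mats)
  estep_from_loglik(ll, weights0)$gamma
}

#' Fit a mixture of Markov chains by EM
#'
#' Fits K mixing weights and K row-stochastic transition matrices to
#' per-participant transition count matrices, by expectation-maximisation
#' with multiple random restarts. The likelihood conditions on each
#' participant's first observed state (no initial-state term). Participants
#' with zero transitions (fewer than two observations) are uninformative
#' and are excluded from the fit with a warning.
#'
#' @param counts List of per-participant transition count matrices, or a
#'   [transition_counts()] tibble.
#' @param K Number of mixture components (>= 1).
#' @param n_restarts Number of random restarts; the best final
#'   log-likelihood wins, ties going to the earliest restart.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence threshold on the relative log-likelihood change.
#' @param epsilon M-step smoothing pseudocount; guarantees strictly
#'   positive (hence regular) fitted chains.
#' @param seed Integer seed making the fit reproducible; restart r uses
#'   `seed + r - 1`.
#' @param init `"dirichlet"` (random responsibilities) or `"pooled"`
#'   (perturbed pooled-MLE matrices).
#' @return An object of class `markov_mixture`: list with `K`, `weights`,
#'   `matrices`, `gamma` (S x K, rownames = participant ids), `ids`,
#'   `log_likelihood`, `trace` (per-iteration log-likelihoods of the winning
#'   restart), `n_iter`, `converged`, `seed`, `epsilon`, `state_labels`,
#'   `n_participants`, `total_transitions`, `excluded_ids`.
#' @examples
#' sp <- cohort_spec(
#'   S = 40, K = 2, weights = c(0.5, 0.5),
#'   matrices = list(sticky_matrix(4, 0.9), sticky_matrix(4, 0.5)),
#'   mean_length = 15, seed = 1
#' )
#' co <- simulate_cohort(sp)
#' cnt <- transition_counts(co$diary)
#' fit <- fit_markov_mixture(cnt, K = 2, n_restarts = 3, seed = 1)
#' glance(fit)
#' @export
fit_markov_mixture <- function(counts, K, n_restarts = 20, max_iter = 500,
                               tol = 1e-8, epsilon = 1e-6, seed = NULL,
                               init = c("dirichlet", "pooled")) {
  init <- match.arg(init)
  stopifnot(K >= 1, n_restarts >= 1)
  fc <- flatten_counts(counts)
  tot <- rowSums(fc$Cmat)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " participant(s) with zero transitions excluded ",
            "from the fit", call. = FALSE)
  }
  keep <- tot > 0
  excluded_ids <- fc$ids[!keep]
  Cmat <- fc$Cmat[keep, , drop = FALSE]
  ids <- fc$ids[keep]
  S <- nrow(Cmat)
  if (S < 1) stop("no participant has any transitions", call. = FALSE)
  if (K > S) {
    stop("K = ", K, " exceeds the ", S, " participants with transitions",
         call. = FALSE)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (!is.null(seed)) set.seed(seed + r - 1)
    gamma <- if (init == "dirichlet") {
      init_gamma_dirichlet(S, K)
    } else {
      init_gamma_pooled(fc$Cmat[keep, , drop = FALSE], fc$n, fc$labels, K,
                        rep(1 / K, K), epsilon)
    }
    model <- mstep_flat(gamma, Cmat, fc$n, fc$labels, epsilon)
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      es <- estep_from_loglik(loglik_matrix(Cmat, model$matrices),
                              model$weights)
      trace <- c(trace, es$loglik)
      if (is.finite(ll_prev) &&
          (es$loglik - ll_prev) < tol * abs(ll_prev)) {
        converged <- TRUE
        gamma <- es$gamma
        break
      }
      ll_prev <- es$loglik
      gamma <- es$gamma
      model <- mstep_flat(gamma, Cmat, fc$n, fc$labels, epsilon)
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(model = model, gamma = gamma, trace = trace,
                   loglik = trace[length(trace)], converged = converged,
                   restart = r)
    }
  }

  rownames(best$gamma) <- ids
  structure(
    list(
      K = K,
      weights = best$model$weights,
      matrices = best$model$matrices,
      gamma = best$gamma,
      ids = ids,
      log_likelihood = best$loglik,
      trace = best$trace,
      n_iter = length(best$trace),
      converged = best$converged,
      restart = best$restart,
      seed = seed,
      epsilon = epsilon,
      init = init,
      state_labels = fc$labels,
      n_states = fc$n,
      n_participants = S,
      total_transitions = sum(Cmat),
      excluded_ids = excluded_ids
    ),
    class = "markov_mixture"
  )
}

#' @export
print.markov_mixture <- function(x, ...) {
  cat("<markov_mixture> K =", x$K, "on", x$n_states, "states;",
      x$n_participants, "participants,", x$total_transitions, "transitions\n")
  cat("  weights:", paste(format(round(x$weights, 3)), collapse = " "), "\n")
  cat("  log-likelihood:", format(x$log_likelihood), "in", x$n_iter,
      "iterations", if (x$converged) "(converged)" else "(max_iter hit)", "\n")
  invisible(x)
}

#' @export
logLik.markov_mixture <- function(object, ...) {
  p <- mixture_n_params(object$K, object$n_states)
  structure(object$log_likelihood, df = p, nobs = object$total_transitions,
            class = "logLik")
}

mixture_n_params <- function(K, n) (K - 1) + K * n * (n - 1)

#' Bayesian information criterion of a fitted mixture
#'
#' `BIC = 2 * negLL + p * log(T)` with `p = (K - 1) + K n (n - 1)` free
#' parameters and `T` the total number of observed transitions.
#'
#' @param object A `markov_mixture` fit.
#' @param ... Unused.
#' @export
BIC.markov_mixture <- function(object, ...) {
  p <- mixture_n_params(object$K, object$n_states)
  -2 * object$log_likelihood + p * log(object$total_transitions)
}

#' Hard cluster assignments from responsibilities
#'
#' Assigns each participant to the component with the highest posterior
#' responsibility; ties go to the lowest component index (reported via a
#' message).
#'
#' @param x A `markov_mixture` fit or a responsibility matrix.
#' @return An integer vector of cluster indices, named by participant where
#'   ids are available.
#' @export
assign_clusters <- function(x) {
  gamma <- if (inherits(x, "markov_mixture")) x$gamma else as.matrix(x)
  top <- max.col(gamma, ties.method = "first")
  ties <- rowSums(gamma == gamma[cbind(seq_len(nrow(gamma)), top)]) > 1
  if (any(ties)) {
    message(sum(ties), " tie(s) in responsibilities broken toward the ",
            "lowest cluster index")
  }
  stats::setNames(top, rownames(gamma))
}

#' Cluster assignments as a tidy table
#'
#' @param fit A `markov_mixture` fit.
#' @return A tibble with `participant_id`, `cluster`, and one `gamma_<k>`
#'   column per component.
#' @export
cluster_assignments <- function(fit) {
  stopifnot(inherits(fit, "markov_mixture"))
  g <- fit$gamma
  out <- tibble::tibble(
    participant_id = fit$ids,
    cluster = unname(assign_clusters(fit))
  )
  gcols <- tibble::as_tibble(g, .name_repair = ~ paste0("gamma_", seq_len(fit$K)))
  dplyr::bind_cols(out, gcols)
}

#' Tidy a fitted Markov mixture
#'
#' @param x A `markov_mixture` fit.
#' @param ... Unused.
#' @return A tibble of transition probabilities: `cluster`, `weight`,
#'   `from`, `to`, `probability`.
#' @export
tidy.markov_mixture <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(c) {
    M <- x$matrices[[c]]
    tibble::tibble(
      cluster = c,
      weight = x$weights[c],
      from = rep(rownames(M), each = ncol(M)),
      to = rep(colnames(M), times = nrow(M)),
      probability = as.vector(t(M))
    )
  })
}

#' One-row summary of a fitted Markov mixture
#'
#' @param x A `markov_mixture` fit.
#' @param ... Unused.
#' @return A tibble with `K`, `log_likelihood`, `n_params`, `bic`,
#'   `n_iter`, `converged`, `n_participants`, `total_transitions`.
#' @export
glance.markov_mixture <- function(x, ...) {
  tibble::tibble(
    K = x$K,
    log_likelihood = x$log_likelihood,
    n_params = mixture_n_params(x$K, x$n_states),
    bic = BIC.markov_mixture(x),
    n_iter = x$n_iter,
    converged = x$converged,
    n_participants = x$n_participants,
    total_transitions = x$total_transitions
  )
}

#' Heatmaps of the fitted per-cluster transition matrices
#'
#' @param object A `markov_mixture` fit.
#' @param ... Unused.
#' @return A ggplot faceted by cluster.
#' @export
autoplot.markov_mixture <- function(object, ...) {
  td <- tidy.markov_mixture(object)
  td$from <- factor(td$from, levels = rev(object$state_labels))
  td$to <- factor(td$to, levels = object$state_labels)
  td$cluster <- sprintf("cluster %d (weight %.2f)", td$cluster, td$weight)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "state next reporting day", y = "state today",
                  fill = "P(transition)") +
    ggplot2::theme_minimal()
}

#' Model-selection scan over the number of components
#'
#' Fits the mixture for each K in `K_range` (same restart policy for each)
#' and tabulates the negative log-likelihood, its decrease relative to the
#' previous K, the parameter count, and the BIC
#' (`2 negLL + p log T`, `T` = total transitions).
#'
#' @inheritParams fit_markov_mixture
#' @param K_range Integer vector of candidate component counts.
#' @param keep_fits Keep the individual fits as an attribute?
#' @return A tibble of class `model_selection` with columns `K`, `n_params`,
#'   `neg_loglik`, `delta_neg_loglik`, `bic`; attribute `"fits"` when
#'   requested.
#' @export
model_selection_scan <- function(counts, K_range, n_restarts = 20,
                                 max_iter = 500, tol = 1e-8, epsilon = 1e-6,
                                 seed = NULL, keep_fits = FALSE) {
  stopifnot(length(K_range) >= 1)
  K_range <- sort(unique(as.integer(K_range)))
  fits <- lapply(K_range, function(K) {
    fit_markov_mixture(counts, K, n_restarts = n_restarts,
                       max_iter = max_iter, tol = tol, epsilon = epsilon,
                       seed = seed)
  })
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(
      K = f$K,
      n_params = mixture_n_params(f$K, f$n_states),
      neg_loglik = -f$log_likelihood,
      bic = BIC.markov_mixture(f)
    )
  })
  tab <- dplyr::mutate(
    tab,
    delta_neg_loglik = dplyr::lag(.data$neg_loglik) - .data$neg_loglik,
    .after = "neg_loglik"
  )
  class(tab) <- c("model_selection", class(tab))
  if (keep_fits) attr(tab, "fits") <- fits
  tab
}

#' Plot a model-selection scan
#'
#' @param object A [model_selection_scan()] table.
#' @param ... Unused.
#' @return A ggplot of BIC and negative log-likelihood against K.
#' @export
autoplot.model_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("K", "neg_loglik", "bic")],
    -"K", names_to = "criterion", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of components K", y = NULL) +
    ggplot2::theme_minimal()
}
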