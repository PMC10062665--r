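#' Test whether a transition matrix is regular (primitive)
#'
#' A chain is regular when some power of its transition matrix is strictly
#' positive, which guarantees a unique stationary distribution. Powers are
#' checked on the positivity pattern up to Wielandt's primitivity bound
#' `(n - 1)^2 + 1`.
#'
#' @param M A row-stochastic matrix.
#' @param max_power Highest power checked (default the Wielandt bound).
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_regular(diag(2)) # FALSE: reducible
#' is_regular(matrix(0.25, 4, 4)) # TRUE at the first power
#' @export
is_regular <- function(M, max_power = (nrow(M) - 1)^2 + 1) {
  M <- as.matrix(M)
  stopifnot(nrow(M) == ncol(M))
  A <- (M > 0) * 1
  B <- A
  for (m in seq_len(max_power)) {
    if (all(B > 0)) return(TRUE)
    B <- (B %*% A > 0) * 1
  }
  FALSE
}

#' Stationary distribution of a regular Markov chain
#'
#' Solves the left eigenvalue problem `x M = x` subject to `x >= 0`,
#' `sum(x) = 1`, by replacing one equation of the singular linear system
#' `(M' - I) x = 0` with the normalisation constraint — deterministic and
#' free of complex arithmetic. The chain must be regular so the solution is
#' unique.
#'
#' @param M A row-stochastic matrix.
#' @return A probability vector `x` (named by the matrix's row labels) with
#'   `max |x M - x| <= 1e-9`.
#' @examples
#' stationary(rbind(c(0.9, 0.1), c(0.5, 0.5))) # (5/6, 1/6)
#' @export
stationary <- function(M) {
  M <- as.matrix(M)
  n <- nrow(M)
  stopifnot(n == ncol(M))
  if (max(abs(rowSums(M) - 1)) > 1e-8 || any(M < 0)) {
    stop("M must be row-stochastic", call. = FALSE)
  }
  if (!is_regular(M)) {
    stop("transition matrix is not regular; stationary distribution is not ",
         "unique", call. = FALSE)
  }
  A <- t(M) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  x <- solve(A, b)
  x[x < 0 & x > -1e-12] <- 0
  x <- x / sum(x)
  resid <- max(abs(as.vector(x %*% M) - x))
  if (resid > 1e-10 || any(x < 0)) {
    stop("stationary solve failed (residual ", format(resid), ")",
         call. = FALSE)
  }
  stats::setNames(x, rownames(M) %||% paste0("S", seq_len(n)))
}

#' Per-cluster stationary distributions of a fitted mixture
#'
#' The stationary probability of state k is the modelled long-run fraction
#' of reporting days a participant of that cluster spends in state k.
#'
#' @param model A `markov_mixture` fit, or a list with `weights` and
#'   `matrices`.
#' @return A tibble of class `occupancy_report`: `cluster`, `weight`,
#'   `state`, `probability`.
#' @export
occupancy_report <- function(model) {
  mats <- model$matrices
  weights <- model$weights
  labels <- rownames(mats[[1]]) %||% paste0("S", seq_len(nrow(mats[[1]])))
  out <- purrr::map_dfr(seq_along(mats), function(c) {
    x <- stationary(mats[[c]])
    tibble::tibble(cluster = c, weight = weights[c], state = labels,
                   probability = unname(x))
  })
  class(out) <- c("occupancy_report", class(out))
  out
}

#' Qualitative regime of a transition matrix
#'
#' Coarse label for a fitted chain: `"sticky"` when the mean diagonal
#' (stay) probability reaches `sticky_threshold`, otherwise
#' `"attract_<state>"` for the state carrying the most stationary mass —
#' the vocabulary used to describe cluster dynamics (e.g. attracted to BH,
#' attracted to GL, or mostly staying put).
#'
#' @param M A regular row-stochastic matrix.
#' @param sticky_threshold Mean-diagonal cutoff for the sticky label
#'   (default 0.5).
#' @return A character scalar.
#' @export
chain_regime <- function(M, sticky_threshold = 0.5) {
  M <- as.matrix(M)
  if (mean(diag(M)) >= sticky_threshold) return("sticky")
  x <- stationary(M)
  paste0("attract_", names(which.max(x)))
}

#' Plot per-cluster stationary distributions
#'
#' @param object An [occupancy_report()].
#' @param ... Unused.
#' @return A ggplot of stationary mass per state, faceted by cluster.
#' @export
autoplot.occupancy_report <- function(object, ...) {
  td <- tibble::as_tibble(object)
  td$state <- factor(td$state, levels = unique(td$state))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$state, y = .data$probability)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "stationary probability") +
    ggplot2::theme_minimal()
}
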