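#' Fit the sticky-diagonal null model to pooled transition counts
#'
#' The null model assumes each state has its own "stay" probability and
#' that, conditional on leaving, all other states are equally likely. With
#' `Y` the pooled transition count matrix, the maximum-likelihood estimates
#' are row totals `N_i = sum_k Y_ik`, stay probabilities `pi_i = Y_ii / N_i`,
#' null transition probabilities `P_ij = pi_i` on the diagonal and
#' `(1 - pi_i) / (n - 1)` off it, and expected counts `E_ij = N_i * P_ij`.
#'
#' Rows with zero total have an undefined stay probability; by convention
#' their `P` row is set uniform, their `E` row zero, and the row is flagged
#' in `zero_rows`.
#'
#' @param Y A square matrix of nonnegative transition counts (n >= 2).
#' @return An object of class `null_fit`: list with `N_hat`, `pi_hat`,
#'   `P_hat`, `E`, `zero_rows` (logical), `labels`.
#' @examples
#' Y <- rbind(c(6, 3, 1), c(1, 8, 1), c(2, 2, 6))
#' fit_null(Y)$E[1, ] # 6 2 2
#' @export
fit_null <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n != ncol(Y) || n < 2) stop("Y must be square with n >= 2", call. = FALSE)
  if (any(Y < 0)) stop("Y must be nonnegative", call. = FALSE)
  labels <- rownames(Y) %||% paste0("S", seq_len(n))
  N_hat <- rowSums(Y)
  zero_rows <- N_hat == 0
  pi_hat <- ifelse(zero_rows, NA_real_, diag(Y) / N_hat)
  P_hat <- matrix((1 - pi_hat) / (n - 1), n, n)
  diag(P_hat) <- pi_hat
  P_hat[zero_rows, ] <- 1 / n
  E <- N_hat * P_hat
  E[zero_rows, ] <- 0
  dimnames(P_hat) <- dimnames(E) <- list(labels, labels)
  structure(
    list(N_hat = stats::setNames(N_hat, labels),
         pi_hat = stats::setNames(pi_hat, labels),
         P_hat = P_hat, E = E, zero_rows = stats::setNames(zero_rows, labels),
         labels = labels),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, ...) {
  cat("<null_fit> sticky-diagonal null on", length(x$N_hat), "states;",
      sum(x$N_hat), "transitions\n")
  cat("  stay probabilities:",
      paste(format(round(x$pi_hat, 3)), collapse = " "), "\n")
  if (any(x$zero_rows)) {
    cat("  zero-count rows:", paste(x$labels[x$zero_rows], collapse = " "), "\n")
  }
  invisible(x)
}

#' Pearson residuals of transition counts against the null model
#'
#' `R_ij = (Y_ij - E_ij) / sqrt(E_ij)`, asymptotically standard normal under
#' a correct null. Cells with zero expected count get residual 0 and are
#' flagged rather than producing NaN or infinity. Note the diagonal
#' residuals are exactly zero whenever the row has any counts, because the
#' null's stay probability is estimated from that same diagonal cell.
#'
#' @param Y The pooled transition count matrix.
#' @param fit Optional [fit_null()] result for `Y`; computed if omitted.
#' @return An object of class `pearson_residuals`: list with `Y`, `E`, `R`,
#'   `flagged` (logical matrix, cells where E = 0), `labels`.
#' @export
pearson_residuals <- function(Y, fit = NULL) {
  Y <- as.matrix(Y)
  if (is.null(fit)) fit <- fit_null(Y)
  stopifnot(inherits(fit, "null_fit"))
  if (!all(dim(Y) == dim(fit$E))) {
    stop("Y and the null fit have mismatched dimensions", call. = FALSE)
  }
  flagged <- fit$E == 0
  R <- matrix(0, nrow(Y), ncol(Y), dimnames = dimnames(fit$E))
  R[!flagged] <- (Y[!flagged] - fit$E[!flagged]) / sqrt(fit$E[!flagged])
  structure(
    list(Y = Y, E = fit$E, R = R, flagged = flagged, labels = fit$labels),
    class = "pearson_residuals"
  )
}

#' @export
print.pearson_residuals <- function(x, ...) {
  ok <- !x$flagged
  cat("<pearson_residuals>", nrow(x$R), "x", ncol(x$R),
      "; range", paste(format(round(range(x$R[ok]), 3)), collapse = " .. "), "\n")
  cat("  cells with |R| > 2:", sum(abs(x$R[ok]) > 2), "\n")
  invisible(x)
}

#' Tidy a Pearson residual matrix
#'
#' @param x A [pearson_residuals()] object.
#' @param ... Unused.
#' @return A tibble with one row per cell: `from`, `to`, `observed`,
#'   `expected`, `residual`, `flagged`.
#' @export
tidy.pearson_residuals <- function(x, ...) {
  n <- nrow(x$R)
  tibble::tibble(
    from = rep(x$labels, each = n),
    to = rep(x$labels, times = n),
    observed = as.vector(t(x$Y)),
    expected = as.vector(t(x$E)),
    residual = as.vector(t(x$R)),
    flagged = as.vector(t(x$flagged))
  )
}

#' Cells with significant Pearson residuals
#'
#' Residuals above 2 in absolute value mark transitions occurring
#' significantly more (positive) or less (negative) often than the null
#' model predicts.
#'
#' @param R A [pearson_residuals()] object or a bare residual matrix.
#' @param threshold Absolute-residual cutoff (default 2).
#' @return A tibble of flagged cells (`from`, `to`, `residual`), sorted by
#'   `abs(residual)` descending; ties broken in row-major cell order.
#' @export
flag_significant <- function(R, threshold = 2) {
  mat <- if (inherits(R, "pearson_residuals")) R$R else as.matrix(R)
  labels <- rownames(mat) %||% paste0("S", seq_len(nrow(mat)))
  n <- nrow(mat)
  idx <- which(abs(mat) > threshold, arr.ind = TRUE)
  vals <- mat[idx]
  ord <- order(-abs(vals), (idx[, 1] - 1) * n + idx[, 2])
  tibble::tibble(
    from = labels[idx[ord, 1]],
    to = labels[idx[ord, 2]],
    residual = vals[ord]
  )
}

#' Normality summary of Pearson residuals
#'
#' Mean, sample standard deviation and histogram bins of the finite,
#' unflagged residual cells. Under a correct null the residuals are
#' approximately standard normal, so the summary should be close to
#' mean 0, sd 1. Flagged (zero-expected) cells are excluded.
#'
#' @param R A [pearson_residuals()] object or a residual matrix.
#' @param bins Suggested number of histogram bins.
#' @return A list with `mean`, `sd` (denominator count - 1), `n_cells`, and
#'   `histogram`, a tibble of bin `mid`, `count`, `density`.
#' @export
residual_normality_summary <- function(R, bins = 30) {
  if (inherits(R, "pearson_residuals")) {
    vals <- R$R[!R$flagged]
  } else {
    vals <- as.vector(as.matrix(R))
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2) {
    stop("need at least 2 finite residual cells", call. = FALSE)
  }
  h <- graphics::hist(vals, breaks = bins, plot = FALSE)
  list(
    mean = mean(vals),
    sd = stats::sd(vals),
    n_cells = length(vals),
    histogram = tibble::tibble(mid = h$mids, count = h$counts, density = h$density)
  )
}

#' Plot Pearson residuals as a heatmap
#'
#' @param object A [pearson_residuals()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pearson_residuals <- function(object, ...) {
  td <- tidy.pearson_residuals(object)
  td$from <- factor(td$from, levels = rev(object$labels))
  td$to <- factor(td$to, levels = object$labels)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$residual)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "state next reporting day", y = "state today",
                  fill = "Pearson\nresidual") +
    ggplot2::theme_minimal()
}
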