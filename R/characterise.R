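#' Cluster-by-covariate 2x2 contingency table
#'
#' Cross-tabulates membership of one cluster against one binary covariate.
#' Participants missing the covariate are excluded (self-report flags are
#' frequently absent).
#'
#' @param assignments A data frame with `participant_id` and `cluster`
#'   (e.g. from [cluster_assignments()]).
#' @param covariates A data frame with `participant_id` and 0/1/NA flag
#'   columns.
#' @param cluster Cluster index to contrast against all other clusters.
#' @param covariate Name of the flag column.
#' @return A 2x2 integer matrix: rows in-cluster/out-of-cluster, columns
#'   with/without the covariate.
#' @export
contingency <- function(assignments, covariates, cluster, covariate) {
  if (!covariate %in% names(covariates)) {
    stop("covariate '", covariate, "' not found", call. = FALSE)
  }
  merged <- dplyr::inner_join(
    tibble::as_tibble(assignments)[, c("participant_id", "cluster")],
    tibble::as_tibble(covariates)[, c("participant_id", covariate)],
    by = "participant_id"
  )
  merged <- merged[!is.na(merged[[covariate]]), ]
  flag <- merged[[covariate]]
  if (!all(flag %in% c(0, 1))) {
    stop("covariate '", covariate, "' must be binary 0/1/NA", call. = FALSE)
  }
  inc <- merged$cluster == cluster
  if (!any(inc)) stop("cluster ", cluster, " is empty", call. = FALSE)
  tab <- matrix(
    c(sum(inc & flag == 1), sum(inc & flag == 0),
      sum(!inc & flag == 1), sum(!inc & flag == 0)),
    2, 2, byrow = TRUE,
    dimnames = list(c("in_cluster", "out_of_cluster"), c("with", "without"))
  )
  tab
}

#' Log odds ratio with Wald 95% confidence interval
#'
#' `log OR = log(ad / bc)` with Wald interval
#' `log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)`. If any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell (flagged). If both
#' cells of a row or column are zero the estimate is undefined and returned
#' as `NA` with `degenerate = TRUE`.
#'
#' @param table A 2x2 matrix of counts `rbind(c(a, b), c(c, d))`.
#' @return A one-row tibble: `log_or`, `ci_low`, `ci_high`, `corrected`,
#'   `degenerate`, `a`, `b`, `c`, `d`, `n`.
#' @examples
#' log_odds_ratio(rbind(c(20, 80), c(10, 90)))
#' @export
log_odds_ratio <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  degenerate <- any(rowSums(table) == 0) || any(colSums(table) == 0)
  corrected <- !degenerate && any(table == 0)
  if (degenerate) {
    est <- ci_low <- ci_high <- NA_real_
  } else {
    t2 <- if (corrected) table + 0.5 else table
    est <- log(t2[1, 1] * t2[2, 2] / (t2[1, 2] * t2[2, 1]))
    se <- sqrt(sum(1 / t2))
    ci_low <- est - 1.96 * se
    ci_high <- est + 1.96 * se
  }
  tibble::tibble(
    log_or = est, ci_low = ci_low, ci_high = ci_high,
    corrected = corrected, degenerate = degenerate,
    a = a, b = b, c = c_, d = d, n = sum(table)
  )
}

#' Log odds ratios of every covariate in every cluster
#'
#' For each cluster and each binary covariate, contrasts in-cluster
#' participants against all other clusters pooled and reports the log odds
#' ratio of carrying the covariate, with a Wald 95% interval.
#'
#' @inheritParams contingency
#' @return A tibble of class `cluster_associations`: `covariate`, `cluster`,
#'   plus the [log_odds_ratio()] columns.
#' @export
cluster_covariate_associations <- function(assignments, covariates) {
  flags <- setdiff(names(covariates), "participant_id")
  clusters <- sort(unique(assignments$cluster))
  out <- purrr::map_dfr(flags, function(v) {
    purrr::map_dfr(clusters, function(k) {
      tab <- contingency(assignments, covariates, k, v)
      dplyr::bind_cols(tibble::tibble(covariate = v, cluster = k),
                       log_odds_ratio(tab))
    })
  })
  class(out) <- c("cluster_associations", class(out))
  out
}

#' Forest plot of cluster-covariate log odds ratios
#'
#' @param object A [cluster_covariate_associations()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_associations <- function(object, ...) {
  td <- tibble::as_tibble(object)
  td <- td[!td$degenerate, ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$log_or, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "log odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
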