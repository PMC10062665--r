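# Hypothetical intervention transforms on reduced-space (GL, GH, BL, BH)
# transition matrices. The mood arm boosts transitions out of bad-mood
# states toward good mood; the pain arm boosts transitions out of
# high-pain states toward low pain. In each treated row a boost beta is
# added to both improved destinations and the remaining mass of the two
# non-improved destinations (which shrinks by 2*beta) is redistributed
# between them by a fixed split.

# Arm geometry in the canonical order GL=1, GH=2, BL=3, BH=4.
arm_geometry <- function(target) {
  switch(target,
    mood = list(treated_rows = c(3L, 4L), boosted_cols = c(1L, 2L),
                split_col = 3L, rest_col = 4L),
    pain = list(treated_rows = c(2L, 4L), boosted_cols = c(1L, 3L),
                split_col = 2L, rest_col = 4L),
    stop("target must be 'mood' or 'pain'", call. = FALSE)
  )
}

#' Specify a hypothetical intervention
#'
#' @param target `"mood"` or `"pain"` — which symptom dimension improves.
#' @param beta Boost added to the probability of each improved destination
#'   state in every treated row; must be feasible for the matrix it is
#'   applied to (see [max_feasible_beta()]).
#' @param split Fraction of the leftover non-improved mass sent to the
#'   destination that is better on the untreated dimension (BL for the mood
#'   arm, GH for the pain arm); the remainder goes to BH. Default 0.8.
#' @return An `intervention_spec` object.
#' @export
intervention_spec <- function(target = c("mood", "pain"), beta, split = 0.8) {
  target <- match.arg(target)
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(split), length(split) == 1, split >= 0, split <= 1)
  structure(list(target = target, beta = beta, split = split),
            class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("<intervention_spec>", x$target, "arm: beta =", x$beta,
      ", split =", x$split, "\n")
  invisible(x)
}

check_reduced_matrix <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != 4 || ncol(M) != 4) {
    stop("intervention transforms act on 4-state reduced matrices",
         call. = FALSE)
  }
  if (max(abs(rowSums(M) - 1)) > 1e-8 || any(M < 0)) {
    stop("M must be row-stochastic", call. = FALSE)
  }
  M
}

apply_arm <- function(M, beta, split, target) {
  M <- check_reduced_matrix(M)
  g <- arm_geometry(target)
  labels <- rownames(M) %||% c("GL", "GH", "BL", "BH")
  out <- M
  for (i in g$treated_rows) {
    leftover <- M[i, g$split_col] + M[i, g$rest_col] - 2 * beta
    if (leftover < -1e-12) {
      stop("beta = ", beta, " infeasible: row ", labels[i],
           " has only ", M[i, g$split_col] + M[i, g$rest_col],
           " mass on its non-improved destinations", call. = FALSE)
    }
    boosted <- M[i, g$boosted_cols] + beta
    if (any(boosted > 1 + 1e-12)) {
      j <- g$boosted_cols[which(boosted > 1 + 1e-12)[1]]
      stop("beta = ", beta, " infeasible: entry (", labels[i], ", ",
           labels[j], ") would exceed 1", call. = FALSE)
    }
    leftover <- max(leftover, 0)
    out[i, g$boosted_cols] <- boosted
    out[i, g$split_col] <- split * leftover
    out[i, g$rest_col] <- (1 - split) * leftover
  }
  out
}

#' Mood-improving transform of a reduced transition matrix
#'
#' In each bad-mood row (BL, BH) the probabilities of moving to the
#' good-mood states GL and GH each increase by `beta`; the remaining mass
#' of the bad-mood destinations, `(M[i,BL] + M[i,BH] - 2 beta)`, is split
#' `split` to BL and `1 - split` to BH. Good-mood rows are untouched; rows
#' still sum to 1 by construction.
#'
#' @param M A 4x4 row-stochastic matrix over (GL, GH, BL, BH).
#' @param spec An [intervention_spec()] with `target = "mood"`, or a
#'   numeric `beta` (with `split` then taken from `...`'s default 0.8).
#' @param split Used when `spec` is a bare beta.
#' @return The transformed matrix.
#' @export
apply_mood_intervention <- function(M, spec, split = 0.8) {
  if (!inherits(spec, "intervention_spec")) {
    spec <- intervention_spec("mood", beta = spec, split = split)
  }
  if (spec$target != "mood") stop("spec targets ", spec$target, call. = FALSE)
  apply_arm(M, spec$beta, spec$split, "mood")
}

#' Pain-improving transform of a reduced transition matrix
#'
#' In each high-pain row (GH, BH) the probabilities of moving to the
#' low-pain states GL and BL each increase by `beta`; the remaining mass of
#' the high-pain destinations is split `split` to GH and `1 - split` to BH.
#' Low-pain rows are untouched.
#'
#' @inheritParams apply_mood_intervention
#' @param spec An [intervention_spec()] with `target = "pain"`, or a bare
#'   beta.
#' @return The transformed matrix.
#' @export
apply_pain_intervention <- function(M, spec, split = 0.8) {
  if (!inherits(spec, "intervention_spec")) {
    spec <- intervention_spec("pain", beta = spec, split = split)
  }
  if (spec$target != "pain") stop("spec targets ", spec$target, call. = FALSE)
  apply_arm(M, spec$beta, spec$split, "pain")
}

#' Apply an intervention spec to a matrix
#'
#' @param M A 4x4 row-stochastic matrix over (GL, GH, BL, BH).
#' @param spec An [intervention_spec()].
#' @return The transformed matrix.
#' @export
apply_intervention <- function(M, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  apply_arm(M, spec$beta, spec$split, spec$target)
}

#' Largest feasible intervention boost for a matrix
#'
#' The largest `beta` keeping every transformed entry in `[0, 1]`: the
#' minimum over treated rows of both half the mass currently on the two
#' non-improved destinations and the headroom `1 - M[i, j]` of each boosted
#' entry.
#'
#' @param M A 4x4 row-stochastic matrix over (GL, GH, BL, BH).
#' @param target `"mood"` or `"pain"`.
#' @return A single nonnegative number.
#' @examples
#' max_feasible_beta(matrix(0.25, 4, 4), "mood") # 0.25
#' @export
max_feasible_beta <- function(M, target = c("mood", "pain")) {
  target <- match.arg(target)
  M <- check_reduced_matrix(M)
  g <- arm_geometry(target)
  bounds <- vapply(g$treated_rows, function(i) {
    min((M[i, g$split_col] + M[i, g$rest_col]) / 2,
        1 - M[i, g$boosted_cols])
  }, numeric(1))
  max(0, min(bounds))
}

#' Per-cluster intervention report
#'
#' Applies the intervention to each cluster's transition matrix and
#' tabulates the stationary distribution before and after, plus the shift.
#' All matrices must be regular before and after the transform, and `beta`
#' must be feasible for every cluster.
#'
#' @param model A `markov_mixture` fit (or list with `weights`, `matrices`)
#'   over the reduced 4-state space.
#' @param spec An [intervention_spec()].
#' @return A tibble of class `intervention_report`: `cluster`, `state`,
#'   `x_before`, `x_after`, `delta`; the transformed matrices are kept in
#'   attribute `"matrices_after"`.
#' @export
intervention_report <- function(model, spec) {
  stopifnot(inherits(spec, "intervention_spec"))
  mats <- model$matrices
  labels <- rownames(mats[[1]]) %||% c("GL", "GH", "BL", "BH")
  after <- vector("list", length(mats))
  out <- purrr::map_dfr(seq_along(mats), function(c) {
    feas <- max_feasible_beta(mats[[c]], spec$target)
    if (spec$beta > feas + 1e-12) {
      stop("beta = ", spec$beta, " infeasible for cluster ", c,
           " (max feasible ", format(feas), ")", call. = FALSE)
    }
    Mp <- apply_intervention(mats[[c]], spec)
    after[[c]] <<- Mp
    xb <- stationary(mats[[c]])
    xa <- stationary(Mp)
    tibble::tibble(cluster = c, state = labels, x_before = unname(xb),
                   x_after = unname(xa), delta = unname(xa - xb))
  })
  class(out) <- c("intervention_report", class(out))
  attr(out, "matrices_after") <- after
  attr(out, "spec") <- spec
  out
}

#' Plot the stationary-distribution shifts of an intervention
#'
#' @param object An [intervention_report()].
#' @param ... Unused.
#' @return A ggplot of per-state stationary change, faceted by cluster.
#' @export
autoplot.intervention_report <- function(object, ...) {
  td <- tibble::as_tibble(object)
  td$state <- factor(td$state, levels = unique(td$state))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$state, y = .data$delta)) +
    ggplot2::geom_col(fill = "#cc6677") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "change in stationary probability") +
    ggplot2::theme_minimal()
}
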