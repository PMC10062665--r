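#' Read a long-format diary CSV
#'
#' Expects header `participant_id,day,mood,pain` (a pre-encoded `state`
#' column is also accepted); empty cells denote missing scores; `day` may
#' be an integer index or an ISO date, converted to integer day offsets by
#' [build_trajectories()].
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a covariate CSV
#'
#' Expects `participant_id` plus binary flag columns; blank cells denote
#' missing (participant did not report).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path, call. = FALSE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Serialise a fitted mixture to JSON
#'
#' Writes the model parameters (K, weights, row-major matrices, state
#' labels, log-likelihood, seed and fit settings) in a language-neutral
#' JSON schema.
#'
#' @param fit A `markov_mixture` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "markov_mixture"))
  obj <- list(
    K = fit$K,
    weights = fit$weights,
    matrices = lapply(fit$matrices, function(M) unname(apply(M, 1, c, simplify = FALSE))),
    state_labels = fit$state_labels,
    loglik = fit$log_likelihood,
    seed = fit$seed,
    settings = list(epsilon = fit$epsilon, init = fit$init,
                    n_iter = fit$n_iter, converged = fit$converged)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mixture model from JSON
#'
#' @param path A file written by [write_model_json()].
#' @return A list with `K`, `weights`, `matrices` (list of labelled
#'   matrices), `state_labels`, `loglik`, `seed`, `settings`; usable
#'   wherever a model (weights + matrices) is expected.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  labels <- unlist(obj$state_labels)
  mats <- lapply(obj$matrices, function(M) {
    M <- do.call(rbind, lapply(M, unlist))
    dimnames(M) <- list(labels, labels)
    M
  })
  list(K = obj$K, weights = unlist(obj$weights), matrices = mats,
       state_labels = labels, loglik = obj$loglik, seed = obj$seed,
       settings = obj$settings)
}

#' Per-participant transition counts as JSON
#'
#' Row-major integer count matrices keyed by participant id.
#'
#' @param counts A [transition_counts()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_json <- function(counts, path) {
  obj <- stats::setNames(
    lapply(counts$counts, function(M) unname(apply(M, 1, c, simplify = FALSE))),
    counts$participant_id
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
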