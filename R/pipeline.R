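#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages of the analysis in dependency order — ingest (or
#' simulate) a diary, build per-participant transition counts, residual
#' diagnostics on the pooled counts, EM mixture fit (or a model-selection
#' scan when a K range is given), per-cluster stationary distributions,
#' mood- and pain-improving intervention reports, and covariate
#' characterisation — writing tidy CSV tables, a model JSON and a run
#' manifest into `out_dir`. Reruns with the same config and seed reproduce
#' the same outputs.
#'
#' @param config A named list, or path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{input}{Path to a diary CSV, or omit and supply `simulate`.}
#'     \item{simulate}{Either `"mhealth_preset"` or a list of
#'       [cohort_spec()] arguments; used when `input` is absent.}
#'     \item{covariates}{Optional covariate CSV path (ignored when
#'       simulating with a covariate model, which supplies its own).}
#'     \item{space}{`"reduced"` (default) or `"full"` for the residual
#'       stage; clustering always uses the reduced space.}
#'     \item{K}{Number of components (default 4), or `k_range` (vector) to
#'       run a selection scan and fit the BIC-minimising K.}
#'     \item{n_restarts, max_iter, tol}{EM settings.}
#'     \item{beta_mood, beta_pain, split}{Intervention settings (defaults
#'       0.1, 0.1, 0.8); an arm is skipped when infeasible for a cluster.}
#'     \item{seed}{Master seed (default 1).}
#'     \item{out_dir}{Output directory (required).}
#'   }
#' @return The manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  space_kind <- config$space %||% "reduced"
  manifest <- list(
    package_version = as.character(utils::packageVersion("trajmix")),
    r_version = as.character(getRversion()),
    seed = seed, stages = list(), failed_stage = NULL
  )
  outputs <- character(0)
  stage <- function(name, f) {
    res <- tryCatch(f(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      write_manifest(manifest, outputs, out_dir)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- TRUE
    res
  }

  # -- ingest or simulate ----------------------------------------------
  covariates <- NULL
  truth <- NULL
  diary <- stage("ingest", function() {
    if (!is.null(config$input)) {
      if (!is.null(config$covariates)) {
        covariates <<- read_covariates(config$covariates)
      }
      read_diary(config$input)
    } else if (!is.null(config$simulate)) {
      spec <- if (identical(config$simulate, "mhealth_preset")) {
        mhealth_preset(seed = seed)
      } else {
        do.call(cohort_spec, config$simulate)
      }
      cohort <- simulate_cohort(spec, seed = seed)
      truth <<- cohort$truth
      covariates <<- cohort$covariates
      readr::write_csv(cohort$diary, file.path(out_dir, "diary.csv"))
      outputs <<- c(outputs, "diary.csv")
      if (!is.null(truth)) {
        readr::write_csv(truth, file.path(out_dir, "truth.csv"))
        outputs <<- c(outputs, "truth.csv")
      }
      if (!is.null(covariates)) {
        readr::write_csv(covariates, file.path(out_dir, "covariates.csv"))
        outputs <<- c(outputs, "covariates.csv")
      }
      cohort$diary
    } else {
      stop("config needs either `input` or `simulate`")
    }
  })

  space <- state_space(space_kind)
  counts <- stage("counts", function() transition_counts(diary, space))

  stage("residuals", function() {
    Y <- pool_counts(counts)
    res <- pearson_residuals(Y)
    readr::write_csv(tidy.pearson_residuals(res),
                     file.path(out_dir, "residuals.csv"))
    outputs <<- c(outputs, "residuals.csv")
  })

  # clustering always on the reduced space
  red_counts <- if (space_kind == "reduced") counts else {
    stage("recount_reduced",
          function() transition_counts(diary, state_space("reduced")))
  }

  fit <- stage("fit", function() {
    n_restarts <- config$n_restarts %||% 20
    max_iter <- config$max_iter %||% 500
    tol <- config$tol %||% 1e-8
    if (!is.null(config$k_range)) {
      scan <- model_selection_scan(red_counts, config$k_range,
                                   n_restarts = n_restarts,
                                   max_iter = max_iter, tol = tol,
                                   seed = seed, keep_fits = TRUE)
      readr::write_csv(tibble::as_tibble(scan),
                       file.path(out_dir, "selection.csv"))
      outputs <<- c(outputs, "selection.csv")
      attr(scan, "fits")[[which.min(scan$bic)]]
    } else {
      fit_markov_mixture(red_counts, config$K %||% 4,
                         n_restarts = n_restarts, max_iter = max_iter,
                         tol = tol, seed = seed)
    }
  })

  stage("model_outputs", function() {
    write_model_json(fit, file.path(out_dir, "model.json"))
    readr::write_csv(cluster_assignments(fit),
                     file.path(out_dir, "assignments.csv"))
    outputs <<- c(outputs, "model.json", "assignments.csv")
  })

  stage("stationary", function() {
    readr::write_csv(tibble::as_tibble(occupancy_report(fit)),
                     file.path(out_dir, "stationary.csv"))
    outputs <<- c(outputs, "stationary.csv")
  })

  split <- config$split %||% 0.8
  for (arm in c("mood", "pain")) {
    beta <- config[[paste0("beta_", arm)]] %||% 0.1
    stage(paste0("intervene_", arm), function() {
      feas <- min(vapply(fit$matrices, max_feasible_beta, numeric(1),
                         target = arm))
      if (beta > feas) {
        warning("beta_", arm, " = ", beta, " infeasible (max ",
                format(feas), "); arm skipped", call. = FALSE)
        return(invisible(NULL))
      }
      rep_ <- intervention_report(fit, intervention_spec(arm, beta, split))
      f <- paste0("intervention_", arm, ".csv")
      readr::write_csv(tibble::as_tibble(rep_), file.path(out_dir, f))
      outputs <<- c(outputs, f)
    })
  }

  if (!is.null(covariates)) {
    stage("characterise", function() {
      assoc <- cluster_covariate_associations(cluster_assignments(fit),
                                              covariates)
      readr::write_csv(tibble::as_tibble(assoc),
                       file.path(out_dir, "associations.csv"))
      outputs <<- c(outputs, "associations.csv")
    })
  }

  manifest <- write_manifest(manifest, outputs, out_dir)
  invisible(manifest)
}

write_manifest <- function(manifest, outputs, out_dir) {
  files <- file.path(out_dir, outputs)
  manifest$outputs <- as.list(stats::setNames(
    unname(tools::md5sum(files[file.exists(files)])), outputs
  ))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
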