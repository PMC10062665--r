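#' Mood-pain state spaces
#'
#' Construct the state space over which diary trajectories are encoded.
#' The `"full"` space keeps the raw 5x5 Likert grid (25 states, mood-major
#' order, labels `M<mood>P<pain>`). The `"reduced"` space collapses mood to
#' Good (scores 4-5) / Bad (1-3) and pain to Low (1-2) / High (3-5), giving
#' four states in the fixed canonical order GL, GH, BL, BH.
#'
#' @param kind `"reduced"` (default) or `"full"`.
#' @return A `state_space` object: a list with `kind`, `n` (number of
#'   states) and `labels` (ordered state names).
#' @examples
#' state_space("reduced")$labels
#' state_space("full")$n
#' @export
state_space <- function(kind = c("reduced", "full")) {
  kind <- match.arg(kind)
  labels <- if (kind == "reduced") {
    c("GL", "GH", "BL", "BH")
  } else {
    as.vector(t(outer(1:5, 1:5, function(m, p) paste0("M", m, "P", p))))
  }
  structure(
    list(kind = kind, n = length(labels), labels = labels),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("<state_space> ", x$kind, ": ", x$n, " states\n", sep = "")
  cat("  ", paste(utils::head(x$labels, 8), collapse = " "),
      if (x$n > 8) " ..." else "", "\n", sep = "")
  invisible(x)
}

check_scores <- function(mood, pain) {
  bad <- !is.na(mood) & !(mood %in% 1:5) | !is.na(pain) & !(pain %in% 1:5)
  if (any(bad)) {
    stop("invalid Likert score(s): mood and pain must be integers in 1..5 ",
         "(first offending pair: mood=", mood[which(bad)[1]],
         ", pain=", pain[which(bad)[1]], ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Recode Likert mood-pain pairs to reduced states
#'
#' Maps a (mood, pain) score pair to one of the four reduced states:
#' mood 1-3 is Bad, 4-5 Good; pain 1-2 is Low, 3-5 High. States are indexed
#' 1-4 in the fixed order GL, GH, BL, BH.
#'
#' @param mood,pain Integer vectors of Likert scores in 1..5.
#' @return Integer vector of reduced state indices (1 = GL, 2 = GH,
#'   3 = BL, 4 = BH). `NA` scores give `NA`.
#' @examples
#' recode_reduced(4, 1) # GL
#' recode_reduced(c(3, 1), c(3, 5)) # both BH
#' @export
recode_reduced <- function(mood, pain) {
  check_scores(mood, pain)
  good <- mood >= 4
  low <- pain <= 2
  ifelse(good, ifelse(low, 1L, 2L), ifelse(low, 3L, 4L))
}

#' Recode Likert mood-pain pairs to full 25-state indices
#'
#' Index of the (mood, pain) pair in the mood-major 5x5 grid.
#'
#' @inheritParams recode_reduced
#' @return Integer vector of indices in 1..25.
#' @export
recode_full <- function(mood, pain) {
  check_scores(mood, pain)
  (mood - 1L) * 5L + pain
}

#' Encode scores as state indices in a given space
#'
#' @inheritParams recode_reduced
#' @param space A [state_space()].
#' @return Integer state indices in `1..space$n`.
#' @export
state_index <- function(mood, pain, space = state_space("reduced")) {
  stopifnot(inherits(space, "state_space"))
  if (space$kind == "reduced") recode_reduced(mood, pain) else recode_full(mood, pain)
}

#' Build per-participant trajectories from a diary table
#'
#' Takes a long-format diary (one row per participant-day) and returns one
#' encoded trajectory per participant. Days where either score is missing
#' are dropped (only complete pairs are analysed); remaining days are sorted
#' ascending. A participant reporting the same day twice is a data-integrity
#' error.
#'
#' @param diary A data frame with columns `participant_id`, `day` (integer
#'   index or `Date`, converted to integer day offsets), and either `mood`
#'   and `pain` Likert scores or an already-encoded `state` index column
#'   (as produced by [simulate_cohort()]).
#' @param space A [state_space()].
#' @return A tibble with one row per participant: `participant_id`, `n_obs`,
#'   and `trajectory` (list column of tibbles with `day` and `state`).
#' @examples
#' diary <- tibble::tibble(
#'   participant_id = "p1", day = 1:3,
#'   mood = c(4L, 4L, NA), pain = c(1L, 1L, 2L)
#' )
#' build_trajectories(diary)$n_obs # third day dropped
#' @export
build_trajectories <- function(diary, space = state_space("reduced")) {
  stopifnot(inherits(space, "state_space"))
  has_scores <- all(c("mood", "pain") %in% names(diary))
  has_state <- "state" %in% names(diary)
  missing_cols <- setdiff(c("participant_id", "day"), names(diary))
  if (length(missing_cols) > 0 || !(has_scores || has_state)) {
    stop("diary needs columns participant_id, day, and mood+pain or state",
         call. = FALSE)
  }
  diary <- tibble::as_tibble(diary)
  if (inherits(diary$day, "Date")) {
    diary$day <- as.integer(diary$day - min(diary$day, na.rm = TRUE))
  }
  if (has_scores) {
    kept <- dplyr::filter(diary, !is.na(.data$mood), !is.na(.data$pain))
  } else {
    if (any(!is.na(diary$state) &
            (diary$state < 1 | diary$state > space$n))) {
      stop("state indices must lie in 1..", space$n, call. = FALSE)
    }
    kept <- dplyr::filter(diary, !is.na(.data$state))
  }
  dup <- dplyr::count(kept, .data$participant_id, .data$day) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate day for participant ", dup$participant_id[1],
         " (day ", dup$day[1], ")", call. = FALSE)
  }
  if (has_scores) kept$state <- state_index(kept$mood, kept$pain, space)
  traj <- kept |>
    dplyr::arrange(.data$participant_id, .data$day) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_obs = dplyr::n(),
      trajectory = list(dplyr::pick("day", "state")),
      .groups = "drop"
    )
  # participants whose days were all incomplete still appear, with 0 obs
  all_ids <- unique(diary$participant_id)
  lost <- setdiff(all_ids, traj$participant_id)
  if (length(lost) > 0) {
    traj <- dplyr::bind_rows(
      traj,
      tibble::tibble(
        participant_id = lost, n_obs = 0L,
        trajectory = rep(list(tibble::tibble(day = integer(), state = integer())),
                         length(lost))
      )
    )
    traj <- dplyr::arrange(traj, .data$participant_id)
  }
  traj
}

#' Count day-to-next-reporting-day transitions of one trajectory
#'
#' Each consecutive pair of *reporting* days contributes one transition
#' count, regardless of the calendar gap between them; a trajectory with m
#' observations yields m - 1 counts.
#'
#' @param traj A tibble with columns `day` and `state` (one participant,
#'   days strictly increasing), as stored by [build_trajectories()].
#' @param space A [state_space()] giving the matrix dimension and labels.
#' @return An integer `n x n` matrix of transition counts with state labels
#'   as dimnames.
#' @export
count_transitions <- function(traj, space = state_space("reduced")) {
  stopifnot(inherits(space, "state_space"))
  n <- space$n
  C <- matrix(0L, n, n, dimnames = list(space$labels, space$labels))
  s <- traj$state
  if (length(s) >= 2) {
    if (is.unsorted(traj$day, strictly = TRUE)) {
      stop("trajectory days must be strictly increasing", call. = FALSE)
    }
    from <- s[-length(s)]
    to <- s[-1]
    for (k in seq_along(from)) C[from[k], to[k]] <- C[from[k], to[k]] + 1L
  }
  C
}

#' Per-participant transition count matrices from a diary
#'
#' Convenience wrapper: [build_trajectories()] then [count_transitions()]
#' per participant.
#'
#' @inheritParams build_trajectories
#' @return A tibble with `participant_id`, `n_obs`, `n_transitions` and
#'   `counts` (list column of `n x n` integer matrices).
#' @export
transition_counts <- function(diary, space = state_space("reduced")) {
  traj <- build_trajectories(diary, space)
  traj |>
    dplyr::mutate(
      counts = purrr::map(.data$trajectory, count_transitions, space = space),
      n_transitions = pmax(.data$n_obs - 1L, 0L)
    ) |>
    dplyr::select("participant_id", "n_obs", "n_transitions", "counts")
}

#' Pool transition count matrices
#'
#' Elementwise sum of per-participant count matrices, giving the cohort-level
#' count matrix used by the residual diagnostics.
#'
#' @param counts A list of same-dimension count matrices, or a tibble with a
#'   `counts` list column as returned by [transition_counts()].
#' @return A single matrix, the elementwise sum.
#' @export
pool_counts <- function(counts) {
  counts <- counts_list(counts)
  if (length(counts) == 0) stop("no count matrices to pool", call. = FALSE)
  dims <- vapply(counts, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) {
    stop("count matrices have mismatched dimensions", call. = FALSE)
  }
  Reduce(`+`, counts)
}

# Accept either a bare list of matrices or a transition_counts() tibble.
counts_list <- function(counts) {
  if (is.data.frame(counts)) {
    if (!"counts" %in% names(counts)) {
      stop("data frame input must have a `counts` list column", call. = FALSE)
    }
    cl <- counts$counts
    if (!is.null(counts$participant_id)) names(cl) <- counts$participant_id
    return(cl)
  }
  if (is.matrix(counts)) return(list(counts))
  stopifnot(is.list(counts))
  counts
}
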