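#' Cohort container for trial-level data
#'
#' Bundles the long-format trial log of many sessions with the subject
#' design table. A session is identified by its `(subject_id, drug)` pair;
#' each subject belongs to exactly one group and contributes at most one
#' session per drug condition, and missing sessions are allowed (they
#' simply contribute no likelihood terms to a fit).
#'
#' @param trials A trial data frame in the [generate_session()] column
#'   layout (several sessions stacked).
#' @param design Optional data frame with columns `subject_id`, `group`;
#'   derived from `trials` when omitted. Subjects in the design that
#'   contribute no trials are permitted; trials referencing a subject
#'   absent from the design are a design error.
#' @param ground_truth Optional list carrying generating parameters (see
#'   [generate_cohort()]).
#' @return An object of class `prl_cohort` with elements `trials`,
#'   `design`, `ground_truth`.
#' @export
prl_cohort <- function(trials, design = NULL, ground_truth = NULL) {
  trials <- as.data.frame(trials)
  need <- c("subject_id", "group", "drug", "run", "sequence", "trial",
            "stim_left", "stim_right", "correct_stim", "chosen_stim",
            "chosen_side", "reinforcement", "misleading")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(design)) {
    design <- unique(trials[, c("subject_id", "group")])
    rownames(design) <- NULL
  }
  if (anyDuplicated(design$subject_id))
    stop("design error: a subject is listed in more than one group",
         call. = FALSE)
  if (!all(trials$subject_id %in% design$subject_id))
    stop("design error: trials reference a subject absent from the design",
         call. = FALSE)
  ses <- unique(trials[, c("subject_id", "drug")])
  if (!all(trials$drug %in% DRUGS))
    stop("design error: unknown drug label", call. = FALSE)
  if (!all(design$group %in% GROUPS))
    stop("design error: unknown group label", call. = FALSE)
  structure(list(trials = trials, design = design,
                 ground_truth = ground_truth),
            class = "prl_cohort")
}

#' @export
print.prl_cohort <- function(x, ...) {
  ses <- unique(x$trials[, c("subject_id", "drug")])
  cat(sprintf("<prl_cohort> %d subjects, %d sessions, %d trials\n",
              nrow(x$design), nrow(ses), nrow(x$trials)))
  print(table(x$design$group))
  invisible(x)
}

#' Split a cohort's trials into per-session data frames
#'
#' @param cohort A [prl_cohort()].
#' @return Named list of trial data frames, keyed `subject_id:drug`.
#' @export
cohort_sessions <- function(cohort) {
  tr <- cohort$trials
  key <- paste(tr$subject_id, tr$drug, sep = ":")
  lapply(split(tr, factor(key, levels = unique(key))), function(d) {
    d[order(d$trial), , drop = FALSE]
  })
}
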