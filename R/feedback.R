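# Clinical feedback on CAD results. Each radiologist classifies every
# displayed lesion candidate into exactly one of four classes —
#   known_TP:  a true lesion detected in the reader's own interpretation
#   missed_TP: a true lesion the reader had overlooked
#   FP:        a candidate that is clearly not a true lesion
#   pending:   a candidate that cannot be classified either way
# — and may additionally mark the locations of false-negative lesions the
# plug-in failed to report. An entry is only accepted when complete.
# Feedback is append-only per user; multiple users may submit entries on
# one job, and no consensus is computed.

feedback_classes <- c("known_TP", "missed_TP", "FP", "pending")

#' Create a feedback entry
#'
#' @param user user id of the radiologist.
#' @param per_candidate named list mapping candidate rank (as character or
#'   integer names) to one of `known_TP`, `missed_TP`, `FP`, `pending`.
#' @param false_negatives list of 0-based voxel triples marking true
#'   lesions the plug-in failed to report.
#' @return an object of class `feedback_entry`.
#' @export
feedback_entry <- function(user, per_candidate, false_negatives = list()) {
  stopifnot(is.character(user), length(user) == 1L)
  pc <- as.list(per_candidate)
  if (length(pc) > 0L && is.null(names(pc))) {
    names(pc) <- as.character(seq_along(pc))
  }
  structure(
    list(user = user, timestamp = as.numeric(Sys.time()),
         per_candidate = pc,
         false_negatives = lapply(false_negatives, as.numeric)),
    class = "feedback_entry"
  )
}

#' Attach a feedback entry to a finished job
#'
#' The entry is appended iff it is complete: every candidate rank in the
#' job's results is classified with one of the four classes, no unknown
#' rank or class appears, and every false-negative location lies inside
#' the job volume. Otherwise the job is unchanged and the error lists the
#' offending ranks/classes.
#'
#' @param store a [cad_store].
#' @param job_id id of a finished job.
#' @param entry a [feedback_entry].
#' @return the updated job document.
#' @export
record_feedback <- function(store, job_id, entry) {
  stopifnot(inherits(entry, "feedback_entry"))
  job <- load_job(store, job_id)
  if (job$status != "finished") {
    stop("feedback requires a finished job (status: ", job$status, ")",
         call. = FALSE)
  }
  result_ranks <- vapply(job$results, function(c) as.integer(c$rank), 0L)
  given_ranks <- suppressWarnings(as.integer(names(entry$per_candidate)))
  if (any(is.na(given_ranks))) {
    stop("per_candidate names must be candidate ranks", call. = FALSE)
  }
  unknown <- setdiff(given_ranks, result_ranks)
  if (length(unknown) > 0L) {
    stop("feedback references unknown candidate rank(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unclassified <- setdiff(result_ranks, given_ranks)
  if (length(unclassified) > 0L) {
    stop("incomplete feedback: unclassified candidate rank(s): ",
         paste(sort(unclassified), collapse = ", "), call. = FALSE)
  }
  classes <- unlist(entry$per_candidate)
  bad <- setdiff(unique(classes), feedback_classes)
  if (length(bad) > 0L) {
    stop("unknown feedback class(es): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(feedback_classes, collapse = ", "), ")",
         call. = FALSE)
  }
  for (fn in entry$false_negatives) {
    loc <- as.numeric(fn)
    if (length(loc) != 3L || any(loc < 0) ||
        (!is.null(job$dims) && any(loc > unlist(job$dims) - 1L))) {
      stop("false-negative location (", paste(loc, collapse = ","),
           ") outside volume dims", call. = FALSE)
    }
  }
  job$feedback <- c(job$feedback, list(unclass(entry)))
  save_job(store, job)
  job
}

#' Summarize feedback across jobs
#'
#' Flat counts per plug-in of the four candidate classes plus
#' false-negative marks. Counts conserve: the class counts of any
#' partition of the jobs sum to the counts of the whole.
#'
#' @param jobs list of job documents (e.g. from [list_jobs()]).
#' @return data.frame with columns `plugin_id`, `known_TP`, `missed_TP`,
#'   `FP`, `pending`, `fn_marks`, `entries`.
#' @export
summarize_feedback <- function(jobs) {
  rows <- list()
  for (job in jobs) {
    pid <- job$plugin_id
    if (is.null(rows[[pid]])) {
      rows[[pid]] <- c(known_TP = 0L, missed_TP = 0L, FP = 0L,
                       pending = 0L, fn_marks = 0L, entries = 0L)
    }
    for (entry in job$feedback) {
      rows[[pid]]["entries"] <- rows[[pid]]["entries"] + 1L
      for (cls in unlist(entry$per_candidate)) {
        rows[[pid]][cls] <- rows[[pid]][cls] + 1L
      }
      rows[[pid]]["fn_marks"] <- rows[[pid]]["fn_marks"] +
        length(entry$false_negatives)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(plugin_id = character(0), known_TP = integer(0),
                      missed_TP = integer(0), FP = integer(0),
                      pending = integer(0), fn_marks = integer(0),
                      entries = integer(0)))
  }
  out <- data.frame(plugin_id = names(rows),
                    do.call(rbind, rows), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
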