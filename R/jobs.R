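# Sequential plug-in job manager.
#
# The plug-in contract: a job's work directory contains, per input series,
# `series/<i>/volume.mhd`, `series/<i>/volume.raw` and
# `series/<i>/metadata.txt` (key = value lines from a configurable
# selected-tag list with the PHI list always subtracted last), plus a
# writable `out/` directory for `results.json` and display files. Plug-ins
# never receive DICOM files and never see PHI; the work directory is the
# only path a plug-in may touch. Jobs run strictly one at a time, FIFO.

job_statuses <- c("in_queue", "processing", "finished", "failed")

#' Plug-in manifest
#'
#' @param plugin_id plug-in identifier.
#' @param version version string; `plugin_id` + `version` identify one
#'   installable plug-in.
#' @param runtime either an R function of one argument (the work
#'   directory) executed in-process, or
#'   `list(type = "command", command = <chr>, args = <chr vector>)`
#'   executed as a subprocess with the work directory as its working
#'   directory (and only writable path).
#' @param expected_inputs number of input series the plug-in consumes.
#' @param result_schema_version results.json schema version (currently 1).
#' @return an object of class `plugin_manifest`.
#' @export
plugin_manifest <- function(plugin_id, version = "1.0", runtime,
                            expected_inputs = 1L,
                            result_schema_version = 1L) {
  ok_fun <- is.function(runtime)
  ok_cmd <- is.list(runtime) && identical(runtime$type, "command") &&
    is.character(runtime$command)
  if (!ok_fun && !ok_cmd) {
    stop("runtime must be a function(work_dir) or a command descriptor",
         call. = FALSE)
  }
  structure(
    list(plugin_id = plugin_id, version = version, runtime = runtime,
         expected_inputs = as.integer(expected_inputs),
         result_schema_version = as.integer(result_schema_version)),
    class = "plugin_manifest"
  )
}

#' Register a plug-in on a store handle
#'
#' @param store a [cad_store].
#' @param manifest a [plugin_manifest].
#' @return invisibly, the plugin id.
#' @export
register_plugin <- function(store, manifest) {
  stopifnot(inherits(store, "cad_store"), inherits(manifest, "plugin_manifest"))
  store$plugins[[manifest$plugin_id]] <- manifest
  invisible(manifest$plugin_id)
}

job_doc_defaults <- function(doc) {
  doc$feedback <- if (is.null(doc$feedback)) list() else doc$feedback
  doc$results <- if (is.null(doc$results)) list() else doc$results
  doc
}

#' Load a job document
#' @param store a [cad_store].
#' @param job_id job id.
#' @return job document (list).
#' @export
load_job <- function(store, job_id) {
  doc <- store_read_doc(store, "jobs", job_id)
  if (is.null(doc)) stop("no such job: ", job_id, call. = FALSE)
  job_doc_defaults(doc)
}

#' List all jobs in the store
#' @param store a [cad_store].
#' @return list of job documents, ordered by queue position.
#' @export
list_jobs <- function(store) {
  files <- list.files(file.path(store$path, "jobs"), pattern = "\\.json$",
                      full.names = TRUE)
  jobs <- lapply(files, function(f) job_doc_defaults(jsonlite::read_json(f)))
  pos <- vapply(jobs, function(j) as.numeric(j$fifo_pos), 0)
  jobs[order(pos)]
}

save_job <- function(store, job) {
  store_write_doc(store, "jobs", job$job_id, job)
  invisible(job)
}

#' Enqueue a plug-in job
#'
#' The requester must hold every input series' domain in their domain set
#' (admins bypass). The job enters the FIFO queue with status `in_queue`.
#'
#' @param store a [cad_store].
#' @param plugin_id a registered plug-in id.
#' @param series_uids character vector of input series UIDs.
#' @param user a [user_context].
#' @return the job document.
#' @export
enqueue_job <- function(store, plugin_id, series_uids, user) {
  stopifnot(inherits(store, "cad_store"))
  manifest <- store$plugins[[plugin_id]]
  if (is.null(manifest)) stop("unknown plugin: ", plugin_id, call. = FALSE)
  if (length(series_uids) != manifest$expected_inputs) {
    stop("plugin ", plugin_id, " expects ", manifest$expected_inputs,
         " input series, got ", length(series_uids), call. = FALSE)
  }
  for (uid in series_uids) {
    entry <- store_series_entry(store, uid)
    if (is.null(entry)) stop("no such series: ", uid, call. = FALSE)
    if (!user_can_access(user, entry$domain)) {
      stop("access denied: series ", uid, " is in domain \"", entry$domain,
           "\"; a requester may only use series whose domain is in their ",
           "domain set", call. = FALSE)
    }
  }
  existing <- list_jobs(store)
  next_pos <- if (length(existing) == 0L) 1L else
    max(vapply(existing, function(j) as.numeric(j$fifo_pos), 0)) + 1L
  job <- list(
    job_id = random_id(), plugin_id = plugin_id,
    series_uids = as.list(series_uids),
    status = "in_queue", fifo_pos = next_pos,
    requested_by = user$user_id,
    timing = list(queued = as.numeric(Sys.time()), started = NULL,
                  ended = NULL),
    dims = NULL, results = list(), feedback = list(), error = NULL
  )
  save_job(store, job)
  job
}

selected_plugin_tags <- function() {
  path <- system.file("extdata", "plugin_tags.txt", package = "radcad")
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Populate a job's sandbox work directory
#'
#' Converts each input series into a MetaImage pair and a plain-text
#' metadata file under `series/<i>/` (0-based), and creates the writable
#' `out/` directory. No DICOM file is written and no PHI-list tag (nor
#' any private tag) appears in `metadata.txt`: the selected-tag list is
#' intersected with the header and the PHI list is subtracted last.
#'
#' @param store a [cad_store].
#' @param job_id id of a job with status `in_queue`.
#' @param phi_tags PHI tag list subtracted from the metadata.
#' @return the work directory path.
#' @export
prepare_job_inputs <- function(store, job_id,
                               phi_tags = default_phi_tags()) {
  job <- load_job(store, job_id)
  if (job$status != "in_queue") {
    stop("job ", job_id, " is not in_queue (status: ", job$status, ")",
         call. = FALSE)
  }
  work_dir <- file.path(store$path, "jobs", safe_name(job$job_id), "work")
  dir.create(file.path(work_dir, "out"), recursive = TRUE,
             showWarnings = FALSE)
  selected <- selected_plugin_tags()

  uids <- unlist(job$series_uids)
  for (i in seq_along(uids)) {
    sdir <- file.path(store$path, "series", safe_name(uids[i]))
    md <- jsonlite::read_json(file.path(sdir, "metadata.json"))
    vol <- read_mhd(file.path(sdir, "volume.mhd"))
    jdir <- file.path(work_dir, "series", as.character(i - 1L))
    dir.create(jdir, recursive = TRUE, showWarnings = FALSE)
    write_mhd(vol, file.path(jdir, "volume.mhd"))

    kv <- unlist(md$key_values)
    keep <- intersect(selected, names(kv))
    keep <- setdiff(keep, phi_tags)
    keep <- keep[!is_private_tag_key(keep)]
    writeLines(paste(keep, "=", kv[keep]),
               file.path(jdir, "metadata.txt"))
    if (i == 1L) job$dims <- as.integer(dim(vol$data))
  }
  save_job(store, job)
  work_dir
}

results_schema_problems <- function(doc, dims) {
  problems <- character(0)
  if (is.null(doc$candidates)) {
    return("results.json lacks a \"candidates\" array")
  }
  ranks <- integer(0)
  for (cand in doc$candidates) {
    if (is.null(cand$rank) || is.null(cand$location_voxel) ||
        is.null(cand$confidence)) {
      problems <- c(problems,
                    "candidate lacks rank/location_voxel/confidence")
      next
    }
    ranks <- c(ranks, as.integer(cand$rank))
    loc <- as.numeric(unlist(cand$location_voxel))
    if (length(loc) != 3L) {
      problems <- c(problems, paste0("candidate rank ", cand$rank,
                                     ": location_voxel is not a triple"))
    } else if (!is.null(dims) &&
               (any(loc < 0) || any(loc > unlist(dims) - 1L))) {
      problems <- c(problems, paste0("candidate rank ", cand$rank,
                                     ": location outside volume dims"))
    }
  }
  n <- length(doc$candidates)
  if (length(problems) == 0L && !identical(sort(ranks), seq_len(n))) {
    problems <- c(problems,
                  "candidate ranks are not unique and contiguous from 1")
  }
  problems
}

#' Run the oldest queued job
#'
#' Strictly sequential: refuses to start while another job is processing.
#' The oldest `in_queue` job has its inputs prepared, then its plug-in
#' runtime is executed against the work directory — an R function runs
#' in-process, a command descriptor runs as a subprocess with the work
#' directory as its working directory. stdout/stderr are captured to
#' `job.log`. On success `out/results.json` is validated and parsed and
#' the job finishes; a runtime error, nonzero exit, or malformed results
#' file fails the job with the reason recorded, and the queue proceeds to
#' the next job on the next call.
#'
#' @param store a [cad_store].
#' @return the completed job document (status `finished` or `failed`).
#' @export
run_next_job <- function(store) {
  jobs <- list_jobs(store)
  statuses <- vapply(jobs, `[[`, "", "status")
  if (any(statuses == "processing")) {
    stop("a job is already processing; the manager is strictly sequential",
         call. = FALSE)
  }
  queue <- jobs[statuses == "in_queue"]
  if (length(queue) == 0L) stop("no job in queue", call. = FALSE)
  job <- queue[[1]]

  fail <- function(job, reason) {
    job$status <- "failed"
    job$error <- reason
    job$timing$ended <- as.numeric(Sys.time())
    save_job(store, job)
    job
  }

  work_dir <- tryCatch(prepare_job_inputs(store, job$job_id),
                       error = function(e) e)
  job <- load_job(store, job$job_id)
  job$status <- "processing"
  job$timing$started <- as.numeric(Sys.time())
  save_job(store, job)
  if (inherits(work_dir, "error")) {
    return(fail(job, paste("preprocessing error:",
                           conditionMessage(work_dir))))
  }

  manifest <- store$plugins[[job$plugin_id]]
  if (is.null(manifest)) {
    return(fail(job, paste("plugin not registered:", job$plugin_id)))
  }

  log_path <- file.path(dirname(work_dir), "job.log")
  if (is.function(manifest$runtime)) {
    run_err <- NULL
    log_lines <- utils::capture.output(
      res <- tryCatch(manifest$runtime(work_dir),
                      error = function(e) {
                        run_err <<- conditionMessage(e)
                        NULL
                      }),
      type = "output")
    writeLines(c(log_lines, if (!is.null(run_err)) paste("ERROR:", run_err)),
               log_path)
    if (!is.null(run_err)) {
      return(fail(job, paste("plugin error:", run_err)))
    }
  } else {
    old <- setwd(work_dir)
    status <- tryCatch(
      system2(manifest$runtime$command,
              args = as.character(manifest$runtime$args),
              stdout = log_path, stderr = log_path),
      error = function(e) -1L,
      finally = setwd(old))
    if (!identical(as.integer(status), 0L)) {
      return(fail(job, paste0("plugin exited with status ", status,
                              " (see job.log)")))
    }
  }

  results_path <- file.path(work_dir, "out", "results.json")
  if (!file.exists(results_path)) {
    return(fail(job, "plugin produced no out/results.json"))
  }
  doc <- tryCatch(jsonlite::read_json(results_path), error = function(e) e)
  if (inherits(doc, "error")) {
    return(fail(job, paste("malformed results.json:",
                           conditionMessage(doc))))
  }
  problems <- results_schema_problems(doc, job$dims)
  if (length(problems) > 0L) {
    return(fail(job, paste("results.json violates the result schema:",
                           paste(problems, collapse = "; "))))
  }

  job$results <- doc$candidates
  job$displays <- doc$displays
  job$status <- "finished"
  job$timing$ended <- as.numeric(Sys.time())
  save_job(store, job)
  job
}
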