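# Clinical-case data model: projects define attribute schemas; cases hold
# series references plus an append-only list of revisions. Revisions are
# immutable snapshots (copy semantics): no operation rewrites history, a
# correction is always a new revision. The series list of a case can
# never shrink.

#' Create a project
#'
#' A project groups cases and fixes, at the project level, the schemas
#' that case attributes and label attributes must validate against.
#'
#' @param name project name.
#' @param case_attribute_schema,label_attribute_schema schema documents
#'   within the supported subset (see [check_schema()]).
#' @param project_id optional id; a fresh random id is generated when
#'   omitted.
#' @return an object of class `cad_project`.
#' @export
cad_project <- function(name, case_attribute_schema = list(),
                        label_attribute_schema = list(),
                        project_id = NULL) {
  check_schema(case_attribute_schema)
  check_schema(label_attribute_schema)
  structure(
    list(project_id = if (is.null(project_id)) random_id() else project_id,
         name = name,
         case_attribute_schema = case_attribute_schema,
         label_attribute_schema = label_attribute_schema),
    class = "cad_project"
  )
}

# 160-bit random hex id; collision probability negligible at any realistic
# store size
random_id <- function() {
  paste0(sprintf("%02x", sample.int(256L, 20L, replace = TRUE) - 1L),
         collapse = "")
}

#' Content fingerprint of a series volume
#'
#' SHA-256 over the image (slice) count followed by the per-slice pixel
#' buffers in slice order. Any change to pixel content or slice count
#' changes the fingerprint; geometry metadata does not enter it.
#'
#' @param volume a [cad_volume].
#' @return hex digest string.
#' @export
series_fingerprint <- function(volume) {
  stopifnot(inherits(volume, "cad_volume"))
  nz <- volume$dims[3]
  parts <- vector("list", nz + 1L)
  parts[[1]] <- u32le(nz)
  for (k in seq_len(nz)) {
    parts[[k + 1L]] <- pixels_to_raw(as.vector(volume$data[, , k]),
                                     volume$value_type)
  }
  digest::digest(do.call(c, parts), algo = "sha256", serialize = FALSE)
}

new_revision <- function(creator, description, case_attributes,
                         series_labels, timestamp = NULL) {
  structure(
    list(creator = creator,
         timestamp = if (is.null(timestamp)) as.numeric(Sys.time())
                     else timestamp,
         description = description,
         case_attributes = case_attributes,
         series_labels = series_labels),
    class = "case_revision"
  )
}

#' Create a clinical case
#'
#' A case gets a fresh globally unique identifier, one initial empty
#' revision, and a content fingerprint per series (used later by
#' [series_integrity_check()]).
#'
#' @param project a [cad_project].
#' @param series list of series, each a list with `metadata` (a
#'   [series_metadata]) and `volume` (a [cad_volume]) — the shape returned
#'   by [load_dicom_series()]. At least one is required.
#' @param domain access-control domain string for the case.
#' @param creator user id recorded on the initial revision.
#' @return an object of class `clinical_case`.
#' @export
create_case <- function(project, series, domain = "default",
                        creator = "system") {
  stopifnot(inherits(project, "cad_project"))
  if (length(series) < 1L) stop("a case needs at least one series",
                                call. = FALSE)
  refs <- lapply(series, function(s) {
    stopifnot(inherits(s$metadata, "series_metadata"),
              inherits(s$volume, "cad_volume"))
    list(series_uid = s$metadata$series_uid,
         fingerprint = series_fingerprint(s$volume))
  })
  uids <- vapply(refs, `[[`, "", "series_uid")
  labels0 <- stats::setNames(rep(list(list()), length(uids)), uids)
  structure(
    list(case_id = random_id(),
         project_id = project$project_id,
         domain = domain,
         series_refs = refs,
         revisions = list(new_revision(creator, "initial revision",
                                       list(), labels0))),
    class = "clinical_case"
  )
}

#' @export
print.clinical_case <- function(x, ...) {
  cat("<clinical_case> ", x$case_id, "\n  project: ", x$project_id,
      "  domain: ", x$domain, "\n  series: ", length(x$series_refs),
      "  revisions: ", length(x$revisions), "\n", sep = "")
  invisible(x)
}

case_series_uids <- function(case) {
  vapply(case$series_refs, `[[`, "", "series_uid")
}

#' Append a revision to a case
#'
#' Validates the case attributes and every label's attributes against the
#' project schemas, then appends a new immutable revision. All prior
#' revisions are untouched and the series list never changes. On schema
#' violation the case is returned unchanged via an error that lists every
#' failing field.
#'
#' @param case a [clinical_case].
#' @param project the case's [cad_project] (source of the schemas).
#' @param attributes case attribute document.
#' @param labels named list: series_uid -> list of [voxel_label] /
#'   [geometric_label]. Omitted series get an empty label list.
#' @param creator user id.
#' @param description free-text revision description.
#' @return the case with one more revision.
#' @export
add_revision <- function(case, project, attributes = list(),
                         labels = list(), creator = "system",
                         description = "") {
  stopifnot(inherits(case, "clinical_case"), inherits(project, "cad_project"))
  uids <- case_series_uids(case)
  unknown <- setdiff(names(labels), uids)
  if (length(unknown) > 0L) {
    stop("labels reference series not in this case: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  problems <- character(0)
  res <- validate_attributes(attributes, project$case_attribute_schema)
  if (!res$ok) {
    problems <- c(problems, paste0("case attributes: ",
                                   res$violations$message))
  }
  for (uid in names(labels)) {
    for (lab in labels[[uid]]) {
      lres <- validate_attributes(lab$attributes,
                                  project$label_attribute_schema)
      if (!lres$ok) {
        problems <- c(problems,
                      paste0("label \"", lab$name, "\" (series ", uid, "): ",
                             lres$violations$message))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("attribute validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }

  series_labels <- stats::setNames(rep(list(list()), length(uids)), uids)
  for (uid in names(labels)) series_labels[[uid]] <- labels[[uid]]

  last_t <- case$revisions[[length(case$revisions)]]$timestamp
  rev <- new_revision(creator, description, attributes, series_labels,
                      timestamp = max(as.numeric(Sys.time()), last_t))
  case$revisions <- c(case$revisions, list(rev))
  case
}

#' Check series content against the fingerprints stored at case creation
#'
#' Fires a warning report iff any series' current content fingerprint
#' differs from the one recorded when the case was created (pixel edits
#' and slice count changes both alter the fingerprint). A series that is
#' absent from `current` yields a distinct "missing series" warning.
#'
#' @param case a [clinical_case].
#' @param current named list: series_uid -> current [cad_volume].
#' @return a list with `ok` (logical) and `warnings` (character vector
#'   naming each offending series).
#' @export
series_integrity_check <- function(case, current) {
  stopifnot(inherits(case, "clinical_case"))
  warnings <- character(0)
  for (ref in case$series_refs) {
    uid <- ref$series_uid
    vol <- current[[uid]]
    if (is.null(vol)) {
      warnings <- c(warnings, paste0("missing series: ", uid))
    } else if (!identical(series_fingerprint(vol), ref$fingerprint)) {
      warnings <- c(warnings,
                    paste0("series content changed since case creation: ",
                           uid))
    }
  }
  list(ok = length(warnings) == 0L, warnings = warnings)
}
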