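# On-disk JSON-document store plus the image repository tree. Attribute
# documents are stored verbatim (flexible schema), one JSON document per
# entity, written atomically (write-to-temp then rename) so the store is
# crash-consistent at single-document granularity.
#
# Layout under the store root:
#   series/<uid>/volume.mhd|.raw, metadata.json, entry.json
#   projects/<id>.json   cases/<id>.json   jobs/<id>.json
#   jobs/<id>/work/...   per-job sandbox work directories

#' Open (or create) a store
#'
#' @param path store root directory.
#' @return an object of class `cad_store`. Plug-in registrations are held
#'   in memory on the store handle; documents and images persist on disk.
#' @export
cad_store <- function(path) {
  for (d in c("", "series", "projects", "cases", "jobs")) {
    dir.create(file.path(path, d), recursive = TRUE, showWarnings = FALSE)
  }
  env <- new.env(parent = emptyenv())
  env$path <- normalizePath(path)
  env$plugins <- list()
  env$queue_counter <- 0L
  class(env) <- "cad_store"
  env
}

#' @export
print.cad_store <- function(x, ...) {
  cat("<cad_store> ", x$path, "\n  series: ",
      length(list.dirs(file.path(x$path, "series"), recursive = FALSE)),
      "  cases: ",
      length(list.files(file.path(x$path, "cases"), pattern = "\\.json$")),
      "  plugins: ", length(x$plugins), "\n", sep = "")
  invisible(x)
}

store_doc_path <- function(store, collection, id) {
  file.path(store$path, collection, paste0(safe_name(id), ".json"))
}

store_write_doc <- function(store, collection, id, doc) {
  write_doc(doc, store_doc_path(store, collection, id))
}

store_read_doc <- function(store, collection, id) {
  p <- store_doc_path(store, collection, id)
  if (!file.exists(p)) return(NULL)
  jsonlite::read_json(p)
}

#' User context for access control
#'
#' @param user_id non-empty user id.
#' @param domains character vector of domains the user may access.
#' @param roles subset of `annotator`, `operator`, `admin`.
#' @return an object of class `user_context`.
#' @export
user_context <- function(user_id, domains = character(),
                         roles = "annotator") {
  if (!is.character(user_id) || length(user_id) != 1L || !nzchar(user_id)) {
    stop("user_id must be a non-empty string", call. = FALSE)
  }
  bad <- setdiff(roles, c("annotator", "operator", "admin"))
  if (length(bad) > 0L) {
    stop("unknown role(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(user_id = user_id, domains = as.character(domains),
                 roles = roles),
            class = "user_context")
}

is_admin <- function(user) "admin" %in% user$roles

user_can_access <- function(user, domain) {
  is_admin(user) || domain %in% user$domains
}

require_role <- function(user, allowed) {
  if (!any(user$roles %in% allowed)) {
    stop("user \"", user$user_id, "\" lacks required role (needs one of: ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Store a series in the repository
#'
#' Persists the volume (MetaImage pair) and metadata under the series
#' UID, tagged with an access-control domain. Re-storing the same series
#' with identical content is a no-op; re-storing with different content
#' replaces the images and bumps the entry version — dependent cases will
#' then trip [series_integrity_check()].
#'
#' @param store a [cad_store].
#' @param volume a [cad_volume].
#' @param metadata a [series_metadata].
#' @param domain access-control domain string.
#' @param user a [user_context]; role `operator` or `admin` required.
#' @return the repository entry: list(series_uid, domain, storage_path,
#'   fingerprint, version).
#' @export
store_series <- function(store, volume, metadata, domain, user) {
  stopifnot(inherits(store, "cad_store"), inherits(volume, "cad_volume"),
            inherits(metadata, "series_metadata"))
  require_role(user, c("operator", "admin"))
  uid <- metadata$series_uid
  fp <- series_fingerprint(volume)
  sdir <- file.path(store$path, "series", safe_name(uid))
  entry_path <- file.path(sdir, "entry.json")

  if (file.exists(entry_path)) {
    entry <- jsonlite::read_json(entry_path)
    if (identical(entry$fingerprint, fp)) {
      return(entry_from_doc(entry))
    }
    version <- as.integer(entry$version) + 1L
  } else {
    version <- 1L
  }
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  write_mhd(volume, file.path(sdir, "volume.mhd"))
  write_doc(list(series_uid = uid, modality = metadata$modality,
                 key_values = as.list(metadata$key_values),
                 phi_removed = metadata$phi_removed),
            file.path(sdir, "metadata.json"))
  entry <- list(series_uid = uid, domain = domain,
                storage_path = sdir, fingerprint = fp, version = version)
  write_doc(entry, entry_path)
  entry_from_doc(entry)
}

entry_from_doc <- function(e) {
  list(series_uid = e$series_uid, domain = e$domain,
       storage_path = e$storage_path, fingerprint = e$fingerprint,
       version = as.integer(e$version))
}

store_series_entry <- function(store, uid) {
  p <- file.path(store$path, "series", safe_name(uid), "entry.json")
  if (!file.exists(p)) return(NULL)
  entry_from_doc(jsonlite::read_json(p))
}

#' List repository entries visible to a user
#'
#' @param store a [cad_store].
#' @param user a [user_context].
#' @return list of repository entries whose domain is in the user's
#'   domain set (admins see everything).
#' @export
list_series <- function(store, user) {
  dirs <- list.dirs(file.path(store$path, "series"), recursive = FALSE)
  entries <- list()
  for (d in dirs) {
    p <- file.path(d, "entry.json")
    if (file.exists(p)) {
      entries[[length(entries) + 1L]] <- entry_from_doc(jsonlite::read_json(p))
    }
  }
  access_filter(user, entries)
}

#' Filter repository entries by domain access
#'
#' An entry is visible iff its domain is in the user's domain set; users
#' with the admin role see all entries.
#'
#' @param user a [user_context].
#' @param entries list of repository entries.
#' @return the visible subset, in input order.
#' @export
access_filter <- function(user, entries) {
  stopifnot(inherits(user, "user_context"))
  if (is_admin(user)) return(entries)
  Filter(function(e) e$domain %in% user$domains, entries)
}

#' Fetch a stored series
#'
#' @param store a [cad_store].
#' @param series_uid series UID.
#' @param user a [user_context]; the series' domain must be in the user's
#'   domain set.
#' @return list(metadata, volume, entry).
#' @export
fetch_series <- function(store, series_uid, user) {
  entry <- store_series_entry(store, series_uid)
  if (is.null(entry)) stop("no such series: ", series_uid, call. = FALSE)
  if (!user_can_access(user, entry$domain)) {
    stop("access denied: series ", series_uid, " is in domain \"",
         entry$domain, "\", not among user \"", user$user_id,
         "\" domains", call. = FALSE)
  }
  sdir <- file.path(store$path, "series", safe_name(series_uid))
  md <- jsonlite::read_json(file.path(sdir, "metadata.json"))
  list(metadata = series_metadata(md$series_uid, md$modality,
                                  unlist(md$key_values),
                                  phi_removed = isTRUE(md$phi_removed)),
       volume = read_mhd(file.path(sdir, "volume.mhd")),
       entry = entry)
}

#' Persist a case document
#' @param store a [cad_store].
#' @param case a [clinical_case].
#' @return invisibly, the case id.
#' @export
store_case <- function(store, case) {
  stopifnot(inherits(case, "clinical_case"))
  prev <- store_read_doc(store, "cases", case$case_id)
  if (!is.null(prev)) {
    old_uids <- vapply(prev$series_refs, `[[`, "", "series_uid")
    if (!all(old_uids %in% case_series_uids(case))) {
      stop("the series list of a case can never shrink", call. = FALSE)
    }
  }
  store_write_doc(store, "cases", case$case_id, case_to_doc(case))
  invisible(case$case_id)
}

#' Load a case document
#' @param store a [cad_store].
#' @param case_id case id.
#' @return a [clinical_case].
#' @export
load_case <- function(store, case_id) {
  doc <- store_read_doc(store, "cases", case_id)
  if (is.null(doc)) stop("no such case: ", case_id, call. = FALSE)
  doc_to_case(doc)
}

#' Persist a project document
#' @param store a [cad_store].
#' @param project a [cad_project].
#' @return invisibly, the project id.
#' @export
store_project <- function(store, project) {
  stopifnot(inherits(project, "cad_project"))
  store_write_doc(store, "projects", project$project_id,
                  project_to_doc(project))
  invisible(project$project_id)
}

#' Load a project document
#' @param store a [cad_store].
#' @param project_id project id.
#' @return a [cad_project].
#' @export
load_project <- function(store, project_id) {
  doc <- store_read_doc(store, "projects", project_id)
  if (is.null(doc)) stop("no such project: ", project_id, call. = FALSE)
  doc_to_project(doc)
}
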