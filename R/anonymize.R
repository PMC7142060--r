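# PHI (protected health information) removal from series metadata.
# The tag list is configuration, not code: a plain-text file of tag
# keywords (one per line, `#` comments). Private tags (odd group numbers)
# are always removed regardless of the list.

#' Read a PHI tag list from a config file
#'
#' One DICOM tag keyword per line; blank lines and `#` comments ignored.
#'
#' @param path file path; defaults to the list shipped with the package.
#' @return character vector of tag keywords.
#' @export
load_phi_tags <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "phi_tags.txt", package = "radcad")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

default_phi_tags <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_phi_tags()
    cache
  }
})

is_private_tag_key <- function(keys) {
  m <- regmatches(keys, regexec("^\\(([0-9A-Fa-f]{4}),[0-9A-Fa-f]{4}\\)$", keys))
  vapply(m, function(g) {
    if (length(g) < 2L) return(FALSE)
    strtoi(g[2], 16L) %% 2L == 1L
  }, logical(1))
}

#' Remove protected health information from series metadata
#'
#' Drops every tag on the PHI list, plus all private tags (odd DICOM group
#' numbers), from the metadata's key/value set. All other tags are
#' preserved verbatim and pixel data is never touched (metadata carries no
#' pixels). Idempotent: anonymizing twice equals anonymizing once; tags
#' missing from the input are a no-op.
#'
#' @param meta a [series_metadata].
#' @param phi_tags character vector of tag keywords to strip; defaults to
#'   the shipped PHI list.
#' @return the anonymized [series_metadata] with `phi_removed = TRUE`.
#' @export
anonymize <- function(meta, phi_tags = default_phi_tags()) {
  stopifnot(inherits(meta, "series_metadata"))
  kv <- meta$key_values
  keep <- !(names(kv) %in% phi_tags) & !is_private_tag_key(names(kv))
  series_metadata(
    series_uid = meta$series_uid,
    modality = meta$modality,
    key_values = kv[keep],
    phi_removed = TRUE
  )
}
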