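# Anonymized case export/import. The archive is a plain directory:
#
#   case.json                      case + project document (revisions with
#                                  run-length-encoded voxel masks)
#   series/<uid>/volume.mhd|.raw   the volume, MetaImage pair
#   series/<uid>/metadata.json     anonymized series metadata
#   series/<uid>/labels/<n>.mhd|.raw  latest-revision voxel labels as
#                                  uint8 0/1 full-grid volumes
#
# Everything a case consists of travels with it, PHI does not: metadata is
# passed through anonymize() on the way out. Import rebuilds a case equal
# to the original up to anonymized fields and a fresh store identity.

label_to_doc <- function(lab) {
  if (inherits(lab, "voxel_label")) {
    list(type = "voxel", name = lab$name,
         offset = as.integer(lab$offset), size = as.integer(lab$size),
         rle = mask_to_rle(lab$mask), attributes = lab$attributes,
         display = lab$display)
  } else if (inherits(lab, "geometric_label")) {
    list(type = "geometric", kind = lab$kind, plane = lab$plane,
         slice_index = lab$slice_index, bounds = lab$bounds,
         attributes = lab$attributes, display = lab$display)
  } else stop("unknown label class", call. = FALSE)
}

doc_to_label <- function(d) {
  if (identical(d$type, "voxel")) {
    mask <- rle_to_mask(d$rle)
    voxel_label(d$name, mask = mask,
                offset = as.integer(unlist(d$offset)),
                attributes = d$attributes,
                color = d$display$color, alpha = d$display$alpha)
  } else if (identical(d$type, "geometric")) {
    geometric_label(d$kind, d$plane, d$slice_index,
                    as.numeric(unlist(d$bounds)),
                    attributes = d$attributes,
                    color = d$display$color, alpha = d$display$alpha)
  } else stop("unknown label type in document", call. = FALSE)
}

revision_to_doc <- function(rev) {
  list(creator = rev$creator, timestamp = rev$timestamp,
       description = rev$description,
       case_attributes = rev$case_attributes,
       series_labels = lapply(rev$series_labels, function(labs) {
         lapply(labs, label_to_doc)
       }))
}

doc_to_revision <- function(d) {
  sl <- lapply(d$series_labels, function(labs) lapply(labs, doc_to_label))
  new_revision(d$creator, d$description,
               if (is.null(d$case_attributes)) list() else d$case_attributes,
               sl, timestamp = as.numeric(d$timestamp))
}

case_to_doc <- function(case) {
  list(case_id = case$case_id, project_id = case$project_id,
       domain = case$domain, series_refs = case$series_refs,
       revisions = lapply(case$revisions, revision_to_doc))
}

doc_to_case <- function(d) {
  structure(
    list(case_id = d$case_id, project_id = d$project_id,
         domain = d$domain,
         series_refs = lapply(d$series_refs, function(r) {
           list(series_uid = r$series_uid, fingerprint = r$fingerprint)
         }),
         revisions = lapply(d$revisions, doc_to_revision)),
    class = "clinical_case"
  )
}

project_to_doc <- function(project) unclass(project)

doc_to_project <- function(d) {
  cad_project(d$name,
              case_attribute_schema = if (is.null(d$case_attribute_schema))
                list() else d$case_attribute_schema,
              label_attribute_schema = if (is.null(d$label_attribute_schema))
                list() else d$label_attribute_schema,
              project_id = d$project_id)
}

write_doc <- function(doc, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp, path)
}

safe_name <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Export a case as an anonymized archive directory
#'
#' Writes the full case (all revisions) plus, per series, the anonymized
#' metadata, the volume as a MetaImage pair, and every voxel label of the
#' latest revision as a uint8 0/1 full-grid MetaImage pair.
#'
#' @param case a [clinical_case].
#' @param project the case's [cad_project].
#' @param series_data named list: series_uid -> list(metadata, volume).
#' @param dir destination directory (created if needed).
#' @param phi_tags PHI tag list used for anonymization.
#' @return invisibly, `dir`.
#' @export
export_case <- function(case, project, series_data, dir,
                        phi_tags = default_phi_tags()) {
  stopifnot(inherits(case, "clinical_case"))
  uids <- case_series_uids(case)
  missing <- setdiff(uids, names(series_data))
  if (length(missing) > 0L) {
    stop("series data missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_doc(list(case = case_to_doc(case),
                 project = project_to_doc(project)),
            file.path(dir, "case.json"))

  latest <- case$revisions[[length(case$revisions)]]
  for (uid in uids) {
    sdir <- file.path(dir, "series", safe_name(uid))
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    sd <- series_data[[uid]]
    write_mhd(sd$volume, file.path(sdir, "volume.mhd"))
    meta <- anonymize(sd$metadata, phi_tags)
    write_doc(list(series_uid = meta$series_uid, modality = meta$modality,
                   key_values = as.list(meta$key_values),
                   phi_removed = meta$phi_removed),
              file.path(sdir, "metadata.json"))
    labs <- latest$series_labels[[uid]]
    vox <- Filter(function(l) inherits(l, "voxel_label"), labs)
    if (length(vox) > 0L) {
      ldir <- file.path(sdir, "labels")
      dir.create(ldir, showWarnings = FALSE)
      for (lab in vox) {
        full <- label_to_volume(lab, dim(sd$volume$data))
        lv <- cad_volume(array(as.integer(full), dim(full)),
                         spacing = sd$volume$spacing,
                         origin = sd$volume$origin,
                         row_dir = sd$volume$row_dir,
                         col_dir = sd$volume$col_dir,
                         value_type = "uint8")
        write_mhd(lv, file.path(ldir, paste0(safe_name(lab$name), ".mhd")))
      }
    }
  }
  invisible(dir)
}

#' Import a case archive
#'
#' Validates the archive structure (all problems are reported at once),
#' then rebuilds the case, its project, and the per-series metadata and
#' volumes. The imported case receives a fresh case id; the original id
#' is kept in `imported_from`.
#'
#' @param dir archive directory written by [export_case()].
#' @return a list with `case`, `project` and `series` (named list:
#'   series_uid -> list(metadata, volume)).
#' @export
import_case <- function(dir) {
  problems <- character(0)
  case_path <- file.path(dir, "case.json")
  if (!file.exists(case_path)) {
    stop("malformed archive: missing case.json", call. = FALSE)
  }
  doc <- jsonlite::read_json(case_path)
  if (is.null(doc$case) || is.null(doc$project)) {
    stop("malformed archive: case.json lacks case/project documents",
         call. = FALSE)
  }
  case <- doc_to_case(doc$case)
  project <- doc_to_project(doc$project)

  uids <- case_series_uids(case)
  series <- list()
  for (uid in uids) {
    sdir <- file.path(dir, "series", safe_name(uid))
    vol_path <- file.path(sdir, "volume.mhd")
    meta_path <- file.path(sdir, "metadata.json")
    if (!dir.exists(sdir)) {
      problems <- c(problems, paste0("missing series directory: ", uid))
      next
    }
    if (!file.exists(vol_path)) {
      problems <- c(problems, paste0("missing volume.mhd for series ", uid))
    }
    if (!file.exists(meta_path)) {
      problems <- c(problems, paste0("missing metadata.json for series ", uid))
    }
    if (file.exists(vol_path) && file.exists(meta_path)) {
      md <- jsonlite::read_json(meta_path)
      series[[uid]] <- list(
        metadata = series_metadata(md$series_uid, md$modality,
                                   unlist(md$key_values),
                                   phi_removed = isTRUE(md$phi_removed)),
        volume = read_mhd(vol_path)
      )
    }
  }
  if (length(problems) > 0L) {
    stop("malformed archive:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  case$imported_from <- case$case_id
  case$case_id <- random_id()
  list(case = case, project = project, series = series)
}
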