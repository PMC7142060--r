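#' DICOM series metadata
#'
#' Holds the series identity plus an ordered set of header key/values
#' selected from the DICOM header. `phi_removed` records whether the
#' metadata has passed through [anonymize()].
#'
#' @param series_uid series instance UID (opaque string).
#' @param modality modality string (`"CT"`, `"MR"`, ...).
#' @param key_values named character vector of (tag keyword, string value)
#'   pairs, in header order.
#' @param phi_removed logical; `TRUE` once PHI tags have been stripped.
#' @return an object of class `series_metadata`.
#' @export
series_metadata <- function(series_uid, modality = "OT",
                            key_values = character(), phi_removed = FALSE) {
  stopifnot(is.character(series_uid), length(series_uid) == 1L)
  kv <- as.character(key_values)
  names(kv) <- names(key_values)
  structure(
    list(series_uid = series_uid, modality = modality,
         key_values = kv, phi_removed = isTRUE(phi_removed)),
    class = "series_metadata"
  )
}

#' @export
print.series_metadata <- function(x, ...) {
  cat("<series_metadata> ", x$series_uid, " (", x$modality, "), ",
      length(x$key_values), " tags",
      if (x$phi_removed) ", PHI removed" else "", "\n", sep = "")
  invisible(x)
}

#' Load a DICOM series into a volume
#'
#' Reads a set of per-slice DICOM payloads belonging to one series, orders
#' the slices by the projection of ImagePositionPatient onto the slice
#' normal (ascending; ties broken by InstanceNumber), derives the slice
#' spacing from adjacent position differences, applies the rescale
#' slope/intercept, and returns a geometry-complete volume plus the series
#' metadata. The input file order is irrelevant.
#'
#' @param files character vector of file paths, or a list of raw vectors
#'   (complete Part-10 payloads).
#' @return a list with components `volume` (a [cad_volume]) and `metadata`
#'   (a [series_metadata]).
#' @export
load_dicom_series <- function(files) {
  if (length(files) < 1L) stop("need at least one DICOM file", call. = FALSE)
  if (is.character(files)) files <- as.list(files)
  slices <- lapply(files, dicom_decode)

  el1 <- slices[[1]]$elements
  uid <- el1$SeriesInstanceUID
  if (is.null(uid)) stop("first slice lacks SeriesInstanceUID", call. = FALSE)
  for (s in slices) {
    u <- s$elements$SeriesInstanceUID
    if (is.null(u) || u != uid) {
      stop("mixed series: found SeriesInstanceUID ",
           if (is.null(u)) "<absent>" else u, " alongside ", uid,
           call. = FALSE)
    }
  }

  nx <- el1$Columns
  ny <- el1$Rows
  ps <- el1$PixelSpacing
  for (s in slices) {
    if (!identical(s$elements$Columns, nx) || !identical(s$elements$Rows, ny)) {
      stop("non-uniform in-plane image size across slices", call. = FALSE)
    }
    if (!identical(s$elements$PixelSpacing, ps)) {
      stop("non-uniform pixel spacing across slices", call. = FALSE)
    }
  }
  if (is.null(nx) || is.null(ny)) stop("missing Rows/Columns", call. = FALSE)
  # DICOM PixelSpacing is (row spacing, column spacing) = (dy, dx)
  psv <- if (is.null(ps)) c(1, 1) else ds_values(ps)
  sy <- psv[1]
  sx <- psv[2]

  iop <- if (!is.null(el1$ImageOrientationPatient)) {
    ds_values(el1$ImageOrientationPatient)
  } else c(1, 0, 0, 0, 1, 0)
  row_dir <- iop[1:3]
  col_dir <- iop[4:6]
  normal <- cross3(row_dir, col_dir)

  nz <- length(slices)
  ipp <- t(vapply(slices, function(s) {
    p <- s$elements$ImagePositionPatient
    if (is.null(p)) c(0, 0, 0) else ds_values(p)
  }, numeric(3)))
  inst <- vapply(slices, function(s) {
    v <- s$elements$InstanceNumber
    if (is.null(v)) 0 else as.numeric(v)
  }, numeric(1))

  pos <- as.numeric(ipp %*% normal)
  ord <- order(pos, inst)
  slices <- slices[ord]
  ipp <- ipp[ord, , drop = FALSE]
  pos <- pos[ord]

  if (nz > 1L) {
    gaps <- diff(pos)
    ref <- stats::median(gaps)
    if (ref <= 0) stop("slice positions are not strictly increasing",
                       call. = FALSE)
    bad <- which(abs(gaps - ref) / ref > 1e-3)
    if (length(bad) > 0L) {
      b <- bad[1]
      stop(sprintf(paste0("non-uniform slice spacing: gap between slices %d",
                          " and %d is %.6f mm (expected %.6f mm)"),
                   b - 1L, b, gaps[b], ref), call. = FALSE)
    }
    sz <- mean(gaps)
  } else {
    sz <- if (!is.null(el1$SliceThickness)) ds_values(el1$SliceThickness)[1]
          else 1.0
  }

  bits <- if (is.null(el1$BitsAllocated)) 16L else el1$BitsAllocated
  pixrep <- if (is.null(el1$PixelRepresentation)) 0L else el1$PixelRepresentation
  value_type <- if (bits == 8L) "uint8" else if (pixrep == 1L) "int16" else "uint16"

  slope <- if (!is.null(el1$RescaleSlope)) ds_values(el1$RescaleSlope)[1] else 1
  intercept <- if (!is.null(el1$RescaleIntercept)) {
    ds_values(el1$RescaleIntercept)[1]
  } else 0

  expected <- nx * ny * element_size(value_type)
  data <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    praw <- slices[[k]]$pixel_raw
    if (is.null(praw) || length(praw) != expected) {
      stop("slice ", k - 1L, ": pixel buffer has ",
           if (is.null(praw)) 0L else length(praw),
           " bytes, expected ", expected, call. = FALSE)
    }
    data[, , k] <- raw_to_pixels(praw, value_type)
  }
  if (slope != 1 || intercept != 0) data <- data * slope + intercept

  volume <- cad_volume(
    data, spacing = c(sx, sy, sz), origin = ipp[1, ],
    row_dir = row_dir, col_dir = col_dir,
    value_type = value_type, rescale = c(slope, intercept)
  )

  kv <- unlist(lapply(slices[[1]]$elements, function(v) as.character(v)[1]))
  metadata <- series_metadata(
    series_uid = uid,
    modality = if (!is.null(el1$Modality)) el1$Modality else "OT",
    key_values = kv,
    phi_removed = FALSE
  )
  list(volume = volume, metadata = metadata)
}
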