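# Minimal single-frame DICOM Part-10 codec.
#
# Supported dialect: Explicit VR Little Endian (1.2.840.10008.1.2.1),
# monochrome, one frame per file, no sequences. Anything else is rejected
# explicitly. This is the import surface for series produced by scanners or
# by the synthetic generator; plug-ins never see DICOM (see prepare_job_inputs).

EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"

# keyword -> (group, element, VR); the tags this codec reads and writes
dicom_dictionary <- function() {
  d <- rbind(
    c("SOPClassUID",                "0008", "0016", "UI"),
    c("SOPInstanceUID",             "0008", "0018", "UI"),
    c("Modality",                   "0008", "0060", "CS"),
    c("InstitutionName",            "0008", "0080", "LO"),
    c("ReferringPhysicianName",     "0008", "0090", "PN"),
    c("SeriesDescription",          "0008", "103E", "LO"),
    c("PatientName",                "0010", "0010", "PN"),
    c("PatientID",                  "0010", "0020", "LO"),
    c("PatientBirthDate",           "0010", "0030", "DA"),
    c("PatientSex",                 "0010", "0040", "CS"),
    c("PatientAddress",             "0010", "1040", "LO"),
    c("SliceThickness",             "0018", "0050", "DS"),
    c("KVP",                        "0018", "0060", "DS"),
    c("StudyInstanceUID",           "0020", "000D", "UI"),
    c("SeriesInstanceUID",          "0020", "000E", "UI"),
    c("InstanceNumber",             "0020", "0013", "IS"),
    c("ImagePositionPatient",       "0020", "0032", "DS"),
    c("ImageOrientationPatient",    "0020", "0037", "DS"),
    c("SamplesPerPixel",            "0028", "0002", "US"),
    c("PhotometricInterpretation",  "0028", "0004", "CS"),
    c("Rows",                       "0028", "0010", "US"),
    c("Columns",                    "0028", "0011", "US"),
    c("PixelSpacing",               "0028", "0030", "DS"),
    c("BitsAllocated",              "0028", "0100", "US"),
    c("BitsStored",                 "0028", "0101", "US"),
    c("HighBit",                    "0028", "0102", "US"),
    c("PixelRepresentation",        "0028", "0103", "US"),
    c("RescaleIntercept",           "0028", "1052", "DS"),
    c("RescaleSlope",               "0028", "1053", "DS"),
    c("PixelData",                  "7FE0", "0010", "OW")
  )
  data.frame(keyword = d[, 1], group = strtoi(d[, 2], 16L),
             element = strtoi(d[, 3], 16L), vr = d[, 4],
             stringsAsFactors = FALSE)
}

.dicom_dict <- dicom_dictionary()

# little-endian byte helpers -------------------------------------------------

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

# signed/unsigned 16-bit pixel buffers in little-endian order
pixels_to_raw <- function(values, value_type) {
  v <- round(as.numeric(values))
  rng <- value_type_range(value_type)
  if (any(v < rng[1] | v > rng[2])) {
    stop("pixel values out of range for ", value_type, call. = FALSE)
  }
  if (value_type == "uint8") return(as.raw(v))
  if (value_type == "int16") v <- ifelse(v < 0, v + 65536, v)
  as.raw(rbind(v %% 256, v %/% 256))
}

raw_to_pixels <- function(bytes, value_type) {
  if (value_type == "uint8") return(as.integer(bytes))
  v <- readBin(bytes, "integer", n = length(bytes) %/% 2L, size = 2L,
               signed = (value_type == "int16"), endian = "little")
  as.integer(v)
}

# encoding -------------------------------------------------------------------

long_form_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

encode_element <- function(group, element, vr, value_bytes) {
  n <- length(value_bytes)
  if (n %% 2L == 1L) stop("odd element length", call. = FALSE)
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% long_form_vrs) {
    c(head, as.raw(c(0, 0)), u32le(n), value_bytes)
  } else {
    if (n > 65534) stop("value too long for short-form VR", call. = FALSE)
    c(head, u16le(n), value_bytes)
  }
}

encode_string_element <- function(group, element, vr, value) {
  b <- charToRaw(as.character(value))
  if (length(b) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    b <- c(b, pad)
  }
  encode_element(group, element, vr, b)
}

#' Encode one image slice as a DICOM Part-10 payload
#'
#' Produces a single-frame monochrome DICOM file image (Explicit VR Little
#' Endian) from a pixel matrix and a named list of header values. Used by
#' the synthetic series generator; exported so tests and fixtures can build
#' DICOM payloads without touching a scanner.
#'
#' @param pixels integer matrix, `(nx, ny)` with column index x fastest
#'   (matches the in-memory volume layout; x maps to DICOM Columns, y to
#'   Rows).
#' @param tags named list of header values by dictionary keyword
#'   (`SeriesInstanceUID`, `ImagePositionPatient`, `PixelSpacing`, ...).
#'   Numeric vectors for DS tags are joined with `\\`.
#' @param value_type storage type of the pixel buffer.
#' @return a raw vector: the complete Part-10 file image.
#' @export
dicom_encode_slice <- function(pixels, tags, value_type = "int16") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  dict <- .dicom_dict
  nx <- nrow(pixels)
  ny <- ncol(pixels)

  defaults <- list(
    SOPClassUID = "1.2.840.10008.5.1.4.1.1.7",
    PhotometricInterpretation = "MONOCHROME2",
    SamplesPerPixel = 1L,
    Rows = ny,
    Columns = nx,
    BitsAllocated = if (value_type == "uint8") 8L else 16L,
    BitsStored = if (value_type == "uint8") 8L else 16L,
    HighBit = if (value_type == "uint8") 7L else 15L,
    PixelRepresentation = if (value_type == "int16") 1L else 0L
  )
  for (k in names(defaults)) if (is.null(tags[[k]])) tags[[k]] <- defaults[[k]]
  tags$PixelData <- NULL

  known <- names(tags) %in% dict$keyword
  if (any(!known)) {
    stop("unknown DICOM keyword(s): ",
         paste(names(tags)[!known], collapse = ", "), call. = FALSE)
  }

  rows <- dict[match(names(tags), dict$keyword), ]
  ord <- order(rows$group, rows$element)
  parts <- vector("list", length(ord) + 1L)
  for (i in seq_along(ord)) {
    r <- rows[ord[i], ]
    val <- tags[[r$keyword]]
    if (r$vr == "US") {
      parts[[i]] <- encode_element(r$group, r$element, "US",
                                   u16le(as.integer(val)))
    } else {
      s <- paste(vapply(val, format_ds, ""), collapse = "\\")
      parts[[i]] <- encode_string_element(r$group, r$element, r$vr, s)
    }
  }
  parts[[length(parts)]] <- encode_element(
    0x7FE0, 0x0010, "OW", pixels_to_raw(as.vector(pixels), value_type))
  dataset <- do.call(c, parts)

  sop_uid <- if (!is.null(tags$SOPInstanceUID)) tags$SOPInstanceUID else "0"
  meta <- c(
    encode_element(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    encode_string_element(0x0002, 0x0002, "UI", tags$SOPClassUID),
    encode_string_element(0x0002, 0x0003, "UI", sop_uid),
    encode_string_element(0x0002, 0x0010, "UI", EXPLICIT_VR_LE)
  )
  c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
    encode_element(0x0002, 0x0000, "UL", u32le(length(meta))),
    meta, dataset)
}

format_ds <- function(x) {
  if (is.character(x)) return(x)
  s <- formatC(x, format = "fg", digits = 10)
  gsub(" ", "", s)
}

# decoding -------------------------------------------------------------------

ru16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

ru32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

#' Parse one DICOM Part-10 payload
#'
#' Decodes the supported dialect (Explicit VR Little Endian, single-frame
#' monochrome). Compressed or otherwise unsupported transfer syntaxes and
#' sequence elements are rejected with an explicit error.
#'
#' @param x a raw vector or a file path.
#' @return a list with `elements` (named list of decoded values by keyword;
#'   unknown tags use a `"(gggg,eeee)"` key), `pixel_raw` (raw pixel
#'   buffer) and `transfer_syntax`.
#' @export
dicom_decode <- function(x) {
  bytes <- if (is.raw(x)) x else readBin(x, "raw", n = file.size(x))
  if (length(bytes) < 160 ||
      rawToChar(bytes[129:132]) != "DICM") {
    stop("not a DICOM Part-10 payload (missing DICM magic)", call. = FALSE)
  }
  dict <- .dicom_dict
  pos <- 133L
  n <- length(bytes)
  elements <- list()
  pixel_raw <- NULL
  transfer_syntax <- NULL
  ts_checked <- FALSE

  while (pos + 7L <= n) {
    group <- ru16(bytes, pos)
    element <- ru16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr)) {
      stop("unsupported dialect: element without explicit VR at byte ",
           pos, call. = FALSE)
    }
    if (vr %in% long_form_vrs) {
      len <- ru32(bytes, pos + 8L)
      val_at <- pos + 12L
    } else {
      len <- ru16(bytes, pos + 6L)
      val_at <- pos + 8L
    }
    if (vr == "SQ") stop("unsupported dialect: sequence elements", call. = FALSE)
    if (len == 4294967295) {
      stop("unsupported dialect: undefined-length element", call. = FALSE)
    }
    if (val_at + len - 1L > n) stop("truncated DICOM element", call. = FALSE)
    val_bytes <- if (len > 0) bytes[val_at:(val_at + len - 1L)] else raw(0)

    if (group > 2L && !ts_checked) {
      if (is.null(transfer_syntax) || transfer_syntax != EXPLICIT_VR_LE) {
        stop("unsupported transfer syntax: ",
             if (is.null(transfer_syntax)) "<absent>" else transfer_syntax,
             " (only Explicit VR Little Endian is supported)", call. = FALSE)
      }
      ts_checked <- TRUE
    }

    if (group == 2L && element == 0x0010) {
      transfer_syntax <- trim_dicom_string(val_bytes)
    } else if (group == 0x7FE0 && element == 0x0010) {
      pixel_raw <- val_bytes
    } else if (group > 2L) {
      hit <- which(dict$group == group & dict$element == element)
      key <- if (length(hit) == 1L) dict$keyword[hit] else
        sprintf("(%04X,%04X)", group, element)
      elements[[key]] <- if (vr == "US") {
        ru16(val_bytes, 1L)
      } else {
        trim_dicom_string(val_bytes)
      }
    }
    pos <- val_at + as.integer(len)
  }
  list(elements = elements, pixel_raw = pixel_raw,
       transfer_syntax = transfer_syntax)
}

trim_dicom_string <- function(val_bytes) {
  val_bytes <- val_bytes[val_bytes != as.raw(0L)]
  sub("[ ]+$", "", rawToChar(val_bytes))
}

ds_values <- function(s) as.numeric(strsplit(s, "\\\\")[[1]])
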