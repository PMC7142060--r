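# ITK MetaImage (.mhd + .raw) reader/writer.
#
# Supported dialect — deliberately narrow so that the plug-in contract is
# bit-exact and dependency-free: 3D, uncompressed, little-endian, local
# raw file, element types MET_SHORT / MET_USHORT / MET_UCHAR. Anything
# else is an explicit rejection, never a silent best-effort read.

met_types <- c(int16 = "MET_SHORT", uint16 = "MET_USHORT", uint8 = "MET_UCHAR")

#' Write a volume as an ITK MetaImage pair
#'
#' Emits `<path>.mhd` (ASCII header: NDims, DimSize, ElementSpacing,
#' Offset, TransformMatrix, ElementType, ElementDataFile) and
#' `<path>.raw` (the voxel buffer in x-fastest order, little-endian).
#'
#' @param volume a [cad_volume]; `value_type` must be one of int16,
#'   uint16, uint8.
#' @param path destination path; a trailing `.mhd` is optional.
#' @return invisibly, the `.mhd` path.
#' @export
write_mhd <- function(volume, path) {
  stopifnot(inherits(volume, "cad_volume"))
  met <- met_types[[volume$value_type]]
  if (is.null(met)) {
    stop("unsupported value_type for MHD export: ", volume$value_type,
         call. = FALSE)
  }
  base <- sub("\\.mhd$", "", path)
  mhd_path <- paste0(base, ".mhd")
  raw_name <- paste0(basename(base), ".raw")

  # %.17g guarantees doubles survive the ASCII round trip bit-exactly
  g17 <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  tm <- c(volume$row_dir, volume$col_dir, volume$normal)
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =", g17(tm)),
    paste("Offset =", g17(volume$origin)),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", g17(volume$spacing)),
    paste("DimSize =", paste(volume$dims, collapse = " ")),
    paste("ElementType =", met),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(header, mhd_path)

  con <- file(file.path(dirname(mhd_path), raw_name), "wb")
  on.exit(close(con))
  v <- round(as.vector(volume$data))
  if (volume$value_type == "uint8") {
    writeBin(as.raw(v), con)
  } else {
    if (volume$value_type == "uint16") v <- ifelse(v > 32767, v - 65536, v)
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  }
  invisible(mhd_path)
}

parse_mhd_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed MHD header line: ", lines[bad][1],
                     call. = FALSE)
  vals <- vapply(kv, `[`, "", 3L)
  names(vals) <- vapply(kv, `[`, "", 2L)
  vals
}

#' Read an ITK MetaImage pair
#'
#' Inverse of [write_mhd()] for the supported dialect. Compressed data,
#' big-endian data, non-3D images, list-mode data files and unsupported
#' element types are rejected explicitly; a raw file whose byte length
#' disagrees with DimSize is an error stating both numbers.
#'
#' @param path path to the `.mhd` header.
#' @return a [cad_volume].
#' @export
read_mhd <- function(path) {
  if (!file.exists(path)) stop("no such MHD header: ", path, call. = FALSE)
  h <- parse_mhd_header(path)

  if (isTRUE(toupper(unname(h["CompressedData"])) == "TRUE")) {
    stop("unsupported dialect: CompressedData=True", call. = FALSE)
  }
  if (isTRUE(toupper(unname(h["BinaryDataByteOrderMSB"])) == "TRUE")) {
    stop("unsupported dialect: big-endian element data", call. = FALSE)
  }
  if (!is.na(h["NDims"]) && h["NDims"] != "3") {
    stop("unsupported dialect: NDims=", h["NDims"], " (only 3 supported)",
         call. = FALSE)
  }
  met <- h["ElementType"]
  value_type <- names(met_types)[match(met, met_types)]
  if (is.na(value_type)) {
    stop("unsupported dialect: ElementType=", met, call. = FALSE)
  }
  datafile <- h["ElementDataFile"]
  if (is.na(datafile)) stop("MHD header lacks ElementDataFile", call. = FALSE)
  if (datafile %in% c("LIST", "LOCAL")) {
    stop("unsupported dialect: ElementDataFile=", datafile, call. = FALSE)
  }

  dims <- as.integer(strsplit(trimws(h["DimSize"]), "\\s+")[[1]])
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    stop("invalid DimSize: ", h["DimSize"], call. = FALSE)
  }
  spacing <- if (!is.na(h["ElementSpacing"])) {
    as.numeric(strsplit(trimws(h["ElementSpacing"]), "\\s+")[[1]])
  } else c(1, 1, 1)
  origin <- if (!is.na(h["Offset"])) {
    as.numeric(strsplit(trimws(h["Offset"]), "\\s+")[[1]])
  } else c(0, 0, 0)
  tm <- if (!is.na(h["TransformMatrix"])) {
    as.numeric(strsplit(trimws(h["TransformMatrix"]), "\\s+")[[1]])
  } else c(1, 0, 0, 0, 1, 0, 0, 0, 1)

  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path)) {
    stop("missing raw file: ", raw_path, call. = FALSE)
  }
  esize <- element_size(value_type)
  expected <- prod(dims) * esize
  actual <- file.size(raw_path)
  if (actual != expected) {
    stop("raw file length mismatch: DimSize ", paste(dims, collapse = "x"),
         " implies ", expected, " bytes but ", basename(raw_path),
         " has ", actual, " bytes", call. = FALSE)
  }

  bytes <- readBin(raw_path, "raw", n = expected)
  v <- raw_to_pixels(bytes, value_type)
  cad_volume(
    array(v, dim = dims), spacing = spacing, origin = origin,
    row_dir = tm[1:3], col_dir = tm[4:6], value_type = value_type
  )
}
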