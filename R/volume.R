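#' 3D image volume with patient-space geometry
#'
#' A `cad_volume` is the unit that CAD plug-ins and the MPR engine consume:
#' a 3D scalar grid plus the geometry needed to place every voxel in
#' patient space (LPS, the DICOM convention). Voxel indices are 0-based;
#' `data[x + 1, y + 1, z + 1]` holds the voxel at 0-based index `(x, y, z)`.
#'
#' @param data 3D numeric array, dimension `(nx, ny, nz)` in (column index
#'   x, row index y, slice index z) order.
#' @param spacing numeric length-3, voxel spacing `(sx, sy, sz)` in mm,
#'   all strictly positive.
#' @param origin numeric length-3, patient-space position (mm) of voxel
#'   `(0, 0, 0)`.
#' @param row_dir,col_dir unit direction cosines (length-3) of the image
#'   row and column axes; must be orthogonal.
#' @param value_type storage element type: `"int16"`, `"uint16"` or
#'   `"uint8"`.
#' @param rescale numeric length-2 `(slope, intercept)` that was applied to
#'   stored values at load time (recorded for provenance; `data` already
#'   holds rescaled values).
#'
#' @return An object of class `cad_volume`.
#' @export
cad_volume <- function(data,
                       spacing = c(1, 1, 1),
                       origin = c(0, 0, 0),
                       row_dir = c(1, 0, 0),
                       col_dir = c(0, 1, 0),
                       value_type = "int16",
                       rescale = c(1, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  row_dir <- as.numeric(row_dir)
  col_dir <- as.numeric(col_dir)
  stopifnot(length(spacing) == 3L, length(origin) == 3L,
            length(row_dir) == 3L, length(col_dir) == 3L)
  if (any(spacing <= 0)) {
    stop("spacing components must be strictly positive", call. = FALSE)
  }
  if (abs(sqrt(sum(row_dir^2)) - 1) > 1e-6 ||
      abs(sqrt(sum(col_dir^2)) - 1) > 1e-6) {
    stop("direction cosines must be unit length", call. = FALSE)
  }
  if (abs(sum(row_dir * col_dir)) > 1e-6) {
    stop("row/column direction cosines must be orthogonal", call. = FALSE)
  }
  value_type <- match.arg(value_type, c("int16", "uint16", "uint8"))
  structure(
    list(
      data = data,
      dims = dim(data),
      spacing = spacing,
      origin = origin,
      row_dir = row_dir,
      col_dir = col_dir,
      normal = cross3(row_dir, col_dir),
      value_type = value_type,
      rescale = as.numeric(rescale)
    ),
    class = "cad_volume"
  )
}

#' @export
print.cad_volume <- function(x, ...) {
  cat("<cad_volume> ", paste(x$dims, collapse = " x "),
      " ", x$value_type, "\n", sep = "")
  cat("  spacing (mm): ", paste(format(x$spacing), collapse = ", "), "\n",
      sep = "")
  cat("  origin  (mm): ", paste(format(x$origin), collapse = ", "), "\n",
      sep = "")
  cat("  range: [", min(x$data), ", ", max(x$data), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.cad_volume <- function(x) x$dims

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# 3x3 matrix whose columns are the patient-space steps for one voxel along
# x, y, z; maps 0-based voxel indices to mm offsets from the origin.
index_to_mm_matrix <- function(volume) {
  cbind(volume$row_dir * volume$spacing[1],
        volume$col_dir * volume$spacing[2],
        volume$normal * volume$spacing[3])
}

#' Convert voxel indices to patient-space millimetres
#'
#' Maps 0-based (possibly fractional) voxel indices to patient-space mm via
#' `origin + index * spacing` along the direction cosines. Voxel `(0,0,0)`
#' maps exactly to the volume origin.
#'
#' @param volume a [cad_volume].
#' @param index numeric length-3 index triple, or an `n x 3` matrix of them.
#' @return mm coordinates with the same shape as `index`.
#' @export
voxel_to_mm <- function(volume, index) {
  m <- index_to_mm_matrix(volume)
  if (is.matrix(index)) {
    sweep(index %*% t(m), 2, volume$origin, "+")
  } else {
    as.numeric(volume$origin + m %*% as.numeric(index))
  }
}

#' Convert patient-space millimetres to continuous voxel indices
#'
#' Exact inverse of [voxel_to_mm()] (direction cosines are orthonormal, so
#' the inverse is a transpose and a division by spacing).
#'
#' @param volume a [cad_volume].
#' @param mm numeric length-3 mm triple, or an `n x 3` matrix of them.
#' @return continuous 0-based voxel indices, same shape as `mm`.
#' @export
mm_to_voxel <- function(volume, mm) {
  rot <- cbind(volume$row_dir, volume$col_dir, volume$normal)
  if (is.matrix(mm)) {
    d <- sweep(mm, 2, volume$origin, "-") %*% rot
    sweep(d, 2, volume$spacing, "/")
  } else {
    as.numeric(t(rot) %*% (as.numeric(mm) - volume$origin) / volume$spacing)
  }
}

# bytes per stored element for each supported value type
element_size <- function(value_type) {
  switch(value_type,
         int16 = 2L, uint16 = 2L, uint8 = 1L,
         stop("unsupported value_type: ", value_type, call. = FALSE))
}

value_type_range <- function(value_type) {
  switch(value_type,
         int16 = c(-32768, 32767),
         uint16 = c(0, 65535),
         uint8 = c(0, 255))
}
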