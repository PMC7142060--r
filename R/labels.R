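# Voxel labels: sparse binary masks with an offset bounding box inside a
# series' voxel grid — the gold-standard annotation unit. The bounding box
# is kept tight on every mutation; an all-empty label has size (0,0,0) and
# is legal (a named-but-unpainted label).

#' Create a voxel label
#'
#' @param name label name (unique within a revision's series entry).
#' @param mask logical (or 0/1) 3D array; its dimensions are the label
#'   size. Use `array(logical(0), c(0, 0, 0))` for an empty label.
#' @param offset 0-based voxel index of the bounding-box corner in the
#'   series grid.
#' @param attributes attribute document for the label.
#' @param color display colour (hex string).
#' @param alpha display opacity in `[0, 1]`.
#' @return an object of class `voxel_label`, tightness-normalized.
#' @export
voxel_label <- function(name, mask = array(logical(0), c(0, 0, 0)),
                        offset = c(0, 0, 0), attributes = list(),
                        color = "#ff0000", alpha = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a 3D array", call. = FALSE)
  }
  lab <- structure(
    list(name = name, offset = as.integer(offset),
         size = dim(mask), mask = array(as.logical(mask), dim(mask)),
         attributes = attributes,
         display = list(color = color, alpha = alpha)),
    class = "voxel_label"
  )
  tighten_label(lab)
}

#' @export
print.voxel_label <- function(x, ...) {
  cat("<voxel_label> \"", x$name, "\" ", sum(x$mask), " voxels, bbox ",
      paste(x$size, collapse = "x"), " at (",
      paste(x$offset, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Number of set voxels in a label
#' @param label a [voxel_label].
#' @return integer count.
#' @export
label_voxel_count <- function(label) sum(label$mask)

# shrink the bounding box so every face touches a set voxel
tighten_label <- function(label) {
  m <- label$mask
  if (length(m) == 0L || !any(m)) {
    label$offset <- c(0L, 0L, 0L)
    label$size <- c(0L, 0L, 0L)
    label$mask <- array(logical(0), c(0, 0, 0))
    return(label)
  }
  w <- which(m, arr.ind = TRUE)
  lo <- apply(w, 2, min)
  hi <- apply(w, 2, max)
  label$mask <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  label$offset <- as.integer(label$offset + lo - 1L)
  label$size <- dim(label$mask)
  label
}

#' Expand a voxel label to a full-grid binary volume
#'
#' @param label a [voxel_label].
#' @param dims series grid dimensions `(nx, ny, nz)`.
#' @return logical 3D array of dimension `dims` with set voxels exactly at
#'   `offset + mask` positions.
#' @export
label_to_volume <- function(label, dims) {
  stopifnot(inherits(label, "voxel_label"))
  dims <- as.integer(dims)
  if (any(label$offset < 0L) || any(label$offset + label$size > dims)) {
    stop("label bounding box (offset ", paste(label$offset, collapse = ","),
         ", size ", paste(label$size, collapse = "x"),
         ") exceeds grid ", paste(dims, collapse = "x"), call. = FALSE)
  }
  full <- array(FALSE, dim = dims)
  if (all(label$size > 0L)) {
    full[label$offset[1] + seq_len(label$size[1]),
         label$offset[2] + seq_len(label$size[2]),
         label$offset[3] + seq_len(label$size[3])] <- label$mask
  }
  full
}

#' Build a tight voxel label from a full-grid binary volume
#'
#' Inverse of [label_to_volume()] (after tightness normalization).
#'
#' @param full logical/0-1 3D array covering the whole series grid.
#' @param name label name.
#' @param ... further arguments passed to [voxel_label()].
#' @return a [voxel_label].
#' @export
volume_to_label <- function(full, name = "label", ...) {
  voxel_label(name, mask = array(as.logical(full), dim(full)),
              offset = c(0, 0, 0), ...)
}

#' Apply a spherical brush to a voxel label
#'
#' Sets (paint) or clears (erase) every voxel whose centre lies within
#' `radius_mm` of the brush centre, distances measured in mm
#' (spacing-aware). The bounding box is re-tightened afterwards.
#' Idempotent: painting the same brush twice equals painting once, and
#' paint followed by erase with the identical brush restores an empty
#' region.
#'
#' @param label a [voxel_label].
#' @param center 0-based voxel index triple of the brush centre (within
#'   the series grid).
#' @param radius_mm brush radius in mm.
#' @param mode `"paint"` or `"erase"`.
#' @param dims series grid dimensions.
#' @param spacing voxel spacing in mm.
#' @return the updated [voxel_label].
#' @export
paint_voxels <- function(label, center, radius_mm,
                         mode = c("paint", "erase"),
                         dims, spacing = c(1, 1, 1)) {
  mode <- match.arg(mode)
  dims <- as.integer(dims)
  center <- as.numeric(center)
  if (any(center < 0) || any(center > dims - 1L)) {
    stop("brush center outside series grid", call. = FALSE)
  }
  full <- label_to_volume(label, dims)
  ball <- sphere_mask(dims, as.numeric(spacing), center, radius_mm)
  if (mode == "paint") full <- full | ball else full <- full & !ball
  out <- volume_to_label(full, name = label$name,
                         attributes = label$attributes,
                         color = label$display$color,
                         alpha = label$display$alpha)
  out
}

#' Create a 2D geometric annotation
#'
#' Ellipse or rectangle on one orthogonal plane, stored in mm bounds.
#' Geometric annotations are stored and round-tripped with the case but
#' never rasterized to voxels.
#'
#' @param kind `"ellipse"` or `"rectangle"`.
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param slice_index 0-based slice index along the plane's fixed axis.
#' @param bounds numeric length-4 `(min_u, min_v, max_u, max_v)` in mm;
#'   must have positive extent.
#' @param attributes attribute document.
#' @param color,alpha display style.
#' @return an object of class `geometric_label`.
#' @export
geometric_label <- function(kind = c("ellipse", "rectangle"),
                            plane = c("axial", "sagittal", "coronal"),
                            slice_index, bounds, attributes = list(),
                            color = "#00ff00", alpha = 1) {
  kind <- match.arg(kind)
  plane <- match.arg(plane)
  bounds <- as.numeric(bounds)
  stopifnot(length(bounds) == 4L)
  if (bounds[3] <= bounds[1] || bounds[4] <= bounds[2]) {
    stop("bounds must have positive extent", call. = FALSE)
  }
  structure(
    list(kind = kind, plane = plane, slice_index = as.integer(slice_index),
         bounds = bounds, attributes = attributes,
         display = list(color = color, alpha = alpha)),
    class = "geometric_label"
  )
}

# run-length encoding used when a mask is embedded in a JSON document
mask_to_rle <- function(mask) {
  v <- as.integer(mask)
  if (length(v) == 0L) return(list(dims = dim(mask), lengths = integer(0),
                                   values = integer(0)))
  r <- rle(v)
  list(dims = dim(mask), lengths = as.integer(r$lengths),
       values = as.integer(r$values))
}

rle_to_mask <- function(enc) {
  dims <- as.integer(unlist(enc$dims))
  v <- inverse.rle(list(lengths = as.integer(unlist(enc$lengths)),
                        values = as.integer(unlist(enc$values))))
  array(as.logical(v), dims)
}
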