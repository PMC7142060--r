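# Multiplanar reconstruction (MPR) kernel.
#
# One deterministic section-extraction engine serves every consumer
# (viewer-style orthogonal planes, oblique planes, candidate snapshots):
# computing a section in one vectorised pass is bit-identical to sampling
# pixel by pixel, so there is exactly one reconstruction result per
# (volume, plane) pair.

#' Oblique section specification
#'
#' Defines a sampling plane in patient space. Output pixel `(i, j)`
#' (0-based) samples the volume at exactly `origin + i * u_axis +
#' j * v_axis` — sample-at-corner, with no half-pixel offset.
#'
#' @param origin mm triple: patient-space position of output pixel (0, 0).
#' @param u_axis,v_axis mm vectors spanning one output pixel step along
#'   section-x and section-y; must be non-parallel.
#' @param out_size integer `(w, h)` output size in pixels.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param fill_value scalar used for samples outside the volume; `NULL`
#'   (default) means the volume minimum is used at sampling time.
#' @return an object of class `section_spec`.
#' @export
section_spec <- function(origin, u_axis, v_axis, out_size,
                         interpolation = c("trilinear", "nearest"),
                         fill_value = NULL) {
  origin <- as.numeric(origin)
  u_axis <- as.numeric(u_axis)
  v_axis <- as.numeric(v_axis)
  out_size <- as.integer(out_size)
  stopifnot(length(origin) == 3L, length(u_axis) == 3L,
            length(v_axis) == 3L, length(out_size) == 2L)
  if (sqrt(sum(cross3(u_axis, v_axis)^2)) <= 1e-9) {
    stop("u_axis and v_axis must be nonzero and not parallel", call. = FALSE)
  }
  if (any(out_size < 1L)) stop("out_size must be positive", call. = FALSE)
  structure(
    list(origin = origin, u_axis = u_axis, v_axis = v_axis,
         out_size = out_size,
         interpolation = match.arg(interpolation),
         fill_value = fill_value),
    class = "section_spec"
  )
}

#' Extract an orthogonal grid plane
#'
#' Copies one stored grid plane exactly — no interpolation, lossless.
#' `axial` fixes z, `sagittal` fixes x, `coronal` fixes y; `index` is
#' 0-based along the fixed axis.
#'
#' @param volume a [cad_volume].
#' @param axis `"axial"`, `"sagittal"` or `"coronal"`.
#' @param index 0-based slice index along the fixed axis.
#' @return a numeric matrix; first dimension is section-x.
#' @export
orthogonal_section <- function(volume,
                               axis = c("axial", "sagittal", "coronal"),
                               index) {
  stopifnot(inherits(volume, "cad_volume"))
  axis <- match.arg(axis)
  d <- volume$dims
  nmax <- switch(axis, axial = d[3], sagittal = d[1], coronal = d[2])
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) || index < 0L || index >= nmax) {
    stop(sprintf("index %s out of range for %s axis (valid: 0..%d)",
                 index, axis, nmax - 1L), call. = FALSE)
  }
  switch(axis,
         axial = volume$data[, , index + 1L],
         sagittal = volume$data[index + 1L, , ],
         coronal = volume$data[, index + 1L, ])
}

#' Extract an oblique section
#'
#' Samples the volume on an arbitrary plane. Output pixel `(i, j)`
#' (0-based; stored at `[i + 1, j + 1]`) samples patient-space position
#' `origin + i * u_axis + j * v_axis` with the spec's interpolation.
#' Samples outside the volume yield the fill value. Fully deterministic.
#'
#' In trilinear mode, samples landing exactly on a voxel boundary use the
#' mathematical weights: a zero-weight neighbour contributes nothing even
#' when it lies outside the grid, so the volume's faces are sampled
#' without fill bleeding.
#'
#' @param volume a [cad_volume].
#' @param spec a [section_spec].
#' @return numeric matrix of dimension `(w, h)`.
#' @export
oblique_section <- function(volume, spec) {
  stopifnot(inherits(volume, "cad_volume"), inherits(spec, "section_spec"))
  w <- spec$out_size[1]
  h <- spec$out_size[2]
  fill <- if (is.null(spec$fill_value)) min(volume$data) else spec$fill_value

  ii <- rep(0:(w - 1L), times = h)
  jj <- rep(0:(h - 1L), each = w)
  pts <- outer(ii, spec$u_axis) + outer(jj, spec$v_axis)
  pts <- sweep(pts, 2, spec$origin, "+")
  idx <- mm_to_voxel(volume, pts)

  vals <- if (spec$interpolation == "nearest") {
    sample_nearest(volume, idx, fill)
  } else {
    sample_trilinear(volume, idx, fill)
  }
  matrix(vals, nrow = w, ncol = h)
}

sample_nearest <- function(volume, idx, fill) {
  d <- volume$dims
  xi <- floor(idx + 0.5)
  inside <- xi[, 1] >= 0 & xi[, 1] <= d[1] - 1 &
    xi[, 2] >= 0 & xi[, 2] <= d[2] - 1 &
    xi[, 3] >= 0 & xi[, 3] <= d[3] - 1
  out <- rep(fill, nrow(idx))
  lin <- 1 + xi[inside, 1] + d[1] * (xi[inside, 2] + d[2] * xi[inside, 3])
  out[inside] <- volume$data[lin]
  out
}

sample_trilinear <- function(volume, idx, fill) {
  d <- volume$dims
  # snap samples within 1e-9 voxel of the volume boundary onto it, so that
  # planes constructed to lie exactly on the grid are not pushed outside
  # by floating-point noise in the patient-space arithmetic
  tol <- 1e-9
  for (a in 1:3) {
    col <- idx[, a]
    col[col > -tol & col < 0] <- 0
    hi <- d[a] - 1
    col[col > hi & col < hi + tol] <- hi
    idx[, a] <- col
  }
  x0 <- floor(idx)
  fr <- idx - x0
  acc <- numeric(nrow(idx))
  bad <- logical(nrow(idx))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) fr[, 1] else 1 - fr[, 1]) *
      (if (cy) fr[, 2] else 1 - fr[, 2]) *
      (if (cz) fr[, 3] else 1 - fr[, 3])
    xi <- x0[, 1] + cx
    yi <- x0[, 2] + cy
    zi <- x0[, 3] + cz
    inside <- xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
      zi >= 0 & zi <= d[3] - 1
    bad <- bad | (wt > 0 & !inside)
    v <- numeric(length(wt))
    lin <- 1 + xi[inside] + d[1] * (yi[inside] + d[2] * zi[inside])
    v[inside] <- volume$data[lin]
    acc <- acc + wt * v
  }
  ifelse(bad, fill, acc)
}

#' Window/level display specification
#'
#' Standard radiology display transform: stored values in the range
#' `level - width/2 .. level + width/2` map linearly onto display greys
#' 0..255.
#'
#' @param level window centre, in stored-value units.
#' @param width window width, strictly positive.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(level, width) {
  if (!is.numeric(width) || width <= 0) {
    stop("window width must be > 0", call. = FALSE)
  }
  structure(list(level = level, width = width), class = "window_spec")
}

#' Map a section to 8-bit display greys
#'
#' `out = round(clamp((v - (level - width/2)) / width, 0, 1) * 255)`,
#' rounding half up (so the window centre maps to 128). Monotone
#' non-decreasing in the input.
#'
#' @param image numeric matrix (a section).
#' @param window a [window_spec].
#' @return integer matrix with values in 0..255.
#' @export
apply_window <- function(image, window) {
  stopifnot(inherits(window, "window_spec"))
  lo <- window$level - window$width / 2
  t <- pmin(pmax((image - lo) / window$width, 0), 1)
  out <- as.integer(floor(t * 255 + 0.5))
  if (is.matrix(image)) dim(out) <- dim(image)
  out
}

#' Export a windowed section as a grayscale PNG
#'
#' @param image8 integer matrix from [apply_window()] (values 0..255,
#'   first dimension section-x).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_section_png <- function(image8, path) {
  stopifnot(is.matrix(image8))
  if (any(image8 < 0 | image8 > 255)) {
    stop("image values must be in 0..255", call. = FALSE)
  }
  png::writePNG(t(image8) / 255, path)
  invisible(path)
}
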