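# Toy CAD plug-in: threshold + 26-connected component analysis. This
# stands in for real detection algorithms so that the whole harness
# (inputs, sandbox, results contract, feedback) can be exercised against
# planted ground truth.

# label the TRUE voxels of a logical 3D array into 26-connected
# components; returns a list of integer index matrices (one per component)
connected_components_26 <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  n <- length(lin)
  if (n == 0L) return(list())
  # 0-based coordinates of each set voxel
  z <- (lin - 1L) %/% (d[1] * d[2])
  r <- (lin - 1L) %% (d[1] * d[2])
  y <- r %/% d[1]
  x <- r %% d[1]

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # only half the neighbourhood is needed; each pair is visited once
  offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & (offs[, 2] > 0 |
                                      (offs[, 2] == 0 & offs[, 1] > 0))), ,
               drop = FALSE]

  for (k in seq_len(nrow(offs))) {
    nxv <- x + offs[k, 1]
    nyv <- y + offs[k, 2]
    nzv <- z + offs[k, 3]
    ok <- nxv >= 0 & nxv < d[1] & nyv >= 0 & nyv < d[2] &
      nzv >= 0 & nzv < d[3]
    nl <- 1L + nxv + d[1] * (nyv + d[2] * nzv)
    j <- match(nl, lin)           # neighbour's position in the voxel list
    hit <- which(ok & !is.na(j))
    for (i in hit) {
      ri <- find(i)
      rj <- find(j[i])
      if (ri != rj) parent[ri] <- rj
    }
  }

  roots <- vapply(seq_len(n), find, 0L)
  comp_ids <- split(seq_len(n), roots)
  lapply(comp_ids, function(ix) cbind(x = x[ix], y = y[ix], z = z[ix]))
}

#' Detect bright blobs in a volume
#'
#' Thresholds the volume, labels 26-connected components, drops components
#' smaller than `min_voxels`, and returns them as ranked lesion
#' candidates: rank 1 is the largest component (ties broken by ascending
#' centroid z, then y, then x, keeping the ranking deterministic),
#' location is the rounded component centroid (0-based voxel index), and
#' confidence is the component's mean intensity.
#'
#' @param volume a [cad_volume].
#' @param threshold voxels strictly above this value are foreground.
#' @param min_voxels minimum component size kept.
#' @return a data.frame with columns `rank`, `x`, `y`, `z` (rounded
#'   centroid), `voxels`, `confidence`, `volume_mm3`; zero rows when
#'   nothing is found.
#' @export
toy_blob_detector <- function(volume, threshold, min_voxels = 1L) {
  stopifnot(inherits(volume, "cad_volume"))
  comps <- connected_components_26(volume$data > threshold)
  comps <- Filter(function(m) nrow(m) >= min_voxels, comps)
  empty <- data.frame(rank = integer(0), x = integer(0), y = integer(0),
                      z = integer(0), voxels = integer(0),
                      confidence = numeric(0), volume_mm3 = numeric(0))
  if (length(comps) == 0L) return(empty)

  voxel_mm3 <- prod(volume$spacing)
  rows <- lapply(comps, function(m) {
    ctr <- colMeans(m)
    vals <- volume$data[1L + m[, 1] + volume$dims[1] *
                          (m[, 2] + volume$dims[2] * m[, 3])]
    data.frame(x = floor(ctr[1] + 0.5), y = floor(ctr[2] + 0.5),
               z = floor(ctr[3] + 0.5),
               cx = ctr[1], cy = ctr[2], cz = ctr[3],
               voxels = nrow(m), confidence = mean(vals),
               volume_mm3 = nrow(m) * voxel_mm3)
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$voxels, tab$cz, tab$cy, tab$cx)
  tab <- tab[ord, c("x", "y", "z", "voxels", "confidence", "volume_mm3")]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Runtime closure for the toy detector plug-in
#'
#' Builds an in-process plug-in runtime obeying the job contract: it reads
#' `series/0/volume.mhd` from the job work directory, runs
#' [toy_blob_detector()], and writes `out/results.json` (schema version
#' 1: `{"candidates": [{"rank", "location_voxel", "confidence",
#' "volume_mm3"}], "displays": []}`).
#'
#' @param threshold,min_voxels passed to [toy_blob_detector()].
#' @return a function of one argument (the work directory path), suitable
#'   as the `runtime` of a [plugin_manifest()].
#' @export
toy_plugin_runtime <- function(threshold, min_voxels = 1L) {
  force(threshold); force(min_voxels)
  function(work_dir) {
    vol <- read_mhd(file.path(work_dir, "series", "0", "volume.mhd"))
    cands <- toy_blob_detector(vol, threshold, min_voxels)
    out <- list(
      candidates = lapply(seq_len(nrow(cands)), function(i) {
        list(rank = cands$rank[i],
             location_voxel = c(cands$x[i], cands$y[i], cands$z[i]),
             confidence = cands$confidence[i],
             volume_mm3 = cands$volume_mm3[i])
      }),
      displays = list()
    )
    jsonlite::write_json(out, file.path(work_dir, "out", "results.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(NULL)
  }
}
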