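#' @include vlsm.R
NULL

#' @describeIn makeLabelAtlas grid dimensions of the atlas volume
#' @param x a LabelAtlas
#' @export
setMethod("gridDims", "LabelAtlas", function(x) gridDims(x@labels))

#' @describeIn makeLabelAtlas voxel-to-world affine
#' @export
setMethod("worldAffine", "LabelAtlas", function(x) worldAffine(x@labels))

#' @describeIn makeLabelAtlas voxel volume in mm^3
#' @export
setMethod("voxelVolume", "LabelAtlas", function(x) voxelVolume(x@labels))

setMethod("show", "LabelAtlas", function(object) {
  cat(sprintf("LabelAtlas '%s': %d labelled structures\n",
              object@atlasName, nrow(object@names)))
})

#' Percent overlap of a cluster with atlas structures
#'
#' For each structure, percent = 100 x (cluster voxels carrying that label) /
#' (cluster size). Rows are sorted by descending percent; structures below
#' `floorPercent` are dropped after the unlabelled remainder is computed, so
#' raising the floor never changes surviving rows. Full precision is kept in
#' the `percent` column; `percent_rounded` carries the integer rendering used
#' in human-readable tables.
#'
#' @param clusterVoxels m x 3 matrix of member voxel indices (1-based), e.g.
#'   one element of a \linkS4class{VlsmReport}'s `clusterVoxels`
#' @param atlas a \linkS4class{LabelAtlas} on the same grid
#' @param floorPercent report floor (default 1, i.e. only overlaps >= 1%)
#' @param reference optional \linkS4class{VolumeGrid} to enforce the shared
#'   grid (e.g. the t-map's grid)
#' @return data.frame (atlas_name, label_id, name, voxels, percent,
#'   percent_rounded) with attribute `unlabelled_percent`
#' @export
labelOverlap <- function(clusterVoxels, atlas, floorPercent = 1,
                         reference = NULL) {
  if (!is.null(reference)) .checkSameGrid(atlas@labels, reference,
                                          "atlas and cluster grid")
  stopifnot(is.matrix(clusterVoxels), ncol(clusterVoxels) == 3L)
  total <- nrow(clusterVoxels)
  labs <- atlas@labels@data[clusterVoxels]
  unlabPct <- 100 * sum(labs == 0) / total
  tab <- table(labs[labs != 0])
  out <- data.frame(atlas_name = atlas@atlasName,
                    label_id = as.integer(names(tab)),
                    voxels = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$name <- atlas@names$name[match(out$label_id, atlas@names$label_id)]
  out$percent <- 100 * out$voxels / total
  out <- out[order(-out$percent), , drop = FALSE]
  out <- out[out$percent >= floorPercent, , drop = FALSE]
  out$percent_rounded <- round(out$percent)
  rownames(out) <- NULL
  out <- out[, c("atlas_name", "label_id", "name", "voxels", "percent",
                 "percent_rounded")]
  attr(out, "unlabelled_percent") <- unlabPct
  out
}

#' Cluster-tract intersection
#'
#' Counts cluster voxels falling inside the canonical tract; a zero count is
#' the "cluster did not overlap with the tract" statement.
#'
#' @param clusterVoxels m x 3 matrix of member voxel indices
#' @param tract a \linkS4class{TractMap} on the same grid
#' @return list with `voxels`, `percent` (of the cluster) and `overlaps`
#' @export
tractIntersection <- function(clusterVoxels, tract) {
  stopifnot(is.matrix(clusterVoxels), ncol(clusterVoxels) == 3L)
  inTract <- tract@mask@data[clusterVoxels]
  v <- sum(inTract)
  list(voxels = as.integer(v),
       percent = 100 * v / nrow(clusterVoxels),
       overlaps = v > 0)
}

#' Atlas tables for every significant cluster of a VLSM report
#'
#' @param report a \linkS4class{VlsmReport}
#' @param atlases list of \linkS4class{LabelAtlas} objects; each is reported
#'   independently (a voxel may count in a grey-matter structure and a
#'   white-matter tract simultaneously)
#' @param tract optional \linkS4class{TractMap} for the tract-intersection
#'   statement
#' @param floorPercent report floor (default 1)
#' @return data.frame of stacked overlap rows with a cluster_id column
#' @export
reportClusterAnatomy <- function(report, atlases, tract = NULL,
                                 floorPercent = 1) {
  cl <- clusters(report)
  if (!nrow(cl)) return(data.frame())
  sig <- which(cl$significant)
  pieces <- list()
  for (i in sig) {
    vox <- report@clusterVoxels[[i]]
    for (atl in atlases) {
      ov <- labelOverlap(vox, atl, floorPercent, reference = report@tmap@t)
      if (nrow(ov)) {
        ov$cluster_id <- cl$cluster_id[i]
        pieces[[length(pieces) + 1L]] <- ov
      }
    }
    if (!is.null(tract)) {
      ti <- tractIntersection(vox, tract)
      pieces[[length(pieces) + 1L]] <- data.frame(
        atlas_name = "canonical tract", label_id = NA_integer_,
        name = if (ti$overlaps) "tract overlap" else "no tract overlap",
        voxels = ti$voxels, percent = ti$percent,
        percent_rounded = round(ti$percent), cluster_id = cl$cluster_id[i])
    }
  }
  if (!length(pieces)) return(data.frame())
  do.call(rbind, pieces)
}
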