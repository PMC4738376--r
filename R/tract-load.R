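#' @include volume-grid.R
NULL

#' Build a TractMap from a binary tract volume
#'
#' Computes the axial cross-sectional area profile A(z) (tract voxels per
#' slice times in-plane voxel area), its maximum A_max, and the slice support.
#' "Slice" is an axial plane of the analysis grid (third index), matching the
#' geometry of a descending tract.
#'
#' @param mask binary \linkS4class{VolumeGrid}
#' @return a \linkS4class{TractMap}
#' @export
tractMap <- function(mask) {
  a <- mask@affine
  # in-plane voxel area: |cross product| of the first two affine columns
  c1 <- a[1:3, 1]; c2 <- a[1:3, 2]
  cr <- c(c1[2] * c2[3] - c1[3] * c2[2],
          c1[3] * c2[1] - c1[1] * c2[3],
          c1[1] * c2[2] - c1[2] * c2[1])
  inPlaneArea <- sqrt(sum(cr^2))
  counts <- apply(mask@data, 3L, sum)
  sliceArea <- counts * inPlaneArea
  zSupport <- which(sliceArea > 0)
  if (length(zSupport) == 0L) stop("empty tract")
  new("TractMap", mask = mask, sliceArea = as.numeric(sliceArea),
      maxArea = max(sliceArea), zSupport = as.integer(zSupport))
}

#' @describeIn tractMap grid dimensions of the tract volume
#' @param x a TractMap
#' @export
setMethod("gridDims", "TractMap", function(x) gridDims(x@mask))

#' @describeIn tractMap voxel-to-world affine
#' @export
setMethod("worldAffine", "TractMap", function(x) worldAffine(x@mask))

#' @describeIn tractMap voxel volume in mm^3
#' @export
setMethod("voxelVolume", "TractMap", function(x) voxelVolume(x@mask))

setMethod("show", "TractMap", function(object) {
  cat(sprintf(
    "TractMap: %d voxels over %d axial slices; A_max = %.1f mm^2 (slice %d)\n",
    sum(object@mask@data), length(object@zSupport), object@maxArea,
    object@zSupport[which.max(object@sliceArea[object@zSupport])]))
})

#' Weighted tract lesion load (wCST-LL) of one lesion
#'
#' For each axial slice z in the tract's support, the lesion-tract overlap
#' volume o(z) (mm^3) is weighted by the ratio of the maximum tract
#' cross-sectional area to that slice's area, `A_max / A(z)`, correcting for
#' the narrowing of the corticospinal tract as it descends into the posterior
#' limb of the internal capsule. The load is `sum_z o(z) * A_max / A(z) / 1000`
#' in cm^3.
#'
#' A lesion with no voxel on any slice of the tract's axial support (e.g. a
#' medullary lesion below a supratentorial tract template) is flagged
#' `outside_tract_support` and its load reported as missing rather than zero.
#'
#' @param lesion binary \linkS4class{VolumeGrid} on the tract's grid
#' @param tract a \linkS4class{TractMap}
#' @return a \linkS4class{LoadResult}
#' @examples
#' \dontrun{
#' res <- weightedTractLoad(mask, tract)
#' res@wcstLlCm3
#' }
#' @export
weightedTractLoad <- function(lesion, tract) {
  .checkSameGrid(lesion, tract@mask, "lesion and tract")
  vv <- voxelVolume(tract)
  zs <- tract@zSupport
  lesionPerSlice <- apply(lesion@data, 3L, sum)
  if (all(lesionPerSlice[zs] == 0) && sum(lesion@data) > 0) {
    status <- "outside_tract_support"
    perSlice <- data.frame(z = integer(), overlap_mm3 = numeric(),
                           area_mm2 = numeric(), weight = numeric(),
                           weighted_mm3 = numeric())
    return(new("LoadResult", wcstLlCm3 = NA_real_, perSlice = perSlice,
               status = status))
  }
  overlapCounts <- vapply(zs, function(z)
    sum(lesion@data[, , z] * tract@mask@data[, , z]), numeric(1))
  o <- overlapCounts * vv
  A <- tract@sliceArea[zs]
  w <- tract@maxArea / A
  perSlice <- data.frame(z = zs, overlap_mm3 = o, area_mm2 = A,
                         weight = w, weighted_mm3 = o * w)
  new("LoadResult", wcstLlCm3 = sum(o * w) / 1000, perSlice = perSlice,
      status = "ok")
}

setMethod("show", "LoadResult", function(object) {
  if (object@status == "ok")
    cat(sprintf("LoadResult: wCST-LL = %.4f cm^3 over %d contributing slices\n",
                object@wcstLlCm3, sum(object@perSlice$overlap_mm3 > 0)))
  else
    cat("LoadResult: lesion outside tract axial support (load missing)\n")
})

#' Weighted tract lesion loads for a whole cohort
#'
#' One row per subject. Subjects whose lesion lies entirely outside the
#' tract's axial support are flagged `outside_tract_support` with a missing
#' load; downstream load regressions exclude them (they are not coerced to 0).
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param tract a \linkS4class{TractMap}
#' @return data.frame with columns subject_id, wcst_ll_cm3, status
#' @export
cohortLoads <- function(cohort, tract) {
  res <- lapply(cohort@masks, weightedTractLoad, tract = tract)
  data.frame(subject_id = records(cohort)$subject_id,
             wcst_ll_cm3 = vapply(res, slot, numeric(1), "wcstLlCm3"),
             status = vapply(res, slot, character(1), "status"),
             row.names = NULL, stringsAsFactors = FALSE)
}
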