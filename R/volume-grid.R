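#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a VolumeGrid
#'
#' @param data 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix; if `NULL`, an axis-aligned affine
#'   with edge `voxelMm` is built, centred so the grid is symmetric about
#'   x = y = z = 0 mm (the mid-sagittal plane x = 0 then bisects the grid,
#'   which is what hemisphere flipping requires).
#' @param voxelMm isotropic voxel edge in mm (only used when `affine` is NULL).
#' @return a \linkS4class{VolumeGrid}
#' @examples
#' g <- volumeGrid(array(0, c(16, 16, 16)), voxelMm = 2)
#' voxelVolume(g)  # 8 mm^3
#' @export
volumeGrid <- function(data, affine = NULL, voxelMm = 1) {
  if (is.null(dim(data)) || length(dim(data)) != 3L)
    stop("unsupported shape: data must be a 3-D array")
  if (is.null(affine)) {
    d <- dim(data)
    affine <- diag(c(voxelMm, voxelMm, voxelMm, 1))
    affine[1:3, 4] <- -(d - 1) / 2 * voxelMm
  }
  new("VolumeGrid", data = data, affine = affine)
}

#' @describeIn volumeGrid dimensions of the voxel lattice
#' @param x a VolumeGrid
#' @export
setMethod("gridDims", "VolumeGrid", function(x) dim(x@data))

#' @describeIn volumeGrid the 4x4 voxel-to-world matrix
#' @export
setMethod("worldAffine", "VolumeGrid", function(x) x@affine)

#' @describeIn volumeGrid voxel volume in mm^3 (|det| of the 3x3 block)
#' @export
setMethod("voxelVolume", "VolumeGrid",
          function(x) abs(det(x@affine[1:3, 1:3, drop = FALSE])))

setMethod("show", "VolumeGrid", function(object) {
  d <- gridDims(object)
  cat(sprintf("VolumeGrid %d x %d x %d, voxel %.3g mm^3, %d nonzero voxels\n",
              d[1], d[2], d[3], voxelVolume(object),
              sum(object@data != 0)))
})

#' Map voxel indices to world (mm) coordinates
#'
#' @param grid a \linkS4class{VolumeGrid}
#' @param idx m x 3 matrix (or length-3 vector) of 1-based voxel indices
#' @return m x 3 matrix of mm coordinates
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- rbind(idx)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(grid@affine)
  out[, 1:3, drop = FALSE]
}

#' Map world (mm) coordinates to (fractional) voxel indices
#'
#' @param grid a \linkS4class{VolumeGrid}
#' @param xyz m x 3 matrix (or length-3 vector) of mm coordinates
#' @return m x 3 matrix of 1-based (possibly fractional) voxel indices
#' @export
worldToVoxel <- function(grid, xyz) {
  xyz <- rbind(xyz)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(grid@affine))
  out[, 1:3, drop = FALSE] + 1
}

#' Convert a voxel count to millilitres
#'
#' The bookkeeping used throughout cluster and lesion-volume reporting:
#' `n * voxel volume (mm^3) / 1000`. On the default 2 mm isotropic grid a
#' 309-voxel cluster is 2.472 mL.
#'
#' @param nVoxels non-negative voxel count (vectorised)
#' @param grid a \linkS4class{VolumeGrid} supplying the voxel volume
#' @return volume in mL
#' @export
voxelsToMl <- function(nVoxels, grid) {
  stopifnot(all(nVoxels >= 0))
  nVoxels * voxelVolume(grid) / 1000
}

#' Mirror a right-hemisphere lesion onto the left
#'
#' Lesions are pooled in one hemisphere before voxelwise analysis: right-sided
#' masks are reflected about the mid-sagittal plane x = 0 mm, left-sided masks
#' pass through unchanged. The reflection is performed in index space, which
#' requires the first index axis to be aligned with the world x axis and the
#' grid to be symmetric about x = 0; oblique or off-centre grids are rejected
#' rather than resampled (resampling would blur a binary mask).
#'
#' @param mask binary \linkS4class{VolumeGrid}
#' @param side "left" or "right"
#' @return a \linkS4class{VolumeGrid} with the same lesioned-voxel count
#' @export
flipToLeft <- function(mask, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") return(mask)
  a <- mask@affine
  offAxis <- max(abs(a[1, 2:3]), abs(a[2:3, 1]))
  if (offAxis > 1e-6)
    stop("unsupported orientation: x axis of the affine is not aligned ",
         "with the first index axis; refusing to flip an oblique grid")
  nx <- dim(mask@data)[1L]
  xFirst <- a[1, 1] * 0 + a[1, 4]          # world x of index 1
  xLast  <- a[1, 1] * (nx - 1) + a[1, 4]   # world x of index nx
  if (abs(xFirst + xLast) > 1e-6)
    stop("unsupported orientation: grid is not symmetric about x = 0 mm; ",
         "cannot mirror about the mid-sagittal plane without resampling")
  out <- mask
  out@data <- mask@data[nx:1, , , drop = FALSE]
  out
}

#' Stack a cohort's masks into a subjects-by-voxels matrix
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @return n x V numeric 0/1 matrix (V = number of voxels, column-major
#'   voxel order)
#' @export
lesionMatrix <- function(cohort) {
  n <- nSubjects(cohort)
  V <- prod(gridDims(cohort))
  out <- matrix(0, n, V)
  for (i in seq_len(n)) out[i, ] <- as.vector(cohort@masks[[i]]@data)
  out
}

# shared grid-compatibility check
.checkSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a@data), dim(b@data)) ||
      max(abs(a@affine - b@affine)) > 1e-6)
    stop("cohort-consistency error: ", what, " do not share grid and affine")
  invisible(TRUE)
}
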