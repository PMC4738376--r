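#' @include AllClasses.R
NULL

#' Grid dimensions of a volume-bearing object
#' @param x a VolumeGrid, LesionCohort, TractMap or LabelAtlas
#' @return integer(3) voxel counts
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' Voxel-to-world affine of a volume-bearing object
#' @param x a VolumeGrid, LesionCohort, TractMap or LabelAtlas
#' @return 4x4 matrix
#' @export
setGeneric("worldAffine", function(x) standardGeneric("worldAffine"))

#' Volume of one voxel in mm^3
#' @param x a VolumeGrid, LesionCohort, TractMap or LabelAtlas
#' @return scalar mm^3
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' Number of subjects in a cohort
#' @param x a LesionCohort
#' @return integer count
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Behavioural records of a cohort
#' @param x a LesionCohort
#' @return data.frame, one row per subject
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Lesion masks of a cohort
#' @param x a LesionCohort
#' @return named list of VolumeGrid masks
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))

#' Supra-threshold clusters of a VLSM report
#' @param x a VlsmReport
#' @return data.frame of cluster statistics
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
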