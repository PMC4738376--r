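#' @import methods
NULL

#' VolumeGrid: a 3-D scalar lattice in world (mm) coordinates
#'
#' The common substrate for binary lesion masks, t-statistic maps and integer
#' label atlases. The `affine` slot is the 4x4 NIfTI-style voxel-to-world map:
#' world mm coordinates of the voxel with R index `(i, j, k)` are
#' `affine %*% c(i - 1, j - 1, k - 1, 1)` (NIfTI affines address 0-based
#' indices; R arrays are 1-based).
#'
#' @slot data 3-D numeric array (mask values in \{0, 1\}, t values, or integer
#'   labels depending on use).
#' @slot affine 4x4 invertible voxel-index-to-mm matrix.
#' @export
setClass("VolumeGrid", representation(data = "array", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  if (any(d < 1L)) msg <- c(msg, "all three dimensions must be >= 1")
  a <- object@affine
  if (!all(dim(a) == c(4L, 4L))) {
    msg <- c(msg, "affine must be 4x4")
  } else {
    det3 <- det(a[1:3, 1:3, drop = FALSE])
    if (!is.finite(det3) || abs(det3) < 1e-12)
      msg <- c(msg, "affine must be invertible")
    if (any(a[4, ] != c(0, 0, 0, 1)))
      msg <- c(msg, "affine bottom row must be (0, 0, 0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' LesionCohort: aligned lesion masks and behavioural records
#'
#' One binary \linkS4class{VolumeGrid} per subject, all sharing a grid and
#' affine, index-aligned with a behavioural table (one row per subject).
#'
#' @slot masks list of binary VolumeGrid objects.
#' @slot records data.frame with one row per subject; columns include
#'   `subject_id`, `side`, per-measure baseline/outcome/change scores,
#'   `age`, `fazekas`, `time_days`, `lesion_volume_cm3`.
#' @slot log character vector of provenance messages (exclusions, warnings).
#' @export
setClass("LesionCohort",
         representation(masks = "list", records = "data.frame",
                        log = "character"))

setValidity("LesionCohort", function(object) {
  msg <- character()
  n <- length(object@masks)
  if (n != nrow(object@records))
    msg <- c(msg, "masks and records must have equal length")
  if (!"subject_id" %in% names(object@records))
    msg <- c(msg, "records must carry a subject_id column")
  else if (anyDuplicated(object@records$subject_id))
    msg <- c(msg, "duplicate subject_id")
  if (n > 0L) {
    if (!all(vapply(object@masks, is, logical(1), "VolumeGrid")))
      msg <- c(msg, "all masks must be VolumeGrid objects")
    else {
      d1 <- dim(object@masks[[1L]]@data)
      a1 <- object@masks[[1L]]@affine
      same <- vapply(object@masks, function(m)
        identical(dim(m@data), d1) && max(abs(m@affine - a1)) < 1e-6,
        logical(1))
      if (!all(same)) msg <- c(msg, "all masks must share dimensions and affine")
    }
    if (!is.null(names(object@masks)) &&
        !identical(unname(names(object@masks)),
                   unname(as.character(object@records$subject_id))))
      msg <- c(msg, "mask names must match records subject_id order")
  }
  if (length(msg)) msg else TRUE
})

#' TractMap: a canonical binary tract with its axial area profile
#'
#' Houses the canonical corticospinal tract (or any descending tract) used for
#' weighted lesion-load scoring. The per-slice cross-sectional area profile
#' A(z) is recomputable from the mask and drives the slice weights
#' `A_max / A(z)`.
#'
#' @slot mask binary \linkS4class{VolumeGrid}.
#' @slot sliceArea numeric, A(z) in mm^2 for every axial slice z.
#' @slot maxArea numeric, max over z of A(z).
#' @slot zSupport integer, slice indices (1-based) where A(z) > 0.
#' @export
setClass("TractMap",
         representation(mask = "VolumeGrid", sliceArea = "numeric",
                        maxArea = "numeric", zSupport = "integer"))

setValidity("TractMap", function(object) {
  msg <- character()
  nz <- dim(object@mask@data)[3L]
  if (length(object@sliceArea) != nz)
    msg <- c(msg, "sliceArea must have one entry per axial slice")
  if (length(object@zSupport) == 0L || object@maxArea <= 0)
    msg <- c(msg, "tract must be non-empty (maxArea > 0)")
  else {
    if (abs(object@maxArea - max(object@sliceArea[object@zSupport])) > 1e-9)
      msg <- c(msg, "maxArea must equal the maximum slice area over zSupport")
    if (any(object@sliceArea[object@zSupport] <= 0))
      msg <- c(msg, "zSupport must index slices with positive area")
  }
  if (length(msg)) msg else TRUE
})

#' LabelAtlas: an integer-labelled parcellation with a name table
#'
#' @slot labels integer-valued \linkS4class{VolumeGrid} (0 = background).
#' @slot names data.frame with columns `label_id`, `name`.
#' @slot atlasName single string naming the atlas.
#' @export
setClass("LabelAtlas",
         representation(labels = "VolumeGrid", names = "data.frame",
                        atlasName = "character"))

setValidity("LabelAtlas", function(object) {
  msg <- character()
  if (!all(c("label_id", "name") %in% names(object@names)))
    msg <- c(msg, "names table needs label_id and name columns")
  ids <- unique(as.vector(object@labels@data))
  ids <- ids[ids != 0]
  if (!all(ids %in% object@names$label_id))
    msg <- c(msg, "every nonzero label must have a name entry")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: all knobs of the synthetic lesion cohort
#'
#' Defaults describe the emulated study: ~50 subjects with blob-like lesions
#' concentrated in a striatocapsular hotspot on a 2 mm isotropic grid, walking
#' outcome generated as a linear function of overlap with a designated effect
#' region plus covariates and Gaussian noise, and ordinal FAC/MRMI outcomes
#' from a latent cumulative-logit model. See [simConfig()].
#'
#' @slot gridDims integer(3) voxel counts.
#' @slot voxelMm voxel edge length in mm (isotropic).
#' @slot nSubjects number of subjects.
#' @slot hotspotCentre numeric(3), 1-based voxel coordinate of the lesion
#'   hotspot.
#' @slot hotspotSdMm SD (mm) of the Gaussian scatter of lesion centres.
#' @slot lesionRadiusRange numeric(2), min/max lesion radius in mm.
#' @slot effectRegion integer matrix (m x 3) of 1-based voxel indices whose
#'   damage drives the behavioural effect.
#' @slot effectBeta walking-speed change (m/s) per mL of effect-region overlap
#'   (<= 0: damage hurts).
#' @slot walkIntercept intercept of the walking change model (m/s).
#' @slot baselineBeta,ageBeta,timeBeta covariate coefficients of the walking
#'   change model.
#' @slot noiseSd Gaussian noise SD of the walking change model (m/s).
#' @slot ordinalBeta latent logit-scale coefficient per mL of effect-region
#'   overlap shared by the FAC/MRMI generators (<= 0).
#' @slot ordinalBaselineBeta,ordinalAgeBeta latent-scale covariate
#'   coefficients of the ordinal generators.
#' @slot facCutpoints strictly increasing latent thresholds for FAC (5 values
#'   giving categories 0..5).
#' @slot mrmiCutpoints strictly increasing latent thresholds for MRMI (40
#'   values giving categories 0..40).
#' @slot seed integer master seed; per-subject substreams derive from it.
#' @export
setClass("SimulationConfig",
         representation(gridDims = "integer", voxelMm = "numeric",
                        nSubjects = "integer", hotspotCentre = "numeric",
                        hotspotSdMm = "numeric", lesionRadiusRange = "numeric",
                        effectRegion = "matrix", effectBeta = "numeric",
                        walkIntercept = "numeric", baselineBeta = "numeric",
                        ageBeta = "numeric", timeBeta = "numeric",
                        noiseSd = "numeric", ordinalBeta = "numeric",
                        ordinalBaselineBeta = "numeric",
                        ordinalAgeBeta = "numeric",
                        facCutpoints = "numeric", mrmiCutpoints = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (any(object@lesionRadiusRange <= 0) ||
      diff(object@lesionRadiusRange) < 0)
    msg <- c(msg, "lesionRadiusRange must be a positive increasing interval")
  if (is.unsorted(object@facCutpoints, strictly = TRUE))
    msg <- c(msg, "facCutpoints must be strictly increasing")
  if (is.unsorted(object@mrmiCutpoints, strictly = TRUE))
    msg <- c(msg, "mrmiCutpoints must be strictly increasing")
  er <- object@effectRegion
  if (ncol(er) != 3L) msg <- c(msg, "effectRegion must be an m x 3 matrix")
  else if (any(er < 1L) ||
           any(sweep(er, 2L, object@gridDims, ">")))
    msg <- c(msg, "effectRegion must lie inside gridDims")
  if (length(msg)) msg else TRUE
})

#' VlsmConfig: settings of a voxel-based lesion-symptom mapping run
#'
#' Defaults reproduce the canonical analysis plan: voxels lesioned in at least
#' 6 subjects, cluster-forming p < 0.005, 5000 permutations, corrected alpha
#' 0.05, 26-connectivity, one-sided damage-lowers-score testing, and nuisance
#' covariates age, Fazekas, time to baseline and the analysed measure's
#' baseline score. See [vlsmConfig()].
#'
#' @slot minLesioned minimum subjects lesioned at a voxel for it to be tested.
#' @slot pUncorrected cluster-forming uncorrected p threshold.
#' @slot nPermutations number of permutations for FWE correction.
#' @slot alphaCorrected corrected significance level.
#' @slot connectivity 6, 18 or 26 neighbourhood for cluster formation.
#' @slot direction "damage_lowers_score" (one-sided) or "two_sided".
#' @slot covariateNames nuisance covariate columns of the records table;
#'   the placeholder "baseline" resolves to the analysed measure's baseline.
#' @slot freedmanLane logical; permute residuals under the reduced model
#'   instead of raw behavioural rows.
#' @slot seed integer seed for the permutation stream.
#' @export
setClass("VlsmConfig",
         representation(minLesioned = "integer", pUncorrected = "numeric",
                        nPermutations = "integer", alphaCorrected = "numeric",
                        connectivity = "integer", direction = "character",
                        covariateNames = "character",
                        freedmanLane = "logical", seed = "integer"))

setValidity("VlsmConfig", function(object) {
  msg <- character()
  if (object@minLesioned < 2L) msg <- c(msg, "minLesioned must be >= 2")
  if (object@pUncorrected <= 0 || object@pUncorrected >= 1)
    msg <- c(msg, "pUncorrected must lie in (0, 1)")
  if (object@nPermutations < 100L)
    msg <- c(msg, "nPermutations must be >= 100")
  if (!object@connectivity %in% c(6L, 18L, 26L))
    msg <- c(msg, "connectivity must be 6, 18 or 26")
  if (!object@direction %in% c("damage_lowers_score", "two_sided"))
    msg <- c(msg, "direction must be damage_lowers_score or two_sided")
  if (length(msg)) msg else TRUE
})

#' TMap: a voxelwise t-statistic map over a search volume
#'
#' @slot t \linkS4class{VolumeGrid} of t values (NA outside the search volume
#'   and at inestimable voxels).
#' @slot df residual degrees of freedom of the voxelwise model.
#' @slot search logical 3-D array flagging tested (estimable) voxels.
#' @slot counts \linkS4class{VolumeGrid} of per-voxel lesion-overlap counts.
#' @export
setClass("TMap",
         representation(t = "VolumeGrid", df = "numeric", search = "array",
                        counts = "VolumeGrid"))

#' VlsmReport: the full result of one VLSM analysis
#'
#' @slot measure analysed measure ("walk", "fac" or "mrmi").
#' @slot config the \linkS4class{VlsmConfig} used.
#' @slot tmap the observed \linkS4class{TMap}.
#' @slot clusters data.frame, one row per supra-threshold cluster: size,
#'   volume (mL), peak t, peak/centre-of-mass mm coordinates, corrected p,
#'   significance flag.
#' @slot clusterVoxels list of m x 3 matrices of member voxel indices
#'   (1-based), parallel to `clusters`.
#' @slot permMax numeric, the permutation distribution of the search-volume
#'   maximum t.
#' @slot tThreshold cluster-forming t threshold actually applied.
#' @slot log provenance messages.
#' @export
setClass("VlsmReport",
         representation(measure = "character", config = "VlsmConfig",
                        tmap = "TMap", clusters = "data.frame",
                        clusterVoxels = "list", permMax = "numeric",
                        tThreshold = "numeric", log = "character"))

#' LoadResult: one subject's weighted tract lesion load
#'
#' @slot wcstLlCm3 the weighted load in cm^3 (NA when the lesion lies entirely
#'   outside the tract's axial support).
#' @slot perSlice data.frame with per-slice overlap, area, weight and weighted
#'   contribution.
#' @slot status "ok" or "outside_tract_support".
#' @export
setClass("LoadResult",
         representation(wcstLlCm3 = "numeric", perSlice = "data.frame",
                        status = "character"))
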