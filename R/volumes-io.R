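#' @include volume-grid.R
NULL

.behaviourCols <- c("subject_id", "side", "walk_baseline", "walk_outcome",
                    "fac_baseline", "fac_outcome", "mrmi_baseline",
                    "mrmi_outcome", "age", "fazekas", "time_days")

.readAffine <- function(img) {
  a <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(a) <- list(dim = dim(a))
  a
}

#' Read a NIfTI volume as a binary lesion mask
#'
#' Any nonzero voxel becomes 1 (delineation tools emit 0/1 or 0/255
#' interchangeably); a warning is raised when values outside \{0, 1\} are
#' binarized. 4-D inputs are rejected.
#'
#' @param path path to a 3-D NIfTI volume (.nii or .nii.gz)
#' @param reference optional \linkS4class{VolumeGrid}; dimensions and affine
#'   must match it to within 1e-6 mm
#' @return a binary \linkS4class{VolumeGrid}
#' @export
readMask <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("unsupported shape: expected a 3-D volume, got ",
         length(dim(img)), "-D: ", path)
  vals <- array(as.vector(img), dim(img))
  if (any(!vals %in% c(0, 1))) {
    warning("binarizing non-{0,1} values at > 0 in ", basename(path))
    vals <- (vals > 0) * 1
  }
  g <- volumeGrid(vals, affine = .readAffine(img))
  if (!is.null(reference)) .checkSameGrid(g, reference, "mask and reference")
  g
}

#' Read a NIfTI volume without binarization (t-maps, atlases, tracts)
#' @inheritParams readMask
#' @return a \linkS4class{VolumeGrid}
#' @export
readVolume <- function(path, reference = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("unsupported shape: expected a 3-D volume: ", path)
  g <- volumeGrid(array(as.vector(img), dim(img)), affine = .readAffine(img))
  if (!is.null(reference)) .checkSameGrid(g, reference, "volume and reference")
  g
}

#' Write a VolumeGrid as NIfTI
#'
#' @param grid a \linkS4class{VolumeGrid}
#' @param path output path (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeVolume <- function(grid, path) {
  pd <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(grid@data, pixdim = pd)
  RNifti::sform(img) <- structure(grid@affine, code = 2L)
  RNifti::qform(img) <- structure(grid@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label atlas (NIfTI + TSV name table)
#'
#' @param path integer-labelled NIfTI volume
#' @param namesPath TSV with columns label_id, name
#' @param atlasName display name of the atlas
#' @param reference optional grid to validate against
#' @return a \linkS4class{LabelAtlas}
#' @export
readLabelAtlas <- function(path, namesPath, atlasName = basename(path),
                           reference = NULL) {
  g <- readVolume(path, reference)
  g@data <- round(g@data)
  tab <- utils::read.delim(namesPath, stringsAsFactors = FALSE)
  new("LabelAtlas", labels = g, names = tab, atlasName = atlasName)
}

#' Read a canonical tract mask and derive its area profile
#'
#' @param path binary tract NIfTI
#' @param reference optional grid to validate against
#' @return a \linkS4class{TractMap}
#' @export
readTract <- function(path, reference = NULL) {
  tractMap(readMask(path, reference))
}

#' Load an aligned lesion cohort from a fixture/data directory
#'
#' Joins one mask file per behavioural row on `subject_id` (mask files are
#' `<subject_id>.nii.gz` or `.nii` under `maskDir`). Right-sided lesions are
#' flipped onto the left hemisphere. Rows without a mask, masks without a row,
#' and subjects with missing outcome scores are excluded with a provenance log
#' entry rather than an error.
#'
#' @param maskDir directory of per-subject mask volumes
#' @param behaviourTable CSV with the required headers (subject_id, side,
#'   walk/fac/mrmi baseline and outcome, age, fazekas, time_days)
#' @param flip flip right-sided masks to the left (default TRUE)
#' @return a \linkS4class{LesionCohort}; the exclusion log is in `@log`
#' @export
loadCohort <- function(maskDir, behaviourTable, flip = TRUE) {
  tab <- utils::read.csv(behaviourTable, stringsAsFactors = FALSE)
  missingCols <- setdiff(.behaviourCols, names(tab))
  if (length(missingCols))
    stop("behaviour table lacks required columns: ",
         paste(missingCols, collapse = ", "))
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in behaviour table")
  log <- character()

  outcomeCols <- c("walk_outcome", "fac_outcome", "mrmi_outcome")
  bad <- !stats::complete.cases(tab[outcomeCols])
  if (any(bad)) {
    log <- c(log, paste0("excluded (missing outcome): ",
                         tab$subject_id[bad]))
    warning(sum(bad), " subject(s) excluded for missing outcome scores")
    tab <- tab[!bad, , drop = FALSE]
  }

  maskPath <- function(id) {
    for (ext in c(".nii.gz", ".nii")) {
      p <- file.path(maskDir, paste0(id, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }
  paths <- vapply(tab$subject_id, maskPath, character(1))
  if (any(is.na(paths))) {
    log <- c(log, paste0("excluded (missing mask): ",
                         tab$subject_id[is.na(paths)]))
    warning(sum(is.na(paths)), " subject(s) excluded for missing masks")
    tab <- tab[!is.na(paths), , drop = FALSE]
    paths <- paths[!is.na(paths)]
  }
  allMasks <- list.files(maskDir, pattern = "\\.nii(\\.gz)?$")
  orphan <- setdiff(sub("\\.nii(\\.gz)?$", "", allMasks), tab$subject_id)
  if (length(orphan))
    log <- c(log, paste0("unmatched mask (no behavioural row): ", orphan))
  if (nrow(tab) == 0L) stop("no subjects left after exclusions")

  ref <- NULL
  msk <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    m <- readMask(paths[i], ref)
    if (is.null(ref)) ref <- m
    if (flip && tab$side[i] == "right") m <- flipToLeft(m, "right")
    msk[[i]] <- m
  }
  names(msk) <- tab$subject_id
  lesionCohort(msk, tab, log = log)
}

#' Assemble a LesionCohort from masks and a behavioural table
#'
#' Computes change scores (outcome - baseline per measure) and lesion volumes,
#' and validates alignment.
#'
#' @param masks named list of binary \linkS4class{VolumeGrid}, one per subject
#' @param records behavioural data.frame with the required headers
#' @param log optional provenance messages to carry along
#' @return a \linkS4class{LesionCohort}
#' @export
lesionCohort <- function(masks, records, log = character()) {
  records$walk_change <- records$walk_outcome - records$walk_baseline
  records$fac_change <- records$fac_outcome - records$fac_baseline
  records$mrmi_change <- records$mrmi_outcome - records$mrmi_baseline
  if (length(masks)) {
    vv <- voxelVolume(masks[[1L]])
    records$lesion_volume_cm3 <-
      vapply(masks, function(m) sum(m@data) * vv / 1000, numeric(1))[
        seq_along(masks)]
  }
  rownames(records) <- NULL
  new("LesionCohort", masks = masks, records = records, log = log)
}

#' @describeIn lesionCohort number of subjects
#' @param x a LesionCohort
#' @export
setMethod("nSubjects", "LesionCohort", function(x) length(x@masks))

#' @describeIn lesionCohort the behavioural records table
#' @export
setMethod("records", "LesionCohort", function(x) x@records)

#' @describeIn lesionCohort the named list of masks
#' @export
setMethod("masks", "LesionCohort", function(x) x@masks)

#' @describeIn lesionCohort grid dimensions shared by all masks
#' @export
setMethod("gridDims", "LesionCohort",
          function(x) gridDims(x@masks[[1L]]))

#' @describeIn lesionCohort shared voxel-to-world affine
#' @export
setMethod("worldAffine", "LesionCohort",
          function(x) worldAffine(x@masks[[1L]]))

#' @describeIn lesionCohort voxel volume in mm^3
#' @export
setMethod("voxelVolume", "LesionCohort",
          function(x) voxelVolume(x@masks[[1L]]))

setMethod("show", "LesionCohort", function(object) {
  d <- gridDims(object)
  cat(sprintf("LesionCohort: %d subjects on a %d x %d x %d grid (%.3g mm^3/voxel)\n",
              nSubjects(object), d[1], d[2], d[3], voxelVolume(object)))
  if (length(object@log))
    cat("  provenance:", length(object@log), "logged event(s)\n")
})

#' Subset a cohort by subject
#'
#' @param x a \linkS4class{LesionCohort}
#' @param i subject indices (integer or logical)
#' @param j,drop,... unused
#' @return the subset \linkS4class{LesionCohort}
#' @export
setMethod("[", "LesionCohort", function(x, i, j, ..., drop = FALSE) {
  new("LesionCohort", masks = x@masks[i],
      records = x@records[i, , drop = FALSE], log = x@log)
})
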