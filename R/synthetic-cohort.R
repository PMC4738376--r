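#' @include volumes-io.R tract-load.R
NULL

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate the study conditions the package is designed for: ~50
#' subjects on a 32^3 grid of 2 mm isotropic voxels (the grid is symmetric
#' about x = 0 mm), blob-like lesions whose centres scatter around a
#' striatocapsular hotspot in the left hemisphere so that the maximum
#' per-voxel overlap is around 24 of 50, a walking-speed change score that is
#' a linear function of lesion overlap with a designated effect region plus
#' age/time/baseline covariates and Gaussian noise, and ordinal FAC (0-5) and
#' MRMI (0-40) outcomes from latent cumulative-logit models sharing the same
#' lesion effect.
#'
#' @param gridDims integer(3); default c(32, 32, 32)
#' @param voxelMm voxel edge (mm); default 2
#' @param nSubjects default 50
#' @param hotspotCentre 1-based voxel coordinate of the lesion hotspot;
#'   default c(9, 16, 15) (left striatocapsular territory)
#' @param hotspotSdMm scatter of lesion centres (mm); default 7
#' @param lesionRadiusRange lesion radius interval (mm); default c(5, 14)
#' @param effectRegion m x 3 matrix of voxel indices; default a
#'   5 x 5 x 6-voxel block around the hotspot straddling two atlas labels
#' @param effectBeta walking change (m/s) per mL overlap; default -0.35
#' @param walkIntercept default 0.65 m/s
#' @param baselineBeta default -0.2
#' @param ageBeta default -0.003 per year
#' @param timeBeta default -0.002 per day
#' @param noiseSd default 0.08 m/s
#' @param ordinalBeta latent logit per mL overlap; default -2
#' @param ordinalBaselineBeta default 1
#' @param ordinalAgeBeta default -0.04 per year
#' @param facCutpoints default c(-6, -4.5, -3, -1.5, 0)
#' @param mrmiCutpoints default seq(0.5, 39.5) - 8
#' @param seed master seed; default 42
#' @return a \linkS4class{SimulationConfig}
#' @export
simConfig <- function(gridDims = c(32L, 32L, 32L), voxelMm = 2,
                      nSubjects = 50L,
                      hotspotCentre = c(9, 16, 15), hotspotSdMm = 7,
                      lesionRadiusRange = c(5, 14),
                      effectRegion = NULL,
                      effectBeta = -0.35, walkIntercept = 0.65,
                      baselineBeta = -0.2, ageBeta = -0.003,
                      timeBeta = -0.002, noiseSd = 0.08,
                      ordinalBeta = -2, ordinalBaselineBeta = 1,
                      ordinalAgeBeta = -0.04,
                      facCutpoints = c(-6, -4.5, -3, -1.5, 0),
                      mrmiCutpoints = seq(0.5, 39.5, by = 1) - 8,
                      seed = 42L) {
  if (is.null(effectRegion))
    effectRegion <- as.matrix(expand.grid(i = 7:11, j = 14:18, k = 12:17))
  dimnames(effectRegion) <- NULL
  storage.mode(effectRegion) <- "integer"
  new("SimulationConfig", gridDims = as.integer(gridDims),
      voxelMm = voxelMm, nSubjects = as.integer(nSubjects),
      hotspotCentre = as.numeric(hotspotCentre), hotspotSdMm = hotspotSdMm,
      lesionRadiusRange = as.numeric(lesionRadiusRange),
      effectRegion = effectRegion, effectBeta = effectBeta,
      walkIntercept = walkIntercept, baselineBeta = baselineBeta,
      ageBeta = ageBeta, timeBeta = timeBeta, noiseSd = noiseSd,
      ordinalBeta = ordinalBeta, ordinalBaselineBeta = ordinalBaselineBeta,
      ordinalAgeBeta = ordinalAgeBeta, facCutpoints = facCutpoints,
      mrmiCutpoints = as.numeric(mrmiCutpoints), seed = as.integer(seed))
}

# reference grid of a configuration (empty, symmetric about the origin)
.configGrid <- function(config) {
  volumeGrid(array(0, config@gridDims), voxelMm = config@voxelMm)
}

# deterministic per-subject substream seed; adding subject n+1 never
# perturbs subjects 1..n
.subSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * i) %% 2147483629)
}

#' Generate the canonical synthetic tract
#'
#' A binary vertical tube spanning the full z-range whose radius is wide at
#' the top, narrowest mid-course and intermediate at the bottom — mimicking a
#' corticospinal tract funnelling from a broad cortical origin into the
#' posterior limb of the internal capsule — so that the slice weighting
#' `A_max / A(z)` in the weighted lesion load is non-trivial.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param radiusProfileMm optional numeric of per-slice radii (mm), length
#'   `gridDims[3]`; overrides the default funnel profile. A constant profile
#'   gives the degenerate all-weights-1 tract.
#' @return a \linkS4class{TractMap}
#' @export
makeTract <- function(config, radiusProfileMm = NULL) {
  d <- config@gridDims
  nz <- d[3L]
  if (is.null(radiusProfileMm)) {
    kNarrow <- round(0.45 * nz)
    z <- seq_len(nz)
    radiusProfileMm <- ifelse(
      z >= kNarrow,
      3 + 4.5 * ((z - kNarrow) / (nz - kNarrow))^2,
      3 + 1.5 * ((kNarrow - z) / max(kNarrow - 1, 1))^2)
  }
  stopifnot(length(radiusProfileMm) == nz)
  grid <- .configGrid(config)
  centre <- config@hotspotCentre[1:2] + c(1.0, 0.5)  # just lateral of hotspot
  xi <- (seq_len(d[1L]) - centre[1L]) * config@voxelMm
  yj <- (seq_len(d[2L]) - centre[2L]) * config@voxelMm
  dist2 <- outer(xi^2, yj^2, "+")
  arr <- array(0, d)
  for (k in seq_len(nz))
    arr[, , k] <- (dist2 <= radiusProfileMm[k]^2) * 1
  grid@data <- arr
  tractMap(grid)
}

# carve one blob lesion: voxelized sphere with radial boundary jitter
.carveLesion <- function(d, voxelMm, centreVox, radiusMm, jitterFrac = 0.12) {
  rVox <- radiusMm / voxelMm
  lo <- pmax(1L, floor(centreVox - rVox - 1))
  hi <- pmin(d, ceiling(centreVox + rVox + 1))
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  dist <- sqrt(colSums((t(box) - centreVox)^2)) * voxelMm
  eps <- stats::runif(nrow(box), -1, 1)
  inside <- dist <= radiusMm * (1 + jitterFrac * eps)
  sel <- box[inside, , drop = FALSE]
  if (nrow(sel) == 0L)  # guarantee at least the (clamped) centre voxel
    sel <- rbind(pmin(pmax(round(centreVox), 1L), d))
  arr <- array(0, d)
  arr[sel] <- 1
  arr
}

# overlap (in mL) of a mask array with the configured effect region
.effectOverlapMl <- function(arr, config) {
  vv <- config@voxelMm^3
  sum(arr[config@effectRegion]) * vv / 1000
}

.drawCovariates <- function() {
  list(age = round(stats::runif(1, 35, 90), 1),
       fazekas = sample(0:3, 1, prob = c(0.3, 0.35, 0.25, 0.1)),
       time_days = round(stats::runif(1, 7, 42)),
       walk_baseline = round(stats::runif(1, 0.05, 1.0), 3),
       fac_baseline = sample(0:3, 1, prob = c(0.4, 0.3, 0.2, 0.1)),
       mrmi_baseline = sample(5:35, 1),
       side = sample(c("left", "right"), 1))
}

#' Generate a synthetic lesion cohort with known ground truth
#'
#' Per subject (each on its own seed substream): a lesion centre is drawn from
#' a 3-D Gaussian around the hotspot, a blob lesion carved, covariates drawn,
#' and behavioural scores generated.
#'
#' Walking change is
#' `walkIntercept + effectBeta * overlap_mL + baselineBeta * baseline +
#' ageBeta * age + timeBeta * time + N(0, noiseSd)`, truncated so the outcome
#' speed is non-negative. FAC and MRMI outcomes threshold latent responses
#' `ordinalBeta * overlap_mL + ordinalBaselineBeta * baseline +
#' ordinalAgeBeta * age + Logistic(0, 1)` at the configured cutpoints, which
#' makes proportional-odds recovery testable by construction.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return list with elements `cohort` (\linkS4class{LesionCohort}) and
#'   `truth` (per-subject effect-region overlap in mL, the configured
#'   coefficients, and the effect region's centre of mass in mm)
#' @export
makeCohort <- function(config) {
  d <- config@gridDims
  grid <- .configGrid(config)
  hotspotMm <- voxelToWorld(grid, config@hotspotCentre)
  n <- config@nSubjects
  maskList <- vector("list", n)
  rows <- vector("list", n)
  overlapMl <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.subSeed(config@seed, i))
    cv <- .drawCovariates()
    centreMm <- drop(hotspotMm) + stats::rnorm(3) * config@hotspotSdMm
    centreVox <- drop(worldToVoxel(grid, centreMm))
    centreVox <- pmin(pmax(centreVox, 2), d - 1)
    radius <- stats::runif(1, config@lesionRadiusRange[1L],
                           config@lesionRadiusRange[2L])
    arr <- .carveLesion(d, config@voxelMm, centreVox, radius)
    ov <- .effectOverlapMl(arr, config)
    overlapMl[i] <- ov

    walkChange <- config@walkIntercept + config@effectBeta * ov +
      config@baselineBeta * cv$walk_baseline + config@ageBeta * cv$age +
      config@timeBeta * cv$time_days + stats::rnorm(1, 0, config@noiseSd)
    walkOutcome <- max(0, cv$walk_baseline + walkChange)

    latFac <- config@ordinalBeta * ov +
      config@ordinalBaselineBeta * cv$fac_baseline +
      config@ordinalAgeBeta * cv$age + stats::rlogis(1)
    facOutcome <- sum(latFac > config@facCutpoints)

    latMrmi <- config@ordinalBeta * ov +
      config@ordinalBaselineBeta * cv$mrmi_baseline +
      config@ordinalAgeBeta * cv$age + stats::rlogis(1)
    mrmiOutcome <- sum(latMrmi > config@mrmiCutpoints)

    m <- grid
    m@data <- arr
    maskList[[i]] <- m
    rows[[i]] <- data.frame(
      subject_id = sprintf("sub%03d", i), side = cv$side,
      walk_baseline = cv$walk_baseline,
      walk_outcome = walkOutcome,
      fac_baseline = cv$fac_baseline, fac_outcome = facOutcome,
      mrmi_baseline = cv$mrmi_baseline, mrmi_outcome = mrmiOutcome,
      age = cv$age, fazekas = cv$fazekas, time_days = cv$time_days,
      stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, rows)
  names(maskList) <- recs$subject_id
  cohort <- lesionCohort(maskList, recs)
  if (all(overlapMl == 0))
    warning("configuration: effect region has zero overlap with every lesion")
  erMm <- voxelToWorld(grid, config@effectRegion)
  truth <- list(
    overlap_ml = stats::setNames(overlapMl, recs$subject_id),
    coefficients = c(walk_intercept = config@walkIntercept,
                     effect_beta = config@effectBeta,
                     baseline_beta = config@baselineBeta,
                     age_beta = config@ageBeta, time_beta = config@timeBeta,
                     noise_sd = config@noiseSd,
                     ordinal_beta = config@ordinalBeta,
                     ordinal_baseline_beta = config@ordinalBaselineBeta,
                     ordinal_age_beta = config@ordinalAgeBeta),
    effect_centre_mm = colMeans(erMm))
  list(cohort = cohort, truth = truth)
}

#' Generate a null cohort (identical lesions, no lesion-behaviour link)
#'
#' Same lesion geometry and covariates as [makeCohort()] under the same seed,
#' but with the lesion effect coefficients forced to zero, so behavioural
#' scores are exchangeable with respect to lesion location. Used for
#' family-wise-error calibration.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{LesionCohort}
#' @export
makeNullCohort <- function(config) {
  config@effectBeta <- 0
  config@ordinalBeta <- 0
  makeCohort(config)$cohort
}

#' Generate the synthetic quadrant label atlas
#'
#' Tiles the grid into four named rectangular parcels (left/right x
#' anterior/posterior), so every voxel carries exactly one label and the
#' default effect region straddles the two left-hemisphere parcels — which
#' makes percent-overlap reporting non-trivial.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @return a \linkS4class{LabelAtlas}
#' @export
makeLabelAtlas <- function(config) {
  d <- config@gridDims
  xSplit <- ceiling(d[1L] / 2)
  ySplit <- ceiling(d[2L] / 2)
  arr <- array(0L, d)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  lab <- 1L + (idx[, 1] > xSplit) * 2L + (idx[, 2] > ySplit) * 1L
  arr[idx] <- lab
  grid <- .configGrid(config)
  grid@data <- arr
  nm <- data.frame(
    label_id = 1:4,
    name = c("left striatocapsular / insular complex",
             "left frontal white matter",
             "right striatocapsular / insular complex",
             "right frontal white matter"),
    stringsAsFactors = FALSE)
  new("LabelAtlas", labels = grid, names = nm,
      atlasName = "synthetic quadrant atlas")
}

#' Write a complete synthetic fixture directory
#'
#' Writes `masks/<subject_id>.nii.gz` (right-sided subjects are mirrored back
#' to the right hemisphere so that [loadCohort()] exercises its flipping),
#' `tract.nii.gz`, `atlas.nii.gz` + `atlas_names.tsv`, `behaviour.csv`,
#' `truth.json` and `config.yaml`.
#'
#' @param config a \linkS4class{SimulationConfig}
#' @param dir output directory (created if absent)
#' @return the directory path, invisibly
#' @export
writeCohortFixture <- function(config, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  sim <- makeCohort(config)
  cohort <- sim$cohort
  recs <- records(cohort)
  for (i in seq_len(nSubjects(cohort))) {
    m <- cohort@masks[[i]]
    if (recs$side[i] == "right") m <- flipToLeft(m, "right")  # mirror back out
    writeVolume(m, file.path(dir, "masks",
                             paste0(recs$subject_id[i], ".nii.gz")))
  }
  tract <- makeTract(config)
  writeVolume(tract@mask, file.path(dir, "tract.nii.gz"))
  atlas <- makeLabelAtlas(config)
  writeVolume(atlas@labels, file.path(dir, "atlas.nii.gz"))
  utils::write.table(atlas@names, file.path(dir, "atlas_names.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(recs[, .behaviourCols], file.path(dir, "behaviour.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(configAsList(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialize a SimulationConfig to a plain list (for YAML round-trips)
#' @param config a \linkS4class{SimulationConfig}
#' @return named list
#' @export
configAsList <- function(config) {
  sl <- slotNames(config)
  out <- lapply(sl, function(s) {
    v <- slot(config, s)
    if (is.matrix(v)) as.data.frame(v) else v
  })
  names(out) <- sl
  out
}

#' Rebuild a SimulationConfig from a list (e.g. read from config.yaml)
#' @param lst named list as produced by [configAsList()]
#' @return a \linkS4class{SimulationConfig}
#' @export
configFromList <- function(lst) {
  er <- as.matrix(as.data.frame(lst$effectRegion))
  dimnames(er) <- NULL
  storage.mode(er) <- "integer"
  simConfig(gridDims = lst$gridDims, voxelMm = lst$voxelMm,
            nSubjects = lst$nSubjects, hotspotCentre = lst$hotspotCentre,
            hotspotSdMm = lst$hotspotSdMm,
            lesionRadiusRange = lst$lesionRadiusRange, effectRegion = er,
            effectBeta = lst$effectBeta, walkIntercept = lst$walkIntercept,
            baselineBeta = lst$baselineBeta, ageBeta = lst$ageBeta,
            timeBeta = lst$timeBeta, noiseSd = lst$noiseSd,
            ordinalBeta = lst$ordinalBeta,
            ordinalBaselineBeta = lst$ordinalBaselineBeta,
            ordinalAgeBeta = lst$ordinalAgeBeta,
            facCutpoints = lst$facCutpoints,
            mrmiCutpoints = lst$mrmiCutpoints, seed = lst$seed)
}
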