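#' @include volumes-io.R
NULL

#' Build a VLSM configuration
#'
#' Defaults are the canonical analysis settings: test only voxels lesioned in
#' at least 6 subjects, form clusters at uncorrected p < 0.005, correct the
#' cluster peak t by 5000 permutations at corrected alpha 0.05, label
#' connected components with the 26-neighbourhood, test one-sided in the
#' damage-lowers-score direction, and adjust for age, Fazekas score, time to
#' baseline and the analysed measure's baseline score.
#'
#' @param minLesioned default 6
#' @param pUncorrected default 0.005
#' @param nPermutations default 5000
#' @param alphaCorrected default 0.05
#' @param connectivity 6, 18 or 26 (default 26)
#' @param direction "damage_lowers_score" (default) or "two_sided"
#' @param covariateNames default c("age", "fazekas", "time_days", "baseline");
#'   "baseline" resolves to `<measure>_baseline`
#' @param freedmanLane permute reduced-model residuals instead of raw
#'   behavioural rows (default FALSE: rows, i.e. score and covariates jointly,
#'   are shuffled against the masks)
#' @param seed permutation seed (default 1)
#' @return a \linkS4class{VlsmConfig}
#' @export
vlsmConfig <- function(minLesioned = 6L, pUncorrected = 0.005,
                       nPermutations = 5000L, alphaCorrected = 0.05,
                       connectivity = 26L,
                       direction = c("damage_lowers_score", "two_sided"),
                       covariateNames = c("age", "fazekas", "time_days",
                                          "baseline"),
                       freedmanLane = FALSE, seed = 1L) {
  direction <- match.arg(direction)
  new("VlsmConfig", minLesioned = as.integer(minLesioned),
      pUncorrected = pUncorrected, nPermutations = as.integer(nPermutations),
      alphaCorrected = alphaCorrected, connectivity = as.integer(connectivity),
      direction = direction, covariateNames = covariateNames,
      freedmanLane = freedmanLane, seed = as.integer(seed))
}

#' Search volume: voxels with enough lesioned and spared subjects
#'
#' A voxel enters the search volume when it is lesioned in at least
#' `minLesioned` subjects and spared in at least 2 (a voxel lesioned in every
#' subject has no comparison group). Also returns the raw per-voxel
#' lesion-overlap count map.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param minLesioned minimum lesioned-subject count (default 6)
#' @return list with `search` (logical 3-D array), `counts`
#'   (\linkS4class{VolumeGrid} of overlap counts) and `nSearch`
#' @export
buildSearchVolume <- function(cohort, minLesioned = 6L) {
  n <- nSubjects(cohort)
  d <- gridDims(cohort)
  counts <- array(0, d)
  for (m in cohort@masks) counts <- counts + m@data
  search <- counts >= minLesioned & (n - counts) >= 2
  cg <- cohort@masks[[1L]]
  cg@data <- counts
  list(search = search, counts = cg, nSearch = sum(search))
}

# precompute the covariate-model pieces shared by all voxels and permutations
.tPrep <- function(y, C) {
  n <- length(y)
  k <- ncol(C)
  qrC <- qr(C)
  if (qrC$rank < k) stop("covariate design matrix is rank deficient")
  resY <- qr.resid(qrC, y)
  list(C = C, qrC = qrC, resY = resY, yMy = sum(resY^2),
       G = chol2inv(chol(crossprod(C))), n = n, k = k, df = n - k - 1)
}

# voxelwise covariate-adjusted t for a whole lesion matrix at once.
# For voxel v with lesion indicator L_v, the model is
#   score = b0 + bL * L_v + covariates + e;
# with M the covariate-projection residual maker, the coefficient and its t
# follow from L'My and L'ML (Frisch-Waugh). Sign is flipped so positive t
# means lesioned subjects score LOWER after adjustment ("damage hurts").
.tCore <- function(prep, L) {
  CL <- crossprod(prep$C, L)
  lml <- colSums(L * L) - colSums(CL * (prep$G %*% CL))
  lmy <- drop(crossprod(L, prep$resY))
  ok <- lml > 1e-8
  beta <- ifelse(ok, lmy / lml, NA_real_)
  rss <- prep$yMy - ifelse(ok, lmy^2 / lml, 0)
  ok <- ok & rss > max(prep$yMy, 1) * 1e-12
  tval <- ifelse(ok, -beta / sqrt(rss / prep$df / lml), NA_real_)
  list(t = tval, estimable = ok)
}

#' Covariate-adjusted voxel t statistic
#'
#' Fits `score ~ lesion + covariates` by least squares at one voxel and
#' returns the lesion coefficient's t statistic with the sign convention that
#' positive t means lesioned subjects have lower adjusted scores. With no
#' covariates this equals the pooled-variance two-sample t statistic.
#'
#' @param scores per-subject numeric scores
#' @param lesionStatus per-subject 0/1 lesion indicator
#' @param covariates optional data.frame/matrix of nuisance covariates
#' @return list with `t`, `df` and `estimable`
#' @export
voxelT <- function(scores, lesionStatus, covariates = NULL) {
  if (sum(lesionStatus == 1) < 2 || sum(lesionStatus == 0) < 2)
    stop("need at least 2 subjects in each lesion group")
  C <- cbind(intercept = rep(1, length(scores)))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))
  prep <- .tPrep(scores, C)
  core <- .tCore(prep, matrix(as.numeric(lesionStatus), ncol = 1))
  list(t = core$t[1L], df = prep$df, estimable = core$estimable[1L])
}

# resolve covariate names for a measure and assemble the design pieces
.vlsmDesign <- function(cohort, measure, config) {
  recs <- records(cohort)
  y <- recs[[paste0(measure, "_change")]]
  covNames <- sub("^baseline$", paste0(measure, "_baseline"),
                  config@covariateNames)
  C <- cbind(intercept = rep(1, nrow(recs)))
  if (length(covNames))
    C <- cbind(C, as.matrix(recs[, covNames, drop = FALSE]))
  list(y = y, C = C, covNames = covNames)
}

#' Compute the voxelwise t-map for one measure
#'
#' Applies the covariate-adjusted voxel model at every search-volume voxel,
#' using the measure's change score as response (FAC and MRMI change scores
#' are treated as numeric here). Voxels where the model is inestimable are
#' removed from the search volume with a log entry.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param measure "walk", "fac" or "mrmi"
#' @param config a \linkS4class{VlsmConfig}
#' @return a \linkS4class{TMap}
#' @export
computeTMap <- function(cohort, measure = c("walk", "fac", "mrmi"),
                        config = vlsmConfig()) {
  measure <- match.arg(measure)
  sv <- buildSearchVolume(cohort, config@minLesioned)
  des <- .vlsmDesign(cohort, measure, config)
  d <- gridDims(cohort)
  tArr <- array(NA_real_, d)
  search <- sv$search
  if (sv$nSearch > 0L) {
    L <- lesionMatrix(cohort)[, which(search), drop = FALSE]
    prep <- .tPrep(des$y, des$C)
    core <- .tCore(prep, L)
    tArr[which(search)] <- core$t
    if (any(!core$estimable)) {
      bad <- which(search)[!core$estimable]
      search[bad] <- FALSE
    }
    df <- prep$df
  } else {
    df <- nrow(records(cohort)) - ncol(des$C) - 1
  }
  tg <- cohort@masks[[1L]]
  tg@data <- tArr
  new("TMap", t = tg, df = as.numeric(df), search = search,
      counts = sv$counts)
}

# neighbourhood offsets for 6/18/26-connectivity
.connOffsets <- function(connectivity) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(off != 0)
  keep <- switch(as.character(connectivity),
                 "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1)
  off[keep, , drop = FALSE]
}

# label connected components of a logical 3-D array; returns an integer array
.labelComponents <- function(arr, connectivity = 26L) {
  d <- dim(arr)
  lab <- array(0L, d)
  idx <- which(arr)
  if (!length(idx)) return(lab)
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  off <- .connOffsets(connectivity)
  compOf <- integer(length(idx))
  comp <- 0L
  for (s in seq_along(idx)) {
    if (compOf[s] != 0L) next
    comp <- comp + 1L
    frontier <- s
    compOf[s] <- comp
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nb <- fc[rep(seq_len(nrow(fc)), each = nrow(off)), , drop = FALSE] +
        off[rep(seq_len(nrow(off)), times = nrow(fc)), , drop = FALSE]
      keep <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[keep, , drop = FALSE]
      ids <- unique(pos[nb])
      ids <- ids[ids != 0L]
      ids <- ids[compOf[ids] == 0L]
      compOf[ids] <- comp
      frontier <- ids
    }
  }
  lab[idx] <- compOf
  lab
}

# cluster-forming t threshold from the uncorrected p
.tThreshold <- function(config, df) {
  if (config@direction == "two_sided")
    stats::qt(1 - config@pUncorrected / 2, df)
  else
    stats::qt(1 - config@pUncorrected, df)
}

#' Form candidate clusters from a t-map
#'
#' Converts the cluster-forming uncorrected p to a Student-t cutoff at the
#' map's degrees of freedom (one-sided in the configured direction, or on |t|
#' when two-sided), then labels connected supra-threshold components at the
#' configured connectivity. Each component is reported with its size, peak t,
#' peak coordinate, and (unweighted) centre of mass in mm.
#'
#' @param tmap a \linkS4class{TMap}
#' @param config a \linkS4class{VlsmConfig}
#' @return list with `clusters` (data.frame, possibly 0 rows), `voxels` (list
#'   of m x 3 member index matrices) and `tThreshold`
#' @export
formClusters <- function(tmap, config = vlsmConfig()) {
  thr <- .tThreshold(config, tmap@df)
  tArr <- tmap@t@data
  stat <- if (config@direction == "two_sided") abs(tArr) else tArr
  supra <- !is.na(stat) & stat > thr & tmap@search
  lab <- .labelComponents(supra, config@connectivity)
  empty <- data.frame(cluster_id = integer(), size_voxels = integer(),
                      size_ml = numeric(), peak_t = numeric(),
                      peak_x_mm = numeric(), peak_y_mm = numeric(),
                      peak_z_mm = numeric(), com_x_mm = numeric(),
                      com_y_mm = numeric(), com_z_mm = numeric())
  if (!any(supra))
    return(list(clusters = empty, voxels = list(), tThreshold = thr))
  ncomp <- max(lab)
  rows <- vector("list", ncomp)
  voxList <- vector("list", ncomp)
  for (cid in seq_len(ncomp)) {
    vox <- arrayInd(which(lab == cid), dim(lab))
    tv <- stat[vox]
    mm <- voxelToWorld(tmap@t, vox)
    peak <- which.max(tv)
    rows[[cid]] <- data.frame(
      cluster_id = cid, size_voxels = nrow(vox),
      size_ml = voxelsToMl(nrow(vox), tmap@t),
      peak_t = tv[peak],
      peak_x_mm = mm[peak, 1], peak_y_mm = mm[peak, 2],
      peak_z_mm = mm[peak, 3],
      com_x_mm = mean(mm[, 1]), com_y_mm = mean(mm[, 2]),
      com_z_mm = mean(mm[, 3]))
    voxList[[cid]] <- vox
  }
  cl <- do.call(rbind, rows)
  ord <- order(-cl$peak_t)
  cl <- cl[ord, , drop = FALSE]
  cl$cluster_id <- seq_len(nrow(cl))
  rownames(cl) <- NULL
  list(clusters = cl, voxels = voxList[ord], tThreshold = thr)
}

# permutation distribution of the search-volume maximum t.
# Shuffling behavioural rows (score + covariates jointly) against the fixed
# masks is implemented as applying the inverse shuffle to the rows of the
# lesion matrix, which leaves the covariate projection fixed.
.permMaxT <- function(L, y, C, config, search = NULL) {
  prep <- .tPrep(y, C)
  n <- length(y)
  B <- config@nPermutations
  twoSided <- config@direction == "two_sided"
  out <- numeric(B)
  useFL <- isTRUE(config@freedmanLane)
  fitted0 <- if (useFL) qr.fitted(prep$qrC, y) else NULL
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    if (useFL) {
      yStar <- fitted0 + prep$resY[perm]
      prepB <- .tPrep(yStar, C)
      core <- .tCore(prepB, L)
    } else {
      core <- .tCore(prep, L[perm, , drop = FALSE])
    }
    tv <- core$t[core$estimable]
    if (!length(tv)) { out[b] <- -Inf; next }
    out[b] <- if (twoSided) max(abs(tv)) else max(tv)
  }
  out
}

#' Permutation FWE correction of candidate clusters
#'
#' Permutes the assignment of behavioural rows (score and covariates together)
#' to lesion masks `nPermutations` times, recording each permutation's maximum
#' t over the fixed search volume. A cluster with observed peak t* gets
#' corrected p = (1 + #\{permutation max >= t*\}) / (nPermutations + 1);
#' clusters with corrected p below `alphaCorrected` are flagged significant.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param measure "walk", "fac" or "mrmi"
#' @param config a \linkS4class{VlsmConfig}
#' @param candidates result of [formClusters()]
#' @param tmap the observed \linkS4class{TMap} (defines the search volume)
#' @return list with `clusters` (data.frame gaining p_corrected and
#'   significant columns) and `permMax` (the null max-t sample)
#' @export
permutationCorrect <- function(cohort, measure, config, candidates, tmap) {
  des <- .vlsmDesign(cohort, measure, config)
  L <- lesionMatrix(cohort)[, which(tmap@search), drop = FALSE]
  set.seed(config@seed)
  permMax <- .permMaxT(L, des$y, des$C, config)
  cl <- candidates$clusters
  if (nrow(cl)) {
    cl$p_corrected <- vapply(cl$peak_t, function(tstar)
      (1 + sum(permMax >= tstar)) / (config@nPermutations + 1), numeric(1))
    cl$significant <- cl$p_corrected < config@alphaCorrected
  } else {
    cl$p_corrected <- numeric(0)
    cl$significant <- logical(0)
  }
  list(clusters = cl, permMax = permMax)
}

#' Run a complete VLSM analysis for one measure
#'
#' Orchestrates search-volume construction, the voxelwise covariate-adjusted
#' t-map, cluster formation at the uncorrected threshold, and max-statistic
#' permutation FWE correction. Deterministic given the config seed.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param measure "walk", "fac" or "mrmi"
#' @param config a \linkS4class{VlsmConfig}
#' @return a \linkS4class{VlsmReport}
#' @export
runVlsm <- function(cohort, measure = c("walk", "fac", "mrmi"),
                    config = vlsmConfig()) {
  measure <- match.arg(measure)
  log <- character()
  tmap <- computeTMap(cohort, measure, config)
  if (sum(tmap@search) == 0L) {
    log <- c(log, "empty search volume: no voxel meets the overlap criteria")
    return(new("VlsmReport", measure = measure, config = config, tmap = tmap,
               clusters = data.frame(), clusterVoxels = list(),
               permMax = numeric(), tThreshold = NA_real_, log = log))
  }
  cand <- formClusters(tmap, config)
  corr <- permutationCorrect(cohort, measure, config, cand, tmap)
  log <- c(log, sprintf("search volume: %d voxels; df = %d; t threshold %.3f",
                        sum(tmap@search), as.integer(tmap@df),
                        cand$tThreshold),
           sprintf("%d candidate cluster(s), %d significant at alpha %.3g",
                   nrow(corr$clusters), sum(corr$clusters$significant),
                   config@alphaCorrected))
  new("VlsmReport", measure = measure, config = config, tmap = tmap,
      clusters = corr$clusters, clusterVoxels = cand$voxels,
      permMax = corr$permMax, tThreshold = cand$tThreshold, log = log)
}

#' @describeIn runVlsm cluster table of a report
#' @param x a VlsmReport
#' @export
setMethod("clusters", "VlsmReport", function(x) x@clusters)

setMethod("show", "VlsmReport", function(object) {
  cat(sprintf("VlsmReport (%s): %d search voxels, %d cluster(s), %d significant\n",
              object@measure, sum(object@tmap@search),
              nrow(object@clusters),
              if (nrow(object@clusters)) sum(object@clusters$significant)
              else 0L))
  if (nrow(object@clusters)) {
    print(utils::head(object@clusters, 5))
  }
})

#' Leave-one-out stability of the principal VLSM cluster
#'
#' Repeats the VLSM analysis dropping one subject at a time and reports the
#' displacement (mm) of the matched significant cluster's centre of mass from
#' the whole-group cluster. Folds with no significant cluster are reported as
#' missing, not zero. The classical internal-validation summary is the count
#' of folds within `tolMm` of the whole-group centre.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param measure "walk", "fac" or "mrmi"
#' @param config a \linkS4class{VlsmConfig}
#' @param tolMm displacement tolerance for the summary count (default 1.4 mm)
#' @param report optional precomputed whole-group \linkS4class{VlsmReport}
#' @return data.frame (subject_id, displacement_mm) with attributes
#'   `reference_com` and `n_within_tol`
#' @export
looStability <- function(cohort, measure = c("walk", "fac", "mrmi"),
                         config = vlsmConfig(), tolMm = 1.4, report = NULL) {
  measure <- match.arg(measure)
  if (is.null(report)) report <- runVlsm(cohort, measure, config)
  cl <- clusters(report)
  if (!nrow(cl) || !any(cl$significant))
    stop("no significant whole-group cluster to validate")
  ref <- cl[cl$significant, , drop = FALSE]
  ref <- ref[which.max(ref$peak_t), ]
  refCom <- c(ref$com_x_mm, ref$com_y_mm, ref$com_z_mm)
  n <- nSubjects(cohort)
  disp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sub <- cohort[-i]
    rep_i <- runVlsm(sub, measure, config)
    cli <- clusters(rep_i)
    if (nrow(cli) && any(cli$significant)) {
      sig <- cli[cli$significant, , drop = FALSE]
      dd <- sqrt((sig$com_x_mm - refCom[1])^2 +
                 (sig$com_y_mm - refCom[2])^2 +
                 (sig$com_z_mm - refCom[3])^2)
      disp[i] <- min(dd)
    }
  }
  out <- data.frame(subject_id = records(cohort)$subject_id,
                    displacement_mm = disp)
  attr(out, "reference_com") <- refCom
  attr(out, "n_within_tol") <- sum(!is.na(disp) & disp <= tolMm)
  out
}
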