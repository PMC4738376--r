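# Shared fixtures. Small 20^3 cohorts keep module tests fast; the default
# 32^3 / 50-subject configuration is exercised in the acceptance tests.

smallConfig <- function(nSubjects = 20L, seed = 11L, ...) {
  simConfig(gridDims = c(20L, 20L, 20L), voxelMm = 2, nSubjects = nSubjects,
            hotspotCentre = c(6, 10, 9), hotspotSdMm = 6,
            lesionRadiusRange = c(4, 10),
            effectRegion = as.matrix(expand.grid(i = 4:8, j = 8:12,
                                                 k = 7:11)),
            seed = seed, ...)
}

# cache the default small cohort across tests in one session
.fixtureEnv <- new.env(parent = emptyenv())

smallCohortSim <- function() {
  if (is.null(.fixtureEnv$sim)) .fixtureEnv$sim <- makeCohort(smallConfig())
  .fixtureEnv$sim
}

defaultCohortSim <- function() {
  if (is.null(.fixtureEnv$simDefault))
    .fixtureEnv$simDefault <- makeCohort(simConfig())
  .fixtureEnv$simDefault
}

# a single-voxel mask on a given grid
pointMask <- function(grid, i, j, k) {
  g <- grid
  g@data[] <- 0
  g@data[i, j, k] <- 1
  g
}

# brute-force weighted tract load: explicit per-voxel loop over the
# slice-weighting definition, independent of the package's vectorised path
bruteLoad <- function(lesionArr, tractArr, voxelMm) {
  d <- dim(tractArr)
  inPlane <- voxelMm^2
  vv <- voxelMm^3
  areas <- vapply(seq_len(d[3]), function(k) sum(tractArr[, , k]) * inPlane,
                  numeric(1))
  aMax <- max(areas)
  total <- 0
  anyInSupport <- FALSE
  for (k in seq_len(d[3])) {
    if (areas[k] <= 0) next
    if (sum(lesionArr[, , k]) > 0) anyInSupport <- TRUE
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      if (lesionArr[i, j, k] == 1 && tractArr[i, j, k] == 1)
        total <- total + vv * aMax / areas[k]
  }
  if (!anyInSupport && sum(lesionArr) > 0) return(NA_real_)
  total / 1000
}

# normal-equations least-squares oracle for the voxelwise model
oracleVoxelT <- function(y, lesion, C) {
  X <- cbind(C, lesion = lesion)
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * solve(XtX)[ncol(X), ncol(X)])
  list(t = -drop(beta[ncol(X)] / se), df = df)
}

# O(n^2) tie-corrected Kendall tau-b oracle
bruteTauB <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- sum(vapply(split(x, x), function(g) length(g) * (length(g) - 1) / 2,
                   numeric(1)))
  ty <- sum(vapply(split(y, y), function(g) length(g) * (length(g) - 1) / 2,
                   numeric(1)))
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# build a tiny cohort directly from arrays + a records table
arrayCohort <- function(arrs, recs, voxelMm = 2) {
  grids <- lapply(arrs, volumeGrid, voxelMm = voxelMm)
  names(grids) <- recs$subject_id
  lesionCohort(grids, recs)
}

# minimal valid records table for n subjects
minimalRecords <- function(n, walk_change = NULL, seed = 99) {
  set.seed(seed)
  wb <- round(runif(n, 0.1, 1), 3)
  if (is.null(walk_change)) walk_change <- round(rnorm(n, 0.2, 0.1), 3)
  data.frame(subject_id = sprintf("s%02d", seq_len(n)),
             side = rep("left", n),
             walk_baseline = wb, walk_outcome = wb + walk_change,
             fac_baseline = sample(0:2, n, TRUE),
             fac_outcome = sample(2:5, n, TRUE),
             mrmi_baseline = sample(5:20, n, TRUE),
             mrmi_outcome = sample(20:40, n, TRUE),
             age = round(runif(n, 40, 85), 1),
             fazekas = sample(0:3, n, TRUE),
             time_days = sample(7:40, n, TRUE),
             stringsAsFactors = FALSE)
}
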