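test_that("search volume applies both the overlap floor and a comparison group", {
  d <- c(6, 6, 6)
  n <- 10
  arrs <- lapply(1:n, function(i) array(0, d))
  # voxel A lesioned in 5, voxel B in 6, voxel C in all 10
  for (i in 1:5) arrs[[i]][2, 2, 2] <- 1
  for (i in 1:6) arrs[[i]][3, 3, 3] <- 1
  for (i in 1:10) arrs[[i]][4, 4, 4] <- 1
  co <- arrayCohort(arrs, minimalRecords(n))
  sv <- buildSearchVolume(co, 6L)
  expect_false(sv$search[2, 2, 2])   # below the overlap floor
  expect_true(sv$search[3, 3, 3])
  expect_false(sv$search[4, 4, 4])   # lesioned in all: no comparison group

  # counts map equals brute-force per-voxel summation
  manual <- Reduce(`+`, lapply(arrs, identity))
  expect_equal(sv$counts@data, manual)

  # empty search volume is an explicit empty result, not an exception
  sv0 <- buildSearchVolume(co, 9L)
  expect_equal(sv0$nSearch, 0)
  rep0 <- runVlsm(co, "walk", vlsmConfig(minLesioned = 9L,
                                         nPermutations = 100L))
  expect_equal(nrow(clusters(rep0)), 0)
  expect_true(any(grepl("empty search volume", rep0@log)))
})

test_that("voxelT equals the pooled two-sample t without covariates", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(10:30, 1)
    lesion <- rbinom(n, 1, 0.4)
    if (sum(lesion) < 2 || sum(1 - lesion) < 2) next
    y <- rnorm(n, 1, 0.5)
    vt <- voxelT(y, lesion)
    tt <- t.test(y[lesion == 0], y[lesion == 1], var.equal = TRUE)
    expect_equal(vt$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(vt$df, n - 2)
  }
  # equal group means -> t = 0
  y0 <- c(1, 2, 3, 1, 2, 3)
  expect_equal(voxelT(y0, c(1, 1, 1, 0, 0, 0))$t, 0)
})

test_that("voxelT sign convention: damage that lowers scores gives positive t", {
  set.seed(1)
  lesion <- rep(c(1, 0), each = 10)
  y <- rnorm(20, 1) - lesion * 2   # lesioned subjects score much lower
  expect_gt(voxelT(y, lesion)$t, 0)
})

test_that("covariate-adjusted voxel t matches the normal-equations oracle", {
  set.seed(7)
  n <- 35
  covs <- cbind(age = runif(n, 40, 85), fazekas = sample(0:3, n, TRUE),
                time = runif(n, 7, 42), base = runif(n, 0, 1))
  for (rep in 1:20) {
    lesion <- rbinom(n, 1, 0.35)
    if (sum(lesion) < 2 || sum(1 - lesion) < 2) next
    y <- rnorm(n) + 0.02 * covs[, "age"] - lesion
    vt <- voxelT(y, lesion, covs)
    or <- oracleVoxelT(y, lesion, cbind(1, covs))
    expect_equal(vt$t, or$t, tolerance = 1e-8)
    expect_equal(vt$df, or$df)
    # df = n - model columns at every estimable voxel
    expect_equal(vt$df, n - 6)
  }
})

test_that("the t-map is invariant under joint reordering of subjects", {
  sim <- smallCohortSim()
  co <- sim$cohort
  cfg <- vlsmConfig(nPermutations = 100L)
  tm <- computeTMap(co, "walk", cfg)
  set.seed(8)
  perm <- sample(nSubjects(co))
  tmP <- computeTMap(co[perm], "walk", cfg)
  expect_equal(tm@t@data, tmP@t@data)
  expect_equal(tm@search, tmP@search)
})

test_that("connected components match the igraph oracle and the corner rule", {
  # two voxels touching only at a corner: one cluster at 26, two at 6
  arr <- array(FALSE, c(4, 4, 4))
  arr[1, 1, 1] <- TRUE; arr[2, 2, 2] <- TRUE
  lab26 <- LesionTopo:::.labelComponents(arr, 26L)
  lab6 <- LesionTopo:::.labelComponents(arr, 6L)
  expect_equal(max(lab26), 1L)
  expect_equal(max(lab6), 2L)

  skip_if_not_installed("igraph")
  oracleComponents <- function(arr, connectivity) {
    idx <- which(arr)
    if (!length(idx)) return(0L)
    coords <- arrayInd(idx, dim(arr))
    off <- LesionTopo:::.connOffsets(connectivity)
    edges <- NULL
    for (a in seq_along(idx)) {
      nb <- sweep(off, 2, coords[a, ], `+`)
      for (b in seq_along(idx)) {
        if (b <= a) next
        if (any(colSums(abs(t(nb) - coords[b, ])) == 0))
          edges <- rbind(edges, c(a, b))
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }
  set.seed(12)
  for (conn in c(6L, 18L, 26L)) {
    arr <- array(runif(10 * 10 * 10) < 0.2, c(10, 10, 10))
    lab <- LesionTopo:::.labelComponents(arr, conn)
    mem <- oracleComponents(arr, conn)
    got <- lab[which(arr)]
    # same partition up to label renaming
    expect_equal(max(got), max(mem))
    expect_true(all(tapply(mem, got, function(v) length(unique(v))) == 1))
  }
})

test_that("cluster formation thresholds at the t quantile and reports geometry", {
  sim <- smallCohortSim()
  co <- sim$cohort
  cfg <- vlsmConfig(nPermutations = 100L)
  tm <- computeTMap(co, "walk", cfg)
  cand <- formClusters(tm, cfg)
  expect_equal(cand$tThreshold, qt(1 - 0.005, tm@df))
  if (nrow(cand$clusters)) {
    expect_true(all(cand$clusters$peak_t > cand$tThreshold))
    # every member voxel is supra-threshold and inside the search volume
    for (i in seq_along(cand$voxels)) {
      vox <- cand$voxels[[i]]
      expect_true(all(tm@t@data[vox] > cand$tThreshold))
      expect_true(all(tm@search[vox]))
      # centre of mass is the unweighted mean of member mm coordinates
      mm <- voxelToWorld(tm@t, vox)
      expect_equal(unname(colMeans(mm)),
                   unname(as.numeric(cand$clusters[i, c("com_x_mm",
                                                        "com_y_mm",
                                                        "com_z_mm")])))
    }
  }
  # no voxel above an impossibly high threshold -> empty list, no error
  cfgHi <- vlsmConfig(pUncorrected = 1e-12, nPermutations = 100L)
  expect_equal(nrow(formClusters(tm, cfgHi)$clusters), 0)
})

test_that("corrected p has the permutation floor and is monotone in peak t", {
  sim <- smallCohortSim()
  co <- sim$cohort
  cfg <- vlsmConfig(nPermutations = 200L, seed = 5L)
  rep1 <- runVlsm(co, "walk", cfg)
  cl <- clusters(rep1)
  expect_true(all(cl$p_corrected >= 1 / 201))
  expect_true(all(cl$p_corrected <= 1))
  if (nrow(cl) > 1) {
    ord <- order(-cl$peak_t)
    expect_true(all(diff(cl$p_corrected[ord]) >= 0))
  }
  # an observed peak above every permutation max hits the floor exactly
  if (any(cl$peak_t > max(rep1@permMax)))
    expect_equal(min(cl$p_corrected), 1 / 201)
})

test_that("VLSM runs are reproducible given the seed", {
  sim <- smallCohortSim()
  cfg <- vlsmConfig(nPermutations = 150L, seed = 9L)
  r1 <- runVlsm(sim$cohort, "walk", cfg)
  r2 <- runVlsm(sim$cohort, "walk", cfg)
  expect_identical(clusters(r1), clusters(r2))
  expect_identical(r1@permMax, r2@permMax)
})

test_that("shrinking the search volume never adds candidate clusters", {
  sim <- smallCohortSim()
  co <- sim$cohort
  c6 <- vlsmConfig(minLesioned = 6L, nPermutations = 100L)
  c8 <- vlsmConfig(minLesioned = 8L, nPermutations = 100L)
  tm6 <- computeTMap(co, "walk", c6)
  tm8 <- computeTMap(co, "walk", c8)
  expect_true(all(tm8@search <= tm6@search))
  supra6 <- sum(tm6@t@data > formClusters(tm6, c6)$tThreshold, na.rm = TRUE)
  supra8 <- sum(tm8@t@data > formClusters(tm8, c8)$tThreshold, na.rm = TRUE)
  expect_lte(supra8, supra6)
})

test_that("leave-one-out folds count the cohort and tolerate duplicates", {
  cfg <- smallConfig(nSubjects = 16L, seed = 19L,
                     effectBeta = -0.6, noiseSd = 0.05)
  sim <- makeCohort(cfg)
  vcfg <- vlsmConfig(minLesioned = 4L, nPermutations = 200L, seed = 2L)
  rep0 <- runVlsm(sim$cohort, "walk", vcfg)
  expect_true(any(clusters(rep0)$significant))
  lo <- looStability(sim$cohort, "walk", vcfg, report = rep0)
  expect_equal(nrow(lo), 16)
  expect_true(all(is.na(lo$displacement_mm) | lo$displacement_mm >= 0))

  # duplicated subject: dropping one copy leaves the map unchanged
  co <- sim$cohort
  recs17 <- records(co)
  extra <- recs17[1, ]
  extra$subject_id <- "dup01"
  dup <- lesionCohort(c(masks(co), list(dup01 = co@masks[[1L]])),
                      rbind(recs17, extra))
  tmFull <- computeTMap(co, "walk", vcfg)
  tmDrop <- computeTMap(dup[-17], "walk", vcfg)
  expect_equal(tmFull@t@data, tmDrop@t@data)
})

test_that("Freedman-Lane permutation variant runs and stays calibrated-ish", {
  sim <- smallCohortSim()
  cfgFL <- vlsmConfig(nPermutations = 150L, seed = 4L, freedmanLane = TRUE)
  repFL <- runVlsm(sim$cohort, "walk", cfgFL)
  expect_equal(length(repFL@permMax), 150L)
  expect_true(all(is.finite(repFL@permMax)))
})
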