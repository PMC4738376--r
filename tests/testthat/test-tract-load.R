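# The worked example: a 3-slice tract with areas [4, 2, 2] mm^2 on a 1 mm
# grid; a lesion covering 2 tract voxels on slice 2 and 1 on slice 3 loads
# (2 * 4/2 + 1 * 4/2) mm^3 = 6 mm^3 = 0.006 cm^3.
test_that("weightedTractLoad reproduces the hand-computed slice weighting", {
  d <- c(4, 4, 3)
  tractArr <- array(0, d)
  tractArr[1:2, 1:2, 1] <- 1            # slice 1: 4 voxels, A = 4 mm^2
  tractArr[1:2, 1, 2] <- 1              # slice 2: 2 voxels, A = 2 mm^2
  tractArr[1:2, 1, 3] <- 1              # slice 3: 2 voxels, A = 2 mm^2
  tract <- tractMap(volumeGrid(tractArr, voxelMm = 1))
  expect_equal(tract@sliceArea, c(4, 2, 2))
  expect_equal(tract@maxArea, 4)

  lesArr <- array(0, d)
  lesArr[1:2, 1, 2] <- 1                # 2 tract voxels on slice 2
  lesArr[1, 1, 3] <- 1                  # 1 tract voxel on slice 3
  res <- weightedTractLoad(volumeGrid(lesArr, voxelMm = 1), tract)
  expect_equal(res@wcstLlCm3, 0.006)
  expect_equal(res@status, "ok")
  expect_true(all(res@perSlice$weight >= 1))
  expect_equal(sum(res@perSlice$weighted_mm3) / 1000, res@wcstLlCm3)
})

test_that("full-tract lesion loads the full-width equivalent of every slice", {
  cfg <- smallConfig()
  tract <- makeTract(cfg)
  lesion <- tract@mask       # lesion exactly equal to (hence containing) tract
  res <- weightedTractLoad(lesion, tract)
  dz <- cfg@voxelMm
  expected <- sum(tract@maxArea * dz * length(tract@zSupport)) / 1000
  expect_equal(res@wcstLlCm3, expected, tolerance = 1e-12)
})

test_that("disjoint lesions load zero; off-support lesions are flagged", {
  cfg <- smallConfig()
  tract <- makeTract(cfg)
  g <- tract@mask

  # in z-support but disjoint in-plane
  far <- pointMask(g, 18, 18, 10)
  expect_equal(tract@mask@data[18, 18, 10], 0)
  res <- weightedTractLoad(far, tract)
  expect_equal(res@wcstLlCm3, 0)
  expect_equal(res@status, "ok")

  # tract with empty lower slices; a lesion entirely below the support
  d <- c(6, 6, 8)
  tArr <- array(0, d); tArr[3:4, 3:4, 5:8] <- 1
  tr2 <- tractMap(volumeGrid(tArr, voxelMm = 2))
  expect_equal(tr2@zSupport, 5:8)
  low <- volumeGrid(array(0, d), voxelMm = 2)
  low@data[3, 3, 2] <- 1
  res2 <- weightedTractLoad(low, tr2)
  expect_equal(res2@status, "outside_tract_support")
  expect_true(is.na(res2@wcstLlCm3))

  # grid mismatch and empty tract are errors
  expect_error(weightedTractLoad(volumeGrid(array(0, c(5, 5, 5))), tr2),
               "cohort-consistency")
  expect_error(tractMap(volumeGrid(array(0, d), voxelMm = 2)), "empty tract")
})

test_that("loads equal the brute-force per-voxel oracle on random pairs", {
  cfg <- smallConfig()
  tract <- makeTract(cfg)
  set.seed(101)
  for (rep in 1:30) {
    arr <- array(rbinom(prod(cfg@gridDims), 1, runif(1, 0.02, 0.3)),
                 cfg@gridDims)
    res <- weightedTractLoad(volumeGrid(arr, voxelMm = cfg@voxelMm), tract)
    oracle <- bruteLoad(arr, tract@mask@data, cfg@voxelMm)
    if (is.na(oracle)) expect_true(is.na(res@wcstLlCm3))
    else expect_equal(res@wcstLlCm3, oracle, tolerance = 1e-9)
  }
})

test_that("load is monotone in the lesion and additive over disjoint parts", {
  cfg <- smallConfig()
  tract <- makeTract(cfg)
  set.seed(55)
  for (rep in 1:10) {
    a <- array(rbinom(prod(cfg@gridDims), 1, 0.1), cfg@gridDims)
    extra <- array(rbinom(prod(cfg@gridDims), 1, 0.1), cfg@gridDims)
    sup <- pmin(a + extra, 1)   # superset of a
    la <- weightedTractLoad(volumeGrid(a, voxelMm = 2), tract)@wcstLlCm3
    ls <- weightedTractLoad(volumeGrid(sup, voxelMm = 2), tract)@wcstLlCm3
    expect_gte(ls, la)

    # split sup into two disjoint halves; loads add
    half <- array(0, cfg@gridDims); half[1:10, , ] <- 1
    p1 <- sup * half; p2 <- sup * (1 - half)
    l1 <- weightedTractLoad(volumeGrid(p1, voxelMm = 2), tract)@wcstLlCm3
    l2 <- weightedTractLoad(volumeGrid(p2, voxelMm = 2), tract)@wcstLlCm3
    if (!is.na(l1) && !is.na(l2)) expect_equal(l1 + l2, ls, tolerance = 1e-12)
  }
})

test_that("a constant-area tract reduces the load to plain overlap volume", {
  cfg <- smallConfig()
  tract <- makeTract(cfg, radiusProfileMm = rep(6, cfg@gridDims[3]))
  expect_true(all(tract@sliceArea == tract@maxArea))
  set.seed(77)
  arr <- array(rbinom(prod(cfg@gridDims), 1, 0.2), cfg@gridDims)
  res <- weightedTractLoad(volumeGrid(arr, voxelMm = 2), tract)
  plain <- sum(arr * tract@mask@data) * 8 / 1000
  expect_equal(res@wcstLlCm3, plain, tolerance = 1e-12)
})

test_that("load is robust to coarsening the grid (same anatomy, 2x voxel)", {
  # voxelize the same continuous sphere lesion and cylinder tract at 1 mm
  # and 2 mm; the weighted loads should agree within the fixed 15% band
  voxelize <- function(voxelMm, n, centre, radius, axis, rTube) {
    d <- rep(n / voxelMm, 3)
    g <- volumeGrid(array(0, d), voxelMm = voxelMm)
    idx <- as.matrix(expand.grid(i = 1:d[1], j = 1:d[2], k = 1:d[3]))
    mm <- voxelToWorld(g, idx)
    les <- array(0, d)
    les[idx[sqrt(rowSums(sweep(mm, 2, centre)^2)) <= radius, , drop = FALSE]] <- 1
    tub <- array(0, d)
    keep <- sqrt((mm[, 1] - axis[1])^2 + (mm[, 2] - axis[2])^2) <=
      rTube * (1 + 0.5 * (mm[, 3] / (n / 2)))   # funnel: wider at top
    tub[idx[keep, , drop = FALSE]] <- 1
    list(lesion = g2 <- { g@data <- les; g },
         tract = tractMap({ t <- volumeGrid(tub, voxelMm = voxelMm); t }))
  }
  fine <- voxelize(1, 32, centre = c(2, 1, 3), radius = 7,
                   axis = c(0, 0), rTube = 6)
  coarse <- voxelize(2, 32, centre = c(2, 1, 3), radius = 7,
                     axis = c(0, 0), rTube = 6)
  lf <- weightedTractLoad(fine$lesion, fine$tract)@wcstLlCm3
  lc <- weightedTractLoad(coarse$lesion, coarse$tract)@wcstLlCm3
  expect_lt(abs(lc - lf) / lf, 0.15)
})

test_that("cohortLoads flags off-support subjects and matches per-subject calls", {
  cfg <- smallConfig(nSubjects = 8L, seed = 3L)
  sim <- makeCohort(cfg)
  # tract occupying only upper slices so a low lesion can fall outside
  tr <- makeTract(cfg)
  tArr <- tr@mask@data; tArr[, , 1:10] <- 0
  tr <- tractMap({ g <- tr@mask; g@data <- tArr; g })
  co <- sim$cohort
  # force subject 2's lesion entirely below the support
  low <- array(0, cfg@gridDims); low[9:10, 9:10, 1:3] <- 1
  co@masks[[2]]@data <- low
  tab <- cohortLoads(co, tr)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$status[2], "outside_tract_support")
  expect_true(is.na(tab$wcst_ll_cm3[2]))
  ok <- which(tab$status == "ok")
  for (i in ok[1:3])
    expect_equal(tab$wcst_ll_cm3[i],
                 weightedTractLoad(co@masks[[i]], tr)@wcstLlCm3)
  # all-empty lesions load 0
  co0 <- co
  for (i in 1:8) co0@masks[[i]]@data[] <- 0
  expect_true(all(cohortLoads(co0, tr)$wcst_ll_cm3 == 0))
})
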