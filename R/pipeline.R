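#' @include vlsm.R atlas-report.R behaviour-stats.R synthetic-cohort.R
NULL

.writeClusterVolume <- function(report, path) {
  d <- gridDims(report@tmap@t)
  arr <- array(0L, d)
  cl <- clusters(report)
  for (i in seq_len(nrow(cl)))
    arr[report@clusterVoxels[[i]]] <- cl$cluster_id[i]
  g <- report@tmap@t
  g@data <- arr
  writeVolume(g, path)
}

#' Run the complete analysis plan on a cohort directory
#'
#' Reproduces the full pipeline on any cohort laid out as a fixture directory
#' (masks/, behaviour.csv, tract.nii.gz, atlas.nii.gz + atlas_names.tsv):
#' load and flip, weighted tract lesion loads, the regression battery per
#' measure (multiple regression for walk and MRMI, proportional odds for
#' FAC) with load + age/Fazekas/baseline/time, one VLSM run per measure,
#' atlas labelling and tract intersection of significant clusters,
#' leave-one-out stability of the principal cluster, and the two sensitivity
#' reruns (minimum overlap 10; cluster-forming p 0.001). A manifest with
#' config, seed, input hashes and per-stage timing makes runs reproducible.
#'
#' @param cohortDir directory containing masks/ and behaviour.csv
#' @param outDir report directory to create
#' @param tractPath canonical tract NIfTI (default `<cohortDir>/tract.nii.gz`)
#' @param atlasPaths named list of `list(volume=, names=)` atlas paths;
#'   default the fixture's atlas.nii.gz + atlas_names.tsv if present
#' @param config a \linkS4class{VlsmConfig} (its seed drives all permutation
#'   streams)
#' @param measures subset of c("walk", "fac", "mrmi")
#' @param loo run leave-one-out stability for the principal significant
#'   cluster (default TRUE; by far the slowest stage)
#' @param sensitivity run the two sensitivity reruns (default TRUE)
#' @return the report directory path, invisibly; all tables are also written
#'   as CSV under `outDir`
#' @export
runAll <- function(cohortDir, outDir,
                   tractPath = file.path(cohortDir, "tract.nii.gz"),
                   atlasPaths = NULL, config = vlsmConfig(),
                   measures = c("walk", "fac", "mrmi"),
                   loo = TRUE, sensitivity = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    v <- force(expr)
    timing[[name]] <<- round(proc.time()[["elapsed"]] - s, 2)
    v
  }

  cohort <- stage("load", loadCohort(file.path(cohortDir, "masks"),
                                     file.path(cohortDir, "behaviour.csv")))
  tract <- stage("tract", readTract(tractPath,
                                    reference = cohort@masks[[1L]]))
  if (is.null(atlasPaths)) {
    av <- file.path(cohortDir, "atlas.nii.gz")
    an <- file.path(cohortDir, "atlas_names.tsv")
    if (file.exists(av) && file.exists(an))
      atlasPaths <- list(synthetic = list(volume = av, names = an))
    else atlasPaths <- list()
  }
  atlases <- lapply(names(atlasPaths), function(nm)
    readLabelAtlas(atlasPaths[[nm]]$volume, atlasPaths[[nm]]$names,
                   atlasName = nm, reference = cohort@masks[[1L]]))

  loads <- stage("loads", cohortLoads(cohort, tract))
  utils::write.csv(loads, file.path(outDir, "loads.csv"), row.names = FALSE)

  summ <- summarizeCohort(cohort)
  utils::write.csv(summ$variables, file.path(outDir, "descriptives.csv"),
                   row.names = FALSE)
  utils::write.csv(summ$effects, file.path(outDir, "change_effects.csv"),
                   row.names = FALSE)

  for (m in measures) {
    reg <- stage(paste0("regression_", m), loadRegression(cohort, loads, m))
    utils::write.csv(reg, file.path(outDir, paste0("regression_", m, ".csv")),
                     row.names = FALSE)
  }

  reports <- list()
  logLines <- cohort@log
  for (m in measures) {
    rep_m <- stage(paste0("vlsm_", m), runVlsm(cohort, m, config))
    reports[[m]] <- rep_m
    logLines <- c(logLines, paste0("[", m, "] ", rep_m@log))
    writeVolume(rep_m@tmap@counts,
                file.path(outDir, paste0("overlap_count.nii.gz")))
    tg <- rep_m@tmap@t
    tg@data[is.na(tg@data)] <- 0
    writeVolume(tg, file.path(outDir, paste0("tmap_", m, ".nii.gz")))
    .writeClusterVolume(rep_m, file.path(outDir,
                                         paste0("clusters_", m, ".nii.gz")))
    utils::write.csv(clusters(rep_m),
                     file.path(outDir, paste0("clusters_", m, ".csv")),
                     row.names = FALSE)
    anat <- reportClusterAnatomy(rep_m, atlases, tract)
    if (nrow(anat))
      utils::write.csv(anat, file.path(outDir, paste0("anatomy_", m, ".csv")),
                       row.names = FALSE)
  }

  if (sensitivity) {
    for (m in measures) {
      cl <- clusters(reports[[m]])
      if (!nrow(cl) || !any(cl$significant)) next
      cfg10 <- config; cfg10@minLesioned <- 10L
      cfg001 <- config; cfg001@pUncorrected <- 0.001
      s10 <- stage(paste0("sens_minles10_", m), runVlsm(cohort, m, cfg10))
      s001 <- stage(paste0("sens_p001_", m), runVlsm(cohort, m, cfg001))
      utils::write.csv(clusters(s10),
                       file.path(outDir,
                                 paste0("clusters_", m, "_minles10.csv")),
                       row.names = FALSE)
      utils::write.csv(clusters(s001),
                       file.path(outDir, paste0("clusters_", m, "_p001.csv")),
                       row.names = FALSE)
    }
  }

  if (loo) {
    for (m in measures) {
      cl <- clusters(reports[[m]])
      if (!nrow(cl) || !any(cl$significant)) next
      lo <- stage(paste0("loo_", m),
                  looStability(cohort, m, config, report = reports[[m]]))
      utils::write.csv(lo, file.path(outDir, paste0("loo_", m, ".csv")),
                       row.names = FALSE)
      logLines <- c(logLines, sprintf(
        "[%s] leave-one-out: %d/%d folds within 1.4 mm",
        m, attr(lo, "n_within_tol"), nrow(lo)))
      break  # principal cluster only
    }
  }

  inputs <- c(file.path(cohortDir, "behaviour.csv"), tractPath)
  manifest <- list(
    package_version = as.character(utils::packageVersion("LesionTopo")),
    seed = config@seed,
    config = list(minLesioned = config@minLesioned,
                  pUncorrected = config@pUncorrected,
                  nPermutations = config@nPermutations,
                  alphaCorrected = config@alphaCorrected,
                  connectivity = config@connectivity,
                  direction = config@direction,
                  covariateNames = config@covariateNames,
                  freedmanLane = config@freedmanLane),
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    exclusion_log = cohort@log,
    timing_s = as.list(timing),
    total_s = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(logLines, file.path(outDir, "log.txt"))
  invisible(outDir)
}

#' Per-hemisphere VLSM reruns
#'
#' Repeats the VLSM stage separately on the left- and right-sided subsets of
#' the cohort (no pooling across hemispheres). Subsets below `minSubjects`
#' are skipped with a log entry. Because a subset's overlap counts can only
#' drop, the union of subset search volumes is contained in the pooled one.
#'
#' @param cohort a \linkS4class{LesionCohort}
#' @param measure "walk", "fac" or "mrmi"
#' @param config a \linkS4class{VlsmConfig}
#' @param minSubjects minimum subset size to analyse (default 10)
#' @return named list with elements `left` and `right`, each a
#'   \linkS4class{VlsmReport} or a skip message
#' @export
runSideSplit <- function(cohort, measure = c("walk", "fac", "mrmi"),
                         config = vlsmConfig(), minSubjects = 10L) {
  measure <- match.arg(measure)
  out <- list()
  for (s in c("left", "right")) {
    idx <- which(records(cohort)$side == s)
    if (length(idx) < minSubjects) {
      out[[s]] <- sprintf("skipped: only %d %s-sided subject(s)",
                          length(idx), s)
      next
    }
    out[[s]] <- runVlsm(cohort[idx], measure, config)
  }
  out
}
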