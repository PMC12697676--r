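## Config-driven orchestration of the full study design: simulate a
## cohort, fit both cognitive models, score patients, map every
## phenotype with LBM / sLNM / fLNM, and compare the spatial
## inter-correlations of the domain maps between models.

#' Build a validated pipeline configuration
#'
#' All simulation and analysis parameters with study-scale defaults
#' (473 patients, 20.8% missingness, 1000 map permutations, 10000
#' comparison permutations, v = 1, alpha = 0.05, 5x5 CV). Every stage
#' derives its own RNG stream from the mandatory master seed.
#'
#' @param seed master seed (mandatory).
#' @param ... overrides of the defaults listed in the source.
#' @return a named list of class `ldmConfig`.
#' @export
pipelineConfig <- function(seed, ...) {
  if (missing(seed)) stop("a master seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    nPatients = 473L,
    dims = c(20L, 24L, 20L), voxelSize = 3,
    nParcels = 20L, nNetworks = 5L,
    streamlinesPerEdge = 5L, edgeDensity = 1,
    nSubjectsFunc = 12L, nTimepoints = 120L, withinNetworkCorr = 0.4,
    lesionSize = list(rMin = 1.2, rMax = 3.5),
    missingRate = 0.208,
    gLoading = 0.6, domainLoading = 0.45,
    effects = c(g = 3, memory = 3, speed = 3, visuospatial = 3,
                language = 3),
    anatomyRadius = 2.2,
    gParcels = 2L,
    nPermMap = 1000L, nPermCompare = 10000L, v = 1L, alpha = 0.05,
    folds = 5L, repeats = 5L, minLesion = 4L,
    phenotypes = "factors", nStarts = 3L, runPlsr = FALSE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  battery <- defaultTestBattery()
  okFactors <- c("g", unique(battery$domain))
  bad <- setdiff(names(cfg$effects), okFactors)
  if (length(bad))
    stop("effects refer to unknown factors: ", paste(bad, collapse = ", "))
  if (!cfg$phenotypes %in% c("factors", "tests"))
    stop("phenotypes must be 'factors' or 'tests'")
  cfg$mappedDomains <- setdiff(unique(battery$domain), "crystallized")
  class(cfg) <- "ldmConfig"
  cfg
}

simPieces <- function(cfg, what = c("brain", "tract", "func", "cohort")) {
  out <- list()
  out$brain <- makeBrain(cfg$dims, cfg$voxelSize, cfg$nParcels,
                         cfg$nNetworks, seed = cfg$seed)
  if ("tract" %in% what)
    out$tract <- makeTractogram(out$brain$grid, out$brain$parcellation,
                                cfg$streamlinesPerEdge, cfg$edgeDensity,
                                seed = cfg$seed)
  if ("func" %in% what)
    out$func <- makeNormativeFunctional(out$brain$grid,
                                        out$brain$networks,
                                        cfg$nSubjectsFunc,
                                        cfg$nTimepoints,
                                        cfg$withinNetworkCorr,
                                        seed = cfg$seed)
  if ("cohort" %in% what) {
    lesions <- sampleLesions(out$brain$grid, cfg$nPatients,
                             cfg$lesionSize, seed = cfg$seed)
    nper <- stats::setNames(rep(1L, length(cfg$effects)),
                            names(cfg$effects))
    if ("g" %in% names(nper)) nper[["g"]] <- cfg$gParcels
    anatomy <- planAnatomy(out$brain, cfg$effects, cfg$anatomyRadius,
                           nper, seed = cfg$seed)
    truth <- defaultGroundTruthParams(gLoading = cfg$gLoading,
                                      domainLoading = cfg$domainLoading)
    gb <- generateBehavior(out$brain$grid, lesions, truth, anatomy,
                           cfg$missingRate, seed = cfg$seed)
    out$cohort <- gb$cohort
    out$truth <- gb$truth
    out$anatomy <- anatomy
  }
  out
}

stageSimulate <- function(cfg, outdir) {
  sw <- simPieces(cfg, c("brain", "tract", "cohort"))
  grid <- sw$brain$grid
  writeVolume(sw$brain$parcellation@labels, grid,
              file.path(outdir, "parcellation.nii.gz"))
  writeVolume(sw$brain$networks, grid, file.path(outdir, "networks.nii.gz"))
  writeTsv(data.frame(parcel = seq_len(cfg$nParcels),
                      network = sw$brain$parcellation@parcelNetworks),
           file.path(outdir, "parcel_networks.tsv"))
  writeLesionStack(sw$cohort, file.path(outdir, "lesions.nii.gz"))
  writeTsv(cbind(patient = sw$cohort@patientIds,
                 as.data.frame(behavior(sw$cohort))),
           file.path(outdir, "behavior.tsv"))
  writeTsv(cbind(patient = sw$cohort@patientIds,
                 as.data.frame(sw$truth@scores)),
           file.path(outdir, "truth_scores.tsv"))
  writeTractogramJsonl(sw$tract, grid,
                       file.path(outdir, "tractogram.jsonl"))
  writeJson(lapply(sw$anatomy, function(a)
    list(effect = a$effect, nVoxels = length(a$voxels),
         voxels = a$voxels)),
    file.path(outdir, "anatomy.json"))
  invisible(outdir)
}

loadCohortArtifacts <- function(cfg, outdir) {
  beh <- readTsv(file.path(outdir, "behavior.tsv"))
  Y <- as.matrix(beh[, -1, drop = FALSE])
  rownames(Y) <- beh$patient
  st <- readLesionStack(file.path(outdir, "lesions.nii.gz"))
  brain <- simPieces(cfg, "brain")$brain
  list(behavior = Y, lesions = st$lesions, brain = brain)
}

stageFitFactors <- function(cfg, outdir) {
  art <- loadCohortArtifacts(cfg, outdir)
  for (model in c("bifactor", "correlated")) {
    spec <- if (model == "bifactor") bifactorSpec()
            else correlatedFactorsSpec()
    fit <- fitCfa(art$behavior, spec, nStarts = cfg$nStarts,
                  seed = childSeed(cfg$seed, paste0("fit-", model)))
    idx <- fitIndices(fit, behavior = art$behavior)
    om <- omegaHierarchical(fit)
    writeModelJson(fit, idx, om,
                   file.path(outdir, sprintf("model_%s.json", model)))
    sc <- factorScores(fit, art$behavior)
    writeTsv(cbind(patient = rownames(art$behavior),
                   as.data.frame(sc)),
             file.path(outdir, sprintf("scores_%s.tsv", model)))
  }
  invisible(outdir)
}

## phenotype table: which score columns are mapped for which model
mapTargets <- function(cfg, outdir) {
  if (cfg$phenotypes == "tests") {
    beh <- readTsv(file.path(outdir, "behavior.tsv"))
    tests <- colnames(beh)[-1]
    return(data.frame(model = "tests", phenotype = tests,
                      stringsAsFactors = FALSE))
  }
  rbind(
    data.frame(model = "bifactor",
               phenotype = c("g", cfg$mappedDomains)),
    data.frame(model = "correlated", phenotype = cfg$mappedDomains))
}

phenotypeScores <- function(cfg, outdir, model, phenotype, behavior) {
  if (cfg$phenotypes == "tests") return(behavior[, phenotype])
  f <- file.path(outdir, sprintf("scores_%s.tsv", model))
  sc <- readTsv(f)
  sc[[phenotype]]
}

stageMap <- function(cfg, outdir, modality) {
  art <- loadCohortArtifacts(cfg, outdir)
  grid <- art$brain$grid
  covar <- matrix(vapply(art$lesions, logLesionVolume, 1.0,
                         grid = grid), ncol = 1)
  targets <- mapTargets(cfg, outdir)

  feats <- switch(modality,
    lbm = list(X = lesionMatrix(art$lesions, grid), edges = NULL),
    slnm = {
      tract <- readTractogramJsonl(file.path(outdir, "tractogram.jsonl"),
                                   grid, cfg$nParcels)
      parc <- art$brain$parcellation
      mats <- lapply(art$lesions, disconnectionMatrix, tractogram = tract,
                     parcellation = parc)
      ef <- edgeFeatures(mats)
      list(X = ef$X, edges = ef$edges)
    },
    flnm = {
      func <- simPieces(cfg, "func")$func
      maps <- lapply(art$lesions, flnmMap, normative = func)
      maskIdx <- maps[[1]]@maskIdx
      X <- t(vapply(maps, function(m) m@values, numeric(length(maskIdx))))
      colnames(X) <- as.character(maskIdx)
      list(X = X, edges = NULL)
    },
    stop("unknown modality ", modality))

  for (i in seq_len(nrow(targets))) {
    model <- targets$model[i]; phen <- targets$phenotype[i]
    y <- phenotypeScores(cfg, outdir, model, phen, art$behavior)
    use <- is.finite(y)
    sm <- permutationFwe(
      feats$X[use, , drop = FALSE], y[use], covar[use, , drop = FALSE],
      nPerm = cfg$nPermMap, v = cfg$v, alpha = cfg$alpha,
      seed = childSeed(cfg$seed, paste(modality, model, phen)),
      minLesion = cfg$minLesion,
      nonZeroFilter = modality == "slnm", modality = modality)
    writeStatMap(sm, file.path(outdir,
                               sprintf("map_%s_%s_%s", modality, model,
                                       phen)),
                 grid = grid, edges = feats$edges)
    if (isTRUE(cfg$runPlsr)) {
      pl <- plsrMap(feats$X[use, , drop = FALSE], y[use],
                    covar[use, , drop = FALSE], folds = cfg$folds,
                    repeats = cfg$repeats,
                    seed = childSeed(cfg$seed,
                                     paste("plsr", modality, model, phen)),
                    minLesion = cfg$minLesion,
                    nonZeroFilter = modality == "slnm")
      writeJson(list(nComponents = pl$nComponents,
                     varianceExplained = pl$varianceExplained,
                     cvCor = pl$cvCor,
                     weights = as.list(pl$weights)),
                file.path(outdir, sprintf("plsr_%s_%s_%s.json", modality,
                                          model, phen)))
    }
  }
  invisible(outdir)
}

stageCompare <- function(cfg, outdir) {
  if (cfg$phenotypes == "tests")
    stop("comparison is defined for factor phenotypes, not raw tests")
  for (modality in c("lbm", "slnm", "flnm")) {
    readMap <- function(model, phen) {
      f <- file.path(outdir, sprintf("map_%s_%s_%s.tsv", modality, model,
                                     phen))
      readTsv(f)
    }
    doms <- cfg$mappedDomains
    bf <- lapply(doms, readMap, model = "bifactor")
    cf <- lapply(doms, readMap, model = "correlated")
    ids <- lapply(c(bf, cf), function(d) d$feature)
    common <- Reduce(intersect, ids)
    tvec <- function(d) d$t[match(common, d$feature)]
    mb <- lapply(bf, tvec); names(mb) <- doms
    mc <- lapply(cf, tvec); names(mc) <- doms
    res <- compareModelMaps(mb, mc, nPerm = cfg$nPermCompare,
                            seed = childSeed(cfg$seed,
                                             paste0("compare-", modality)))
    offdiag <- function(M) M[upper.tri(M)]
    writeJson(list(
      modality = modality, domains = doms,
      corrBifactor = res@corrBifactor,
      corrCorrelated = res@corrCorrelated,
      meanRBifactor = mean(offdiag(res@corrBifactor)),
      sdRBifactor = stats::sd(offdiag(res@corrBifactor)),
      meanRCorrelated = mean(offdiag(res@corrCorrelated)),
      sdRCorrelated = stats::sd(offdiag(res@corrCorrelated)),
      tObserved = res@tObserved, pPerm = res@pPerm, nPerm = res@nPerm,
      alternative = res@alternative, nFeatures = length(common),
      seed = cfg$seed),
      file.path(outdir, sprintf("compare_%s.json", modality)))
    writeTsv(res@zPairs, file.path(outdir,
                                   sprintf("compare_%s_pairs.tsv",
                                           modality)))
  }
  invisible(outdir)
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `fit-factors`, `map-lbm`, `map-slnm`,
#' `map-flnm`, `compare`. Each stage reads its upstream artifacts from
#' `outdir` and fails with an explicit dependency error when they are
#' missing; rerunning a stage overwrites its own outputs (idempotent).
#'
#' @param stage stage name.
#' @param config an `ldmConfig` from [pipelineConfig()].
#' @param outdir run directory.
#' @return `outdir`, invisibly.
#' @export
runStage <- function(stage, config, outdir) {
  stopifnot(inherits(config, "ldmConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  res <- switch(stage,
    "simulate" = stageSimulate(config, outdir),
    "fit-factors" = stageFitFactors(config, outdir),
    "map-lbm" = stageMap(config, outdir, "lbm"),
    "map-slnm" = stageMap(config, outdir, "slnm"),
    "map-flnm" = stageMap(config, outdir, "flnm"),
    "compare" = stageCompare(config, outdir),
    stop("unknown stage: ", stage))
  cat(sprintf("[%s] finished in %.1fs\n", stage,
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = file.path(outdir, "run.log"), append = TRUE)
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate -> fit both factor models -> score -> LBM/sLNM/fLNM per
#' phenotype per model -> compare map inter-correlations; then writes a
#' provenance manifest (config echo + hash, seed, package version, file
#' inventory). Reruns with the same config and seed produce
#' bit-identical TSV/JSON outputs.
#'
#' @param config an `ldmConfig`.
#' @param outdir run directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
runAll <- function(config, outdir) {
  stopifnot(inherits(config, "ldmConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfgFile <- file.path(outdir, "config.json")
  writeJson(unclass(config), cfgFile)
  stages <- c("simulate", "fit-factors", "map-lbm", "map-slnm",
              "map-flnm", if (config$phenotypes == "factors") "compare")
  for (st in stages) {
    ok <- try(runStage(st, config, outdir), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("stage '", st, "' failed: ", attr(ok, "condition")$message)
  }
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        c("manifest.json", "run.log")))
  writeJson(list(
    configHash = unname(tools::md5sum(cfgFile)),
    seed = config$seed,
    package = "gLDM",
    version = as.character(utils::packageVersion("gLDM")),
    stages = stages, files = files),
    file.path(outdir, "manifest.json"))
  invisible(outdir)
}
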