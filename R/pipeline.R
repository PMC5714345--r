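#' Pipeline run configuration
#'
#' Bundles every stage's settings into one serialisable object. The single
#' global \code{seed} is fanned out to per-stage sub-seeds (stable under
#' stage re-ordering), so one (config, seed) pair fully determines every
#' numeric artifact of [runAll()].
#'
#' @param scene a [sceneConfig()]; its seed is overridden by \code{seed}.
#' @param texture a [textureConfig()].
#' @param weights a [spatialWeights()].
#' @param alpha hotspot significance level.
#' @param agbHighThreshold AGB mask for hotspots (Mg/ha; the high-AGB
#'   convention is 180).
#' @param sampleN driver-analysis sample size (study design: 1500 pixels).
#' @param screenThreshold correlation-screening cut-off for AGB predictors.
#' @param folds cross-validation folds.
#' @param seed global integer seed.
#' @param outDir default output directory for [runAll()].
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(scene = sceneConfig(), texture = textureConfig(),
                      weights = spatialWeights(), alpha = 0.05,
                      agbHighThreshold = 180, sampleN = 1500,
                      screenThreshold = 0.75, folds = 10, seed = 1,
                      outDir = "agbird-run") {
  scene$seed <- as.integer(seed)
  structure(list(scene = scene, texture = texture, weights = weights,
                 alpha = alpha, agbHighThreshold = agbHighThreshold,
                 sampleN = as.integer(sampleN),
                 screenThreshold = screenThreshold, folds = as.integer(folds),
                 seed = as.integer(seed), outDir = outDir),
            class = "runConfig")
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML schema mirrors [runConfig()]: top-level keys \code{scene},
#' \code{texture}, \code{weights}, \code{alpha}, \code{agbHighThreshold},
#' \code{sampleN}, \code{screenThreshold}, \code{folds}, \code{seed},
#' \code{outDir}, each scene/texture/weights key named as in the
#' corresponding constructor. Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return \code{readRunConfig} returns a \code{runConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  checkKeys <- function(got, allowed, where) {
    bad <- setdiff(names(got), allowed)
    if (length(bad))
      stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "))
  }
  checkKeys(y, c("scene", "texture", "weights", "alpha", "agbHighThreshold",
                 "sampleN", "screenThreshold", "folds", "seed", "outDir"),
            "config")
  args <- list()
  if (!is.null(y$scene)) {
    checkKeys(y$scene, names(formals(sceneConfig)), "scene")
    if (!is.null(y$scene$rangeEffects))
      y$scene$rangeEffects <- unlist(y$scene$rangeEffects)
    if (!is.null(y$scene$agbRange)) y$scene$agbRange <- unlist(y$scene$agbRange)
    args$scene <- do.call(sceneConfig, y$scene)
  }
  if (!is.null(y$texture)) {
    checkKeys(y$texture, names(formals(textureConfig)), "texture")
    if (!is.null(y$texture$offsets))
      y$texture$offsets <- do.call(rbind, lapply(y$texture$offsets, unlist))
    args$texture <- do.call(textureConfig, y$texture)
  }
  if (!is.null(y$weights)) {
    checkKeys(y$weights, c("scheme", "bandDistance", "includeSelf"), "weights")
    args$weights <- do.call(spatialWeights, y$weights)
  }
  for (k in c("alpha", "agbHighThreshold", "sampleN", "screenThreshold",
              "folds", "seed", "outDir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(runConfig, args)
}

#' @rdname readRunConfig
#' @param config a \code{runConfig} to serialise.
#' @export
writeRunConfig <- function(config, path) {
  y <- list(
    scene = config$scene[setdiff(names(config$scene), NULL)],
    texture = list(levels = config$texture$levels,
                   window = config$texture$window,
                   symmetric = config$texture$symmetric,
                   features = config$texture$features,
                   firstOrder = config$texture$firstOrder),
    weights = list(scheme = config$weights@scheme,
                   bandDistance = config$weights@bandDistance,
                   includeSelf = config$weights@includeSelf),
    alpha = config$alpha, agbHighThreshold = config$agbHighThreshold,
    sampleN = config$sampleN, screenThreshold = config$screenThreshold,
    folds = config$folds, seed = config$seed, outDir = config$outDir)
  y$scene$rangeEffects <- as.list(config$scene$rangeEffects)
  yaml::write_yaml(y, path)
  invisible(path)
}

.stageNames <- c("generate", "calibrate", "texturize", "fit-agb", "richness",
                 "drivers", "congruence")

.configHash <- function(config) {
  ser <- jsonlite::serializeJSON(unclass(config))
  f <- tempfile()
  writeLines(as.character(ser), f)
  unname(tools::md5sum(f))
}

.log <- function(logFile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  cat(msg, "\n", file = logFile, append = TRUE)
}

# stage output manifests, relative to the run directory
.stageOutputs <- function(stage) {
  switch(stage,
    "generate" = file.path("scene", c("dem.asc", "landcover.asc", "hh_dn.asc",
      "hv_dn.asc", "agb_truth.asc", "global_agb.asc", "roads.geojson",
      "rivers.geojson", "plots.csv", "trees.csv", "ranges.geojson",
      "truth.json", "rainfall.asc", "temperature.asc", "seasonality.asc")),
    "calibrate" = c("hh_sigma0.asc", "hv_sigma0.asc", "rfdi.asc"),
    "texturize" = "texture/stack_layers.json",
    "fit-agb" = c("agb_pred.asc", "agb_local_1km.asc", "agb_fused_1km.asc",
                  "fusion_weight.asc", "agb_fit.json"),
    "richness" = c("richness_all.asc", "richness_iucn.asc",
                   "richness_endemic.asc", "pam.csv"),
    "drivers" = c("importance_iucn.csv", "importance_endemic.csv",
                  "pd_curves.csv", "sample.csv", "svr_iucn.json"),
    "congruence" = c("congruence_report.json", "agb_z.asc", "agb_classes.asc",
                     "iucn_z.asc", "iucn_classes.asc", "endemic_z.asc",
                     "endemic_classes.asc"))
}

#' Run the full synthetic study end-to-end
#'
#' Executes generate -> calibrate -> texturize -> fit-agb -> richness ->
#' drivers -> congruence, writing every intermediate artifact plus
#' \code{manifest.json} (config hash, seed, per-stage output checksums and
#' timings) and \code{run.log}. Stages are resumable: when a manifest from
#' an identical (config, seed) exists and a stage's outputs all match their
#' recorded checksums, the stage is skipped; deleting any output re-executes
#' only the stages that produced it. Any stage failure aborts with the stage
#' name and cause; partial outputs are retained.
#'
#' @param config a [runConfig()].
#' @param outDir output directory (defaults to \code{config$outDir}).
#' @return (invisibly) the manifest list.
#' @export
runAll <- function(config, outDir = config$outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  hash <- .configHash(config)
  manifestPath <- file.path(outDir, "manifest.json")
  prev <- NULL
  if (file.exists(manifestPath)) {
    prev <- tryCatch(jsonlite::read_json(manifestPath, simplifyVector = TRUE),
                     error = function(e) NULL)
    if (!is.null(prev) &&
        (!identical(prev$configHash, unname(hash)) ||
         !identical(as.integer(prev$seed), config$seed))) prev <- NULL
  }
  manifest <- list(configHash = unname(hash), seed = config$seed,
                   stages = list())
  for (stage in .stageNames) {
    outs <- .stageOutputs(stage)
    paths <- file.path(outDir, outs)
    resumable <- FALSE
    if (!is.null(prev) && stage %in% names(prev$stages)) {
      rec <- prev$stages[[stage]]
      if (all(file.exists(paths))) {
        sums <- unname(tools::md5sum(paths))
        resumable <- identical(sums, unname(unlist(rec$checksums)))
      }
    }
    if (resumable) {
      .log(logFile, "stage ", stage, ": outputs up to date, skipped")
      manifest$stages[[stage]] <- list(
        executed = FALSE, elapsed = 0,
        checksums = as.list(stats::setNames(unname(tools::md5sum(paths)), outs)))
      next
    }
    .log(logFile, "stage ", stage, ": running")
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ .runStageImpl(stage, config, outDir, logFile); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(ok))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("pipeline stage '", stage, "' did not produce: ",
           paste(basename(missing), collapse = ", "))
    elapsed <- proc.time()[["elapsed"]] - t0
    .log(logFile, "stage ", stage, sprintf(": done in %.1f s", elapsed))
    manifest$stages[[stage]] <- list(
      executed = TRUE, elapsed = elapsed,
      checksums = as.list(stats::setNames(unname(tools::md5sum(paths)), outs)))
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @describeIn runAll run one named stage standalone on the outputs already
#'   in \code{outDir}. Stages: generate, calibrate, texturize, fit-agb,
#'   richness, drivers, congruence.
#' @param stage stage name.
#' @export
runStage <- function(stage, config, outDir = config$outDir) {
  stage <- match.arg(stage, .stageNames)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .runStageImpl(stage, config, outDir, file.path(outDir, "run.log"))
  invisible(stage)
}

.needFile <- function(path, stage) {
  if (!file.exists(path))
    stop("stage '", stage, "' is missing input artifact: ", path)
  path
}

.runStageImpl <- function(stage, config, outDir, logFile) {
  p <- function(...) file.path(outDir, ...)
  seed <- config$seed
  switch(stage,
    "generate" = {
      sc <- generateScene(config$scene, p("scene"))
      bio <- makeBioclim(sc$dem, config$scene)
      writeGrid(bio$rainfall, p("scene", "rainfall.asc"))
      writeGrid(bio$temperature, p("scene", "temperature.asc"))
      writeGrid(bio$seasonality, p("scene", "seasonality.asc"))
    },
    "calibrate" = {
      hh <- readGrid(.needFile(p("scene", "hh_dn.asc"), stage))
      hv <- readGrid(.needFile(p("scene", "hv_dn.asc"), stage))
      hhS <- calibrateSigma0(leeFilter(hh, 3, config$scene$enl))
      hvS <- calibrateSigma0(leeFilter(hv, 3, config$scene$enl))
      writeGrid(hhS, p("hh_sigma0.asc"))
      writeGrid(hvS, p("hv_sigma0.asc"))
      writeGrid(rfdi(sarScene(hhS, hvS)), p("rfdi.asc"))
    },
    "texturize" = {
      dir.create(p("texture"), showWarnings = FALSE)
      nms <- character(0)
      for (band in c("hh", "hv")) {
        g <- readGrid(.needFile(p(paste0(band, "_sigma0.asc")), stage))
        st <- textureStack(g, config$texture, band)
        for (nm in names(st@layers)) {
          writeGrid(st@layers[[nm]], p("texture", paste0(nm, ".asc")))
          nms <- c(nms, nm)
        }
      }
      jsonlite::write_json(nms, p("texture", "stack_layers.json"))
    },
    "fit-agb" = {
      plots <- read.csv(.needFile(p("scene", "plots.csv"), stage))
      trees <- read.csv(.needFile(p("scene", "trees.csv"), stage))
      nms <- unlist(jsonlite::read_json(
        .needFile(p("texture", "stack_layers.json"), stage)))
      layers <- lapply(stats::setNames(nms, nms), function(nm)
        readGrid(p("texture", paste0(nm, ".asc"))))
      agbObs <- plotAgbTable(plots, trees)
      X <- extractAtPlots(layers, plots)
      keep <- screenPredictors(X, config$screenThreshold)
      fit <- rfFit(X[, keep, drop = FALSE], agbObs, folds = config$folds,
                   seed = seed + 40L)
      pred <- predictMap(fit, layers)
      writeGrid(pred, p("agb_pred.asc"))
      f <- round(1000 / pred@cellSize)
      local1k <- aggregateGrid(pred, f, "mean")
      glob <- readGrid(.needFile(p("scene", "global_agb.asc"), stage))
      fus <- fuseMaps(local1k, glob)
      writeGrid(local1k, p("agb_local_1km.asc"))
      writeGrid(fus$fused, p("agb_fused_1km.asc"))
      writeGrid(fus$weight, p("fusion_weight.asc"))
      m <- cvMetrics(fit)
      jsonlite::write_json(list(
        retainedPredictors = fit@retainedPredictors,
        cvMetrics = as.list(m), importance = as.list(fit@importance),
        tuning = fit@tuning[c("mtry", "ntree")]),
        p("agb_fit.json"), auto_unbox = TRUE, digits = NA)
    },
    "richness" = {
      ranges <- layerToRanges(readVector(
        .needFile(p("scene", "ranges.geojson"), stage)))
      template <- readGrid(.needFile(p("agb_fused_1km.asc"), stage))
      pam <- buildPam(ranges, template)
      writeGrid(richnessGrid(pam, "all"), p("richness_all.asc"))
      writeGrid(richnessGrid(pam, "iucn"), p("richness_iucn.asc"))
      writeGrid(richnessGrid(pam, "endemic"), p("richness_endemic.asc"))
      writePamCsv(pam, p("pam.csv"))
    },
    "drivers" = {
      template <- readGrid(.needFile(p("agb_fused_1km.asc"), stage))
      dem <- readGrid(.needFile(p("scene", "dem.asc"), stage))
      lc <- readGrid(.needFile(p("scene", "landcover.asc"), stage))
      sa <- slopeAspect(dem)
      roads <- readVector(.needFile(p("scene", "roads.geojson"), stage))
      rivers <- readVector(.needFile(p("scene", "rivers.geojson"), stage))
      layers <- list(
        agb = template,
        roadDistance = euclideanDistance(roads, template),
        riverDistance = euclideanDistance(rivers, template),
        elevation = dem, slope = sa$slope, aspect = sa$aspect,
        rfdi = readGrid(.needFile(p("rfdi.asc"), stage)),
        landscapeDiversity = landscapeDiversity(lc, 5),
        landscapeFragmentation = landscapeFragmentation(lc, 5),
        rainfall = readGrid(.needFile(p("scene", "rainfall.asc"), stage)),
        temperature = readGrid(.needFile(p("scene", "temperature.asc"), stage)),
        seasonality = readGrid(.needFile(p("scene", "seasonality.asc"), stage)))
      stack <- buildStack(layers, template)
      for (resp in c("iucn", "endemic")) {
        rich <- readGrid(.needFile(p(paste0("richness_", resp, ".asc")), stage))
        smp <- withCallingHandlers(
          sampleCells(stack, rich, config$sampleN, seed + 60L),
          warning = function(w) {
            .log(logFile, "drivers: ", conditionMessage(w))
            invokeRestart("muffleWarning")
          })
        imp <- rankImportance(smp)
        write.csv(data.frame(predictor = names(imp), score = as.numeric(imp),
                             rawR2 = as.numeric(attr(imp, "raw"))),
                  p(paste0("importance_", resp, ".csv")), row.names = FALSE)
        if (resp == "iucn") {
          svr <- svrFit(smp, folds = config$folds, seed = seed + 61L)
          jsonlite::write_json(list(cvR2 = svr$cvR2, best = svr$best),
                               p("svr_iucn.json"), auto_unbox = TRUE,
                               digits = NA)
          top <- head(names(imp), 3)
          pd <- do.call(rbind, lapply(top, function(nm) {
            cv <- partialDependence(smp, nm, seed = seed + 62L)
            cbind(predictor = nm, cv)
          }))
          write.csv(pd, p("pd_curves.csv"), row.names = FALSE)
          write.csv(cbind(cellId = smp$cells, smp$X, richness = smp$y),
                    p("sample.csv"), row.names = FALSE)
        }
      }
    },
    "congruence" = {
      agb <- readGrid(.needFile(p("agb_fused_1km.asc"), stage))
      iu <- readGrid(.needFile(p("richness_iucn.asc"), stage))
      en <- readGrid(.needFile(p("richness_endemic.asc"), stage))
      rep <- congruenceReport(agb, iu, en, config$weights, config$alpha,
                              config$agbHighThreshold)
      for (nm in names(rep@hotspots)) {
        nn <- sub("^agb$", "agb", nm)
        writeGrid(rep@hotspots[[nm]]@z, p(paste0(nn, "_z.asc")))
        writeGrid(rep@hotspots[[nm]]@classes, p(paste0(nn, "_classes.asc")))
      }
      jsonlite::write_json(list(
        agbHighThreshold = rep@agbHighThreshold,
        overlaps = rep@overlaps, correlations = rep@correlations),
        p("congruence_report.json"), dataframe = "rows", auto_unbox = TRUE,
        digits = NA)
    },
    stop("unknown stage: ", stage))
  invisible(TRUE)
}
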