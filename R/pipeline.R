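# End-to-end orchestration: preprocess -> pixel classification -> segment ->
# quantify -> gate -> niches/compartments -> clustering, with provenance.

writeJson <- function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE,
                                                    digits = NA)

#' Run the full analysis pipeline on a MELC run
#'
#' All stage randomness derives from `seed` via [stageSeed()], so a re-run
#' with the same inputs reproduces identical outputs.
#'
#' @param run A [MelcRun-class] (or a run directory readable by [readRun()]).
#' @param labels Pixel label mask (0/1/2/3) at the uncropped image shape used
#'   to train the pixel classifier; ignored when `classifier` is given.
#' @param classifier Optional pre-trained `pixelClassifier` (applied without
#'   retraining).
#' @param outDir Optional output directory; when given, corrected images,
#'   probability maps, label images, `cells.csv`, `niches.json`,
#'   `clusters.csv`, `heatmap.csv`, `embedding.csv`, `shifts.json` and
#'   `provenance.json` are written.
#' @param seed Integer global seed.
#' @param preprocess,segmentation,niche,clustering Stage parameter objects.
#' @param rules Gating rules; default [defaultGatingRules()] for the panel.
#' @param manualThresholds Optional named manual gating thresholds.
#' @param seedType Gated type seeding the niche analysis.
#' @param compartmentConfig Optional named list compartment -> markers for
#'   [segmentCompartments()].
#' @return List with `corrected`, `shifts`, `maps`, `nuclei`, `cells`,
#'   `table` (gated cell table), `counts`, `thresholds`, `niches`,
#'   `enrichment`, `structureProximity`, `compartments`, `clustering`
#'   (embedding, cluster ids, heatmap, agreement) and `classifier`.
#' @export
runPipeline <- function(run, labels = NULL, classifier = NULL, outDir = NULL,
                        seed = 1L,
                        preprocess = preprocessParams(),
                        segmentation = segmentationParams(),
                        niche = nicheParams(),
                        clustering = clusterParams(),
                        rules = NULL, manualThresholds = NULL,
                        seedType = "ILC", compartmentConfig = NULL) {
  if (is.character(run)) run <- readRun(run)
  stopifnot(is(run, "MelcRun"))
  if (is.null(classifier) && is.null(labels))
    stop("config error: either training labels or a classifier is required",
         call. = FALSE)
  if (is.null(rules)) rules <- defaultGatingRules(run@panel)
  if (length(rules) == 0L)
    stop("config error: empty gating rule set", call. = FALSE)
  pan <- run@panel

  pp <- preprocessRun(run, preprocess)
  corrected <- lapply(pp$images, function(x) x / 65535)
  cropMargin <- if (!is.null(preprocess$cropMarginPx)) preprocess$cropMarginPx
                else max(abs(pp$shifts))

  nuclearMarkers <- pan$name[pan$localization == "nuclear"]
  if (length(nuclearMarkers) == 0L)
    stop("config error: panel has no nuclear (DAPI-like) marker", call. = FALSE)
  dapi <- corrected[[nuclearMarkers[1]]]
  summem <- sumMembranes(corrected, pan)
  feats <- computePixelFeatures(list(dapi = dapi, summem = summem))

  if (is.null(classifier)) {
    lab <- labels
    if (cropMargin > 0 && all(dim(lab) == geometry(run)@imageShape))
      lab <- lab[(cropMargin + 1L):(nrow(lab) - cropMargin),
                 (cropMargin + 1L):(ncol(lab) - cropMargin)]
    classifier <- trainPixelClassifier(feats, lab,
                                       seed = stageSeed(seed, "classifier"))
  }
  maps <- predictProbabilityMaps(classifier, feats)

  nuclei <- segmentNuclei(maps, segmentation)
  cells <- segmentCells(nuclei, maps, segmentation)

  tab <- extractMFI(cells, corrected, pan, nuclei = nuclei,
                    geometry = geometry(run))
  th <- defaultThresholds(tab, manual = manualThresholds)
  tab <- gateCells(tab, th, rules)
  counts <- countTypes(tab)

  niches <- NULL; enrichment <- NULL
  if (seedType %in% tab$gated_type) {
    niches <- buildNiches(cells, tab, seedType, niche, geometry(run))
    if (length(niches)) enrichment <- nicheEnrichment(niches, tab, seedType)
  }

  structMarkers <- pan$name[pan$localization == "structure"]
  structProx <- NULL
  if (length(structMarkers) && seedType %in% tab$gated_type) {
    masks <- lapply(structMarkers, function(nm) {
      t0 <- otsuThreshold(as.vector(corrected[[nm]]))
      if (is.na(t0)) t0 <- 0.5
      corrected[[nm]] >= t0
    })
    names(masks) <- structMarkers
    structProx <- structureProximity(tab, masks, cells, seedType, niche,
                                     geometry(run))
  }

  compartments <- NULL
  if (!is.null(compartmentConfig)) {
    compartments <- segmentCompartments(corrected, compartmentConfig,
                                        geometry(run),
                                        thresholds = th$thresholds)
    ac <- assignCompartments(tab, compartments, seed_type = seedType)
    tab <- ac$table
    compartments$seedTypeDistribution <- ac$distribution
  }

  clusteringOut <- NULL
  n <- nrow(tab)
  if (n >= 30L) {
    cp <- clustering
    cp$seed <- stageSeed(seed, "clustering")
    if (3 * cp$perplexity >= n - 1)
      cp$perplexity <- max(2, floor((n - 2) / 3))
    mat <- transformExpression(tab, cp)
    emb <- embedTSNE(mat, cp)
    cl <- clusterCells(emb, k = "auto", seed = cp$seed)
    tab$cluster_id <- NA_integer_
    tab$cluster_id[attr(mat, "kept")] <- as.integer(cl)
    heat <- clusterHeatmap(tab[attr(mat, "kept"), , drop = FALSE], cl)
    agreement <- NULL
    if (seedType %in% tab$gated_type) {
      seedClusters <- cl[tab$gated_type[attr(mat, "kept")] == seedType]
      if (length(seedClusters)) {
        focus <- as.integer(names(sort(table(seedClusters),
                                       decreasing = TRUE))[1])
        agreement <- gateClusterAgreement(tab, focus, seedType,
                                          cluster_id = cl)
      }
    }
    clusteringOut <- list(embedding = emb, clusters = cl, heatmap = heat,
                          agreement = agreement)
  }

  res <- list(corrected = corrected, shifts = pp$shifts, fields = pp$fields,
              maps = maps, nuclei = nuclei, cells = cells, table = tab,
              counts = counts, thresholds = th, niches = niches,
              enrichment = enrichment, structureProximity = structProx,
              compartments = compartments, clustering = clusteringOut,
              classifier = classifier, cropMargin = cropMargin)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(corrected))
      writeImageTiff(corrected[[nm]],
                     file.path(outDir, sprintf("corrected_%s.tif", nm)))
    writeImageTiff(maps@nuc, file.path(outDir, "prob_nuclei.tif"))
    writeImageTiff(maps@mem, file.path(outDir, "prob_membrane.tif"))
    writeImageTiff(maps@ecm, file.path(outDir, "prob_ecm.tif"))
    writeImageTiff(nuclei, file.path(outDir, "nuclei_labels.tif"),
                   type = "label")
    writeImageTiff(cells, file.path(outDir, "cell_labels.tif"),
                   type = "label")
    writeCellTable(tab, file.path(outDir, "cells.csv"))
    writeJson(list(shifts = pp$shifts), file.path(outDir, "shifts.json"))
    if (!is.null(niches))
      writeJson(lapply(niches, function(nc)
        list(seed_cell_id = nc$seed_cell_id,
             member_cell_ids = nc$member_cell_ids,
             composition = as.list(nc$composition))),
        file.path(outDir, "niches.json"))
    if (!is.null(clusteringOut)) {
      utils::write.csv(data.frame(cell_id = names(clusteringOut$clusters),
                                  cluster = as.integer(clusteringOut$clusters)),
                       file.path(outDir, "clusters.csv"), row.names = FALSE)
      utils::write.csv(as.data.frame(clusteringOut$heatmap),
                       file.path(outDir, "heatmap.csv"))
      utils::write.csv(as.data.frame(clusteringOut$embedding),
                       file.path(outDir, "embedding.csv"))
    }
    prov <- list(package = "melcpipe",
                 version = as.character(utils::packageVersion("melcpipe")),
                 seed = seed,
                 parameters = list(preprocess = unclass(preprocess),
                                   segmentation = unclass(segmentation),
                                   niche = unclass(niche),
                                   clustering = unclass(clustering)),
                 timestamp = format(Sys.time(), tz = "UTC"))
    writeJson(prov, file.path(outDir, "provenance.json"))
  }
  res
}
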