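# Two-stage object segmentation: nuclei as primary objects from the nuclei
# probability map, cells as secondary objects grown from nucleus seeds
# against the membrane probability landscape.

#' Segmentation parameters
#'
#' @param nucProbThreshold Threshold on the nuclei probability map.
#' @param minNucleusPx,maxNucleusPx Size filter for primary objects.
#' @param maxCellExpansionPx Hard cap (pixels) on secondary-object growth
#'   beyond the nucleus boundary.
#' @param declump "distance_watershed" splits touching nuclei by a
#'   distance-transform watershed; "none" labels connected components.
#' @return A validated parameter list.
#' @export
segmentationParams <- function(nucProbThreshold = 0.5, minNucleusPx = 40L,
                               maxNucleusPx = 5000L, maxCellExpansionPx = 12L,
                               declump = c("distance_watershed", "none")) {
  declump <- match.arg(declump)
  stopifnot(nucProbThreshold > 0, nucProbThreshold < 1,
            minNucleusPx < maxNucleusPx, maxCellExpansionPx >= 0)
  structure(list(nucProbThreshold = nucProbThreshold,
                 minNucleusPx = as.integer(minNucleusPx),
                 maxNucleusPx = as.integer(maxNucleusPx),
                 maxCellExpansionPx = as.integer(maxCellExpansionPx),
                 declump = declump),
            class = "segmentationParams")
}

#' Segment nuclei (primary objects)
#'
#' Thresholds the nuclei probability map, optionally splits touching nuclei
#' by a watershed on the distance transform, and removes objects outside the
#' size band.
#'
#' @param p_nuc Nuclei probability map (matrix) or [ProbabilityMaps-class].
#' @param params [segmentationParams()].
#' @return Integer label image (0 = background).
#' @export
segmentNuclei <- function(p_nuc, params = segmentationParams()) {
  if (is(p_nuc, "ProbabilityMaps")) p_nuc <- p_nuc@nuc
  assertImage(p_nuc)
  mask <- p_nuc > params$nucProbThreshold
  if (!any(mask)) {
    warning("empty nuclei foreground; returning empty labeling")
    return(matrix(0L, nrow(p_nuc), ncol(p_nuc)))
  }
  if (params$declump == "distance_watershed") {
    dm <- EBImage::distmap(asImg(mask * 1))
    lab <- asMat(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    lab <- asMat(EBImage::bwlabel(asImg(mask * 1)))
  }
  storage.mode(lab) <- "integer"
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < params$minNucleusPx | sizes > params$maxNucleusPx)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab
}

#' Segment cells (secondary objects) from nucleus seeds
#'
#' Grows each nucleus against the membrane probability landscape in two
#' stages: (1) growth through sub-threshold membrane probability (< 0.5),
#' geodesically from the seeds and capped at `maxCellExpansionPx` beyond the
#' nucleus boundary; (2) annexation of the contiguous above-threshold
#' membrane band reachable from stage 1. Growth therefore stops at the far
#' edge of a membrane ridge and never descends past it into background;
#' with a flat zero membrane map it degenerates to an exact distance-capped
#' dilation truncated at neighbors' frontiers. Cell labels equal their seed
#' nucleus labels; every cell contains exactly its own nucleus.
#'
#' @param nuclei Integer nucleus label image.
#' @param p_mem Membrane probability map (matrix) or [ProbabilityMaps-class].
#' @param params [segmentationParams()].
#' @param memThreshold Ridge threshold on the membrane probability.
#' @return Integer cell label image.
#' @export
segmentCells <- function(nuclei, p_mem, params = segmentationParams(),
                         memThreshold = 0.5) {
  if (is(p_mem, "ProbabilityMaps")) p_mem <- p_mem@mem
  assertImage(p_mem)
  assertSameShape(nuclei, p_mem)
  if (!any(nuclei > 0L)) stop("no nucleus seeds", call. = FALSE)
  distToNuc <- distanceToMask(nuclei > 0L)
  capMask <- distToNuc <= params$maxCellExpansionPx
  interiorMask <- capMask & (p_mem < memThreshold | nuclei > 0L)
  lab1 <- asMat(EBImage::propagate(asImg(p_mem), asImg(nuclei),
                                   mask = asImg(interiorMask * 1)))
  bandMask <- (capMask & p_mem >= memThreshold) | lab1 > 0
  lab2 <- asMat(EBImage::propagate(asImg(p_mem), asImg(lab1),
                                   mask = asImg(bandMask * 1)))
  storage.mode(lab2) <- "integer"
  # guard: a nucleus pixel always keeps its own label
  lab2[nuclei > 0L] <- nuclei[nuclei > 0L]
  lab2
}

#' Object-level segmentation quality (precision / recall / F1)
#'
#' Objects are matched greedily by descending intersection-over-union; a
#' match counts if IoU >= `iou_threshold`.
#'
#' @param pred,truth Integer label images of one shape.
#' @param iou_threshold Matching threshold.
#' @return List with `precision`, `recall`, `f1`, `nPred`, `nTruth`,
#'   `nMatched`.
#' @export
segmentationQuality <- function(pred, truth, iou_threshold = 0.5) {
  assertSameShape(pred, truth)
  predIds <- sort(unique(pred[pred > 0L]))
  truthIds <- sort(unique(truth[truth > 0L]))
  nP <- length(predIds); nT <- length(truthIds)
  if (nP == 0L || nT == 0L)
    return(list(precision = if (nP == 0L) NA_real_ else 0,
                recall = 0, f1 = 0, nPred = nP, nTruth = nT, nMatched = 0L))
  both <- pred > 0L & truth > 0L
  ov <- table(factor(pred[both], levels = predIds),
              factor(truth[both], levels = truthIds))
  areaP <- tabulate(pred[pred > 0L], max(predIds))[predIds]
  areaT <- tabulate(truth[truth > 0L], max(truthIds))[truthIds]
  inter <- as.matrix(ov)
  uni <- outer(areaP, areaT, `+`) - inter
  iou <- inter / uni
  matched <- 0L
  while (TRUE) {
    m <- which.max(iou)
    if (iou[m] < iou_threshold || !is.finite(iou[m])) break
    i <- (m - 1L) %% nrow(iou) + 1L
    j <- (m - 1L) %/% nrow(iou) + 1L
    matched <- matched + 1L
    iou[i, ] <- -1; iou[, j] <- -1
  }
  precision <- matched / nP
  recall <- matched / nT
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       nPred = nP, nTruth = nT, nMatched = matched)
}
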