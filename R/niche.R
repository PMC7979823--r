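# 10 um niche analysis, distance-to-structure frequencies and tissue
# compartment segmentation/assignment.

#' Niche parameters
#'
#' @param radiusUm Niche radius around each seed cell (10 um, the average
#'   immune cell diameter).
#' @param membership "centroid_in_region" counts a neighbor if its centroid
#'   pixel lies in the niche region; "any_overlap" if any of its pixels does.
#' @param structureDistanceUm Distance band for structure proximity.
#' @return A validated parameter list.
#' @export
nicheParams <- function(radiusUm = 10.0,
                        membership = c("centroid_in_region", "any_overlap"),
                        structureDistanceUm = 10.0) {
  stopifnot(radiusUm > 0, structureDistanceUm > 0)
  structure(list(radiusUm = radiusUm, membership = match.arg(membership),
                 structureDistanceUm = structureDistanceUm),
            class = "nicheParams")
}

centroidPixelIndex <- function(table, dims) {
  r <- pmin(pmax(round(table$centroid_row_px) + 1L, 1L), dims[1])
  c_ <- pmin(pmax(round(table$centroid_col_px) + 1L, 1L), dims[2])
  cbind(r, c_)
}

#' Build niches around seed cells
#'
#' The niche region of a seed is the Euclidean dilation of the seed cell's
#' pixel mask by `radius_px = round(radiusUm / pixel_pitch)` (31 px at
#' 0.325 um/px for 10 um): every pixel within that distance of the mask.
#' Composition tallies the gated types of member cells (seed excluded) under
#' the configured membership rule; the boundary is inclusive.
#'
#' @param cells Integer cell label image.
#' @param table Gated cell table.
#' @param seed_type Gated type whose cells seed the niches (e.g. "ILC").
#' @param params [nicheParams()].
#' @param geometry [AcquisitionGeometry-class].
#' @return List of niche records: `seed_cell_id`, `region` (logical mask),
#'   `member_cell_ids`, `composition` (named counts over gated types).
#' @export
buildNiches <- function(cells, table, seed_type, params = nicheParams(),
                        geometry) {
  if (is.null(table$gated_type)) stop("table is not gated", call. = FALSE)
  if (!seed_type %in% table$gated_type) {
    if (!seed_type %in% c(table$gated_type, "others"))
      stop("unknown seed_type: ", seed_type, call. = FALSE)
    warning("no cells of seed_type '", seed_type, "'; returning empty list")
    return(list())
  }
  radiusPx <- round(params$radiusUm / geometry@pixelPitchUm)
  seeds <- table$cell_id[table$gated_type == seed_type]
  allTypes <- sort(unique(table$gated_type))
  centPix <- centroidPixelIndex(table, dim(cells))
  lapply(seeds, function(sid) {
    region <- distanceToMask(cells == sid) <= radiusPx
    others <- table$cell_id != sid
    if (params$membership == "centroid_in_region") {
      inside <- region[centPix] & others
    } else {
      memberIds <- setdiff(unique(cells[region & cells > 0L]), c(0L, sid))
      inside <- table$cell_id %in% memberIds
    }
    members <- table$cell_id[inside]
    comp <- table(factor(table$gated_type[inside], levels = allTypes))
    list(seed_cell_id = sid, region = region, member_cell_ids = members,
         composition = stats::setNames(as.integer(comp), allTypes))
  })
}

#' Niche vs whole-tissue type frequencies
#'
#' @param niches Output of [buildNiches()].
#' @param table Gated cell table.
#' @param seed_type Seed type (its cells are excluded from the whole-tissue
#'   reference distribution).
#' @return `data.frame` per type: `whole_tissue_freq`, `niche_freq`,
#'   `per_niche_mean_count`; both frequency columns sum to 1.
#' @export
nicheEnrichment <- function(niches, table, seed_type = NULL) {
  if (length(niches) == 0L) stop("need at least one niche", call. = FALSE)
  pooled <- Reduce(`+`, lapply(niches, `[[`, "composition"))
  seedIds <- sapply(niches, `[[`, "seed_cell_id")
  ref <- table[!(table$cell_id %in% seedIds), , drop = FALSE]
  refCounts <- table(factor(ref$gated_type, levels = names(pooled)))
  data.frame(type = names(pooled),
             whole_tissue_freq = as.numeric(refCounts) / sum(refCounts),
             niche_freq = if (sum(pooled) > 0) as.numeric(pooled) / sum(pooled)
                          else rep(0, length(pooled)),
             per_niche_mean_count = as.numeric(pooled) / length(niches),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of seed-type cells within a distance of each structure
#'
#' Per cell, the minimum Euclidean distance from any pixel of the cell mask
#' to the structure mask (via distance transform), converted to micrometers.
#'
#' @param table Gated cell table.
#' @param structure_masks Named list of logical masks (e.g. vessel, fiber).
#' @param cells Integer cell label image.
#' @param seed_type Gated type to evaluate (e.g. "ILC").
#' @param params [nicheParams()]; uses `structureDistanceUm`.
#' @param geometry [AcquisitionGeometry-class].
#' @return Named numeric: per structure, the fraction of seed-type cells
#'   whose distance is `<= structureDistanceUm` (inclusive).
#' @export
structureProximity <- function(table, structure_masks, cells, seed_type,
                               params = nicheParams(), geometry) {
  seedIds <- table$cell_id[table$gated_type == seed_type]
  out <- stats::setNames(numeric(length(structure_masks)),
                         names(structure_masks))
  for (nm in names(structure_masks)) {
    mask <- structure_masks[[nm]]
    assertSameShape(mask, cells)
    if (!any(mask)) {
      warning("structure mask '", nm, "' is empty; fraction 0")
      out[nm] <- 0
      next
    }
    d <- distanceToMask(mask) * geometry@pixelPitchUm
    minD <- vapply(seedIds, function(id) min(d[cells == id]), 0)
    out[nm] <- mean(minD <= params$structureDistanceUm)
  }
  out
}

#' Segment tissue compartments from smoothed marker scores
#'
#' Each compartment is defined by a set of markers; its score is the
#' Gaussian-smoothed (sigma 20 um) sum of the binarized marker images. Every
#' pixel is assigned to the argmax compartment where the best score exceeds
#' `floor`, else left unassigned (0). A `follicle_border` band of width
#' `borderUm` is carved out of non-follicle pixels adjacent to the follicle
#' compartment when a compartment named "follicle" exists.
#'
#' @param corrected Named list marker -> 2D image in [0,1].
#' @param config Named list compartment -> character vector of markers.
#' @param geometry [AcquisitionGeometry-class].
#' @param thresholds Optional named per-marker binarization thresholds;
#'   markers missing from it are binarized by Otsu.
#' @param smoothSigmaUm Smoothing sigma in micrometers.
#' @param floor Minimum smoothed score for assignment.
#' @param borderUm Width of the follicle border band.
#' @return List with `labels` (integer matrix, 0 = unassigned) and `names`
#'   (compartment name per label).
#' @export
segmentCompartments <- function(corrected, config, geometry,
                                thresholds = NULL, smoothSigmaUm = 20,
                                floor = 0.1, borderUm = 10) {
  if (any(vapply(config, length, 1L) == 0L))
    stop("config error: compartment with no defining markers", call. = FALSE)
  miss <- setdiff(unique(unlist(config)), names(corrected))
  if (length(miss))
    stop("config error: compartment marker(s) not in corrected images: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sigmaPx <- smoothSigmaUm / geometry@pixelPitchUm
  dims <- dim(corrected[[config[[1]][1]]])
  binarize <- function(nm) {
    img <- corrected[[nm]]
    t0 <- if (!is.null(thresholds) && nm %in% names(thresholds))
      thresholds[nm] else otsuThreshold(as.vector(img))
    if (is.na(t0)) t0 <- 0.5
    (img >= t0) * 1
  }
  scores <- lapply(config, function(markers) {
    s <- Reduce(`+`, lapply(markers, binarize))
    asMat(EBImage::gblur(asImg(s), sigmaPx))
  })
  scoreArr <- array(unlist(scores), dim = c(dims, length(scores)))
  best <- apply(scoreArr, 3, identity)  # npix x k
  dim(best) <- c(prod(dims), length(scores))
  top <- max.col(best, ties.method = "first")
  topVal <- best[cbind(seq_len(nrow(best)), top)]
  lab <- ifelse(topVal >= floor, top, 0L)
  lab <- matrix(as.integer(lab), dims[1], dims[2])
  compNames <- names(config)
  if ("follicle" %in% compNames) {
    fol <- lab == which(compNames == "follicle")
    if (any(fol)) {
      borderPx <- round(borderUm / geometry@pixelPitchUm)
      band <- distanceToMask(fol) <= borderPx & !fol
      lab[band] <- length(compNames) + 1L
      compNames <- c(compNames, "follicle_border")
    }
  }
  list(labels = lab, names = compNames)
}

#' Assign cells to compartments by centroid
#'
#' @param table Cell table.
#' @param comp Compartment map from [segmentCompartments()].
#' @param seed_type Optional type for which a per-compartment distribution is
#'   returned (over assigned cells only).
#' @return List with `table` (compartment column filled; unassigned pixels
#'   give "unassigned") and, when `seed_type` is given, `distribution`
#'   (named frequencies summing to 1 over assigned seed-type cells).
#' @export
assignCompartments <- function(table, comp, seed_type = NULL) {
  idx <- centroidPixelIndex(table, dim(comp$labels))
  labv <- comp$labels[idx]
  table$compartment <- ifelse(labv == 0L, "unassigned", comp$names[labv])
  out <- list(table = table)
  if (!is.null(seed_type)) {
    sel <- table$compartment[table$gated_type == seed_type &
                               table$compartment != "unassigned"]
    d <- table(factor(sel, levels = comp$names))
    out$distribution <- if (length(sel))
      stats::setNames(as.numeric(d) / length(sel), comp$names)
    else stats::setNames(rep(NA_real_, length(comp$names)), comp$names)
  }
  out
}
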