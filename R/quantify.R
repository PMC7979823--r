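# Per-cell MFI extraction and flow-cytometry-like threshold gating.

#' Extract per-cell mean fluorescence intensities
#'
#' Nuclear-localized markers are averaged over the cell's nucleus mask,
#' membrane/structure markers over the whole cell mask. Centroids are
#' reported 0-based so that micrometer coordinates are
#' `centroid_px * pixel_pitch_um`.
#'
#' @param cells Integer cell label image.
#' @param corrected Named list marker -> 2D image, intensities in [0,1].
#' @param panel Marker panel.
#' @param nuclei Integer nucleus label image (labels match `cells`); required
#'   when the panel has nuclear markers.
#' @param geometry [AcquisitionGeometry-class] for micrometer coordinates.
#' @return Cell table `data.frame`: `cell_id`, centroids (px and um),
#'   `area_px`, one `mfi_<marker>` column per panel marker.
#' @export
extractMFI <- function(cells, corrected, panel, nuclei = NULL,
                       geometry = NULL) {
  validatePanel(panel)
  miss <- setdiff(panel$name, names(corrected))
  if (length(miss))
    stop("marker image missing: ", paste(miss, collapse = ", "), call. = FALSE)
  for (nm in panel$name) {
    assertSameShape(cells, corrected[[nm]])
    rng <- range(corrected[[nm]])
    if (rng[1] < 0 || rng[2] > 1 + 1e-9)
      stop("marker image '", nm, "' must be scaled to [0,1]", call. = FALSE)
  }
  ids <- sort(unique(cells[cells > 0L]))
  if (length(ids) == 0L) stop("no cells in label image", call. = FALSE)
  pitch <- if (is.null(geometry)) NA_real_ else geometry@pixelPitchUm

  cellPix <- which(cells > 0L)
  cellLab <- cells[cellPix]
  nr <- nrow(cells)
  rowIdx <- (cellPix - 1L) %% nr       # 0-based row
  colIdx <- (cellPix - 1L) %/% nr      # 0-based col
  areas <- as.vector(rowsum(rep(1L, length(cellPix)), cellLab))
  centR <- as.vector(rowsum(rowIdx, cellLab)) / areas
  centC <- as.vector(rowsum(colIdx, cellLab)) / areas

  needNuc <- any(panel$localization == "nuclear")
  if (needNuc) {
    if (is.null(nuclei))
      stop("nucleus labels required for nuclear-localized markers", call. = FALSE)
    nucPix <- which(nuclei > 0L)
    nucLab <- nuclei[nucPix]
    nucAreas <- rep(0L, length(ids))
    ta <- rowsum(rep(1L, length(nucPix)), nucLab)
    nucAreas[match(as.integer(rownames(ta)), ids)] <- as.vector(ta)
    if (any(nucAreas == 0L))
      stop("zero-area nucleus for cell(s): ",
           paste(ids[nucAreas == 0L], collapse = ", "), call. = FALSE)
  }

  tab <- data.frame(cell_id = ids,
                    centroid_row_px = centR, centroid_col_px = centC,
                    centroid_y_um = centR * pitch, centroid_x_um = centC * pitch,
                    area_px = as.integer(areas))
  for (j in seq_len(nrow(panel))) {
    nm <- panel$name[j]
    img <- corrected[[nm]]
    if (panel$localization[j] == "nuclear") {
      s <- rowsum(img[nucPix], nucLab)
      mfi <- rep(0, length(ids))
      mfi[match(as.integer(rownames(s)), ids)] <-
        as.vector(s) / nucAreas[match(as.integer(rownames(s)), ids)]
    } else {
      mfi <- as.vector(rowsum(img[cellPix], cellLab)) / areas
    }
    tab[[paste0("mfi_", nm)]] <- mfi
  }
  tab
}

#' Default per-marker gating thresholds (Otsu on the MFI distribution)
#'
#' For each marker an Otsu threshold is computed on the per-cell MFI
#' distribution over a 256-bin histogram, clipped to [0.05, 0.95]. Manual
#' overrides replace the defaults verbatim.
#'
#' @param table Cell table from [extractMFI()] (>= 20 cells).
#' @param markers Marker names; default = all `mfi_` columns.
#' @param manual Named numeric vector of manual thresholds.
#' @return List with `thresholds` (named numeric) and `provenance`
#'   (named character: "otsu_default" or "manual").
#' @export
defaultThresholds <- function(table, markers = NULL, manual = NULL) {
  if (nrow(table) < 20L)
    stop("need >= 20 cells to estimate thresholds", call. = FALSE)
  if (is.null(markers))
    markers <- sub("^mfi_", "", grep("^mfi_", names(table), value = TRUE))
  th <- stats::setNames(numeric(length(markers)), markers)
  prov <- stats::setNames(rep("otsu_default", length(markers)), markers)
  for (m in markers) {
    x <- table[[paste0("mfi_", m)]]
    if (is.null(x)) stop("no MFI column for marker ", m, call. = FALSE)
    t0 <- otsuThreshold(x)
    if (is.na(t0)) {
      warning("marker ", m, " has a degenerate MFI distribution; threshold 0.5")
      t0 <- 0.5
    }
    th[m] <- min(max(t0, 0.05), 0.95)
  }
  if (!is.null(manual)) {
    bad <- setdiff(names(manual), markers)
    if (length(bad)) stop("manual threshold for unknown marker: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    th[names(manual)] <- manual
    prov[names(manual)] <- "manual"
  }
  list(thresholds = th, provenance = prov)
}

#' Read gating rules from YAML
#'
#' Each rule carries `type`, `priority` (lower evaluates first),
#' `requires_positive`, `requires_negative` and optionally `any_of` — a list
#' of disjunctive clauses, each clause a list of `{marker, sign}` conjuncts
#' (sign "+" or "-").
#'
#' @param path YAML file with a top-level `rules:` list.
#' @return List of gating rules sorted by priority.
#' @export
readGatingRules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$rules)) stop("config error: no 'rules' list in ", path,
                             call. = FALSE)
  rules <- lapply(y$rules, function(r) {
    list(type = as.character(r$type), priority = as.integer(r$priority),
         requires_positive = as.character(unlist(r$requires_positive)),
         requires_negative = as.character(unlist(r$requires_negative)),
         any_of = r$any_of)
  })
  pr <- vapply(rules, `[[`, 1L, "priority")
  if (anyDuplicated(pr)) stop("config error: rule priorities must be unique",
                              call. = FALSE)
  rules[order(pr)]
}

#' Default tonsil gating rule set
#'
#' ILC = Lin-CD45+CD127+ (Lin restricted to the lineage-exclusion markers
#' present in the panel), B = CD45+CD19+, T helper = CD45+CD3+CD4+,
#' cytotoxic T = CD45+CD3+CD8+, plasma = CD138+, myeloid = CD14+ (plus any
#' further panel lineage markers via `any_of`), endothelial = CD31+;
#' anything else falls through to "others".
#'
#' @param panel Marker panel; rules referencing absent markers are trimmed.
#' @return List of gating rules sorted by priority.
#' @export
defaultGatingRules <- function(panel) {
  path <- system.file("extdata", "rules_tonsil.yaml", package = "melcpipe")
  rules <- readGatingRules(path)
  rules <- lapply(rules, function(r) {
    # markers never stained in this run cannot be gated on: trim negatives
    # and unsatisfiable any_of clauses; a missing required positive drops
    # the whole rule
    r$requires_negative <- intersect(r$requires_negative, panel$name)
    if (!is.null(r$any_of)) {
      ok <- vapply(r$any_of, function(clause)
        all(vapply(clause, function(t) t$marker %in% panel$name, NA)), NA)
      hadClauses <- length(r$any_of) > 0
      r$any_of <- r$any_of[ok]
      if (hadClauses && length(r$any_of) == 0L) return(NULL)
    }
    if (!all(r$requires_positive %in% panel$name)) return(NULL)
    r
  })
  rules[!vapply(rules, is.null, NA)]
}

ruleMarkers <- function(rule) {
  m <- c(rule$requires_positive, rule$requires_negative)
  for (clause in rule$any_of)
    m <- c(m, vapply(clause, function(t) as.character(t$marker), ""))
  unique(m)
}

#' Gate cells into types by thresholded marker positivity
#'
#' MFIs are binarized as positive iff `mfi >= threshold`; rules are
#' evaluated in priority order and the first satisfied rule assigns the
#' type; unmatched cells become "others".
#'
#' @param table Cell table with `mfi_` columns.
#' @param thresholds Output of [defaultThresholds()] or a named numeric
#'   vector of thresholds.
#' @param rules Gating rules (see [readGatingRules()]).
#' @return The table with a `gated_type` column filled.
#' @export
gateCells <- function(table, thresholds, rules) {
  if (is.list(thresholds) && !is.null(thresholds$thresholds))
    thresholds <- thresholds$thresholds
  used <- unique(unlist(lapply(rules, ruleMarkers)))
  missTh <- setdiff(used, names(thresholds))
  if (length(missTh))
    stop("config error: no threshold for marker(s): ",
         paste(missTh, collapse = ", "), call. = FALSE)
  missCol <- setdiff(paste0("mfi_", used), names(table))
  if (length(missCol))
    stop("config error: rule references unknown marker column(s): ",
         paste(missCol, collapse = ", "), call. = FALSE)
  pos <- sapply(used, function(m)
    table[[paste0("mfi_", m)]] >= thresholds[m])
  if (nrow(table) == 1L) pos <- matrix(pos, nrow = 1L, dimnames = list(NULL, used))
  type <- rep("others", nrow(table))
  unassigned <- rep(TRUE, nrow(table))
  for (r in rules) {
    ok <- unassigned
    for (m in r$requires_positive) ok <- ok & pos[, m]
    for (m in r$requires_negative) ok <- ok & !pos[, m]
    if (!is.null(r$any_of) && length(r$any_of)) {
      any_ok <- rep(FALSE, nrow(table))
      for (clause in r$any_of) {
        cl <- rep(TRUE, nrow(table))
        for (t in clause) {
          cl <- cl & if (identical(t$sign, "-")) !pos[, t$marker] else pos[, t$marker]
        }
        any_ok <- any_ok | cl
      }
      ok <- ok & any_ok
    }
    type[ok] <- r$type
    unassigned <- unassigned & !ok
  }
  table$gated_type <- type
  table
}

#' Count gated cell types
#'
#' @param table Gated cell table.
#' @return `data.frame` with `type`, `count`, `frequency` (sums to 1),
#'   including "others".
#' @export
countTypes <- function(table) {
  if (is.null(table$gated_type)) stop("table is not gated", call. = FALSE)
  tb <- table(table$gated_type)
  data.frame(type = names(tb), count = as.integer(tb),
             frequency = as.numeric(tb) / nrow(table),
             stringsAsFactors = FALSE, row.names = NULL)
}
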