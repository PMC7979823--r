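# Readers/writers for runs, images and cell tables.
#
# On-disk layout of a run directory (overridable via manifest.json):
#   manifest.json                         geometry + intensity scale
#   panel.yaml                            marker panel
#   reference_phase.tif                   2D reference image
#   blank_{CHANNEL}.tif                   pre-run blank stack per channel
#   cycle{NN}_{CHANNEL}_fluo.tif          per-cycle stain stack
#   cycle{NN}_{CHANNEL}_bleach.tif        per-cycle post-bleach stack
#   cycle{NN}_{CHANNEL}_secondary.tif     optional secondary-only stack
# Stacks are 16-bit multi-page TIFFs; intensities are stored as
# value / intensity_scale so the native float scale round-trips.

stackFileName <- function(cycle, channel, kind)
  sprintf("cycle%02d_%s_%s.tif", cycle, gsub("-", "", channel), kind)

#' Write a 2D image or label/probability map as TIFF
#'
#' @param img Numeric matrix.
#' @param path Output file.
#' @param type "uint16" quantizes [0,1] intensities to 16 bits; "float"
#'   stores 32-bit floats in [0,1] (probability maps); "label" stores
#'   integer labels up to 65535 exactly in a 16-bit image.
#' @return `path`, invisibly.
#' @export
writeImageTiff <- function(img, path, type = c("float", "uint16", "label")) {
  type <- match.arg(type)
  if (type == "label") {
    if (max(img) > 65535L) stop("labels above 65535 are not storable",
                                call. = FALSE)
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  } else if (type == "uint16") {
    tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(pmin(pmax(matrix(as.numeric(img), nrow(img)), 0), 1),
                    path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Read a 2D TIFF written by [writeImageTiff()]
#' @param path TIFF file.
#' @param type Storage type used when writing; "label" restores exact
#'   integer labels.
#' @return Numeric (or integer) matrix.
#' @export
readImageTiff <- function(path, type = c("float", "uint16", "label")) {
  type <- match.arg(type)
  x <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  if (type == "label") x <- matrix(as.integer(round(x * 65535)), nrow(x))
  x
}

writeStackTiff <- function(stack, path, scale) {
  planes <- lapply(seq_len(dim(stack)[3]),
                   function(k) pmin(pmax(stack[, , k] / scale, 0), 1))
  tiff::writeTIFF(planes, path, bits.per.sample = 16L)
  invisible(path)
}

readStackTiff <- function(path, scale) {
  planes <- tiff::readTIFF(path, all = TRUE)
  planes <- lapply(planes, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(planes), dim = c(dim(planes[[1]]), length(planes))) * scale
}

#' Read a marker panel from YAML
#'
#' @param path YAML file with a top-level `markers:` list; each entry carries
#'   `name`, `cycle`, `channel`, `localization` and optionally `gating_role`
#'   and `uses_secondary`.
#' @return A validated panel `data.frame`.
#' @export
readPanel <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$markers)) stop("panel config error: no 'markers' list in ", path,
                               call. = FALSE)
  g <- function(m, f, d) if (is.null(m[[f]])) d else m[[f]]
  markerPanel(
    name = vapply(y$markers, function(m) as.character(m$name), ""),
    cycle = vapply(y$markers, function(m) as.integer(m$cycle), 1L),
    channel = vapply(y$markers, function(m) as.character(m$channel), ""),
    localization = vapply(y$markers, function(m) as.character(m$localization), ""),
    gating_role = vapply(y$markers, function(m) as.character(g(m, "gating_role", "exploratory")), ""),
    uses_secondary = vapply(y$markers, function(m) as.logical(g(m, "uses_secondary", FALSE)), NA))
}

#' Write a marker panel to YAML
#' @param panel Panel `data.frame`.
#' @param path Output YAML file.
#' @return `path`, invisibly.
#' @export
writePanel <- function(panel, path) {
  validatePanel(panel)
  yaml::write_yaml(list(markers = lapply(seq_len(nrow(panel)), function(i)
    as.list(panel[i, , drop = FALSE]))), path)
  invisible(path)
}

#' Write a MelcRun to a run directory
#'
#' @param run A [MelcRun-class].
#' @param path Directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "MelcRun"))
  validObject(run)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- run@geometry
  scale <- max(1, run@reference,
               vapply(run@cycles, function(cy)
                 max(vapply(cy$fluo, max, 0), vapply(cy$bleach, max, 0)),
                 0),
               vapply(run@blank, max, 0))
  manifest <- list(image_shape = g@imageShape, pixel_pitch_um = g@pixelPitchUm,
                   z_steps = g@zSteps, z_step_um = g@zStepUm,
                   max_shift_px = g@maxShiftPx, intensity_scale = scale,
                   blank_channels = names(run@blank))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writePanel(run@panel, file.path(path, "panel.yaml"))
  tiff::writeTIFF(pmin(pmax(run@reference / scale, 0), 1),
                  file.path(path, "reference_phase.tif"), bits.per.sample = 16L)
  for (ch in names(run@blank))
    writeStackTiff(run@blank[[ch]],
                   file.path(path, sprintf("blank_%s.tif", gsub("-", "", ch))),
                   scale)
  for (cy in run@cycles) {
    if (!is.null(cy$phase))
      tiff::writeTIFF(pmin(pmax(cy$phase / scale, 0), 1),
                      file.path(path, sprintf("cycle%02d_phase.tif", cy$cycle)),
                      bits.per.sample = 16L)
    for (nm in names(cy$fluo)) {
      ch <- run@panel$channel[run@panel$name == nm]
      writeStackTiff(cy$fluo[[nm]],
                     file.path(path, stackFileName(cy$cycle, ch, "fluo")), scale)
      writeStackTiff(cy$bleach[[nm]],
                     file.path(path, stackFileName(cy$cycle, ch, "bleach")), scale)
      if (!is.null(cy$secondary[[nm]]))
        writeStackTiff(cy$secondary[[nm]],
                       file.path(path, stackFileName(cy$cycle, ch, "secondary")),
                       scale)
    }
  }
  invisible(path)
}

#' Read a MelcRun from a run directory
#'
#' @param path Run directory written by [writeRun()] (or following the same
#'   layout).
#' @param panel_config Optional path to a panel YAML; defaults to
#'   `panel.yaml` inside `path`.
#' @return A validated [MelcRun-class].
#' @export
readRun <- function(path, panel_config = file.path(path, "panel.yaml")) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("load error: no manifest.json in ", path, call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  pan <- readPanel(panel_config)
  geom <- acquisitionGeometry(imageShape = manifest$image_shape,
                              pixelPitchUm = manifest$pixel_pitch_um,
                              zSteps = manifest$z_steps,
                              zStepUm = manifest$z_step_um,
                              maxShiftPx = manifest$max_shift_px)
  scale <- manifest$intensity_scale
  refFile <- file.path(path, "reference_phase.tif")
  if (!file.exists(refFile)) stop("load error: missing reference_phase.tif",
                                  call. = FALSE)
  reference <- readImageTiff(refFile) * scale
  blank <- list()
  for (ch in manifest$blank_channels) {
    f <- file.path(path, sprintf("blank_%s.tif", gsub("-", "", ch)))
    if (!file.exists(f)) stop("load error: missing blank stack for channel ", ch,
                              call. = FALSE)
    blank[[ch]] <- readStackTiff(f, scale)
  }
  cyc <- sort(unique(pan$cycle))
  firstCycleOfChannel <- vapply(pan$channel, function(ch)
    min(pan$cycle[pan$channel == ch]), 1L)
  names(firstCycleOfChannel) <- pan$name
  cycles <- lapply(cyc, function(ci) {
    rows <- which(pan$cycle == ci)
    fluo <- list(); bl <- list(); sec <- list()
    for (r in rows) {
      nm <- pan$name[r]; ch <- pan$channel[r]
      ff <- file.path(path, stackFileName(ci, ch, "fluo"))
      if (!file.exists(ff))
        stop(sprintf("load error: cycle %d (%s): missing fluorescence stack %s",
                     ci, nm, basename(ff)), call. = FALSE)
      fluo[[nm]] <- readStackTiff(ff, scale)
      bf <- file.path(path, stackFileName(ci, ch, "bleach"))
      if (file.exists(bf)) {
        bl[[nm]] <- readStackTiff(bf, scale)
      } else if (ci == firstCycleOfChannel[nm] && !is.null(blank[[ch]])) {
        bl[[nm]] <- blank[[ch]]
      } else {
        stop(sprintf("load error: cycle %d (%s): missing bleach stack %s",
                     ci, nm, basename(bf)), call. = FALSE)
      }
      sf <- file.path(path, stackFileName(ci, ch, "secondary"))
      if (pan$uses_secondary[r]) {
        if (!file.exists(sf))
          stop(sprintf("load error: cycle %d (%s): marker flagged uses_secondary but %s missing",
                       ci, nm, basename(sf)), call. = FALSE)
        sec[[nm]] <- readStackTiff(sf, scale)
      }
    }
    pf <- file.path(path, sprintf("cycle%02d_phase.tif", ci))
    phase <- if (file.exists(pf)) readImageTiff(pf) * scale else NULL
    list(cycle = ci, phase = phase, fluo = fluo, bleach = bl, secondary = sec)
  })
  run <- new("MelcRun", reference = reference, cycles = cycles, blank = blank,
             panel = pan, geometry = geom)
  validObject(run)
  run
}

#' Write a cell table to CSV
#'
#' Column order is stable: `cell_id`, centroid columns, `area_px`, one
#' `mfi_<marker>` column per panel marker (panel order), `gated_type`,
#' `compartment`, `cluster_id`.
#'
#' @param table Cell table `data.frame` from [extractMFI()] and downstream.
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
writeCellTable <- function(table, path) {
  fixed <- c("cell_id", "centroid_row_px", "centroid_col_px",
             "centroid_y_um", "centroid_x_um", "area_px")
  mfiCols <- grep("^mfi_", names(table), value = TRUE)
  trail <- intersect(c("gated_type", "compartment", "cluster_id"), names(table))
  cols <- c(intersect(fixed, names(table)), mfiCols, trail)
  utils::write.csv(table[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table written by [writeCellTable()]
#' @param path CSV file.
#' @return A `data.frame`.
#' @export
readCellTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
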