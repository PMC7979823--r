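# Synthetic miniature MELC runs with full ground truth.
#
# Cells are rendered as disks: a nuclear disk carrying nuclear markers and a
# membrane shell (nucleus edge -> cell edge) carrying membrane markers.
# Structure markers render on smooth vessel/fiber curves. The acquisition
# model per marker m in channel ch of cycle i is
#
#   fluo_i  = illum * shift_i( blur_z(S_m + R_ch) + af ) + noise
#   bleach_i= illum * shift_i( blur_z(rho*(S_m + R_ch)) + af ) + noise
#
# where S_m is the noiseless marker scene, R_ch the residual signal carried
# over in that channel (R' = rho*(S + R)), af flat autofluorescence, illum a
# fixed camera-side vignette and shift_i the integer stage displacement of
# cycle i. The pre-run blank is illum * af + noise at zero shift. Subtracting
# the previous same-channel bleach from a registered stain image therefore
# recovers illum * S_m exactly in the noiseless limit.

#' Construct a SceneSpec
#'
#' @param imageShape Integer `(rows, cols)`.
#' @param nCells Number of cells.
#' @param typeNames,typeFreqs Cell types and their frequencies (sum to 1).
#' @param expression Matrix types x markers, mean intensities in [0,1].
#' @param panel Marker panel (see [markerPanel()]).
#' @param nucleusRadiusUm,cellRadiusUm Disk radii in micrometers.
#' @param illuminationAmplitude Vignette amplitude (0 = flat field).
#' @param autofluorescence Flat autofluorescence level.
#' @param bleachResidual Signal fraction surviving photobleaching, in [0,1).
#' @param stageShifts Integer matrix cycles x 2; NULL draws them uniformly in
#'   `[-maxShiftPx, maxShiftPx]` from `seed`.
#' @param defocusSigmaPerZ Blur sigma (px) per |z| plane.
#' @param noiseSd Additive Gaussian noise sd.
#' @param seed Integer seed.
#' @param geometry [AcquisitionGeometry-class]; default derives from
#'   `imageShape` with 0.325 um pixels.
#' @return A validated [SceneSpec-class].
#' @export
sceneSpec <- function(imageShape, nCells, typeNames, typeFreqs, expression,
                      panel, nucleusRadiusUm = 3.0, cellRadiusUm = 5.0,
                      illuminationAmplitude = 0.3, autofluorescence = 0.08,
                      bleachResidual = 0.15, stageShifts = NULL,
                      defocusSigmaPerZ = 1.2, noiseSd = 0.02, seed = 1L,
                      geometry = NULL) {
  if (is.null(geometry))
    geometry <- acquisitionGeometry(imageShape, zSteps = 2L, maxShiftPx = 8L)
  nCyc <- length(unique(panel$cycle))
  if (is.null(stageShifts)) {
    set.seed(stageSeed(seed, "stage-shifts"))
    stageShifts <- matrix(sample(seq(-geometry@maxShiftPx, geometry@maxShiftPx),
                                 2L * nCyc, replace = TRUE), ncol = 2L)
  }
  storage.mode(stageShifts) <- "integer"
  new("SceneSpec", imageShape = as.integer(imageShape),
      nCells = as.integer(nCells), typeNames = typeNames,
      typeFreqs = typeFreqs, expression = expression, panel = panel,
      nucleusRadiusUm = nucleusRadiusUm, cellRadiusUm = cellRadiusUm,
      illuminationAmplitude = illuminationAmplitude,
      autofluorescence = autofluorescence, bleachResidual = bleachResidual,
      stageShifts = stageShifts, defocusSigmaPerZ = defocusSigmaPerZ,
      noiseSd = noiseSd, seed = as.integer(seed), geometry = geometry)
}

#' Default tonsil-like scene: 512x512, 150 cells, 12 markers
#'
#' Eight cell types (B, T helper, cytotoxic T, plasma, myeloid, endothelial,
#' ILC, other) with tonsil-like frequencies; ILCs at 0.5% with a floor of two
#' cells. The 12-marker panel spans 7 cycles: DAPI, CD45, CD3, CD4, CD8,
#' CD19, CD138, CD14, CD31, CD127, SMA (vessel walls) and fibronectin
#' (fibers).
#'
#' @param seed Integer seed.
#' @param noiseSd Additive noise sd (default 0.02).
#' @param corruptionFree If TRUE, zero out shifts, vignette, bleach residual,
#'   defocus and noise (autofluorescence stays; it cancels in subtraction).
#' @return A [SceneSpec-class].
#' @export
tonsilSceneSpec <- function(seed = 1L, noiseSd = 0.02, corruptionFree = FALSE) {
  pan <- markerPanel(
    name = c("DAPI", "CD45", "CD3", "CD4", "CD8", "CD19", "CD138",
             "CD14", "CD31", "CD127", "SMA", "Fibronectin"),
    cycle = c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L),
    channel = c("DAPI-like", "PE", "FITC", "PE", "FITC", "PE", "FITC",
                "PE", "FITC", "PE", "FITC", "PE"),
    localization = c("nuclear", rep("membrane", 9L), "structure", "structure"),
    gating_role = c("none", "inclusion", "lineage_exclusion", "exploratory",
                    "exploratory", "lineage_exclusion", "exploratory",
                    "lineage_exclusion", "exploratory", "inclusion",
                    "none", "none"))
  types <- c("B", "T_helper", "T_cytotoxic", "plasma", "myeloid",
             "endothelial", "ILC", "other")
  freqs <- c(0.30, 0.22, 0.10, 0.05, 0.12, 0.08, 0.005, 0.125)
  expr <- matrix(0, length(types), nrow(pan),
                 dimnames = list(types, pan$name))
  expr[, "DAPI"] <- 0.9
  expr["B", c("CD45", "CD19")] <- c(0.6, 0.7)
  expr["T_helper", c("CD45", "CD3", "CD4")] <- c(0.6, 0.7, 0.6)
  expr["T_cytotoxic", c("CD45", "CD3", "CD8")] <- c(0.6, 0.7, 0.6)
  expr["plasma", "CD138"] <- 0.8
  expr["myeloid", c("CD45", "CD14")] <- c(0.6, 0.7)
  expr["endothelial", "CD31"] <- 0.8
  expr["ILC", c("CD45", "CD127")] <- c(0.6, 0.7)
  expr["other", "CD45"] <- 0.55
  sceneSpec(imageShape = c(512L, 512L), nCells = 150L, typeNames = types,
            typeFreqs = freqs, expression = expr, panel = pan,
            illuminationAmplitude = if (corruptionFree) 0 else 0.3,
            bleachResidual = if (corruptionFree) 0 else 0.15,
            stageShifts = if (corruptionFree)
              matrix(0L, length(unique(pan$cycle)), 2L) else NULL,
            defocusSigmaPerZ = if (corruptionFree) 0 else 1.2,
            noiseSd = if (corruptionFree) 0 else noiseSd,
            seed = seed)
}

# largest-remainder apportionment of n among freqs; "ILC" floored at 2
typeCounts <- function(typeNames, freqs, n) {
  raw <- freqs * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  names(cnt) <- typeNames
  if ("ILC" %in% typeNames && cnt["ILC"] < 2L) {
    need <- 2L - cnt["ILC"]
    donor <- which.max(cnt)
    cnt[donor] <- cnt[donor] - need
    cnt["ILC"] <- 2L
  }
  as.integer(cnt)
}

# smooth curve band mask: row = base + slope*col + amp*sin(...)
curveMask <- function(shape, width, seedOffset) {
  m <- matrix(FALSE, shape[1], shape[2])
  cols <- seq_len(shape[2])
  base <- stats::runif(1, 0.15, 0.85) * shape[1]
  slope <- stats::runif(1, -0.25, 0.25)
  amp <- stats::runif(1, 0.03, 0.10) * shape[1]
  per <- stats::runif(1, 0.8, 2.0)
  rows <- base + slope * (cols - shape[2] / 2) +
    amp * sin(2 * pi * per * cols / shape[2] + stats::runif(1, 0, 2 * pi))
  half <- floor(width / 2)
  for (dw in -half:half) {
    rr <- round(rows) + dw
    ok <- rr >= 1 & rr <= shape[1]
    m[cbind(rr[ok], cols[ok])] <- TRUE
  }
  m
}

radialVignette <- function(shape, amplitude) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  cr <- shape[1] * 0.55; cc <- shape[2] * 0.45  # slightly off-center, realistic
  d2 <- (r - cr)^2 + (c_ - cc)^2
  1 - amplitude * d2 / max(d2)
}

#' Simulate a MELC run with ground truth
#'
#' Deterministic given `spec@seed`. See the file header of `R/simulate.R`
#' for the acquisition model.
#'
#' @param spec A [SceneSpec-class].
#' @return A list with elements `run` ([MelcRun-class]) and `truth`
#'   ([GroundTruth-class]).
#' @export
simulateRun <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  validObject(spec)
  shp <- spec@imageShape
  g <- spec@geometry
  pitch <- g@pixelPitchUm
  nucR <- round(spec@nucleusRadiusUm / pitch)
  cellR <- round(spec@cellRadiusUm / pitch)
  set.seed(spec@seed)

  # --- structure curves: one curve set per structure marker ---
  structMarkers <- spec@panel$name[spec@panel$localization == "structure"]
  structureMasks <- list()
  for (i in seq_along(structMarkers)) {
    w <- if (i == 1L) 5L else 2L   # first set vessel-like, later ones fibers
    nCurves <- if (i == 1L) 2L else 3L
    m <- matrix(FALSE, shp[1], shp[2])
    for (k in seq_len(nCurves)) m <- m | curveMask(shp, w, k)
    structureMasks[[structMarkers[i]]] <- m
  }

  # --- cell placement: rejection sampling with hard minimum spacing ---
  margin <- g@maxShiftPx + cellR + 2L
  minDist <- 2 * cellR
  lo <- margin + 1L
  hiR <- shp[1] - margin; hiC <- shp[2] - margin
  centers <- matrix(NA_real_, spec@nCells, 2L)
  placed <- 0L
  attempts <- 0L; maxAttempts <- 2000L * spec@nCells
  while (placed < spec@nCells && attempts < maxAttempts) {
    attempts <- attempts + 1L
    pr <- round(stats::runif(1, lo, hiR)); pc <- round(stats::runif(1, lo, hiC))
    if (placed == 0L ||
        min((centers[seq_len(placed), 1] - pr)^2 +
            (centers[seq_len(placed), 2] - pc)^2) >= minDist^2) {
      placed <- placed + 1L
      centers[placed, ] <- c(pr, pc)
    }
  }
  if (placed < spec@nCells)
    stop(sprintf("placement error: only %d of %d cells placeable at %d px spacing",
                 placed, spec@nCells, minDist), call. = FALSE)

  # --- type assignment ---
  cnt <- typeCounts(spec@typeNames, spec@typeFreqs, spec@nCells)
  types <- sample(rep(spec@typeNames, cnt))

  # --- truth label/class images ---
  nucleusLabels <- matrix(0L, shp[1], shp[2])
  cellLabels <- matrix(0L, shp[1], shp[2])
  for (i in seq_len(spec@nCells))
    cellLabels <- stampDisk(cellLabels, centers[i, 1], centers[i, 2], cellR, i)
  for (i in seq_len(spec@nCells))
    nucleusLabels <- stampDisk(nucleusLabels, centers[i, 1], centers[i, 2], nucR, i)
  classImage <- matrix(3L, shp[1], shp[2])
  classImage[cellLabels > 0L] <- 2L
  classImage[nucleusLabels > 0L] <- 1L

  # --- per-marker noiseless scenes ---
  exprCells <- spec@expression[types, , drop = FALSE]
  rownames(exprCells) <- NULL
  scenes <- list()
  for (j in seq_len(nrow(spec@panel))) {
    nm <- spec@panel$name[j]
    loc <- spec@panel$localization[j]
    s <- matrix(0, shp[1], shp[2])
    if (loc == "structure") {
      if (!is.null(structureMasks[[nm]])) s[structureMasks[[nm]]] <- 0.8
    } else {
      for (i in seq_len(spec@nCells)) {
        e <- exprCells[i, nm]
        if (e <= 0) next
        s <- if (loc == "nuclear")
          stampDisk(s, centers[i, 1], centers[i, 2], nucR, e)
        else
          stampDisk(s, centers[i, 1], centers[i, 2], cellR, e,
                    annulusInner = nucR)
      }
    }
    scenes[[nm]] <- s
  }

  # --- optics / acquisition ---
  illum <- radialVignette(shp, spec@illuminationAmplitude)
  af <- spec@autofluorescence
  nz <- 2L * g@zSteps + 1L
  zs <- seq(-g@zSteps, g@zSteps)
  noisyPlane <- function(base2d) {
    if (spec@noiseSd > 0)
      pmax(base2d + stats::rnorm(length(base2d), 0, spec@noiseSd), 0)
    else base2d
  }
  renderStack <- function(signal, shift) {
    planes <- array(0, dim = c(shp[1], shp[2], nz))
    for (k in seq_len(nz)) {
      sg <- spec@defocusSigmaPerZ * abs(zs[k])
      b <- if (sg > 0) asMat(EBImage::gblur(asImg(signal), sg)) else signal
      planes[, , k] <- noisyPlane(illum * (rollMatrix(b, shift[1], shift[2]) + af))
    }
    planes
  }

  cyc <- sort(unique(spec@panel$cycle))
  residual <- list()  # per channel
  cyclesOut <- vector("list", length(cyc))
  reference <- 0.1 + 0.5 * (classImage == 1L) + 0.4 * (classImage == 2L)
  for (m in structureMasks) reference <- reference + 0.5 * m

  for (ci in seq_along(cyc)) {
    rows <- which(spec@panel$cycle == cyc[ci])
    shift <- spec@stageShifts[ci, ]
    phase <- noisyPlane(rollMatrix(reference, shift[1], shift[2]))
    fluo <- list(); bleach <- list()
    for (r in rows) {
      nm <- spec@panel$name[r]; ch <- spec@panel$channel[r]
      R <- if (is.null(residual[[ch]])) matrix(0, shp[1], shp[2]) else residual[[ch]]
      signal <- scenes[[nm]] + R
      fluo[[nm]] <- renderStack(signal, shift)
      Rnext <- spec@bleachResidual * signal
      bleach[[nm]] <- renderStack(Rnext, shift)
      residual[[ch]] <- Rnext
    }
    cyclesOut[[ci]] <- list(cycle = cyc[ci], phase = phase, fluo = fluo,
                            bleach = bleach, secondary = list())
  }
  zero <- matrix(0, shp[1], shp[2])
  blank <- list()
  for (ch in unique(spec@panel$channel))
    blank[[ch]] <- renderStack(zero, c(0L, 0L))

  run <- new("MelcRun", reference = reference, cycles = cyclesOut,
             blank = blank, panel = spec@panel, geometry = g)
  truth <- new("GroundTruth",
               centersPx = centers - 1,  # 0-based convention
               types = types, nucleusLabels = nucleusLabels,
               cellLabels = cellLabels, classImage = classImage,
               shifts = spec@stageShifts, illumination = illum,
               expression = exprCells, scenes = scenes,
               structureMasks = structureMasks)
  validObject(run)
  list(run = run, truth = truth)
}
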