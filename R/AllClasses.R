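#' @import methods
NULL

CHANNELS <- c("PE", "FITC", "DAPI-like")
LOCALIZATIONS <- c("nuclear", "membrane", "structure")
GATING_ROLES <- c("lineage_exclusion", "inclusion", "exploratory", "none")

#' Build and validate a marker panel
#'
#' A marker panel maps each antibody/stain to its acquisition cycle, filter
#' channel, subcellular localization (which decides whether its MFI is
#' measured over nuclei or whole cells, and whether it enters the
#' sum-membranes composite) and its role in gating.
#'
#' @param name Character marker names (unique).
#' @param cycle Integer acquisition cycle (>= 1) per marker.
#' @param channel One of "PE", "FITC", "DAPI-like" per marker.
#' @param localization One of "nuclear", "membrane", "structure" per marker.
#' @param gating_role One of "lineage_exclusion", "inclusion", "exploratory",
#'   "none" per marker.
#' @param uses_secondary Logical; marker stained via an uncoupled primary +
#'   secondary antibody (background then comes from a secondary-only image).
#' @return A validated `data.frame` with one row per marker.
#' @export
markerPanel <- function(name, cycle, channel, localization,
                        gating_role = "exploratory",
                        uses_secondary = FALSE) {
  p <- data.frame(name = as.character(name),
                  cycle = as.integer(cycle),
                  channel = as.character(channel),
                  localization = as.character(localization),
                  gating_role = rep_len(as.character(gating_role), length(name)),
                  uses_secondary = rep_len(as.logical(uses_secondary), length(name)),
                  stringsAsFactors = FALSE)
  validatePanel(p)
  p
}

validatePanel <- function(panel) {
  req <- c("name", "cycle", "channel", "localization", "gating_role",
           "uses_secondary")
  miss <- setdiff(req, names(panel))
  if (length(miss)) stop("panel config error: missing columns ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(panel$name))
    stop("panel config error: duplicate marker name(s): ",
         paste(unique(panel$name[duplicated(panel$name)]), collapse = ", "),
         call. = FALSE)
  key <- paste(panel$cycle, panel$channel)
  if (anyDuplicated(key))
    stop("panel config error: duplicate (cycle, channel) assignment: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  if (!all(panel$channel %in% CHANNELS))
    stop("panel config error: unknown channel(s): ",
         paste(setdiff(panel$channel, CHANNELS), collapse = ", "), call. = FALSE)
  if (!all(panel$localization %in% LOCALIZATIONS))
    stop("panel config error: unknown localization(s): ",
         paste(setdiff(panel$localization, LOCALIZATIONS), collapse = ", "),
         call. = FALSE)
  if (!all(panel$gating_role %in% GATING_ROLES))
    stop("panel config error: unknown gating_role(s): ",
         paste(setdiff(panel$gating_role, GATING_ROLES), collapse = ", "),
         call. = FALSE)
  if (any(panel$cycle < 1L)) stop("panel config error: cycle must be >= 1",
                                  call. = FALSE)
  invisible(TRUE)
}

#' Acquisition geometry of a MELC run
#'
#' @slot pixelPitchUm Physical pixel pitch in micrometers (0.325 for a 6.5 um
#'   camera pixel behind a 20x objective).
#' @slot zSteps Half-range of the z-stack; each stack has `2*zSteps + 1` planes.
#' @slot zStepUm Axial step in micrometers.
#' @slot imageShape Integer `(rows, cols)`.
#' @slot maxShiftPx Largest stage displacement (pixels) the autofocus may leave.
#' @export
setClass("AcquisitionGeometry",
         representation(pixelPitchUm = "numeric", zSteps = "integer",
                        zStepUm = "numeric", imageShape = "integer",
                        maxShiftPx = "integer"),
         validity = function(object) {
           msg <- character()
           if (object@pixelPitchUm <= 0) msg <- c(msg, "pixelPitchUm must be > 0")
           if (object@zSteps < 0L) msg <- c(msg, "zSteps must be >= 0")
           if (length(object@imageShape) != 2L || any(object@imageShape < 64L))
             msg <- c(msg, "imageShape must be two integers >= 64")
           if (length(msg)) msg else TRUE
         })

#' Construct an AcquisitionGeometry
#'
#' @param imageShape Integer `(rows, cols)`.
#' @param pixelPitchUm Micrometers per pixel.
#' @param zSteps Half-range of z planes.
#' @param zStepUm Micrometers per z step.
#' @param maxShiftPx Maximum expected stage shift in pixels.
#' @return An `AcquisitionGeometry` object.
#' @export
acquisitionGeometry <- function(imageShape, pixelPitchUm = 0.325,
                                zSteps = 7L, zStepUm = 1.0,
                                maxShiftPx = 50L) {
  new("AcquisitionGeometry", pixelPitchUm = pixelPitchUm,
      zSteps = as.integer(zSteps), zStepUm = zStepUm,
      imageShape = as.integer(imageShape), maxShiftPx = as.integer(maxShiftPx))
}

#' A MELC acquisition: reference image plus per-cycle stain/bleach stacks
#'
#' Each cycle record is a list with elements `cycle` (integer), `fluo` and
#' `bleach` (named lists, marker name -> 3D array of `2*zSteps+1` planes),
#' optionally `phase` (the cycle's phase-contrast image, used for
#' registration against the reference) and optionally `secondary` (named
#' list for markers flagged `uses_secondary`).
#' `blank` holds the pre-run background stacks keyed by channel, used as the
#' subtrahend for the first cycle of each channel.
#'
#' @slot reference 2D phase-contrast reference image (matrix).
#' @slot cycles List of cycle records, strictly ascending in cycle index.
#' @slot blank Named list channel -> 3D array (pre-run blank acquisition).
#' @slot panel Marker panel `data.frame` (see [markerPanel()]).
#' @slot geometry An [AcquisitionGeometry-class] object.
#' @export
setClass("MelcRun",
         representation(reference = "matrix", cycles = "list", blank = "list",
                        panel = "data.frame", geometry = "AcquisitionGeometry"),
         validity = function(object) {
           msg <- character()
           shp <- object@geometry@imageShape
           np <- 2L * object@geometry@zSteps + 1L
           if (!all(dim(object@reference) == shp))
             msg <- c(msg, "reference image shape differs from geometry")
           idx <- vapply(object@cycles, function(cy) cy$cycle, integer(1))
           if (is.unsorted(idx, strictly = TRUE))
             msg <- c(msg, "cycles must be strictly ascending by cycle index")
           for (cy in object@cycles) {
             if (!is.null(cy$phase) && !all(dim(cy$phase) == shp))
               msg <- c(msg, sprintf("cycle %d: phase image shape invalid",
                                     cy$cycle))
             for (nm in names(cy$fluo)) {
               d <- dim(cy$fluo[[nm]])
               if (!all(d[1:2] == shp) || d[3] != np)
                 msg <- c(msg, sprintf(
                   "cycle %d marker %s: fluorescence stack must be %dx%dx%d",
                   cy$cycle, nm, shp[1], shp[2], np))
             }
             if (!setequal(names(cy$fluo), names(cy$bleach)))
               msg <- c(msg, sprintf("cycle %d: bleach stacks must match fluorescence markers",
                                     cy$cycle))
             for (nm in names(cy$bleach)) {
               d <- dim(cy$bleach[[nm]])
               if (!all(d[1:2] == shp) || d[3] != np)
                 msg <- c(msg, sprintf("cycle %d marker %s: bleach stack shape invalid",
                                       cy$cycle, nm))
             }
           }
           pm <- sort(object@panel$name)
           rm_ <- sort(unlist(lapply(object@cycles, function(cy) names(cy$fluo))))
           if (!identical(pm, rm_))
             msg <- c(msg, "markers in cycles do not match the panel")
           if (length(msg)) msg else TRUE
         })

#' Per-pixel class probabilities for nuclei / membrane / ECM
#'
#' @slot nuc,mem,ecm Probability images (matrices); they sum to 1 pixelwise.
#' @export
setClass("ProbabilityMaps",
         representation(nuc = "matrix", mem = "matrix", ecm = "matrix"),
         validity = function(object) {
           msg <- character()
           if (!all(dim(object@nuc) == dim(object@mem)) ||
               !all(dim(object@nuc) == dim(object@ecm)))
             msg <- c(msg, "maps must share one shape")
           rng <- range(object@nuc, object@mem, object@ecm)
           if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
             msg <- c(msg, "probabilities must lie in [0,1]")
           s <- object@nuc + object@mem + object@ecm
           if (max(abs(s - 1)) > 1e-6)
             msg <- c(msg, "probabilities must sum to 1 pixelwise (tol 1e-6)")
           if (length(msg)) msg else TRUE
         })

#' Construct ProbabilityMaps
#' @param nuc,mem,ecm Probability matrices summing to one pixelwise.
#' @return A `ProbabilityMaps` object.
#' @export
probabilityMaps <- function(nuc, mem, ecm) new("ProbabilityMaps",
                                               nuc = nuc, mem = mem, ecm = ecm)

#' Scene specification for the synthetic MELC generator
#'
#' Describes a miniature MELC run: cells are disks (nucleus disk + membrane
#' shell), structure markers render on vessel/fiber curves, and the
#' acquisition corruptions (stage shifts, vignetting, autofluorescence, bleach
#' residual, defocus, noise) are explicit parameters so every downstream stage
#' has a ground-truth oracle.
#'
#' @slot imageShape Integer `(rows, cols)`.
#' @slot nCells Number of cells to place.
#' @slot typeNames Cell type names.
#' @slot typeFreqs Type frequencies (sum to 1).
#' @slot expression Matrix types x markers of mean intensities in [0,1].
#' @slot panel Marker panel `data.frame`.
#' @slot nucleusRadiusUm,cellRadiusUm Cell geometry in micrometers.
#' @slot illuminationAmplitude Amplitude of the radial vignette field.
#' @slot autofluorescence Flat tissue autofluorescence level.
#' @slot bleachResidual Multiplicative signal carry-over after bleaching, in [0,1).
#' @slot stageShifts Integer matrix cycles x 2 of per-cycle (dr, dc) shifts.
#' @slot defocusSigmaPerZ Gaussian blur sigma (px) added per |z| plane.
#' @slot noiseSd Additive Gaussian noise sd on the [0,1] intensity scale.
#' @slot seed Integer generator seed.
#' @slot geometry An [AcquisitionGeometry-class].
#' @export
setClass("SceneSpec",
         representation(imageShape = "integer", nCells = "integer",
                        typeNames = "character", typeFreqs = "numeric",
                        expression = "matrix", panel = "data.frame",
                        nucleusRadiusUm = "numeric", cellRadiusUm = "numeric",
                        illuminationAmplitude = "numeric",
                        autofluorescence = "numeric",
                        bleachResidual = "numeric", stageShifts = "matrix",
                        defocusSigmaPerZ = "numeric", noiseSd = "numeric",
                        seed = "integer", geometry = "AcquisitionGeometry"),
         validity = function(object) {
           msg <- character()
           if (abs(sum(object@typeFreqs) - 1) > 1e-9)
             msg <- c(msg, "type frequencies must sum to 1 (tol 1e-9)")
           if (length(object@typeFreqs) != length(object@typeNames))
             msg <- c(msg, "typeFreqs/typeNames length mismatch")
           if (!all(rownames(object@expression) == object@typeNames))
             msg <- c(msg, "expression rows must match typeNames")
           if (!all(colnames(object@expression) %in% object@panel$name))
             msg <- c(msg, "expression columns must be panel markers")
           if (object@bleachResidual < 0 || object@bleachResidual >= 1)
             msg <- c(msg, "bleachResidual must be in [0,1)")
           nCyc <- length(unique(object@panel$cycle))
           if (nrow(object@stageShifts) != nCyc)
             msg <- c(msg, "stageShifts must have one row per cycle")
           if (any(abs(object@stageShifts) > object@geometry@maxShiftPx))
             msg <- c(msg, "stage shifts exceed geometry maxShiftPx")
           if (length(msg)) msg else TRUE
         })

#' Ground truth of a synthetic MELC run
#'
#' @slot centersPx Cell centers, n x 2 matrix of 0-based (row, col).
#' @slot types Character cell type per cell.
#' @slot nucleusLabels,cellLabels Integer label images (cell i -> label i).
#' @slot classImage Integer image: 1 nuclei, 2 membrane, 3 ECM/background.
#' @slot shifts Integer matrix cycles x 2 of true (dr, dc) shifts.
#' @slot illumination True multiplicative illumination field (matrix).
#' @slot expression Matrix cells x markers of true mean expression.
#' @slot scenes Named list marker -> noiseless unshifted signal scene.
#' @slot structureMasks Named list of binary masks (e.g. vessel, fiber).
#' @export
setClass("GroundTruth",
         representation(centersPx = "matrix", types = "character",
                        nucleusLabels = "matrix", cellLabels = "matrix",
                        classImage = "matrix", shifts = "matrix",
                        illumination = "matrix", expression = "matrix",
                        scenes = "list", structureMasks = "list"),
         validity = function(object) {
           msg <- character()
           n <- nrow(object@centersPx)
           if (length(object@types) != n)
             msg <- c(msg, "one type per cell required")
           if (max(object@cellLabels) != n)
             msg <- c(msg, "cell labels must run 1..nCells")
           if (length(msg)) msg else TRUE
         })

# ---- accessors ----

#' @describeIn MelcRun-class Marker panel accessor.
#' @param object A `MelcRun`.
#' @export
setGeneric("panel", function(object) standardGeneric("panel"))
#' @export
setMethod("panel", "MelcRun", function(object) object@panel)
#' @export
setMethod("panel", "SceneSpec", function(object) object@panel)

#' @describeIn MelcRun-class Geometry accessor.
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @export
setMethod("geometry", "MelcRun", function(object) object@geometry)
#' @export
setMethod("geometry", "SceneSpec", function(object) object@geometry)

#' @describeIn MelcRun-class Cycle-record list accessor.
#' @export
setGeneric("cycles", function(object) standardGeneric("cycles"))
#' @export
setMethod("cycles", "MelcRun", function(object) object@cycles)

#' @describeIn MelcRun-class Phase-contrast reference image accessor.
#' @export
setGeneric("referenceImage", function(object) standardGeneric("referenceImage"))
#' @export
setMethod("referenceImage", "MelcRun", function(object) object@reference)

#' Probability map accessor
#' @param object A `ProbabilityMaps`.
#' @param which One of "nuc", "mem", "ecm".
#' @return The requested probability matrix.
#' @export
setGeneric("probMap", function(object, which) standardGeneric("probMap"))
#' @export
setMethod("probMap", "ProbabilityMaps", function(object, which)
  slot(object, match.arg(which, c("nuc", "mem", "ecm"))))

setMethod("show", "MelcRun", function(object) {
  cat(sprintf("MelcRun: %d cycles, %d markers, %dx%d px, %d z-planes\n",
              length(object@cycles), nrow(object@panel),
              object@geometry@imageShape[1], object@geometry@imageShape[2],
              2L * object@geometry@zSteps + 1L))
  cat("  markers:", paste(object@panel$name, collapse = ", "), "\n")
})

setMethod("show", "ProbabilityMaps", function(object) {
  cat(sprintf("ProbabilityMaps %dx%d (nuc/mem/ecm)\n",
              nrow(object@nuc), ncol(object@nuc)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %dx%d px, %d cells, %d types, %d markers, seed %d\n",
              object@imageShape[1], object@imageShape[2], object@nCells,
              length(object@typeNames), nrow(object@panel), object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d cells (%s)\n", nrow(object@centersPx),
              paste(sprintf("%s=%d", names(table(object@types)),
                            as.integer(table(object@types))), collapse = ", ")))
})
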