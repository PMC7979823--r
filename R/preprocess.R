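# Pre-processing chain: registration -> bleach subtraction -> illumination
# correction -> extended-depth-of-field projection -> rolling-ball
# normalization with edge crop and intensity stretch.

#' Preprocessing parameters
#'
#' @param maxShiftPx Registration search radius in pixels.
#' @param splineGrid Blocks per axis for illumination estimation (>= 4).
#' @param illuminationFloor Lower clip for the illumination field.
#' @param edfWindowPx Odd window for the focus (local variance) measure.
#' @param rollingBallRadiusPx Rolling-ball radius for background estimation.
#' @param stretchPercentiles `(low, high)` percentiles mapped to the full
#'   16-bit range.
#' @param cropMarginPx Pixels cropped from each edge; `NULL` uses the largest
#'   observed registration shift.
#' @param illuminationProb Per-block quantile used as the "minimum intensity"
#'   statistic (0 = strict minimum; a small positive value is robust to
#'   sensor noise).
#' @return A validated parameter list.
#' @export
preprocessParams <- function(maxShiftPx = 50L, splineGrid = 16L,
                             illuminationFloor = 0.05, edfWindowPx = 9L,
                             rollingBallRadiusPx = 50L,
                             stretchPercentiles = c(0, 100),
                             cropMarginPx = NULL,
                             illuminationProb = 0.1) {
  stopifnot(maxShiftPx > 0, splineGrid >= 4L, illuminationFloor > 0,
            rollingBallRadiusPx > 0, illuminationProb >= 0,
            illuminationProb < 0.5)
  if (edfWindowPx %% 2L != 1L)
    stop("parameter error: edfWindowPx must be odd", call. = FALSE)
  p <- stretchPercentiles
  if (!(p[1] >= 0 && p[1] < p[2] && p[2] <= 100))
    stop("parameter error: stretch percentiles need 0 <= low < high <= 100",
         call. = FALSE)
  structure(list(maxShiftPx = as.integer(maxShiftPx),
                 splineGrid = as.integer(splineGrid),
                 illuminationFloor = illuminationFloor,
                 edfWindowPx = as.integer(edfWindowPx),
                 rollingBallRadiusPx = as.integer(rollingBallRadiusPx),
                 stretchPercentiles = p, cropMarginPx = cropMarginPx,
                 illuminationProb = illuminationProb),
            class = "preprocessParams")
}

#' Register an image to a reference by cross-correlation
#'
#' Finds the integer shift `(dr, dc)` with `|dr|, |dc| <= maxShiftPx`
#' maximizing the cross-correlation of the mean-subtracted images (computed
#' circularly via FFT). Ties are broken by smallest `|dr| + |dc|`, then
#' lexicographically. The returned `registered` image is `moving` translated
#' by `-shift` with zero fill.
#'
#' @param moving,reference 2D images of identical shape.
#' @param maxShiftPx Search radius; must be `< min(dim)/4`.
#' @return List with `shift` (integer `(dr, dc)`) and `registered` (matrix).
#' @export
registerCycle <- function(moving, reference, maxShiftPx = 50L) {
  assertImage(moving); assertImage(reference)
  assertSameShape(moving, reference)
  if (maxShiftPx >= min(dim(moving)) / 4)
    stop("maxShiftPx must be < min(image dim)/4", call. = FALSE)
  if (stats::sd(moving) == 0 || stats::sd(reference) == 0)
    stop("degenerate-correlation error: constant image", call. = FALSE)
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  cand <- expand.grid(dr = -maxShiftPx:maxShiftPx, dc = -maxShiftPx:maxShiftPx)
  val <- cc[cbind(cand$dr %% nr + 1L, cand$dc %% nc + 1L)]
  tol <- 1e-8 * max(abs(val), 1)
  best <- val >= max(val) - tol
  sub <- cand[best, , drop = FALSE]
  ord <- order(abs(sub$dr) + abs(sub$dc), sub$dr, sub$dc)
  shift <- as.integer(unlist(sub[ord[1], ]))
  list(shift = shift,
       registered = translateMatrix(moving, -shift[1], -shift[2]))
}

#' Subtract a bleach (background) image from a stain image
#'
#' Pairing follows the acquisition chain: the post-bleach image of the
#' previous cycle in the same channel is the background of the current
#' stain; the first cycle of a channel uses the pre-run blank. Output is
#' clamped at zero.
#'
#' @param fluo,bleach_prev Registered 2D images of one shape.
#' @return `pmax(fluo - bleach_prev, 0)`.
#' @export
subtractBackground <- function(fluo, bleach_prev) {
  assertImage(fluo); assertImage(bleach_prev)
  assertSameShape(fluo, bleach_prev)
  pmax(fluo - bleach_prev, 0)
}

#' Subtract a secondary-antibody-only image
#'
#' For markers stained indirectly, the secondary-only acquisition replaces
#' the bleach image as the background estimate; same clamped-difference
#' contract as [subtractBackground()].
#'
#' @param fluo_primary,fluo_secondary_only Registered 2D images.
#' @return Clamped difference image.
#' @export
subtractSecondary <- function(fluo_primary, fluo_secondary_only) {
  subtractBackground(fluo_primary, fluo_secondary_only)
}

#' Estimate the uneven-illumination field from a bleach image
#'
#' The image is partitioned into `splineGrid x splineGrid` blocks; in each
#' block a minimum-intensity statistic (quantile `prob`, 0 = strict minimum)
#' and its pixel location are taken, and a tensor-product cubic smoothing
#' spline is fitted through these points and evaluated at every pixel. The
#' surface is normalized to mean 1 and clipped below at `floor`.
#'
#' @param bleach Nonnegative 2D image (typically the mean projection of a
#'   registered bleach stack).
#' @param splineGrid Blocks per axis (>= 4).
#' @param floor Lower clip of the normalized field.
#' @param prob Per-block quantile used as the minimum statistic.
#' @return Matrix field with `mean(field) == 1`, `min(field) >= floor`.
#' @export
estimateIllumination <- function(bleach, splineGrid = 16L, floor = 0.05,
                                 prob = 0) {
  assertImage(bleach)
  if (splineGrid < 4L) stop("parameter error: splineGrid must be >= 4",
                            call. = FALSE)
  if (min(bleach) < 0) stop("bleach image must be nonnegative", call. = FALSE)
  nr <- nrow(bleach); nc <- ncol(bleach)
  rEdges <- round(seq(0, nr, length.out = splineGrid + 1L))
  cEdges <- round(seq(0, nc, length.out = splineGrid + 1L))
  pts <- data.frame(r = numeric(0), c = numeric(0), z = numeric(0))
  for (i in seq_len(splineGrid)) {
    rows <- (rEdges[i] + 1L):rEdges[i + 1L]
    for (j in seq_len(splineGrid)) {
      cols <- (cEdges[j] + 1L):cEdges[j + 1L]
      blk <- bleach[rows, cols, drop = FALSE]
      q <- stats::quantile(blk, prob, names = FALSE, type = 1)
      at <- which(blk <= q)[1]  # type-1 quantile is an observed value
      pr <- rows[(at - 1L) %% length(rows) + 1L]
      pc <- cols[(at - 1L) %/% length(rows) + 1L]
      pts <- rbind(pts, data.frame(r = pr, c = pc, z = q))
    }
  }
  if (stats::sd(pts$z) == 0) {
    field <- matrix(1, nr, nc)
  } else {
    k <- min(8L, splineGrid)
    fit <- mgcv::gam(z ~ te(r, c, k = c(k, k), bs = "cr"), data = pts,
                     method = "REML")
    grid <- expand.grid(r = seq_len(nr), c = seq_len(nc))
    field <- matrix(as.numeric(stats::predict(fit, grid)), nr, nc)
    field <- field / mean(field)
  }
  pmax(field, floor)
}

#' Divide an image by a mean-one illumination field
#'
#' @param img 2D image.
#' @param field Illumination field with `mean(field) == 1` (tol 1e-6).
#' @param floor Contract floor; fields below it are rejected.
#' @return `img / field`.
#' @export
correctIllumination <- function(img, field, floor = 0.05) {
  assertImage(img); assertImage(field)
  assertSameShape(img, field)
  if (abs(mean(field) - 1) > 1e-6)
    stop("contract violation: illumination field must have mean 1", call. = FALSE)
  if (min(field) < floor - 1e-9)
    stop("contract violation: illumination field below floor", call. = FALSE)
  img / field
}

#' Extended-depth-of-field projection of a z-stack
#'
#' Per pixel, the plane maximizing the local intensity variance in a
#' `window x window` neighborhood is selected; the selection-index map is
#' median-filtered with the same window and the output takes each pixel from
#' its selected plane. Ties select the lowest z index.
#'
#' @param zstack 3D array (rows x cols x planes).
#' @param window_px Odd window size.
#' @return 2D matrix.
#' @export
extendedDepthOfField <- function(zstack, window_px = 9L) {
  stopifnot(length(dim(zstack)) == 3L)
  if (window_px %% 2L != 1L)
    stop("parameter error: window must be odd", call. = FALSE)
  nz <- dim(zstack)[3]
  if (nz == 1L) return(zstack[, , 1])
  nr <- dim(zstack)[1]; nc <- dim(zstack)[2]
  box <- matrix(1 / window_px^2, window_px, window_px)
  bestVar <- matrix(-Inf, nr, nc)
  idx <- matrix(1L, nr, nc)
  for (k in seq_len(nz)) {
    p <- zstack[, , k]
    mu <- asMat(EBImage::filter2(asImg(p), box))
    mu2 <- asMat(EBImage::filter2(asImg(p * p), box))
    v <- mu2 - mu^2
    upd <- v > bestVar
    bestVar[upd] <- v[upd]
    idx[upd] <- k
  }
  sm <- asMat(EBImage::medianFilter(asImg((idx - 1) / (nz - 1)),
                                    size = floor(window_px / 2)))
  idx <- matrix(pmin(pmax(round(sm * (nz - 1)) + 1, 1), nz), nr, nc)
  out <- matrix(0, nr, nc)
  lin <- seq_len(nr * nc)
  out[lin] <- zstack[lin + (as.vector(idx) - 1L) * (nr * nc)]
  out
}

# ImageJ-style rolling-ball background: downscale, grayscale disc opening,
# upscale, cap at the image
rollingBallBackground <- function(img, radius) {
  shrink <- if (radius >= 16) 4L else 1L
  nr <- nrow(img); nc <- ncol(img)
  if (shrink > 1L) {
    small <- asMat(EBImage::resize(asImg(img), w = ceiling(nr / shrink),
                                   h = ceiling(nc / shrink)))
  } else small <- img
  r <- max(1L, round(radius / shrink))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  op <- EBImage::opening(asImg(small), brush)
  bg <- if (shrink > 1L) asMat(EBImage::resize(op, w = nr, h = nc)) else asMat(op)
  pmin(bg, img)
}

#' Rolling-ball background removal, edge crop and 16-bit intensity stretch
#'
#' @param img Nonnegative 2D image.
#' @param params [preprocessParams()]; uses `rollingBallRadiusPx`,
#'   `cropMarginPx` and `stretchPercentiles`.
#' @param cropMarginPx Overrides `params$cropMarginPx`.
#' @return Cropped float image on the 16-bit scale `[0, 65535]`.
#' @export
normalizeImage <- function(img, params = preprocessParams(),
                           cropMarginPx = params$cropMarginPx) {
  assertImage(img)
  if (min(img) < 0) stop("image must be nonnegative", call. = FALSE)
  out <- img - rollingBallBackground(img, params$rollingBallRadiusPx)
  m <- if (is.null(cropMarginPx)) params$maxShiftPx else as.integer(cropMarginPx)
  if (m > 0) {
    if (nrow(out) - 2L * m < 64L || ncol(out) - 2L * m < 64L)
      stop("crop error: fewer than 64 px per side would remain", call. = FALSE)
    out <- out[(m + 1L):(nrow(out) - m), (m + 1L):(ncol(out) - m)]
  }
  p <- params$stretchPercentiles
  lo <- stats::quantile(out, p[1] / 100, names = FALSE)
  hi <- stats::quantile(out, p[2] / 100, names = FALSE)
  if (hi <= lo) return(matrix(0, nrow(out), ncol(out)))
  pmin(pmax((out - lo) / (hi - lo), 0), 1) * 65535
}

#' Run the full pre-processing chain on a MELC run
#'
#' Per cycle, a moving image (sum of central stain planes over the cycle's
#' channels) is registered to the phase-contrast reference; the shift is
#' applied to every plane of the cycle's stacks. Backgrounds (previous
#' same-channel bleach, or pre-run blank, or secondary-only image) are
#' subtracted plane-wise, the illumination field estimated from the cycle's
#' own registered bleach is divided out, the stack is projected by
#' extended depth of field and the projection is rolling-ball normalized,
#' cropped by the largest observed shift and stretched to the 16-bit range.
#'
#' @param run A [MelcRun-class].
#' @param params [preprocessParams()].
#' @return List with `images` (named list marker -> corrected matrix, all of
#'   one shape), `shifts` (cycles x 2 integer matrix) and `fields` (named
#'   list marker -> estimated illumination field).
#' @export
preprocessRun <- function(run, params = preprocessParams()) {
  stopifnot(is(run, "MelcRun"))
  g <- run@geometry
  maxShift <- min(params$maxShiftPx, g@maxShiftPx)
  nz <- 2L * g@zSteps + 1L
  mid <- g@zSteps + 1L
  pan <- run@panel

  shifts <- matrix(0L, length(run@cycles), 2L,
                   dimnames = list(NULL, c("dr", "dc")))
  registered <- list()   # per marker: list(fluo=stack, bleach=stack)
  for (ii in seq_along(run@cycles)) {
    cy <- run@cycles[[ii]]
    # the per-cycle phase-contrast image is the preferred moving image, as
    # on the instrument; without one, fall back to the summed stain planes
    moving <- if (!is.null(cy$phase)) cy$phase
              else Reduce(`+`, lapply(cy$fluo, function(s) s[, , mid]))
    reg <- registerCycle(moving, run@reference, maxShift)
    shifts[ii, ] <- reg$shift
    tr <- function(stack) {
      out <- stack
      for (k in seq_len(nz))
        out[, , k] <- translateMatrix(stack[, , k], -reg$shift[1], -reg$shift[2])
      out
    }
    for (nm in names(cy$fluo)) {
      registered[[nm]] <- list(cycle = cy$cycle, fluo = tr(cy$fluo[[nm]]),
                               bleach = tr(cy$bleach[[nm]]),
                               secondary = if (!is.null(cy$secondary[[nm]]))
                                 tr(cy$secondary[[nm]]) else NULL)
    }
  }

  cropMargin <- if (!is.null(params$cropMarginPx)) params$cropMarginPx
                else max(abs(shifts))
  prevBleach <- run@blank  # blank acquired at zero shift, already aligned
  images <- list(); fields <- list()
  for (ci in order(vapply(run@cycles, `[[`, 1L, "cycle"))) {
    cy <- run@cycles[[ci]]
    for (nm in names(cy$fluo)) {
      ch <- pan$channel[pan$name == nm]
      rec <- registered[[nm]]
      useSecondary <- isTRUE(pan$uses_secondary[pan$name == nm])
      if (useSecondary && is.null(rec$secondary))
        stop("missing secondary image for marker ", nm, call. = FALSE)
      backStack <- if (useSecondary) rec$secondary else prevBleach[[ch]]
      if (is.null(backStack))
        stop("no background stack available for channel ", ch, call. = FALSE)
      sub <- rec$fluo
      for (k in seq_len(nz))
        sub[, , k] <- subtractBackground(rec$fluo[, , k], backStack[, , k])
      # illumination is camera-fixed: estimate it from the unregistered
      # bleach, then move the field into the registered frame (neutral
      # padding at the border, which the edge crop removes anyway)
      bleachProj <- rowMeans(cy$bleach[[nm]], dims = 2)
      field <- estimateIllumination(bleachProj, params$splineGrid,
                                    params$illuminationFloor,
                                    prob = params$illuminationProb)
      sh <- shifts[ci, ]
      if (any(sh != 0L)) {
        field <- translateMatrix(field - 1, -sh[1], -sh[2]) + 1
        field <- pmax(field / mean(field), params$illuminationFloor)
      }
      for (k in seq_len(nz))
        sub[, , k] <- correctIllumination(sub[, , k], field,
                                          params$illuminationFloor)
      edf <- extendedDepthOfField(sub, params$edfWindowPx)
      images[[nm]] <- normalizeImage(edf, params, cropMarginPx = cropMargin)
      fields[[nm]] <- field
      prevBleach[[ch]] <- rec$bleach
    }
  }
  images <- images[pan$name]  # stable panel order
  list(images = images, shifts = shifts, fields = fields)
}
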