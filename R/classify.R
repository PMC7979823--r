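# Random-forest pixel classification into nuclei / membrane / ECM.
#
# Features mirror an interactive pixel-classification default: per input
# image (DAPI and sum-membranes) and per scale, Gaussian-smoothed intensity,
# gradient magnitude, Laplacian of Gaussian and the two structure-tensor
# eigenvalues.

DEFAULT_FEATURE_SCALES <- c(0.7, 1.0, 1.6, 3.5, 5.0)

#' Sum-membranes composite image
#'
#' Pixelwise sum of all membrane-localized marker images, rescaled to [0,1]
#' by its maximum.
#'
#' @param corrected Named list marker -> 2D image.
#' @param panel Marker panel.
#' @return 2D matrix in [0,1].
#' @export
sumMembranes <- function(corrected, panel) {
  validatePanel(panel)
  mem <- panel$name[panel$localization == "membrane"]
  mem <- intersect(mem, names(corrected))
  if (length(mem) == 0L)
    stop("config error: no membrane-localized markers in panel", call. = FALSE)
  s <- Reduce(`+`, corrected[mem])
  if (max(s) > 0) s <- s / max(s)
  s
}

#' Compute the pixel feature stack
#'
#' @param intensity_images List of 2D images (DAPI-like and sum-membranes);
#'   names are used in feature names.
#' @param scales Numeric Gaussian scales.
#' @return 3D array rows x cols x features with dimnames on the feature axis;
#'   feature count is `5 * length(scales) * length(images)`.
#' @export
computePixelFeatures <- function(intensity_images,
                                 scales = DEFAULT_FEATURE_SCALES) {
  stopifnot(length(scales) > 0)
  if (is.null(names(intensity_images)))
    names(intensity_images) <- paste0("img", seq_along(intensity_images))
  nr <- nrow(intensity_images[[1]]); nc <- ncol(intensity_images[[1]])
  sobelR <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  feats <- list()
  for (nm in names(intensity_images)) {
    img <- intensity_images[[nm]]
    rng <- max(img) - min(img)
    imgN <- if (rng > 0) (img - min(img)) / rng else img * 0
    for (s in scales) {
      gi <- EBImage::gblur(asImg(imgN), s)
      gmat <- asMat(gi)
      gr <- asMat(EBImage::filter2(gi, sobelR))
      gc <- asMat(EBImage::filter2(gi, t(sobelR)))
      gm <- sqrt(gr^2 + gc^2)
      lg <- asMat(EBImage::filter2(gi, lap))
      # structure tensor smoothed at the same scale
      sxx <- asMat(EBImage::gblur(asImg(gr * gr), s))
      syy <- asMat(EBImage::gblur(asImg(gc * gc), s))
      sxy <- asMat(EBImage::gblur(asImg(gr * gc), s))
      tr <- sxx + syy
      dd <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
      l1 <- (tr + dd) / 2
      l2 <- (tr - dd) / 2
      base <- sprintf("%s_s%.1f", nm, s)
      feats[[paste0(base, "_gauss")]] <- gmat
      feats[[paste0(base, "_gradmag")]] <- gm
      feats[[paste0(base, "_log")]] <- lg
      feats[[paste0(base, "_st1")]] <- l1
      feats[[paste0(base, "_st2")]] <- l2
    }
  }
  array(unlist(feats, use.names = FALSE),
        dim = c(nr, nc, length(feats)),
        dimnames = list(NULL, NULL, names(feats)))
}

featureMatrix <- function(features, pixels = NULL) {
  nf <- dim(features)[3]
  npix <- prod(dim(features)[1:2])
  m <- features
  dim(m) <- c(npix, nf)
  colnames(m) <- dimnames(features)[[3]]
  if (!is.null(pixels)) m <- m[pixels, , drop = FALSE]
  m
}

#' Train the three-class random-forest pixel classifier
#'
#' Labeled pixels are class-balanced by downsampling to the smallest class
#' (capped), and a 100-tree random forest is fitted deterministically for a
#' given seed.
#'
#' @param features Feature stack from [computePixelFeatures()].
#' @param labels Integer label mask: 0 unlabeled, 1 nuclei, 2 membrane, 3 ECM.
#' @param seed Integer seed.
#' @param n_trees Number of trees.
#' @param max_per_class Cap on training pixels per class.
#' @return A `pixelClassifier` object (random forest + frozen feature recipe
#'   + out-of-bag accuracy).
#' @export
trainPixelClassifier <- function(features, labels, seed = 1L, n_trees = 100L,
                                 max_per_class = 3000L) {
  stopifnot(length(dim(features)) == 3L)
  if (!all(labels %in% 0:3))
    stop("labels must be 0 (unlabeled), 1 (nuclei), 2 (membrane), 3 (ECM)",
         call. = FALSE)
  counts <- tabulate(labels[labels > 0L], 3L)
  if (any(counts < 50L))
    stop("training error: each class needs >= 50 labeled pixels (have ",
         paste(counts, collapse = "/"), ")", call. = FALSE)
  set.seed(seed)
  nPer <- min(counts, max_per_class)
  pick <- unlist(lapply(1:3, function(k) {
    idx <- which(labels == k)
    sample(idx, nPer)
  }))
  X <- featureMatrix(features, pick)
  y <- factor(labels[pick], levels = 1:3, labels = c("nuc", "mem", "ecm"))
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees)
  structure(list(forest = rf,
                 recipe = list(features = dimnames(features)[[3]]),
                 oobAccuracy = 1 - rf$err.rate[n_trees, "OOB"],
                 seed = seed, nTrees = n_trees, labelCounts = counts),
            class = "pixelClassifier")
}

#' @export
print.pixelClassifier <- function(x, ...) {
  cat(sprintf("pixelClassifier: %d trees, %d features, OOB accuracy %.3f\n",
              x$nTrees, length(x$recipe$features), x$oobAccuracy))
  invisible(x)
}

#' Predict nuclei/membrane/ECM probability maps
#'
#' @param model A `pixelClassifier`.
#' @param features Feature stack whose feature names match the model's
#'   frozen recipe (order-independent).
#' @return A [ProbabilityMaps-class].
#' @export
predictProbabilityMaps <- function(model, features) {
  stopifnot(inherits(model, "pixelClassifier"))
  have <- dimnames(features)[[3]]
  if (!setequal(have, model$recipe$features))
    stop("feature recipe mismatch between model and features", call. = FALSE)
  X <- featureMatrix(features)[, model$recipe$features, drop = FALSE]
  p <- stats::predict(model$forest, X, type = "prob")
  nr <- dim(features)[1]; nc <- dim(features)[2]
  s <- rowSums(p)
  p <- p / s
  probabilityMaps(nuc = matrix(p[, "nuc"], nr, nc),
                  mem = matrix(p[, "mem"], nr, nc),
                  ecm = matrix(p[, "ecm"], nr, nc))
}

#' Derive a training label mask from a ground-truth class image
#'
#' Mimics manual scribbles: each class region is eroded by one pixel and a
#' given fraction of the image area is sampled from it, class-balanced.
#'
#' @param classImage Integer image of classes 1..3.
#' @param fraction Fraction of image pixels to label (default 0.06, ~6%).
#' @param seed Integer seed.
#' @param region Optional logical mask restricting sampling (e.g. one image
#'   corner, as when an annotator labels a small region).
#' @return Integer label mask (0 = unlabeled).
#' @export
labelsFromClassImage <- function(classImage, fraction = 0.06, seed = 1L,
                                 region = NULL) {
  set.seed(seed)
  total <- round(fraction * length(classImage))
  per <- ceiling(total / 3)
  out <- matrix(0L, nrow(classImage), ncol(classImage))
  kern <- EBImage::makeBrush(3, "box")
  for (k in 1:3) {
    m <- classImage == k
    m <- asMat(EBImage::erode(asImg(m * 1), kern)) > 0.5
    if (!is.null(region)) m <- m & region
    idx <- which(m)
    if (length(idx) == 0L) next
    out[sample(idx, min(per, length(idx)))] <- k
  }
  out
}
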