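# Shared fixtures (computed once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

withFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# 256x256 tonsil-like scene, 25 cells: the workhorse for module tests
smallSpec <- function(seed = 1L, noiseSd = 0.02, corruptionFree = FALSE) {
  base <- tonsilSceneSpec(seed = seed, noiseSd = noiseSd,
                          corruptionFree = corruptionFree)
  sceneSpec(imageShape = c(256L, 256L), nCells = 25L,
            typeNames = base@typeNames, typeFreqs = base@typeFreqs,
            expression = base@expression, panel = base@panel,
            illuminationAmplitude = base@illuminationAmplitude,
            autofluorescence = base@autofluorescence,
            bleachResidual = base@bleachResidual,
            stageShifts = if (corruptionFree)
              matrix(0L, length(unique(base@panel$cycle)), 2L) else NULL,
            defocusSigmaPerZ = base@defocusSigmaPerZ,
            noiseSd = base@noiseSd, seed = seed)
}

# 160x160 scene with one cell of each type: every cycle carries signal
microSpec <- function(seed = 1L, noiseSd = 0.05) {
  base <- tonsilSceneSpec(seed = seed)
  sceneSpec(imageShape = c(160L, 160L), nCells = 8L,
            typeNames = base@typeNames, typeFreqs = rep(1 / 8, 8),
            expression = base@expression, panel = base@panel,
            noiseSd = noiseSd, seed = seed)
}

smallSimNoisy <- function() withFixture("smallSimNoisy",
                                        simulateRun(smallSpec(101)))
smallSimCF <- function() withFixture("smallSimCF",
                                     simulateRun(smallSpec(102, corruptionFree = TRUE)))

cropBy <- function(x, m) {
  if (m == 0) return(x)
  x[(m + 1):(nrow(x) - m), (m + 1):(ncol(x) - m)]
}

# preprocess + classify + segment + quantify + gate on the noisy small sim
smallChain <- function() withFixture("smallChain", {
  sim <- smallSimNoisy()
  pp <- preprocessRun(sim$run)
  corrected <- lapply(pp$images, function(x) x / 65535)
  m <- max(abs(pp$shifts))
  classImg <- cropBy(sim$truth@classImage, m)
  feats <- computePixelFeatures(list(dapi = corrected$DAPI,
                                     summem = sumMembranes(corrected,
                                                           panel(sim$run))))
  labs <- labelsFromClassImage(classImg, 0.06, seed = 11)
  model <- trainPixelClassifier(feats, labs, seed = 12)
  maps <- predictProbabilityMaps(model, feats)
  nuclei <- segmentNuclei(maps)
  cells <- segmentCells(nuclei, maps)
  tab <- extractMFI(cells, corrected, panel(sim$run), nuclei = nuclei,
                    geometry = geometry(sim$run))
  th <- suppressWarnings(defaultThresholds(tab))
  tab <- gateCells(tab, th, defaultGatingRules(panel(sim$run)))
  list(sim = sim, pp = pp, corrected = corrected, margin = m,
       classImg = classImg, feats = feats, model = model, maps = maps,
       nuclei = nuclei, cells = cells, table = tab, thresholds = th)
})

# match predicted cells to ground-truth cells by nearest centroid,
# returning the truth type mapped onto gating vocabulary
truthTypesFor <- function(tab, truth, margin) {
  cent <- truth@centersPx - margin
  idx <- vapply(seq_len(nrow(tab)), function(i)
    which.min((cent[, 1] - tab$centroid_row_px[i])^2 +
                (cent[, 2] - tab$centroid_col_px[i])^2), 1L)
  tt <- truth@types[idx]
  tt[tt == "other"] <- "others"
  tt
}

# ---- independent oracles ----

# exhaustive normalized cross-correlation over all shifts within maxShift
bruteForceShift <- function(moving, reference, maxShift) {
  a <- reference - mean(reference)
  best <- -Inf; bestShift <- c(0L, 0L)
  for (dr in -maxShift:maxShift) for (dc in -maxShift:maxShift) {
    b <- moving
    b <- b[((seq_len(nrow(b)) - 1 + dr) %% nrow(b)) + 1,
           ((seq_len(ncol(b)) - 1 + dc) %% ncol(b)) + 1]
    v <- sum(a * (b - mean(b)))
    if (v > best + 1e-9 ||
        (abs(v - best) <= 1e-9 &&
         (abs(dr) + abs(dc) < sum(abs(bestShift))))) {
      best <- v; bestShift <- c(dr, dc)
    }
  }
  bestShift
}

# O(N^2) niche membership: distance from a point to a label mask
bruteMinDistToMask <- function(pt, mask) {
  px <- which(mask, arr.ind = TRUE)
  sqrt(min((px[, 1] - pt[1])^2 + (px[, 2] - pt[2])^2))
}

bruteNicheComposition <- function(cells, tab, seedId, radiusPx,
                                  membership = "centroid_in_region") {
  seedMask <- cells == seedId
  types <- sort(unique(tab$gated_type))
  comp <- setNames(integer(length(types)), types)
  members <- integer(0)
  for (i in seq_len(nrow(tab))) {
    id <- tab$cell_id[i]
    if (id == seedId) next
    if (membership == "centroid_in_region") {
      pt <- c(round(tab$centroid_row_px[i]) + 1, round(tab$centroid_col_px[i]) + 1)
      d <- bruteMinDistToMask(pt, seedMask)
    } else {
      px <- which(cells == id, arr.ind = TRUE)
      sp <- which(seedMask, arr.ind = TRUE)
      d <- sqrt(min(outer(px[, 1], sp[, 1], `-`)^2 +
                      outer(px[, 2], sp[, 2], `-`)^2))
    }
    if (d <= radiusPx) {
      members <- c(members, id)
      comp[tab$gated_type[i]] <- comp[tab$gated_type[i]] + 1L
    }
  }
  list(members = members, composition = comp)
}

# brute-force Otsu: exhaustive over 256-bin split points; ties across the
# empty-gap plateau resolved to the middle split, as documented
bruteOtsu <- function(x, nbins = 256) {
  br <- seq(0, 1, length.out = nbins + 1)
  h <- tabulate(findInterval(pmin(pmax(x, 0), 1), br, rightmost.closed = TRUE),
                nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  v <- rep(-Inf, nbins - 1)
  for (k in 1:(nbins - 1)) {
    w0 <- sum(h[1:k]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:k] * mids[1:k]) / w0
    m1 <- sum(h[(k + 1):nbins] * mids[(k + 1):nbins]) / w1
    v[k] <- w0 * w1 * (m0 - m1)^2
  }
  ties <- which(v >= max(v) - abs(max(v)) * 1e-12)
  k <- ties[ceiling(length(ties) / 2)]
  mids[k] + (mids[2] - mids[1]) / 2
}

# draw an MFI table directly from type expression profiles (no imaging)
mixtureTable <- function(n, seed, noiseSd = 0.05, freqs = NULL) {
  base <- tonsilSceneSpec(seed = 1L)
  types <- base@typeNames
  if (is.null(freqs)) freqs <- base@typeFreqs
  set.seed(seed)
  cnt <- round(freqs * n)
  cnt[1] <- cnt[1] + n - sum(cnt)
  if ("ILC" %in% types && cnt[types == "ILC"] < 2) cnt[types == "ILC"] <- 2L
  lab <- sample(rep(types, cnt))
  m <- base@expression[lab, , drop = FALSE]
  m <- pmin(pmax(m + matrix(rnorm(length(m), 0, noiseSd), nrow(m)), 0), 1)
  tab <- data.frame(cell_id = seq_along(lab))
  for (j in colnames(base@expression)) tab[[paste0("mfi_", j)]] <- m[, j]
  tab$true_type <- lab
  tab
}

clusterPurity <- function(clusters, labels) {
  tb <- table(clusters, labels)
  sum(apply(tb, 1, max)) / length(labels)
}
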