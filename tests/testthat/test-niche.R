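# A hand-built 128x128 scene with disk cells at known positions
nicheScene <- function() {
  shape <- 128L
  cells <- matrix(0L, shape, shape)
  centers <- rbind(c(40, 40), c(40, 80), c(64, 40), c(90, 90), c(100, 30),
                   c(30, 100), c(64, 75), c(85, 55))
  types <- c("ILC", "B", "plasma", "B", "T_helper", "ILC", "plasma", "others")
  for (i in seq_len(nrow(centers)))
    cells[(row(cells) - centers[i, 1])^2 +
            (col(cells) - centers[i, 2])^2 <= 6^2] <- i
  tab <- data.frame(cell_id = seq_len(nrow(centers)),
                    centroid_row_px = centers[, 1] - 1,
                    centroid_col_px = centers[, 2] - 1,
                    area_px = as.integer(table(cells[cells > 0])),
                    gated_type = types)
  list(cells = cells, table = tab,
       geometry = acquisitionGeometry(c(shape, shape)))
}

test_that("niche composition equals the brute-force Euclidean oracle under both rules", {
  sc <- nicheScene()
  radiusPx <- round(10 / 0.325)
  for (rule in c("centroid_in_region", "any_overlap")) {
    niches <- buildNiches(sc$cells, sc$table, "ILC",
                          nicheParams(membership = rule), sc$geometry)
    expect_length(niches, 2)
    for (nc in niches) {
      oracle <- bruteNicheComposition(sc$cells, sc$table, nc$seed_cell_id,
                                      radiusPx, membership = rule)
      expect_identical(sort(nc$member_cell_ids), sort(oracle$members))
      expect_identical(nc$composition, oracle$composition)
    }
  }
})

test_that("a seed with no neighbors in range has an all-zero composition", {
  shape <- 128L
  cells <- matrix(0L, shape, shape)
  cells[(row(cells) - 30)^2 + (col(cells) - 30)^2 <= 5^2] <- 1L
  cells[(row(cells) - 110)^2 + (col(cells) - 110)^2 <= 5^2] <- 2L
  tab <- data.frame(cell_id = 1:2, centroid_row_px = c(29, 109),
                    centroid_col_px = c(29, 109), area_px = c(81L, 81L),
                    gated_type = c("ILC", "B"))
  n <- buildNiches(cells, tab, "ILC", nicheParams(),
                   acquisitionGeometry(c(shape, shape)))
  expect_equal(sum(n[[1]]$composition), 0)
  expect_error(buildNiches(cells, tab, "nope", nicheParams(),
                           acquisitionGeometry(c(shape, shape))),
               "unknown seed_type")
})

test_that("a one-pixel seed produces a niche area within 2% of pi r^2", {
  shape <- 128L
  cells <- matrix(0L, shape, shape)
  cells[64, 64] <- 1L
  tab <- data.frame(cell_id = 1L, centroid_row_px = 63, centroid_col_px = 63,
                    area_px = 1L, gated_type = "ILC")
  n <- buildNiches(cells, tab, "ILC", nicheParams(),
                   acquisitionGeometry(c(shape, shape)))
  radiusPx <- round(10 / 0.325)
  expect_equal(radiusPx, 31)
  expect_lt(abs(sum(n[[1]]$region) - pi * radiusPx^2) / (pi * radiusPx^2),
            0.02)
})

test_that("uniform placement yields niche frequencies near tissue frequencies", {
  set.seed(55)
  shape <- 400L
  n <- 260L
  pos <- cbind(sample(20:(shape - 20), n, TRUE), sample(20:(shape - 20), n, TRUE))
  keep <- !duplicated(pos)
  pos <- pos[keep, ]
  n <- nrow(pos)
  cells <- matrix(0L, shape, shape)
  cells[pos] <- seq_len(n)
  types <- sample(c("B", "T_helper", "myeloid", "others"), n, TRUE,
                  prob = c(0.4, 0.3, 0.2, 0.1))
  types[sample(n, 12)] <- "ILC"
  tab <- data.frame(cell_id = seq_len(n), centroid_row_px = pos[, 1] - 1,
                    centroid_col_px = pos[, 2] - 1, area_px = 1L,
                    gated_type = types)
  niches <- buildNiches(cells, tab, "ILC", nicheParams(),
                        acquisitionGeometry(c(shape, shape)))
  en <- nicheEnrichment(niches, tab, "ILC")
  m <- sum(sapply(niches, function(x) sum(x$composition)))
  for (i in seq_len(nrow(en))) {
    if (en$type[i] == "ILC") next
    p <- en$whole_tissue_freq[i]
    sdBin <- sqrt(p * (1 - p) / m)
    expect_lt(abs(en$niche_freq[i] - p), 3 * sdBin + 1e-9)
  }
})

test_that("constructed plasma-near-ILC co-placement is detected as enrichment", {
  sc <- nicheScene()  # plasma cells sit within 10 um of both ILC seeds
  niches <- buildNiches(sc$cells, sc$table, "ILC", nicheParams(), sc$geometry)
  en <- nicheEnrichment(niches, sc$table, "ILC")
  pl <- en[en$type == "plasma", ]
  expect_gt(pl$niche_freq, pl$whole_tissue_freq)
  # a single niche holding one plasma cell only gives niche_freq 1
  one <- niches[1]
  one[[1]]$composition[] <- 0L
  one[[1]]$composition["plasma"] <- 1L
  en1 <- nicheEnrichment(one, sc$table, "ILC")
  expect_equal(en1$niche_freq[en1$type == "plasma"], 1)
})

test_that("structure proximity matches a brute-force pixel-distance oracle", {
  sc <- nicheScene()
  mask <- matrix(FALSE, 128, 128)
  mask[, 60:63] <- TRUE   # vertical band
  prox <- structureProximity(sc$table, list(band = mask), sc$cells, "ILC",
                             nicheParams(), sc$geometry)
  # oracle: exact min distance from every ILC cell pixel to the band
  seedIds <- sc$table$cell_id[sc$table$gated_type == "ILC"]
  bandPx <- which(mask, arr.ind = TRUE)
  inRange <- vapply(seedIds, function(id) {
    px <- which(sc$cells == id, arr.ind = TRUE)
    d <- sqrt(min(outer(px[, 1], bandPx[, 1], `-`)^2 +
                    outer(px[, 2], bandPx[, 2], `-`)^2))
    d * 0.325 <= 10
  }, NA)
  expect_equal(unname(prox["band"]), mean(inRange))
  # overlap counts; far cells do not; monotone in the distance band
  expect_equal(unname(structureProximity(sc$table,
                                         list(m = sc$cells == 1), sc$cells,
                                         "ILC", nicheParams(), sc$geometry)["m"]),
               0.5)
  p5 <- structureProximity(sc$table, list(band = mask), sc$cells, "ILC",
                           nicheParams(structureDistanceUm = 5), sc$geometry)
  expect_lte(p5["band"], prox["band"])
  expect_warning(structureProximity(sc$table, list(e = mask & FALSE),
                                    sc$cells, "ILC", nicheParams(),
                                    sc$geometry), "empty")
})

test_that("compartment segmentation labels a follicle blob with a border band", {
  shape <- 200L
  geo <- acquisitionGeometry(c(shape, shape))
  cd20 <- matrix(0, shape, shape)
  cd20[(row(cd20) - 100)^2 + (col(cd20) - 100)^2 <= 40^2] <- 1
  cd3 <- matrix(0, shape, shape)
  comp <- segmentCompartments(list(CD20 = cd20, CD3 = cd3),
                              list(follicle = "CD20", t_zone = "CD3"), geo,
                              thresholds = c(CD20 = 0.5, CD3 = 0.5),
                              smoothSigmaUm = 6.5)
  expect_true("follicle_border" %in% comp$names)
  centerLab <- comp$labels[100, 100]
  expect_equal(comp$names[centerLab], "follicle")
  # a point ~5 um outside the smoothed follicle edge sits in the border band
  folMask <- comp$labels == which(comp$names == "follicle")
  dOut <- EBImage::distmap(EBImage::Image(1 - folMask))
  band <- dOut > 0 & dOut <= round(10 / 0.325)
  expect_true(all(comp$labels[band] == which(comp$names == "follicle_border")))
  # everything below the floor stays unassigned
  comp0 <- segmentCompartments(list(CD20 = cd20 * 0, CD3 = cd3),
                               list(follicle = "CD20", t_zone = "CD3"), geo,
                               thresholds = c(CD20 = 0.5, CD3 = 0.5),
                               smoothSigmaUm = 6.5)
  expect_true(all(comp0$labels == 0L))
  expect_error(segmentCompartments(list(CD20 = cd20),
                                   list(follicle = character(0)), geo),
               "no defining markers")
})

test_that("compartment assignment uses centroids and excludes unassigned cells", {
  shape <- 200L
  geo <- acquisitionGeometry(c(shape, shape))
  cd20 <- matrix(0, shape, shape)
  cd20[(row(cd20) - 100)^2 + (col(cd20) - 100)^2 <= 40^2] <- 1
  sma <- matrix(0, shape, shape); sma[, 1:30] <- 1
  comp <- segmentCompartments(list(CD20 = cd20, SMA = sma),
                              list(follicle = "CD20", septum = "SMA"), geo,
                              thresholds = c(CD20 = 0.5, SMA = 0.5),
                              smoothSigmaUm = 6.5)
  tab <- data.frame(cell_id = 1:3,
                    centroid_row_px = c(99, 99, 99),
                    centroid_col_px = c(99, 14, 185),
                    gated_type = c("ILC", "ILC", "B"))
  ac <- assignCompartments(tab, comp, seed_type = "ILC")
  expect_equal(ac$table$compartment[1], "follicle")
  expect_equal(ac$table$compartment[2], "septum")
  expect_equal(sum(ac$distribution, na.rm = TRUE), 1)
  # all ILCs placed in the septum -> septum fraction 1
  tab2 <- tab; tab2$centroid_col_px <- c(10, 14, 185)
  ac2 <- assignCompartments(tab2, comp, seed_type = "ILC")
  expect_equal(unname(ac2$distribution["septum"]), 1)
})
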