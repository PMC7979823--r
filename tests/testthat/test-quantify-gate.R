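test_that("MFI is the mean over the right mask per localization", {
  pan <- markerPanel(c("N", "M"), 1:2, c("DAPI-like", "PE"),
                     c("nuclear", "membrane"))
  cells <- matrix(0L, 64, 64); nuc <- matrix(0L, 64, 64)
  cells[20:40, 20:40] <- 1L
  nuc[28:32, 28:32] <- 1L
  imgs <- list(N = matrix(0.8, 64, 64), M = matrix(0.4, 64, 64))
  tab <- extractMFI(cells, imgs, pan, nuclei = nuc,
                    geometry = acquisitionGeometry(c(64, 64)))
  expect_equal(tab$mfi_M, 0.4)
  expect_equal(tab$mfi_N, 0.8)   # measured on the nucleus mask
  expect_equal(tab$area_px, 21L * 21L)
  expect_equal(tab$centroid_row_px, 29)  # 0-based mean of rows 20..40
  expect_equal(tab$centroid_y_um, 29 * 0.325)
  # missing marker image and missing nucleus are hard errors
  expect_error(extractMFI(cells, imgs[1], pan, nuclei = nuc), "missing")
  expect_error(extractMFI(cells, imgs, pan, nuclei = matrix(0L, 64, 64)),
               "zero-area nucleus")
  expect_error(extractMFI(cells, list(N = imgs$N, M = imgs$M * 3), pan,
                          nuclei = nuc), "scaled")
})

test_that("noiseless MFIs equal expression times footprint coverage", {
  sim <- smallSimCF()
  truth <- sim$truth
  run <- sim$run
  scenes01 <- lapply(truth@scenes, function(s) pmin(s, 1))
  tab <- extractMFI(truth@cellLabels, scenes01, panel(run),
                    nuclei = truth@nucleusLabels, geometry = geometry(run))
  memMask <- truth@classImage == 2
  for (i in seq_len(nrow(tab))) {
    id <- tab$cell_id[i]
    cellMask <- truth@cellLabels == id
    coverage <- sum(cellMask & memMask) / sum(cellMask)
    for (mk in c("CD45", "CD19", "CD3")) {
      expected <- unname(truth@expression[id, mk]) * coverage
      expect_equal(tab[[paste0("mfi_", mk)]][i], expected,
                   tolerance = 0.02 + 1e-9, ignore_attr = TRUE)
    }
    expect_equal(tab$mfi_DAPI[i], unname(truth@expression[id, "DAPI"]),
                 tolerance = 0.02, ignore_attr = TRUE)
  }
})

test_that("Otsu default thresholds match the brute-force oracle and honor overrides", {
  set.seed(41)
  x <- c(rnorm(120, 0.1, 0.05), rnorm(80, 0.7, 0.05))
  tab <- data.frame(cell_id = seq_along(x), mfi_A = pmin(pmax(x, 0), 1),
                    mfi_B = 0.3)
  th <- suppressWarnings(defaultThresholds(tab))
  expect_gt(th$thresholds["A"], 0.25)
  expect_lt(th$thresholds["A"], 0.55)
  expect_equal(unname(th$thresholds["A"]), bruteOtsu(tab$mfi_A),
               tolerance = 1 / 256 + 1e-9)
  expect_equal(unname(th$thresholds["B"]), 0.5)  # degenerate marker
  expect_warning(defaultThresholds(tab), "degenerate")
  th2 <- suppressWarnings(defaultThresholds(tab, manual = c(A = 0.42)))
  expect_equal(unname(th2$thresholds["A"]), 0.42)
  expect_equal(unname(th2$provenance["A"]), "manual")
  expect_error(defaultThresholds(tab[1:5, ]), ">= 20 cells")
})

test_that("gating applies the ILC/lineage and lineage-positive rules in priority order", {
  pan <- tonsilSceneSpec(1)@panel
  rules <- defaultGatingRules(pan)
  mk <- function(...) {
    v <- list(...)
    tab <- data.frame(cell_id = 1)
    for (m in pan$name) tab[[paste0("mfi_", m)]] <- 0.01
    for (m in names(v)) tab[[paste0("mfi_", m)]] <- v[[m]]
    tab
  }
  th <- setNames(rep(0.3, nrow(pan)), pan$name)
  gate1 <- function(tab) gateCells(tab, th, rules)$gated_type
  expect_equal(gate1(mk(CD45 = .6, CD127 = .6)), "ILC")
  expect_equal(gate1(mk(CD45 = .6, CD127 = .6, CD3 = .6)), "others")  # Lin+ blocks ILC
  expect_equal(gate1(mk(CD45 = .6, CD3 = .6, CD4 = .6)), "T_helper")
  expect_equal(gate1(mk(CD45 = .6, CD3 = .6, CD8 = .6)), "T_cytotoxic")
  expect_equal(gate1(mk(CD45 = .6, CD19 = .6)), "B")
  expect_equal(gate1(mk(CD138 = .6)), "plasma")
  expect_equal(gate1(mk(CD14 = .6)), "myeloid")
  expect_equal(gate1(mk(CD31 = .6)), "endothelial")
  expect_equal(gate1(mk()), "others")
  # positivity is threshold-inclusive
  expect_equal(gate1(mk(CD31 = 0.3)), "endothelial")
  # unknown marker in a rule is a config error
  badRules <- rules
  badRules[[1]]$requires_positive <- c("CD45", "NOPE")
  expect_error(gateCells(mk(), th, badRules), "NOPE")
})

test_that("gating is order-independent and counts are normalized", {
  tab <- mixtureTable(80, seed = 42)
  pan <- tonsilSceneSpec(1)@panel
  rules <- defaultGatingRules(pan)
  th <- suppressWarnings(defaultThresholds(tab))
  g1 <- gateCells(tab, th, rules)
  perm <- sample(nrow(tab))
  g2 <- gateCells(tab[perm, ], th, rules)
  expect_equal(g2$gated_type[order(perm)], g1$gated_type)
  ct <- countTypes(g1)
  expect_equal(sum(ct$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(ct$count), nrow(tab))
  # 10 cells with 4 B -> frequency 0.4
  toy <- data.frame(cell_id = 1:10,
                    gated_type = c(rep("B", 4), rep("others", 6)))
  expect_equal(countTypes(toy)$frequency[countTypes(toy)$type == "B"], 0.4)
})

test_that("gating recovers ground-truth types from profile mixtures", {
  pan <- tonsilSceneSpec(1)@panel
  rules <- defaultGatingRules(pan)
  # noiseless: 100% recovery
  tab0 <- mixtureTable(120, seed = 43, noiseSd = 0)
  g0 <- gateCells(tab0, suppressWarnings(defaultThresholds(tab0)), rules)
  truth0 <- ifelse(tab0$true_type == "other", "others", tab0$true_type)
  expect_equal(mean(g0$gated_type == truth0), 1)
  # noisy (sd 0.05): >= 95%
  tab1 <- mixtureTable(200, seed = 44, noiseSd = 0.05)
  g1 <- gateCells(tab1, suppressWarnings(defaultThresholds(tab1)), rules)
  truth1 <- ifelse(tab1$true_type == "other", "others", tab1$true_type)
  expect_gte(mean(g1$gated_type == truth1), 0.95)
})
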