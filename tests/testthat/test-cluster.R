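test_that("arcsinh transform matches closed form and preserves ranking", {
  tab <- data.frame(cell_id = 1:4, mfi_A = c(0, 0.2, 0.5, 1),
                    mfi_B = c(0.3, 0.1, 0.05, 0.9))
  m <- transformExpression(tab, clusterParams(arcsinhScale = 0.2))
  expect_equal(m[1, "A"], 0)
  expect_equal(m[2, "A"], 0.8813735870, tolerance = 1e-9)  # asinh(1)
  expect_identical(order(m[, "B"]), order(tab$mfi_B))
  # colon-mode cut-off drops cells expressing no marker above 0.1
  tab2 <- rbind(tab, data.frame(cell_id = 5, mfi_A = 0.04, mfi_B = 0.09))
  m2 <- transformExpression(tab2, clusterParams(applyCutoff = TRUE))
  expect_equal(nrow(m2), 4)
  expect_false("5" %in% rownames(m2))
})

test_that("the t-SNE embedding is seed-reproducible and separates distinct profiles", {
  set.seed(61)
  x <- rbind(matrix(rnorm(60 * 5, 0), ncol = 5),
             matrix(rnorm(60 * 5, 10), ncol = 5))
  rownames(x) <- seq_len(nrow(x))
  p <- clusterParams(perplexity = 15, nComponents = 5, seed = 7)
  e1 <- embedTSNE(x, p)
  e2 <- embedTSNE(x, p)
  expect_identical(e1, e2)
  labs <- rep(1:2, each = 60)
  sil <- cluster::silhouette(labs, dist(e1))
  expect_gte(mean(sil[, "sil_width"]), 0.5)
  expect_error(embedTSNE(x[1:20, ], clusterParams(perplexity = 30)),
               "perplexity")
})

test_that("clustering auto-selects k on mixtures and is stable under permutation", {
  set.seed(62)
  x <- rbind(matrix(rnorm(50 * 2, 0, 0.3), ncol = 2),
             matrix(rnorm(50 * 2, 5, 0.3), ncol = 2),
             sweep(matrix(rnorm(50 * 2, 0, 0.3), ncol = 2), 2, c(0, 7), `+`))
  rownames(x) <- seq_len(nrow(x))
  truth <- rep(1:3, each = 50)
  for (meth in c("density", "kmeans")) {
    cl <- clusterCells(x, k = "auto", seed = 3, kRange = 2:8, method = meth)
    expect_equal(length(unique(cl)), 3)
    expect_gte(clusterPurity(cl, truth), 0.9)
  }
  expect_equal(unique(clusterCells(x, k = 1, seed = 3)), 1L)
  # a duplicated-and-jittered single profile stays one blob
  y <- matrix(rep(c(1, 2), each = 60), ncol = 2) + rnorm(120, 0, 0.05)
  expect_equal(length(unique(clusterCells(y, k = "auto"))), 1)
  # permuting the rows gives the same partition up to label renaming
  perm <- sample(nrow(x))
  for (kk in list(3, "auto")) {
    cl1 <- clusterCells(x, k = kk, seed = 3)
    cl2 <- clusterCells(x[perm, ], k = kk, seed = 3)[order(perm)]
    tb <- table(cl1, cl2)
    expect_equal(sum(apply(tb, 1, max)), nrow(x))
  }
  expect_error(clusterCells(x, k = 500), "exceeds")
})

test_that("the cluster heat-map rescales each marker across clusters", {
  tab <- data.frame(cell_id = 1:6,
                    mfi_A = c(0.8, 0.9, 0.0, 0.1, 0.0, 0.1),
                    mfi_B = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
                    mfi_C = c(0.1, 0.3, 0.6, 0.8, 0.2, 0.4))
  cl <- c(1, 1, 2, 2, 3, 3)
  h <- clusterHeatmap(tab, cl)
  expect_equal(unname(h[, "A"]), c(1, 0, 0), tolerance = 1e-9)  # means .85/.05/.05
  expect_equal(unname(h[, "B"]), c(0, 0, 0))  # constant marker convention
  means <- c(0.2, 0.7, 0.3)
  expect_equal(unname(h[, "C"]), (means - min(means)) / diff(range(means)))
})

test_that("gate-cluster agreement reproduces direct fractions and marginals", {
  tab <- data.frame(cell_id = 1:30,
                    gated_type = c(rep("ILC", 23), rep("T_helper", 2),
                                   rep("plasma", 1), rep("B", 4)),
                    cluster_id = c(rep(1L, 26), rep(2L, 4)))
  a <- gateClusterAgreement(tab, 1L, "ILC")
  expect_equal(a$fraction, 23 / 26, tolerance = 1e-12)
  expect_equal(round(100 * a$fraction, 1), 88.5)
  expect_equal(unname(rowSums(a$confusion)), c(26, 4))
  # a cluster equal to the gated ILCs scores 1
  tab2 <- tab; tab2$cluster_id <- ifelse(tab2$gated_type == "ILC", 1L, 2L)
  expect_equal(gateClusterAgreement(tab2, 1L, "ILC")$fraction, 1)
  expect_error(gateClusterAgreement(tab, 9L, "ILC"), "empty cluster")
})

test_that("end-to-end clustering of profile mixtures recovers types and the ILC cluster", {
  # desk-scale mixture keeping the absolute ILC count near the embedding's
  # resolution limit (a population below the perplexity cannot form its own
  # t-SNE blob): 26 ILCs among 400 cells
  freqs <- c(0.28, 0.21, 0.095, 0.05, 0.115, 0.075, 0.065, 0.11)
  tab <- mixtureTable(400, seed = 63, noiseSd = 0.05, freqs = freqs)
  pan <- tonsilSceneSpec(1)@panel
  tab <- gateCells(tab, suppressWarnings(defaultThresholds(tab)),
                   defaultGatingRules(pan))
  p <- clusterParams(seed = 64)
  m <- transformExpression(tab, p)
  emb <- embedTSNE(m, p)
  cl <- clusterCells(emb, k = "auto", seed = 64)
  expect_gte(clusterPurity(cl, tab$true_type), 0.9)
  ilcCl <- as.integer(names(which.max(table(cl[tab$gated_type == "ILC"]))))
  ag <- gateClusterAgreement(tab, ilcCl, "ILC", cluster_id = cl)
  expect_gte(ag$fraction, 0.9)
})
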