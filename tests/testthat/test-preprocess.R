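test_that("registration recovers identity and known rolls, matching exhaustive search", {
  set.seed(31)
  img <- matrix(runif(96 * 96), 96)
  img <- asinh(img + outer(sin(1:96 / 5), cos(1:96 / 7)))  # structured
  r0 <- registerCycle(img, img, 10)
  expect_equal(r0$shift, c(0L, 0L))
  expect_equal(r0$registered, img)
  moving <- img[((seq_len(96) - 1 - 3) %% 96) + 1, ((seq_len(96) - 1 + 2) %% 96) + 1]
  r1 <- registerCycle(moving, img, 10)
  expect_equal(r1$shift, c(3L, -2L))
  expect_equal(bruteForceShift(moving, img, 10), c(3L, -2L))
  # registered content matches the reference away from the zero-filled border
  expect_equal(r1$registered[5:92, 5:92], img[5:92, 5:92])
})

test_that("correlation ties break to the smallest L1 shift, then lexicographically", {
  per <- matrix(0, 64, 64)
  per[(row(per) %% 4) == 0] <- 1  # periodic rows, period 4
  r <- registerCycle(per, per, 9)
  expect_equal(r$shift, c(0L, 0L))  # (±4,0), (±8,0) tie but are larger
  expect_error(registerCycle(matrix(1, 64, 64), matrix(1, 64, 64), 5),
               "degenerate-correlation")
})

test_that("bleach subtraction is clamped pixel arithmetic", {
  f <- matrix(1000, 4, 4); b <- matrix(300, 4, 4)
  expect_equal(subtractBackground(f, b), matrix(700, 4, 4))
  expect_equal(subtractBackground(f, f), matrix(0, 4, 4))
  expect_equal(subtractBackground(f, matrix(1200, 4, 4)), matrix(0, 4, 4))
  expect_error(subtractBackground(f, matrix(1, 3, 3)), "shape mismatch")
  expect_equal(subtractSecondary(f, matrix(0, 4, 4)), f)
})

test_that("illumination estimation recovers a flat field and a known smooth field", {
  expect_equal(estimateIllumination(matrix(5, 128, 128), 8),
               matrix(1, 128, 128))
  shape <- c(256L, 256L)
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  g <- 1 - 0.3 * ((r - 140)^2 + (cc - 115)^2) /
    max((r - 140)^2 + (cc - 115)^2)
  field <- estimateIllumination(0.1 * g, 16, 0.05, prob = 0)
  expect_lt(max(abs(field - g / mean(g))), 0.02)
  expect_gte(min(field), 0.05)
  # strong vignette: the floor clip engages
  g2 <- 1 - 0.999 * ((r - 128)^2 + (cc - 128)^2) /
    max((r - 128)^2 + (cc - 128)^2)
  f2 <- estimateIllumination(g2, 16, 0.3, prob = 0)
  expect_gte(min(f2), 0.3)
  expect_error(estimateIllumination(matrix(1, 64, 64), 3), "splineGrid")
})

test_that("illumination correction divides out an estimated field to within 2% on signal", {
  sim <- smallSimCF()
  scene <- sim$truth@scenes$CD45
  shape <- dim(scene)
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  g <- 1 - 0.3 * ((r - 150)^2 + (cc - 100)^2) /
    max((r - 150)^2 + (cc - 100)^2)
  field <- estimateIllumination(0.08 * g, 16, 0.05, prob = 0)
  corrected <- correctIllumination(scene * g, field)
  flat <- scene * mean(g)
  sel <- scene > 0.1
  expect_lt(max(abs(corrected[sel] - flat[sel]) / flat[sel]), 0.02)
  # identity and contract checks
  img <- matrix(runif(64 * 64), 64)
  expect_equal(correctIllumination(img, matrix(1, 64, 64)), img)
  expect_error(correctIllumination(img, matrix(1.5, 64, 64)), "mean 1")
})

test_that("illumination correction shrinks background variability on vignetted scenes", {
  base <- tonsilSceneSpec(1)
  spec <- sceneSpec(imageShape = c(256L, 256L), nCells = 25L,
                    typeNames = base@typeNames, typeFreqs = base@typeFreqs,
                    expression = base@expression, panel = base@panel,
                    illuminationAmplitude = 0.35, bleachResidual = 0,
                    stageShifts = matrix(0L, 7, 2), defocusSigmaPerZ = 0,
                    noiseSd = 0, seed = 33)
  sim <- simulateRun(spec)
  mid <- geometry(spec)@zSteps + 1
  fluo <- cycles(sim$run)[[2]]$fluo$CD45[, , mid]
  bleach <- rowMeans(cycles(sim$run)[[2]]$bleach$CD45, dims = 2)
  field <- estimateIllumination(bleach, 16, 0.05, prob = 0)
  corrected <- correctIllumination(fluo, field)
  bg <- sim$truth@cellLabels == 0 & !Reduce(`|`, sim$truth@structureMasks)
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(corrected[bg]), 0.2 * cv(fluo[bg]))
})

test_that("extended depth of field picks the sharp plane and honors ties", {
  one <- array(runif(64 * 64), dim = c(64, 64, 1))
  expect_equal(extendedDepthOfField(one, 9), one[, , 1])
  set.seed(34)
  sharp <- matrix(runif(96 * 96), 96)
  blur <- function(m)
    as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(m), 4)))
  blurred <- blur(sharp)
  left <- col(sharp) <= 48
  p1 <- ifelse(left, sharp, blurred)
  p3 <- ifelse(left, blurred, sharp)
  stack <- array(c(p1, blurred, p3), dim = c(96, 96, 3))
  out <- extendedDepthOfField(stack, 9)
  core <- function(m, cols) m[10:86, cols]
  expect_equal(core(out, 10:38), core(sharp, 10:38))
  expect_equal(core(out, 58:86), core(sharp, 58:86))
  same <- array(rep(sharp, 3), dim = c(96, 96, 3))
  expect_equal(extendedDepthOfField(same, 9), sharp)
  expect_error(extendedDepthOfField(stack, 8), "odd")
})

test_that("normalization flattens constants, stretches to 16-bit, and preserves contrast", {
  p <- preprocessParams(rollingBallRadiusPx = 20, cropMarginPx = 0)
  expect_equal(normalizeImage(matrix(7, 128, 128), p),
               matrix(0, 128, 128))
  set.seed(35)
  img <- matrix(runif(128 * 128, 0.2, 0.4), 128)
  out <- normalizeImage(img, p)
  expect_equal(min(out), 0)
  expect_equal(max(out), 65535)
  # ramp + disk: disk-background contrast preserved within 5%
  ramp <- outer(seq(0.2, 0.6, length.out = 128), rep(1, 128))
  disk <- matrix(0, 128, 128)
  disk[(row(disk) - 64)^2 + (col(disk) - 64)^2 <= 8^2] <- 0.5
  img2 <- ramp + disk
  sub <- img2 - melcpipe:::rollingBallBackground(img2, 20)
  inDisk <- disk > 0
  ring <- !inDisk & (row(disk) - 64)^2 + (col(disk) - 64)^2 <= 14^2
  contrastIn <- mean(img2[inDisk]) - mean(img2[ring])
  contrastSub <- mean(sub[inDisk]) - mean(sub[ring])
  expect_lt(abs(contrastSub - contrastIn) / contrastIn, 0.05)
  expect_error(normalizeImage(img, p, cropMarginPx = 40), "crop error")
})

test_that("the full chain recovers every ground-truth shift and crops symmetrically", {
  ch <- smallChain()
  expect_identical(ch$pp$shifts, ch$sim$truth@shifts,
                   ignore_attr = TRUE)
  expect_equal(unname(ch$pp$shifts), unname(ch$sim$truth@shifts))
  m <- ch$margin
  expect_equal(dim(ch$pp$images[[1]]),
               geometry(ch$sim$run)@imageShape - 2L * m)
  expect_equal(names(ch$pp$images), panel(ch$sim$run)$name)
  expect_true(all(vapply(ch$pp$images, min, 0) >= 0))
})
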