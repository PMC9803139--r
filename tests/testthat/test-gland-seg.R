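# Segmentation network: shape contracts, loss/weight formulas, tiling and
# instance post-processing.

deskSegConfig <- function(epochs = 2L) {
  segConfig(patch_size = 80L, width_scale = 1 / 8,
            blocks_per_stage = c(1L, 1L, 1L, 1L), epochs = epochs,
            min_area = 15, edge_thickness = 3)
}

test_that("network maps H x W x 3 to H x W x 3 class scores", {
  set.seed(1)
  net <- buildGaglNet(deskSegConfig())
  for (sz in c(80L, 96L)) {
    y <- net$forward(array(runif(sz * sz * 3), c(sz, sz, 3)),
                     training = FALSE)
    expect_equal(dim(y$value), c(sz, sz, 3L))
  }
  expect_error(segConfig(patch_size = 100L), "divisible")
})

test_that("global branch final feature stride follows the stage strides", {
  set.seed(1)
  net <- glandflow:::.netNew(list())
  enc <- glandflow:::.resEncoder(net, "g", 3L, 4L, blocks = rep(1L, 4))
  x <- glandflow:::agConst(array(runif(64 * 64 * 3), c(64, 64, 3)))
  h <- enc$stem(x, FALSE)
  for (s in 1:4) h <- enc$stages[[s]](h, FALSE)
  expect_equal(dim(h$value)[1:2], c(8L, 8L))     # stride 8 with dilated last
  enc16 <- glandflow:::.resEncoder(net, "g2", 3L, 4L, blocks = rep(1L, 4),
                                   last_stride = 2L, last_dil = 1L)
  h2 <- enc16$stem(x, FALSE)
  for (s in 1:4) h2 <- enc16$stages[[s]](h2, FALSE)
  expect_equal(dim(h2$value)[1:2], c(4L, 4L))    # stride 16 baseline
})

test_that("class weights are batch inverse frequencies", {
  balanced <- matrix(rep(0:2, length.out = 99), 9, 11)
  expect_true(all(abs(classWeights(balanced) - 1) < 1e-12))
  lab <- matrix(c(rep(0L, 80), rep(1L, 10), rep(2L, 10)), 10, 10)
  w <- classWeights(lab)
  expect_equal(unique(w[lab == 0L]), 100 / (3 * 80), tolerance = 1e-12)
  expect_equal(unique(w[lab == 1L]), 100 / (3 * 10), tolerance = 1e-12)
  # weighted pixel mass equal across present classes
  expect_equal(sum(w[lab == 0L]), sum(w[lab == 2L]), tolerance = 1e-9)
  # a lone class carries weight N/(3N) = 1/3; absent classes weight 0
  only0 <- matrix(0L, 4, 4)
  expect_true(all(abs(classWeights(only0) - 1 / 3) < 1e-12))
  mixed <- classWeights(list(matrix(0L, 2, 2), matrix(1L, 2, 2)))
  expect_length(mixed, 2L)
})

test_that("segmentation loss matches a hand-summed oracle", {
  # perfect prediction, no regularization -> 0
  lab <- matrix(sample(0:2, 16, TRUE), 4, 4)
  perfect <- array(0, c(4, 4, 3))
  for (k in 0:2) perfect[, , k + 1] <- (lab == k) * 1
  expect_equal(segLoss(perfect, lab, matrix(1, 4, 4)), 0, tolerance = 1e-5)
  # single pixel at t = exp(-1) -> 1
  p1 <- array(c(exp(-1), 1 - exp(-1), 0), c(1, 1, 3))
  expect_equal(segLoss(p1, matrix(0L, 1, 1), matrix(1, 1, 1)), 1,
               tolerance = 1e-9)
  # random tile vs naive per-pixel loop
  set.seed(21)
  probs <- array(runif(4 * 4 * 3), c(4, 4, 3))
  probs <- probs / array(rep(apply(probs, c(1, 2), sum), 3), dim(probs))
  w <- matrix(runif(16), 4, 4)
  oracle <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      oracle <- oracle - w[i, j] * log(probs[i, j, lab[i, j] + 1])
    }
  }
  expect_equal(segLoss(probs, lab, w), oracle, tolerance = 1e-6)
  expect_error(segLoss(probs * NA, lab, w), "NaN")
})

test_that("zero learning rate leaves weights untouched, training reduces loss", {
  set.seed(3)
  tiles <- lapply(1:2, function(i) generateTile(segPhantomSpec(30L + i)))
  cfg0 <- deskSegConfig(epochs = 2L)
  cfg0$lr <- 1e-12; cfg0$weight_decay <- 0; cfg0$momentum <- 0
  net <- buildGaglNet(cfg0)
  before <- lapply(net$params, function(p) p$value)
  trainSeg(net, tiles, cfg0, seed = 5L, augment = FALSE)
  after <- lapply(net$params, function(p) p$value)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)), before, after)), 1e-9)
  expect_lt(diff(range(net$loss_history)), 1e-6)

  cfg <- deskSegConfig(epochs = 5L)
  net2 <- buildGaglNet(cfg)
  trainSeg(net2, tiles, cfg, seed = 5L, augment = FALSE)
  expect_lt(net2$loss_history[5], net2$loss_history[1])
})

test_that("overlap tiling stitches to the input size and matches direct calls", {
  set.seed(4)
  cfg <- deskSegConfig()
  net <- buildGaglNet(cfg)
  # populate batch-norm running statistics so inference mode is defined
  for (i in 1:3) {
    net$forward(array(runif(80 * 80 * 3), c(80, 80, 3)), training = TRUE)
  }
  img <- array(runif(80 * 80 * 3), c(80, 80, 3))
  direct <- net$forward(img, training = FALSE)$value
  tiled <- predictTiled(net, img, tile = 80L, overlap = 0L)
  expect_equal(dim(tiled$probs), c(80L, 80L, 3L))
  expect_lt(max(abs(glandflow:::.softmax3(direct) - tiled$probs)), 1e-10)
  big <- array(runif(160 * 120 * 3), c(160, 120, 3))
  out <- predictTiled(net, big, tile = 80L, overlap = 16L)
  expect_equal(dim(out$probs), c(160L, 120L, 3L))
  expect_true(all(abs(apply(out$probs, c(1, 2), sum) - 1) < 1e-6))
  # stitching consistency probed with a short-range model (3x3 mean
  # filter), whose border effects cannot outrun the kept margins: the
  # stitched result must equal whole-image inference everywhere
  box3 <- list(forward = function(img, training = FALSE) {
    H <- dim(img)[1]; W <- dim(img)[2]
    pad <- array(0, c(H + 2L, W + 2L, 3L))
    pad[2:(H + 1L), 2:(W + 1L), ] <- img
    acc <- array(0, c(H, W, 3L))
    for (di in 0:2) {
      for (dj in 0:2) {
        acc <- acc + pad[(1L + di):(H + di), (1L + dj):(W + dj), ,
                         drop = FALSE]
      }
    }
    list(value = acc / 9)
  })
  flat <- array(runif(160 * 160 * 3), c(160, 160, 3))
  whole <- predictTiled(box3, flat, tile = 160L, overlap = 0L)
  stitched <- predictTiled(box3, flat, tile = 80L, overlap = 32L)
  expect_lt(max(abs(whole$probs - stitched$probs)), 1e-10)
  # a constant-colour image yields a spatially uniform prediction away
  # from the borders
  const <- predictTiled(box3, array(0.6, c(96, 96, 3)), tile = 96L,
                        overlap = 0L)
  inner <- const$probs[2:95, 2:95, ]
  expect_lt(max(abs(sweep(inner, 3, inner[1, 1, ]))), 1e-12)
})

test_that("post-processing separates rings, fills holes and thresholds area", {
  expect_equal(max(postprocess(matrix(0L, 32, 32), min_area = 5)), 0L)
  # two rings sharing an edge band stay distinct
  am <- matrix(0L, 24, 40)
  mk_ring <- function(cy, cx, r) {
    for (i in 1:24) for (j in 1:40) {
      d <- sqrt((i - cy)^2 + (j - cx)^2)
      if (d <= r - 3) am[i, j] <<- 1L else if (d <= r) am[i, j] <<- 2L
    }
  }
  mk_ring(12, 12, 9)
  mk_ring(12, 29, 9)   # edge bands touch around x = 20-21
  out <- postprocess(am, min_area = 5, edge_thickness = 3)
  expect_equal(max(out), 2L)
  # reclaimed instances include the edge band pixels
  expect_gt(sum(out > 0), sum(am == 1L))
  # area threshold boundary: area == min_area kept, min_area - 1 removed
  one <- matrix(0L, 16, 16)
  one[5:8, 5:8] <- 1L            # 16-pixel lumen
  expect_equal(max(postprocess(one, min_area = 16)), 1L)
  expect_equal(max(postprocess(one, min_area = 17)), 0L)
})

test_that("post-processing of one-hot ground truth recovers the instances", {
  s <- generateTile(segPhantomSpec(77L))
  lab <- labelMap(s)
  rebuilt <- postprocess(lab, min_area = 5,
                         edge_thickness = 3)
  gt <- instanceMask(s)
  m <- matchObjects(gt, rebuilt)
  expect_equal(m$n_tp, nrow(glandTable(s)))
  expect_equal(m$n_fp, 0L)
  expect_gt(objectDice(gt, rebuilt), 0.97)
})
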