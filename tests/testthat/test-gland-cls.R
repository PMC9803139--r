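# Classifier: crop preparation, focal loss, deformable attention and the
# training loop's degenerate behaviours.

tinyAttn <- function(levels = 3L) {
  deformAttnConfig(embed_dim = 8L, n_heads = 2L, n_levels = levels,
                   n_points = 2L, n_layers = 1L, ffn_dim = 16L)
}

tinyClsConfig <- function(...) {
  clsConfig(input_size = 48L, width_scale = 1 / 16, attn = tinyAttn(),
            epochs = 1L, ...)
}

test_that("prepareCrop rescales isotropically and pads to a square", {
  id <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(prepareCrop(id), id)
  wide <- array(1, c(448, 224, 3))
  out <- prepareCrop(wide)
  expect_equal(dim(out), c(224L, 224L, 3L))
  # scaled content occupies 224 x 112, centred with 56-px zero bands
  expect_true(all(out[, 1:56, ] == 0))
  expect_true(all(out[, 169:224, ] == 0))
  expect_true(all(out[, 57:168, ] > 0))
  set.seed(5)
  for (i in 1:10) {
    h <- sample(1:300, 1); w <- sample(1:300, 1)
    expect_equal(dim(prepareCrop(array(runif(h * w * 3), c(h, w, 3)))),
                 c(224L, 224L, 3L))
  }
  expect_error(prepareCrop(matrix(0, 3, 3)), "non-empty")
})

test_that("focal loss follows its closed form and limits", {
  expect_lt(focalLoss(1, 1 - 1e-9), 1e-8)
  expect_lt(focalLoss(0, 1e-9), 1e-8)
  expect_equal(focalLoss(1, 0.5, gamma = 2), 0.25 * log(2),
               tolerance = 1e-9)
  set.seed(6)
  p <- rep(c(0, 1), 10)
  s <- runif(20, 0.05, 0.95)
  bce <- -(p * log(s) + (1 - p) * log(1 - s))
  expect_equal(focalLoss(p, s, gamma = 0), bce, tolerance = 1e-12)
  expect_true(all(focalLoss(p, s, gamma = 2) >= 0))
  # monotone: decreasing in s for p = 1, increasing for p = 0
  sgrid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(focalLoss(rep(1, 19), sgrid)) < 0))
  expect_true(all(diff(focalLoss(rep(0, 19), sgrid)) > 0))
  expect_error(focalLoss(0.5, 0.5), "binary")
})

test_that("msdam agrees with the per-query loop oracle", {
  set.seed(7)
  cfg <- deformAttnConfig(embed_dim = 8L, n_heads = 2L, n_levels = 2L,
                          n_points = 2L, n_layers = 1L)
  pyramid <- list(array(rnorm(8 * 8 * 5), c(8, 8, 5)),
                  array(rnorm(4 * 4 * 3), c(4, 4, 3)))
  params <- msdamParams(cfg, level_channels = c(5L, 3L))
  params$b_off$value <- rnorm(length(params$b_off$value), sd = 1.5)
  params$w_att$value <- matrix(rnorm(length(params$w_att$value), sd = 0.5),
                               nrow(params$w_att$value))
  Nq <- 6L
  query <- matrix(rnorm(Nq * 8), Nq, 8)
  ref <- cbind(runif(Nq), runif(Nq))
  out <- msdam(query, ref, pyramid, params, cfg)
  oracle <- bruteMsdam(query, ref, pyramid, params, cfg)
  expect_lt(max(abs(out$value - oracle)), 1e-5)
  # attention weights sum to one per head over levels x points
  sums <- apply(out$attn, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-8))
  expect_error(msdam(query, cbind(ref[, 1] + 2, ref[, 2]), pyramid, params,
                     cfg), "reference points")
})

test_that("degenerate attention reduces to the value projection at the point", {
  set.seed(8)
  cfg <- deformAttnConfig(embed_dim = 4L, n_heads = 1L, n_levels = 1L,
                          n_points = 2L, n_layers = 1L)
  H <- 6L
  pyramid <- list(array(rnorm(H * H * 4), c(H, H, 4)))
  params <- msdamParams(cfg, level_channels = 4L)
  params$w_off$value[] <- 0; params$b_off$value[] <- 0
  params$w_att$value[] <- 0; params$b_att$value[] <- 0  # uniform weights
  params$w_out$value <- diag(4); params$b_out$value[] <- 0
  # reference at the centre of pixel (3, 4) (1-based)
  ref <- matrix(c((2 + 0.5) / H, (3 + 0.5) / H), 1)
  q <- matrix(rnorm(4), 1)
  out <- msdam(q, ref, pyramid, params, cfg)
  vm <- matrix(pyramid[[1]], H * H, 4) %*% params$w_val[[1]]$value
  expect_equal(as.vector(out$value), vm[3 + 3 * H, ], tolerance = 1e-10)
})

test_that("classifier emits calibrated scores and honours zero-init head", {
  set.seed(9)
  cfg <- tinyClsConfig()
  net <- buildImglVtnet(cfg)
  crop <- prepareCrop(array(runif(30 * 40 * 3), c(30, 40, 3)), 48L)
  out <- net$forward(crop, training = FALSE)
  expect_equal(out$score, 0.5)          # sigmoid(0) with zero-init head
  df <- classifyCrops(net, list(list(image = crop, id = 4L)))
  expect_equal(df$id, 4L)
  expect_true(df$score > 0 && df$score < 1)
})

test_that("training degenerates correctly: zero lr and frozen teacher", {
  set.seed(10)
  cfg <- tinyClsConfig(lr = 1e-12)
  net <- buildImglVtnet(cfg)
  crops <- lapply(1:2, function(i) {
    list(image = array(runif(20 * 20 * 3), c(20, 20, 3)),
         label = c("IM", "normal")[i])
  })
  before <- lapply(net$params, function(p) p$value)
  trainCls(net, crops, config = cfg, seed = 2L, augment = FALSE)
  after <- lapply(net$params, function(p) p$value)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)), before, after)),
            1e-8)
  # EMA decay 1 freezes the teacher at initialization
  cfg2 <- tinyClsConfig(lr = 1e-3, ema_decay = 1)
  net2 <- buildImglVtnet(cfg2)
  init <- lapply(net2$params, function(p) p$value)
  trainCls(net2, crops, unlabeled = crops[1], config = cfg2,
           mean_teacher = TRUE, seed = 2L, augment = FALSE)
  drift <- max(mapply(function(nm) {
    max(abs(net2$teacher$params[[nm]] - init[[nm]]))
  }, names(init)))
  expect_lt(drift, 1e-12)
})
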