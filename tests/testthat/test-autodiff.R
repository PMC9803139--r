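# Finite-difference verification of the autodiff engine's building blocks.

ag <- function(name) getFromNamespace(name, "glandflow")

test_that("convolution family gradients match finite differences", {
  set.seed(11)
  H <- 6L; W <- 6L; cin <- 2L; cout <- 3L
  x0 <- array(rnorm(H * W * cin), c(H, W, cin))
  w <- ag("agParam")(array(rnorm(3 * 3 * cin * cout, sd = 0.3),
                           c(3, 3, cin, cout)))
  b <- ag("agParam")(rnorm(cout))
  wt <- ag("agParam")(array(rnorm(4 * 4 * cout * cin, sd = 0.3),
                            c(4, 4, cout, cin)))
  cases <- list(
    plain = function(x) ag("agSum")(ag("agPow")(
      ag("agConv2d")(x, w, b, stride = 1L, pad = 1L), 2)),
    strided = function(x) ag("agSum")(ag("agPow")(
      ag("agConv2d")(x, w, b, stride = 2L, pad = 1L), 2)),
    dilated = function(x) ag("agSum")(ag("agPow")(
      ag("agConv2d")(x, w, b, stride = 1L, pad = 2L, dil = 2L), 2)),
    transposed = function(x) ag("agSum")(ag("agPow")(
      ag("agConvT2d")(x, wt, b, stride = 2L, pad = 1L), 2)))
  for (nm in names(cases)) {
    f <- cases[[nm]]
    xt <- ag("agParam")(x0)
    ag("agBackward")(f(xt))
    ng <- numGrad(function(v) f(ag("agTensor")(v))$value, x0)
    expect_lt(max(abs(xt$grad - ng)), 1e-4)
    # weight gradients through the same loss
    ag("agZeroGrad")(list(w, wt, b))
    ag("agBackward")(f(ag("agTensor")(x0)))
    for (p in list(w, b)) {
      if (is.null(p$grad)) next
      ngp <- numGrad(function(v) {
        old <- p$value; p$value <- v
        r <- f(ag("agTensor")(x0))$value
        p$value <- old
        r
      }, p$value)
      expect_lt(max(abs(p$grad - ngp)), 1e-3)
      ag("agZeroGrad")(list(p))
    }
  }
})

test_that("normalization, pooling and fused-loss gradients are correct", {
  set.seed(12)
  H <- 6L; W <- 6L; C <- 2L
  x0 <- array(rnorm(H * W * C), c(H, W, C))
  g1 <- ag("agParam")(rnorm(C)); b1 <- ag("agParam")(rnorm(C))
  st <- new.env()
  lab <- matrix(sample(0:2, H * W, TRUE), H, W)
  wts <- matrix(runif(H * W), H, W)
  wk <- ag("agParam")(array(rnorm(C * 3, sd = 0.3), c(1, 1, C, 3)))
  cases <- list(
    bnorm = function(x) ag("agSum")(ag("agPow")(
      ag("agBnorm")(x, g1, b1, st, training = TRUE), 2)),
    gnorm = function(x) ag("agSum")(ag("agPow")(
      ag("agGroupNorm")(x, 2L, g1, b1), 2)),
    maxpool = function(x) ag("agSum")(ag("agPow")(ag("agMaxpool2")(x), 2)),
    gap = function(x) ag("agSum")(ag("agPow")(ag("agGap")(x), 2)),
    softnll = function(x) ag("agSoftmaxNll")(
      ag("agConv2d")(x, wk), lab, wts))
  for (nm in names(cases)) {
    f <- cases[[nm]]
    xt <- ag("agParam")(x0)
    ag("agBackward")(f(xt))
    ng <- numGrad(function(v) f(ag("agTensor")(v))$value, x0)
    expect_lt(max(abs(xt$grad - ng)), 1e-3)
  }
})

test_that("focal BCE node matches the numeric focal loss and its gradient", {
  set.seed(13)
  z <- rnorm(6)
  p <- rep(c(0, 1), 3)
  node <- ag("agFocalBce")(ag("agParam")(z), p, gamma = 2)
  s <- 1 / (1 + exp(-z))
  expect_equal(node$value, mean(focalLoss(p, s, gamma = 2)), tolerance = 1e-9)
  zt <- ag("agParam")(z)
  ag("agBackward")(ag("agFocalBce")(zt, p, gamma = 2))
  ng <- numGrad(function(v) ag("agFocalBce")(ag("agTensor")(v), p, 2)$value,
                z)
  expect_lt(max(abs(zt$grad - ng)), 1e-6)
})

test_that("group normalization output has per-group zero mean unit variance", {
  set.seed(14)
  x <- ag("agTensor")(array(rnorm(8 * 8 * 4, mean = 3, sd = 2),
                            c(8, 8, 4)))
  g <- ag("agParam")(rep(1, 4)); b <- ag("agParam")(rep(0, 4))
  y <- ag("agGroupNorm")(x, 2L, g, b)$value
  for (grp in 1:2) {
    v <- as.vector(y[, , (2 * grp - 1):(2 * grp)])
    expect_lt(abs(mean(v)), 1e-4)
    expect_lt(abs(stats::sd(v) - 1), 1e-2)
  }
})
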