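# Phantom generator: determinism, ground-truth consistency, IM rendering.

test_that("empty and deterministic generation behave as specified", {
  sp0 <- deskPhantomSpec(seed = 3L, nGlands = 0L)
  s0 <- generateTile(sp0)
  expect_true(all(instanceMask(s0) == 0L))
  expect_equal(nrow(glandTable(s0)), 0L)

  sp <- deskPhantomSpec(seed = 7L, nGlands = 5L)
  a <- generateTile(sp)
  b <- generateTile(sp)
  expect_identical(phantomImage(a), phantomImage(b))
  expect_identical(instanceMask(a), instanceMask(b))
  expect_identical(glandTable(a), glandTable(b))
})

test_that("ground-truth layers are mutually consistent", {
  s <- generateTile(deskPhantomSpec(seed = 1L, nGlands = 5L,
                                    imFraction = 0.4))
  lab <- labelMap(s)
  inst <- instanceMask(s)
  # lumen+edge pixels are exactly the instance foreground
  expect_identical(lab > 0L, inst > 0L)
  # per-class pixel counts conserve the tile area
  expect_equal(sum(tabulate(as.vector(lab) + 1L, 3L)), length(lab))
  expect_true(all(mucosaMask(s)[inst > 0L] == 1L))
  expect_true(all(tissueMask(s)[mucosaMask(s) == 1L] == 1L))
  # every edge ring encloses a lumen of the same instance
  for (id in glandTable(s)$id) {
    expect_gt(sum(lab == 1L & inst == id), 0)
    expect_gt(sum(lab == 2L & inst == id), 0)
  }
})

test_that("IM allocation and rendered areas follow the scale factor", {
  s <- generateTile(deskPhantomSpec(seed = 1L, nGlands = 5L,
                                    imFraction = 0.4))
  tab <- glandTable(s)
  expect_equal(sum(tab$class == "IM"), 2L)   # round(0.4 * 5)
  # pixel-count oracle: areas re-measured from the emitted mask
  areas <- vapply(tab$id, function(id) sum(instanceMask(s) == id),
                  numeric(1))
  expect_equal(unname(areas), tab$area)
  ratio <- mean(tab$area[tab$class == "IM"]) /
    mean(tab$area[tab$class == "normal"])
  expect_gt(ratio, 1.5^2 * 0.75)
  expect_lt(ratio, 1.5^2 * 1.25)
})

test_that("pseudo-WSI stitching renumbers ids and scales dimensions", {
  sp <- deskPhantomSpec(seed = 2L, nGlands = 4L)
  w22 <- generatePseudoWSI(sp, rows = 2L, cols = 2L)
  expect_equal(dim(phantomImage(w22))[1:2], rep(2L * sp@tileSize, 2))
  k <- nrow(glandTable(w22))
  expect_identical(sort(unique(as.vector(instanceMask(w22)))),
                   c(0L, seq_len(k)))
  expect_identical(sort(glandTable(w22)$id), seq_len(k))
  w11 <- generatePseudoWSI(sp, rows = 1L, cols = 1L)
  expect_equal(dim(phantomImage(w11)), dim(phantomImage(generateTile(sp))))
})

test_that("gland crops cover bounding boxes and balance classes", {
  s <- generateTile(deskPhantomSpec(seed = 4L, nGlands = 5L,
                                    imFraction = 0.4))
  crops <- makeGlandCrops(s)
  expect_length(crops, 5L)
  inst <- instanceMask(s)
  for (cr in crops) {
    px <- which(inst == cr$id, arr.ind = TRUE)
    expect_equal(dim(cr$image)[1:2],
                 c(diff(range(px[, 1])) + 1L, diff(range(px[, 2])) + 1L))
  }
  # class balance over ~200 glands at imFraction 0.5
  labels <- unlist(lapply(1:50, function(i) {
    glandTable(generateTile(deskPhantomSpec(seed = 400L + i, nGlands = 4L,
                                            imFraction = 0.5)))$class
  }))
  expect_equal(sum(labels == "IM"), sum(labels == "normal"))
})

test_that("infeasible packing fails with an explicit error", {
  sp <- phantomSpec(tileSize = 64L, nGlands = 40L,
                    glandRadiusRange = c(8, 10), edgeThickness = 2,
                    seed = 1L)
  expect_error(generateTile(sp, max_attempts = 30L), "infeasible")
})

test_that("artifacts perturb the image but never the ground truth", {
  clean <- generateTile(deskPhantomSpec(seed = 9L, nGlands = 4L))
  art <- generateTile(deskPhantomSpec(seed = 9L, nGlands = 4L,
                                      artifactTypes = c("pen", "debris")))
  expect_identical(instanceMask(clean), instanceMask(art))
  expect_identical(tissueMask(clean), tissueMask(art))
  expect_false(identical(phantomImage(clean), phantomImage(art)))
})
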