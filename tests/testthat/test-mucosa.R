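# Weak supervision chain: k-means seeding, exact graph cuts, U-Net
# contracts and mucosa morphology.

test_that("k-means seeding separates a two-tone image and is deterministic", {
  img <- array(0, c(20, 20, 3))
  img[, 1:10, ] <- 0.95                      # white background half
  img[, 11:20, 1] <- 0.9; img[, 11:20, 2] <- 0.55; img[, 11:20, 3] <- 0.65
  sd1 <- kmeansSeed(img, k = 2L, seed = 1L, unlabeled_quantile = 0)
  expect_true(all(sd1$labels[, 1:10] == 0L))
  expect_true(all(sd1$labels[, 11:20] == 1L))
  sd2 <- kmeansSeed(img, k = 2L, seed = 1L, unlabeled_quantile = 0)
  expect_identical(sd1$labels, sd2$labels)
  expect_warning(kmeansSeed(array(0.5, c(8, 8, 3)), k = 3L), "degenerate")
})

test_that("phantom seeding accuracy beats 0.95 against the tissue mask", {
  s <- generateTile(denseMucosaSpec(seed = 31L))
  sd <- kmeansSeed(phantomImage(s), k = 3L, seed = 1L)
  lab <- sd$labels
  ok <- !is.na(lab)
  acc <- mean(lab[ok] == tissueMask(s)[ok])
  expect_gt(acc, 0.95)
})

test_that("graph-cut solves decoupled and smoothing-dominated energies", {
  # all pairwise costs zero -> per-pixel argmin of the unary term
  set.seed(41)
  H <- 3L; W <- 4L
  unary <- cbind(runif(H * W), runif(H * W))
  idx <- matrix(seq_len(H * W), H, W)
  edges <- rbind(cbind(as.vector(idx[-H, ]), as.vector(idx[-1, ])),
                 cbind(as.vector(idx[, -W]), as.vector(idx[, -1])))
  g0 <- structure(list(H = H, W = W, unary = unary, edges = edges,
                       pair = rep(0, nrow(edges))), class = "graph_spec")
  out <- graphcutLabels(g0)
  expect_identical(as.vector(out$labels),
                   as.integer(unary[, 2] < unary[, 1]))
  # uniform unary with a dominant Potts term -> a single label everywhere
  gS <- g0
  gS$unary <- cbind(rep(0.5, H * W), runif(H * W, 0.45, 0.55))
  gS$pair <- rep(100, nrow(edges))
  outS <- graphcutLabels(gS)
  expect_equal(length(unique(as.vector(outS$labels))), 1L)
  gneg <- g0; gneg$pair <- rep(-1, nrow(edges))
  expect_error(graphcutLabels(gneg), "submodular")
})

test_that("2x2 toy energy matches exhaustive enumeration", {
  unary <- rbind(c(1.0, 0.2), c(0.3, 0.8), c(0.6, 0.45), c(0.05, 0.9))
  edges <- rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4))
  g <- structure(list(H = 2L, W = 2L, unary = unary, edges = edges,
                      pair = c(0.25, 0.4, 0.15, 0.3)),
                 class = "graph_spec")
  out <- graphcutLabels(g)
  brute <- bruteGraphMin(g)
  expect_equal(out$energy, brute$energy, tolerance = 1e-12)
  expect_identical(as.vector(out$labels), brute$labels)
})

test_that("energy construction follows the contrast-sensitive Potts form", {
  s <- generateTile(denseMucosaSpec(seed = 32L))
  img <- phantomImage(s)
  sd <- kmeansSeed(img, k = 3L, seed = 1L)
  expect_error(buildEnergy(img, sd, lambda = -1), "lambda")
  g <- buildEnergy(img, sd, lambda = 7)
  px <- matrix(img, nrow(g$unary), 3L)
  # closed form on a handful of random edges
  set.seed(42)
  for (e in sample(nrow(g$edges), 20L)) {
    d2 <- sum((px[g$edges[e, 1], ] - px[g$edges[e, 2], ])^2)
    expect_equal(g$pair[e], 7 * exp(-g$beta * d2), tolerance = 1e-12)
  }
  # lambda = 0 reduces the cut to nearest-centroid unary labelling
  g0 <- buildEnergy(img, sd, lambda = 0)
  out <- graphcutLabels(g0)
  expect_identical(as.vector(out$labels),
                   as.integer(g0$unary[, 2] < g0$unary[, 1]))
  # hard-clamped seeds never flip, even under heavy smoothing
  gBig <- buildEnergy(img, sd, lambda = 500)
  outBig <- graphcutLabels(gBig)
  hard <- g$unary[, 1] >= 1e6 | g$unary[, 2] >= 1e6
  clamped_label <- as.integer(g$unary[, 1] >= 1e6)  # cost on bg => tissue
  expect_true(all(as.vector(outBig$labels)[hard] == clamped_label[hard]))
})

test_that("graph-cut energy never exceeds the seed labelling energy", {
  s <- generateTile(denseMucosaSpec(seed = 33L))
  sd <- kmeansSeed(phantomImage(s), k = 3L, seed = 1L)
  g <- buildEnergy(phantomImage(s), sd, lambda = 10)
  out <- graphcutLabels(g)
  seedlab <- sd$labels
  seedlab[is.na(seedlab)] <- 0L
  expect_lte(out$energy, graphEnergy(g, seedlab))
  expect_equal(out$energy, graphEnergy(g, out$labels), tolerance = 1e-9)
})

test_that("U-Net keeps spatial dimensions and zero lr keeps weights", {
  set.seed(43)
  cfg <- unetConfig(width_scale = 1 / 16, patch_size = 32L,
                    batch_size = 2L, epochs = 1L)
  un <- buildTissueUnet(cfg)
  for (sz in c(32L, 48L)) {
    z <- un$forward(array(runif(sz * sz * 3), c(sz, sz, 3)),
                    training = FALSE)
    expect_equal(dim(z$value), c(sz, sz, 1L))
  }
  cfg0 <- cfg; cfg0$lr <- 1e-13
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  lab <- matrix(rbinom(32 * 32, 1, 0.5), 32, 32)
  before <- lapply(un$params, function(p) p$value)
  trainTissueUnet(list(img), list(lab), cfg0, seed = 3L, model = un)
  after <- lapply(un$params, function(p) p$value)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)), before, after)),
            1e-8)
})

test_that("segmentTissue removes small debris and returns a binary mask", {
  set.seed(44)
  cfg <- unetConfig(width_scale = 1 / 16, patch_size = 64L,
                    batch_size = 20L, epochs = 10L)
  s <- generateTile(denseMucosaSpec(seed = 34L,
                                    artifactTypes = "debris"))
  sd <- kmeansSeed(phantomImage(s), k = 3L, seed = 1L)
  cut <- graphcutLabels(buildEnergy(phantomImage(s), sd))
  un <- trainTissueUnet(list(phantomImage(s)), list(cut$labels), cfg,
                        seed = 4L)
  mask <- segmentTissue(un, phantomImage(s), tile = 128L, overlap = 16L,
                        min_artifact_area = 120, min_hole_area = 400)
  expect_true(all(mask %in% c(0L, 1L)))
  # debris blobs (area << 120) outside tissue must be gone
  comp <- EBImage::bwlabel(mask)
  areas <- tabulate(comp[comp > 0])
  expect_true(all(areas >= 120))
  expect_gt(pixelDice(tissueMask(s), mask), 0.9)
})

test_that("mucosa closing merges neighbours and stays inside tissue", {
  tissue <- matrix(1L, 40, 60)
  glands <- matrix(0L, 40, 60)
  glands[16:24, 10:18] <- 1L
  glands[16:24, 29:37] <- 2L          # 10 px apart
  mm <- mucosaMaskFromGlands(glands, tissue, dilate_r = 6, erode_r = 6)
  expect_equal(max(EBImage::bwlabel(mm$M)), 1L)        # merged
  expect_true(all(mm$Gt[glands > 0] == 1L))            # closing extensive
  expect_true(all(mm$M <= tissue))
  # idempotence of the closing on its own output
  mm2 <- mucosaMaskFromGlands(mm$Gt, tissue, dilate_r = 6, erode_r = 6)
  expect_identical(mm2$Gt, mm$Gt)
  # empty gland mask -> empty mucosa
  mm0 <- mucosaMaskFromGlands(matrix(0L, 40, 60), tissue, 6, 6)
  expect_equal(sum(mm0$M), 0L)
  expect_error(mucosaMaskFromGlands(glands, tissue, dilate_r = 2,
                                    erode_r = 5))
})
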