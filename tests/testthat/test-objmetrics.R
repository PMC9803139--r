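# Object-level metrics against definitions and brute-force oracles.

test_that("matching follows the >50%-of-gt-area rule", {
  m <- matrix(0L, 10, 10)
  m[2:4, 2:4] <- 1L
  m[6:9, 6:9] <- 2L
  same <- matchObjects(m, m)
  expect_equal(same$n_tp, 2L)
  expect_equal(same$n_fp + same$n_fn, 0L)
  # 40% coverage is not a detection
  gt <- matrix(0L, 10, 10); gt[1:2, 1:5] <- 1L       # area 10
  seg <- matrix(0L, 10, 10); seg[1:2, 1:2] <- 1L     # overlap 4 (40%)
  m40 <- matchObjects(gt, seg)
  expect_equal(c(m40$n_tp, m40$n_fp, m40$n_fn), c(0L, 1L, 1L))
  seg[1:2, 1:3] <- 1L                                # overlap 6 (60%)
  m60 <- matchObjects(gt, seg)
  expect_equal(m60$n_tp, 1L)
  # constructed 3 gt / 2 seg with 60% / 55% / 0% overlaps
  gt3 <- matrix(0L, 12, 30)
  gt3[2:11, 1:10] <- 1L; gt3[2:11, 11:20] <- 2L; gt3[2:11, 21:30] <- 3L
  seg2 <- matrix(0L, 12, 30)
  seg2[2:11, 1:6] <- 1L                              # 60% of gt 1
  seg2[2:11, 12:17] <- 2L                            # 55% (wait: 60) of gt 2
  m32 <- matchObjects(gt3, seg2)
  oracle <- bruteMatchCounts(gt3, seg2)
  expect_equal(c(m32$n_tp, m32$n_fp, m32$n_fn),
               unname(c(oracle["tp"], oracle["fp"], oracle["fn"])))
})

test_that("detection scores follow the F1 formulas", {
  mk <- function(tp, fp, fn) list(n_tp = tp, n_fp = fp, n_fn = fn)
  expect_equal(unname(f1Detection(mk(10, 0, 0))), c(1, 1, 1))
  expect_equal(unname(f1Detection(mk(1, 1, 1))), c(0.5, 0.5, 0.5))
  r <- f1Detection(mk(3, 1, 2))
  expect_equal(unname(r), c(0.75, 0.6, 2 * 0.75 * 0.6 / 1.35),
               tolerance = 1e-12)
  expect_warning(z <- f1Detection(mk(0, 0, 0)), "no objects")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("object Dice matches hand counts and the brute-force oracle", {
  m <- matrix(0L, 8, 8); m[2:3, 2:3] <- 1L
  expect_equal(objectDice(m, m), 1)
  # 2x2 squares offset by one column: overlap 2, D = 0.5
  gt <- matrix(0L, 6, 6); gt[1:2, 1:2] <- 1L
  seg <- matrix(0L, 6, 6); seg[1:2, 2:3] <- 1L
  expect_equal(objectDice(gt, seg), 0.5, tolerance = 1e-12)
  disj <- matrix(0L, 6, 6); disj[5:6, 5:6] <- 1L
  expect_equal(objectDice(gt, disj), 0)
  expect_equal(objectDice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_equal(objectDice(gt, matrix(0L, 6, 6)), 0)
})

test_that("object Hausdorff matches forced cases and the naive oracle", {
  m <- matrix(0L, 8, 8); m[3:5, 3:5] <- 1L
  expect_equal(objectHausdorff(m, m), 0)
  a <- matrix(0L, 5, 5); a[1, 1] <- 1L
  b <- matrix(0L, 5, 5); b[1, 4] <- 1L
  expect_equal(objectHausdorff(a, b), 3)
  expect_error(objectHausdorff(a, matrix(0L, 5, 5)), "at least one")
})

test_that("all three metrics agree exactly with oracles on random masks", {
  set.seed(77)
  for (i in 1:40) {
    gt <- randomInstanceMask(12L)
    seg <- randomInstanceMask(12L)
    if (max(gt) == 0L || max(seg) == 0L) next
    expect_equal(objectDice(gt, seg), bruteObjectDice(gt, seg),
                 tolerance = 1e-12)
    expect_equal(objectHausdorff(gt, seg), bruteObjectHausdorff(gt, seg),
                 tolerance = 1e-12)
    m <- matchObjects(gt, seg)
    o <- bruteMatchCounts(gt, seg)
    expect_equal(c(m$n_tp, m$n_fp, m$n_fn),
                 unname(c(o["tp"], o["fp"], o["fn"])))
    # symmetry and bounds
    expect_equal(objectDice(gt, seg), objectDice(seg, gt),
                 tolerance = 1e-12)
    expect_gte(objectDice(gt, seg), 0)
    expect_lte(objectDice(gt, seg), 1)
  }
})

test_that("hausdorff does not increase when both masks dilate identically", {
  set.seed(78)
  br <- EBImage::makeBrush(3, "box")
  for (i in 1:10) {
    gt <- randomInstanceMask(12L, n_obj = 1L)
    seg <- randomInstanceMask(12L, n_obj = 1L)
    if (max(gt) == 0L || max(seg) == 0L) next
    h0 <- objectHausdorff(gt, seg)
    gtd <- matrix(as.integer(EBImage::dilate(gt > 0, br)), 12, 12)
    segd <- matrix(as.integer(EBImage::dilate(seg > 0, br)), 12, 12)
    expect_lte(objectHausdorff(gtd, segd), h0 + 1e-9)
  }
})

test_that("directory evaluation pairs files and averages reports", {
  td <- withr::local_tempdir()
  gtd <- file.path(td, "gt"); segd <- file.path(td, "seg")
  dir.create(gtd); dir.create(segd)
  set.seed(79)
  for (i in 1:3) {
    m <- randomInstanceMask(14L)
    writeInstanceMask(m, file.path(gtd, sprintf("img%d.tif", i)))
    writeInstanceMask(m, file.path(segd, sprintf("img%d.tif", i)))
  }
  rep <- evaluateMasks(gtd, segd)
  expect_equal(nrow(rep), 4L)                     # 3 images + mean row
  expect_true(all(rep$f1 == 1))
  expect_true(all(rep$object_dice == 1))
  expect_true(all(rep$object_hausdorff == 0))
  # unmatched files warn and are skipped
  writeInstanceMask(randomInstanceMask(14L), file.path(segd, "extra.tif"))
  expect_warning(rep2 <- evaluateMasks(gtd, segd), "unmatched")
  expect_equal(nrow(rep2), 4L)
  expect_error(evaluateMasks(gtd, file.path(td, "empty")), "no predicted")
})
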