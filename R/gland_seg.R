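# Two-branch gland segmentation network ("GAGL-Net"): a global residual
# four-stage encoder (7x7 stem, dilated final stage) and a local VGG-style
# encoder (3x3 stem) with multi-level upsampling heads. Both branches'
# full-resolution maps are concatenated ahead of the 3-class head
# (background / lumen / edge). Training uses the class-weighted negative
# log-likelihood with SGD; large images are segmented by overlap tiling and
# post-processed into instance masks.

#' Segmentation configuration
#'
#' @param patch_size training/inference patch edge in pixels; must be a
#'   multiple of 8 (the network's downsampling factor).
#' @param lr,weight_decay,momentum SGD hyperparameters (defaults 0.005,
#'   0.01, 0.9).
#' @param epochs,batch_size training schedule.
#' @param width_scale channel-width multiplier (1 = the full-width model,
#'   1/8 = desk-scale).
#' @param blocks_per_stage residual blocks in each of the 4 global stages.
#' @param last_stage_stride,last_stage_dilation stride/dilation of the
#'   final global stage (1 and 2 preserve resolution at stride 8).
#' @param pretrained_init reserved flag for initializing the two
#'   downsampling paths from pretrained weights; no weight archive ships
#'   with the package, so only `FALSE` (He initialization) is accepted.
#' @param min_area post-processing area threshold (px^2).
#' @param edge_thickness edge-band reclaim radius used by [postprocess()].
#' @return a list of class `seg_config`.
#' @export
segConfig <- function(patch_size = 480L, lr = 0.005, weight_decay = 0.01,
                      momentum = 0.9, epochs = 30L, batch_size = 1L,
                      width_scale = 1, blocks_per_stage = c(3L, 4L, 6L, 3L),
                      last_stage_stride = 1L, last_stage_dilation = 2L,
                      pretrained_init = FALSE, min_area = 250,
                      edge_thickness = 3) {
  stopifnot(lr > 0, weight_decay >= 0, momentum >= 0)
  if (patch_size %% 8L != 0L) {
    stop("patch_size must be divisible by 8, the network stride")
  }
  if (isTRUE(pretrained_init)) {
    stop("pretrained_init: no pretrained weight archive is bundled; ",
         "use pretrained_init = FALSE")
  }
  structure(list(patch_size = as.integer(patch_size), lr = lr,
                 weight_decay = weight_decay, momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 width_scale = width_scale,
                 blocks_per_stage = as.integer(blocks_per_stage),
                 last_stage_stride = as.integer(last_stage_stride),
                 last_stage_dilation = as.integer(last_stage_dilation),
                 min_area = min_area, edge_thickness = edge_thickness),
            class = "seg_config")
}

#' Build the two-branch gland segmentation network
#'
#' The global branch is a residual 4-stage encoder with a 7x7 stem whose
#' final stage keeps resolution (stride 1, dilation 2; overall stride 8),
#' upsampled back to full resolution by a deconvolution chain. The local
#' branch is a VGG-style encoder with a 3x3 stem and three pooling steps,
#' with deconvolution heads bringing each level back to full resolution.
#' All branch outputs are concatenated into a fused map feeding the 3-class
#' head; every convolution is followed by batch normalization and ReLU.
#'
#' @param config a [segConfig()].
#' @return a network handle whose `$forward(image, training)` maps an
#'   `[H, W, 3]` array (H, W multiples of 8) to `[H, W, 3]` class scores.
#' @export
buildGaglNet <- function(config = segConfig()) {
  w <- max(1L, round(64 * config$width_scale))
  net <- .netNew(list(type = "gagl", seg = unclass(config), width = w))

  enc <- .resEncoder(net, "glob", 3L, w, blocks = config$blocks_per_stage,
                     last_stride = config$last_stage_stride,
                     last_dil = config$last_stage_dilation)
  glob_stride <- 2L * 2L * 2L * config$last_stage_stride
  glob_up <- .upChain(net, "glob.up", enc$channels[4], w,
                      as.integer(round(log2(glob_stride))))

  # local branch: 3x3 stem block at full resolution, then three
  # conv-conv-pool blocks; heads upsample levels 2..4 back to full size
  lb1a <- .convBR(net, "loc.b1a", 3L, w, 3L)
  lb1b <- .convBR(net, "loc.b1b", w, w, 3L)
  lb2a <- .convBR(net, "loc.b2a", w, 2L * w, 3L)
  lb2b <- .convBR(net, "loc.b2b", 2L * w, 2L * w, 3L)
  lb3a <- .convBR(net, "loc.b3a", 2L * w, 4L * w, 3L)
  lb3b <- .convBR(net, "loc.b3b", 4L * w, 4L * w, 3L)
  lb4a <- .convBR(net, "loc.b4a", 4L * w, 8L * w, 3L)
  lb4b <- .convBR(net, "loc.b4b", 8L * w, 8L * w, 3L)
  up2 <- .upChain(net, "loc.up2", 2L * w, w, 1L)
  up3 <- .upChain(net, "loc.up3", 4L * w, w, 2L)
  up4 <- .upChain(net, "loc.up4", 8L * w, w, 3L)

  fuse <- .convBR(net, "fuse", 5L * w, 2L * w, 1L)
  head_w <- .netParam(net, "head.w", heInit(c(3L, 3L, 2L * w, 3L),
                                            9L * 2L * w))
  head_b <- .netParam(net, "head.b", numeric(3L))

  net$forward <- function(image, training = TRUE) {
    if (anyNA(image)) stop("NA pixels in input image")
    x <- agConst(image)
    g <- enc$stem(x, training)
    for (s in 1:4) g <- enc$stages[[s]](g, training)
    gu <- glob_up(g, training)

    l1 <- lb1b(lb1a(x, training), training)
    l2 <- lb2b(lb2a(agMaxpool2(l1), training), training)
    l3 <- lb3b(lb3a(agMaxpool2(l2), training), training)
    l4 <- lb4b(lb4a(agMaxpool2(l3), training), training)
    fusion <- agConcatC(list(l1, up2(l2, training), up3(l3, training),
                             up4(l4, training), gu))
    f <- fuse(fusion, training)
    agConv2d(f, head_w, head_b, stride = 1L, pad = 1L)
  }
  net
}

#' Inverse-frequency class weights for 3-class label batches
#'
#' For a batch with N pixels, a pixel of class c receives weight
#' `N / (3 * count(c))`; classes absent from the batch get weight 0. The
#' weighted pixel mass of every class present is then equal.
#'
#' @param labels3 an integer matrix/array (values 0, 1, 2) or a list of
#'   such label maps forming the batch.
#' @return per-pixel weight maps matching the input (a list if the input
#'   was a list).
#' @export
classWeights <- function(labels3) {
  maps <- if (is.list(labels3)) labels3 else list(labels3)
  all_lab <- unlist(lapply(maps, as.vector))
  n <- length(all_lab)
  counts <- tabulate(all_lab + 1L, nbins = 3L)
  wcls <- ifelse(counts > 0, n / (3 * counts), 0)
  out <- lapply(maps, function(m) {
    w <- m
    w[] <- wcls[as.vector(m) + 1L]
    w
  })
  if (is.list(labels3)) out else out[[1]]
}

#' Class-weighted segmentation loss
#'
#' `l2_coeff * sum(weights^2 of the model) - sum_p w_p log t_p(r_p)` with
#' one-hot reference labels: an L2 term plus the weighted negative
#' log-likelihood of the true class. Probabilities are clipped at 1e-7
#' before the log. By default `l2_coeff = 0` because weight decay is
#' applied by the optimizer during training.
#'
#' @param probs `[H, W, 3]` array of per-pixel class probabilities.
#' @param labels3 integer matrix of reference classes (0, 1, 2).
#' @param weights per-pixel weight matrix (see [classWeights()]).
#' @param l2_coeff coefficient of the L2 regularization term.
#' @param model optional network handle supplying the weights for the L2
#'   term.
#' @return scalar loss.
#' @export
segLoss <- function(probs, labels3, weights, l2_coeff = 0, model = NULL) {
  stopifnot(identical(dim(probs)[1:2], dim(labels3)),
            identical(dim(labels3), dim(weights)),
            all(is.finite(weights)), all(weights >= 0))
  if (anyNA(probs) || any(!is.finite(probs))) {
    stop("NaN or infinite values in predicted probabilities")
  }
  H <- dim(probs)[1]; W <- dim(probs)[2]
  pick <- matrix(probs, H * W, 3L)[cbind(seq_len(H * W),
                                         as.vector(labels3) + 1L)]
  nll <- -sum(as.vector(weights) * log(pmax(pick, 1e-7)))
  l2 <- 0
  if (l2_coeff > 0 && !is.null(model)) {
    l2 <- l2_coeff * sum(vapply(model$params,
                                function(p) sum(p$value^2), numeric(1)))
  }
  l2 + nll
}

#' Train the segmentation network on labeled tiles
#'
#' SGD with momentum and weight decay on the class-weighted negative
#' log-likelihood (the optimizer's mean-per-pixel loss; [segLoss()] reports
#' the unnormalized sum). Tiles are augmented on the fly with flips,
#' 90-degree rotations and circular shifts. Deterministic under `seed`.
#'
#' @param model from [buildGaglNet()].
#' @param tiles list of tiles, each `list(image, labels3)` (or a
#'   [PhantomSample]).
#' @param config a [segConfig()].
#' @param seed integer seed.
#' @param augment logical; disable to train on the raw tiles.
#' @return the model (updated in place), with `$loss_history` of per-epoch
#'   mean losses attached.
#' @export
trainSeg <- function(model, tiles, config = segConfig(), seed = 1L,
                     augment = TRUE) {
  stopifnot(length(tiles) >= 1L)
  tiles <- lapply(tiles, function(t) {
    if (is(t, "PhantomSample")) list(image = phantomImage(t),
                                     labels3 = labelMap(t)) else t
  })
  set.seed(seed)
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(tiles))
    ep_loss <- 0
    for (ti in ord) {
      t <- tiles[[ti]]
      if (augment) {
        aug <- .augmentArrays(list(t$image, t$labels3))
        img <- aug[[1]]; lab <- aug[[2]]
      } else {
        img <- t$image; lab <- t$labels3
      }
      wts <- classWeights(lab)
      logits <- model$forward(img, training = TRUE)
      loss <- agSoftmaxNll(logits, lab, wts / length(lab))
      if (!is.finite(loss$value)) {
        stop(sprintf("training diverged (loss %g) at epoch %d", loss$value,
                     ep))
      }
      agBackward(loss)
      sgdStep(model$params, lr = config$lr, momentum = config$momentum,
              weight_decay = config$weight_decay)
      ep_loss <- ep_loss + loss$value
    }
    hist[ep] <- ep_loss / length(tiles)
  }
  model$loss_history <- hist
  model
}

# Reflect-pad an [H, W, C] array to at least (th, tw).
.padReflect <- function(img, th, tw) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H >= th && W >= tw) return(img)
  ri <- seq_len(max(H, th)); ci <- seq_len(max(W, tw))
  refl <- function(i, n) {
    # reflect indices 1..n outward (period 2n-2)
    j <- (i - 1L) %% (2L * n - 2L)
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  img[refl(ri, H), refl(ci, W), , drop = FALSE]
}

# Overlap-tile driver: predicts tile windows with `fn` ([h,w,3] ->
# [h,w,C]) and stitches central regions.
.stitchTiles <- function(image, tile, overlap, fn, out_channels) {
  stopifnot(overlap >= 0L, overlap < tile)
  H0 <- dim(image)[1]; W0 <- dim(image)[2]
  img <- .padReflect(image, tile, tile)
  H <- dim(img)[1]; W <- dim(img)[2]
  stride <- tile - overlap
  starts <- function(n) {
    s <- seq(1L, max(1L, n - tile + 1L), by = stride)
    if (s[length(s)] + tile - 1L < n) s <- c(s, n - tile + 1L)
    unique(s)
  }
  si <- starts(H); sj <- starts(W)
  margin <- overlap %/% 2L
  out <- array(0, c(H, W, out_channels))
  prev_i <- 0L
  for (a in seq_along(si)) {
    s_i <- si[a]
    keep_i0 <- if (a == 1L) 1L else max(prev_i + 1L, s_i + margin)
    keep_i1 <- if (a == length(si)) H else s_i + tile - 1L - margin
    prev_j <- 0L
    for (b in seq_along(sj)) {
      s_j <- sj[b]
      keep_j0 <- if (b == 1L) 1L else max(prev_j + 1L, s_j + margin)
      keep_j1 <- if (b == length(sj)) W else s_j + tile - 1L - margin
      pred <- fn(img[s_i:(s_i + tile - 1L), s_j:(s_j + tile - 1L), ,
                     drop = FALSE])
      out[keep_i0:keep_i1, keep_j0:keep_j1, ] <-
        pred[(keep_i0 - s_i + 1L):(keep_i1 - s_i + 1L),
             (keep_j0 - s_j + 1L):(keep_j1 - s_j + 1L), , drop = FALSE]
      prev_j <- keep_j1
    }
    prev_i <- keep_i1
  }
  out[seq_len(H0), seq_len(W0), , drop = FALSE]
}

.softmax3 <- function(logits) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; K <- dim(logits)[3]
  m <- matrix(logits, H * W, K)
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  array(e / rowSums(e), c(H, W, K))
}

#' Overlap-tile segmentation of a large image
#'
#' Tiles the image with stride `tile - overlap`, predicts each tile, keeps
#' each tile's central region (borders keep their outer margins) and
#' stitches the class scores; output size equals input size. With a
#' tile-sized image and zero overlap this equals a direct model call.
#'
#' @param model from [buildGaglNet()] (or any handle with a compatible
#'   `$forward`).
#' @param image `[H, W, 3]` array; reflect-padded up to the tile size if
#'   smaller.
#' @param tile tile edge (multiple of 8).
#' @param overlap overlap between neighboring tiles (< tile).
#' @return a `seg_prediction`: list with `probs` (`[H, W, 3]` softmax
#'   probabilities) and `argmax` (integer matrix, 0 background / 1 lumen /
#'   2 edge).
#' @export
predictTiled <- function(model, image, tile = 480L, overlap = 64L) {
  logits <- .stitchTiles(image, as.integer(tile), as.integer(overlap),
                         function(patch) {
                           model$forward(patch, training = FALSE)$value
                         }, 3L)
  probs <- .softmax3(logits)
  am <- apply(matrix(probs, prod(dim(probs)[1:2]), 3L), 1L, which.max) - 1L
  structure(list(probs = probs,
                 argmax = matrix(as.integer(am), dim(probs)[1],
                                 dim(probs)[2])),
            class = "seg_prediction")
}

# fill holes in a binary matrix that are smaller than min_hole_area
.fillSmallHoles <- function(mask, min_hole_area) {
  inv <- EBImage::bwlabel(1 - mask)
  areas <- tabulate(inv[inv > 0])
  border <- unique(c(inv[1, ], inv[nrow(inv), ], inv[, 1], inv[, ncol(inv)]))
  fill <- which(areas < min_hole_area & !(seq_along(areas) %in% border))
  mask[inv %in% fill] <- 1L
  mask
}

#' Post-process a 3-class prediction into an instance mask
#'
#' Lumen-class connected components (the edge class acts as a separator
#' between touching glands) are labeled, their holes filled and small
#' components removed; each surviving component then reclaims the
#' surrounding epithelial edge band by growing into foreground pixels up to
#' `edge_thickness + 1` px away, pixels going to the nearest component.
#' Final ids are 1..K in raster order of component centroids.
#'
#' @param pred a `seg_prediction` (or an argmax-compatible integer matrix).
#' @param min_area components smaller than this many px^2 are removed.
#' @param edge_policy `"reclaim"` (grow components over the edge band,
#'   default) or `"lumen"` (keep bare lumen components).
#' @param edge_thickness reclaim radius in pixels.
#' @return integer instance mask (0 background, ids 1..K).
#' @export
postprocess <- function(pred, min_area = 250, edge_policy = c("reclaim",
                                                              "lumen"),
                        edge_thickness = 3) {
  edge_policy <- match.arg(edge_policy)
  am <- if (inherits(pred, "seg_prediction")) pred$argmax else pred
  lumen <- matrix(as.integer(am == 1L), nrow(am), ncol(am))
  fg <- am >= 1L
  if (!any(lumen > 0L)) return(matrix(0L, nrow(am), ncol(am)))
  lab <- EBImage::bwlabel(lumen)
  lab <- EBImage::fillHull(lab)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  if (!any(lab > 0L)) return(matrix(0L, nrow(am), ncol(am)))
  if (edge_policy == "reclaim") {
    # geodesic growth over foreground, limited by distance to the lumen
    seeds <- EBImage::Image(lab)
    grown <- EBImage::propagate(EBImage::Image(matrix(0, nrow(am),
                                                      ncol(am))),
                                seeds, mask = EBImage::Image(fg * 1))
    grown <- EBImage::imageData(grown)
    dist <- EBImage::imageData(EBImage::distmap(1 - (lab > 0L)))
    grown[dist > edge_thickness + 1] <- 0L
    grown[lab > 0L] <- lab[lab > 0L]
    lab <- grown
  }
  # renumber 1..K by raster order of centroids
  ids <- sort(unique(lab[lab > 0L]))
  cents <- t(vapply(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }, numeric(2)))
  ord <- order(cents[, 1], cents[, 2])
  out <- matrix(0L, nrow(am), ncol(am))
  for (k in seq_along(ord)) out[lab == ids[ord[k]]] <- k
  out
}
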