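# Weakly supervised tissue segmentation: k-means colour clustering seeds a
# binary (tissue / background) pixel labelling, a contrast-sensitive Potts
# energy is minimized exactly by s-t min-cut, and the resulting label maps
# train a U-Net used for overlap-tile inference on whole slides. The
# mucosa mask is a morphological closing of the gland mask intersected with
# the tissue mask.

#' k-means colour seeding of tissue vs background
#'
#' Clusters per-pixel RGB colours with k-means; the brightest cluster (by
#' centroid luminance) becomes background, all others tissue. Per-pixel
#' confidence is the margin between the second-best and best centroid
#' distance; pixels below the `unlabeled_quantile` of the margin are marked
#' unlabeled (NA).
#'
#' @param image `[H, W, 3]` array in [0, 1].
#' @param k number of clusters (>= 2; default 3 so stain-like intermediate
#'   colours get their own cluster before collapsing to binary).
#' @param seed RNG seed (k-means initialization).
#' @param unlabeled_quantile fraction of lowest-confidence pixels marked NA.
#' @return list with `labels` (matrix: 1 tissue, 0 background, NA
#'   unlabeled), `confidence` (matrix), `centers` (k x 3), `cluster`
#'   (matrix of raw cluster ids), `tissue_clusters` (integer vector).
#' @export
kmeansSeed <- function(image, k = 3L, seed = 1L, unlabeled_quantile = 0.1) {
  stopifnot(k >= 2L)
  H <- dim(image)[1]; W <- dim(image)[2]
  px <- matrix(image, H * W, 3L)
  n_distinct <- nrow(unique(px))
  if (n_distinct < k) {
    warning("degenerate image: fewer distinct colours than clusters; ",
            "labelling everything as one class")
    lum <- mean(px)
    lab <- matrix(if (lum > 0.85) 0L else 1L, H, W)
    return(list(labels = lab, confidence = matrix(1, H, W),
                centers = matrix(colMeans(px), 1L), cluster = matrix(1L, H, W),
                tissue_clusters = if (lum > 0.85) integer(0) else 1L))
  }
  set.seed(seed)
  km <- stats::kmeans(px, centers = k, nstart = 3L, iter.max = 50L)
  # distance margins to centroids
  d2 <- vapply(seq_len(k), function(c) {
    rowSums((px - matrix(km$centers[c, ], H * W, 3L, byrow = TRUE))^2)
  }, numeric(H * W))
  srt <- t(apply(d2, 1L, sort))[, 1:2, drop = FALSE]
  conf <- sqrt(srt[, 2]) - sqrt(srt[, 1])
  lum <- km$centers %*% c(0.299, 0.587, 0.114)
  bg_cluster <- which.max(lum)
  lab <- ifelse(km$cluster == bg_cluster, 0L, 1L)
  thr <- stats::quantile(conf, unlabeled_quantile)
  lab[conf < thr] <- NA_integer_
  list(labels = matrix(lab, H, W), confidence = matrix(conf, H, W),
       centers = km$centers, cluster = matrix(km$cluster, H, W),
       tissue_clusters = setdiff(seq_len(k), bg_cluster))
}

#' Build the pixel-grid graph energy for tissue/background labelling
#'
#' Unary cost of label l at pixel p is the squared colour distance to the
#' mean colour of the seed pixels carrying label l; seeds above the
#' `clamp_quantile` of confidence are hard-clamped (large finite cost on
#' the opposite label). Pairwise cost on 4-neighbour edges is the
#' contrast-sensitive Potts form `lambda * exp(-beta * ||I_p - I_q||^2)`
#' for differing labels (0 otherwise) — symmetric and submodular.
#'
#' @param image `[H, W, 3]` array.
#' @param seeds result of [kmeansSeed()].
#' @param lambda smoothness weight (>= 0).
#' @param beta contrast scale; default `1 / (2 * mean ||I_p - I_q||^2)`
#'   over the 4-neighbour edges.
#' @param clamp_quantile confidence quantile above which seed labels are
#'   hard-clamped.
#' @param clamp_cost the large finite cost implementing the clamp.
#' @return a `graph_spec` list: `H`, `W`, `unary` (n x 2 matrix, columns =
#'   cost of background, tissue), `edges` (m x 2 pixel indices), `pair`
#'   (length-m Potts weights).
#' @export
buildEnergy <- function(image, seeds, lambda = 10, beta = NULL,
                        clamp_quantile = 0.8, clamp_cost = 1e6) {
  if (lambda < 0) stop("lambda must be >= 0")
  H <- dim(image)[1]; W <- dim(image)[2]
  n <- H * W
  px <- matrix(image, n, 3L)
  lab <- as.vector(seeds$labels)
  conf <- as.vector(seeds$confidence)
  mean_col <- function(sel) {
    if (!any(sel)) colMeans(px) else colMeans(px[sel, , drop = FALSE])
  }
  c_bg <- mean_col(!is.na(lab) & lab == 0L)
  c_ts <- mean_col(!is.na(lab) & lab == 1L)
  unary <- cbind(
    rowSums((px - matrix(c_bg, n, 3L, byrow = TRUE))^2),
    rowSums((px - matrix(c_ts, n, 3L, byrow = TRUE))^2))
  thr <- stats::quantile(conf, clamp_quantile)
  hard <- !is.na(lab) & conf >= thr
  unary[hard & lab == 0L, 2L] <- clamp_cost
  unary[hard & lab == 1L, 1L] <- clamp_cost
  # 4-neighbour edges on the pixel grid (column-major indices)
  idx <- matrix(seq_len(n), H, W)
  e_v <- cbind(as.vector(idx[-H, ]), as.vector(idx[-1, ]))
  e_h <- cbind(as.vector(idx[, -W]), as.vector(idx[, -1]))
  edges <- rbind(e_v, e_h)
  dcol2 <- rowSums((px[edges[, 1], ] - px[edges[, 2], ])^2)
  if (is.null(beta)) beta <- 1 / (2 * max(mean(dcol2), 1e-12))
  if (beta < 0) stop("beta must be >= 0")
  pair <- lambda * exp(-beta * dcol2)
  structure(list(H = H, W = W, unary = unary, edges = edges, pair = pair,
                 beta = beta, lambda = lambda),
            class = "graph_spec")
}

#' Energy of a binary labelling under a graph spec
#'
#' Sum of unary costs of the assigned labels plus the Potts pairwise cost
#' on edges whose endpoints disagree.
#'
#' @param graph a `graph_spec` (see [buildEnergy()]).
#' @param labels vector/matrix of 0/1 labels, one per pixel.
#' @return scalar energy.
#' @export
graphEnergy <- function(graph, labels) {
  l <- as.vector(labels)
  stopifnot(length(l) == nrow(graph$unary), all(l %in% c(0, 1)))
  u <- sum(graph$unary[cbind(seq_along(l), l + 1L)])
  d <- l[graph$edges[, 1]] != l[graph$edges[, 2]]
  u + sum(graph$pair[d])
}

#' Exact binary labelling by s-t minimum cut
#'
#' Minimizes the unary + Potts energy exactly through the max-flow/min-cut
#' equivalence (the Potts pairwise term with non-negative weights is
#' submodular). Negative pairwise weights are rejected.
#'
#' @param graph a `graph_spec` from [buildEnergy()] (or assembled by hand).
#' @return list with `labels` (H x W matrix of 0 background / 1 tissue)
#'   and `energy`.
#' @export
graphcutLabels <- function(graph) {
  if (any(graph$pair < 0)) {
    stop("non-submodular energy: pairwise costs must be non-negative")
  }
  if (any(!is.finite(graph$unary)) || any(graph$unary < 0)) {
    stop("unary costs must be finite and non-negative")
  }
  n <- nrow(graph$unary)
  s <- n + 1L
  t <- n + 2L
  # source side = label 0 (background): cap(s->p) = C_p(1), cap(p->t) =
  # C_p(0), so the cut pays exactly the assigned label's cost.
  el <- rbind(cbind(s, seq_len(n)),
              cbind(seq_len(n), t),
              graph$edges,
              graph$edges[, 2:1])
  caps <- c(graph$unary[, 2L], graph$unary[, 1L], graph$pair, graph$pair)
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  fl <- igraph::max_flow(g, source = s, target = t,
                         capacity = caps)
  lab <- rep(1L, n)
  p1 <- as.integer(fl$partition1)
  lab[p1[p1 <= n]] <- 0L
  labm <- matrix(lab, graph$H, graph$W)
  list(labels = labm, energy = graphEnergy(graph, lab))
}

#' U-Net configuration
#'
#' @param depth number of pooling steps (3).
#' @param channels encoder channel counts, length `depth + 1`.
#' @param patch_size training patch edge (divisible by `2^depth`).
#' @param batch_size patches per epoch draw.
#' @param epochs,lr Adam schedule.
#' @param width_scale multiplier applied to `channels`.
#' @return a list of class `unet_config`.
#' @export
unetConfig <- function(depth = 3L, channels = c(64L, 128L, 256L, 512L),
                       patch_size = 296L, batch_size = 40L, epochs = 8L,
                       lr = 1e-3, width_scale = 1) {
  stopifnot(length(channels) == depth + 1L)
  structure(list(depth = as.integer(depth),
                 channels = pmax(1L, round(channels * width_scale)),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr,
                 width_scale = width_scale),
            class = "unet_config")
}

#' Build a U-Net for binary tissue segmentation
#'
#' Standard encoder-decoder with skip connections: `depth` pooling steps,
#' double-conv blocks with batch normalization and ReLU, stride-2
#' deconvolution upsampling and a sigmoid head.
#'
#' @param config a [unetConfig()].
#' @return network handle; `$forward(image, training)` maps `[H, W, 3]`
#'   (H, W divisible by `2^depth`) to `[H, W, 1]` tissue logits.
#' @export
buildTissueUnet <- function(config = unetConfig()) {
  ch <- config$channels
  depth <- config$depth
  net <- .netNew(list(type = "unet", unet = unclass(config)))
  down <- list()
  prev <- 3L
  for (d in seq_len(depth + 1L)) {
    a <- .convBR(net, sprintf("enc%d.a", d), prev, ch[d], 3L)
    b <- .convBR(net, sprintf("enc%d.b", d), ch[d], ch[d], 3L)
    down[[d]] <- local({
      a0 <- a; b0 <- b
      function(x, tr) b0(a0(x, tr), tr)
    })
    prev <- ch[d]
  }
  ups <- list()
  decs <- list()
  for (d in seq_len(depth)) {
    cin <- ch[d + 1L]; cskip <- ch[d]
    wup <- .netParam(net, sprintf("up%d.w", d),
                     heInit(c(2L, 2L, cskip, cin), 4L * cin))
    bnu <- .netBn(net, sprintf("up%d", d), cskip)
    ups[[d]] <- local({
      w0 <- wup; bn0 <- bnu
      function(x, tr) agRelu(agBnorm(agConvT2d(x, w0, NULL, stride = 2L),
                                     bn0$g, bn0$b, bn0$st, training = tr))
    })
    a <- .convBR(net, sprintf("dec%d.a", d), 2L * cskip, cskip, 3L)
    b <- .convBR(net, sprintf("dec%d.b", d), cskip, cskip, 3L)
    decs[[d]] <- local({
      a0 <- a; b0 <- b
      function(x, tr) b0(a0(x, tr), tr)
    })
  }
  head_w <- .netParam(net, "head.w", heInit(c(1L, 1L, ch[1], 1L), ch[1]))
  head_b <- .netParam(net, "head.b", 0)
  net$forward <- function(image, training = TRUE) {
    x <- agConst(image)
    skips <- list()
    for (d in seq_len(depth)) {
      x <- down[[d]](x, training)
      skips[[d]] <- x
      x <- agMaxpool2(x)
    }
    x <- down[[depth + 1L]](x, training)
    for (d in rev(seq_len(depth))) {
      x <- ups[[d]](x, training)
      x <- decs[[d]](agConcatC(list(skips[[d]], x)), training)
    }
    agConv2d(x, head_w, head_b)
  }
  net
}

#' Train the tissue U-Net on graph-cut label maps
#'
#' Random patches are sampled from the images, paired with the
#' corresponding graph-cut labels and optimized with Adam on per-pixel
#' binary cross-entropy. Deterministic under `seed`.
#'
#' @param images list of `[H, W, 3]` arrays.
#' @param labelmaps list of matching 0/1 matrices (graph-cut outputs).
#' @param config a [unetConfig()].
#' @param seed integer seed.
#' @param model optional pre-built network (otherwise built from config).
#' @return trained network with `$loss_history`.
#' @export
trainTissueUnet <- function(images, labelmaps, config = unetConfig(),
                            seed = 1L, model = NULL) {
  stopifnot(length(images) >= 1L, length(images) == length(labelmaps))
  set.seed(seed)
  if (is.null(model)) model <- buildTissueUnet(config)
  ps <- config$patch_size
  step <- 0L
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0
    for (bi in seq_len(config$batch_size)) {
      i <- sample.int(length(images), 1L)
      img <- images[[i]]; lab <- labelmaps[[i]]
      H <- dim(img)[1]; W <- dim(img)[2]
      p <- min(ps, H, W)
      p <- max(8L, (p %/% (2L^config$depth)) * (2L^config$depth))
      i0 <- sample.int(H - p + 1L, 1L)
      j0 <- sample.int(W - p + 1L, 1L)
      pi <- img[i0:(i0 + p - 1L), j0:(j0 + p - 1L), , drop = FALSE]
      pl <- lab[i0:(i0 + p - 1L), j0:(j0 + p - 1L)]
      aug <- .augmentArrays(list(pi, pl), max_shift = 0L)
      logits <- model$forward(aug[[1]], training = TRUE)
      # pixel BCE via the 2-class softmax node on (0, logit)
      z <- logits$value
      target <- aug[[2]]
      loss <- agFocalBce(agNode(as.vector(z), list(logits), function(g) {
        list(array(g, dim(z)))
      }), p = as.vector(target), gamma = 0)
      if (!is.finite(loss$value)) stop("U-Net training diverged (NaN loss)")
      agBackward(loss)
      step <- step + 1L
      adamStep(model$params, lr = config$lr, step = step)
      ep_loss <- ep_loss + loss$value
    }
    hist[ep] <- ep_loss / config$batch_size
  }
  model$loss_history <- hist
  model
}

#' Segment tissue in a large image with the trained U-Net
#'
#' Overlap-tile inference (shared with the gland segmentation machinery),
#' thresholded at 0.5, followed by morphological cleanup: connected
#' components smaller than `min_artifact_area` are removed and holes
#' smaller than `min_hole_area` are filled.
#'
#' @param model trained U-Net.
#' @param image `[H, W, 3]` array.
#' @param tile,overlap overlap-tile parameters.
#' @param min_artifact_area,min_hole_area cleanup thresholds (px^2).
#' @return binary integer matrix (1 = tissue).
#' @export
segmentTissue <- function(model, image, tile = 296L, overlap = 32L,
                          min_artifact_area = 500, min_hole_area = 500) {
  depth <- model$config$unet$depth %||% 3L
  f <- 2L^depth
  tile <- max(f, (as.integer(tile) %/% f) * f)
  probs <- .stitchTiles(image, tile, as.integer(overlap), function(patch) {
    1 / (1 + exp(-model$forward(patch, training = FALSE)$value))
  }, 1L)
  mask <- matrix(as.integer(probs[, , 1] >= 0.5), dim(image)[1],
                 dim(image)[2])
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0L])
  drop <- which(areas < min_artifact_area)
  if (length(drop)) mask[lab %in% drop] <- 0L
  .fillSmallHoles(mask, min_hole_area)
}

#' Mucosa mask from glands and tissue
#'
#' Morphological closing of the gland foreground — dilation by `dilate_r`
#' then erosion by `erode_r` with disc structuring elements — merges
#' neighbouring glands while keeping outer boundaries consistent; the
#' result is intersected with the tissue mask, so the mucosa is always a
#' subset of the tissue.
#'
#' @param glands instance mask (or binary gland mask).
#' @param tissue binary tissue mask, same size.
#' @param dilate_r,erode_r disc radii in px, `dilate_r >= erode_r >= 0`.
#' @return list (`mucosa_masks`): `T` tissue, `Gt` transformed gland mask,
#'   `M` mucosa (all 0/1 integer matrices).
#' @export
mucosaMaskFromGlands <- function(glands, tissue, dilate_r = 25,
                                 erode_r = 25) {
  stopifnot(identical(dim(glands), dim(tissue)), dilate_r >= erode_r,
            erode_r >= 0)
  g <- (glands > 0) * 1
  gt <- g
  if (dilate_r > 0) {
    gt <- EBImage::dilate(gt, EBImage::makeBrush(2L * round(dilate_r) + 1L,
                                                 "disc"))
  }
  if (erode_r > 0) {
    gt <- EBImage::erode(gt, EBImage::makeBrush(2L * round(erode_r) + 1L,
                                                "disc"))
  }
  gt <- matrix(as.integer(gt > 0), nrow(tissue), ncol(tissue))
  m <- gt * (tissue > 0)
  list(T = matrix(as.integer(tissue > 0), nrow(tissue), ncol(tissue)),
       Gt = gt, M = matrix(as.integer(m), nrow(tissue), ncol(tissue)))
}
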