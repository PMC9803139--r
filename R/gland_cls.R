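# Gland classification ("IMGL-VTNet"): a residual backbone feeds a
# three-level feature pyramid that is aligned to a common resolution,
# concatenated and group-normalized; a deformable-attention encoder
# (MSDAM + FFN) enhances the fused features, and average pooling plus a
# fully connected sigmoid head scores each gland crop as normal vs IM.
# Training uses focal loss with Adam and an optional mean-teacher scheme.

#' Deformable-attention configuration
#'
#' @param embed_dim model width d (divisible by `n_heads`).
#' @param n_heads attention heads.
#' @param n_levels pyramid levels sampled (3 for the backbone pyramid).
#' @param n_points sampling points per head per level.
#' @param n_layers encoder layers (MSDAM + FFN each).
#' @param ffn_dim hidden width of the feed-forward network.
#' @return list of class `deform_attn_config`.
#' @export
deformAttnConfig <- function(embed_dim = 256L, n_heads = 8L, n_levels = 3L,
                             n_points = 4L, n_layers = 2L,
                             ffn_dim = 2L * embed_dim) {
  stopifnot(embed_dim %% n_heads == 0L)
  structure(list(embed_dim = as.integer(embed_dim),
                 n_heads = as.integer(n_heads),
                 n_levels = as.integer(n_levels),
                 n_points = as.integer(n_points),
                 n_layers = as.integer(n_layers),
                 ffn_dim = as.integer(ffn_dim)),
            class = "deform_attn_config")
}

#' Classifier configuration
#'
#' @param input_size crop edge after [prepareCrop()] (224 at full scale).
#' @param width_scale backbone channel multiplier.
#' @param attn a [deformAttnConfig()].
#' @param lr,epochs,batch_size Adam schedule.
#' @param gamma focal-loss focusing parameter.
#' @param ema_decay mean-teacher EMA decay.
#' @param consistency_weight final weight of the mean-teacher consistency
#'   term (ramped linearly over the first 20% of steps).
#' @param threshold decision threshold on the score.
#' @return list of class `cls_config`.
#' @export
clsConfig <- function(input_size = 224L, width_scale = 1,
                      attn = deformAttnConfig(), lr = 1e-3, epochs = 6L,
                      batch_size = 8L, gamma = 2, ema_decay = 0.99,
                      consistency_weight = 1, threshold = 0.5) {
  stopifnot(input_size %% 8L == 0L)
  structure(list(input_size = as.integer(input_size),
                 width_scale = width_scale, attn = attn, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), gamma = gamma,
                 ema_decay = ema_decay,
                 consistency_weight = consistency_weight,
                 threshold = threshold),
            class = "cls_config")
}

#' Resize and pad a gland crop to the classifier input size
#'
#' Isotropic rescale so the longer side equals `size`, then symmetric
#' zero-padding of the shorter side; the aspect ratio is preserved.
#'
#' @param crop `[h, w, 3]` array, both dims >= 1.
#' @param size target edge (default 224).
#' @return `[size, size, 3]` array.
#' @export
prepareCrop <- function(crop, size = 224L) {
  d <- dim(crop)
  if (is.null(d) || length(d) != 3L || d[1] < 1L || d[2] < 1L) {
    stop("crop must be a non-empty [h, w, 3] array")
  }
  sc <- size / max(d[1:2])
  nh <- max(1L, round(d[1] * sc))
  nw <- max(1L, round(d[2] * sc))
  if (nh == d[1] && nw == d[2]) {
    res <- crop
  } else {
    res <- EBImage::resize(crop, w = nh, h = nw)
    res <- array(res, c(nh, nw, 3L))
  }
  out <- array(0, c(size, size, 3L))
  i0 <- (size - nh) %/% 2L
  j0 <- (size - nw) %/% 2L
  out[(i0 + 1L):(i0 + nh), (j0 + 1L):(j0 + nw), ] <- res
  out
}

#' Binary focal loss
#'
#' `FL = w_focal * BCE(p, s)` with `w_focal = (1 - s)^gamma` for p = 1 and
#' `s^gamma` for p = 0, and `BCE = -[p log s + (1 - p) log(1 - s)]`; always
#' non-negative, and 0 in the limit s -> p. `gamma = 0` recovers plain
#' binary cross-entropy.
#'
#' @param p binary ground truth (0/1), vectorized.
#' @param s predicted score in (0, 1), clipped at `eps`.
#' @param gamma focusing parameter (default 2).
#' @param eps clipping bound.
#' @return focal loss per element (same length as `p`).
#' @export
focalLoss <- function(p, s, gamma = 2, eps = 1e-7) {
  if (!all(p %in% c(0, 1))) stop("ground truth p must be binary (0/1)")
  s <- pmin(pmax(s, eps), 1 - eps)
  w <- ifelse(p == 1, (1 - s)^gamma, s^gamma)
  bce <- -(p * log(s) + (1 - p) * log(1 - s))
  w * bce
}

# Sinusoidal 2-D positional encoding for an Hp x Wp grid, d channels.
.posEncoding2d <- function(Hp, Wp, d) {
  stopifnot(d %% 4L == 0L)
  dq <- d %/% 4L
  freq <- 1 / (100^((seq_len(dq) - 1) / dq))
  iy <- rep(seq_len(Hp) - 1L, times = Wp)
  ix <- rep(seq_len(Wp) - 1L, each = Hp)
  cbind(sin(outer(iy, freq)), cos(outer(iy, freq)),
        sin(outer(ix, freq)), cos(outer(ix, freq)))
}

#' Create a standalone MSDAM parameter set
#'
#' Mostly useful for experimenting with [msdam()] outside a full network:
#' value projections per pyramid level, offset and attention linear layers
#' and the output projection, randomly initialized under the current RNG
#' state.
#'
#' @param config a [deformAttnConfig()].
#' @param level_channels channel count of each pyramid level.
#' @return a named list of parameter tensors (each with `$value`).
#' @export
msdamParams <- function(config, level_channels) {
  net <- .netNew(list(type = "msdam"))
  .msdamParams(net, "msdam", config, level_channels)
}

# Parameters of one MSDAM block for given level channel counts.
.msdamParams <- function(net, name, config, level_channels) {
  d <- config$embed_dim
  M <- config$n_heads; L <- config$n_levels; K <- config$n_points
  stopifnot(length(level_channels) == L)
  list(
    w_val = lapply(seq_len(L), function(l) {
      .netParam(net, sprintf("%s.val%d.w", name, l),
                heInit(c(level_channels[l], d), level_channels[l]))
    }),
    w_off = .netParam(net, paste0(name, ".off.w"),
                      array(0, c(d, M * L * K * 2L))),
    b_off = .netParam(net, paste0(name, ".off.b"),
                      stats::rnorm(M * L * K * 2L, sd = 0.5)),
    w_att = .netParam(net, paste0(name, ".att.w"),
                      heInit(c(d, M * L * K), d) * 0.01),
    b_att = .netParam(net, paste0(name, ".att.b"), numeric(M * L * K)),
    w_out = .netParam(net, paste0(name, ".out.w"), heInit(c(d, d), d)),
    b_out = .netParam(net, paste0(name, ".out.b"), numeric(d))
  )
}

# Differentiable bilinear gather of rows from a value matrix vm ([Hl*Wl,
# dh] tensor) at continuous 0-based (y, x) locations (ag vectors), with
# zero padding outside the map.
.bilinearSample <- function(vm, Hl, Wl, loc_y, loc_x) {
  y0 <- floor(loc_y$value); x0 <- floor(loc_x$value)
  fy <- agSub(loc_y, agConst(y0))
  fx <- agSub(loc_x, agConst(x0))
  one <- agConst(rep(1, length(y0)))
  wy0 <- agSub(one, fy); wx0 <- agSub(one, fx)
  corner <- function(iy, ix, wy, wx) {
    valid <- as.numeric(iy >= 0 & iy <= Hl - 1 & ix >= 0 & ix <= Wl - 1)
    iyc <- pmin(pmax(iy, 0), Hl - 1)
    ixc <- pmin(pmax(ix, 0), Wl - 1)
    idx <- iyc + ixc * Hl + 1   # column-major [H, W] raster
    w <- agMul(agMul(wy, wx), agConst(valid))
    agRowscale(agGatherRows(vm, idx), w)
  }
  s <- agAdd(corner(y0, x0, wy0, wx0), corner(y0 + 1, x0, fy, wx0))
  s <- agAdd(s, corner(y0, x0 + 1, wy0, fx))
  agAdd(s, corner(y0 + 1, x0 + 1, fy, fx))
}

#' Multi-scale deformable attention (MSDAM)
#'
#' For each query q with normalized reference point r, samples `n_points`
#' learned offset locations per head and per pyramid level by bilinear
#' interpolation of the value-projected level maps, combines them with
#' attention weights that are softmax-normalized over the levels x points
#' slots of each head, concatenates the heads and applies the output
#' projection. Offsets and weights are linear functions of the query.
#'
#' @param query `[Nq, d]` tensor (or plain matrix) of query features.
#' @param ref `[Nq, 2]` matrix of normalized (row, col) reference points in
#'   `[0, 1]^2`.
#' @param pyramid list of `n_levels` feature maps `[Hl, Wl, Cl]` (tensors
#'   or arrays).
#' @param params parameter set from the internal constructor (a list with
#'   `w_val`, `w_off`, `b_off`, `w_att`, `b_att`, `w_out`, `b_out`).
#' @param config a [deformAttnConfig()].
#' @return `[Nq, d]` tensor of enhanced features; `$attn` holds the
#'   realized attention weights `[Nq, M, L, K]`, `$loc` the sampling
#'   locations.
#' @export
msdam <- function(query, ref, pyramid, params, config) {
  if (any(ref < 0 | ref > 1)) {
    stop("reference points must lie in [0, 1]^2")
  }
  q <- agConst(query)
  pyramid <- lapply(pyramid, agConst)
  d <- config$embed_dim
  M <- config$n_heads; L <- config$n_levels; K <- config$n_points
  stopifnot(length(pyramid) == L, ncol(q$value) == d)
  dh <- d %/% M
  Nq <- nrow(q$value)
  vals <- lapply(seq_len(L), function(l) {
    agMatmul(agAsMat(pyramid[[l]]), params$w_val[[l]])
  })
  shapes <- lapply(pyramid, function(p) dim(p$value))
  off <- agAdd(agMatmul(q, params$w_off), .agRowBroadcast(params$b_off, Nq))
  logits <- agAdd(agMatmul(q, params$w_att), .agRowBroadcast(params$b_att,
                                                             Nq))
  attn_list <- vector("list", M)
  head_out <- vector("list", M)
  attn_real <- array(0, c(Nq, M, L, K))
  loc_real <- array(0, c(Nq, M, L, K, 2L))
  for (m in seq_len(M)) {
    acols <- ((m - 1L) * L * K + 1L):(m * L * K)
    A <- agSoftmaxRows(agCols(logits, acols))
    acc <- NULL
    slot <- 0L
    for (l in seq_len(L)) {
      Hl <- shapes[[l]][1]; Wl <- shapes[[l]][2]
      vh <- agCols(vals[[l]], ((m - 1L) * dh + 1L):(m * dh))
      for (k in seq_len(K)) {
        slot <- slot + 1L
        ci <- (((m - 1L) * L + (l - 1L)) * K + (k - 1L)) * 2L
        oy <- agCols(off, ci + 1L)
        ox <- agCols(off, ci + 2L)
        base_y <- ref[, 1] * Hl - 0.5
        base_x <- ref[, 2] * Wl - 0.5
        ly <- agAdd(agConst(base_y), .agDrop(oy))
        lx <- agAdd(agConst(base_x), .agDrop(ox))
        sampled <- .bilinearSample(vh, Hl, Wl, ly, lx)
        wslot <- .agDrop(agCols(A, slot))
        acc <- if (is.null(acc)) agRowscale(sampled, wslot) else
          agAdd(acc, agRowscale(sampled, wslot))
        attn_real[, m, l, k] <- A$value[, slot]
        loc_real[, m, l, k, 1] <- ly$value
        loc_real[, m, l, k, 2] <- lx$value
      }
    }
    head_out[[m]] <- acc
  }
  out <- agCbind(head_out)
  out <- agAdd(agMatmul(out, params$w_out),
               .agRowBroadcast(params$b_out, Nq))
  out$attn <- attn_real
  out$loc <- loc_real
  out
}

# broadcast a parameter vector across Nq rows (grad = column sums)
.agRowBroadcast <- function(p, n) {
  agNode(matrix(p$value, n, length(p$value), byrow = TRUE), list(p),
         function(g) list(colSums(g)))
}

# [N, 1] matrix tensor -> length-N vector tensor
.agDrop <- function(x) {
  agNode(as.vector(x$value), list(x), function(g) list(matrix(g, ncol = 1L)))
}

#' Build the gland classifier
#'
#' Backbone (residual 4-stage encoder shared with the segmentation global
#' branch) -> pyramid alignment (two deconvolved coarse maps plus an
#' embedded fine map at 1/4 resolution) -> concatenation + group
#' normalization -> deformable-attention encoder layers -> average pooling
#' -> fully connected sigmoid head.
#'
#' @param config a [clsConfig()].
#' @return network handle; `$forward(crop, training)` maps a prepared
#'   `[S, S, 3]` crop to a scalar score tensor in (0, 1) (`$score`), with
#'   the logit available as the tensor value.
#' @export
buildImglVtnet <- function(config = clsConfig()) {
  w <- max(1L, round(64 * config$width_scale))
  ac <- config$attn
  d <- ac$embed_dim
  net <- .netNew(list(type = "imgl", cls = unclass(config), width = w))
  enc <- .resEncoder(net, "bb", 3L, w, blocks = c(1L, 1L, 1L, 1L))
  ch <- enc$channels              # /2, /4, /8, /8(dilated)
  up1 <- .upChain(net, "pyr.f1", ch[4], d, 1L)   # coarse /8 -> /4
  up2 <- .upChain(net, "pyr.f2", ch[3], d, 1L)   # /8 -> /4
  emb3 <- .convBR(net, "pyr.f3", ch[2], d, 1L)   # fine /4 embed
  gn <- .netBn(net, "pyr.gn", 3L * d)
  fuse_w <- .netParam(net, "pyr.fuse.w", heInit(c(1L, 1L, 3L * d, d),
                                                3L * d))
  fuse_b <- .netParam(net, "pyr.fuse.b", numeric(d))
  scale_emb <- .netParam(net, "pyr.scale", stats::rnorm(d, sd = 0.02))
  layers <- lapply(seq_len(ac$n_layers), function(li) {
    list(att = .msdamParams(net, sprintf("enc%d.att", li), ac, rep(d, 3L)),
         ffn1_w = .netParam(net, sprintf("enc%d.ffn1.w", li),
                            heInit(c(d, ac$ffn_dim), d)),
         ffn1_b = .netParam(net, sprintf("enc%d.ffn1.b", li),
                            numeric(ac$ffn_dim)),
         ffn2_w = .netParam(net, sprintf("enc%d.ffn2.w", li),
                            heInit(c(ac$ffn_dim, d), ac$ffn_dim)),
         ffn2_b = .netParam(net, sprintf("enc%d.ffn2.b", li), numeric(d)))
  })
  head_w <- .netParam(net, "head.w", array(0, c(d, 1L)))
  head_b <- .netParam(net, "head.b", 0)

  net$forward <- function(crop, training = TRUE) {
    stopifnot(all(dim(crop)[1:2] == config$input_size))
    x <- agConst(crop - 0.5)
    h <- enc$stem(x, training)
    s1 <- enc$stages[[1]](h, training)
    s2 <- enc$stages[[2]](s1, training)
    s3 <- enc$stages[[3]](s2, training)
    s4 <- enc$stages[[4]](s3, training)
    f1 <- up1(s4, training)
    f2 <- up2(s3, training)
    f3 <- emb3(s2, training)
    cat3 <- agConcatC(list(f1, f2, f3))
    cat3 <- agGroupNorm(cat3, 3L, gn$g, gn$b)
    fused <- agRelu(agConv2d(cat3, fuse_w, fuse_b))
    Hp <- dim(fused$value)[1]; Wp <- dim(fused$value)[2]
    xq <- agAsMat(fused)
    pos <- .posEncoding2d(Hp, Wp, d)
    ref <- cbind((rep(seq_len(Hp), times = Wp) - 0.5) / Hp,
                 (rep(seq_len(Wp), each = Hp) - 0.5) / Wp)
    pyr <- list(f1, f2, f3)
    for (ly in layers) {
      q <- agAdd(agAdd(xq, agConst(pos)), .agRowBroadcast(scale_emb, Hp * Wp))
      att <- msdam(q, ref, pyr, ly$att, ac)
      xq <- agAdd(xq, att)
      ffn <- agAdd(agMatmul(agRelu(agAdd(agMatmul(xq, ly$ffn1_w),
                                         .agRowBroadcast(ly$ffn1_b,
                                                         Hp * Wp))),
                            ly$ffn2_w),
                   .agRowBroadcast(ly$ffn2_b, Hp * Wp))
      xq <- agAdd(xq, ffn)
    }
    pooled <- agMean2d(xq)
    logit <- agAdd(agLinear(pooled, head_w), head_b)
    logit$score <- 1 / (1 + exp(-logit$value))
    logit
  }
  net
}

# column means of a matrix tensor -> vector tensor
agMean2d <- function(x) {
  n <- nrow(x$value)
  agNode(colMeans(x$value), list(x), function(g) {
    list(matrix(rep(g, each = n) / n, n, ncol(x$value)))
  })
}

#' Score prepared crops with the classifier
#'
#' @param model from [buildImglVtnet()] (trained).
#' @param crops list of crops (any size; passed through [prepareCrop()]).
#' @param threshold decision threshold on the score.
#' @return data.frame with columns id (if present in crops), score, class.
#' @export
classifyCrops <- function(model, crops, threshold = NULL) {
  cfg <- model$config$cls
  if (is.null(threshold)) threshold <- cfg$threshold %||% 0.5
  rows <- lapply(seq_along(crops), function(i) {
    cr <- crops[[i]]
    img <- if (is.list(cr)) cr$image else cr
    s <- model$forward(prepareCrop(img, cfg$input_size),
                       training = FALSE)$score
    data.frame(id = if (is.list(cr) && !is.null(cr$id)) cr$id else i,
               score = s, class = if (s >= threshold) "IM" else "normal",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train the gland classifier
#'
#' Adam on the focal loss over labeled crops; when `mean_teacher` is TRUE
#' and unlabeled crops are given, an exponential-moving-average teacher
#' scores augmented unlabeled crops and the squared score difference to
#' the student is added, with the consistency weight ramped linearly over
#' the first 20% of steps. Deterministic under `seed`.
#'
#' @param model from [buildImglVtnet()].
#' @param labeled list of `list(image, label)` with label "IM"/"normal" (or
#'   1/0).
#' @param unlabeled optional list of crops (images or lists with `$image`).
#' @param config a [clsConfig()].
#' @param mean_teacher enable the mean-teacher consistency term.
#' @param seed integer seed.
#' @param augment random flips/rotations during training.
#' @return the trained model, with `$loss_history` and (when enabled)
#'   `$teacher` (parameter snapshot) attached.
#' @export
trainCls <- function(model, labeled, unlabeled = list(),
                     config = clsConfig(), mean_teacher = FALSE, seed = 1L,
                     augment = TRUE) {
  stopifnot(length(labeled) >= 1L)
  set.seed(seed)
  to01 <- function(lb) if (is.character(lb)) as.numeric(lb == "IM") else
    as.numeric(lb)
  prepared <- lapply(labeled, function(cr) {
    list(image = prepareCrop(cr$image, config$input_size),
         p = to01(cr$label))
  })
  prep_unlab <- lapply(unlabeled, function(cr) {
    img <- if (is.list(cr)) cr$image else cr
    prepareCrop(img, config$input_size)
  })
  use_mt <- isTRUE(mean_teacher) && length(prep_unlab) > 0L
  teacher <- if (use_mt) .netStateDump(model) else NULL
  teacher_net <- if (use_mt) {
    tn <- buildImglVtnet(config)
    .netStateLoad(tn, teacher)
    tn
  } else NULL
  total_steps <- config$epochs * length(prepared)
  ramp_steps <- max(1L, round(0.2 * total_steps))
  step <- 0L
  hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(prepared))
    ep_loss <- 0
    for (i in ord) {
      cr <- prepared[[i]]
      img <- if (augment) .augmentArrays(list(cr$image), max_shift = 0L)[[1]]
      else cr$image
      logit <- model$forward(img, training = TRUE)
      loss <- agFocalBce(logit, cr$p, gamma = config$gamma)
      if (use_mt) {
        u <- prep_unlab[[sample.int(length(prep_unlab), 1L)]]
        ua <- if (augment) .augmentArrays(list(u), max_shift = 0L)[[1]] else u
        ts <- teacher_net$forward(ua, training = FALSE)$score
        ss <- agSigmoid(model$forward(ua, training = TRUE))
        wc <- config$consistency_weight * min(1, step / ramp_steps)
        cons <- agMul(agPow(agSub(ss, agConst(ts)), 2), agConst(wc))
        loss <- agAdd(loss, cons)
      }
      if (!is.finite(loss$value)) {
        stop(sprintf("classifier training diverged at epoch %d", ep))
      }
      agBackward(loss)
      step <- step + 1L
      adamStep(model$params, lr = config$lr, step = step)
      if (use_mt) {
        a <- config$ema_decay
        for (nm in names(model$params)) {
          teacher_net$params[[nm]]$value <-
            a * teacher_net$params[[nm]]$value +
            (1 - a) * model$params[[nm]]$value
        }
        # normalization statistics follow the student directly
        for (nm in names(model$states)) {
          st <- model$states[[nm]]
          tst <- teacher_net$states[[nm]]
          for (f in ls(st)) tst[[f]] <- st[[f]]
        }
      }
      ep_loss <- ep_loss + loss$value
    }
    hist[ep] <- ep_loss / length(prepared)
  }
  model$loss_history <- hist
  if (use_mt) model$teacher <- .netStateDump(teacher_net)
  model
}
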