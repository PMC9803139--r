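# Minimal reverse-mode automatic differentiation on dense arrays.
#
# A tensor is an environment holding a numeric value, an accumulated
# gradient, its parents in the computation graph and a backward closure
# that maps the output gradient to parent gradients.  Image tensors are
# column-major [H, W, C] arrays; convolution lowering (im2col/col2im)
# runs in C++, matrix products go through BLAS.

agTensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- requires_grad
  t$needs <- requires_grad
  t$parents <- list()
  t$bw <- NULL
  class(t) <- "ag_tensor"
  t
}

agParam <- function(value) agTensor(value, requires_grad = TRUE)

agIsTensor <- function(x) inherits(x, "ag_tensor")

agConst <- function(x) if (agIsTensor(x)) x else agTensor(x)

# Create an op node. bw(g) must return a list of gradients aligned with
# `parents` (NULL for parents that need no gradient).
agNode <- function(value, parents, bw) {
  t <- agTensor(value)
  t$parents <- parents
  t$needs <- any(vapply(parents, function(p) isTRUE(p$needs), logical(1)))
  if (t$needs) t$bw <- bw
  t
}

zerosLike <- function(v) {
  z <- v
  z[] <- 0
  z
}

agAccum <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

.ag_state <- new.env(parent = emptyenv())
.ag_state$epoch <- 0L

# Reverse sweep from a scalar loss tensor.
agBackward <- function(t) {
  stopifnot(length(t$value) == 1L)
  order <- list()
  .ag_state$epoch <- .ag_state$epoch + 1L
  mark <- .ag_state$epoch
  visit <- function(node) {
    if (identical(node$.mark, mark)) return(invisible(NULL))
    node$.mark <- mark
    for (p in node$parents) if (isTRUE(p$needs)) visit(p)
    order[[length(order) + 1L]] <<- node
    invisible(NULL)
  }
  visit(t)
  t$grad <- 1
  for (node in rev(order)) {
    if (is.null(node$bw) || is.null(node$grad)) next
    gs <- node$bw(node$grad)
    ps <- node$parents
    for (i in seq_along(ps)) {
      if (!is.null(gs[[i]]) && isTRUE(ps[[i]]$needs)) agAccum(ps[[i]], gs[[i]])
    }
  }
  invisible(t)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- elementwise and reduction ops ----

agAdd <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value + b$value, list(a, b), function(g) {
    ga <- if (length(a$value) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$value) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

agSub <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value - b$value, list(a, b), function(g) {
    ga <- if (length(a$value) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(b$value) == 1L && length(g) > 1L) sum(-g) else -g
    list(ga, gb)
  })
}

agMul <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agNode(a$value * b$value, list(a, b), function(g) {
    ga <- g * b$value
    gb <- g * a$value
    if (length(a$value) == 1L && length(ga) > 1L) ga <- sum(ga)
    if (length(b$value) == 1L && length(gb) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

agNeg <- function(a) agNode(-a$value, list(a), function(g) list(-g))

agLog <- function(a) agNode(log(a$value), list(a), function(g) list(g / a$value))

agPow <- function(a, p) {
  agNode(a$value^p, list(a), function(g) list(g * p * a$value^(p - 1)))
}

agRelu <- function(a) {
  m <- a$value > 0
  agNode(a$value * m, list(a), function(g) list(g * m))
}

agSigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  agNode(s, list(a), function(g) list(g * s * (1 - s)))
}

agSum <- function(a) agNode(sum(a$value), list(a), function(g) {
  gg <- zerosLike(a$value)
  gg[] <- g
  list(gg)
})

agMean <- function(a) {
  n <- length(a$value)
  agNode(mean(a$value), list(a), function(g) {
    gg <- zerosLike(a$value)
    gg[] <- g / n
    list(gg)
  })
}

agMatmul <- function(a, b) {
  agNode(a$value %*% b$value, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

# Scale row i of matrix X by w[i].
agRowscale <- function(x, w) {
  agNode(x$value * as.vector(w$value), list(x, w), function(g) {
    list(g * as.vector(w$value), rowSums(g * x$value))
  })
}

agSoftmaxRows <- function(x) {
  v <- x$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  p <- e / rowSums(e)
  agNode(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

agGatherRows <- function(x, idx) {
  idx <- as.integer(idx)
  agNode(x$value[idx, , drop = FALSE], list(x), function(g) {
    dx <- zerosLike(x$value)
    agg <- rowsum(g, group = idx)
    rows <- as.integer(rownames(agg))
    dx[rows, ] <- dx[rows, , drop = FALSE] + agg
    list(dx)
  })
}

## ---- convolution family ----

agConv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L, dil = 1L) {
  dx <- dim(x$value); H <- dx[1]; W <- dx[2]; Cin <- dx[3]
  dw <- dim(w$value); kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  stopifnot(dw[3] == Cin)
  Hout <- (H + 2L * pad - dil * (kh - 1L) - 1L) %/% stride + 1L
  Wout <- (W + 2L * pad - dil * (kw - 1L) - 1L) %/% stride + 1L
  cols <- cpp_im2col(x$value, H, W, Cin, kh, kw, stride, pad, dil)
  Wmat <- matrix(w$value, kh * kw * Cin, Cout)
  ymat <- cols %*% Wmat                       # [Hout*Wout, Cout]
  if (!is.null(b)) ymat <- ymat + rep(b$value, each = Hout * Wout)
  y <- array(ymat, c(Hout, Wout, Cout))
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agNode(y, parents, function(g) {
    gmat <- matrix(g, Hout * Wout, Cout)
    dWv <- crossprod(cols, gmat)
    dim(dWv) <- dw
    dxv <- NULL
    if (isTRUE(x$needs)) {
      dcols <- gmat %*% t(Wmat)
      dxv <- cpp_col2im(dcols, H, W, Cin, kh, kw, stride, pad, dil)
    }
    if (is.null(b)) list(dxv, dWv) else list(dxv, dWv, colSums(gmat))
  })
}

# Transposed convolution; weight array [kh, kw, Cout, Cin] so that the
# lowering reuses the im2col row layout of the adjoint convolution.
agConvT2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  dx <- dim(x$value); H <- dx[1]; W <- dx[2]; Cin <- dx[3]
  dw <- dim(w$value); kh <- dw[1]; kw <- dw[2]; Cout <- dw[3]
  stopifnot(dw[4] == Cin)
  Hout <- (H - 1L) * stride + kh - 2L * pad
  Wout <- (W - 1L) * stride + kw - 2L * pad
  xmat <- matrix(x$value, H * W, Cin)
  Wmat <- matrix(w$value, kh * kw * Cout, Cin)
  cols <- xmat %*% t(Wmat)                    # [H*W, kh*kw*Cout]
  y <- cpp_col2im(cols, Hout, Wout, Cout, kh, kw, stride, pad, 1L)
  if (!is.null(b)) y <- y + rep(b$value, each = Hout * Wout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agNode(y, parents, function(g) {
    dcols <- cpp_im2col(g, Hout, Wout, Cout, kh, kw, stride, pad, 1L)
    dWv <- crossprod(dcols, xmat)
    dim(dWv) <- dw
    dxv <- NULL
    if (isTRUE(x$needs)) {
      dxv <- array(dcols %*% Wmat, c(H, W, Cin))
    }
    if (is.null(b)) list(dxv, dWv)
    else list(dxv, dWv, colSums(matrix(g, Hout * Wout, Cout)))
  })
}

## ---- normalization ----

# Spatial normalization over H x W per channel. With single-sample
# forward passes the batch statistics are the sample's own spatial
# moments; the same statistics are used at inference time so train and
# eval behaviour coincide exactly (running moments are tracked as state
# for introspection).
agBnorm <- function(x, gamma, beta, state, training = TRUE, eps = 1e-5,
                    momentum = 0.1) {
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  n <- H * W
  xm <- matrix(x$value, n, C)
  mu <- colMeans(xm)
  va <- colMeans(xm^2) - mu^2
  if (training) {
    if (is.null(state$mean)) {
      state$mean <- mu
      state$var <- va
    } else {
      state$mean <- (1 - momentum) * state$mean + momentum * mu
      state$var <- (1 - momentum) * state$var + momentum * va
    }
  }
  invstd <- 1 / sqrt(va + eps)
  scale <- gamma$value * invstd
  shift <- beta$value - mu * scale
  ym <- xm * rep(scale, each = n) + rep(shift, each = n)
  agNode(array(ym, d), list(x, gamma, beta), function(g) {
    gm <- matrix(g, n, C)
    xhat <- (xm - rep(mu, each = n)) * rep(invstd, each = n)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxv <- NULL
    if (isTRUE(x$needs)) {
      dxhat <- gm * rep(gamma$value, each = n)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dxm <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
        rep(invstd, each = n)
      dxv <- array(dxm, d)
    }
    list(dxv, dgamma, dbeta)
  })
}

# Group normalization over (H, W, channels-in-group).
agGroupNorm <- function(x, n_groups, gamma, beta, eps = 1e-5) {
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(C %% n_groups == 0L)
  cg <- C %/% n_groups
  n <- H * W * cg
  xg <- matrix(x$value, H * W * cg, n_groups)
  mu <- colMeans(xg)
  va <- colMeans(xg^2) - mu^2
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xg - rep(mu, each = n)) * rep(invstd, each = n)
  xhat_a <- array(xhat, d)
  gch <- rep(gamma$value, each = H * W)
  bch <- rep(beta$value, each = H * W)
  ym <- as.vector(xhat_a) * gch + bch
  agNode(array(ym, d), list(x, gamma, beta), function(g) {
    gv <- as.vector(g)
    gm3 <- array(gv, d)
    dgamma <- colSums(matrix(gv * as.vector(xhat_a), H * W, C))
    dbeta <- colSums(matrix(gv, H * W, C))
    dxv <- NULL
    if (isTRUE(x$needs)) {
      dxhat <- matrix(as.vector(gm3) * gch, H * W * cg, n_groups)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      dxg <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
        rep(invstd, each = n)
      dxv <- array(dxg, d)
    }
    list(dxv, dgamma, dbeta)
  })
}

## ---- pooling, concat, linear ----

agMaxpool2 <- function(x) {
  d <- dim(x$value); H <- d[1]; W <- d[2]; C <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a11 <- x$value[io, jo, , drop = FALSE]
  a21 <- x$value[io + 1L, jo, , drop = FALSE]
  a12 <- x$value[io, jo + 1L, , drop = FALSE]
  a22 <- x$value[io + 1L, jo + 1L, , drop = FALSE]
  m <- pmax(a11, a21, a12, a22)
  m1 <- a11 == m
  m2 <- (a21 == m) & !m1
  m3 <- (a12 == m) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  agNode(m, list(x), function(g) {
    dx <- zerosLike(x$value)
    dx[io, jo, ] <- g * m1
    dx[io + 1L, jo, ] <- g * m2
    dx[io, jo + 1L, ] <- g * m3
    dx[io + 1L, jo + 1L, ] <- g * m4
    list(dx)
  })
}

# Global average pooling [H, W, C] -> length-C vector.
agGap <- function(x) {
  d <- dim(x$value); n <- d[1] * d[2]
  agNode(colMeans(matrix(x$value, n, d[3])), list(x), function(g) {
    list(array(rep(g, each = n) / n, d))
  })
}

agConcatC <- function(xs) {
  dims <- lapply(xs, function(t) dim(t$value))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], numeric(1))
  v <- array(unlist(lapply(xs, function(t) t$value)), c(H, W, sum(cs)))
  agNode(v, xs, function(g) {
    off <- cumsum(c(0, cs))
    lapply(seq_along(xs), function(i) {
      g[, , (off[i] + 1L):off[i + 1L], drop = FALSE]
    })
  })
}

# Dense layer; x a vector (length n_in) or matrix [B, n_in]; W [n_in, n_out].
agLinear <- function(x, w, b = NULL) {
  xv <- x$value
  is_mat <- is.matrix(xv)
  xm <- if (is_mat) xv else matrix(xv, 1L)
  ym <- xm %*% w$value
  if (!is.null(b)) ym <- ym + rep(b$value, each = nrow(ym))
  yv <- if (is_mat) ym else as.vector(ym)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  agNode(yv, parents, function(g) {
    gm <- if (is_mat) g else matrix(g, 1L)
    dxm <- gm %*% t(w$value)
    dxv <- if (is_mat) dxm else as.vector(dxm)
    dwv <- t(xm) %*% gm
    if (is.null(b)) list(dxv, dwv) else list(dxv, dwv, colSums(gm))
  })
}

# Fused softmax + weighted negative log-likelihood over a 3-class (or
# k-class) per-pixel map.  labels: integer matrix in 0..K-1; weights: a
# non-negative per-pixel matrix.  Probabilities are clipped at `eps`
# before the log.  The node caches class probabilities in $probs.
agSoftmaxNll <- function(logits, labels, weights, eps = 1e-7) {
  d <- dim(logits$value); H <- d[1]; W <- d[2]; K <- d[3]
  lm <- matrix(logits$value, H * W, K)
  if (anyNA(lm) || any(!is.finite(lm))) {
    stop("non-finite values in prediction logits")
  }
  mx <- do.call(pmax, lapply(seq_len(K), function(k) lm[, k]))
  e <- exp(lm - mx)
  p <- e / rowSums(e)
  li <- as.vector(labels) + 1L
  wv <- as.vector(weights)
  pick <- p[cbind(seq_len(H * W), li)]
  loss <- -sum(wv * log(pmax(pick, eps)))
  node <- agNode(loss, list(logits), function(g) {
    onehot <- matrix(0, H * W, K)
    onehot[cbind(seq_len(H * W), li)] <- 1
    dm <- (p - onehot) * wv * g
    list(array(dm, d))
  })
  node$probs <- array(p, d)
  node
}

## ---- reshapes, slices, small-matrix helpers ----

# [H, W, C] -> [H*W, C] (row index = i + (j-1)*H, column-major raster).
agAsMat <- function(x) {
  d <- dim(x$value)
  agNode(matrix(x$value, d[1] * d[2], d[3]), list(x), function(g) {
    list(array(g, d))
  })
}

agAsArr3 <- function(x, H, W) {
  C <- ncol(x$value)
  agNode(array(x$value, c(H, W, C)), list(x), function(g) {
    list(matrix(g, H * W, C))
  })
}

agCols <- function(x, idx) {
  idx <- as.integer(idx)
  agNode(x$value[, idx, drop = FALSE], list(x), function(g) {
    dx <- zerosLike(x$value)
    dx[, idx] <- g
    list(dx)
  })
}

agCbind <- function(xs) {
  cs <- vapply(xs, function(t) ncol(t$value), numeric(1))
  agNode(do.call(cbind, lapply(xs, function(t) t$value)), xs, function(g) {
    off <- cumsum(c(0, cs))
    lapply(seq_along(xs), function(i) {
      g[, (off[i] + 1L):off[i + 1L], drop = FALSE]
    })
  })
}

# Binary focal loss on logits (vector), hard targets p in {0,1}; returns the
# mean over the batch. Scores are clipped at eps before the logs.
agFocalBce <- function(logits, p, gamma = 2, eps = 1e-7) {
  z <- logits$value
  if (any(!is.finite(z))) stop("non-finite classifier logits")
  s <- 1 / (1 + exp(-z))
  sc <- pmin(pmax(s, eps), 1 - eps)
  n <- length(z)
  fl <- ifelse(p == 1, (1 - sc)^gamma * (-log(sc)), sc^gamma * (-log(1 - sc)))
  agNode(mean(fl), list(logits), function(g) {
    dfl_ds <- ifelse(
      p == 1,
      -gamma * (1 - sc)^(gamma - 1) * (-log(sc)) - (1 - sc)^gamma / sc,
      gamma * sc^(gamma - 1) * (-log(1 - sc)) + sc^gamma / (1 - sc))
    list(g * dfl_ds * s * (1 - s) / n)
  })
}

## ---- initializers and optimizers ----

heInit <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

makeConvParam <- function(kh, kw, cin, cout) {
  agParam(heInit(c(kh, kw, cin, cout), kh * kw * cin))
}

makeConvTParam <- function(kh, kw, cout, cin) {
  agParam(heInit(c(kh, kw, cout, cin), kh * kw * cin))
}

makeBiasParam <- function(n) agParam(numeric(n))

# SGD with classical momentum and decoupled L2 weight decay.
sgdStep <- function(params, lr, momentum = 0.9, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    if (is.null(p$.vel)) p$.vel <- zerosLike(p$value)
    p$.vel <- momentum * p$.vel + g
    p$value <- p$value - lr * p$.vel
  }
  agZeroGrad(params)
}

adamStep <- function(params, lr, step, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad + weight_decay * p$value
    if (is.null(p$.m)) {
      p$.m <- zerosLike(p$value)
      p$.v <- zerosLike(p$value)
    }
    p$.m <- beta1 * p$.m + (1 - beta1) * g
    p$.v <- beta2 * p$.v + (1 - beta2) * g^2
    mhat <- p$.m / (1 - beta1^step)
    vhat <- p$.v / (1 - beta2^step)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  agZeroGrad(params)
}
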