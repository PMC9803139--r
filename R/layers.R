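# Reusable network building blocks on top of the autodiff engine. A "net"
# is an environment with a named parameter list, per-layer normalization
# state, a config and a forward closure; builders register parameters as
# they compose layers.

.netNew <- function(config = list()) {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$states <- list()
  net$config <- config
  class(net) <- "glandflow_net"
  net
}

.netParam <- function(net, name, value) {
  p <- agParam(value)
  net$params[[name]] <- p
  p
}

.netBn <- function(net, name, C) {
  st <- new.env(parent = emptyenv())
  net$states[[name]] <- st
  list(g = .netParam(net, paste0(name, ".gamma"), rep(1, C)),
       b = .netParam(net, paste0(name, ".beta"), rep(0, C)),
       st = st)
}

#' @export
print.glandflow_net <- function(x, ...) {
  n <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<%s network: %d parameter tensors, %s weights>\n",
              x$config$type %||% "glandflow", length(x$params),
              format(n, big.mark = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# conv -> batchnorm -> ReLU
.convBR <- function(net, name, cin, cout, k = 3L, stride = 1L, dil = 1L,
                    relu = TRUE) {
  force(stride); force(dil); force(relu)     # loop-safe closure capture
  w <- .netParam(net, paste0(name, ".w"), heInit(c(k, k, cin, cout),
                                                 k * k * cin))
  bn <- .netBn(net, name, cout)
  pad <- dil * (k - 1L) %/% 2L
  function(x, training = TRUE) {
    y <- agConv2d(x, w, NULL, stride = stride, pad = pad, dil = dil)
    y <- agBnorm(y, bn$g, bn$b, bn$st, training = training)
    if (relu) agRelu(y) else y
  }
}

# Basic residual block: two 3x3 conv-BN with identity (or 1x1-projected)
# skip, ReLU after the sum.
.resBlock <- function(net, name, cin, cout, stride = 1L, dil = 1L) {
  force(stride); force(dil)
  c1 <- .convBR(net, paste0(name, ".c1"), cin, cout, 3L, stride, dil)
  c2 <- .convBR(net, paste0(name, ".c2"), cout, cout, 3L, 1L, dil,
                relu = FALSE)
  proj <- NULL
  if (cin != cout || stride != 1L) {
    proj <- .convBR(net, paste0(name, ".proj"), cin, cout, 1L, stride, 1L,
                    relu = FALSE)
  }
  function(x, training = TRUE) {
    y <- c2(c1(x, training), training)
    sk <- if (is.null(proj)) x else proj(x, training)
    agRelu(agAdd(y, sk))
  }
}

# Four-stage residual encoder with a 7x7 stem (stride 2). Stage strides
# default to 1,2,2 and a dilated (stride 1, dilation 2) last stage, giving
# a final feature stride of 8. Returns per-stage forward closures.
.resEncoder <- function(net, name, cin, width, blocks = c(1L, 1L, 1L, 1L),
                        last_stride = 1L, last_dil = 2L) {
  stem <- .convBR(net, paste0(name, ".stem"), cin, width, 7L, 2L, 1L)
  chans <- width * c(1L, 2L, 4L, 8L)
  strides <- c(1L, 2L, 2L, last_stride)
  dils <- c(1L, 1L, 1L, last_dil)
  stages <- list()
  prev <- width
  for (s in 1:4) {
    blks <- list()
    for (b in seq_len(blocks[s])) {
      blks[[b]] <- .resBlock(net, sprintf("%s.s%d.b%d", name, s, b),
                             if (b == 1L) prev else chans[s], chans[s],
                             stride = if (b == 1L) strides[s] else 1L,
                             dil = dils[s])
    }
    stages[[s]] <- local({
      bl <- blks
      function(x, training = TRUE) {
        for (f in bl) x <- f(x, training)
        x
      }
    })
    prev <- chans[s]
  }
  list(stem = stem, stages = stages, channels = chans)
}

# Chain of stride-2 deconvolutions (each followed by BN + ReLU) that
# upsamples by 2^n_steps.
.upChain <- function(net, name, cin, cout, n_steps) {
  steps <- list()
  prev <- cin
  for (i in seq_len(n_steps)) {
    co <- if (i == n_steps) cout else max(cout, prev %/% 2L)
    w <- .netParam(net, sprintf("%s.d%d.w", name, i),
                   heInit(c(4L, 4L, co, prev), 16L * prev))
    bn <- .netBn(net, sprintf("%s.d%d", name, i), co)
    steps[[i]] <- local({
      w0 <- w; bn0 <- bn
      function(x, training = TRUE) {
        y <- agConvT2d(x, w0, NULL, stride = 2L, pad = 1L)
        agRelu(agBnorm(y, bn0$g, bn0$b, bn0$st, training = training))
      }
    })
    prev <- co
  }
  function(x, training = TRUE) {
    for (f in steps) x <- f(x, training)
    x
  }
}

# Snapshot / restore parameter values and normalization statistics.
.netStateDump <- function(net) {
  list(params = lapply(net$params, function(p) p$value),
       states = lapply(net$states, function(st) as.list(st)),
       config = net$config)
}

.netStateLoad <- function(net, dump) {
  stopifnot(identical(sort(names(net$params)), sort(names(dump$params))))
  for (nm in names(dump$params)) net$params[[nm]]$value <- dump$params[[nm]]
  for (nm in names(dump$states)) {
    st <- net$states[[nm]]
    for (f in names(dump$states[[nm]])) st[[f]] <- dump$states[[nm]][[f]]
  }
  invisible(net)
}

# On-the-fly augmentation shared by the trainers: random 90-degree
# rotations, flips and integer circular shifts, applied consistently to the
# image and any aligned label planes.
.augmentArrays <- function(arrays, max_shift = 8L) {
  k <- sample(0:3, 1L)
  fh <- stats::runif(1) < 0.5
  fv <- stats::runif(1) < 0.5
  sh <- sample(-max_shift:max_shift, 2L, replace = TRUE)
  lapply(arrays, function(a) {
    m3 <- length(dim(a)) == 3L
    rot1 <- function(x) if (m3) aperm(x, c(2, 1, 3))[rev(seq_len(ncol(x))), , , drop = FALSE] else t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
    for (i in seq_len(k)) a <- rot1(a)
    if (fh) a <- if (m3) a[, rev(seq_len(ncol(a))), , drop = FALSE] else a[, rev(seq_len(ncol(a))), drop = FALSE]
    if (fv) a <- if (m3) a[rev(seq_len(nrow(a))), , , drop = FALSE] else a[rev(seq_len(nrow(a))), , drop = FALSE]
    ri <- ((seq_len(nrow(a)) - 1L - sh[1]) %% nrow(a)) + 1L
    ci <- ((seq_len(ncol(a)) - 1L - sh[2]) %% ncol(a)) + 1L
    if (m3) a[ri, ci, , drop = FALSE] else a[ri, ci, drop = FALSE]
  })
}
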