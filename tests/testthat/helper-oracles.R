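# Brute-force oracles and tiny fixture builders shared across tests. All
# oracles are deliberately naive (loops, enumeration) and independent of
# the package's vectorized implementations.

# random small instance mask with 2..4 blob-ish objects
randomInstanceMask <- function(size = 12L, n_obj = sample(2:4, 1L)) {
  m <- matrix(0L, size, size)
  for (k in seq_len(n_obj)) {
    cy <- runif(1, 2, size - 1)
    cx <- runif(1, 2, size - 1)
    r <- runif(1, 1.2, size / 3)
    for (i in seq_len(size)) {
      for (j in seq_len(size)) {
        if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- k
      }
    }
  }
  # relabel to drop fully overwritten objects
  ids <- sort(unique(m[m > 0L]))
  out <- matrix(0L, size, size)
  for (k in seq_along(ids)) out[m == ids[k]] <- k
  out
}

# object Dice straight from its definition, loops only
bruteObjectDice <- function(gt, seg) {
  gids <- sort(unique(gt[gt > 0]))
  sids <- sort(unique(seg[seg > 0]))
  if (!length(gids) && !length(sids)) return(1)
  if (!length(gids) || !length(sids)) return(0)
  dice <- function(a, b) {
    i <- sum(a & b)
    if (sum(a) + sum(b) == 0) 1 else 2 * i / (sum(a) + sum(b))
  }
  tot_s <- sum(seg > 0)
  s1 <- 0
  for (s in sids) {
    S <- seg == s
    best <- 0; bestov <- -1
    for (g in gids) {
      ov <- sum(S & (gt == g))
      if (ov > bestov) { bestov <- ov; best <- g }
    }
    d <- if (bestov > 0) dice(gt == best, S) else 0
    s1 <- s1 + sum(S) / tot_s * d
  }
  tot_g <- sum(gt > 0)
  s2 <- 0
  for (g in gids) {
    G <- gt == g
    best <- 0; bestov <- -1
    for (s in sids) {
      ov <- sum(G & (seg == s))
      if (ov > bestov) { bestov <- ov; best <- s }
    }
    d <- if (bestov > 0) dice(G, seg == best) else 0
    s2 <- s2 + sum(G) / tot_g * d
  }
  0.5 * (s1 + s2)
}

# symmetric Hausdorff between two pixel sets, O(n^2) double loop
bruteHausdorff <- function(A, B) {
  pa <- which(A, arr.ind = TRUE) - 1
  pb <- which(B, arr.ind = TRUE) - 1
  h <- function(P, Q) {
    worst <- 0
    for (i in seq_len(nrow(P))) {
      best <- Inf
      for (j in seq_len(nrow(Q))) {
        d <- sqrt(sum((P[i, ] - Q[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(h(pa, pb), h(pb, pa))
}

# object Hausdorff by definition (same pairing rule as the implementation)
bruteObjectHausdorff <- function(gt, seg) {
  gids <- sort(unique(gt[gt > 0]))
  sids <- sort(unique(seg[seg > 0]))
  cen <- function(m, id) {
    px <- which(m == id, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }
  partner <- function(m_a, id_a, m_b, ids_b) {
    ovs <- vapply(ids_b, function(b) sum(m_a == id_a & m_b == b), numeric(1))
    if (any(ovs > 0)) return(ids_b[which.max(ovs)])
    ca <- cen(m_a, id_a)
    d2 <- vapply(ids_b, function(b) sum((cen(m_b, b) - ca)^2), numeric(1))
    ids_b[which.min(d2)]
  }
  tot_s <- sum(seg > 0); tot_g <- sum(gt > 0)
  s1 <- 0
  for (s in sids) {
    g <- partner(seg, s, gt, gids)
    s1 <- s1 + sum(seg == s) / tot_s * bruteHausdorff(gt == g, seg == s)
  }
  s2 <- 0
  for (g in gids) {
    s <- partner(gt, g, seg, sids)
    s2 <- s2 + sum(gt == g) / tot_g * bruteHausdorff(gt == g, seg == s)
  }
  0.5 * (s1 + s2)
}

# detection counts via exhaustive assignment maximization (one-to-one,
# candidate pairs must cover > 50% of the gt object's area)
bruteMatchCounts <- function(gt, seg) {
  gids <- sort(unique(gt[gt > 0]))
  sids <- sort(unique(seg[seg > 0]))
  cand <- list()
  for (g in gids) {
    for (s in sids) {
      ov <- sum(gt == g & seg == s)
      if (ov > 0.5 * sum(gt == g)) {
        cand[[length(cand) + 1L]] <- c(g = g, s = s, ov = ov)
      }
    }
  }
  best <- 0
  if (length(cand)) {
    # enumerate subsets (candidate lists are tiny on these fixtures)
    n <- length(cand)
    for (mask in seq_len(2^n) - 1L) {
      sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
      gs <- vapply(cand[sel], `[`, numeric(1), "g")
      ss <- vapply(cand[sel], `[`, numeric(1), "s")
      if (anyDuplicated(gs) || anyDuplicated(ss)) next
      best <- max(best, length(sel))
    }
  }
  c(tp = best, fp = length(sids) - best, fn = length(gids) - best)
}

# exhaustive minimizer of a graph_spec energy (binary labels)
bruteGraphMin <- function(graph) {
  n <- nrow(graph$unary)
  best_e <- Inf
  best_l <- NULL
  for (code in seq_len(2^n) - 1L) {
    lab <- as.integer(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
    e <- glandflow::graphEnergy(graph, lab)
    if (e < best_e) {
      best_e <- e
      best_l <- lab
    }
  }
  list(energy = best_e, labels = best_l)
}

# naive per-query/per-point deformable attention oracle
bruteMsdam <- function(query, ref, pyramid, params, config) {
  d <- config$embed_dim
  M <- config$n_heads; L <- config$n_levels; K <- config$n_points
  dh <- d %/% M
  Nq <- nrow(query)
  vals <- lapply(seq_len(L), function(l) {
    Fm <- matrix(pyramid[[l]], prod(dim(pyramid[[l]])[1:2]),
                 dim(pyramid[[l]])[3])
    Fm %*% params$w_val[[l]]$value
  })
  sample_bilinear <- function(vm, Hl, Wl, y, x, cols) {
    y0 <- floor(y); x0 <- floor(x)
    fy <- y - y0; fx <- x - x0
    acc <- numeric(length(cols))
    for (c in list(c(y0, x0, (1 - fy) * (1 - fx)),
                   c(y0 + 1, x0, fy * (1 - fx)),
                   c(y0, x0 + 1, (1 - fy) * fx),
                   c(y0 + 1, x0 + 1, fy * fx))) {
      iy <- c[1]; ix <- c[2]; w <- c[3]
      if (iy >= 0 && iy <= Hl - 1 && ix >= 0 && ix <= Wl - 1) {
        acc <- acc + w * vm[iy + ix * Hl + 1, cols]
      }
    }
    acc
  }
  out <- matrix(0, Nq, d)
  for (q in seq_len(Nq)) {
    qv <- query[q, ]
    off <- qv %*% params$w_off$value + params$b_off$value
    logits <- qv %*% params$w_att$value + params$b_att$value
    heads <- numeric(0)
    for (m in seq_len(M)) {
      slots <- ((m - 1) * L * K + 1):(m * L * K)
      a <- exp(logits[slots] - max(logits[slots]))
      a <- a / sum(a)
      acc <- numeric(dh)
      slot <- 0
      for (l in seq_len(L)) {
        Hl <- dim(pyramid[[l]])[1]; Wl <- dim(pyramid[[l]])[2]
        cols <- ((m - 1) * dh + 1):(m * dh)
        for (k in seq_len(K)) {
          slot <- slot + 1
          ci <- (((m - 1) * L + (l - 1)) * K + (k - 1)) * 2
          y <- ref[q, 1] * Hl - 0.5 + off[ci + 1]
          x <- ref[q, 2] * Wl - 0.5 + off[ci + 2]
          acc <- acc + a[slot] *
            sample_bilinear(vals[[l]], Hl, Wl, y, x, cols)
        }
      }
      heads <- c(heads, acc)
    }
    out[q, ] <- heads %*% params$w_out$value + params$b_out$value
  }
  out
}

# desk-scale segmentation phantom used by the training-recovery checks
segPhantomSpec <- function(seed) {
  phantomSpec(tileSize = 80L, nGlands = 3L, glandRadiusRange = c(5, 8),
              edgeThickness = 2, mucosaBandFraction = 0.75, seed = seed)
}

# numeric central-difference gradient for autodiff checks
numGrad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
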