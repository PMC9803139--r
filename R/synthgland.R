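# Synthetic H&E-like gland phantoms with exact ground truth.
#
# Glands are perturbed-ellipse rings (purple epithelial edge band enclosing
# a lumen) packed without overlap inside a textured mucosa band, which sits
# inside a wavy tissue band on a bright background. IM glands are enlarged
# and carry white goblet-like vacuoles. Everything downstream (segmentation,
# classification, mucosa extraction, features) can be trained and scored
# against the emitted ground truth.

# H&E-inspired palette, RGB in [0, 1]. The lumen carries a faint mucinous
# pink tint so that tissue vs background is chromatically separable (lumens
# belong to the tissue/mucosa ground truth).
.phantom_palette <- list(
  background = c(0.968, 0.960, 0.966),
  stroma     = c(0.886, 0.698, 0.773),
  mucosa     = c(0.855, 0.647, 0.745),
  epithelium = c(0.549, 0.373, 0.647),
  lumen      = c(0.933, 0.843, 0.890),
  goblet     = c(0.980, 0.972, 0.980),
  pen        = c(0.102, 0.149, 0.400),
  debris     = c(0.286, 0.235, 0.196)
)

# Smooth pseudo-random boundary wave evaluated at global x coordinates.
.bandWave <- function(x, amp, wavelength) {
  a <- amp * stats::runif(2, 0.4, 1)
  lam <- wavelength * stats::runif(2, 0.7, 1.4)
  ph <- stats::runif(2, 0, 2 * pi)
  a[1] * sin(2 * pi * x / lam[1] + ph[1]) +
    a[2] * sin(2 * pi * x / lam[2] + ph[2])
}

# Tissue/mucosa band geometry as functions of the global column coordinate.
# Drawing it from its own RNG stream makes stitched tiles share one band.
.makeBandLayout <- function(H, seed) {
  set.seed(seed)
  th <- 0.68 * H
  amp <- 0.02 * H
  top0 <- (H - th) / 2
  bot0 <- (H + th) / 2
  a <- amp * stats::runif(4, 0.4, 1)
  lam <- 0.9 * H * stats::runif(4, 0.7, 1.5)
  ph <- stats::runif(4, 0, 2 * pi)
  wave <- function(x, i) {
    a[i] * sin(2 * pi * x / lam[i] + ph[i]) +
      a[i + 2] * sin(2 * pi * x / lam[i + 2] + ph[i + 2])
  }
  list(
    tissueTop = function(x) top0 + wave(x, 1),
    tissueBot = function(x) bot0 + wave(x, 2)
  )
}

# Polar radius of a perturbed ellipse at angles theta.
.glandRadius <- function(theta, r, shp) {
  A <- r * shp$aspect
  B <- r / shp$aspect
  t2 <- theta - shp$rot
  base <- A * B / sqrt((B * cos(t2))^2 + (A * sin(t2))^2)
  harm <- 1 + shp$c[1] * cos(2 * theta + shp$phi[1]) +
    shp$c[2] * cos(3 * theta + shp$phi[2]) +
    shp$c[3] * cos(4 * theta + shp$phi[3])
  base * harm
}

.sampleShape <- function() {
  list(aspect = stats::runif(1, 0.85, 1.2),
       rot = stats::runif(1, 0, pi),
       c = stats::runif(3, 0, 0.07),
       phi = stats::runif(3, 0, 2 * pi))
}

#' Generate one synthetic gland phantom tile
#'
#' Renders a tile according to a [PhantomSpec]: a wavy tissue band on a
#' bright background, a mucosa band inside it, and non-overlapping
#' perturbed-ellipse gland rings whose epithelial edge band encloses a
#' lumen. IM glands are enlarged by `imScaleFactor` and receive white
#' goblet-like vacuoles. Output is deterministic in the spec's seed.
#'
#' @param spec a [PhantomSpec].
#' @param max_attempts rejection-sampling attempts per gland before the
#'   packing is declared infeasible.
#' @return a [PhantomSample].
#' @export
generateTile <- function(spec, max_attempts = 500L) {
  validObject(spec)
  layout <- .makeBandLayout(spec@tileSize, spec@seed)
  set.seed(spec@seed + 1L)
  .renderTile(spec, layout, col_offset = 0L, max_attempts = max_attempts)
}

# Core renderer; RNG state is the caller's.
.renderTile <- function(spec, layout, col_offset = 0L, max_attempts = 500L) {
  H <- spec@tileSize
  W <- H
  pal <- .phantom_palette
  xg <- (seq_len(W) - 1L) + col_offset      # global column coordinates
  tTop <- layout$tissueTop(xg)
  tBot <- layout$tissueBot(xg)
  rows <- matrix(seq_len(H) - 1L, H, W)
  tissue <- (rows >= rep(tTop, each = H)) & (rows <= rep(tBot, each = H))
  bandH <- tBot - tTop
  mh <- spec@mucosaBandFraction * bandH
  mTop <- tTop + (bandH - mh) / 2
  mBot <- mTop + mh
  mucosa <- (rows >= rep(mTop, each = H)) & (rows <= rep(mBot, each = H))
  mucosa <- mucosa & tissue

  instances <- matrix(0L, H, W)
  labels3 <- matrix(0L, H, W)
  occupied <- matrix(FALSE, H, W)

  n_im <- round(spec@imFraction * spec@nGlands)
  classes <- rep("normal", spec@nGlands)
  if (n_im > 0) classes[seq_len(n_im)] <- "IM"
  # randomize which slots are IM (ids stay raster-ordered later)
  if (spec@nGlands > 1) classes <- sample(classes)

  mTopMax <- max(mTop); mBotMin <- min(mBot)

  # rasterize one candidate; NULL if it overlaps or leaves the band
  try_place <- function(cx, cy, r, shp, clearance = 2) {
    rmax <- r * max(shp$aspect, 1 / shp$aspect) * (1 + sum(shp$c))
    i0 <- max(1L, floor(cy - rmax - 2)); i1 <- min(H, ceiling(cy + rmax + 3))
    j0 <- max(1L, floor(cx - rmax - 2)); j1 <- min(W, ceiling(cx + rmax + 3))
    ii <- matrix((i0:i1) - 1, i1 - i0 + 1, j1 - j0 + 1)
    jj <- matrix((j0:j1) - 1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
    dy <- ii - cy
    dx <- jj - cx
    rho <- sqrt(dx^2 + dy^2)
    th <- atan2(dy, dx)
    Rb <- .glandRadius(th, r, shp)
    inside <- rho <= Rb
    pad <- rho <= (Rb + clearance)
    occ_sub <- occupied[i0:i1, j0:j1, drop = FALSE]
    muc_sub <- mucosa[i0:i1, j0:j1, drop = FALSE]
    if (any(pad & occ_sub) || any(inside & !muc_sub)) return(NULL)
    lum <- rho <= (Rb - spec@edgeThickness)
    list(i0 = i0, j0 = j0, inside = inside, lum = lum,
         edge = inside & !lum, pad = pad, cx = cx, cy = cy, r = r,
         shp = shp)
  }
  commit <- function(g) {
    i1 <- g$i0 + nrow(g$inside) - 1L
    j1 <- g$j0 + ncol(g$inside) - 1L
    occ <- occupied[g$i0:i1, g$j0:j1]
    occ[g$pad] <- TRUE
    occupied[g$i0:i1, g$j0:j1] <<- occ
  }

  glands <- list()
  if (spec@arrangement == "rows" && spec@nGlands > 0L) {
    # jittered regular rows spanning the band, like packed foveolae
    r_hi <- spec@glandRadiusRange[2]
    rmax_typ <- r_hi * 1.3 *
      (if (spec@imFraction > 0) spec@imScaleFactor else 1)
    usable <- mBotMin - mTopMax
    nr <- max(1L, min(2L, floor(usable / (2 * rmax_typ + 2))))
    per_row <- ceiling(spec@nGlands / nr)
    k <- 0L
    for (rw in seq_len(nr)) {
      y0 <- mTopMax + (rw - 0.5) * usable / nr
      for (ix in seq_len(per_row)) {
        if (k >= spec@nGlands) break
        k <- k + 1L
        is_im <- classes[k] == "IM"
        cx0 <- (ix - 0.5) * W / per_row + stats::runif(1, -2, 2)
        cy0 <- y0 + stats::runif(1, -1.5, 1.5)
        r0 <- stats::runif(1, spec@glandRadiusRange[1],
                           spec@glandRadiusRange[2])
        if (is_im) r0 <- r0 * spec@imScaleFactor
        placed <- FALSE
        for (att in seq_len(60L)) {
          shp <- .sampleShape()
          g <- try_place(cx0, cy0, r0, shp, clearance = 1)
          if (!is.null(g)) {
            g$is_im <- is_im
            glands[[length(glands) + 1L]] <- g
            commit(g)
            placed <- TRUE
            break
          }
          r0 <- max(spec@glandRadiusRange[1] * 0.8, r0 * 0.93)
          cy0 <- cy0 + stats::runif(1, -1, 1)
        }
        if (!placed) {
          stop(sprintf(paste0("infeasible gland packing: gland %d of %d ",
                              "could not be placed in row arrangement"),
                       k, spec@nGlands))
        }
      }
    }
  } else {
    for (k in seq_len(spec@nGlands)) {
      is_im <- classes[k] == "IM"
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        r0 <- stats::runif(1, spec@glandRadiusRange[1],
                           spec@glandRadiusRange[2])
        r <- if (is_im) r0 * spec@imScaleFactor else r0
        shp <- .sampleShape()
        rmax <- r * max(shp$aspect, 1 / shp$aspect) * (1 + sum(shp$c))
        ylo <- mTopMax + rmax + 1
        yhi <- mBotMin - rmax - 1
        if (ylo >= yhi || 2 * (rmax + 2) >= W) next
        cx <- stats::runif(1, rmax + 2, W - rmax - 2)
        cy <- stats::runif(1, ylo, yhi)
        g <- try_place(cx, cy, r, shp)
        if (!is.null(g)) {
          g$is_im <- is_im
          glands[[length(glands) + 1L]] <- g
          commit(g)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf(paste0("infeasible gland packing: gland %d of %d could ",
                            "not be placed after %d attempts"),
                     k, spec@nGlands, max_attempts))
      }
    }
  }

  # raster order of centroids fixes instance ids
  if (length(glands)) {
    ord <- order(vapply(glands, function(g) g$cy, numeric(1)),
                 vapply(glands, function(g) g$cx, numeric(1)))
    glands <- glands[ord]
  }
  vacuoles <- list()
  for (k in seq_along(glands)) {
    g <- glands[[k]]
    rows_k <- g$i0:(g$i0 + nrow(g$inside) - 1L)
    cols_k <- g$j0:(g$j0 + ncol(g$inside) - 1L)
    subI <- instances[rows_k, cols_k]; subI[g$inside] <- k
    instances[rows_k, cols_k] <- subI
    subL <- labels3[rows_k, cols_k]
    subL[g$lum] <- 1L; subL[g$edge] <- 2L
    labels3[rows_k, cols_k] <- subL
    if (g$is_im) {
      nv <- sample(spec@gobletRange[1]:spec@gobletRange[2], 1L)
      for (v in seq_len(nv)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.55) * (g$r - spec@edgeThickness)
        vr <- max(1.2, stats::runif(1, 0.09, 0.15) * g$r)
        vacuoles[[length(vacuoles) + 1L]] <-
          c(g$cy + rad * sin(ang), g$cx + rad * cos(ang), vr, k)
      }
    }
  }

  # ground-truth mucosa: the gland-bearing layer — tissue rows spanned by
  # the glands plus a small lamina-propria margin (the placement band is
  # the fallback when the tile is empty)
  if (any(instances > 0L)) {
    gr <- range(which(rowSums(instances > 0L) > 0L))
    margin <- 3L
    rlo <- max(1L, gr[1] - margin)
    rhi <- min(H, gr[2] + margin)
    band <- matrix(FALSE, H, W)
    band[rlo:rhi, ] <- TRUE
    mucosa <- tissue & band
  }

  img <- .renderImage(H, W, tissue, mucosa, labels3, instances,
                      vacuoles, pal)
  if (length(spec@artifactTypes)) {
    img <- .applyArtifacts(img, tissue, spec@artifactTypes, pal)
  }

  areas <- if (length(glands)) tabulate(instances[instances > 0],
                                        nbins = length(glands)) else integer(0)
  tab <- data.frame(
    id = seq_along(glands),
    class = vapply(glands, function(g) if (g$is_im) "IM" else "normal",
                   character(1)),
    area = as.numeric(areas),
    stringsAsFactors = FALSE)

  new("PhantomSample", image = img, instances = instances, labels3 = labels3,
      tissueMask = matrix(as.integer(tissue), H, W),
      mucosaMask = matrix(as.integer(mucosa), H, W),
      glandTable = tab)
}

.renderImage <- function(H, W, tissue, mucosa, labels3, instances,
                         vacuoles, pal) {
  img <- array(0, c(H, W, 3))
  base <- matrix("background", H, W)
  base[tissue] <- "stroma"
  base[mucosa] <- "mucosa"
  base[labels3 == 1L] <- "lumen"
  base[labels3 == 2L] <- "epithelium"
  for (v in vacuoles) {
    i0 <- max(1L, floor(v[1] - v[3])); i1 <- min(H, ceiling(v[1] + v[3] + 1))
    j0 <- max(1L, floor(v[2] - v[3])); j1 <- min(W, ceiling(v[2] + v[3] + 1))
    ii <- matrix((i0:i1) - 1, i1 - i0 + 1, j1 - j0 + 1)
    jj <- matrix((j0:j1) - 1, i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
    disk <- (ii - v[1])^2 + (jj - v[2])^2 <= v[3]^2
    subB <- base[i0:i1, j0:j1]
    subL <- instances[i0:i1, j0:j1] == v[4] & subB == "lumen"
    subB[disk & subL] <- "goblet"
    base[i0:i1, j0:j1] <- subB
  }
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    for (nm in unique(as.vector(base))) {
      plane[base == nm] <- pal[[nm]][ch]
    }
    img[, , ch] <- plane
  }
  noise <- array(stats::rnorm(H * W * 3, sd = 0.02), c(H, W, 3))
  img <- pmin(pmax(img + noise, 0), 1)
  img
}

.applyArtifacts <- function(img, tissue, types, pal) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if ("pen" %in% types) {
    # a dark marker stroke across the tile
    x <- seq_len(W)
    y0 <- stats::runif(1, 0.1, 0.9) * H
    slope <- stats::runif(1, -0.3, 0.3)
    yc <- y0 + slope * x
    for (j in x) {
      i <- round(yc[j] + seq(-1, 1))
      i <- i[i >= 1 & i <= H]
      for (ch in 1:3) img[i, j, ch] <- 0.7 * img[i, j, ch] + 0.3 * pal$pen[ch]
    }
  }
  if ("blur" %in% types) {
    sz <- round(stats::runif(1, 0.15, 0.3) * H)
    i0 <- sample.int(H - sz, 1L); j0 <- sample.int(W - sz, 1L)
    patch <- img[i0:(i0 + sz), j0:(j0 + sz), , drop = FALSE]
    img[i0:(i0 + sz), j0:(j0 + sz), ] <- EBImage::gblur(patch, sigma = 3)
  }
  if ("debris" %in% types) {
    bg <- which(!tissue, arr.ind = TRUE)
    n <- sample(2:4, 1L)
    if (nrow(bg) > 0) {
      for (k in seq_len(n)) {
        p <- bg[sample.int(nrow(bg), 1L), ]
        rr <- stats::runif(1, 2, 5)
        i0 <- max(1L, floor(p[1] - rr)); i1 <- min(H, ceiling(p[1] + rr))
        j0 <- max(1L, floor(p[2] - rr)); j1 <- min(W, ceiling(p[2] + rr))
        ii <- matrix((i0:i1), i1 - i0 + 1, j1 - j0 + 1)
        jj <- matrix((j0:j1), i1 - i0 + 1, j1 - j0 + 1, byrow = TRUE)
        disk <- (ii - p[1])^2 + (jj - p[2])^2 <= rr^2
        for (ch in 1:3) {
          sub <- img[i0:i1, j0:j1, ch]
          sub[disk] <- pal$debris[ch]
          img[i0:i1, j0:j1, ch] <- sub
        }
      }
    }
  }
  img
}

#' Desk-scale phantom conditions
#'
#' The fixed small-tile study conditions used throughout the package's own
#' experiments: 128 px tiles, base gland radii 6-9 px, a 2.5 px epithelial
#' edge band and a wide mucosa band so that 1.5x-enlarged IM glands still
#' pack. Only the gland population (count, IM fraction) and the seed vary
#' between experiments.
#'
#' @param seed RNG seed.
#' @param nGlands gland count per tile.
#' @param imFraction fraction of IM glands.
#' @param artifactTypes optional artifact set, see [PhantomSpec].
#' @return a [PhantomSpec].
#' @export
deskPhantomSpec <- function(seed = 1L, nGlands = 5L, imFraction = 0,
                            artifactTypes = character(0)) {
  phantomSpec(tileSize = 128L, nGlands = nGlands,
              glandRadiusRange = c(6, 9), edgeThickness = 2.5,
              imFraction = imFraction, mucosaBandFraction = 0.75,
              artifactTypes = artifactTypes, seed = seed)
}

#' Gland-dense mucosa phantom conditions
#'
#' Small-tile conditions emulating a gland-packed mucosa (as in real
#' gastric tissue, where foveolae and glands tile the layer almost
#' continuously): many small glands in a tighter band, used by the
#' tissue/mucosa segmentation experiments where the mucosa must be
#' reconstructable from the glands by morphological closing.
#'
#' @param seed RNG seed.
#' @param nGlands gland count (default 16; use fewer for atrophic or
#'   IM-dominated slides, whose enlarged glands fit fewer per layer).
#' @param imFraction fraction of IM glands.
#' @param artifactTypes optional artifact set.
#' @return a [PhantomSpec].
#' @export
denseMucosaSpec <- function(seed = 1L, nGlands = 16L, imFraction = 0,
                            artifactTypes = character(0)) {
  phantomSpec(tileSize = 128L, nGlands = nGlands,
              glandRadiusRange = c(4, 6), edgeThickness = 1.5,
              imFraction = imFraction, mucosaBandFraction = 0.55,
              artifactTypes = artifactTypes, arrangement = "rows",
              seed = seed)
}

#' Stitch independently generated tiles into a pseudo whole-slide image
#'
#' Generates `rows x cols` tiles that share one tissue/mucosa band layout
#' per tile row (so the band runs contiguously across each row, like a
#' biopsy fragment) and stitches them into one large [PhantomSample] with
#' globally renumbered instance ids.
#'
#' @param spec a [PhantomSpec] describing each tile.
#' @param rows,cols grid dimensions (>= 1).
#' @return a [PhantomSample] of size `(rows * tileSize) x (cols * tileSize)`.
#' @export
generatePseudoWSI <- function(spec, rows = 1L, cols = 1L) {
  validObject(spec)
  stopifnot(rows >= 1L, cols >= 1L)
  H <- spec@tileSize
  bigH <- rows * H; bigW <- cols * H
  img <- array(0, c(bigH, bigW, 3))
  inst <- matrix(0L, bigH, bigW)
  lab <- matrix(0L, bigH, bigW)
  tis <- matrix(0L, bigH, bigW)
  muc <- matrix(0L, bigH, bigW)
  tabs <- list()
  next_id <- 0L
  for (r in seq_len(rows)) {
    layout <- .makeBandLayout(H, spec@seed + 7L * r)
    for (cc in seq_len(cols)) {
      set.seed(spec@seed + 1000L * r + cc)
      s <- .renderTile(spec, layout, col_offset = (cc - 1L) * H)
      ri <- ((r - 1L) * H + 1L):(r * H)
      ci <- ((cc - 1L) * H + 1L):(cc * H)
      img[ri, ci, ] <- s@image
      sub <- s@instances
      sub[sub > 0L] <- sub[sub > 0L] + next_id
      inst[ri, ci] <- sub
      lab[ri, ci] <- s@labels3
      tis[ri, ci] <- s@tissueMask
      muc[ri, ci] <- s@mucosaMask
      t <- s@glandTable
      if (nrow(t)) {
        t$id <- t$id + next_id
        tabs[[length(tabs) + 1L]] <- t
      }
      next_id <- next_id + nrow(t)
    }
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(id = integer(0), class = character(0), area = numeric(0))
  new("PhantomSample", image = img, instances = inst, labels3 = lab,
      tissueMask = tis, mucosaMask = muc, glandTable = tab)
}

#' Extract per-gland image crops for classification
#'
#' Cuts the bounding box of every gland out of a sample's image, blanks
#' non-gland pixels to the background colour, and attaches the ground-truth
#' class label — the hand-off from segmentation to gland classification.
#'
#' @param sample a [PhantomSample] with at least one gland, or a plain list
#'   with elements `image`, `instances` and `glandTable`.
#' @param pad bounding-box margin in pixels (0 = exact bounding boxes).
#' @return a list of `list(image, label, id)` entries, one per gland.
#' @export
makeGlandCrops <- function(sample, pad = 0L) {
  if (is(sample, "PhantomSample")) {
    inst <- instanceMask(sample)
    img <- phantomImage(sample)
    tab <- glandTable(sample)
  } else {
    inst <- sample$instances
    img <- sample$image
    tab <- sample$glandTable
  }
  if (nrow(tab) == 0L) stop("sample contains no glands")
  bg <- .phantom_palette$background
  lapply(seq_len(nrow(tab)), function(k) {
    id <- tab$id[k]
    px <- which(inst == id, arr.ind = TRUE)
    i0 <- max(1L, min(px[, 1]) - pad); i1 <- min(nrow(inst), max(px[, 1]) + pad)
    j0 <- max(1L, min(px[, 2]) - pad); j1 <- min(ncol(inst), max(px[, 2]) + pad)
    crop <- img[i0:i1, j0:j1, , drop = FALSE]
    m <- inst[i0:i1, j0:j1] == id
    for (ch in 1:3) {
      plane <- crop[, , ch]
      plane[!m] <- bg[ch]
      crop[, , ch] <- plane
    }
    list(image = crop, label = tab$class[k], id = id)
  })
}
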