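#' Specification of a synthetic gland phantom
#'
#' Describes one synthetic H&E-like tile: geometry of the tissue and mucosa
#' bands, the gland population (count, radii, edge thickness), the fraction
#' of intestinal-metaplasia (IM) glands and how they are rendered, optional
#' artifacts, and the RNG seed. The same spec and seed always produce a
#' bit-identical tile.
#'
#' @slot tileSize integer (height = width), pixels; at least 64.
#' @slot nGlands integer number of glands to place.
#' @slot glandRadiusRange length-2 numeric, min/max base gland radius (px).
#' @slot edgeThickness numeric, epithelial edge-band thickness (px).
#' @slot imFraction numeric in [0, 1]; IM glands get
#'   `round(imFraction * nGlands)` of the population.
#' @slot imScaleFactor numeric > 1, radius multiplier for IM glands.
#' @slot gobletRange length-2 integer, per-IM-gland goblet-vacuole count
#'   range (inclusive).
#' @slot mucosaBandFraction numeric in (0, 1], mucosa band height as a
#'   fraction of tissue height.
#' @slot artifactTypes character subset of `c("pen", "blur", "debris")`;
#'   empty by default.
#' @slot arrangement `"random"` (rejection-sampled placement) or `"rows"`
#'   (jittered regular rows, emulating densely packed foveolae).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(
    tileSize = "integer",
    nGlands = "integer",
    glandRadiusRange = "numeric",
    edgeThickness = "numeric",
    imFraction = "numeric",
    imScaleFactor = "numeric",
    gobletRange = "integer",
    mucosaBandFraction = "numeric",
    artifactTypes = "character",
    arrangement = "character",
    seed = "integer"
  ),
  prototype(
    tileSize = 480L,
    nGlands = 7L,
    glandRadiusRange = c(24, 40),
    edgeThickness = 3,
    imFraction = 0,
    imScaleFactor = 1.5,
    gobletRange = c(4L, 8L),
    mucosaBandFraction = 0.6,
    artifactTypes = character(0),
    arrangement = "random",
    seed = 1L
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (length(object@tileSize) != 1L || object@tileSize < 64L)
    msg <- c(msg, "tileSize must be a single integer >= 64")
  if (object@nGlands < 0L)
    msg <- c(msg, "nGlands must be >= 0")
  rr <- object@glandRadiusRange
  if (length(rr) != 2L || any(rr <= 0) || rr[1] > rr[2])
    msg <- c(msg, "glandRadiusRange must be positive and ordered")
  if (object@imFraction < 0 || object@imFraction > 1)
    msg <- c(msg, "imFraction must lie in [0, 1]")
  if (object@imScaleFactor <= 1)
    msg <- c(msg, "imScaleFactor must exceed 1")
  if (object@edgeThickness <= 0 || rr[1] <= object@edgeThickness + 2)
    msg <- c(msg, "edgeThickness must be positive and leave room for a lumen")
  if (object@mucosaBandFraction <= 0 || object@mucosaBandFraction > 1)
    msg <- c(msg, "mucosaBandFraction must lie in (0, 1]")
  if (!all(object@artifactTypes %in% c("pen", "blur", "debris")))
    msg <- c(msg, "artifactTypes must be a subset of pen/blur/debris")
  if (!object@arrangement %in% c("random", "rows"))
    msg <- c(msg, "arrangement must be 'random' or 'rows'")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomSpec Constructor with spec defaults.
#' @param tileSize,nGlands,glandRadiusRange,edgeThickness,imFraction,imScaleFactor,gobletRange,mucosaBandFraction,artifactTypes,seed
#'   see the corresponding slots.
#' @export
phantomSpec <- function(tileSize = 480L, nGlands = 7L,
                        glandRadiusRange = NULL, edgeThickness = 3,
                        imFraction = 0, imScaleFactor = 1.5,
                        gobletRange = c(4L, 8L), mucosaBandFraction = 0.6,
                        artifactTypes = character(0),
                        arrangement = "random", seed = 1L) {
  if (is.null(glandRadiusRange)) {
    # scale the default radii with the tile so desk-scale tiles stay feasible
    glandRadiusRange <- c(24, 40) * tileSize / 480
    glandRadiusRange[1] <- max(glandRadiusRange[1], edgeThickness + 3)
    glandRadiusRange[2] <- max(glandRadiusRange[2], glandRadiusRange[1])
  }
  new("PhantomSpec",
    tileSize = as.integer(tileSize), nGlands = as.integer(nGlands),
    glandRadiusRange = as.numeric(glandRadiusRange),
    edgeThickness = as.numeric(edgeThickness),
    imFraction = as.numeric(imFraction),
    imScaleFactor = as.numeric(imScaleFactor),
    gobletRange = as.integer(gobletRange),
    mucosaBandFraction = as.numeric(mucosaBandFraction),
    artifactTypes = as.character(artifactTypes),
    arrangement = as.character(arrangement), seed = as.integer(seed))
}

#' A synthetic gland phantom with exact ground truth
#'
#' One generated tile (or stitched pseudo-WSI): the rendered RGB image plus
#' aligned ground truth — instance labels (0 background, 1..K glands), the
#' 3-class map (0 background, 1 lumen, 2 edge), binary tissue and mucosa
#' masks, and a per-gland table (id, class, area in px^2).
#'
#' @slot image numeric array [H, W, 3] in [0, 1].
#' @slot instances integer matrix [H, W], GlaS-dialect instance labels.
#' @slot labels3 integer matrix [H, W] with values 0/1/2.
#' @slot tissueMask,mucosaMask integer matrices [H, W] with values 0/1.
#' @slot glandTable data.frame with columns id, class ("normal"/"IM"), area.
#' @export
setClass("PhantomSample",
  representation(
    image = "array",
    instances = "matrix",
    labels3 = "matrix",
    tissueMask = "matrix",
    mucosaMask = "matrix",
    glandTable = "data.frame"
  )
)

setValidity("PhantomSample", function(object) {
  d <- dim(object@image)
  msg <- character(0)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "image must be [H, W, 3]")
  for (s in c("instances", "labels3", "tissueMask", "mucosaMask")) {
    if (!identical(dim(slot(object, s)), d[1:2]))
      msg <- c(msg, paste(s, "must share the image's spatial dimensions"))
  }
  ids <- sort(unique(as.vector(object@instances)))
  ids <- ids[ids > 0]
  if (!identical(as.integer(ids), sort(as.integer(object@glandTable$id))))
    msg <- c(msg, "glandTable ids must match instance labels exactly")
  if (any(object@mucosaMask > object@tissueMask))
    msg <- c(msg, "mucosaMask must be a subset of tissueMask")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhantomSample Per-gland ground-truth table accessor.
#' @param object,x a `PhantomSample`.
#' @export
setGeneric("glandTable", function(object) standardGeneric("glandTable"))
#' @rdname PhantomSample
#' @export
setMethod("glandTable", "PhantomSample", function(object) object@glandTable)

#' @describeIn PhantomSample Instance-label matrix accessor.
#' @export
setGeneric("instanceMask", function(object) standardGeneric("instanceMask"))
#' @rdname PhantomSample
#' @export
setMethod("instanceMask", "PhantomSample", function(object) object@instances)

#' @describeIn PhantomSample 3-class label map accessor.
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))
#' @rdname PhantomSample
#' @export
setMethod("labelMap", "PhantomSample", function(object) object@labels3)

#' @describeIn PhantomSample Binary tissue mask accessor.
#' @export
setGeneric("tissueMask", function(object) standardGeneric("tissueMask"))
#' @rdname PhantomSample
#' @export
setMethod("tissueMask", "PhantomSample", function(object) object@tissueMask)

#' @describeIn PhantomSample Binary mucosa mask accessor.
#' @export
setGeneric("mucosaMask", function(object) standardGeneric("mucosaMask"))
#' @rdname PhantomSample
#' @export
setMethod("mucosaMask", "PhantomSample", function(object) object@mucosaMask)

#' @describeIn PhantomSample RGB image accessor.
#' @export
setGeneric("phantomImage", function(object) standardGeneric("phantomImage"))
#' @rdname PhantomSample
#' @export
setMethod("phantomImage", "PhantomSample", function(object) object@image)

#' @rdname PhantomSample
#' @export
setMethod("show", "PhantomSample", function(object) {
  d <- dim(object@image)
  tab <- object@glandTable
  cat(sprintf("PhantomSample %dx%d px, %d gland(s) (%d IM)\n",
              d[1], d[2], nrow(tab), sum(tab$class == "IM")))
  cat(sprintf("  tissue %.1f%%, mucosa %.1f%% of tile\n",
              100 * mean(object@tissueMask), 100 * mean(object@mucosaMask)))
  invisible(object)
})

#' @rdname PhantomSpec
#' @param object a `PhantomSpec`.
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0("PhantomSpec %dx%d px, %d glands (IM fraction %.2f, ",
                     "scale %.2f), seed %d\n"),
              object@tileSize, object@tileSize, object@nGlands,
              object@imFraction, object@imScaleFactor, object@seed))
  invisible(object)
})
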