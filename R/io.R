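# Readers and writers for the pipeline's on-disk formats: GlaS-dialect
# instance masks (16-bit single-channel TIFF, or PNG for small label
# counts), 8-bit binary masks and RGB images as PNG, CSV tables, YAML run
# configs and serialized model checkpoints with a JSON config sidecar.

.maskExt <- function(path) tolower(tools::file_ext(path))

#' Read a GlaS-dialect instance mask
#'
#' Accepts single-channel integer TIFF (16-bit) or PNG; labels are
#' preserved exactly (0 = background, k > 0 = object k; no relabeling).
#'
#' @param path file path (.tif/.tiff/.png).
#' @return integer matrix.
#' @export
readInstanceMask <- function(path) {
  ext <- .maskExt(path)
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth %||% 8L
    m <- img * (2^depth - 1)
  } else {
    stop("unsupported mask format '", ext, "'; use TIFF or PNG")
  }
  if (length(dim(m)) == 3L) {
    same <- all(vapply(seq_len(dim(m)[3])[-1], function(k) {
      all(m[, , k] == m[, , 1])
    }, logical(1)))
    if (dim(m)[3] > 1L && !same) {
      stop("mask at ", path, " is RGB; instance masks must be ",
           "single-channel integer images")
    }
    m <- m[, , 1]
  }
  if (max(abs(m - round(m))) > 1e-6) {
    stop("mask at ", path, " is float-valued; instance masks must hold ",
         "integer labels")
  }
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}

#' Write a GlaS-dialect instance mask
#'
#' 16-bit single-channel TIFF (any label count up to 65535) or 8-bit PNG
#' (up to 255 labels).
#'
#' @param mask integer matrix (0 background, positive ids).
#' @param path output path (.tif/.tiff/.png).
#' @export
writeInstanceMask <- function(mask, path) {
  stopifnot(min(mask) >= 0L)
  ext <- .maskExt(path)
  if (ext %in% c("tif", "tiff")) {
    stopifnot(max(mask) <= 65535L)
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    if (max(mask) > 255L) {
      stop("more than 255 labels; write a 16-bit TIFF instead")
    }
    png::writePNG(mask / 255, path)
  } else {
    stop("unsupported mask format '", ext, "'")
  }
  invisible(path)
}

#' Write a binary mask as 8-bit PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output .png path.
#' @export
writeBinaryMask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a binary mask written by [writeBinaryMask()]
#' @param path .png path.
#' @return 0/1 integer matrix.
#' @export
readBinaryMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' Save a network checkpoint
#'
#' Parameter values and normalization statistics are serialized next to a
#' JSON sidecar describing the architecture config, from which the model
#' can be rebuilt.
#'
#' @param model a network handle (gagl / unet / imgl).
#' @param path checkpoint path (`.rds`); the sidecar is `<path>.json`.
#' @export
saveModel <- function(model, path) {
  dump <- .netStateDump(model)
  saveRDS(dump, path)
  declass <- function(x) {
    if (is.list(x)) lapply(unclass(x), declass) else x
  }
  jsonlite::write_json(declass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network checkpoint saved by [saveModel()]
#' @param path checkpoint path.
#' @return a rebuilt network handle with restored weights.
#' @export
loadModel <- function(path) {
  dump <- readRDS(path)
  cfg <- dump$config
  model <- switch(cfg$type,
    gagl = buildGaglNet(do.call(segConfig, cfg$seg)),
    unet = {
      uu <- cfg$unet
      uu$channels <- unlist(uu$channels)   # stored already width-scaled
      uu$width_scale <- 1
      buildTissueUnet(do.call(unetConfig, uu))
    },
    imgl = {
      cc <- cfg$cls
      cc$attn <- do.call(deformAttnConfig, cc$attn)
      buildImglVtnet(do.call(clsConfig, cc))
    },
    stop("unknown model type '", cfg$type, "'"))
  .netStateLoad(model, dump)
  model
}

#' Default run configuration for the end-to-end workflow
#'
#' @param seed global seed.
#' @param out_dir output directory.
#' @param n_per_group phantom slides per cohort group.
#' @param segmentation `"oracle"` (ground-truth instances) or a gagl
#'   checkpoint path.
#' @param classifier `"oracle"` (ground-truth classes), `"off"`, or an
#'   imgl checkpoint path.
#' @param tissue `"oracle"` or a unet checkpoint path.
#' @param tile,overlap overlap-tile parameters for checkpoint-based stages.
#' @param min_area,dilate_r,erode_r post-processing / mucosa morphology.
#' @param cohort per-group generator settings: named list of lists with
#'   `n_glands` and `im_fraction`.
#' @return a list of class `run_config`.
#' @export
runConfig <- function(seed = 1L, out_dir = tempfile("glandflow"),
                      n_per_group = 10L, segmentation = "oracle",
                      classifier = "oracle", tissue = "oracle",
                      tile = 128L, overlap = 32L, min_area = 8,
                      dilate_r = 12, erode_r = 8,
                      cohort = list(
                        normal = list(n_glands = 16L, im_fraction = 0),
                        GA = list(n_glands = 10L, im_fraction = 0),
                        IM = list(n_glands = 5L, im_fraction = 1))) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_per_group = as.integer(n_per_group),
                 segmentation = segmentation, classifier = classifier,
                 tissue = tissue, tile = as.integer(tile),
                 overlap = as.integer(overlap), min_area = min_area,
                 dilate_r = dilate_r, erode_r = erode_r, cohort = cohort),
            class = "run_config")
}

.runConfigKeys <- c("seed", "out_dir", "n_per_group", "segmentation",
                    "classifier", "tissue", "tile", "overlap", "min_area",
                    "dilate_r", "erode_r", "cohort")

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to [runConfig()]
#' defaults. The round trip through [saveRunConfig()] is lossless.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
loadRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), .runConfigKeys)
  if (length(bad)) {
    stop("unknown run-config keys: ", paste(bad, collapse = ", "))
  }
  do.call(runConfig, raw)
}

#' Save a run configuration as YAML
#' @param config a `run_config`.
#' @param path output path.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable short hash of a config (FNV-1a over its serialized YAML text).
.configHash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
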