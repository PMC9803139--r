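# Sydney-system inspired per-slide quantification: mean gland area, gland
# count per mucosa area and gland area fraction, compared across normal /
# gastric-atrophy (GA) / intestinal-metaplasia (IM) groups.

#' Per-gland objects from an instance mask
#'
#' @param instances integer instance mask.
#' @param classes optional data.frame (id, class) attaching classifier
#'   output (or ground truth) to each gland.
#' @return data.frame with id, area and (if supplied) class.
#' @export
glandObjectsFromMask <- function(instances, classes = NULL) {
  ids <- sort(unique(instances[instances > 0L]))
  df <- data.frame(id = as.integer(ids),
                   area = as.numeric(tabulate(instances[instances > 0L],
                                              nbins = max(instances))[ids]))
  if (!is.null(classes)) {
    df$class <- classes$class[match(df$id, classes$id)]
  }
  df
}

#' Slide-level gland/mucosa features
#'
#' Computes, for one slide, the mean gland area (px^2), the ratio of gland
#' count to mucosa area (glands/px^2), the gland area fraction (total gland
#' area / mucosa area) and, when gland classes are available, the mean area
#' of IM-classified glands.
#'
#' @param glands data.frame with per-gland `area` (and optional `class`),
#'   e.g. from [glandObjectsFromMask()], or a list of such gland objects.
#' @param mucosa binary mucosa mask (or its pixel area as a scalar).
#' @param group cohort group label ("normal", "GA" or "IM").
#' @param slide_id identifier carried through to the output row.
#' @return one-row data.frame (`slide`, `group`, `n_glands`,
#'   `mean_gland_area`, `n_glands_per_mucosa`, `gland_area_fraction`, and
#'   `mean_im_gland_area` when classes are present).
#' @export
slideFeatures <- function(glands, mucosa, group = NA_character_,
                          slide_id = "slide") {
  if (is.list(glands) && !is.data.frame(glands)) {
    glands <- do.call(rbind, lapply(glands, as.data.frame))
  }
  marea <- if (length(mucosa) == 1L) as.numeric(mucosa) else
    sum(mucosa > 0)
  if (marea <= 0) stop("mucosa area must be positive")
  n <- nrow(glands)
  if (n > 0 && any(glands$area <= 0)) stop("gland areas must be positive")
  row <- data.frame(
    slide = slide_id, group = group, n_glands = n,
    mean_gland_area = if (n > 0) mean(glands$area) else NA_real_,
    n_glands_per_mucosa = n / marea,
    gland_area_fraction = if (n > 0) sum(glands$area) / marea else 0,
    stringsAsFactors = FALSE)
  if (n > 0 && !is.null(glands$class)) {
    im <- glands$area[glands$class == "IM"]
    row$mean_im_gland_area <- if (length(im)) mean(im) else NA_real_
  }
  row
}

#' Express mean gland areas relative to the normal-group reference
#'
#' Divides every slide's mean gland area (and IM mean area, if present) by
#' the grand mean over the reference group's slides, so the reference
#' group's ratios average 1 by construction.
#'
#' @param rows data.frame of [slideFeatures()] rows.
#' @param reference_group group used as reference (default "normal").
#' @return `rows` with added `area_ratio` (and `im_area_ratio`) columns.
#' @export
referenceRatio <- function(rows, reference_group = "normal") {
  ref <- rows$mean_gland_area[rows$group == reference_group]
  ref <- ref[!is.na(ref)]
  if (!length(ref)) stop("no rows in reference group '", reference_group, "'")
  ref_mean <- mean(ref)
  rows$area_ratio <- rows$mean_gland_area / ref_mean
  if (!is.null(rows$mean_im_gland_area)) {
    rows$im_area_ratio <- rows$mean_im_gland_area / ref_mean
  }
  rows
}

#' Pairwise group comparison of a slide feature
#'
#' Two-sided Mann-Whitney U tests for every pair of groups with
#' Benjamini-Hochberg correction across the pairs (Welch t available as an
#' alternative), plus group medians and IQRs for box-plot style summaries.
#'
#' @param rows data.frame of [slideFeatures()] rows.
#' @param feature column name to compare.
#' @param test `"wilcox"` (default) or `"t"` (Welch).
#' @return list with `comparisons` (group1, group2, statistic, p, p_adj)
#'   and `summary` (group, n, median, iqr).
#' @export
groupCompare <- function(rows, feature = "mean_gland_area",
                         test = c("wilcox", "t")) {
  test <- match.arg(test)
  stopifnot(feature %in% names(rows))
  groups <- unique(rows$group)
  if (length(groups) < 2L) stop("need at least two groups")
  for (g in groups) {
    v <- rows[[feature]][rows$group == g]
    if (sum(!is.na(v)) < 3L) {
      stop("group '", g, "' has fewer than 3 usable rows")
    }
  }
  pairs <- utils::combn(sort(groups), 2L)
  comps <- lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    v1 <- rows[[feature]][rows$group == g1]
    v2 <- rows[[feature]][rows$group == g2]
    ht <- if (test == "wilcox") {
      suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE))
    } else {
      stats::t.test(v1, v2)
    }
    data.frame(group1 = g1, group2 = g2, feature = feature,
               statistic = unname(ht$statistic), p = ht$p.value,
               stringsAsFactors = FALSE)
  })
  comps <- do.call(rbind, comps)
  comps$p_adj <- stats::p.adjust(comps$p, method = "BH")
  summ <- do.call(rbind, lapply(sort(groups), function(g) {
    v <- rows[[feature]][rows$group == g]
    data.frame(group = g, n = sum(!is.na(v)),
               median = stats::median(v, na.rm = TRUE),
               iqr = stats::IQR(v, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  list(comparisons = comps, summary = summ)
}
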