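# Object-level evaluation of instance segmentations, following the GlaS
# contest conventions: detection F1 with the >50%-of-ground-truth-area
# matching rule, area-weighted bidirectional object Dice, and the analogous
# object Hausdorff on pixel coordinates.

.objAreas <- function(mask) {
  k <- max(mask)
  if (k == 0L) return(numeric(0))
  tabulate(mask[mask > 0L], nbins = k)
}

# Overlap table between positive labels of two aligned masks:
# data.frame(gt, seg, overlap).
.overlapTable <- function(gt, seg) {
  sel <- gt > 0L & seg > 0L
  if (!any(sel)) {
    return(data.frame(gt = integer(0), seg = integer(0),
                      overlap = numeric(0)))
  }
  t <- table(gt = gt[sel], seg = seg[sel])
  df <- as.data.frame(t, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  data.frame(gt = as.integer(df$gt), seg = as.integer(df$seg),
             overlap = as.numeric(df$Freq))
}

#' Match segmented objects to ground-truth objects
#'
#' A segmented object counts as a true positive iff its overlap with some
#' ground-truth object exceeds 50% of that ground-truth object's area.
#' Candidate pairs are accepted greedily by descending overlap (ties broken
#' by the smaller segmentation id); every object takes part in at most one
#' match.
#'
#' @param gt,seg aligned integer instance masks (0 background, ids > 0).
#' @return a list with `pairs` (data.frame gt, seg, overlap), and counts
#'   `n_tp`, `n_fp`, `n_fn`.
#' @export
matchObjects <- function(gt, seg) {
  stopifnot(identical(dim(gt), dim(seg)))
  gt_areas <- .objAreas(gt)
  seg_areas <- .objAreas(seg)
  ov <- .overlapTable(gt, seg)
  cand <- ov[ov$overlap > 0.5 * gt_areas[ov$gt], , drop = FALSE]
  cand <- cand[order(-cand$overlap, cand$seg), , drop = FALSE]
  used_gt <- logical(length(gt_areas))
  used_seg <- logical(length(seg_areas))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    g <- cand$gt[i]; s <- cand$seg[i]
    if (!used_gt[g] && !used_seg[s]) {
      used_gt[g] <- TRUE
      used_seg[s] <- TRUE
      keep[i] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  n_tp <- nrow(pairs)
  list(pairs = pairs,
       n_tp = n_tp,
       n_fp = sum(seg_areas > 0) - n_tp,
       n_fn = sum(gt_areas > 0) - n_tp)
}

#' Detection precision, recall and F1 from an object match
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R). The all-zero degenerate
#' case returns 0 for all three with a warning.
#'
#' @param match result of [matchObjects()].
#' @return named numeric vector (precision, recall, f1).
#' @export
f1Detection <- function(match) {
  tp <- match$n_tp; fp <- match$n_fp; fn <- match$n_fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) {
    warning("no objects on either side; detection scores undefined, using 0")
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

.diceSets <- function(inter, a, b) {
  if (a + b == 0) return(1)
  2 * inter / (a + b)
}

#' Object-level Dice between two instance masks
#'
#' Area-weighted bidirectional Dice: each segmented object is compared with
#' the ground-truth object it overlaps most (Dice 0 when it overlaps none),
#' weighted by its share of the total segmented area; symmetrically for
#' ground-truth objects; the two sums are averaged. 1 when both masks are
#' empty, 0 when exactly one side is empty.
#'
#' @param gt,seg aligned integer instance masks.
#' @return a number in [0, 1].
#' @export
objectDice <- function(gt, seg) {
  stopifnot(identical(dim(gt), dim(seg)))
  gt_areas <- .objAreas(gt)
  seg_areas <- .objAreas(seg)
  ng <- sum(gt_areas > 0); ns <- sum(seg_areas > 0)
  if (ng == 0 && ns == 0) return(1)
  if (ng == 0 || ns == 0) return(0)
  ov <- .overlapTable(gt, seg)
  half <- function(areas_a, ov_a, ov_b, ov_n, areas_b) {
    # for each object a (ids with positive area): best-overlap partner b
    tot <- sum(areas_a)
    s <- 0
    for (a in which(areas_a > 0)) {
      rows <- ov_a == a
      d <- 0
      if (any(rows)) {
        i <- which(rows)[which.max(ov_n[rows])]
        b <- ov_b[i]
        d <- .diceSets(ov_n[i], areas_a[a], areas_b[b])
      }
      s <- s + areas_a[a] / tot * d
    }
    s
  }
  0.5 * (half(seg_areas, ov$seg, ov$gt, ov$overlap, gt_areas) +
           half(gt_areas, ov$gt, ov$seg, ov$overlap, seg_areas))
}

.objCentroids <- function(mask) {
  ids <- sort(unique(mask[mask > 0L]))
  t(vapply(ids, function(id) {
    px <- which(mask == id, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }, numeric(2)))
}

.hausdorffPair <- function(pa, pb) {
  max(cpp_max_min_dist(pa[, 1], pa[, 2], pb[, 1], pb[, 2]),
      cpp_max_min_dist(pb[, 1], pb[, 2], pa[, 1], pa[, 2]))
}

#' Object-level Hausdorff distance between two instance masks
#'
#' Same area weighting as [objectDice()], with the symmetric Hausdorff
#' distance on 0-based pixel-center coordinates (Euclidean norm) in place of
#' Dice. An object without any overlapping counterpart is paired with the
#' object whose centroid is nearest on the other side.
#'
#' @param gt,seg aligned integer instance masks; both must contain at least
#'   one object.
#' @return distance in pixels (>= 0).
#' @export
objectHausdorff <- function(gt, seg) {
  stopifnot(identical(dim(gt), dim(seg)))
  gt_areas <- .objAreas(gt)
  seg_areas <- .objAreas(seg)
  if (!sum(gt_areas > 0) || !sum(seg_areas > 0))
    stop("objectHausdorff requires at least one object on each side")
  ov <- .overlapTable(gt, seg)
  gt_ids <- which(gt_areas > 0)
  seg_ids <- which(seg_areas > 0)
  coords <- function(mask, id) {
    px <- which(mask == id, arr.ind = TRUE) - 1
    px
  }
  gt_px <- lapply(gt_ids, coords, mask = gt)
  names(gt_px) <- gt_ids
  seg_px <- lapply(seg_ids, coords, mask = seg)
  names(seg_px) <- seg_ids
  cen <- function(px) c(mean(px[, 1]), mean(px[, 2]))
  gt_cen <- t(vapply(gt_px, cen, numeric(2)))
  seg_cen <- t(vapply(seg_px, cen, numeric(2)))
  partner <- function(a, ov_a, ov_b, cen_a, cen_b, ids_b) {
    rows <- ov_a == a
    if (any(rows)) {
      i <- which(rows)[which.max(ov$overlap[rows])]
      return(ov_b[i])
    }
    d2 <- rowSums((cen_b - matrix(cen_a, nrow(cen_b), 2, byrow = TRUE))^2)
    ids_b[which.min(d2)]
  }
  tot_s <- sum(seg_areas); tot_g <- sum(gt_areas)
  s1 <- 0
  for (s in seg_ids) {
    g <- partner(s, ov$seg, ov$gt, seg_cen[as.character(s), ], gt_cen, gt_ids)
    h <- .hausdorffPair(gt_px[[as.character(g)]], seg_px[[as.character(s)]])
    s1 <- s1 + seg_areas[s] / tot_s * h
  }
  s2 <- 0
  for (g in gt_ids) {
    s <- partner(g, ov$gt, ov$seg, gt_cen[as.character(g), ], seg_cen, seg_ids)
    h <- .hausdorffPair(gt_px[[as.character(g)]], seg_px[[as.character(s)]])
    s2 <- s2 + gt_areas[g] / tot_g * h
  }
  0.5 * (s1 + s2)
}

#' Plain pixel-level Dice on the foreground of two masks
#'
#' @param gt,seg aligned masks; positive entries are foreground.
#' @return a number in [0, 1]; 1 when both are empty.
#' @export
pixelDice <- function(gt, seg) {
  stopifnot(identical(dim(gt), dim(seg)))
  a <- gt > 0; b <- seg > 0
  .diceSets(sum(a & b), sum(a), sum(b))
}

#' Evaluate a directory of predicted masks against ground truth
#'
#' Pairs files by name, computes detection precision/recall/F1, object Dice,
#' object Hausdorff and pixel Dice per image, and appends an unweighted mean
#' row. Unmatched filenames are reported with a warning and skipped.
#'
#' @param gt_dir,seg_dir directories of instance masks (any format readable
#'   by [readInstanceMask()]).
#' @param out_csv optional path to also write the report as CSV.
#' @return a data.frame, one row per image plus a `mean` row.
#' @export
evaluateMasks <- function(gt_dir, seg_dir, out_csv = NULL) {
  mask_pat <- "\\.(tif|tiff|png)$"
  gt_files <- sort(list.files(gt_dir, pattern = mask_pat,
                              ignore.case = TRUE))
  seg_files <- sort(list.files(seg_dir, pattern = mask_pat,
                               ignore.case = TRUE))
  if (length(seg_files) == 0L) stop("no predicted masks in ", seg_dir)
  common <- intersect(gt_files, seg_files)
  extra <- setdiff(union(gt_files, seg_files), common)
  if (length(extra)) {
    warning("skipping unmatched files: ", paste(extra, collapse = ", "))
  }
  if (length(common) == 0L) stop("no filename-matched mask pairs")
  rows <- lapply(common, function(f) {
    gt <- readInstanceMask(file.path(gt_dir, f))
    seg <- readInstanceMask(file.path(seg_dir, f))
    m <- matchObjects(gt, seg)
    det <- f1Detection(m)
    oh <- if (max(gt) > 0 && max(seg) > 0) objectHausdorff(gt, seg) else NA
    data.frame(image = f, precision = det["precision"],
               recall = det["recall"], f1 = det["f1"],
               object_dice = objectDice(gt, seg),
               object_hausdorff = oh,
               pixel_dice = pixelDice(gt, seg),
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  mean_row <- rep[1, ]
  mean_row$image <- "mean"
  for (cl in names(rep)[-1]) mean_row[[cl]] <- mean(rep[[cl]], na.rm = TRUE)
  out <- rbind(rep, mean_row)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
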