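#' @title Detection evaluation: IoU, matching, AP and mAP
#' @description
#' COCO-style evaluation of axis-aligned box detections. Detections are
#' greedily matched to ground truths in descending confidence order, one
#' ground truth per true positive; average precision integrates the
#' precision–recall curve either with 101-point interpolation (the COCO
#' convention, the default) or with all-point interpolation; mAP averages
#' AP over classes and then over IoU thresholds (`mAP@0.50` at threshold
#' 0.50, `mAP@0.50:0.95` over thresholds 0.50 to 0.95 in steps of 0.05).
#' Detections and ground truths are data frames with columns `image_id`,
#' `category_id`, `x_min`, `y_min`, `x_max`, `y_max`, plus `score` for
#' detections.
#' @name metrics
NULL

#' Intersection over union of box sets
#'
#' @param a,b numeric matrices (n x 4 and m x 4) of half-open boxes
#'   `x_min, y_min, x_max, y_max`.
#' @return n x m matrix of IoU values; degenerate (zero-area) boxes
#'   contribute zero overlap.
#' @export
box_iou <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 4L)
  b <- matrix(as.numeric(b), ncol = 4L)
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  if (n == 0L || m == 0L) return(out)
  area_a <- pmax(a[, 3L] - a[, 1L], 0) * pmax(a[, 4L] - a[, 2L], 0)
  area_b <- pmax(b[, 3L] - b[, 1L], 0) * pmax(b[, 4L] - b[, 2L], 0)
  for (j in seq_len(m)) {
    iw <- pmin(a[, 3L], b[j, 3L]) - pmax(a[, 1L], b[j, 1L])
    ih <- pmin(a[, 4L], b[j, 4L]) - pmax(a[, 2L], b[j, 2L])
    inter <- pmax(iw, 0) * pmax(ih, 0)
    un <- area_a + area_b[j] - inter
    out[, j] <- ifelse(un > 0, inter / un, 0)
  }
  out
}

box_cols <- c("x_min", "y_min", "x_max", "y_max")

# greedy confidence-ordered matching for one class; returns TP flags in
# descending-score order plus the number of ground truths
match_class <- function(dets, gts, iou_threshold) {
  ord <- order(-dets$score)
  dets <- dets[ord, , drop = FALSE]
  npos <- nrow(gts)
  tp <- logical(nrow(dets))
  used <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(dets))) {
    img <- dets$image_id[i]
    g <- gts[gts$image_id == img, , drop = FALSE]
    if (nrow(g) == 0L) next
    key <- as.character(img)
    taken <- if (is.null(used[[key]])) logical(nrow(g)) else used[[key]]
    ious <- box_iou(as.matrix(dets[i, box_cols]), as.matrix(g[, box_cols]))
    ious[1L, taken] <- -1
    j <- which.max(ious[1L, ])
    if (length(j) == 1L && ious[1L, j] >= iou_threshold) {
      tp[i] <- TRUE
      taken[j] <- TRUE
      used[[key]] <- taken
    } else used[[key]] <- taken
  }
  list(tp = tp, npos = npos, scores = dets$score)
}

#' Average precision for one class
#'
#' Detections are sorted by descending confidence and matched greedily,
#' one ground truth per true positive, at the given IoU threshold. The
#' precision–recall curve (recall = TP / (TP + FN)) is integrated with
#' the chosen interpolation rule.
#'
#' @param dets detection data frame (`image_id`, `score`, box columns).
#' @param gts ground-truth data frame (`image_id`, box columns).
#' @param iou_threshold IoU required for a true positive (default 0.5).
#' @param interpolation "coco101" (101 recall points, the default) or
#'   "allpoint" (exact area under the interpolated curve).
#' @return AP in `[0, 1]`; 0 when there are no detections. With no
#'   ground truths the class is undefined: `NA` with a warning.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5,
                              interpolation = c("coco101", "allpoint")) {
  interpolation <- match.arg(interpolation)
  if (nrow(gts) == 0L) {
    warning("no ground truths; AP undefined for this class")
    return(NA_real_)
  }
  if (nrow(dets) == 0L) return(0)
  m <- match_class(dets, gts, iou_threshold)
  tp_cum <- cumsum(m$tp)
  fp_cum <- cumsum(!m$tp)
  recall <- tp_cum / m$npos
  precision <- tp_cum / (tp_cum + fp_cum)
  ap_from_pr(precision, recall, interpolation)
}

# integrate a PR curve: precision envelope (max to the right), then
# either the exact step integral or the COCO 101-point mean
ap_from_pr <- function(precision, recall, interpolation) {
  env <- rev(cummax(rev(precision)))
  if (interpolation == "allpoint") {
    r_prev <- c(0, recall[-length(recall)])
    return(sum((recall - r_prev) * env))
  }
  grid <- seq(0, 1, by = 0.01)
  p_at <- vapply(grid, function(r) {
    i <- which(recall >= r)
    if (length(i) == 0L) 0 else env[i[1L]]
  }, numeric(1))
  mean(p_at)
}

#' Evaluate detections: per-class AP, mAP@0.50, mAP@0.50:0.95
#'
#' @param dets detection data frame with `image_id`, `category_id`,
#'   `score` and box columns.
#' @param gts ground-truth data frame with `image_id`, `category_id` and
#'   box columns; its categories define the class set.
#' @param thresholds IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param interpolation passed to [average_precision()].
#' @return object of class `eval_result`: `ap` (class x threshold
#'   matrix), `map_per_threshold`, `map50` (if 0.50 evaluated), `map`
#'   (mean over all thresholds), `thresholds`, `classes`.
#' @export
map_eval <- function(dets, gts, thresholds = seq(0.5, 0.95, by = 0.05),
                     interpolation = "coco101") {
  classes <- sort(unique(gts$category_id))
  if (length(classes) == 0L) stop("ground truth has no categories")
  ap <- matrix(NA_real_, length(classes), length(thresholds),
               dimnames = list(as.character(classes),
                               sprintf("%.2f", thresholds)))
  for (ci in seq_along(classes)) {
    dc <- dets[dets$category_id == classes[ci], , drop = FALSE]
    gc <- gts[gts$category_id == classes[ci], , drop = FALSE]
    for (ti in seq_along(thresholds)) {
      ap[ci, ti] <- average_precision(dc, gc, thresholds[ti],
                                      interpolation)
    }
  }
  map_t <- colMeans(ap, na.rm = TRUE)
  structure(list(ap = ap, map_per_threshold = map_t,
                 map50 = if ("0.50" %in% colnames(ap)) map_t[["0.50"]]
                         else NA_real_,
                 map = mean(map_t),
                 thresholds = thresholds, classes = classes),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result> ", length(x$classes), " classes, ",
      length(x$thresholds), " IoU thresholds\n", sep = "")
  if (!is.na(x$map50)) cat(sprintf("  mAP@0.50      : %.4f\n", x$map50))
  cat(sprintf("  mAP@%.2f:%.2f : %.4f\n", min(x$thresholds),
              max(x$thresholds), x$map))
  invisible(x)
}

#' Recall of one class at a score and IoU threshold
#'
#' Fraction of that class's ground truths matched by a detection with
#' `score >= score_threshold` under greedy confidence-ordered matching.
#'
#' @inheritParams average_precision
#' @param score_threshold minimum confidence for a detection to count.
#' @return recall in `[0, 1]`.
#' @export
detection_recall <- function(dets, gts, iou_threshold = 0.5,
                             score_threshold = 0.25) {
  if (nrow(gts) == 0L) return(NA_real_)
  dets <- dets[dets$score >= score_threshold, , drop = FALSE]
  if (nrow(dets) == 0L) return(0)
  m <- match_class(dets, gts, iou_threshold)
  sum(m$tp) / m$npos
}

#' Ground-truth data frame of a sample list
#'
#' @param samples list of [detection_sample()] objects (or compatible
#'   lists with `boxes` and `labels`).
#' @return data frame with `image_id`, `category_id` and box columns.
#' @export
samples_to_gt <- function(samples) {
  rows <- lapply(samples, function(s) {
    if (nrow(s$boxes) == 0L) return(NULL)
    data.frame(image_id = s$id, category_id = s$labels,
               x_min = s$boxes[, 1L], y_min = s$boxes[, 2L],
               x_max = s$boxes[, 3L], y_max = s$boxes[, 4L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
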