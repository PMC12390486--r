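# Detection evaluation: greedy confidence-ranked matching, precision/recall,
# average precision (all-points envelope or 101-point), mAP@0.5 and
# mAP@0.5:0.95.
#
# Detections and ground truth travel as data frames with normalized xyxy
# boxes: columns image_id, class_id, x1, y1, x2, y2 (+ conf for detections).

#' Pairwise IoU between two sets of xyxy boxes
#' @param a,b matrices or data.frames with columns x1, y1, x2, y2.
#' @return `nrow(a)` x `nrow(b)` IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- as.matrix(a[, c("x1", "y1", "x2", "y2")])
  b <- as.matrix(b[, c("x1", "y1", "x2", "y2")])
  n <- nrow(a); m <- nrow(b)
  ix1 <- pmax(matrix(a[, 1], n, m), matrix(b[, 1], n, m, byrow = TRUE))
  iy1 <- pmax(matrix(a[, 2], n, m), matrix(b[, 2], n, m, byrow = TRUE))
  ix2 <- pmin(matrix(a[, 3], n, m), matrix(b[, 3], n, m, byrow = TRUE))
  iy2 <- pmin(matrix(a[, 4], n, m), matrix(b[, 4], n, m, byrow = TRUE))
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- matrix(aa, n, m) + matrix(ab, n, m, byrow = TRUE) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Greedy per-class non-maximum suppression
#' @param dets detection data.frame (`image_id, class_id, x1..y2, conf`).
#' @param iou_threshold suppression IoU.
#' @return filtered data.frame.
#' @export
nms_detections <- function(dets, iou_threshold = 0.45) {
  if (nrow(dets) == 0) return(dets)
  keep <- logical(nrow(dets))
  for (grp in split(seq_len(nrow(dets)),
                    list(dets$image_id, dets$class_id), drop = TRUE)) {
    g <- grp[order(-dets$conf[grp])]
    while (length(g)) {
      keep[g[1]] <- TRUE
      if (length(g) == 1) break
      iou <- box_iou(dets[g[1], ], dets[g[-1], ])
      g <- g[-1][iou[1, ] <= iou_threshold]
    }
  }
  dets[keep, , drop = FALSE]
}

#' Match detections to ground truth
#'
#' Per class: detections are ranked by descending confidence (ties broken by
#' detection index) and matched greedily, each to the not-yet-matched ground
#' truth of highest IoU at or above the threshold within the same image.
#'
#' @param dets detection data.frame.
#' @param gts ground-truth data.frame (no `conf`).
#' @param iou_threshold matching IoU in (0, 1\].
#' @return `match_result`: per-class ranked TP flags with confidences and
#'   ground-truth counts.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("iou_threshold must be in (0, 1]")
  classes <- sort(unique(c(dets$class_id, gts$class_id)))
  per_class <- list()
  for (cl in classes) {
    dc <- dets[dets$class_id == cl, , drop = FALSE]
    gc <- gts[gts$class_id == cl, , drop = FALSE]
    ord <- order(-dc$conf, seq_len(nrow(dc)))
    dc <- dc[ord, , drop = FALSE]
    tp <- logical(nrow(dc))
    used <- logical(nrow(gc))
    for (i in seq_len(nrow(dc))) {
      cand <- which(gc$image_id == dc$image_id[i] & !used)
      if (!length(cand)) next
      iou <- box_iou(dc[i, ], gc[cand, , drop = FALSE])[1, ]
      j <- which.max(iou)
      if (iou[j] >= iou_threshold) {
        tp[i] <- TRUE
        used[cand[j]] <- TRUE
      }
    }
    per_class[[as.character(cl)]] <- list(tp = tp, conf = dc$conf,
                                          n_gt = nrow(gc))
  }
  structure(list(per_class = per_class, iou_threshold = iou_threshold),
            class = "match_result")
}

#' Counts and precision/recall at a confidence threshold
#' @param match a `match_result`.
#' @param conf_threshold operating confidence.
#' @return list with TP, FP, FN, precision, recall.
#' @export
match_counts <- function(match, conf_threshold = 0.25) {
  tp <- fp <- fn <- 0L
  for (m in match$per_class) {
    sel <- m$conf >= conf_threshold
    tp <- tp + sum(m$tp[sel])
    fp <- fp + sum(!m$tp[sel])
    fn <- fn + (m$n_gt - sum(m$tp[sel]))
  }
  pr <- precision_recall(tp, fp, fn)
  list(TP = tp, FP = fp, FN = fn, precision = pr[1], recall = pr[2])
}

#' Precision and recall from counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; both defined as 0 when their
#' denominator is 0.
#' @param TP,FP,FN nonnegative counts.
#' @return numeric length-2 `(precision, recall)`.
#' @export
precision_recall <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  p <- if (TP + FP > 0) TP / (TP + FP) else 0
  r <- if (TP + FN > 0) TP / (TP + FN) else 0
  c(precision = p, recall = r)
}

#' Average precision from ranked TP flags
#'
#' All-points method (default): area under the precision envelope, i.e.
#' precision at each recall level replaced by the maximum precision at that
#' recall or beyond, summed over recall increments — the exact integral of
#' the interpolated p(r). `method = "coco101"` samples the envelope at 101
#' recall points instead.
#'
#' @param tp logical vector of ranked TP flags (descending confidence).
#' @param n_gt number of ground-truth instances (>= 1).
#' @param method `"all_points"` or `"coco101"`.
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(tp, n_gt, method = c("all_points", "coco101")) {
  method <- match.arg(method)
  if (n_gt < 1) stop("n_gt must be >= 1 (exclude absent classes upstream)")
  if (!length(tp)) return(0)
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(tp)
  rec <- cum_tp / n_gt
  env <- rev(cummax(rev(prec)))
  if (method == "all_points") {
    prev_r <- c(0, head(rec, -1))
    sum((rec - prev_r) * env)
  } else {
    pts <- seq(0, 1, by = 0.01)
    vals <- vapply(pts, function(r) {
      ok <- rec >= r
      if (any(ok)) max(env[ok]) else 0
    }, 0)
    mean(vals)
  }
}

#' Evaluate a detector on a labeled image set
#'
#' Runs the model, filters at a low confidence floor, applies per-class NMS,
#' and computes per-class AP@0.5, mAP@0.5, mAP@0.5:0.95 (10 IoU thresholds)
#' and precision/recall at the operating confidence threshold. Classes
#' absent from the ground truth are excluded from the class mean (with a
#' warning).
#'
#' @param model a trainable `model_graph`.
#' @param images list of `annotated_image`.
#' @param conf_threshold operating confidence for precision/recall.
#' @param nms_iou NMS IoU threshold.
#' @param ap_method AP integration method, see [average_precision()].
#' @param batch_size forward-pass batch size.
#' @return an `eval_result` list: `per_class_ap50`, `map50`, `map5095`,
#'   `precision`, `recall`, `counts`, `params`, `flops`.
#' @export
evaluate_detector <- function(model, images, conf_threshold = 0.25,
                              nms_iou = 0.45, ap_method = "all_points",
                              batch_size = 16) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$pixels)
  dets <- list()
  gts <- list()
  for (start in seq(1, length(images), by = batch_size)) {
    sel <- start:min(start + batch_size - 1, length(images))
    xb <- images_to_batch(images[sel])
    outs <- forward(model, xb)
    ids <- vapply(images[sel], `[[`, "", "id")
    dets[[length(dets) + 1]] <-
      decode_detections(outs, model, d[1:2], image_ids = ids)
  }
  dets <- nms_detections(do.call(rbind, dets), nms_iou)
  for (im in images) {
    b <- im$boxes
    if (nrow(b))
      gts[[length(gts) + 1]] <- data.frame(
        image_id = im$id, class_id = b$class_id,
        x1 = b$cx - b$w / 2, y1 = b$cy - b$h / 2,
        x2 = b$cx + b$w / 2, y2 = b$cy + b$h / 2)
  }
  gts <- if (length(gts)) do.call(rbind, gts) else
    data.frame(image_id = character(), class_id = integer(), x1 = numeric(),
               y1 = numeric(), x2 = numeric(), y2 = numeric())
  evaluate_detections(dets, gts, conf_threshold = conf_threshold,
                      ap_method = ap_method, params = count_params(model),
                      flops = count_flops(model, d[1:2]))
}

#' @rdname evaluate_detector
#' @param dets,gts detection / ground-truth data.frames (normalized xyxy).
#' @param params,flops optional accounting numbers carried into the result.
#' @export
evaluate_detections <- function(dets, gts, conf_threshold = 0.25,
                                ap_method = "all_points", params = NA,
                                flops = NA) {
  gt_classes <- sort(unique(gts$class_id))
  absent <- setdiff(unique(dets$class_id), gt_classes)
  if (length(absent))
    warning("classes absent from ground truth excluded from mAP: ",
            paste(absent, collapse = ", "))
  ap_at <- function(thr) {
    m <- match_detections(dets, gts, thr)
    vapply(as.character(gt_classes), function(cl) {
      pc <- m$per_class[[cl]]
      if (is.null(pc)) return(0)
      average_precision(pc$tp, pc$n_gt, ap_method)
    }, 0)
  }
  ap50 <- ap_at(0.5)
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap_all <- vapply(thrs, ap_at, numeric(length(gt_classes)))
  if (is.null(dim(ap_all))) ap_all <- matrix(ap_all, nrow = 1)
  m50 <- match_detections(dets, gts, 0.5)
  cnt <- match_counts(m50, conf_threshold)
  structure(list(
    per_class_ap50 = ap50,
    per_class_ap5095 = rowMeans(ap_all),
    map50 = if (length(ap50)) mean(ap50) else 0,
    map5095 = if (length(ap50)) mean(rowMeans(ap_all)) else 0,
    precision = unname(cnt$precision), recall = unname(cnt$recall),
    counts = cnt[c("TP", "FP", "FN")],
    conf_threshold = conf_threshold, params = params, flops = flops),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> mAP@0.5 %.3f | mAP@0.5:0.95 %.3f | P %.3f | R %.3f\n",
    x$map50, x$map5095, x$precision, x$recall))
  invisible(x)
}

#' Write an eval result as JSON
#' @param result an `eval_result`.
#' @param path output file.
#' @export
write_eval_json <- function(result, path) {
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
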