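# Anchor-free detection loss and box decoding for MiniDet-style heads.
#
# Assignment rule: each ground-truth object is assigned to the scale whose
# stride best matches its size (argmin |log2(size / (4 * stride))|, ties to
# the lower stride) and to the cell containing its center; a cell holds at
# most one object (first listed wins). Box regression predicts
# left/top/right/bottom distances from the cell center, d = softplus(t) *
# stride, so initial boxes always overlap the cell they sit on.

assign_targets <- function(boxes, strides, input_hw, grid_hw) {
  if (is.null(boxes) || nrow(boxes) == 0) return(NULL)
  H <- input_hw[1]; W <- input_hw[2]
  out <- NULL
  taken <- lapply(seq_along(strides), function(i) character())
  for (r in seq_len(nrow(boxes))) {
    bw <- boxes$w[r] * W; bh <- boxes$h[r] * H
    size <- sqrt(bw * bh)
    k <- which.min(abs(log2(size / (4 * strides))))
    st <- strides[k]
    col <- min(grid_hw[[k]][2], max(1L, floor(boxes$cx[r] * W / st) + 1L))
    row <- min(grid_hw[[k]][1], max(1L, floor(boxes$cy[r] * H / st) + 1L))
    key <- paste(row, col)
    if (key %in% taken[[k]]) next
    taken[[k]] <- c(taken[[k]], key)
    out <- rbind(out, data.frame(scale = k, row = row, col = col,
                                 class_id = boxes$class_id[r],
                                 cx = boxes$cx[r], cy = boxes$cy[r],
                                 w = boxes$w[r], h = boxes$h[r]))
  }
  out
}

# IoU of an axis-aligned pred box (given as l/t/r/b distances from a center)
# with a ground-truth box, plus the gradient w.r.t. the four distances.
iou_ltrb <- function(xc, yc, d, gt) {
  x1 <- xc - d[1]; y1 <- yc - d[2]; x2 <- xc + d[3]; y2 <- yc + d[4]
  iw <- min(x2, gt[3]) - max(x1, gt[1])
  ih <- min(y2, gt[4]) - max(y1, gt[2])
  ap <- (x2 - x1) * (y2 - y1)
  ag <- (gt[3] - gt[1]) * (gt[4] - gt[2])
  if (iw <= 0 || ih <= 0) {
    return(list(iou = 0, grad = numeric(4)))
  }
  I <- iw * ih
  U <- ap + ag - I
  # d/d{x1,y1,x2,y2}
  dI <- c(if (x1 > gt[1]) -ih else 0, if (y1 > gt[2]) -iw else 0,
          if (x2 < gt[3]) ih else 0, if (y2 < gt[4]) iw else 0)
  dAp <- c(-(y2 - y1), -(x2 - x1), (y2 - y1), (x2 - x1))
  diou_dq <- (dI * U - I * (dAp - dI)) / U^2
  # q = (x1,y1,x2,y2); dq/dd = (-1,-1,+1,+1)
  list(iou = I / U, grad = diou_dq * c(-1, -1, 1, 1))
}

#' Detection loss for MiniDet outputs
#'
#' Computes the three task-loss components: `lbbox` is mean (1 - IoU) over
#' assigned positive cells, `lconf` is binary cross-entropy of the
#' objectness/confidence map over all cells at all scales, and `lcls` is
#' binary cross-entropy over class logits at positive cells. Optionally
#' returns the analytic gradients w.r.t. the raw head output tensors.
#'
#' @param outputs named list of head tensors as returned by [forward()].
#' @param targets list (length batch) of ground-truth box data frames with
#'   columns `class_id, cx, cy, w, h` (YOLO-normalized).
#' @param model the `model_graph` that produced `outputs`.
#' @param input_hw input height/width in pixels.
#' @param with_grads logical; also return gradient arrays.
#' @return list with `lbbox`, `lconf`, `lcls`, `n_pos`, and (optionally)
#'   `grads`, a named list of arrays aligned with `outputs`.
#' @export
detection_loss <- function(outputs, targets, model, input_hw,
                           with_grads = TRUE) {
  strides <- model$strides
  scales <- names(model$head_outputs)
  nc <- model$n_classes
  H <- input_hw[1]; W <- input_hw[2]
  grid_hw <- lapply(seq_along(scales), function(k) {
    dim(outputs[[model$head_outputs[[k]]$obj]])[1:2]
  })
  N <- dim(outputs[[model$head_outputs[[1]]$obj]])[4]

  grads <- list()
  obj_t <- list()
  for (k in seq_along(scales)) {
    ho <- model$head_outputs[[k]]
    obj_t[[k]] <- array(0, dim(outputs[[ho$obj]]))
    if (with_grads) {
      grads[[ho$cls]] <- array(0, dim(outputs[[ho$cls]]))
      grads[[ho$box]] <- array(0, dim(outputs[[ho$box]]))
    }
  }

  pos <- list()
  for (n in seq_len(N)) {
    a <- assign_targets(targets[[n]], strides, input_hw, grid_hw)
    if (!is.null(a)) { a$img <- n; pos[[length(pos) + 1]] <- a }
  }
  pos <- if (length(pos)) do.call(rbind, pos) else NULL
  n_pos <- if (is.null(pos)) 0L else nrow(pos)

  lbbox <- 0; lcls <- 0
  if (n_pos > 0) {
    for (r in seq_len(n_pos)) {
      k <- pos$scale[r]; st <- strides[k]
      ho <- model$head_outputs[[k]]
      row <- pos$row[r]; col <- pos$col[r]; n <- pos$img[r]
      tvec <- outputs[[ho$box]][row, col, , n]
      sp <- sigmoid(tvec)
      d <- softplus(tvec) * st
      xc <- (col - 0.5) * st; yc <- (row - 0.5) * st
      gt <- c((pos$cx[r] - pos$w[r] / 2) * W, (pos$cy[r] - pos$h[r] / 2) * H,
              (pos$cx[r] + pos$w[r] / 2) * W, (pos$cy[r] + pos$h[r] / 2) * H)
      io <- iou_ltrb(xc, yc, d, gt)
      lbbox <- lbbox + (1 - io$iou)
      z <- outputs[[ho$cls]][row, col, , n]
      tcls <- numeric(nc); tcls[pos$class_id[r] + 1] <- 1
      lcls <- lcls + sum(bce_with_logits(z, tcls))
      obj_t[[k]][row, col, 1, n] <- 1
      if (with_grads) {
        grads[[ho$box]][row, col, , n] <- grads[[ho$box]][row, col, , n] -
          io$grad * sp * st / n_pos
        grads[[ho$cls]][row, col, , n] <- grads[[ho$cls]][row, col, , n] +
          (sigmoid(z) - tcls) / (n_pos * nc)
      }
    }
    lbbox <- lbbox / n_pos
    lcls <- lcls / (n_pos * nc)
  }

  n_cells <- sum(vapply(seq_along(scales), function(k)
    prod(dim(obj_t[[k]])), 0))
  lconf <- 0
  for (k in seq_along(scales)) {
    ho <- model$head_outputs[[k]]
    z <- outputs[[ho$obj]]
    lconf <- lconf + sum(bce_with_logits(z, obj_t[[k]]))
    if (with_grads)
      grads[[ho$obj]] <- (sigmoid(z) - obj_t[[k]]) / n_cells
  }
  lconf <- lconf / n_cells

  out <- list(lbbox = lbbox, lconf = lconf, lcls = lcls, n_pos = n_pos)
  if (with_grads) out$grads <- grads
  out
}

#' Decode raw head outputs into detections
#'
#' Converts per-cell predictions into normalized xyxy boxes with confidences
#' `sigmoid(obj) * max_c sigmoid(cls_c)`, keeping cells above a confidence
#' floor. Follow with [nms_detections()] before evaluation.
#'
#' @param outputs named list from [forward()].
#' @param model the producing `model_graph`.
#' @param input_hw input height/width in pixels.
#' @param conf_threshold confidence floor (low by default so the full
#'   precision-recall curve is available to AP).
#' @param image_ids optional ids for the batch dimension.
#' @return data.frame `image_id, class_id, x1, y1, x2, y2, conf`.
#' @export
decode_detections <- function(outputs, model, input_hw,
                              conf_threshold = 0.001, image_ids = NULL) {
  strides <- model$strides
  H <- input_hw[1]; W <- input_hw[2]
  res <- list()
  N <- dim(outputs[[model$head_outputs[[1]]$obj]])[4]
  ids <- image_ids %||% as.character(seq_len(N))
  for (k in seq_along(model$head_outputs)) {
    ho <- model$head_outputs[[k]]
    st <- strides[k]
    dcls <- dim(outputs[[ho$cls]])
    hs <- dcls[1]; ws <- dcls[2]; nc <- dcls[3]
    cells <- hs * ws
    rowv <- rep(seq_len(hs), times = ws)
    colv <- rep(seq_len(ws), each = hs)
    xc <- (colv - 0.5) * st; yc <- (rowv - 0.5) * st
    for (n in seq_len(N)) {
      cm <- sigmoid(matrix(outputs[[ho$cls]][, , , n], cells, nc))
      best <- max.col(cm, ties.method = "first")
      bp <- cm[cbind(seq_len(cells), best)]
      conf <- sigmoid(as.vector(outputs[[ho$obj]][, , 1, n])) * bp
      keep <- which(conf >= conf_threshold)
      if (!length(keep)) next
      bm <- matrix(outputs[[ho$box]][, , , n], cells, 4)
      d <- softplus(bm[keep, , drop = FALSE]) * st
      res[[length(res) + 1]] <- data.frame(
        image_id = ids[n], class_id = best[keep] - 1L,
        x1 = pmax(0, (xc[keep] - d[, 1]) / W),
        y1 = pmax(0, (yc[keep] - d[, 2]) / H),
        x2 = pmin(1, (xc[keep] + d[, 3]) / W),
        y2 = pmin(1, (yc[keep] + d[, 4]) / H),
        conf = conf[keep])
    }
  }
  if (!length(res))
    return(data.frame(image_id = character(), class_id = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), conf = numeric()))
  do.call(rbind, res)
}
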