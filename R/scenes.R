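# Synthetic pest-scene generator: multi-class shapes of distinct color and
# scale on a textured green background, YOLO-normalized boxes, the standard
# photometric/geometric augmentations, and stratified 7:2:1 splitting.

#' Scene specification
#'
#' Describes the synthetic benchmark: image size, class appearances (shape
#' family, base color, scale range), object count range, background texture
#' and a seed. The five default classes mimic field-pest variety: distinct
#' shape families (ellipse, capsule, cluster-of-dots) and pairwise-distinct
#' colors so the classes are learnable.
#'
#' @param image_size integer edge length in pixels (square images).
#' @param n_classes number of classes; must match `class_appearance`.
#' @param objects_per_image integer length-2 inclusive range.
#' @param class_appearance list per class: `shape` one of `"ellipse"`,
#'   `"capsule"`, `"dots"`; `color` RGB in \[0,1\]; `scale` length-2 range as
#'   a fraction of image width, strictly inside (0, 1).
#' @param class_mix class sampling probabilities (default uniform).
#' @param min_color_dist minimum pairwise euclidean RGB distance.
#' @param seed default seed used by [generate_scene()].
#' @return a `scene_spec`.
#' @export
scene_spec <- function(image_size = 224L, n_classes = 5L,
                       objects_per_image = c(1L, 4L),
                       class_appearance = NULL,
                       class_mix = NULL, min_color_dist = 0.25,
                       seed = 0L) {
  class_appearance <- class_appearance %||% default_appearance(n_classes)
  if (length(class_appearance) != n_classes)
    stop("class_appearance must have one entry per class")
  for (a in class_appearance) {
    if (a$scale[1] <= 0 || a$scale[2] >= 1 || a$scale[1] > a$scale[2])
      stop("scale ranges must be strictly inside (0, 1)")
    if (!a$shape %in% c("ellipse", "capsule", "dots"))
      stop("unknown shape family: ", a$shape)
  }
  cols <- do.call(rbind, lapply(class_appearance, `[[`, "color"))
  if (n_classes > 1) {
    dmin <- min(stats::dist(cols))
    if (dmin < min_color_dist)
      stop(sprintf("class colors too close (min RGB distance %.3f < %.3f)",
                   dmin, min_color_dist))
  }
  mix <- class_mix %||% rep(1 / n_classes, n_classes)
  stopifnot(length(mix) == n_classes, all(mix >= 0))
  structure(list(image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 objects_per_image = as.integer(objects_per_image),
                 class_appearance = class_appearance,
                 class_mix = mix / sum(mix), seed = as.integer(seed)),
            class = "scene_spec")
}

default_appearance <- function(n_classes) {
  base <- list(
    list(shape = "ellipse", color = c(0.35, 0.20, 0.10), scale = c(0.10, 0.25)),
    list(shape = "capsule", color = c(0.90, 0.85, 0.20), scale = c(0.12, 0.30)),
    list(shape = "ellipse", color = c(0.85, 0.25, 0.15), scale = c(0.10, 0.25)),
    list(shape = "dots",    color = c(0.08, 0.08, 0.25), scale = c(0.12, 0.28)),
    list(shape = "capsule", color = c(0.25, 0.40, 0.85), scale = c(0.10, 0.25)))
  if (n_classes > length(base))
    stop("default appearances cover up to ", length(base), " classes")
  base[seq_len(n_classes)]
}

empty_boxes <- function() {
  data.frame(class_id = integer(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric())
}

validate_boxes <- function(boxes) {
  if (nrow(boxes) == 0) return(invisible(TRUE))
  ok <- boxes$w > 0 & boxes$h > 0 &
    boxes$cx - boxes$w / 2 >= -1e-9 & boxes$cx + boxes$w / 2 <= 1 + 1e-9 &
    boxes$cy - boxes$h / 2 >= -1e-9 & boxes$cy + boxes$h / 2 <= 1 + 1e-9
  if (!all(ok)) stop("invalid ground-truth box (outside [0,1] or nonpositive)")
  invisible(TRUE)
}

annotated_image <- function(pixels, boxes, id) {
  validate_boxes(boxes)
  structure(list(pixels = pixels, boxes = boxes, id = id),
            class = "annotated_image")
}

# Smooth green background: vertical gradient plus low-frequency random
# mottling (a sum of random sinusoids), so thresholding alone cannot find
# the objects.
paint_background <- function(size) {
  gx <- matrix(rep(seq(0, 1, length.out = size), size), size, size)
  gy <- t(gx)
  g <- 0.30 + 0.12 * gy
  for (i in 1:4) {
    fx <- runif(1, 1, 4); fy <- runif(1, 1, 4); ph <- runif(2, 0, 2 * pi)
    g <- g + 0.035 * sin(2 * pi * fx * gx + ph[1]) *
      sin(2 * pi * fy * gy + ph[2])
  }
  px <- array(0, c(size, size, 3))
  px[, , 1] <- pmin(pmax(g * 0.55, 0), 1)
  px[, , 2] <- pmin(pmax(g + 0.08, 0), 1)
  px[, , 3] <- pmin(pmax(g * 0.35, 0), 1)
  px
}

# Paint one object; returns its mask and analytic axis-aligned extent
# (px, half-open pixel convention) or NULL if it cannot be placed.
paint_object <- function(px, app, size) {
  half_max <- app$scale[2] * size / 2
  if (2 * half_max >= size - 4)
    stop("object scale range incompatible with image size ", size)
  s <- runif(1, app$scale[1], app$scale[2]) * size / 2  # half-size in px
  theta <- runif(1, 0, pi)
  shape <- app$shape
  if (shape == "ellipse") {
    a <- s; b <- s * runif(1, 0.55, 0.9)
    hw <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    hh <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  } else if (shape == "capsule") {
    r <- s * runif(1, 0.25, 0.4)
    L <- s - r
    hw <- abs(L * cos(theta)) + r
    hh <- abs(L * sin(theta)) + r
  } else {
    k <- sample(4:7, 1)
    rd <- s * runif(1, 0.18, 0.28)
    ang <- runif(k, 0, 2 * pi)
    rad <- runif(k, 0, s - rd)
    dx <- rad * cos(ang); dy <- rad * sin(ang)
    hw <- max(abs(dx)) + rd; hh <- max(abs(dy)) + rd
  }
  cx <- runif(1, hw + 1, size - hw - 1)
  cy <- runif(1, hh + 1, size - hh - 1)
  xs <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)  # col coord
  ys <- matrix(rep(seq_len(size) - 0.5, times = size), size, size) # row coord
  rx <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  ry <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  mask <- switch(shape,
    ellipse = (rx / a)^2 + (ry / b)^2 <= 1,
    capsule = {
      t <- pmin(pmax(rx, -L), L)
      (rx - t)^2 + ry^2 <= r^2
    },
    dots = {
      m <- matrix(FALSE, size, size)
      for (i in seq_len(k))
        m <- m | ((xs - cx - dx[i])^2 + (ys - cy - dy[i])^2 <= rd^2)
      m
    })
  jit <- runif(3, -0.06, 0.06)
  shade <- 1 - 0.25 * sqrt(pmin((rx^2 + ry^2) / (s^2 + 1e-9), 1))
  for (ch in 1:3) {
    layer <- px[, , ch]
    col <- pmin(pmax(app$color[ch] + jit[ch], 0), 1)
    layer[mask] <- pmin(pmax(col * shade[mask], 0), 1)
    px[, , ch] <- layer
  }
  list(px = px, mask = mask,
       extent = c(x1 = cx - hw, y1 = cy - hh, x2 = cx + hw, y2 = cy + hh))
}

#' Generate one synthetic annotated scene
#'
#' Paints the requested number of objects (classes drawn from the
#' scene spec's mixture) on a textured
#' background; every painted object keeps at least 40% of its area visible
#' (placement is re-sampled, and the object skipped after 25 tries), and the
#' returned boxes are the analytic axis-aligned extents of the painted
#' shapes (normalized YOLO center format). Identical (spec, seed) pairs give
#' byte-identical output.
#'
#' @param spec a [scene_spec()].
#' @param seed integer; defaults to `spec$seed`.
#' @param id image id string.
#' @return an `annotated_image`.
#' @export
generate_scene <- function(spec, seed = spec$seed, id = paste0("img", seed)) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(seed, {
    size <- spec$image_size
    px <- paint_background(size)
    n_obj <- if (spec$objects_per_image[1] == spec$objects_per_image[2])
      spec$objects_per_image[1] else
      sample(spec$objects_per_image[1]:spec$objects_per_image[2], 1)
    boxes <- empty_boxes()
    vis_masks <- list()
    orig_area <- numeric()
    if (n_obj > 0) {
      for (i in seq_len(n_obj)) {
        cl <- sample.int(spec$n_classes, 1, prob = spec$class_mix)
        placed <- NULL
        for (try in 1:25) {
          cand <- paint_object(px, spec$class_appearance[[cl]], size)
          ok <- TRUE
          for (j in seq_along(vis_masks)) {
            if (sum(vis_masks[[j]] & !cand$mask) < 0.4 * orig_area[j]) {
              ok <- FALSE; break
            }
          }
          if (ok) { placed <- cand; break }
        }
        if (is.null(placed)) next
        px <- placed$px
        for (j in seq_along(vis_masks))
          vis_masks[[j]] <- vis_masks[[j]] & !placed$mask
        vis_masks[[length(vis_masks) + 1]] <- placed$mask
        orig_area <- c(orig_area, sum(placed$mask))
        e <- placed$extent
        boxes <- rbind(boxes, data.frame(
          class_id = cl - 1L,
          cx = (e[["x1"]] + e[["x2"]]) / 2 / size,
          cy = (e[["y1"]] + e[["y2"]]) / 2 / size,
          w = (e[["x2"]] - e[["x1"]]) / size,
          h = (e[["y2"]] - e[["y1"]]) / size))
      }
    }
    annotated_image(px, boxes, id)
  })
}

#' Generate a list of scenes
#' @param spec a [scene_spec()].
#' @param n number of images.
#' @param seed base seed; image i uses `seed + i`.
#' @param prefix id prefix.
#' @return list of `annotated_image`.
#' @export
generate_scenes <- function(spec, n, seed = spec$seed, prefix = "img") {
  lapply(seq_len(n), function(i)
    generate_scene(spec, seed = seed + i, id = sprintf("%s%05d", prefix, i)))
}

# --- augmentations ----------------------------------------------------------

#' Photometric augmentation: additive Gaussian noise
#'
#' Adds i.i.d. N(0, sigma^2) noise per pixel/channel, clips to \[0,1\];
#' boxes are untouched.
#' @param img an `annotated_image`.
#' @param sigma noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return augmented `annotated_image`.
#' @export
add_gaussian_noise <- function(img, sigma, seed = 0L) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(img)
  with_seed(seed, {
    px <- img$pixels + array(rnorm(length(img$pixels), sd = sigma),
                             dim(img$pixels))
    annotated_image(pmin(pmax(px, 0), 1), img$boxes, img$id)
  })
}

#' Photometric augmentation: brightness scaling
#' @param img an `annotated_image`.
#' @param factor multiplier, within `range`.
#' @param range allowed factor range (default 0.7-1.3, i.e. +/-30%).
#' @return augmented `annotated_image`.
#' @export
brightness_adjust <- function(img, factor, range = c(0.7, 1.3)) {
  if (factor < range[1] || factor > range[2])
    stop("brightness factor ", factor, " outside [", range[1], ", ",
         range[2], "]")
  annotated_image(pmin(pmax(img$pixels * factor, 0), 1), img$boxes, img$id)
}

#' Geometric augmentation: rotation, scaling and translation
#'
#' Applies the affine map (rotation about the image center, then scaling,
#' then translation by a fraction of the image size) with bilinear sampling;
#' pixels mapped from outside the source are filled with the mean border
#' color. Each box becomes the axis-aligned hull of its 4 transformed
#' corners, clipped to the image; boxes whose clipped area falls below
#' `min_visible` of the transformed area are dropped.
#'
#' @param img an `annotated_image`.
#' @param rotation_deg rotation in degrees, within `rot_range`.
#' @param translate_frac length-2 translation as a fraction of size.
#' @param scale isotropic scale factor.
#' @param rot_range,trans_range,scale_range allowed parameter ranges
#'   (defaults: +/-30 degrees, +/-20%, 0.8-1.2).
#' @param min_visible minimum clipped/transformed area ratio to keep a box.
#' @param fill optional RGB fill color.
#' @return augmented `annotated_image`.
#' @export
geometric_augment <- function(img, rotation_deg = 0, translate_frac = c(0, 0),
                              scale = 1,
                              rot_range = c(-30, 30),
                              trans_range = c(-0.2, 0.2),
                              scale_range = c(0.8, 1.2),
                              min_visible = 0.2, fill = NULL) {
  if (rotation_deg < rot_range[1] || rotation_deg > rot_range[2])
    stop("rotation ", rotation_deg, " outside allowed range")
  if (any(translate_frac < trans_range[1]) || any(translate_frac > trans_range[2]))
    stop("translation outside allowed range")
  if (scale < scale_range[1] || scale > scale_range[2])
    stop("scale ", scale, " outside allowed range")
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  cx <- W / 2; cy <- H / 2
  th <- rotation_deg * pi / 180
  tx <- translate_frac[1] * W; ty <- translate_frac[2] * H
  if (is.null(fill)) {
    border <- rbind(img$pixels[1, , ], img$pixels[H, , ],
                    img$pixels[, 1, ], img$pixels[, W, ])
    fill <- colMeans(border)
  }
  # inverse map output (x', y') -> source (x, y)
  xo <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  yo <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  ux <- (xo - cx - tx) / scale
  uy <- (yo - cy - ty) / scale
  xs <- cos(th) * ux + sin(th) * uy + cx
  ys <- -sin(th) * ux + cos(th) * uy + cy
  out <- array(0, d)
  x0 <- floor(xs - 0.5); y0 <- floor(ys - 0.5)
  fx <- xs - 0.5 - x0; fy <- ys - 0.5 - y0
  inb <- function(xx, yy) xx >= 0 & xx <= W - 1 & yy >= 0 & yy <= H - 1
  idx <- function(xx, yy) {
    xx <- pmin(pmax(xx, 0), W - 1); yy <- pmin(pmax(yy, 0), H - 1)
    yy + 1 + H * xx
  }
  any_in <- inb(x0, y0) | inb(x0 + 1, y0) | inb(x0, y0 + 1) | inb(x0 + 1, y0 + 1)
  for (ch in 1:3) {
    layer <- img$pixels[, , ch]
    v00 <- layer[idx(x0, y0)]; v10 <- layer[idx(x0 + 1, y0)]
    v01 <- layer[idx(x0, y0 + 1)]; v11 <- layer[idx(x0 + 1, y0 + 1)]
    v00[!inb(x0, y0)] <- fill[ch]; v10[!inb(x0 + 1, y0)] <- fill[ch]
    v01[!inb(x0, y0 + 1)] <- fill[ch]; v11[!inb(x0 + 1, y0 + 1)] <- fill[ch]
    val <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
      (1 - fx) * fy * v01 + fx * fy * v11
    val[!any_in] <- fill[ch]
    out[, , ch] <- matrix(val, H, W)
  }
  # forward-map the box corners
  fwd <- function(x, y) {
    rx <- cos(th) * (x - cx) - sin(th) * (y - cy)
    ry <- sin(th) * (x - cx) + cos(th) * (y - cy)
    cbind(scale * rx + cx + tx, scale * ry + cy + ty)
  }
  nb <- empty_boxes()
  b <- img$boxes
  for (r in seq_len(nrow(b))) {
    px1 <- (b$cx[r] - b$w[r] / 2) * W; px2 <- (b$cx[r] + b$w[r] / 2) * W
    py1 <- (b$cy[r] - b$h[r] / 2) * H; py2 <- (b$cy[r] + b$h[r] / 2) * H
    corners <- fwd(c(px1, px2, px1, px2), c(py1, py1, py2, py2))
    x1 <- min(corners[, 1]); x2 <- max(corners[, 1])
    y1 <- min(corners[, 2]); y2 <- max(corners[, 2])
    area_t <- (x2 - x1) * (y2 - y1)
    cx1 <- max(x1, 0); cx2 <- min(x2, W)
    cy1 <- max(y1, 0); cy2 <- min(y2, H)
    area_c <- max(cx2 - cx1, 0) * max(cy2 - cy1, 0)
    if (area_t <= 0 || area_c < min_visible * area_t) next
    nb <- rbind(nb, data.frame(class_id = b$class_id[r],
                               cx = (cx1 + cx2) / 2 / W,
                               cy = (cy1 + cy2) / 2 / H,
                               w = (cx2 - cx1) / W, h = (cy2 - cy1) / H))
  }
  annotated_image(out, nb, img$id)
}

#' Randomly augment a dataset
#'
#' Expands a list of images by `times` random augmentations each (Gaussian
#' noise sd 0.05, rotation +/-30 degrees, translation +/-20%, scale
#' 0.8-1.2x, brightness +/-30%), keeping the originals.
#'
#' @param images list of `annotated_image`.
#' @param times augmented copies per image.
#' @param seed RNG seed.
#' @return expanded list.
#' @export
augment_dataset <- function(images, times = 1, seed = 0L) {
  out <- images
  with_seed(seed, {
    for (t in seq_len(times)) {
      for (im in images) {
        seeds <- sample.int(1e7, 2)
        a <- add_gaussian_noise(im, runif(1, 0, 0.05), seed = seeds[1])
        a <- geometric_augment(a, runif(1, -30, 30),
                               runif(2, -0.2, 0.2), runif(1, 0.8, 1.2))
        a <- brightness_adjust(a, runif(1, 0.7, 1.3))
        a$id <- sprintf("%s_aug%d", im$id, t)
        out[[length(out) + 1]] <- a
      }
    }
  })
  out
}

#' Stratified 7:2:1 split with deterministic rounding
#'
#' Per class: `n_train = round(r_train * n)`, `n_val = round(r_val * n)`
#' (half rounds up), and the test set takes the remainder — the unique
#' simple rounding rule consistent with the reference per-class split
#' counts. Item assignment within a class is a seeded permutation.
#'
#' @param per_class_totals positive integer vector of class totals.
#' @param ratios train/val/test fractions summing to 1.
#' @param seed permutation seed.
#' @return a `split_counts` list: `per_class` data.frame (`n_total, n_train,
#'   n_val, n_test`) and `assignment`, a per-class factor of
#'   train/val/test labels in item order.
#' @export
split_dataset <- function(per_class_totals, ratios = c(0.7, 0.2, 0.1),
                          seed = 0L) {
  stopifnot(all(per_class_totals > 0), abs(sum(ratios) - 1) < 1e-9)
  n_tr <- round_half_up(ratios[1] * per_class_totals)
  n_va <- round_half_up(ratios[2] * per_class_totals)
  n_te <- per_class_totals - n_tr - n_va
  if (any(n_te < 0))
    stop("ratios leave a negative test count after rounding")
  assignment <- with_seed(seed, lapply(seq_along(per_class_totals), function(i) {
    lab <- rep(c("train", "val", "test"), c(n_tr[i], n_va[i], n_te[i]))
    factor(lab[sample.int(per_class_totals[i])],
           levels = c("train", "val", "test"))
  }))
  structure(list(
    per_class = data.frame(n_total = per_class_totals, n_train = n_tr,
                           n_val = n_va, n_test = n_te),
    assignment = assignment), class = "split_counts")
}
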