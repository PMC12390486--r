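# Synthetic scene generation, augmentation and splitting.

test_that("scene generation honors object counts, box invariants and determinism", {
  spec <- scene_spec(image_size = 96L, seed = 3L)

  none <- generate_scene(scene_spec(image_size = 96L,
                                    objects_per_image = c(0L, 0L), seed = 1L))
  expect_equal(nrow(none$boxes), 0)

  img <- generate_scene(spec, seed = 11)
  b <- img$boxes
  expect_true(all(b$w > 0 & b$h > 0))
  expect_true(all(b$cx - b$w / 2 >= -1e-9 & b$cx + b$w / 2 <= 1 + 1e-9))
  expect_true(all(b$cy - b$h / 2 >= -1e-9 & b$cy + b$h / 2 <= 1 + 1e-9))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))

  expect_identical(generate_scene(spec, seed = 11), img)
})

test_that("painted extents match the analytic ellipse bounds within 2 px", {
  app <- list(shape = "ellipse", color = c(0.8, 0.2, 0.2),
              scale = c(0.2, 0.35))
  for (seed in 1:5) {
    obj <- pk$with_seed(seed, {
      px <- array(0.5, c(96, 96, 3))
      pk$paint_object(px, app, 96L)
    })
    painted <- which(obj$mask, arr.ind = TRUE)
    # arr.ind: row (y), col (x); centers at -0.5 offsets
    expect_lte(obj$extent[["x1"]], min(painted[, 2]) - 0.5 + 2)
    expect_gte(obj$extent[["x2"]], max(painted[, 2]) - 0.5 - 2)
    expect_lte(obj$extent[["y1"]], min(painted[, 1]) - 0.5 + 2)
    expect_gte(obj$extent[["y2"]], max(painted[, 1]) - 0.5 - 2)
    # and the extent is tight: no slack beyond 2 px on any side
    expect_lte(min(painted[, 2]) - 0.5 - obj$extent[["x1"]], 2)
    expect_lte(obj$extent[["x2"]] - (max(painted[, 2]) - 0.5), 2)
  }
})

test_that("scale ranges incompatible with the image size are rejected", {
  app <- list(list(shape = "ellipse", color = c(0.8, 0.2, 0.2),
                   scale = c(0.95, 0.99)))
  spec <- scene_spec(image_size = 32L, n_classes = 1L,
                     class_appearance = app, objects_per_image = c(1L, 1L))
  expect_error(generate_scene(spec, seed = 1), "incompatible")
})

test_that("class colors must be pairwise distinct", {
  app <- list(
    list(shape = "ellipse", color = c(0.5, 0.5, 0.5), scale = c(0.1, 0.2)),
    list(shape = "capsule", color = c(0.52, 0.5, 0.5), scale = c(0.1, 0.2)))
  expect_error(scene_spec(n_classes = 2L, class_appearance = app),
               "colors too close")
})

test_that("gaussian noise perturbs pixels at the requested sigma and spares labels", {
  base <- pk$annotated_image(array(0.5, c(64, 64, 3)),
                             data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                                        w = 0.2, h = 0.2), "flat")
  expect_identical(add_gaussian_noise(base, 0, seed = 1), base)
  noisy <- add_gaussian_noise(base, 0.1, seed = 2)
  resid <- noisy$pixels - base$pixels
  interior <- abs(base$pixels + resid - 0.5) < 0.49  # unclipped pixels
  expect_lt(abs(sd(resid[interior]) - 0.1) / 0.1, 0.05)
  expect_identical(noisy$boxes, base$boxes)
  expect_error(add_gaussian_noise(base, -0.1), "nonnegative")
})

test_that("brightness adjustment multiplies, clips and spares labels", {
  img <- generate_scene(scene_spec(image_size = 64L, seed = 1L))
  expect_equal(brightness_adjust(img, 1.0)$pixels, img$pixels)
  hi <- pk$annotated_image(array(0.9, c(8, 8, 3)), pk$empty_boxes(), "h")
  expect_equal(brightness_adjust(hi, 1.3)$pixels, array(1, c(8, 8, 3)))
  lo <- pk$annotated_image(array(0.5, c(8, 8, 3)), pk$empty_boxes(), "l")
  expect_equal(brightness_adjust(lo, 0.7)$pixels, array(0.35, c(8, 8, 3)))
  expect_identical(brightness_adjust(img, 1.2)$boxes, img$boxes)
  expect_error(brightness_adjust(img, 1.5), "outside")
})

test_that("geometric augmentation: identity, rotation arithmetic, clipping and drops", {
  img <- generate_scene(scene_spec(image_size = 64L, seed = 2L), seed = 21)
  id <- geometric_augment(img, 0, c(0, 0), 1)
  expect_equal(id$pixels, img$pixels, tolerance = 1e-12)
  expect_equal(id$boxes, img$boxes)

  # centered square of side s rotated 30 degrees -> side s (cos30 + sin30)
  sq <- pk$annotated_image(array(0.5, c(64, 64, 3)),
                           data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                                      w = 0.25, h = 0.25), "sq")
  rot <- geometric_augment(sq, 30, c(0, 0), 1)
  f <- cos(pi / 6) + sin(pi / 6)
  expect_equal(rot$boxes$w, 0.25 * f, tolerance = 1e-9)
  expect_equal(rot$boxes$h, 0.25 * f, tolerance = 1e-9)
  expect_equal(rot$boxes$cx, 0.5, tolerance = 1e-9)
  expect_equal(rot$boxes$cy, 0.5, tolerance = 1e-9)

  # translation pushes a box over the right edge: clipped area keeps it
  near <- pk$annotated_image(array(0.5, c(64, 64, 3)),
                             data.frame(class_id = 0L, cx = 0.9, cy = 0.5,
                                        w = 0.16, h = 0.16), "n")
  tr <- geometric_augment(near, 0, c(0.2, 0), 1)
  # transformed box: cx 1.1, spans [1.02, 1.18] -> fully outside, dropped
  expect_equal(nrow(tr$boxes), 0)
  near2 <- pk$annotated_image(array(0.5, c(64, 64, 3)),
                              data.frame(class_id = 0L, cx = 0.85, cy = 0.5,
                                         w = 0.3, h = 0.3), "n2")
  tr2 <- geometric_augment(near2, 0, c(0.2, 0), 1)
  # spans [0.9, 1.2] -> visible fraction 1/3 >= 20%, kept and clipped at 1
  expect_equal(nrow(tr2$boxes), 1)
  expect_equal(tr2$boxes$cx + tr2$boxes$w / 2, 1, tolerance = 1e-9)
  expect_equal(tr2$boxes$w, 0.1, tolerance = 1e-9)

  expect_error(geometric_augment(img, 45), "outside")
  expect_error(geometric_augment(img, 0, c(0.5, 0)), "outside")
  expect_error(geometric_augment(img, 0, c(0, 0), 2), "outside")
})

test_that("surviving boxes contain the transformed painted object", {
  spec <- scene_spec(image_size = 96L, objects_per_image = c(1L, 1L),
                     seed = 0L)
  bg_spec <- scene_spec(image_size = 96L, objects_per_image = c(0L, 0L))
  for (seed in 31:35) {
    bg <- generate_scene(bg_spec, seed = seed)  # same background, no objects
    img <- generate_scene(spec, seed = seed)
    mask <- apply(abs(img$pixels - bg$pixels) > 1e-6, c(1, 2), any)
    if (!any(mask) || nrow(img$boxes) == 0) next
    rot <- 15; sc <- 1.1; tf <- c(0.05, -0.05)
    aug <- geometric_augment(img, rot, tf, sc)
    if (nrow(aug$boxes) == 0) next
    px <- which(mask, arr.ind = TRUE)
    x <- px[, 2] - 0.5; y <- px[, 1] - 0.5
    th <- rot * pi / 180
    rx <- cos(th) * (x - 48) - sin(th) * (y - 48)
    ry <- sin(th) * (x - 48) + cos(th) * (y - 48)
    tx <- (sc * rx + 48 + tf[1] * 96) / 96
    ty <- (sc * ry + 48 + tf[2] * 96) / 96
    b <- aug$boxes[1, ]
    vis <- tx >= 0 & tx <= 1 & ty >= 0 & ty <= 1  # pixels still in frame
    inside <- tx >= b$cx - b$w / 2 - 1e-9 & tx <= b$cx + b$w / 2 + 1e-9 &
      ty >= b$cy - b$h / 2 - 1e-9 & ty <= b$cy + b$h / 2 + 1e-9
    expect_gte(mean(inside[vis]), 0.95)
  }
})

test_that("stratified split reproduces the reference per-class arithmetic", {
  totals <- c(650, 563, 541, 606, 670)
  s <- split_dataset(totals, seed = 1)
  expect_equal(s$per_class$n_train, c(455, 394, 379, 424, 469))
  expect_equal(s$per_class$n_val, c(130, 113, 108, 121, 134))
  expect_equal(s$per_class$n_test, c(65, 56, 54, 61, 67))
  expect_equal(rowSums(s$per_class[, 2:4]), s$per_class$n_total,
               ignore_attr = TRUE)
  expect_equal(sum(s$per_class$n_train), 2121)
  expect_equal(sum(s$per_class$n_val), 606)
  expect_equal(sum(s$per_class$n_test), 303)

  exact <- split_dataset(10)
  expect_equal(unlist(exact$per_class[1, 2:4]), c(n_train = 7, n_val = 2,
                                                  n_test = 1))
  # assignment is a seeded permutation with matching counts
  expect_equal(as.vector(table(s$assignment[[1]])), c(455, 130, 65))
  expect_identical(split_dataset(totals, seed = 4)$assignment,
                   split_dataset(totals, seed = 4)$assignment)
  expect_error(split_dataset(100, ratios = c(0.6, 0.45, -0.05)), "negative")
})

test_that("YOLO dataset io round-trips and rejects malformed labels", {
  dir <- withr::local_tempdir()
  imgs <- tiny_images(6, seed = 40)
  write_yolo_dataset(imgs, dir, class_names = paste0("pest", 1:5))
  back <- read_yolo_dataset(dir, split = "train")
  expect_length(back, 6)
  ids <- vapply(back, `[[`, "", "id")
  for (im in imgs) {
    got <- back[[which(ids == im$id)]]
    expect_equal(got$boxes, im$boxes, tolerance = 1e-4)
    expect_equal(dim(got$pixels), dim(im$pixels))
    expect_lt(max(abs(got$pixels - im$pixels)), 1 / 255)
  }
  man <- read_yolo_manifest(dir)
  expect_equal(man$nc, 5)
  expect_equal(unlist(man$names), paste0("pest", 1:5))

  # empty label file round-trips as an empty box list
  none <- pk$annotated_image(array(0.5, c(32, 32, 3)), pk$empty_boxes(), "e0")
  d2 <- withr::local_tempdir()
  write_yolo_dataset(list(none), d2)
  expect_equal(nrow(read_yolo_dataset(d2)[[1]]$boxes), 0)

  # exact formatting of a label line
  line <- pk$format_label_lines(data.frame(class_id = 1L, cx = 0.5, cy = 0.5,
                                           w = 0.25, h = 0.25))
  expect_identical(line, "1 0.500000 0.500000 0.250000 0.250000")

  lab <- file.path(d2, "labels", "train", "e0.txt")
  writeLines("0 0.5 0.5", lab)
  expect_error(read_yolo_dataset(d2), "e0.txt line 1")
  writeLines("0 1.5 0.5 0.1 0.1", lab)
  expect_error(read_yolo_dataset(d2), "outside \\[0,1\\]")
})

test_that("random-box label round trip is exact at 6 decimals", {
  pk$with_seed(77, {
    boxes <- data.frame(class_id = sample(0:4, 100, replace = TRUE),
                        cx = runif(100, 0.3, 0.7), cy = runif(100, 0.3, 0.7),
                        w = runif(100, 0.05, 0.4), h = runif(100, 0.05, 0.4))
  })
  im <- pk$annotated_image(array(0.5, c(32, 32, 3)), boxes, "many")
  d <- withr::local_tempdir()
  write_yolo_dataset(list(im), d)
  got <- read_yolo_dataset(d)[[1]]$boxes
  expect_equal(got, boxes, tolerance = 1e-4)
})
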