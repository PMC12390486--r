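# YOLO-format dataset input/output: one PNG per image, one text label file
# per image ("class cx cy w h", normalized, 6 decimals), and a YAML manifest
# listing class names and split directories.

format_label_lines <- function(boxes) {
  if (nrow(boxes) == 0) return(character())
  sprintf("%d %.6f %.6f %.6f %.6f", boxes$class_id, boxes$cx, boxes$cy,
          boxes$w, boxes$h)
}

parse_label_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) != 5)
      stop("malformed label line (", length(f), " fields, expected 5) in ",
           path, " line ", i)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("malformed label line (non-numeric field) in ", path, " line ", i)
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop("label values outside [0,1] in ", path, " line ", i)
    data.frame(class_id = as.integer(v[1]), cx = v[2], cy = v[3],
               w = v[4], h = v[5])
  })
  do.call(rbind, rows)
}

#' Write a dataset in the common YOLO layout
#'
#' Creates `images/<split>/<id>.png`, `labels/<split>/<id>.txt` and a
#' `data.yaml` manifest (class names plus split directories). Boxes are
#' written as `class cx cy w h` with 6 decimals, so a read/write round trip
#' is exact at that precision.
#'
#' @param images list of `annotated_image`.
#' @param directory output root.
#' @param split character/factor vector (`"train"`, `"val"`, `"test"`) per
#'   image; default puts everything in `train`.
#' @param class_names character vector of class names.
#' @return the directory, invisibly.
#' @export
write_yolo_dataset <- function(images, directory,
                               split = rep("train", length(images)),
                               class_names = NULL) {
  stopifnot(length(split) == length(images))
  split <- as.character(split)
  splits <- unique(split)
  for (s in splits) {
    dir.create(file.path(directory, "images", s), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(directory, "labels", s), recursive = TRUE,
               showWarnings = FALSE)
  }
  for (i in seq_along(images)) {
    im <- images[[i]]
    png::writePNG(im$pixels,
                  file.path(directory, "images", split[i],
                            paste0(im$id, ".png")))
    writeLines(format_label_lines(im$boxes),
               file.path(directory, "labels", split[i],
                         paste0(im$id, ".txt")))
  }
  if (is.null(class_names)) {
    ncl <- max(c(0L, unlist(lapply(images, function(im) im$boxes$class_id)))) + 1L
    class_names <- paste0("class", seq_len(ncl) - 1L)
  }
  manifest <- list(path = ".",
                   train = "images/train", val = "images/val",
                   test = "images/test",
                   nc = length(class_names), names = as.list(class_names))
  yaml::write_yaml(manifest, file.path(directory, "data.yaml"))
  invisible(directory)
}

#' Read a YOLO-layout dataset
#'
#' @param directory dataset root written by [write_yolo_dataset()] (or any
#'   images/labels YOLO tree).
#' @param split which split subdirectory to read; `NULL` reads all present.
#' @return list of `annotated_image`. Malformed label lines raise an error
#'   naming the file and line.
#' @export
read_yolo_dataset <- function(directory, split = NULL) {
  img_root <- file.path(directory, "images")
  splits <- split %||% list.dirs(img_root, recursive = FALSE,
                                 full.names = FALSE)
  out <- list()
  for (s in splits) {
    files <- sort(list.files(file.path(img_root, s), pattern = "\\.png$",
                             full.names = TRUE))
    for (f in files) {
      id <- sub("\\.png$", "", basename(f))
      px <- png::readPNG(f)
      if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
      lab <- file.path(directory, "labels", s, paste0(id, ".txt"))
      boxes <- if (file.exists(lab)) parse_label_file(lab) else empty_boxes()
      out[[length(out) + 1]] <- annotated_image(px[, , 1:3, drop = FALSE],
                                                boxes, id)
    }
  }
  out
}

#' Read the dataset manifest
#' @param directory dataset root.
#' @return named list (class names, split paths).
#' @export
read_yolo_manifest <- function(directory) {
  yaml::read_yaml(file.path(directory, "data.yaml"))
}
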