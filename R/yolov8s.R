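#' Build the YOLOv8s accounting graph
#'
#' Constructs an untrained, layer-exact description of the publicly
#' documented YOLOv8 architecture at the small ('s') scaling: depth
#' multiplier 0.33, width multiplier 0.50, maximum width 1024, C2f blocks
#' with split/shortcut structure, SPPF, and the decoupled anchor-free head
#' with a 16-bin distribution-focal box branch. The graph supports
#' [count_params()], [count_flops()] and pruning-plan construction; it is not
#' meant to be trained (weights are zero-initialized).
#'
#' @param n_classes number of classes for the detection head (default 80).
#' @return a `model_graph`.
#' @export
build_yolov8s_graph <- function(n_classes = 80L) {
  wmul <- 0.50; dmul <- 0.33; max_w <- 1024L
  wdiv <- function(c) {
    c <- min(c, max_w) * wmul
    max(8L, (as.integer(c + 4L) %/% 8L) * 8L)
  }
  dep <- function(n) max(1L, as.integer(round(n * dmul)))

  b <- gb_new(3L, init = "zero")

  c2f <- function(id, input, c2, n, shortcut) {
    c_ <- as.integer(c2 * 0.5)
    cv1 <- gb_cba(b, paste0(id, ".cv1"), input, 2L * c_, k = 1L)
    y1 <- gb_slice(b, paste0(id, ".y1"), cv1, 1L, c_)
    y2 <- gb_slice(b, paste0(id, ".y2"), cv1, c_ + 1L, 2L * c_)
    parts <- c(y1, y2)
    prev <- y2
    for (i in seq_len(n)) {
      m1 <- gb_cba(b, sprintf("%s.m%d.cv1", id, i), prev, c_)
      m2 <- gb_cba(b, sprintf("%s.m%d.cv2", id, i), m1, c_)
      prev <- if (shortcut) gb_add(b, sprintf("%s.m%d.add", id, i),
                                   c(prev, m2)) else m2
      parts <- c(parts, prev)
    }
    cat <- gb_concat(b, paste0(id, ".cat"), parts)
    gb_cba(b, paste0(id, ".cv2"), cat, c2, k = 1L)
  }

  p1 <- gb_cba(b, "b0", "input", wdiv(64), stride = 2L)
  p2 <- gb_cba(b, "b1", p1, wdiv(128), stride = 2L)
  x2 <- c2f("b2", p2, wdiv(128), dep(3), TRUE)
  p3c <- gb_cba(b, "b3", x2, wdiv(256), stride = 2L)
  x4 <- c2f("b4", p3c, wdiv(256), dep(6), TRUE)
  p4c <- gb_cba(b, "b5", x4, wdiv(512), stride = 2L)
  x6 <- c2f("b6", p4c, wdiv(512), dep(6), TRUE)
  p5c <- gb_cba(b, "b7", x6, wdiv(1024), stride = 2L)
  x8 <- c2f("b8", p5c, wdiv(1024), dep(3), TRUE)
  x9 <- gb_sppf(b, "b9", x8, wdiv(1024))

  u10 <- gb_upsample(b, "h10.up", x9)
  x12 <- c2f("h12", gb_concat(b, "h11.cat", c(u10, x6)), wdiv(512), dep(3), FALSE)
  u13 <- gb_upsample(b, "h13.up", x12)
  x15 <- c2f("h15", gb_concat(b, "h14.cat", c(u13, x4)), wdiv(256), dep(3), FALSE)
  d16 <- gb_cba(b, "h16", x15, wdiv(256), stride = 2L)
  x18 <- c2f("h18", gb_concat(b, "h17.cat", c(d16, x12)), wdiv(512), dep(3), FALSE)
  d19 <- gb_cba(b, "h19", x18, wdiv(512), stride = 2L)
  x21 <- c2f("h21", gb_concat(b, "h20.cat", c(d19, x9)), wdiv(1024), dep(3), FALSE)

  taps <- c(p3 = x15, p4 = x18, p5 = x21)
  reg_max <- 16L
  c2h <- max(16L, gb_chan(b, x15) %/% 4L, 4L * reg_max)
  c3h <- max(gb_chan(b, x15), min(n_classes, 100L))
  head_outputs <- list()
  for (s in names(taps)) {
    tap <- taps[[s]]
    b1 <- gb_cba(b, paste0("det_", s, ".box1"), tap, c2h)
    b2 <- gb_cba(b, paste0("det_", s, ".box2"), b1, c2h)
    bo <- gb_conv(b, paste0("det_", s, ".box"), b2, 4L * reg_max)
    dfl <- gb_put(b, mk_dfl(paste0("det_", s, ".dfl"), bo, reg_max), 4L)
    c1 <- gb_cba(b, paste0("det_", s, ".cls1"), tap, c3h)
    c2 <- gb_cba(b, paste0("det_", s, ".cls2"), c1, c3h)
    co <- gb_conv(b, paste0("det_", s, ".cls"), c2, as.integer(n_classes))
    head_outputs[[s]] <- list(cls = co, box = bo, dfl = dfl)
  }

  new_model_graph(b$layers, input_channels = 3L,
                  n_classes = as.integer(n_classes), strides = c(8, 16, 32),
                  head_taps = unname(taps), head_outputs = head_outputs,
                  meta = list(name = "yolov8s", accounting_only = TRUE))
}
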