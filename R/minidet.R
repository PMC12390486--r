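#' Build MiniDet, a small trainable anchor-free single-stage detector
#'
#' MiniDet is the teacher/student testbed of this package: a conv-BN-SiLU
#' backbone with residual stages and an SPPF block, a top-down plus bottom-up
#' neck, and decoupled per-scale heads (class scores, box regression as
#' left/top/right/bottom distances, and an explicit objectness/confidence
#' branch) at strides 8, 16 and 32. Every conv except the final head
#' projections is followed by BatchNorm, so the whole network is prunable by
#' BatchNorm scaling factors.
#'
#' @param width channel multiplier applied to the base widths (16, 32, 64,
#'   128, 256); must leave every stage with at least one channel.
#' @param depth block-repeat multiplier for the residual stages
#'   (`max(1, round(depth))` blocks per stage).
#' @param n_classes number of object classes.
#' @param seed optional integer; fixes weight initialization.
#' @return a `model_graph` with `head_taps` at the three neck outputs and
#'   `head_outputs` naming the per-scale cls/box/obj tensors.
#' @export
build_minidet <- function(width = 1.0, depth = 1.0, n_classes = 5L,
                          seed = NULL) {
  stopifnot(width > 0, depth > 0)
  base <- c(16L, 32L, 64L, 128L, 256L)
  ch <- as.integer(round(base * width))
  if (any(ch < 1))
    stop("width ", width, " leaves a stage with 0 channels (base widths ",
         paste(base, collapse = "/"), ")")
  n_rep <- max(1L, as.integer(round(depth)))
  with_seed(seed, {
    b <- gb_new(3L, init = "he")

    res_stage <- function(id, input, c_out, n) {
      x <- input
      for (i in seq_len(n)) {
        a <- gb_cba(b, sprintf("%s.b%d.cv1", id, i), x, c_out)
        a <- gb_cba(b, sprintf("%s.b%d.cv2", id, i), a, c_out)
        x <- gb_add(b, sprintf("%s.b%d.add", id, i), c(a, x))
      }
      x
    }

    stem <- gb_cba(b, "stem", "input", ch[1], stride = 2L)       # /2
    d1 <- gb_cba(b, "d1", stem, ch[2], stride = 2L)              # /4
    s1 <- res_stage("s1", d1, ch[2], n_rep)
    d2 <- gb_cba(b, "d2", s1, ch[3], stride = 2L)                # /8
    s2 <- res_stage("s2", d2, ch[3], n_rep)
    d3 <- gb_cba(b, "d3", s2, ch[4], stride = 2L)                # /16
    s3 <- res_stage("s3", d3, ch[4], n_rep)
    d4 <- gb_cba(b, "d4", s3, ch[5], stride = 2L)                # /32
    p5 <- gb_sppf(b, "sppf", d4, ch[5])

    # top-down
    up5 <- gb_upsample(b, "up5", p5)
    n4 <- gb_cba(b, "n4", gb_concat(b, "cat4", c(up5, s3)), ch[4], k = 1L)
    up4 <- gb_upsample(b, "up4", n4)
    n3 <- gb_cba(b, "n3", gb_concat(b, "cat3", c(up4, s2)), ch[3], k = 1L)
    # bottom-up
    dn3 <- gb_cba(b, "dn3", n3, ch[3], stride = 2L)
    n4b <- gb_cba(b, "n4b", gb_concat(b, "cat4b", c(dn3, n4)), ch[4], k = 1L)
    dn4 <- gb_cba(b, "dn4", n4b, ch[4], stride = 2L)
    n5b <- gb_cba(b, "n5b", gb_concat(b, "cat5b", c(dn4, p5)), ch[5], k = 1L)

    taps <- c(p3 = n3, p4 = n4b, p5 = n5b)
    head_outputs <- list()
    for (s in names(taps)) {
      tap <- taps[[s]]
      cw <- gb_chan(b, tap)
      cls_stem <- gb_cba(b, paste0("head_", s, ".cls_stem"), tap, cw)
      cls <- gb_conv(b, paste0("head_", s, ".cls"), cls_stem, n_classes)
      box_stem <- gb_cba(b, paste0("head_", s, ".box_stem"), tap, cw)
      box <- gb_conv(b, paste0("head_", s, ".box"), box_stem, 4L)
      obj <- gb_conv(b, paste0("head_", s, ".obj"), box_stem, 1L)
      head_outputs[[s]] <- list(cls = cls, box = box, obj = obj)
    }

    g <- new_model_graph(b$layers, input_channels = 3L,
                         n_classes = as.integer(n_classes),
                         strides = c(8, 16, 32), head_taps = unname(taps),
                         head_outputs = head_outputs,
                         meta = list(name = "minidet", width = width,
                                     depth = depth))
    # start objectness at a low prior so early confidence loss is calm
    for (s in names(taps))
      g$layers[[paste0("head_", s, ".obj")]]$bias <- -2
    g
  })
}

# BNs that get a conservative protection cap (max prune fraction 0.5) by
# default: the first backbone BN and every BN feeding a detection-head
# projection (a conv with no following BN), found by walking single-input
# layers upstream from each head projection.
default_protected_bns <- function(model) {
  bns <- names(model$layers)[vapply(model$layers,
                                    function(l) l$kind == "bn", TRUE)]
  prot <- bns[1]
  for (ly in model$layers) {
    if (ly$kind != "conv" || !is.null(ly$bn_id)) next
    cur <- ly$inputs[1]
    while (cur != "input" && !is.null(model$layers[[cur]])) {
      up <- model$layers[[cur]]
      if (up$kind == "bn") { prot <- c(prot, up$id); break }
      if (length(up$inputs) != 1 || !(up$kind %in% c("act", "bn"))) break
      cur <- up$inputs[1]
    }
  }
  prot <- unique(prot)
  setNames(rep(0.5, length(prot)), prot)
}
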