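# Shared fixtures: access to graph-construction internals and small cached
# models/datasets so expensive setup runs once per session.

pk <- asNamespace("prunekd")

.fixture_env <- new.env()

fixture <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

# a conv -> bn -> act chain graph with given per-layer channels and gammas
chain_graph <- function(channels, gammas = NULL, in_ch = 3L, k = 3L,
                        seed = 1L) {
  pk$with_seed(seed, {
    b <- pk$gb_new(in_ch, init = "he")
    x <- "input"
    for (i in seq_along(channels))
      x <- pk$gb_cba(b, paste0("c", i), x, channels[i])
    g <- pk$new_model_graph(b$layers, input_channels = in_ch)
    if (!is.null(gammas)) {
      for (i in seq_along(gammas))
        g$layers[[paste0("c", i, ".bn")]]$gamma <- gammas[[i]]
    }
    g
  })
}

# random small graph (chains with occasional residual add and sppf) used by
# the accounting oracle
random_graph <- function(seed) {
  pk$with_seed(seed, {
    b <- pk$gb_new(3L, init = "he")
    x <- "input"
    n <- sample(3:6, 1)
    ch <- sample(c(4L, 6L, 8L, 12L), n, replace = TRUE)
    for (i in seq_len(n)) {
      x <- pk$gb_cba(b, paste0("c", i), x, ch[i], k = sample(c(1L, 3L), 1))
      if (runif(1) < 0.3) {
        a <- pk$gb_cba(b, paste0("r", i), x, ch[i])
        x <- pk$gb_add(b, paste0("a", i), c(a, x))
      }
    }
    if (runif(1) < 0.5) x <- pk$gb_sppf(b, "sp", x, ch[n])
    pk$new_model_graph(b$layers, input_channels = 3L)
  })
}

# shape-arithmetic parameter count, independent of the stored arrays
shape_param_count <- function(model) {
  tot <- 0
  for (ly in model$layers) {
    if (ly$kind == "conv")
      tot <- tot + ly$k^2 * ly$in_ch * ly$out_ch +
        (if (is.null(ly$bias)) 0 else ly$out_ch)
    if (ly$kind == "bn") tot <- tot + 2 * ly$channels
    if (ly$kind == "dfl") tot <- tot + ly$bins
  }
  tot
}

# randomize BN stats so eval-mode forward is nontrivial
randomize_bn <- function(model, seed = 1L) {
  pk$with_seed(seed, {
    for (id in names(model$layers)) {
      if (model$layers[[id]]$kind != "bn") next
      n <- model$layers[[id]]$channels
      model$layers[[id]]$gamma <- runif(n, 0.2, 1.5)
      model$layers[[id]]$beta <- rnorm(n, 0, 0.2)
      model$layers[[id]]$rmean <- rnorm(n, 0, 0.3)
      model$layers[[id]]$rvar <- runif(n, 0.5, 2)
    }
    model
  })
}

max_out_diff <- function(a, b) max(mapply(function(x, y) max(abs(x - y)), a, b))

head_output_ids <- function(model) unlist(model$head_outputs, use.names = FALSE)

tiny_images <- function(n = 24, seed = 100, size = 64) {
  fixture(sprintf("imgs_%d_%d_%d", n, seed, size),
          generate_scenes(benchmark_spec(size, seed = seed), n, seed = seed))
}

small_train_images <- function() tiny_images(60, seed = 5)

pretrained_small <- function() {
  fixture("pretrained_small", {
    m <- build_minidet(0.25, 1, 5, seed = 8)
    train_detector(m, small_train_images(), epochs = 8, batch_size = 8,
                   seed = 9)$model
  })
}

# independent greedy matcher written with plain loops (oracle for
# match_detections)
brute_match_counts <- function(dets, gts, thr) {
  tp <- 0L; fp <- 0L
  used <- rep(FALSE, nrow(gts))
  for (cl in unique(dets$class_id)) {
    idx <- which(dets$class_id == cl)
    idx <- idx[order(-dets$conf[idx], idx)]
    for (i in idx) {
      best <- 0; bestj <- NA
      for (j in seq_len(nrow(gts))) {
        if (used[j] || gts$class_id[j] != cl ||
            gts$image_id[j] != dets$image_id[i]) next
        ix <- max(0, min(dets$x2[i], gts$x2[j]) - max(dets$x1[i], gts$x1[j]))
        iy <- max(0, min(dets$y2[i], gts$y2[j]) - max(dets$y1[i], gts$y1[j]))
        inter <- ix * iy
        un <- (dets$x2[i] - dets$x1[i]) * (dets$y2[i] - dets$y1[i]) +
          (gts$x2[j] - gts$x1[j]) * (gts$y2[j] - gts$y1[j]) - inter
        iou <- if (un > 0) inter / un else 0
        if (iou > best) { best <- iou; bestj <- j }
      }
      if (!is.na(bestj) && best >= thr) { tp <- tp + 1L; used[bestj] <- TRUE }
      else fp <- fp + 1L
    }
  }
  fn <- sum(!used)
  c(tp = tp, fp = fp, fn = fn)
}

# independent all-points AP: plain-loop envelope and rectangle summation
brute_ap <- function(tp, n_gt) {
  if (!length(tp)) return(0)
  prec <- numeric(length(tp)); rec <- numeric(length(tp))
  cum <- 0
  for (i in seq_along(tp)) {
    cum <- cum + as.numeric(tp[i])
    prec[i] <- cum / i
    rec[i] <- cum / n_gt
  }
  ap <- 0; prev <- 0
  for (i in seq_along(tp)) {
    env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev) * env
    prev <- rec[i]
  }
  ap
}

random_detection_set <- function(seed) {
  pk$with_seed(seed, {
    n_gt <- sample(1:6, 1)
    n_det <- sample(0:10, 1)
    tp <- if (n_det > 0) {
      flags <- runif(n_det) < 0.5
      # at most n_gt true positives
      if (sum(flags) > n_gt) flags[which(flags)[-(seq_len(n_gt))]] <- FALSE
      flags
    } else logical()
    list(tp = tp, n_gt = n_gt)
  })
}
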