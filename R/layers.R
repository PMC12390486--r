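# Elementary layer forward/backward kernels operating on (H, W, C, N) arrays.
# Each layer is a plain list tagged with `kind`; the graph engine in graph.R
# threads tensors through them and accumulates gradients in reverse order.

conv_out_hw <- function(hw, k, stride, pad) {
  c((hw[1] + 2 * pad - k) %/% stride + 1,
    (hw[2] + 2 * pad - k) %/% stride + 1)
}

conv_fwd <- function(layer, x) {
  d <- dim(x)
  k <- layer$k
  if (k == 1L && layer$stride == 1L) {
    # 1x1 fast path: plain channel mixing
    cols <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])
    ho <- d[1]; wo <- d[2]
  } else {
    cols <- im2col_cpp(x, k, layer$stride, layer$pad)
    hw <- conv_out_hw(d[1:2], k, layer$stride, layer$pad)
    ho <- hw[1]; wo <- hw[2]
  }
  wm <- matrix(layer$weight, nrow = k * k * layer$in_ch)
  y <- crossprod(wm, cols)
  if (!is.null(layer$bias)) y <- y + layer$bias
  out <- aperm(array(y, c(layer$out_ch, ho, wo, d[4])), c(2, 3, 1, 4))
  list(out = out, cache = list(cols = cols, xdim = d))
}

conv_bwd <- function(layer, cache, dy) {
  d <- cache$xdim
  k <- layer$k
  dyd <- dim(dy)
  dym <- matrix(aperm(dy, c(3, 1, 2, 4)), nrow = layer$out_ch)
  dw <- cache$cols %*% t(dym)
  dim(dw) <- c(k, k, layer$in_ch, layer$out_ch)
  db <- if (!is.null(layer$bias)) rowSums(dym) else NULL
  wm <- matrix(layer$weight, nrow = k * k * layer$in_ch)
  dcols <- wm %*% dym
  if (k == 1L && layer$stride == 1L) {
    dx <- aperm(array(dcols, c(layer$in_ch, d[1], d[2], d[4])), c(2, 3, 1, 4))
  } else {
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], k, layer$stride, layer$pad)
  }
  pg <- list(weight = dw)
  if (!is.null(db)) pg$bias <- db
  list(dins = list(dx), pgrads = pg)
}

bn_fwd <- function(layer, x, train) {
  d <- dim(x)
  if (train) {
    m <- ch_mean(x)
    xc <- x - bcast_ch(m, d)
    v <- ch_mean(xc * xc)            # biased batch variance
    inv <- 1 / sqrt(v + layer$eps)
    xhat <- xc * bcast_ch(inv, d)
    layer$rmean <- (1 - layer$momentum) * layer$rmean + layer$momentum * m
    layer$rvar <- (1 - layer$momentum) * layer$rvar + layer$momentum * v
  } else {
    inv <- 1 / sqrt(layer$rvar + layer$eps)
    xhat <- (x - bcast_ch(layer$rmean, d)) * bcast_ch(inv, d)
  }
  out <- xhat * bcast_ch(layer$gamma, d) + bcast_ch(layer$beta, d)
  list(out = out, cache = list(xhat = xhat, inv = inv, train = train, xdim = d),
       layer = layer)
}

bn_bwd <- function(layer, cache, dy) {
  d <- cache$xdim
  dgamma <- ch_sum(dy * cache$xhat)
  dbeta <- ch_sum(dy)
  g_inv <- bcast_ch(layer$gamma * cache$inv, d)
  if (cache$train) {
    m <- d[1] * d[2] * d[4]
    dx <- g_inv / m *
      (m * dy - bcast_ch(dbeta, d) - cache$xhat * bcast_ch(dgamma, d))
  } else {
    dx <- dy * g_inv
  }
  list(dins = list(dx), pgrads = list(gamma = dgamma, beta = dbeta))
}

act_fwd <- function(layer, x) {
  out <- switch(layer$fun,
    silu = x * sigmoid(x),
    relu = pmax(x, 0),
    stop("unknown activation: ", layer$fun))
  list(out = out, cache = list(x = x))
}

act_bwd <- function(layer, cache, dy) {
  x <- cache$x
  dx <- switch(layer$fun,
    silu = { s <- sigmoid(x); dy * (s * (1 + x * (1 - s))) },
    relu = dy * (x > 0))
  list(dins = list(dx), pgrads = NULL)
}

upsample_fwd <- function(layer, x) {
  f <- layer$factor
  d <- dim(x)
  out <- x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), , ,
           drop = FALSE]
  list(out = out, cache = list(xdim = d))
}

upsample_bwd <- function(layer, cache, dy) {
  f <- layer$factor
  d <- cache$xdim
  a <- array(dy, c(f, d[1], f * d[2] * d[3] * d[4]))
  r1 <- colSums(a)                              # (H, fW*C*N)
  dim(r1) <- c(d[1], f * d[2], d[3], d[4])
  a2 <- aperm(r1, c(2, 1, 3, 4))
  dim(a2) <- c(f, d[2], d[1] * d[3] * d[4])
  r2 <- colSums(a2)                             # (W, H*C*N)
  dim(r2) <- c(d[2], d[1], d[3], d[4])
  list(dins = list(aperm(r2, c(2, 1, 3, 4))), pgrads = NULL)
}

maxpool_fwd <- function(layer, x) {
  r <- maxpool_fwd_cpp(x, layer$k, layer$stride, layer$pad)
  list(out = r$out, cache = list(argmax = r$argmax, xdim = dim(x)))
}

maxpool_bwd <- function(layer, cache, dy) {
  list(dins = list(maxpool_bwd_cpp(dy, cache$argmax, cache$xdim)),
       pgrads = NULL)
}

concat_fwd <- function(layer, ins) {
  d1 <- dim(ins[[1]])
  cs <- vapply(ins, function(x) dim(x)[3], numeric(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (x in ins) {
    cc <- dim(x)[3]
    out[, , at + seq_len(cc), ] <- x
    at <- at + cc
  }
  list(out = out, cache = list(cs = cs))
}

concat_bwd <- function(layer, cache, dy) {
  at <- 0L
  dins <- lapply(cache$cs, function(cc) {
    g <- dy[, , at + seq_len(cc), , drop = FALSE]
    at <<- at + cc
    g
  })
  list(dins = dins, pgrads = NULL)
}

slice_fwd <- function(layer, x) {
  list(out = x[, , layer$ch_start:layer$ch_end, , drop = FALSE],
       cache = list(xdim = dim(x)))
}

slice_bwd <- function(layer, cache, dy) {
  dx <- array(0, cache$xdim)
  dx[, , layer$ch_start:layer$ch_end, ] <- dy
  list(dins = list(dx), pgrads = NULL)
}

layer_forward <- function(layer, ins, train = FALSE) {
  switch(layer$kind,
    conv = conv_fwd(layer, ins[[1]]),
    bn = bn_fwd(layer, ins[[1]], train),
    act = act_fwd(layer, ins[[1]]),
    add = list(out = Reduce(`+`, ins), cache = list(n = length(ins))),
    concat = concat_fwd(layer, ins),
    upsample = upsample_fwd(layer, ins[[1]]),
    maxpool = maxpool_fwd(layer, ins[[1]]),
    slice = slice_fwd(layer, ins[[1]]),
    dfl = stop("dfl layers are accounting-only and have no forward pass"),
    stop("unknown layer kind: ", layer$kind))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    conv = conv_bwd(layer, cache, dy),
    bn = bn_bwd(layer, cache, dy),
    act = act_bwd(layer, cache, dy),
    add = list(dins = rep(list(dy), cache$n), pgrads = NULL),
    concat = concat_bwd(layer, cache, dy),
    upsample = upsample_bwd(layer, cache, dy),
    maxpool = maxpool_bwd(layer, cache, dy),
    slice = slice_bwd(layer, cache, dy),
    stop("no backward for layer kind: ", layer$kind))
}
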