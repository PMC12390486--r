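# Graph-builder helpers: a tiny mutable accumulator used by the detector
# constructors. Every conv (except final head projections) is emitted as
# conv -> BN -> activation so the whole network is prunable by BN gamma.

gb_new <- function(in_ch = 3L, init = "he") {
  e <- new.env(parent = emptyenv())
  e$layers <- list()
  e$ch <- c(input = as.integer(in_ch))
  e$init <- init
  e
}

gb_put <- function(b, ly, out_ch) {
  if (ly$id %in% names(b$layers)) stop("duplicate layer id: ", ly$id)
  b$layers[[ly$id]] <- ly
  b$ch[[ly$id]] <- as.integer(out_ch)
  ly$id
}

gb_chan <- function(b, id) {
  force(id)  # id may be a builder call whose side effect registers the tensor
  b$ch[[id]]
}

# conv + BN + activation; returns the activation tensor id ("<id>.act").
gb_cba <- function(b, id, input, out_ch, k = 3L, stride = 1L, act = "silu") {
  cin <- gb_chan(b, input)
  gb_put(b, mk_conv(paste0(id, ".conv"), input, cin, out_ch, k, stride,
                    bn_id = paste0(id, ".bn"), init = b$init), out_ch)
  gb_put(b, mk_bn(paste0(id, ".bn"), paste0(id, ".conv"), out_ch), out_ch)
  gb_put(b, mk_act(paste0(id, ".act"), paste0(id, ".bn"), act), out_ch)
  paste0(id, ".act")
}

# bare conv (head projection), bias on, no BN
gb_conv <- function(b, id, input, out_ch, k = 1L, stride = 1L) {
  cin <- gb_chan(b, input)
  gb_put(b, mk_conv(id, input, cin, out_ch, k, stride, bias = TRUE,
                    init = b$init), out_ch)
}

gb_add <- function(b, id, inputs)
  gb_put(b, mk_add(id, inputs), gb_chan(b, inputs[1]))
gb_concat <- function(b, id, inputs)
  gb_put(b, mk_concat(id, inputs), sum(vapply(inputs, function(i) gb_chan(b, i), 0L)))
gb_upsample <- function(b, id, input)
  gb_put(b, mk_upsample(id, input), gb_chan(b, input))
gb_maxpool <- function(b, id, input, k = 5L, stride = 1L, pad = 2L)
  gb_put(b, mk_maxpool(id, input, k, stride, pad), gb_chan(b, input))
gb_slice <- function(b, id, input, from, to)
  gb_put(b, mk_slice(id, input, from, to), to - from + 1L)

gb_sppf <- function(b, id, input, out_ch) {
  cin <- gb_chan(b, input)
  half <- cin %/% 2L
  cv1 <- gb_cba(b, paste0(id, ".cv1"), input, half, k = 1L)
  p1 <- gb_maxpool(b, paste0(id, ".p1"), cv1)
  p2 <- gb_maxpool(b, paste0(id, ".p2"), p1)
  p3 <- gb_maxpool(b, paste0(id, ".p3"), p2)
  cat <- gb_concat(b, paste0(id, ".cat"), c(cv1, p1, p2, p3))
  gb_cba(b, paste0(id, ".cv2"), cat, out_ch, k = 1L)
}
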