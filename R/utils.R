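# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Round half away from zero (commercial rounding). base::round() rounds half
# to even, which would make split arithmetic depend on floating parity.
round_half_up <- function(x) floor(x + 0.5)

# Broadcast a per-channel vector over an (H, W, C, N) tensor.
bcast_ch <- function(v, d) {
  rep(rep(v, each = d[1] * d[2]), times = d[4])
}

# Per-channel sum / mean over (H, W, N) of an (H, W, C, N) tensor.
ch_sum <- function(x) {
  d <- dim(x)
  m <- matrix(x, nrow = d[1] * d[2], ncol = d[3] * d[4])
  s <- colSums(m)
  rowSums(matrix(s, nrow = d[3], ncol = d[4]))
}

ch_mean <- function(x) {
  d <- dim(x)
  ch_sum(x) / (d[1] * d[2] * d[4])
}

sigmoid <- function(x) plogis(x)

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Numerically stable binary cross-entropy with logits; returns elementwise loss.
bce_with_logits <- function(z, t) {
  pmax(z, 0) - z * t + log1p(exp(-abs(z)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
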