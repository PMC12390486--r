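# ModelGraph: an ordered, layer-level description of a detector supporting
# forward execution, gradient accumulation, parameter access, accounting and
# channel surgery. Layers are listed in topological order; each names the
# tensors it consumes ("input" is the image batch).

new_model_graph <- function(layers, input_channels = 3L, n_classes = NULL,
                            strides = NULL, head_taps = character(),
                            head_outputs = NULL, meta = list()) {
  names(layers) <- vapply(layers, `[[`, "", "id")
  g <- structure(list(
    layers = layers, input_channels = input_channels, n_classes = n_classes,
    strides = strides, head_taps = head_taps, head_outputs = head_outputs,
    meta = meta), class = "model_graph")
  validate_graph(g)
  g
}

# Channel count of every tensor in the graph (named by producing layer).
tensor_channels <- function(model) {
  ch <- c(input = model$input_channels)
  for (ly in model$layers) {
    ins <- ch[ly$inputs]
    ch[[ly$id]] <- switch(ly$kind,
      conv = ly$out_ch,
      bn = ly$channels,
      concat = sum(ins),
      slice = ly$ch_end - ly$ch_start + 1L,
      dfl = 4L,
      ins[[1]])
  }
  ch
}

validate_graph <- function(model) {
  ch <- c(input = model$input_channels)
  for (ly in model$layers) {
    miss <- setdiff(ly$inputs, names(ch))
    if (length(miss))
      stop("layer '", ly$id, "' consumes unknown tensor(s): ",
           paste(miss, collapse = ", "))
    ins <- unname(ch[ly$inputs])
    out <- switch(ly$kind,
      conv = {
        if (ins[1] != ly$in_ch)
          stop("layer '", ly$id, "': in_ch ", ly$in_ch,
               " != producer channels ", ins[1])
        if (dim(ly$weight)[4] != ly$out_ch || dim(ly$weight)[3] != ly$in_ch)
          stop("layer '", ly$id, "': weight shape inconsistent")
        ly$out_ch
      },
      bn = {
        if (ins[1] != ly$channels)
          stop("BN '", ly$id, "': channels ", ly$channels,
               " != producer channels ", ins[1])
        if (any(ly$rvar < 0)) stop("BN '", ly$id, "': negative running variance")
        ly$channels
      },
      add = {
        if (length(unique(ins)) != 1)
          stop("add '", ly$id, "': unequal input channels (",
               paste(ins, collapse = ","), ")")
        ins[1]
      },
      concat = sum(ins),
      slice = {
        if (ly$ch_end > ins[1] || ly$ch_start < 1)
          stop("slice '", ly$id, "': range outside input channels")
        ly$ch_end - ly$ch_start + 1L
      },
      dfl = 4L,
      ins[1])
    ch[[ly$id]] <- out
  }
  invisible(TRUE)
}

# --- layer constructors used by the builders -------------------------------

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

mk_conv <- function(id, input, in_ch, out_ch, k = 3L, stride = 1L,
                    pad = (k - 1L) %/% 2L, bias = FALSE, bn_id = NULL,
                    init = c("he", "zero")) {
  init <- match.arg(init)
  w <- if (init == "he") he_init(k, in_ch, out_ch) else
    array(0, c(k, k, in_ch, out_ch))
  list(id = id, kind = "conv", inputs = input, in_ch = as.integer(in_ch),
       out_ch = as.integer(out_ch), k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad), weight = w,
       bias = if (bias) numeric(out_ch) else NULL, bn_id = bn_id)
}

mk_bn <- function(id, input, channels, eps = 1e-5, momentum = 0.1) {
  list(id = id, kind = "bn", inputs = input, channels = as.integer(channels),
       gamma = rep(1, channels), beta = numeric(channels),
       rmean = numeric(channels), rvar = rep(1, channels),
       eps = eps, momentum = momentum)
}

mk_act <- function(id, input, fun = "silu")
  list(id = id, kind = "act", inputs = input, fun = fun)
mk_add <- function(id, inputs) list(id = id, kind = "add", inputs = inputs)
mk_concat <- function(id, inputs) list(id = id, kind = "concat", inputs = inputs)
mk_upsample <- function(id, input, factor = 2L)
  list(id = id, kind = "upsample", inputs = input, factor = as.integer(factor))
mk_maxpool <- function(id, input, k = 5L, stride = 1L, pad = 2L)
  list(id = id, kind = "maxpool", inputs = input, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
mk_slice <- function(id, input, ch_start, ch_end)
  list(id = id, kind = "slice", inputs = input,
       ch_start = as.integer(ch_start), ch_end = as.integer(ch_end))
mk_dfl <- function(id, input, bins = 16L)
  list(id = id, kind = "dfl", inputs = input, bins = as.integer(bins),
       weight = seq(0, bins - 1))

# --- execution --------------------------------------------------------------

# Run the graph given preset tensors (normally list(input = x)). Layers whose
# inputs are not available are skipped, so presetting intermediate tensors
# (e.g. neck taps) executes only the downstream sub-graph such as the heads.
graph_run <- function(model, preset, train = FALSE, keep_cache = TRUE) {
  outs <- preset
  caches <- list()
  computed <- character()
  for (ly in model$layers) {
    if (ly$id %in% names(outs)) next
    if (!all(ly$inputs %in% names(outs))) next
    ins <- lapply(ly$inputs, function(i) outs[[i]])
    r <- layer_forward(ly, ins, train)
    outs[[ly$id]] <- r$out
    if (keep_cache) caches[[ly$id]] <- r$cache
    if (!is.null(r$layer)) model$layers[[ly$id]] <- r$layer
    computed <- c(computed, ly$id)
  }
  list(outs = outs, caches = caches, computed = computed, model = model)
}

# Reverse pass over a graph_run() result. `seeds` maps tensor ids to gradient
# arrays (any tensors, including intermediates). Returns per-layer parameter
# gradients and gradients w.r.t. the preset tensors named in `want`.
graph_grad <- function(model, run, seeds, want = character(),
                       param_grads = TRUE) {
  d <- seeds
  pgrads <- list()
  for (id in rev(run$computed)) {
    g <- d[[id]]
    if (is.null(g)) next
    ly <- model$layers[[id]]
    b <- layer_backward(ly, run$caches[[id]], g)
    if (param_grads && !is.null(b$pgrads)) pgrads[[id]] <- b$pgrads
    for (i in seq_along(ly$inputs)) {
      tid <- ly$inputs[i]
      gi <- b$dins[[i]]
      d[[tid]] <- if (is.null(d[[tid]])) gi else d[[tid]] + gi
    }
    d[[id]] <- NULL   # free
  }
  list(pgrads = pgrads, tensor_grads = d[want])
}

# Plain forward pass; returns requested tensors.
#' Run a detector forward
#'
#' Executes a model graph on a batch of images in inference or training mode.
#' In inference (eval) mode BatchNorm layers use their running statistics, so
#' repeated calls on the same input are bitwise identical.
#'
#' @param model a `model_graph`.
#' @param x numeric array of shape (H, W, C, N), pixel values in \[0, 1\];
#'   H and W must be divisible by 32 for the three-scale detectors built here.
#' @param taps character vector of tensor ids to return (defaults to the
#'   model's head outputs plus its distillation tap points).
#' @param train logical; training mode uses batch statistics in BatchNorm.
#' @return named list of tensors, each (H', W', C', N).
#' @export
forward <- function(model, x, taps = NULL, train = FALSE) {
  stopifnot(inherits(model, "model_graph"))
  d <- dim(x)
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[3] != model$input_channels)
    stop("input has ", d[3], " channels; model expects ", model$input_channels)
  if (!is.null(model$strides) && (d[1] %% 32 != 0 || d[2] %% 32 != 0))
    stop("input height/width must be divisible by 32, got ", d[1], "x", d[2])
  run <- graph_run(model, list(input = x), train = train, keep_cache = FALSE)
  ids <- taps %||% unique(c(unlist(model$head_outputs), model$head_taps))
  if (is.null(ids) || !length(ids)) ids <- tail(run$computed, 1)
  run$outs[ids]
}

# --- parameters -------------------------------------------------------------

param_names_of <- function(ly) {
  switch(ly$kind,
    conv = if (is.null(ly$bias)) "weight" else c("weight", "bias"),
    bn = c("gamma", "beta"),
    character())
}

#' Extract all learnable parameters of a model
#' @param model a `model_graph`.
#' @return named list `"layer/param"` of numeric arrays.
#' @export
get_params <- function(model) {
  out <- list()
  for (ly in model$layers)
    for (p in param_names_of(ly))
      out[[paste0(ly$id, "/", p)]] <- ly[[p]]
  out
}

#' @rdname get_params
#' @param params named list as returned by [get_params()].
#' @export
set_params <- function(model, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1]]
    model$layers[[parts[1]]][[parts[2]]] <- params[[nm]]
  }
  model
}

# --- accounting -------------------------------------------------------------

#' Count learnable parameters of a model graph
#'
#' Sums the elements of every stored weight, bias and BatchNorm scale/shift
#' array (running statistics are buffers, not parameters).
#' @param model a `model_graph`.
#' @return integer-valued numeric scalar.
#' @export
count_params <- function(model) {
  tot <- 0
  for (ly in model$layers) {
    for (p in param_names_of(ly)) tot <- tot + length(ly[[p]])
    if (ly$kind == "dfl") tot <- tot + length(ly$weight)
  }
  tot
}

#' Count forward-pass FLOPs of a model graph
#'
#' Convolutions are counted as 2 multiply-accumulate operations per output
#' element (the convention under which a canonical small YOLOv8 totals about
#' 28.6 G at 640x640) plus one add per element for bias; BatchNorm,
#' activations, adds and pooling count one operation per output element;
#' upsampling and concatenation are free.
#'
#' @param model a `model_graph`.
#' @param input_hw integer length-2: input height and width.
#' @return FLOPs for a single image, in raw operations (divide by 1e9 for G).
#' @export
count_flops <- function(model, input_hw = c(640, 640)) {
  hw <- list(input = as.integer(input_hw))
  chs <- tensor_channels(model)
  tot <- 0
  for (ly in model$layers) {
    ih <- hw[[ly$inputs[1]]]
    oh <- switch(ly$kind,
      conv = conv_out_hw(ih, ly$k, ly$stride, ly$pad),
      maxpool = conv_out_hw(ih, ly$k, ly$stride, ly$pad),
      upsample = ih * ly$factor,
      ih)
    n_out <- prod(oh)
    tot <- tot + switch(ly$kind,
      conv = 2 * ly$k^2 * ly$in_ch * ly$out_ch * n_out +
        (if (is.null(ly$bias)) 0 else ly$out_ch * n_out),
      bn = ,
      act = ,
      add = ,
      maxpool = chs[[ly$id]] * n_out,
      dfl = 2 * ly$bins * 4 * n_out,
      0)
    hw[[ly$id]] <- oh
  }
  tot
}

#' @export
print.model_graph <- function(x, ...) {
  cat("<model_graph> ", x$meta$name %||% "", "\n", sep = "")
  cat("  layers: ", length(x$layers),
      " | params: ", format(count_params(x), big.mark = ","),
      " | BN layers: ", sum(vapply(x$layers, function(l) l$kind == "bn", TRUE)),
      "\n", sep = "")
  if (length(x$head_taps))
    cat("  head taps: ", paste(x$head_taps, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# --- persistence ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are a single JSON document holding the structural description
#' of the graph plus every parameter and buffer array (with dimensions), so a
#' checkpoint fully reconstructs the model.
#'
#' @param model a `model_graph`.
#' @param path file path (conventionally `.json`).
#' @export
save_checkpoint <- function(model, path) {
  enc_layer <- function(ly) {
    for (p in c("weight", "bias", "gamma", "beta", "rmean", "rvar")) {
      if (!is.null(ly[[p]])) {
        ly[[p]] <- list(dim = dim(ly[[p]]) %||% length(ly[[p]]),
                        data = as.numeric(ly[[p]]))
      }
    }
    ly
  }
  doc <- list(format = "prunekd-checkpoint-v1",
              input_channels = model$input_channels,
              n_classes = model$n_classes, strides = model$strides,
              head_taps = model$head_taps, head_outputs = model$head_outputs,
              meta = model$meta, layers = lapply(model$layers, enc_layer))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  dec_layer <- function(ly) {
    for (p in c("weight", "bias", "gamma", "beta", "rmean", "rvar")) {
      if (!is.null(ly[[p]])) {
        v <- as.numeric(unlist(ly[[p]]$data))
        dm <- as.integer(unlist(ly[[p]]$dim))
        if (length(dm) > 1) dim(v) <- dm
        ly[[p]] <- v
      }
    }
    for (p in c("in_ch", "out_ch", "k", "stride", "pad", "channels",
                "factor", "ch_start", "ch_end", "bins"))
      if (!is.null(ly[[p]])) ly[[p]] <- as.integer(ly[[p]])
    ly$inputs <- as.character(unlist(ly$inputs))
    ly
  }
  layers <- lapply(doc$layers, dec_layer)
  new_model_graph(layers, input_channels = as.integer(doc$input_channels),
                  n_classes = doc$n_classes,
                  strides = if (is.null(doc$strides)) NULL
                            else as.numeric(unlist(doc$strides)),
                  head_taps = as.character(unlist(doc$head_taps)),
                  head_outputs = doc$head_outputs, meta = doc$meta)
}

#' Export a graph description (no weights) as JSON for inspection
#' @param model a `model_graph`.
#' @param path output file.
#' @export
export_graph_json <- function(model, path) {
  strip <- function(ly) {
    ly$weight <- NULL; ly$bias <- NULL
    ly$gamma <- NULL; ly$beta <- NULL; ly$rmean <- NULL; ly$rvar <- NULL
    ly
  }
  doc <- list(layers = lapply(model$layers, strip),
              head_taps = model$head_taps, meta = model$meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
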