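# BatchNorm-gamma channel scoring, sensitivity reporting, global-threshold
# pruning-plan construction with coupled-channel handling, and structured
# surgery that rebuilds a genuinely smaller dense network.

#' The BatchNorm transform
#'
#' `y = gamma * (z - mu) / sqrt(sigma2 + eps) + beta`, elementwise per
#' channel. Exposed directly because its fixed points anchor the pruning
#' rationale: a channel with gamma near 0 degenerates to the constant beta.
#'
#' @param z input values: a numeric vector aligned with the parameter
#'   vectors, or an (H, W, C, N) array with C matching their length.
#' @param gamma,beta,mu,sigma2 per-channel parameter vectors (equal length).
#' @param eps numerical stability constant, > 0.
#' @return same shape as `z`.
#' @export
bn_transform <- function(z, gamma, beta, mu, sigma2, eps = 1e-5) {
  nch <- length(gamma)
  if (length(beta) != nch || length(mu) != nch || length(sigma2) != nch)
    stop("parameter vectors have unequal channel lengths")
  if (any(sigma2 < 0)) stop("sigma2 must be nonnegative")
  if (eps < 0) stop("eps must be nonnegative")
  inv <- 1 / sqrt(sigma2 + eps)
  if (is.array(z) && length(dim(z)) == 4) {
    if (dim(z)[3] != nch) stop("channel-length mismatch")
    d <- dim(z)
    (z - bcast_ch(mu, d)) * bcast_ch(gamma * inv, d) + bcast_ch(beta, d)
  } else {
    if (length(z) != nch) stop("channel-length mismatch")
    gamma * (z - mu) * inv + beta
  }
}

#' Snapshot the absolute BatchNorm scale factors of a model
#' @param model a `model_graph`.
#' @param epoch optional epoch tag for the snapshot.
#' @return a `gamma_table`: named list of per-BN `|gamma|` vectors.
#' @export
gamma_table <- function(model, epoch = NA) {
  bns <- Filter(function(l) l$kind == "bn", model$layers)
  tab <- lapply(bns, function(l) abs(l$gamma))
  structure(tab, class = "gamma_table", epoch = epoch)
}

#' @rdname gamma_table
#' @param table a `gamma_table`.
#' @param path CSV output path (one row per channel: layer, channel index,
#'   `|gamma|`).
#' @export
write_gamma_csv <- function(table, path) {
  df <- do.call(rbind, lapply(names(table), function(id)
    data.frame(layer_id = id, channel = seq_along(table[[id]]),
               abs_gamma = unname(table[[id]]))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Global channel-importance scores
#'
#' `S_c = |gamma_c| / sum_i |gamma_i|`, the sum running over all prunable
#' channels in the model (global normalization), so the scores always sum
#' to 1 and small scores mark channels likely to be pruned.
#'
#' @param table a [gamma_table()].
#' @return list with `scores` (per-layer list, same shapes as the table) and
#'   `flat` (all scores in layer order).
#' @export
channel_scores <- function(table) {
  flat <- unlist(table, use.names = FALSE)
  tot <- sum(flat)
  if (tot == 0) stop("all gamma values are zero; model is degenerate")
  list(scores = lapply(table, function(g) g / tot), flat = flat / tot)
}

#' L1 sparsity penalty on BatchNorm gammas
#'
#' `lambda * sum |gamma|` over every BatchNorm layer; added to the task loss
#' during [train_sparse()] (its subgradient w.r.t. each gamma is
#' `lambda * sign(gamma)`).
#'
#' @param model a `model_graph`.
#' @param lambda nonnegative strength.
#' @return scalar penalty.
#' @export
sparsity_penalty <- function(model, lambda) {
  stopifnot(lambda >= 0)
  lambda * sum(unlist(gamma_table(model), use.names = FALSE))
}

#' Layer-wise pruning-sensitivity report
#'
#' Mean `|gamma|` per BatchNorm layer: layers with high mean gamma remain
#' strongly channel-dependent (sensitive to pruning), low-mean layers carry
#' redundancy.
#'
#' @param table a [gamma_table()].
#' @return data.frame of class `sensitivity_report` with columns
#'   `layer_index`, `layer_id`, `channels`, `mean_abs_gamma`.
#' @export
sensitivity_report <- function(table) {
  stopifnot(length(table) > 0)
  df <- data.frame(layer_index = seq_along(table),
                   layer_id = names(table),
                   channels = vapply(table, length, 0L),
                   mean_abs_gamma = vapply(table, mean, 0),
                   row.names = NULL)
  class(df) <- c("sensitivity_report", "data.frame")
  df
}

#' @rdname sensitivity_report
#' @param report a `sensitivity_report`.
#' @param path CSV output path.
#' @export
write_sensitivity_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' @rdname sensitivity_report
#' @param ... passed to [graphics::image()].
#' @export
plot_sensitivity <- function(report, ...) {
  m <- matrix(report$mean_abs_gamma, ncol = 1)
  graphics::image(x = report$layer_index, y = 1, z = m,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "BatchNorm layer index", ylab = "",
                  yaxt = "n", main = "Pruning sensitivity (mean |gamma|)",
                  ...)
  invisible(report)
}

# --- coupled-channel analysis ----------------------------------------------

# Union-find over individual BN channels. Residual adds tie channels of
# different BNs position by position; concat and slice shift positions, so
# coupling is tracked per channel, not per layer.
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }
  i
}

# Returns: nodes (bn id -> node index range), ties (union-find parent
# vector), forced (node indices that must be kept because they are added to
# unprunable tensors).
channel_coupling <- function(model) {
  bns <- names(model$layers)[vapply(model$layers,
                                    function(l) l$kind == "bn", TRUE)]
  sizes <- vapply(bns, function(id) model$layers[[id]]$channels, 0L)
  offs <- cumsum(c(0L, sizes))[seq_along(bns)]
  names(offs) <- bns
  uf <- uf_new(sum(sizes))
  forced <- integer()
  handles <- list(input = rep(NA_integer_, model$input_channels))
  for (ly in model$layers) {
    h_in <- handles[ly$inputs]
    handles[[ly$id]] <- switch(ly$kind,
      conv = rep(NA_integer_, ly$out_ch),
      bn = offs[[ly$id]] + seq_len(ly$channels),
      concat = unlist(h_in, use.names = FALSE),
      slice = h_in[[1]][ly$ch_start:ly$ch_end],
      dfl = rep(NA_integer_, 4L),
      add = {
        base <- h_in[[1]]
        for (j in seq_along(h_in)[-1]) {
          other <- h_in[[j]]
          for (p in seq_along(base)) {
            a <- base[p]; b <- other[p]
            if (!is.na(a) && !is.na(b)) {
              ra <- uf_find(uf, a); rb <- uf_find(uf, b)
              if (ra != rb) uf[rb] <- ra
            } else if (is.na(a) && !is.na(b)) {
              forced <- c(forced, b); base[p] <- b
            } else if (!is.na(a) && is.na(b)) {
              forced <- c(forced, a)
            }
          }
        }
        base
      },
      h_in[[1]])
  }
  list(bns = bns, sizes = sizes, offsets = offs, uf = uf, forced = forced)
}

# Layer-level coupled groups (BNs sharing at least one channel tie).
coupled_bn_groups <- function(cpl) {
  roots <- vapply(seq_along(cpl$uf), function(i) uf_find(cpl$uf, i), 0L)
  comp <- split(seq_along(roots), roots)
  comp <- comp[vapply(comp, length, 0L) > 1]
  node_bn <- rep(cpl$bns, cpl$sizes)
  adj <- lapply(comp, function(nodes) unique(node_bn[nodes]))
  adj <- adj[vapply(adj, length, 0L) > 1]
  groups <- list()
  for (g in adj) {
    hit <- which(vapply(groups, function(x) any(g %in% x), TRUE))
    if (length(hit)) {
      merged <- unique(c(unlist(groups[hit]), g))
      groups <- groups[-hit]
      groups[[length(groups) + 1]] <- merged
    } else groups[[length(groups) + 1]] <- g
  }
  groups
}

#' Build a global-threshold pruning plan
#'
#' The threshold is the `ratio`-quantile (lower empirical quantile, no
#' interpolation) of all prunable `|gamma|` in the model; a channel is kept
#' iff `|gamma| > threshold`. The raw decision is then adjusted: layers with
#' a protection cap keep at least their top-`|gamma|` channels up to the
#' cap, every layer keeps at least one channel, and coupled channels
#' (residual adds, shared concat consumers) are merged by elementwise OR so
#' that tied channels share one keep decision. The achieved ratio is
#' recomputed after adjustment and the slack reported.
#'
#' @param model a `model_graph`.
#' @param table a [gamma_table()]; defaults to the model's current gammas.
#' @param ratio target global prune fraction in `[0, 1)`.
#' @param protection named numeric of per-BN maximum prune fractions, or
#'   `"default"` for a 0.5 cap on the first backbone BN and every BN feeding
#'   a detection head, or `NULL` for no caps.
#' @return a `pruning_plan`: ratio, threshold, per-BN keep masks,
#'   layer-level coupled groups, achieved ratio and slack.
#' @export
make_pruning_plan <- function(model, table = NULL, ratio,
                              protection = "default") {
  if (ratio < 0 || ratio >= 1) stop("ratio must be in [0, 1)")
  table <- table %||% gamma_table(model)
  cpl <- channel_coupling(model)
  if (!identical(names(table), cpl$bns))
    table <- table[cpl$bns]
  if (anyNA(names(table)))
    stop("gamma table does not cover this model's BN layers")
  all_g <- unlist(table, use.names = FALSE)
  C <- length(all_g)
  k <- floor(ratio * C)
  threshold <- if (k >= 1) sort(all_g)[k] else -Inf
  masks <- lapply(table, function(g) g > threshold)
  pre_drop <- 1 - sum(unlist(masks)) / C

  if (identical(protection, "default"))
    protection <- default_protected_bns(model)
  if (!is.null(protection) && length(protection)) {
    for (id in intersect(names(protection), names(masks))) {
      g <- table[[id]]
      min_keep <- ceiling((1 - protection[[id]]) * length(g))
      if (sum(masks[[id]]) < min_keep) {
        keep_idx <- order(g, decreasing = TRUE)[seq_len(min_keep)]
        m <- rep(FALSE, length(g)); m[keep_idx] <- TRUE
        masks[[id]] <- m
      }
    }
  }
  for (id in names(masks)) {
    if (!any(masks[[id]])) masks[[id]][which.max(table[[id]])] <- TRUE
  }

  # coupled merge: a channel component is kept iff any member is kept
  flat_keep <- unlist(masks, use.names = FALSE)
  roots <- vapply(seq_along(cpl$uf), function(i) uf_find(cpl$uf, i), 0L)
  keep_by_root <- tapply(flat_keep, roots, any)
  flat_keep <- as.logical(keep_by_root[as.character(roots)])
  if (length(cpl$forced))
    flat_keep[roots %in% roots[cpl$forced]] <- TRUE
  at <- 0L
  for (id in names(masks)) {
    n <- length(masks[[id]])
    masks[[id]] <- flat_keep[at + seq_len(n)]
    at <- at + n
  }

  achieved <- 1 - sum(flat_keep) / C
  structure(list(ratio = ratio, threshold = threshold, masks = masks,
                 coupled_groups = coupled_bn_groups(cpl),
                 protection = protection, achieved_ratio = achieved,
                 pre_adjust_ratio = pre_drop,
                 slack = ratio - achieved,
                 n_channels = C, n_kept = sum(flat_keep)),
            class = "pruning_plan")
}

#' @export
print.pruning_plan <- function(x, ...) {
  cat(sprintf(
    "<pruning_plan> target %.0f%% | achieved %.1f%% (%d of %d channels kept)\n",
    100 * x$ratio, 100 * x$achieved_ratio, x$n_kept, x$n_channels))
  cat(sprintf("  threshold |gamma| > %.4g | slack %.3f | %d coupled group(s)\n",
              x$threshold, x$slack, length(x$coupled_groups)))
  invisible(x)
}

#' Export a pruning plan as JSON (masks as 0/1 strings)
#' @param plan a `pruning_plan`.
#' @param path output file.
#' @export
write_plan_json <- function(plan, path) {
  doc <- list(ratio = plan$ratio, threshold = plan$threshold,
              achieved_ratio = plan$achieved_ratio, slack = plan$slack,
              masks = lapply(plan$masks, function(m)
                paste(as.integer(m), collapse = "")),
              coupled_groups = plan$coupled_groups)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a pruning plan: rebuild a compact model
#'
#' Structured surgery: each pruned BatchNorm loses its dropped channels, the
#' conv producing it loses those output filters, and every consumer loses
#' the matching input slices (concat consumers lose the correct offset
#' ranges; slices are re-indexed into kept-channel coordinates). Surviving
#' weights are copied verbatim, so a ratio-0 plan is an identity rebuild.
#'
#' @param model the `model_graph` the plan was built from.
#' @param plan a [make_pruning_plan()] result.
#' @return a compact `model_graph`.
#' @export
apply_pruning <- function(model, plan) {
  bns <- names(model$layers)[vapply(model$layers,
                                    function(l) l$kind == "bn", TRUE)]
  if (!setequal(bns, names(plan$masks)))
    stop("plan does not match model: BN layer sets differ")
  for (id in bns)
    if (length(plan$masks[[id]]) != model$layers[[id]]$channels)
      stop("plan does not match model: mask length differs at ", id)

  masks <- list(input = rep(TRUE, model$input_channels))
  out_layers <- list()
  for (ly in model$layers) {
    m_in <- masks[ly$inputs]
    new <- ly
    m_out <- switch(ly$kind,
      conv = {
        keep_out <- if (!is.null(ly$bn_id)) plan$masks[[ly$bn_id]] else
          rep(TRUE, ly$out_ch)
        keep_in <- m_in[[1]]
        new$weight <- ly$weight[, , keep_in, keep_out, drop = FALSE]
        if (!is.null(ly$bias)) new$bias <- ly$bias[keep_out]
        new$in_ch <- sum(keep_in); new$out_ch <- sum(keep_out)
        keep_out
      },
      bn = {
        keep <- plan$masks[[ly$id]]
        for (p in c("gamma", "beta", "rmean", "rvar")) new[[p]] <- ly[[p]][keep]
        new$channels <- sum(keep)
        keep
      },
      concat = unlist(m_in, use.names = FALSE),
      slice = {
        m <- m_in[[1]]
        new$ch_start <- as.integer(sum(m[seq_len(ly$ch_start - 1)]) + 1L)
        new$ch_end <- as.integer(sum(m[seq_len(ly$ch_end)]))
        m[ly$ch_start:ly$ch_end]
      },
      add = {
        eq <- vapply(m_in, function(m) identical(m, m_in[[1]]), TRUE)
        if (!all(eq))
          stop("inconsistent masks at add '", ly$id,
               "'; plan was not built with coupling analysis of this model")
        m_in[[1]]
      },
      dfl = rep(TRUE, 4L),
      m_in[[1]])
    masks[[ly$id]] <- m_out
    out_layers[[ly$id]] <- new
  }
  new_model_graph(out_layers, input_channels = model$input_channels,
                  n_classes = model$n_classes, strides = model$strides,
                  head_taps = model$head_taps,
                  head_outputs = model$head_outputs, meta = model$meta)
}
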