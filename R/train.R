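# Training engine: Adam over the graph parameters, with optional L1 sparsity
# on BatchNorm gammas and optional collaborative distillation. train_detector,
# train_sparse and distill_finetune are thin wrappers over one engine so that
# a distillation run with mode = "none" follows exactly the same trajectory
# as plain training under the same seed.

adam_init <- function(lr = 5e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, b1 = beta1, b2 = beta2, eps = eps, t = 0, m = list(), v = list())
}

adam_update <- function(st, params, grads) {
  st$t <- st$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- st$m[[nm]]; v <- st$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- st$b1 * m + (1 - st$b1) * g
    v <- st$b2 * v + (1 - st$b2) * g * g
    st$m[[nm]] <- m; st$v[[nm]] <- v
    mhat <- m / (1 - st$b1^st$t)
    vhat <- v / (1 - st$b2^st$t)
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(state = st, params = params)
}

images_to_batch <- function(images) {
  d <- dim(images[[1]]$pixels)
  x <- array(0, c(d[1], d[2], d[3], length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels
  x
}

train_engine <- function(model, images, epochs, batch_size, lr, seed,
                         lambda = 0, dconf = NULL, teacher = NULL,
                         generators = NULL, freeze = character(),
                         snapshot_gamma = FALSE, verbose = FALSE) {
  stopifnot(length(images) >= 1)
  d <- dim(images[[1]]$pixels)
  input_hw <- d[1:2]
  x_all <- images_to_batch(images)
  targets <- lapply(images, `[[`, "boxes")
  M <- length(images)

  distilling <- !is.null(dconf) && dconf$mode != "none"
  if (distilling && (is.null(teacher) || is.null(generators)))
    stop("distillation requires a teacher model and generator blocks")
  a1 <- if (is.null(dconf)) 1 else dconf$alpha1

  params <- get_params(model)
  if (distilling)
    for (i in seq_along(generators))
      for (nm in names(gp <- get_params(generators[[i]])))
        params[[paste0("gen", i, "::", nm)]] <- gp[[nm]]
  frozen <- vapply(strsplit(names(params), "/", fixed = TRUE),
                   `[[`, "", 1) %in% freeze
  opt <- adam_init(lr = lr)
  history <- NULL
  gamma_history <- list()
  bn_ids <- names(model$layers)[vapply(model$layers,
                                       function(l) l$kind == "bn", TRUE)]

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(M)
      nb <- ceiling(M / batch_size)
      comp <- matrix(0, nb, 6,
                     dimnames = list(NULL, c("lbbox", "lconf", "lcls", "lf",
                                             "ll", "penalty")))
      for (bi in seq_len(nb)) {
        sel <- ord[((bi - 1) * batch_size + 1):min(bi * batch_size, M)]
        xb <- x_all[, , , sel, drop = FALSE]
        tb <- targets[sel]
        run <- graph_run(model, list(input = xb), train = TRUE)
        model <- run$model
        det <- detection_loss(run$outs, tb, model, input_hw)
        seeds <- lapply(det$grads, function(g) a1 * g)
        lf <- 0; ll <- 0
        gen_pgrads <- list()
        if (distilling) {
          t_run <- graph_run(teacher, list(input = xb), train = FALSE,
                             keep_cache = FALSE)
          f_s <- run$outs[model$head_taps]
          f_t <- t_run$outs[teacher$head_taps]
          gruns <- lapply(seq_along(generators), function(i)
            graph_run(generators[[i]], list(input = f_s[[i]])))
          f_hat <- lapply(gruns, function(gr) gr$outs[["g2"]])
          d_hat <- lapply(f_hat, function(f) array(0, dim(f)))
          if (dconf$mode %in% c("feature", "both")) {
            fl <- feature_loss(f_hat, f_t, dconf$normalize_feature_loss,
                               with_grads = TRUE)
            lf <- fl$value
            for (i in seq_along(d_hat))
              d_hat[[i]] <- d_hat[[i]] + dconf$alpha2 * fl$grads[[i]]
          }
          if (dconf$mode %in% c("logit", "both")) {
            hl <- logit_loss(teacher, f_hat, t_run$outs, with_grads = TRUE)
            ll <- hl$value
            for (i in seq_along(d_hat))
              d_hat[[i]] <- d_hat[[i]] + dconf$alpha3 * hl$grads[[i]]
          }
          for (i in seq_along(generators)) {
            gg <- graph_grad(generators[[i]], gruns[[i]],
                             list(g2 = d_hat[[i]]), want = "input")
            for (id in names(gg$pgrads))
              for (p in names(gg$pgrads[[id]]))
                gen_pgrads[[paste0("gen", i, "::", id, "/", p)]] <-
                  gg$pgrads[[id]][[p]]
            tap <- model$head_taps[i]
            seeds[[tap]] <- if (is.null(seeds[[tap]]))
              gg$tensor_grads$input else seeds[[tap]] + gg$tensor_grads$input
          }
        }
        sg <- graph_grad(model, run, seeds)
        grads <- gen_pgrads
        for (id in names(sg$pgrads))
          for (p in names(sg$pgrads[[id]]))
            grads[[paste0(id, "/", p)]] <- sg$pgrads[[id]][[p]]
        penalty <- 0
        if (lambda > 0) {
          for (id in bn_ids) {
            gkey <- paste0(id, "/gamma")
            gam <- model$layers[[id]]$gamma
            penalty <- penalty + lambda * sum(abs(gam))
            if (!is.null(grads[[gkey]]))
              grads[[gkey]] <- grads[[gkey]] + lambda * sign(gam)
          }
        }
        grads <- grads[!(names(grads) %in% names(params)[frozen])]
        total <- a1 * (det$lbbox + det$lconf + det$lcls) + penalty +
          (if (is.null(dconf)) 0 else dconf$alpha2 * lf + dconf$alpha3 * ll)
        if (!is.finite(total))
          stop("training diverged (non-finite loss) at epoch ", ep,
               ", batch ", bi)
        up <- adam_update(opt, params, grads)
        opt <- up$state; params <- up$params
        model <- set_params(model, params[!grepl("^gen\\d+::", names(params))])
        if (distilling)
          for (i in seq_along(generators)) {
            pref <- paste0("gen", i, "::")
            sub <- params[startsWith(names(params), pref)]
            names(sub) <- substring(names(sub), nchar(pref) + 1)
            generators[[i]] <- set_params(generators[[i]], sub)
          }
        comp[bi, ] <- c(det$lbbox, det$lconf, det$lcls, lf, ll, penalty)
      }
      row <- as.data.frame(t(colMeans(comp)))
      row$epoch <- ep
      history <- rbind(history, row)
      if (snapshot_gamma)
        gamma_history[[ep]] <- gamma_table(model, epoch = ep)
      if (verbose)
        message(sprintf(
          "epoch %d: lbbox=%.4f lconf=%.4f lcls=%.4f lf=%.4g ll=%.4g pen=%.4g",
          ep, row$lbbox, row$lconf, row$lcls, row$lf, row$ll, row$penalty))
    }
  })
  list(model = model, generators = generators, history = history,
       gamma_history = gamma_history)
}

#' Train a detector on annotated images
#'
#' Plain task-loss training (bounding-box IoU, objectness BCE, class BCE)
#' with Adam on CPU. All randomness (batch order) derives from `seed`.
#'
#' @param model a trainable `model_graph` (see [build_minidet()]).
#' @param images list of `annotated_image` objects, all the same size.
#' @param epochs,batch_size,lr,seed training hyperparameters.
#' @param freeze character vector of layer ids whose parameters stay fixed.
#' @param verbose print per-epoch loss components.
#' @return list with the trained `model` and a per-epoch `history` data
#'   frame of loss components.
#' @export
train_detector <- function(model, images, epochs = 30, batch_size = 8,
                           lr = 5e-3, seed = 0L, freeze = character(),
                           verbose = FALSE) {
  r <- train_engine(model, images, epochs, batch_size, lr, seed,
                    freeze = freeze, verbose = verbose)
  r[c("model", "history")]
}

#' Sparsity training with an L1 penalty on BatchNorm gammas
#'
#' Minimizes task loss plus `lambda * sum |gamma|` over all BatchNorm scale
#' factors (the subgradient `lambda * sign(gamma)` is added to the gamma
#' gradients), pushing unimportant channels toward zero so that a global
#' threshold can prune them. Per-epoch gamma snapshots are logged.
#'
#' @inheritParams train_detector
#' @param lambda positive L1 strength (default `1e-4`, the usual
#'   network-slimming magnitude).
#' @return list with `model`, `history` (including the penalty column) and
#'   `gamma_history`, a list of [gamma_table()] snapshots.
#' @export
train_sparse <- function(model, images, lambda = 1e-4, epochs = 30,
                         batch_size = 8, lr = 5e-3, seed = 0L,
                         freeze = character(), verbose = FALSE) {
  stopifnot(lambda > 0)
  r <- train_engine(model, images, epochs, batch_size, lr, seed,
                    lambda = lambda, freeze = freeze,
                    snapshot_gamma = TRUE, verbose = verbose)
  r[c("model", "history", "gamma_history")]
}

#' Finetune a pruned student under the collaborative distillation loss
#'
#' Optimizes the student and the generative alignment blocks under the
#' weighted total loss; the teacher runs in eval mode throughout and none of
#' its parameters receive gradients. With `config$mode = "none"` this is
#' exactly plain training of the student (same trajectory for the same
#' seed).
#'
#' @param student the pruned `model_graph` to finetune.
#' @param teacher the frozen original `model_graph`.
#' @param images training images.
#' @param config a [distill_config()].
#' @param generator_seed seed for generator initialization (kept separate
#'   from the batch-order seed so the mode does not perturb batching).
#' @inheritParams train_detector
#' @return list with `model`, `generators` and `history` (five loss
#'   components per epoch).
#' @export
distill_finetune <- function(student, teacher, images, config = distill_config(),
                             epochs = 30, batch_size = 8, lr = 5e-3,
                             seed = 0L, generator_seed = NULL,
                             verbose = FALSE) {
  gens <- NULL
  if (config$mode != "none")
    gens <- build_generator(student, teacher, seed = generator_seed %||%
                              (seed + 101L))
  r <- train_engine(student, images, epochs, batch_size, lr, seed,
                    dconf = config, teacher = teacher, generators = gens,
                    verbose = verbose)
  r[c("model", "generators", "history")]
}
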