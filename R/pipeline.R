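# End-to-end compression pipeline: synthesize data, train a teacher, L1
# sparsity-train, prune, distillation-finetune, evaluate, and report, with
# every stage seeded and every artifact regenerable from config + seed.

#' Benchmark scene specification at desk scale
#'
#' The default synthetic benchmark: 64x64 scenes, five classes at enlarged
#' scale ranges so objects span several stride-8 cells, 1-2 objects per
#' image.
#' @param image_size edge length (pixels).
#' @param seed spec seed.
#' @return a [scene_spec()].
#' @export
benchmark_spec <- function(image_size = 64L, seed = 0L) {
  app <- default_appearance(5L)
  for (i in seq_along(app)) app[[i]]$scale <- c(0.18, 0.42)
  scene_spec(image_size = image_size, n_classes = 5L,
             objects_per_image = c(1L, 2L), class_appearance = app,
             seed = seed)
}

#' Run configuration for the compression pipeline
#'
#' Collects every tunable of the workflow with CPU-feasible defaults (the
#' optimizer is Adam throughout, as in full-scale training). Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param image_size,n_train,n_val benchmark size.
#' @param width,depth MiniDet multipliers.
#' @param epochs,batch_size,lr task-training hyperparameters (also used for
#'   the sparsity and finetune stages unless overridden).
#' @param lambda L1 sparsity strength.
#' @param sparse_epochs,finetune_epochs stage-specific epoch counts.
#' @param ratio pruning ratio (fraction of channels).
#' @param protection `"default"`, `NULL`, or named caps.
#' @param mode distillation mode, see [distill_config()].
#' @param alpha1,alpha2,alpha3,normalize_feature_loss distillation weights.
#' @param out_dir artifact directory (`NULL` for none).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 0L, image_size = 64L, n_train = 200L,
                       n_val = 60L, width = 0.25, depth = 1.0,
                       epochs = 30L, batch_size = 8L, lr = 5e-3,
                       lambda = 1e-4, sparse_epochs = epochs,
                       finetune_epochs = epochs, ratio = 0.5,
                       protection = "default", mode = "both",
                       alpha1 = 1.0, alpha2 = NULL, alpha3 = 2e-4,
                       normalize_feature_loss = FALSE, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v)
}

#' Compression report arithmetic
#'
#' Percent reduction is `100 * (1 - after / before)`, reported to one
#' decimal.
#' @param params_before,params_after,flops_before,flops_after accounting
#'   numbers (any consistent unit).
#' @param metrics optional data.frame of evaluation rows (model, map50,
#'   map5095, precision, recall).
#' @return a `compression_report`.
#' @export
compression_report <- function(params_before, params_after,
                               flops_before = NA, flops_after = NA,
                               metrics = NULL) {
  pct <- function(before, after)
    if (is.na(before) || is.na(after)) NA else
      round(100 * (1 - after / before), 1)
  structure(list(
    params_before = params_before, params_after = params_after,
    flops_before = flops_before, flops_after = flops_after,
    params_reduction_pct = pct(params_before, params_after),
    flops_reduction_pct = pct(flops_before, flops_after),
    metrics = metrics), class = "compression_report")
}

#' @export
print.compression_report <- function(x, ...) {
  cat("<compression_report>\n")
  cat(sprintf("  params: %s -> %s (-%.1f%%)\n",
              format(x$params_before, big.mark = ","),
              format(x$params_after, big.mark = ","),
              x$params_reduction_pct))
  if (!is.na(x$flops_before))
    cat(sprintf("  FLOPs:  %.4g -> %.4g (-%.1f%%)\n", x$flops_before,
                x$flops_after, x$flops_reduction_pct))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @rdname compression_report
#' @param report a `compression_report`.
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname compression_report
#' @export
write_report_md <- function(report, path) {
  lines <- c("# Compression report", "",
             sprintf("- parameters: %s -> %s (%.1f%% reduction)",
                     format(report$params_before, big.mark = ","),
                     format(report$params_after, big.mark = ","),
                     report$params_reduction_pct))
  if (!is.na(report$flops_before))
    lines <- c(lines, sprintf("- FLOPs: %.4g -> %.4g (%.1f%% reduction)",
                              report$flops_before, report$flops_after,
                              report$flops_reduction_pct))
  if (!is.null(report$metrics)) {
    m <- report$metrics
    lines <- c(lines, "",
               paste("|", paste(names(m), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(m)), collapse = " | "), "|"),
               vapply(seq_len(nrow(m)), function(i)
                 paste("|", paste(format(unlist(m[i, ]), digits = 4),
                                  collapse = " | "), "|"), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

eval_row <- function(name, ev) {
  data.frame(model = name, map50 = ev$map50, map5095 = ev$map5095,
             precision = ev$precision, recall = ev$recall)
}

#' Run the full compression experiment
#'
#' Executes the workflow: synthesize benchmark -> train teacher -> L1
#' sparsity-train -> global-threshold prune -> collaborative-distillation
#' finetune -> evaluate, and assembles a [compression_report()]. With
#' `ratio = 0` and `mode = "none"` the pipeline is the identity: no
#' sparsity or finetune stage runs and the report shows 0% reductions with
#' teacher-equal metrics.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return list: `teacher`, `student`, `plan`, `report`, `history` (per
#'   stage), `data` (train/val image lists).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "synth"
  res <- try({
    spec <- benchmark_spec(config$image_size, seed = config$seed)
    train_imgs <- generate_scenes(spec, config$n_train,
                                  seed = config$seed * 1000L)
    val_imgs <- generate_scenes(spec, config$n_val,
                                seed = config$seed * 1000L + 500000L,
                                prefix = "val")
    say("synth: %d train / %d val images", length(train_imgs),
        length(val_imgs))

    stage <- "train-teacher"
    teacher <- build_minidet(config$width, config$depth, 5L,
                             seed = config$seed + 1L)
    tr <- train_detector(teacher, train_imgs, epochs = config$epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = config$seed + 2L, verbose = verbose)
    teacher <- tr$model
    ev_teacher <- evaluate_detector(teacher, val_imgs)
    say("teacher: mAP@0.5 = %.3f", ev_teacher$map50)

    history <- list(teacher = tr$history)
    plan <- NULL
    if (config$ratio > 0) {
      stage <- "train-sparse"
      sp <- train_sparse(teacher, train_imgs, lambda = config$lambda,
                         epochs = config$sparse_epochs,
                         batch_size = config$batch_size, lr = config$lr,
                         seed = config$seed + 3L, verbose = verbose)
      history$sparse <- sp$history
      stage <- "prune"
      plan <- make_pruning_plan(sp$model, ratio = config$ratio,
                                protection = config$protection)
      student <- apply_pruning(sp$model, plan)
      say("prune: %.1f%% channels dropped (target %.0f%%)",
          100 * plan$achieved_ratio, 100 * config$ratio)
    } else {
      student <- teacher
    }
    ev_pruned <- evaluate_detector(student, val_imgs)

    if (config$ratio > 0 || config$mode != "none") {
      stage <- "distill"
      dcfg <- distill_config(mode = config$mode, alpha1 = config$alpha1,
                             alpha2 = config$alpha2, alpha3 = config$alpha3,
                             normalize_feature_loss =
                               config$normalize_feature_loss)
      ft <- distill_finetune(student, teacher, train_imgs, config = dcfg,
                             epochs = config$finetune_epochs,
                             batch_size = config$batch_size, lr = config$lr,
                             seed = config$seed + 4L, verbose = verbose)
      student <- ft$model
      history$finetune <- ft$history
    }
    stage <- "eval"
    ev_student <- evaluate_detector(student, val_imgs)
    say("student: mAP@0.5 = %.3f", ev_student$map50)

    hw <- c(config$image_size, config$image_size)
    report <- compression_report(
      count_params(teacher), count_params(student),
      count_flops(teacher, hw), count_flops(student, hw),
      metrics = rbind(eval_row("teacher", ev_teacher),
                      eval_row("pruned", ev_pruned),
                      eval_row("student", ev_student)))

    out <- list(teacher = teacher, student = student, plan = plan,
                report = report, history = history,
                data = list(train = train_imgs, val = val_imgs))
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_run_config(config, file.path(config$out_dir, "config.yaml"))
      save_checkpoint(teacher, file.path(config$out_dir, "teacher.json"))
      save_checkpoint(student, file.path(config$out_dir, "student.json"))
      if (!is.null(plan))
        write_plan_json(plan, file.path(config$out_dir, "plan.json"))
      write_report_json(report, file.path(config$out_dir, "report.json"))
      write_report_md(report, file.path(config$out_dir, "report.md"))
    }
    out
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop("pipeline failed at stage '", stage, "': ",
         attr(res, "condition")$message)
  res
}

#' Run the ablation grid
#'
#' One row per (mode, ratio, seed): trains a teacher and sparsity model per
#' seed, then prunes at each ratio and finetunes under each distillation
#' mode. Mirrors the module/ratio ablation structure of the method at desk
#' scale.
#'
#' @param config base [run_config()] (its `ratio`/`mode` are overridden).
#' @param modes subset of none/feature/logit/both.
#' @param ratios pruning ratios.
#' @param seeds integer vector (>= 1 seed).
#' @param verbose print progress.
#' @return data.frame with mode, ratio, seed, params, flops, map50,
#'   map5095, precision, recall.
#' @export
run_ablation_grid <- function(config, modes = c("none", "feature", "logit",
                                                "both"),
                              ratios = 0.5, seeds = 0:2, verbose = FALSE) {
  stopifnot(length(seeds) >= 1)
  modes <- match.arg(modes, c("none", "feature", "logit", "both"),
                     several.ok = TRUE)
  rows <- list()
  for (seed in seeds) {
    spec <- benchmark_spec(config$image_size, seed = seed)
    train_imgs <- generate_scenes(spec, config$n_train, seed = seed * 1000L)
    val_imgs <- generate_scenes(spec, config$n_val,
                                seed = seed * 1000L + 500000L, prefix = "val")
    teacher <- build_minidet(config$width, config$depth, 5L, seed = seed + 1L)
    teacher <- train_detector(teacher, train_imgs, epochs = config$epochs,
                              batch_size = config$batch_size, lr = config$lr,
                              seed = seed + 2L)$model
    sparse <- train_sparse(teacher, train_imgs, lambda = config$lambda,
                           epochs = config$sparse_epochs,
                           batch_size = config$batch_size, lr = config$lr,
                           seed = seed + 3L)$model
    for (ratio in ratios) {
      student0 <- if (ratio > 0)
        apply_pruning(sparse, make_pruning_plan(sparse, ratio = ratio,
                                                protection = config$protection))
        else teacher
      for (mode in modes) {
        dcfg <- distill_config(mode = mode, alpha1 = config$alpha1,
                               alpha2 = config$alpha2, alpha3 = config$alpha3,
                               normalize_feature_loss =
                                 config$normalize_feature_loss)
        st <- distill_finetune(student0, teacher, train_imgs, config = dcfg,
                               epochs = config$finetune_epochs,
                               batch_size = config$batch_size,
                               lr = config$lr, seed = seed + 4L)$model
        ev <- evaluate_detector(st, val_imgs)
        if (verbose)
          message(sprintf("seed %d ratio %.2f mode %-7s mAP@0.5 %.3f",
                          seed, ratio, mode, ev$map50))
        rows[[length(rows) + 1]] <- data.frame(
          mode = mode, ratio = ratio, seed = seed,
          params = count_params(st),
          flops = count_flops(st, c(config$image_size, config$image_size)),
          map50 = ev$map50, map5095 = ev$map5095,
          precision = ev$precision, recall = ev$recall)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate an ablation grid by mode and ratio
#' @param grid result of [run_ablation_grid()].
#' @return data.frame of means and standard deviations.
#' @export
aggregate_grid <- function(grid) {
  agg <- function(f) stats::aggregate(
    grid[c("map50", "map5095", "precision", "recall")],
    by = grid[c("mode", "ratio")], FUN = f)
  m <- agg(mean); s <- agg(stats::sd)
  names(s)[-(1:2)] <- paste0(names(s)[-(1:2)], "_sd")
  merge(m, s, by = c("mode", "ratio"))
}
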