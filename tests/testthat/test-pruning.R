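# Channel scoring, sparsity machinery, plan construction and surgery.

test_that("bn_transform follows its definition and fixed points", {
  g <- c(2); b <- c(0.5); mu <- c(1); s2 <- c(4)
  expect_equal(bn_transform(3, g, b, mu, s2, eps = 0), 2.5)
  expect_equal(bn_transform(mu, g, b, mu, s2), b)
  z <- rnorm(5)
  expect_equal(bn_transform(z, rep(1, 5), rep(0, 5), rep(0, 5), rep(1, 5),
                            eps = 0), z)
  expect_error(bn_transform(1:3, g, b, mu, s2), "mismatch")
  expect_error(bn_transform(1, g, b, mu, -1), "nonnegative")
})

test_that("channel scores normalize globally and use absolute values", {
  g <- chain_graph(c(3L, 2L), gammas = list(c(2, 1, 1), c(1, -1)))
  tab <- gamma_table(g)
  expect_equal(unname(tab[["c2.bn"]]), c(1, 1))  # |-1| = 1
  sc <- channel_scores(tab)
  expect_equal(sum(sc$flat), 1, tolerance = 1e-12)
  expect_true(all(sc$flat >= 0))
  one <- channel_scores(structure(list(a = c(2, 1, 1)), class = "gamma_table"))
  expect_equal(unname(one$scores$a), c(0.5, 0.25, 0.25))
  eq <- channel_scores(structure(list(a = rep(3, 8)), class = "gamma_table"))
  expect_equal(unname(eq$scores$a), rep(1 / 8, 8))
  expect_error(channel_scores(structure(list(a = c(0, 0)),
                                        class = "gamma_table")), "degenerate")
})

test_that("sparsity penalty is lambda times the total |gamma|", {
  g <- chain_graph(c(2L, 1L), gammas = list(c(1, -2), 0.5))
  expect_equal(sparsity_penalty(g, 0.01), 0.035)
  expect_equal(sparsity_penalty(g, 0), 0)
  z <- chain_graph(c(2L,  1L), gammas = list(c(0, 0), 0))
  expect_equal(sparsity_penalty(z, 5), 0)
})

test_that("sensitivity report computes per-layer mean |gamma|", {
  g <- chain_graph(c(4L, 3L, 2L),
                   gammas = list(rep(1, 4), c(0, 0, 3), c(2, 4)))
  rep_ <- sensitivity_report(gamma_table(g))
  expect_equal(nrow(rep_), 3)  # one row per prunable BN
  expect_equal(rep_$mean_abs_gamma, c(1, 1, 3))
  expect_true(all(rep_$mean_abs_gamma >= 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_sensitivity_csv(rep_, f)
  expect_equal(read.csv(f)$mean_abs_gamma, c(1, 1, 3))
  g2 <- withr::local_tempfile(fileext = ".csv")
  write_gamma_csv(gamma_table(g), g2)
  tab <- read.csv(g2)
  expect_equal(nrow(tab), 9)
  expect_equal(tab$abs_gamma[5:7], c(0, 0, 3))
})

test_that("pruning plan: toy quantile, ratio 0, forced single channel", {
  g <- chain_graph(c(4L), gammas = list(c(0.9, 0.5, 0.1, 0.05)))
  p <- make_pruning_plan(g, ratio = 0.5, protection = NULL)
  expect_equal(unname(p$masks[["c1.bn"]]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(p$achieved_ratio, 0.5)

  p0 <- make_pruning_plan(g, ratio = 0, protection = NULL)
  expect_true(all(unlist(p0$masks)))
  expect_equal(p0$achieved_ratio, 0)

  # a layer whose gammas all fall below the threshold keeps its largest
  g2 <- chain_graph(c(4L, 4L),
                    gammas = list(c(0.9, 0.8, 0.7, 0.6),
                                  c(0.01, 0.02, 0.03, 0.04)))
  p2 <- make_pruning_plan(g2, ratio = 0.5, protection = NULL)
  expect_equal(unname(p2$masks[["c2.bn"]]), c(FALSE, FALSE, FALSE, TRUE))
  expect_true(all(p2$masks[["c1.bn"]]))

  expect_error(make_pruning_plan(g, ratio = 1), "ratio")
})

test_that("pre-adjustment drop fraction tracks the requested ratio within 1/C", {
  for (seed in 1:10) {
    gam <- pk$with_seed(seed, list(runif(8), runif(5), runif(11)))
    g <- chain_graph(c(8L, 5L, 11L), gammas = gam, seed = seed)
    C <- 24
    for (ratio in c(0.2, 0.5, 0.8)) {
      p <- make_pruning_plan(g, ratio = ratio, protection = NULL)
      expect_lte(abs(p$pre_adjust_ratio - ratio), 1 / C + 1e-12)
    }
  }
})

test_that("pruning is monotone in the ratio (threshold nesting and params)", {
  m <- randomize_bn(build_minidet(0.25, 1, 5, seed = 3), seed = 13)
  tab <- gamma_table(m)
  flat <- unlist(tab)
  prev_params <- Inf
  prev_dropped <- NULL
  for (ratio in c(0.1, 0.3, 0.5, 0.7)) {
    p <- make_pruning_plan(m, ratio = ratio)
    params <- count_params(apply_pruning(m, p))
    expect_lte(params, prev_params)
    prev_params <- params
    dropped <- which(flat <= p$threshold)  # pre-coupling drop set
    if (!is.null(prev_dropped)) expect_true(all(prev_dropped %in% dropped))
    prev_dropped <- dropped
  }
})

test_that("surgery: ratio-0 rebuild and zeroed-channel removal are exact", {
  m <- randomize_bn(build_minidet(0.5, 1, 5, seed = 11), seed = 9)
  xs <- pk$with_seed(21, lapply(1:10, function(i)
    array(runif(64 * 64 * 3), c(64, 64, 3, 1))))
  hids <- head_output_ids(m)

  m0 <- apply_pruning(m, make_pruning_plan(m, ratio = 0))
  expect_equal(count_params(m0), count_params(m))
  for (x in xs[1:3])
    expect_lt(max_out_diff(forward(m, x, taps = hids),
                           forward(m0, x, taps = hids)), 1e-6)

  plan <- make_pruning_plan(m, ratio = 0.4)
  mz <- m
  for (id in names(plan$masks)) {
    drop <- !plan$masks[[id]]
    mz$layers[[id]]$gamma[drop] <- 0
    mz$layers[[id]]$beta[drop] <- 0
  }
  mp <- apply_pruning(mz, plan)
  expect_lt(count_params(mp), count_params(m))
  expect_gt(plan$achieved_ratio, 0)
  for (x in xs)
    expect_lt(max_out_diff(forward(mz, x, taps = hids),
                           forward(mp, x, taps = hids)), 1e-5)

  # plan/model mismatch is rejected
  other <- build_minidet(0.25, 1, 5, seed = 12)
  expect_error(apply_pruning(other, plan), "does not match")
})

test_that("coupled groups tie residual partners and masks stay identical", {
  m <- randomize_bn(build_minidet(0.25, 1, 5, seed = 4), seed = 5)
  plan <- make_pruning_plan(m, ratio = 0.6)
  groups <- plan$coupled_groups
  expect_gt(length(groups), 0)
  # every residual stage couples the stage-input BN with its block cv2 BN
  expect_true(any(vapply(groups, function(g)
    all(c("d2.bn", "s2.b1.cv2.bn") %in% g), TRUE)))
  for (g in groups) {
    ms <- plan$masks[g]
    for (i in seq_along(ms)[-1]) expect_identical(ms[[i]], ms[[1]])
  }
  # every layer keeps at least one channel; slack is reported
  expect_true(all(vapply(plan$masks, any, TRUE)))
  expect_gte(plan$slack, 0)
  f <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, f)
  doc <- jsonlite::read_json(f)
  expect_match(doc$masks[[1]], "^[01]+$")
})

test_that("protection caps floor the kept channels of sensitive layers", {
  m <- randomize_bn(build_minidet(0.25, 1, 5, seed = 6), seed = 7)
  # force tiny gammas on a protected head BN so raw thresholding would
  # remove almost everything
  bn <- "head_p3.cls_stem.bn"
  nch <- m$layers[[bn]]$channels
  m$layers[[bn]]$gamma <- rep(1e-4, nch) * seq_len(nch)
  plan <- make_pruning_plan(m, ratio = 0.7, protection = "default")
  expect_gte(sum(plan$masks[[bn]]), ceiling(0.5 * nch))
  # and the kept ones are the top-|gamma| channels (gammas are increasing)
  kept <- which(plan$masks[[bn]])
  expect_true(all(seq(nch - ceiling(0.5 * nch) + 1, nch) %in% kept))
  plain <- make_pruning_plan(m, ratio = 0.7, protection = NULL)
  expect_lte(sum(plain$masks[[bn]]), sum(plan$masks[[bn]]))
})

test_that("L1 training shrinks gammas: paired runs and planted redundancy", {
  pre <- pretrained_small()
  imgs <- small_train_images()
  plain <- train_detector(pre, imgs, epochs = 30, batch_size = 8,
                          seed = 10)$model
  sparse <- train_sparse(pre, imgs, lambda = 2e-3, epochs = 30,
                         batch_size = 8, seed = 10)
  n_small <- function(mm) sum(unlist(gamma_table(mm)) < 0.01)
  expect_gt(n_small(sparse$model), n_small(plain))
  # per-epoch snapshots logged, penalty nonnegative each epoch
  expect_length(sparse$gamma_history, 30)
  expect_true(all(sparse$history$penalty >= 0))

  # a channel disconnected from the input by construction decays to ~0
  mz <- pre
  w <- mz$layers[["s2.b1.cv1.conv"]]$weight
  w[, , , 3:4] <- 0
  mz$layers[["s2.b1.cv1.conv"]]$weight <- w
  init_g <- abs(mz$layers[["s2.b1.cv1.bn"]]$gamma[3:4])
  r <- train_sparse(mz, imgs, lambda = 1e-3, epochs = 25, batch_size = 8,
                    seed = 11, freeze = "s2.b1.cv1.conv")
  fin_g <- abs(r$model$layers[["s2.b1.cv1.bn"]]$gamma[3:4])
  expect_true(all(fin_g < 0.1 * init_g))
})
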