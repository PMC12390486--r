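# Generative feature distillation, logit distillation through the frozen
# teacher head, and the weighted total loss.

test_that("generator preserves spatial size, maps channels, and can be identity", {
  teacher <- fixture("minidet_small", build_minidet(0.25, 1, 5, seed = 2))
  # pruned student has fewer channels at every tap
  student <- apply_pruning(randomize_bn(teacher, 30),
                           make_pruning_plan(randomize_bn(teacher, 30),
                                             ratio = 0.5))
  gens <- build_generator(student, teacher, seed = 1)
  x <- pk$with_seed(2, array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  fs <- forward(student, x, taps = student$head_taps)
  fhat <- generator_forward(gens, fs)
  ft <- forward(teacher, x, taps = teacher$head_taps)
  for (i in 1:3) expect_identical(dim(fhat[[i]]), dim(ft[[i]]))

  # identity construction: equal channels, identity kernels, nonneg input
  gid <- build_generator(teacher, teacher, seed = 3)
  for (i in seq_along(gid)) {
    ct <- gid[[i]]$layers$g1$out_ch
    w1 <- array(0, c(3, 3, ct, ct)); for (c in seq_len(ct)) w1[2, 2, c, c] <- 1
    gid[[i]]$layers$g1$weight <- w1
    gid[[i]]$layers$g2$weight <- w1
    gid[[i]]$layers$g1$bias <- numeric(ct)
    gid[[i]]$layers$g2$bias <- numeric(ct)
  }
  f_nonneg <- lapply(ft, function(f) pmax(f, 0) + 0 * f)
  fid <- generator_forward(gid, f_nonneg)
  expect_lt(max_out_diff(fid, f_nonneg), 1e-12)
})

test_that("feature loss: zero case, element conventions, tap averaging, scale safety", {
  a <- array(1, c(2, 2, 1, 1)); b <- array(0, c(2, 2, 1, 1))
  expect_equal(feature_loss(list(a), list(a))$value, 0)
  expect_equal(feature_loss(list(a), list(b))$value, 4)               # literal
  expect_equal(feature_loss(list(a), list(b), normalize = TRUE)$value, 1)
  t1 <- array(sqrt(2 / 4), c(2, 2, 1, 1)); t2 <- array(sqrt(6 / 16), c(4, 4, 1, 1))
  z1 <- array(0, c(2, 2, 1, 1)); z2 <- array(0, c(4, 4, 1, 1))
  expect_equal(feature_loss(list(t1, t2), list(z1, z2))$value, 4)     # (2+6)/2
  # per-element normalization is invariant to spatial size at fixed error
  c1 <- array(0.3, c(4, 4, 2, 1)); c2 <- array(0.3, c(8, 8, 2, 1))
  expect_equal(feature_loss(list(c1), list(0 * c1), normalize = TRUE)$value,
               feature_loss(list(c2), list(0 * c2), normalize = TRUE)$value)
  expect_error(feature_loss(list(a), list(z2)), "shapes differ")
})

test_that("feature-loss gradients match finite differences", {
  pk$with_seed(4, {
    fh <- list(array(rnorm(8), c(2, 2, 2, 1)))
    ft <- list(array(rnorm(8), c(2, 2, 2, 1)))
  })
  for (norm in c(FALSE, TRUE)) {
    fl <- feature_loss(fh, ft, norm, with_grads = TRUE)
    eps <- 1e-6
    fh2 <- fh; fh2[[1]][3] <- fh2[[1]][3] + eps
    fd <- (feature_loss(fh2, ft, norm)$value - fl$value) / eps
    expect_equal(fl$grads[[1]][3], fd, tolerance = 1e-4)
  }
})

test_that("logit loss vanishes iff head inputs match and follows batch-mean arithmetic", {
  teacher <- randomize_bn(fixture("minidet_small",
                                  build_minidet(0.25, 1, 5, seed = 2)), 40)
  x <- pk$with_seed(5, array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2)))
  t_run <- pk$graph_run(teacher, list(input = x), keep_cache = FALSE)
  ft <- t_run$outs[teacher$head_taps]
  ll0 <- logit_loss(teacher, ft, t_run$outs)
  expect_equal(ll0$value, 0)
  fh <- lapply(ft, function(f) f + 0.1)
  expect_gt(logit_loss(teacher, fh, t_run$outs)$value, 0)

  # batch-mean arithmetic on a one-conv "head": per-sample norms 1 and 3
  conv <- pk$mk_conv("h", "input", 2L, 2L, k = 1L, bias = TRUE, init = "zero")
  for (c in 1:2) conv$weight[1, 1, c, c] <- 1
  stub <- pk$new_model_graph(list(conv), input_channels = 2L)
  stub$head_taps <- "input"
  stub$head_outputs <- list(p = list(cls = "h"))
  fhat <- array(0, c(1, 1, 2, 2))
  fhat[1, 1, , 1] <- c(1, 0); fhat[1, 1, , 2] <- c(1, sqrt(2))
  tout <- list(h = array(0, c(1, 1, 2, 2)))
  expect_equal(logit_loss(stub, list(fhat), tout)$value, 2)
})

test_that("logit-loss gradients reach the generated features, never the teacher", {
  teacher <- randomize_bn(fixture("minidet_small",
                                  build_minidet(0.25, 1, 5, seed = 2)), 41)
  x <- pk$with_seed(6, array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  t_run <- pk$graph_run(teacher, list(input = x), keep_cache = FALSE)
  ft <- t_run$outs[teacher$head_taps]
  fh <- lapply(ft, function(f) f * 0.9)
  hl <- logit_loss(teacher, fh, t_run$outs, with_grads = TRUE)
  eps <- 1e-5
  fh2 <- fh; fh2[[1]][10] <- fh2[[1]][10] + eps
  fd <- (logit_loss(teacher, fh2, t_run$outs)$value - hl$value) / eps
  expect_equal(hl$grads[[1]][10], fd, tolerance = 1e-3)
})

test_that("total loss weights, zeroes by mode, and rejects bad input", {
  cfg <- distill_config(mode = "both", alpha1 = 1, alpha2 = 0.1, alpha3 = 0.2)
  expect_equal(total_loss(1, 0.5, 0.5, 10, 4, cfg), 3.8)
  cfg0 <- distill_config(mode = "both", alpha1 = 2, alpha2 = 0, alpha3 = 0)
  expect_equal(total_loss(1, 0.5, 0.5, 99, 99, cfg0), 4)
  expect_equal(total_loss(1, 1, 1, 10, 4,
                          distill_config("feature", alpha2 = 1, alpha3 = 1)),
               13)
  expect_equal(total_loss(1, 1, 1, 10, 4,
                          distill_config("logit", alpha2 = 1, alpha3 = 1)), 7)
  expect_equal(total_loss(1, 1, 1, 10, 4,
                          distill_config("none", alpha2 = 1, alpha3 = 1)), 3)
  expect_error(distill_config(alpha1 = -1), "nonnegative")
  expect_error(total_loss(1, NaN, 0, 0, 0, cfg), "non-finite")
})

test_that("mode=none finetune follows the plain-training trajectory bitwise", {
  imgs <- tiny_images(16, seed = 60)
  m <- build_minidet(0.25, 1, 5, seed = 20)
  teacher <- fixture("minidet_small", build_minidet(0.25, 1, 5, seed = 2))
  a <- train_detector(m, imgs, epochs = 3, batch_size = 8, seed = 7)$model
  b <- distill_finetune(m, teacher, imgs,
                        config = distill_config("none"), epochs = 3,
                        batch_size = 8, seed = 7)$model
  expect_identical(get_params(a), get_params(b))
})

test_that("teacher is bit-identical after distillation and losses are logged", {
  imgs <- tiny_images(16, seed = 61)
  teacher <- randomize_bn(fixture("minidet_small",
                                  build_minidet(0.25, 1, 5, seed = 2)), 42)
  student <- apply_pruning(teacher, make_pruning_plan(teacher, ratio = 0.4))
  before <- get_params(teacher)
  r <- distill_finetune(student, teacher, imgs,
                        config = distill_config("both"), epochs = 2,
                        batch_size = 8, seed = 8)
  expect_identical(get_params(teacher), before)
  h <- r$history
  expect_equal(nrow(h), 2)
  expect_true(all(is.finite(unlist(h[c("lbbox", "lconf", "lcls", "lf",
                                       "ll")]))))
  expect_true(all(h$lf > 0) && all(h$ll > 0))
})
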