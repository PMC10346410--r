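test_that("SE squeeze averages each channel over space", {
  u <- array(0, c(2, 2, 3))
  u[, , 1] <- 5
  u[, , 2] <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(se_squeeze(u), c(5, 2.5, 0))
  expect_error(se_squeeze(array(Inf, c(2, 2, 1))), "finite")
})

test_that("SE excitation is a sigmoid-bounded bottleneck", {
  z <- c(0.3, -1.2)
  expect_equal(se_excite(z, matrix(0, 2, 2), matrix(0, 2, 2)), c(0.5, 0.5))
  expect_equal(se_excite(c(0, 0), diag(2), diag(2)), c(0.5, 0.5))
  set.seed(1)
  s <- se_excite(rnorm(8), matrix(rnorm(16), 2, 8), matrix(rnorm(16), 8, 2))
  expect_true(all(s > 0 & s < 1))
  expect_error(se_excite(z, matrix(0, 2, 3), matrix(0, 2, 2)), "shape")
})

test_that("SE scaling multiplies channels by their gates", {
  set.seed(2)
  u <- array(rnorm(24), c(2, 4, 3))
  expect_equal(se_scale(u, c(1, 1, 1)), u)
  expect_equal(se_scale(u, c(0, 0, 0)), u * 0)
  half <- se_scale(u, c(0.5, 1, 2))
  expect_equal(half[, , 1], u[, , 1] * 0.5)
  expect_equal(half[, , 3], u[, , 3] * 2)
  expect_error(se_scale(u, c(1, 1)), "length")
})

test_that("RAM with zero weights is the exact identity", {
  set.seed(3)
  x <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  expect_identical(ram_forward(x), x)
  expect_error(ram_forward(array(NA_real_, c(2, 2, 1))), "finite")
})

test_that("RAM attention gates stay in (0, 1)", {
  set.seed(4)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4))
  p <- branchmorph:::ram_init(4L)
  rc <- branchmorph:::ram_fw(x, p)
  expect_true(all(rc$A > 0 & rc$A < 1))
  # a constant channel has zero variance-pool statistic
  xc <- x; xc[, , 2] <- 3
  f <- xc * (xc > 0)
  expect_equal(stats::var(as.vector(f[, , 2])) * 0, 0)
})

test_that("config validation rejects indivisible SE reduction", {
  expect_error(unet_config(enc_channels = c(6L, 12L), enc_convs = c(1L, 1L),
                           se_reduction = 4L), "divide")
  expect_error(unet_config(num_classes = 1L))
})

test_that("forward pass yields normalized per-pixel class probabilities", {
  net <- small_unet(seed = 5)
  for (hw in list(c(48L, 48L), c(50L, 37L))) {   # incl. non-multiple of 4
    x <- with_seed(6, array(runif(prod(hw) * 3), c(hw, 3L)))
    pr <- unet_forward(net, x)$probs
    expect_equal(dim(pr), c(hw, 3L))
    expect_lt(max(abs(apply(pr, c(1, 2), sum) - 1)), 1e-6)
  }
  mask <- predict_mask(net, with_seed(7, array(runif(48 * 48 * 3), c(48, 48, 3))))
  expect_true(all(mask %in% 0:2))
  expect_error(predict_mask(net, array(0, c(16, 16, 4))), "in_channels")
})

test_that("forcing SE gates to one reproduces the SE-free network exactly", {
  net <- small_unet(seed = 8)
  net_free <- small_unet(seed = 99, use_se = FALSE)
  shared <- intersect(names(net_free$params), names(net$params))
  net_free$params[shared] <- net$params[shared]
  x <- with_seed(9, array(runif(32 * 32 * 3), c(32, 32, 3)))
  expect_identical(unet_forward(net, x, se_identity = TRUE)$probs,
                   unet_forward(net_free, x)$probs)
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- unet_config(in_channels = 2L, num_classes = 3L,
                     enc_channels = c(4L, 8L), enc_convs = c(1L, 1L),
                     se_reduction = 2L)
  net <- build_unet(cfg, seed = 7)
  x <- with_seed(8, array(runif(8 * 8 * 2), c(8, 8, 2)))
  mk <- with_seed(9, matrix(sample(0:2, 64, TRUE), 8, 8))
  fwd <- unet_forward(net, x, want_cache = TRUE)
  lg <- branchmorph:::ce_loss_grad(fwd$probs_full, mk)
  g <- branchmorph:::unet_backward(net, fwd, lg$dlogits)
  lossfn <- function(n) {
    f <- unet_forward(n, x, want_cache = TRUE)
    branchmorph:::ce_loss_grad(f$probs_full, mk)$loss
  }
  set.seed(10)
  for (nm in sample(names(net$params), 12)) {
    k <- sample(length(net$params[[nm]]), 1)
    eps <- 1e-5
    np <- net; np$params[[nm]][k] <- np$params[[nm]][k] + eps
    nn <- net; nn$params[[nm]][k] <- nn$params[[nm]][k] - eps
    num <- (lossfn(np) - lossfn(nn)) / (2 * eps)
    expect_lt(abs(num - g[[nm]][k]) / max(1e-6, abs(num) + abs(g[[nm]][k])),
              1e-4)
  }
})

test_that("training overfits a tiny set, deterministically, with freezing", {
  scenes <- lapply(1:4, function(i)
    render_scene(with_seed(i, random_scene_spec(h = 64L, w = 64L,
                                                n_branches = 2L,
                                                lengths = c(20L, 40L),
                                                widths = c(2L, 5L),
                                                seed = i))))
  imgs <- lapply(scenes, `[[`, "image")
  msks <- lapply(scenes, `[[`, "mask")
  net <- small_unet(seed = 1)

  expect_error(train_unet(net, list(), list()), "empty")
  badmask <- msks; badmask[[1]][1, 1] <- 7L
  expect_error(train_unet(net, imgs, badmask), "num_classes")

  tc <- train_config(lr0 = 1e-3, epochs = 12L, freeze_epochs = 4L,
                     batch_size = 4L, seed = 1L)
  enc_before <- net$params[["enc1_conv1_W"]]
  t1 <- train_unet(net, imgs, msks, tc)
  expect_length(t1$loss_history, 12L)
  expect_lt(t1$loss_history[12], t1$loss_history[1])

  t2 <- train_unet(net, imgs, msks, tc)
  expect_identical(t1$loss_history, t2$loss_history)

  tf <- train_unet(net, imgs, msks,
                   train_config(lr0 = 1e-3, epochs = 2L, freeze_epochs = 2L,
                                batch_size = 4L, seed = 1L))
  expect_identical(tf$params[["enc1_conv1_W"]], enc_before)
  expect_false(identical(tf$params[["dec1_conv1_W"]],
                         net$params[["dec1_conv1_W"]]))

  # batched prediction preserves order
  preds <- predict_mask(t1, imgs)
  expect_length(preds, 4L)
  expect_identical(preds[[2]], predict_mask(t1, imgs[[2]]))
})

test_that("checkpoints round-trip through disk", {
  net <- small_unet(seed = 13)
  x <- with_seed(14, array(runif(32 * 32 * 3), c(32, 32, 3)))
  ck <- file.path(tempdir(), "bm_ckpt.rds")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(predict_mask(net2, x), predict_mask(net, x))
})
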