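# small shared setup for network tests
tiny_config <- pairnet_config(n_blocks = 1, n_channels = 4)

random_input <- function(L, Cin, seed = 1) {
  set.seed(seed)
  x <- array(rnorm(L * L * Cin), c(L, L, Cin))
  for (c in seq_len(Cin)) x[, , c] <- (x[, , c] + t(x[, , c])) / 2
  x
}

test_that("masked normalizations match direct R statistics", {
  set.seed(21)
  L <- 9
  x <- array(rnorm(L * L * 3), c(L, L, 3))
  mask <- separation_mask(L)
  eps <- 1e-5
  # instance normalization: per-channel masked mean/sd (population)
  got <- instance_normalize(x, mask, epsilon = eps)
  for (c in 1:3) {
    v <- x[, , c][mask]
    mu <- mean(v)
    sd_ <- sqrt(mean((v - mu)^2))
    expect_equal(got[, , c], (x[, , c] - mu) / (sd_ + eps),
                 tolerance = 1e-12)
  }
  # row normalization: per (row, channel) over masked-in columns
  got_r <- row_normalize(x, mask, epsilon = eps)
  for (c in 1:3) for (i in 1:L) {
    v <- x[i, mask[i, ], c]
    mu <- mean(v)
    sd_ <- sqrt(mean((v - mu)^2))
    expect_equal(got_r[i, , c], (x[i, , c] - mu) / (sd_ + eps),
                 tolerance = 1e-12)
  }
})

test_that("normalizations map constant channels to zero pre-affine", {
  L <- 8
  x <- array(2.5, c(L, L, 2))
  mask <- separation_mask(L)
  for (f in list(row_normalize, column_normalize, instance_normalize)) {
    expect_equal(max(abs(f(x, mask))), 0, tolerance = 1e-12)
  }
  # affine parameters apply after standardization
  out <- instance_normalize(x, mask, gain = c(2, 2), bias = c(0.5, -1))
  expect_equal(unique(as.vector(out[, , 1])), 0.5)
  expect_equal(unique(as.vector(out[, , 2])), -1)
})

test_that("column normalization is row normalization of the transpose", {
  x <- random_input(10, 3, seed = 22)
  x[, , 2] <- x[, , 2] + matrix(rnorm(100), 10, 10)  # break symmetry
  mask <- separation_mask(10)
  a <- column_normalize(x, mask)
  xt <- x
  for (c in 1:3) xt[, , c] <- t(x[, , c])
  b <- row_normalize(xt, mask)
  for (c in 1:3) expect_equal(a[, , c], t(b[, , c]), tolerance = 1e-12)
})

test_that("groups with fewer than 2 valid entries pass through", {
  L <- 5
  x <- array(rnorm(L * L), c(L, L, 1))
  mask <- matrix(FALSE, L, L)   # nothing valid anywhere
  expect_equal(row_normalize(x, mask), x, tolerance = 1e-12)
  expect_equal(instance_normalize(x, mask), x, tolerance = 1e-12)
})

test_that("zero-weight residual block is the identity", {
  x <- random_input(9, 4, seed = 23)
  out <- resnet_block(x, resnet_block_params(tiny_config),
                      config = tiny_config)
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("initial network predicts 0.5 on masked pairs", {
  # W2 of every block is zero and the head bias is zero, so initial
  # logits are driven only by the head weights acting on normalized
  # features -- with wout zeroed the output is exactly 0.5 on the mask
  x <- random_input(10, 5, seed = 24)
  params <- pairnet_init(tiny_config, 5, seed = 1)
  lay <- betapair:::pairnet_layout(5, 4, 1)
  params[lay$off_wout + seq_len(4 + 1)] <- 0
  probs <- betapair:::pairnet_forward_cpp(params, x, separation_mask(10),
                                          betapair:::cpp_cfg(tiny_config, 5))
  m <- separation_mask(10)
  expect_equal(unique(probs[m]), 0.5, tolerance = 1e-12)
  expect_true(all(probs[!m] == 0))
})

test_that("forward pass is symmetric and masked", {
  x <- random_input(12, 5, seed = 25)
  params <- pairnet_init(tiny_config, 5, seed = 2)
  probs <- betapair:::pairnet_forward_cpp(params, x, separation_mask(12),
                                          betapair:::cpp_cfg(tiny_config, 5))
  expect_equal(probs, t(probs), tolerance = 1e-12)
  expect_true(all(probs >= 0 & probs <= 1))
  expect_true(all(probs[!separation_mask(12)] == 0))
})

test_that("analytic gradients match finite differences", {
  set.seed(26)
  L <- 8; Cin <- 5
  x <- random_input(L, Cin, seed = 26)
  mask <- separation_mask(L)
  y <- matrix(0, L, L)
  y[1, 5] <- y[5, 1] <- 1
  y[2, 8] <- y[8, 2] <- 1
  cfg2 <- pairnet_config(n_blocks = 2, n_channels = 4)
  params <- pairnet_init(cfg2, Cin, seed = 3)
  # perturb all parameters away from special values (zeros, ones)
  params <- params + rnorm(length(params), 0, 0.05)
  ccfg <- betapair:::cpp_cfg(cfg2, Cin)
  lg <- betapair:::pairnet_loss_grad_cpp(params, x, mask, y, ccfg, 1.5)
  eps <- 1e-6
  idxs <- sort(sample(length(params), 50))
  for (k in idxs) {
    p1 <- params; p1[k] <- p1[k] + eps
    p2 <- params; p2[k] <- p2[k] - eps
    num <- (betapair:::pairnet_loss_grad_cpp(p1, x, mask, y, ccfg, 1.5)$loss -
            betapair:::pairnet_loss_grad_cpp(p2, x, mask, y, ccfg, 1.5)$loss) /
      (2 * eps)
    expect_equal(lg$grad[k], num, tolerance = 1e-5)
  }
})

test_that("predictions are equivariant under sequence reversal", {
  # reversing the residue order flips both axes of every 2D channel;
  # with 180-degree-symmetric kernels the probability map flips along
  pr <- generate_dataset(1, simulation_params(length_range = c(20L, 20L),
                                              n_strand_range = c(2L, 2L)),
                         seed = 31)[[1]]
  ft <- protein_features(pr)
  L <- ft$length
  params <- pairnet_init(tiny_config, 56, seed = 5)
  ccfg <- betapair:::cpp_cfg(tiny_config, 56)
  p_fwd <- betapair:::pairnet_forward_cpp(params, ft$channels, ft$mask, ccfg)
  rev_ch <- ft$channels[L:1, L:1, , drop = FALSE]
  p_rev <- betapair:::pairnet_forward_cpp(params, rev_ch,
                                          ft$mask[L:1, L:1], ccfg)
  expect_equal(p_rev, p_fwd[L:1, L:1], tolerance = 1e-10)
})

test_that("training learns a noiseless task and is reproducible", {
  ps <- noiseless_params(45L)
  ds <- generate_dataset(16, ps, seed = 41)
  ctl <- train_control(learning_rate = 2e-3, n_folds = 2, max_epochs = 25,
                       patience = 25, seed = 7)
  cfg <- pairnet_config(n_blocks = 2, n_channels = 8)
  fit <- fit_pairnet(ds, cfg, ctl)
  expect_s3_class(fit, "pairnet")
  expect_identical(length(fit$fold_params), 2L)
  # learns the (easy) noiseless task well in-sample
  preds <- predict(fit, ds)
  rep <- evaluate_per_protein(preds, lapply(ds, `[[`, "labels"), fit$cutoff)
  expect_gt(rep$f1[rep$id == "pooled"], 0.85)
  # same seed reproduces the fit exactly
  fit2 <- fit_pairnet(ds, cfg, ctl)
  expect_identical(fit$fold_params, fit2$fold_params)
  expect_identical(fit$cutoff, fit2$cutoff)
  # history is recorded per fold and epoch
  expect_true(all(c("fold", "epoch", "train_loss", "val_f1") %in%
                    names(fit$history)))
  # S3 surface
  expect_output(print(fit), "ensemble")
  expect_output(print(summary(fit)), "per-fold")
  expect_identical(length(coef(fit)), 2L)
  expect_identical(coef(fit, fold = 1), fit$fold_params[[1]])
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("checkpoint save/load round trip preserves predictions", {
  ps <- noiseless_params(40L)
  ds <- generate_dataset(6, ps, seed = 42)
  fit <- fit_pairnet(ds, pairnet_config(n_blocks = 1, n_channels = 6),
                     train_control(learning_rate = 2e-3, n_folds = 2,
                                   max_epochs = 3, patience = 3, seed = 1))
  dir <- tempfile()
  save_pairnet(fit, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_pairnet(dir)
  # the JSON manifest keeps ~15 significant digits of the cutoff
  expect_equal(back$cutoff, fit$cutoff, tolerance = 1e-12)
  p1 <- predict(fit, ds[[1]])
  p2 <- predict(back, ds[[1]])
  expect_equal(p1$probs, p2$probs, tolerance = 1e-15)
})

test_that("training configuration is validated", {
  expect_error(train_control(n_folds = 1), "n_folds")
  expect_error(train_control(learning_rate = 0), "learning_rate")
  expect_error(pairnet_config(n_blocks = 0), "n_blocks")
  expect_error(pairnet_config(leaky_slope = 1), "leaky_slope")
  ds <- generate_dataset(3, noiseless_params(40L), seed = 1)
  expect_error(fit_pairnet(ds, tiny_config,
                           train_control(n_folds = 5)),
               "more folds than proteins")
  expect_error(fit_pairnet(list(), tiny_config), "empty")
})
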