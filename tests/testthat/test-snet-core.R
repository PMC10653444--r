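# Architecture contracts: configuration, shapes, parameter audits, MCAM
# equation parity, receptive fields and ablation variants.

small_cfg <- function(...) {
  args <- utils::modifyList(list(base_width = 4L, resample_scale = 0.25,
                                 dropout_prob = 0.3), list(...))
  do.call(snet_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(snet_config(depth = 3), "depth 4")
  expect_error(snet_config(dilation_schedule = list(c(2, 2))), "4")
  expect_error(snet_config(convs_per_block = 4), "convs_per_block")
  expect_error(snet_config(resample_scale = 0), "resample_scale")
  expect_equal(snet_channels(snet_config(base_width = 16)), c(16, 32, 64, 128))
})

test_that("structure: four heads by default, one under single supervision", {
  net <- build_network(small_cfg(), seed = 1)
  heads <- grep("^head[0-9]+\\.w$", names(net$params), value = TRUE)
  expect_equal(sort(heads), c("head1.w", "head2.w", "head3.w", "head4.w"))
  net_sl <- build_network(small_cfg(supervision = "single"), seed = 1)
  expect_equal(grep("^head", names(net_sl$params), value = TRUE),
               c("head4.w", "head4.b"))
})

test_that("the single-branch backbone is strictly smaller and has no MCAM parameters", {
  cfg <- small_cfg()
  full <- build_network(cfg, seed = 1)
  bn <- build_network(make_variant(cfg, "BN+SL"), seed = 1)
  expect_lt(count_params(bn), count_params(full))
  expect_length(grep("mcam", names(bn$params)), 0)
  expect_length(grep("enc\\.res", names(bn$params)), 0)
  expect_gt(length(grep("mcam", names(full$params))), 0)
  # backbones of SNet+SL and SNet+ML coincide; only the head count differs
  sl <- build_network(make_variant(cfg, "SNet+SL"), seed = 1)
  ml <- build_network(make_variant(cfg, "SNet+ML"), seed = 1)
  non_head <- function(n) setdiff(names(n$params), grep("^head", names(n$params), value = TRUE))
  expect_identical(non_head(sl), non_head(ml))
  expect_lt(count_params(sl), count_params(ml))
})

test_that("an extra convolution per block adds the analytic parameter count", {
  cfg2 <- small_cfg(convs_per_block = 2L)
  cfg3 <- small_cfg(convs_per_block = 3L)
  n2 <- build_network(cfg2, seed = 1)
  n3 <- build_network(cfg3, seed = 1)
  ch <- snet_channels(cfg2)
  dch <- snet3d:::decoder_channels(cfg2)
  # one extra 3^3 C->C conv (+bias +PReLU slope) per encoder block on both
  # branches and per decoder stage
  extra <- sum(27 * ch^2 + ch + 1) * 2 + sum(27 * dch^2 + dch + 1)
  expect_equal(count_params(n3) - count_params(n2), extra)
})

test_that("encoder feature shapes follow the stride arithmetic", {
  cfg <- small_cfg(resample_scale = 0.5)
  net <- build_network(cfg, seed = 2)
  x <- array(rnorm(32^3), c(32, 32, 32))
  enc <- encode(net, x)
  for (i in 1:4) {
    expect_equal(dim(enc$down[[i]])[1:3], rep(32 / 2^i, 3))
    expect_equal(dim(enc$down[[i]])[4], snet_channels(cfg)[i])
    expect_equal(dim(enc$res[[i]])[1:3], rep(16, 3))
    expect_equal(dim(enc$res[[i]])[4], snet_channels(cfg)[i])
  }
  # single-branch variant has no resampling features
  bn <- build_network(make_variant(cfg, "BN+ML"), seed = 2)
  expect_null(encode(bn, x)$res)
  expect_error(encode(net, array(0, c(24, 32, 32))), "axis 1")
})

test_that("decoder stages double resolution and halve channels", {
  cfg <- small_cfg()
  net <- build_network(cfg, seed = 3)
  x <- array(rnorm(32^3), c(32, 32, 32))
  feats <- encode(net, x)
  dec <- decode(net, feats)
  sizes <- t(vapply(dec, function(d) dim(d)[1:3], integer(3)))
  expect_equal(sizes[, 1], c(4L, 8L, 16L, 32L))
  expect_equal(vapply(dec, function(d) dim(d)[4], integer(1)),
               snet3d:::decoder_channels(cfg))
  # ablated long skips: zeroed encoder features still decode finitely
  zeroed <- feats
  zeroed$down <- lapply(feats$down, function(f) f * 0)
  dec0 <- decode(net, zeroed)
  expect_true(all(vapply(dec0, function(d) all(is.finite(d)), logical(1))))
  expect_equal(lapply(dec0, dim), lapply(dec, dim))
})

test_that("prediction heads emit open-interval probabilities at input size", {
  cfg <- small_cfg()
  net <- build_network(cfg, seed = 4)
  x <- array(rnorm(32^3), c(32, 32, 32))
  preds <- forward(net, x)
  expect_length(preds, 4L)
  for (p in preds) {
    expect_equal(dim(p)[1:3], c(32L, 32L, 32L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("evaluation passes are deterministic; training passes are seeded", {
  cfg <- small_cfg()
  net <- build_network(cfg, seed = 5)
  x <- array(rnorm(32^3), c(32, 32, 32))
  expect_identical(forward(net, x), forward(net, x))
  set.seed(99)
  a <- forward(net, x, training = TRUE)
  set.seed(99)
  b <- forward(net, x, training = TRUE)
  expect_identical(a, b)
  set.seed(100)
  c_ <- forward(net, x, training = TRUE)
  expect_false(identical(a, c_))
})

test_that("MCAM with zeroed convolutions reduces to residual interpolation", {
  cfg <- small_cfg()
  net <- build_network(cfg, seed = 7)
  for (nm in grep("^mcam\\.l1\\..*\\.(w|b)$", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] * 0
  ch <- snet_channels(cfg)[1]
  fd <- array(rnorm(4^3 * ch), c(4, 4, 4, ch, 1))
  fr_same <- array(rnorm(4^3 * ch), c(4, 4, 4, ch, 1))
  got <- mcam(net, 1L, fd, fr_same)
  # equal spatial sizes: Interp is the identity, outputs are plain sums
  expect_equal(got$f_r, fr_same + fd, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(got$f_d, fd + fr_same, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the analytic receptive field composes single-conv edges", {
  expect_equal(conv_rf_edge(3, 1), 3)
  expect_equal(conv_rf_edge(3, 3), 7)
  expect_equal(conv_rf_edge(3, 4), 9)
  expect_equal(conv_rf_edge(3, 5), 11)
  cfg <- snet_config()
  for (i in 1:4) {
    expect_equal(receptive_field(cfg, i, "D")$cumulative_stride, 2L^i)
    expect_equal(receptive_field(cfg, i, "R")$cumulative_stride, 1L)
  }
  # resampling-branch edges grow only by kernel extents
  r1 <- receptive_field(cfg, 1, "R")$edge
  r2 <- receptive_field(cfg, 2, "R")$edge
  expect_equal(r1, 1 + 3 * 2) # transition + two unit-dilation convs
  expect_equal(r2 - r1, 3 * 2)
  expect_error(receptive_field(cfg, 5, "R"), "range error")
})

test_that("all four ablation variants build and run forward", {
  cfg <- small_cfg()
  x <- array(rnorm(32^3), c(32, 32, 32))
  for (v in c("BN+SL", "BN+ML", "SNet+SL", "SNet+ML")) {
    net <- build_network(make_variant(cfg, v), seed = 8)
    preds <- forward(net, x)
    n_heads <- if (grepl("ML", v)) 4L else 1L
    expect_length(preds, n_heads)
    expect_equal(dim(preds[[length(preds)]])[1:3], c(32L, 32L, 32L))
  }
  expect_identical(make_variant(cfg, "SNet+ML"), cfg)
  expect_error(make_variant(cfg, "what"), "unknown variant")
})

test_that("checkpoints round-trip the parameters and config", {
  dir <- withr::local_tempdir()
  net <- build_network(small_cfg(), seed = 9)
  p <- file.path(dir, "ck.rds")
  save_checkpoint(net, p, extra = list(epoch = 3L))
  expect_true(file.exists(paste0(p, ".json")))
  side <- jsonlite::read_json(paste0(p, ".json"))
  expect_equal(side$base_width, 4L)
  ck <- load_checkpoint(p)
  expect_identical(ck$network$params, net$params)
  expect_equal(ck$extra$epoch, 3L)
  x <- array(rnorm(32^3), c(32, 32, 32))
  expect_identical(forward(ck$network, x), forward(net, x))
})
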