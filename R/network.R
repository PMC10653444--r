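# S-Net: S-shaped dual-branch 3D encoder-decoder for thin-structure
# segmentation.
#
# The encoder runs two branches in parallel.  The downsampling branch is the
# conventional one: a 2^3 stride-2 convolution halves the grid at every layer,
# so its receptive field in input voxels grows by 2^i.  The resampling branch
# keeps (a scaled copy of) the input resolution at every layer via 3^3
# stride-1 convolutions, which pins its receptive field growth to the kernel
# extent — the property that lets deep layers still see one-voxel structures.
# At each layer the branches exchange information through a multiple
# cross-aggregation module (MCAM): each branch adds a convolved, trilinearly
# resampled copy of the other.  The decoder upsamples with 2^3 stride-2
# transposed convolutions, concatenates same-resolution encoder features
# (long skips), applies 3^3 convolutions with additive short skips, and every
# decoding stage carries its own prediction head (1x1x1 convolution, trilinear
# upsampling to input size, sigmoid) for deep supervision.

#' Network configuration
#'
#' Builds and validates the configuration of the dual-branch segmentation
#' network. The published architecture uses `depth = 4` encoding layers whose
#' last two blocks employ dilated convolutions with (padding, dilation) pairs
#' (2,2), (3,3), (4,4) and (5,5), dropout probability 0.3, and deep
#' supervision over all four decoding stages.
#'
#' @param in_channels Number of input image channels.
#' @param depth Number of encoding layers; the published configuration is 4.
#' @param base_width Channels at the first encoder layer. Channel counts are
#'   not printed in the original description, so this is fully configurable;
#'   the default 16 doubles per layer (16/32/64/128).
#' @param width_growth Per-layer channel multiplier.
#' @param convs_per_block Number of 3^3 convolutions per encoder/decoder
#'   block (2 or 3).
#' @param dilation_schedule List of four (padding, dilation) pairs used by
#'   the two deepest encoder layers, two pairs per layer in sequence.
#' @param dropout_prob Bernoulli dropout probability applied after every
#'   encoding and decoding layer during training.
#' @param resample_scale Resolution factor of the resampling branch in
#'   (0, 1]. 1 keeps the full input resolution; smaller values trade the
#'   branch's resolution for memory and compute, per-axis target size is
#'   `max(1, round(scale * size))`.
#' @param supervision `"multi"` supervises all `depth` decoder stages,
#'   `"single"` only the full-resolution stage.
#' @param dual_branch If `FALSE` the resampling branch and MCAM are removed,
#'   leaving a residual U-Net backbone.
#' @param mcam_convs Convolutions in each MCAM stack (the published module
#'   uses three 3D convolutions followed by PReLUs).
#' @param threshold Probability threshold for binarizing the inference head.
#' @return An object of class `snet_config`.
#' @export
snet_config <- function(in_channels = 1L, depth = 4L, base_width = 16L,
                        width_growth = 2, convs_per_block = 2L,
                        dilation_schedule = list(c(2L, 2L), c(3L, 3L),
                                                 c(4L, 4L), c(5L, 5L)),
                        dropout_prob = 0.3, resample_scale = 1,
                        supervision = c("multi", "single"),
                        dual_branch = TRUE, mcam_convs = 3L,
                        threshold = 0.5) {
  supervision <- match.arg(supervision)
  depth <- as.integer(depth)
  if (depth != 4L)
    stop("config error: the published architecture has depth 4, got ", depth)
  if (length(dilation_schedule) != 4L)
    stop("config error: dilation_schedule must list 4 (padding, dilation) pairs")
  if (!convs_per_block %in% 2:3)
    stop("config error: convs_per_block must be 2 or 3")
  if (resample_scale <= 0 || resample_scale > 1)
    stop("config error: resample_scale must lie in (0, 1]")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("config error: dropout_prob must lie in [0, 1)")
  cfg <- list(in_channels = as.integer(in_channels), depth = depth,
              base_width = as.integer(base_width),
              width_growth = width_growth,
              convs_per_block = as.integer(convs_per_block),
              dilation_schedule = lapply(dilation_schedule, as.integer),
              dropout_prob = dropout_prob, resample_scale = resample_scale,
              supervision = supervision, dual_branch = isTRUE(dual_branch),
              mcam_convs = as.integer(mcam_convs), threshold = threshold)
  class(cfg) <- "snet_config"
  cfg
}

#' Per-layer channel counts
#' @param config An `snet_config`.
#' @return Integer vector of length `depth`.
#' @export
snet_channels <- function(config) {
  as.integer(round(config$base_width * config$width_growth^(seq_len(config$depth) - 1)))
}

# decoder stage k emits channels C_{depth-k}; the full-resolution stage has
# no shallower encoder layer to mirror, so it keeps C_1
decoder_channels <- function(config) {
  ch <- snet_channels(config)
  c(rev(ch[-length(ch)]), ch[1L])
}

# (padding, dilation) for conv j of the block at layer i
block_dilation <- function(config, layer, j) {
  if (layer <= config$depth - 2L) return(c(1L, 1L))
  base <- if (layer == config$depth - 1L) 0L else 2L
  config$dilation_schedule[[base + ((j - 1L) %% 2L) + 1L]]
}

resampled_size <- function(size, scale) pmax(1L, as.integer(round(scale * size)))

# ---- parameter initialization ----------------------------------------------

init_conv <- function(params, name, k, cin, cout) {
  bound <- sqrt(6 / (cin * k^3))
  params[[paste0(name, ".w")]] <-
    array(stats::runif(k^3 * cin * cout, -bound, bound), c(k, k, k, cin, cout))
  params[[paste0(name, ".b")]] <- numeric(cout)
  params
}

init_prelu <- function(params, name) {
  # freshly allocated scalar: the optimizer updates parameters in place, so
  # no parameter may alias a shared constant
  params[[paste0(name, ".a")]] <- rep(0.25, 1L)
  params
}

#' Build a network from a configuration
#'
#' Allocates and initializes all trainable parameters. Convolution weights are
#' drawn fan-in-scaled uniform from the seeded generator; PReLU slopes start
#' at 0.25; biases at zero.
#'
#' @param config An [snet_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return An object of class `snet_network`: a named parameter list plus the
#'   configuration.
#' @export
build_network <- function(config, seed = 1L) {
  stopifnot(inherits(config, "snet_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  ch <- snet_channels(config)
  cpb <- config$convs_per_block
  p <- list()
  branches <- if (config$dual_branch) c("down", "res") else "down"
  for (br in branches) {
    for (i in seq_len(config$depth)) {
      cin <- if (i == 1L) config$in_channels else ch[i - 1L]
      nm <- sprintf("enc.%s.l%d", br, i)
      k_tr <- if (br == "down") 2L else 3L
      p <- init_conv(p, paste0(nm, ".trans"), k_tr, cin, ch[i])
      p <- init_prelu(p, paste0(nm, ".trans"))
      for (j in seq_len(cpb)) {
        p <- init_conv(p, sprintf("%s.conv%d", nm, j), 3L, ch[i], ch[i])
        p <- init_prelu(p, sprintf("%s.conv%d", nm, j))
      }
    }
  }
  if (config$dual_branch) {
    for (i in seq_len(config$depth)) {
      for (dir in c("d2r", "r2d")) {
        for (j in seq_len(config$mcam_convs)) {
          nm <- sprintf("mcam.l%d.%s.conv%d", i, dir, j)
          p <- init_conv(p, nm, 3L, ch[i], ch[i])
          p <- init_prelu(p, nm)
        }
      }
    }
  }
  dch <- decoder_channels(config)
  for (k in seq_len(config$depth)) {
    cin <- if (k == 1L) ch[config$depth] else dch[k - 1L]
    nm <- sprintf("dec.s%d", k)
    p <- init_conv(p, paste0(nm, ".up"), 2L, cin, dch[k])
    p <- init_prelu(p, paste0(nm, ".up"))
    skip_ch <- if (k < config$depth) ch[config$depth - k] else 0L
    for (j in seq_len(cpb)) {
      cin_j <- if (j == 1L) dch[k] + skip_ch else dch[k]
      p <- init_conv(p, sprintf("%s.conv%d", nm, j), 3L, cin_j, dch[k])
      p <- init_prelu(p, sprintf("%s.conv%d", nm, j))
    }
  }
  heads <- if (config$supervision == "multi") seq_len(config$depth) else config$depth
  for (k in heads) p <- init_conv(p, sprintf("head%d", k), 1L, dch[k], 1L)

  structure(list(params = p, config = config), class = "snet_network")
}

#' Number of trainable parameters
#' @param network An `snet_network`.
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(network) sum(vapply(network$params, length, integer(1)))

#' @export
print.snet_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("S-Net (%s branch, %s supervision): depth %d, base width %d, %s parameters\n",
              if (cfg$dual_branch) "dual" else "single",
              cfg$supervision, cfg$depth, cfg$base_width,
              format(count_params(x), big.mark = ",")))
  invisible(x)
}

# ---- forward graph ----------------------------------------------------------

wrap_params <- function(network) lapply(network$params, ag_const)

conv_prelu <- function(x, pn, name, stride = 1L, pad = 1L, dil = 1L, k = 3L) {
  y <- if (k == 2L && stride == 2L)
    ag_conv3d(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
              stride = 2L, pad = 0L, dil = 1L)
  else
    ag_conv3d(x, pn[[paste0(name, ".w")]], pn[[paste0(name, ".b")]],
              stride = stride, pad = pad, dil = dil)
  ag_prelu(y, pn[[paste0(name, ".a")]])
}

encoder_block <- function(x, pn, cfg, branch, layer) {
  nm <- sprintf("enc.%s.l%d", branch, layer)
  t <- if (branch == "down") conv_prelu(x, pn, paste0(nm, ".trans"), k = 2L, stride = 2L)
       else conv_prelu(x, pn, paste0(nm, ".trans"))
  h <- t
  for (j in seq_len(cfg$convs_per_block)) {
    pd <- block_dilation(cfg, layer, j)
    h <- conv_prelu(h, pn, sprintf("%s.conv%d", nm, j), pad = pd[1], dil = pd[2])
  }
  ag_add(h, t) # residual short skip around the block
}

mcam_stack <- function(x, pn, cfg, layer, dir) {
  h <- x
  for (j in seq_len(cfg$mcam_convs))
    h <- conv_prelu(h, pn, sprintf("mcam.l%d.%s.conv%d", layer, dir, j))
  h
}

# Cross-aggregation at layer i:
#   F_R <- F_R + Interp(F_D + PReLU(Conv(F_D)))
#   F_D <- F_D + Interp(F_R + PReLU(Conv(F_R)))
# both sides read the pre-update features.
mcam_nodes <- function(fd, fr, pn, cfg, layer) {
  if (dim(fd$value)[4] != dim(fr$value)[4])
    stop("mcam: channel counts differ between branches at layer ", layer)
  d_aug <- ag_add(fd, mcam_stack(fd, pn, cfg, layer, "d2r"))
  r_aug <- ag_add(fr, mcam_stack(fr, pn, cfg, layer, "r2d"))
  list(fr = ag_add(fr, ag_interp(d_aug, tensor_spatial(fr$value))),
       fd = ag_add(fd, ag_interp(r_aug, tensor_spatial(fd$value))))
}

encode_nodes <- function(network, x, pn, training = FALSE, mcam_on = TRUE,
                         upto = NULL) {
  cfg <- network$config
  upto <- if (is.null(upto)) cfg$depth else as.integer(upto)
  sz <- tensor_spatial(x$value)
  div <- 2L^cfg$depth
  for (ax in 1:3)
    if (sz[ax] %% div != 0L)
      stop(sprintf("shape error: axis %d has size %d, not divisible by %d",
                   ax, sz[ax], div))
  use_res <- cfg$dual_branch
  fd <- x
  fr <- if (use_res) ag_interp(x, resampled_size(sz, cfg$resample_scale)) else NULL
  down <- vector("list", upto)
  res <- if (use_res) vector("list", upto) else NULL
  for (i in seq_len(upto)) {
    fd <- encoder_block(fd, pn, cfg, "down", i)
    if (use_res) {
      fr <- encoder_block(fr, pn, cfg, "res", i)
      if (mcam_on) {
        cross <- mcam_nodes(fd, fr, pn, cfg, i)
        fd <- cross$fd
        fr <- cross$fr
      }
    }
    if (training && cfg$dropout_prob > 0) {
      fd <- ag_dropout(fd, cfg$dropout_prob)
      if (use_res) fr <- ag_dropout(fr, cfg$dropout_prob)
    }
    down[[i]] <- fd
    if (use_res) res[[i]] <- fr
  }
  list(down = down, res = res)
}

decode_nodes <- function(network, enc, pn, training = FALSE) {
  cfg <- network$config
  x <- enc$down[[cfg$depth]]
  out <- vector("list", cfg$depth)
  for (k in seq_len(cfg$depth)) {
    nm_up <- sprintf("dec.s%d.up", k)
    u <- ag_prelu(ag_convt2(x, pn[[paste0(nm_up, ".w")]], pn[[paste0(nm_up, ".b")]]),
                  pn[[paste0(nm_up, ".a")]])
    h <- if (k < cfg$depth) {
      skip <- enc$down[[cfg$depth - k]]
      if (!all(tensor_spatial(skip$value) == tensor_spatial(u$value)))
        stop("decode: long-skip resolution mismatch at stage ", k)
      ag_concat(u, skip)
    } else u
    for (j in seq_len(cfg$convs_per_block))
      h <- conv_prelu(h, pn, sprintf("dec.s%d.conv%d", k, j))
    x <- ag_add(h, u) # short skip
    if (training && cfg$dropout_prob > 0) x <- ag_dropout(x, cfg$dropout_prob)
    out[[k]] <- x
  }
  out
}

heads_nodes <- function(network, dec, pn, out_size) {
  cfg <- network$config
  ks <- if (cfg$supervision == "multi") seq_len(cfg$depth) else cfg$depth
  preds <- list()
  for (k in ks) {
    h <- ag_conv3d(dec[[k]], pn[[sprintf("head%d.w", k)]],
                   pn[[sprintf("head%d.b", k)]], stride = 1L, pad = 0L, dil = 1L)
    preds[[as.character(k)]] <- ag_sigmoid(ag_interp(h, out_size))
  }
  preds
}

snet_forward_nodes <- function(network, x, training = FALSE, mcam_on = TRUE) {
  pn <- wrap_params(network)
  enc <- encode_nodes(network, x, pn, training = training, mcam_on = mcam_on)
  dec <- decode_nodes(network, enc, pn, training = training)
  preds <- heads_nodes(network, dec, pn, tensor_spatial(x$value))
  list(preds = preds, enc = enc, dec = dec, pn = pn)
}

# ---- exported module surface -------------------------------------------------

#' Run the dual-branch encoder
#'
#' @param network An `snet_network`.
#' @param patch 3D intensity array (or (D,H,W,C,N) tensor); spatial dims must
#'   be divisible by `2^depth`.
#' @return List with per-layer features `down` (downsampling branch, halved
#'   per layer) and `res` (resampling branch, input resolution times
#'   `resample_scale`; `NULL` when `dual_branch` is off).
#' @export
encode <- function(network, patch) {
  x <- ag_const(as_tensor(patch))
  enc <- encode_nodes(network, x, wrap_params(network))
  structure(list(down = lapply(enc$down, function(n) n$value),
                 res = if (is.null(enc$res)) NULL
                       else lapply(enc$res, function(n) n$value)),
            class = "snet_encoder_features")
}

#' Apply one cross-aggregation exchange
#'
#' Computes the MCAM update at one encoder layer from the two branch features:
#' each branch receives the other's features augmented by a convolutional
#' stack and trilinearly resampled to its own grid, through residual addition.
#'
#' @param network An `snet_network` (supplies the layer's MCAM parameters).
#' @param layer Encoder layer index.
#' @param f_d,f_r Downsampling/resampling branch features, (D,H,W,C,N) arrays
#'   with equal channel counts.
#' @return List with updated `f_r` and `f_d` arrays.
#' @export
mcam <- function(network, layer, f_d, f_r) {
  if (!network$config$dual_branch)
    stop("mcam: network was built without the resampling branch")
  if (dim(f_d)[4] != dim(f_r)[4])
    stop("mcam: channel counts must match, got ", dim(f_d)[4], " vs ", dim(f_r)[4])
  pn <- wrap_params(network)
  out <- mcam_nodes(ag_const(f_d), ag_const(f_r), pn, network$config, layer)
  list(f_r = out$fr$value, f_d = out$fd$value)
}

#' Run the decoder on encoder features
#'
#' @param network An `snet_network`.
#' @param feats An `snet_encoder_features` object from [encode()].
#' @return List of `depth` decoder feature arrays, coarsest to finest.
#' @export
decode <- function(network, feats) {
  enc <- list(down = lapply(feats$down, ag_const))
  lapply(decode_nodes(network, enc, wrap_params(network)), function(n) n$value)
}

#' Prediction heads
#'
#' Applies a 1x1x1 convolution, trilinear upsampling to `out_size`, and a
#' sigmoid to each supervised decoder stage.
#'
#' @param network An `snet_network`.
#' @param decoder_feats List of decoder feature arrays from [decode()].
#' @param out_size Target spatial size (the input patch size).
#' @return Named list of probability arrays, one per supervised head; the
#'   full-resolution head (`"4"`) is the inference output.
#' @export
predict_heads <- function(network, decoder_feats, out_size) {
  dec <- lapply(decoder_feats, ag_const)
  preds <- heads_nodes(network, dec, wrap_params(network), as.integer(out_size))
  lapply(preds, function(n) n$value)
}

#' Full forward pass
#'
#' Composes encoder, decoder and prediction heads. In training mode dropout
#' is active and draws from the session RNG; in evaluation mode the pass is
#' deterministic.
#'
#' @param network An `snet_network`.
#' @param patch 3D intensity array or (D,H,W,C,N) tensor.
#' @param training Enable dropout.
#' @return Named list of probability volumes (values strictly in (0,1)), all
#'   at the input resolution; entry `"4"` (the full-resolution stage) is the
#'   designated inference output. Single-supervision networks return only
#'   that head.
#' @export
forward <- function(network, patch, training = FALSE) {
  x <- ag_const(as_tensor(patch))
  out <- snet_forward_nodes(network, x, training = training)
  lapply(out$preds, function(n) n$value)
}

# ---- receptive field ---------------------------------------------------------

branch_stages <- function(config, layer, branch) {
  stages <- list()
  for (i in seq_len(layer)) {
    stages[[length(stages) + 1L]] <-
      if (branch == "D") list(k = 2L, d = 1L, s = 2L)
      else list(k = 3L, d = 1L, s = 1L)
    for (j in seq_len(config$convs_per_block)) {
      pd <- block_dilation(config, i, j)
      stages[[length(stages) + 1L]] <- list(k = 3L, d = pd[2], s = 1L)
    }
  }
  stages
}

#' Analytic receptive field
#'
#' Composes single-convolution receptive fields, `edge = dilation*(k-1)+1`,
#' through the branch: each stage adds `dilation*(k-1)*cumulative_stride`
#' input voxels to the edge and multiplies the cumulative stride by its own.
#' The downsampling branch therefore carries a `2^i` spread multiplier at
#' layer `i`, while the resampling branch keeps cumulative stride 1 — its
#' receptive field never inflates with depth. Sizes are in voxels of the
#' branch's working grid (the input grid when `resample_scale = 1`).
#'
#' @param config An [snet_config()].
#' @param layer Encoder layer in `1..depth`.
#' @param branch `"D"` (downsampling) or `"R"` (resampling).
#' @return List with `edge` (receptive-field edge length), `cumulative_stride`
#'   and the per-stage table.
#' @export
receptive_field <- function(config, layer, branch = c("D", "R")) {
  branch <- match.arg(branch)
  if (layer < 1L || layer > config$depth)
    stop("range error: layer must lie in 1..", config$depth)
  stages <- branch_stages(config, layer, branch)
  rf <- 1L; cs <- 1L
  tab <- data.frame(kernel = integer(), dilation = integer(),
                    stride = integer(), edge = integer(), cum_stride = integer())
  for (st in stages) {
    rf <- rf + st$d * (st$k - 1L) * cs
    cs <- cs * st$s
    tab <- rbind(tab, data.frame(kernel = st$k, dilation = st$d, stride = st$s,
                                 edge = rf, cum_stride = cs))
  }
  list(edge = rf, cumulative_stride = cs, stages = tab)
}

#' Single-convolution receptive field edge
#'
#' @param kernel Kernel size.
#' @param dilation Dilation factor.
#' @return `dilation * (kernel - 1) + 1`.
#' @export
conv_rf_edge <- function(kernel, dilation = 1L) dilation * (kernel - 1L) + 1L

#' Gradient-footprint probe
#'
#' Empirically measures the receptive field of one encoder feature voxel by
#' back-propagating from it to the input and reporting the edge lengths of
#' the bounding box of non-zero input gradient. Cross-branch mixing is
#' disabled during the probe so the measurement isolates the branch's own
#' convolutional path (with MCAM active, every feature deliberately sees the
#' other branch's receptive field as well — that mixing is the module's
#' purpose, not the branch's intrinsic footprint).
#'
#' @param network An `snet_network` (use `resample_scale = 1` so both grids
#'   live in input voxels).
#' @param layer Encoder layer to probe.
#' @param branch `"D"` or `"R"`.
#' @param input_shape Spatial size of the random probe volume; must comfortably
#'   exceed the analytic receptive field to avoid clipping.
#' @param seed Seed for the probe volume.
#' @return Integer vector of three per-axis footprint edge lengths.
#' @export
rf_probe <- function(network, layer, branch = c("D", "R"),
                     input_shape = c(48L, 48L, 48L), seed = 7L) {
  branch <- match.arg(branch)
  if (branch == "R" && !network$config$dual_branch)
    stop("probe: network has no resampling branch")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  x <- ag_const(as_tensor(array(stats::rnorm(prod(input_shape) * network$config$in_channels),
                                c(input_shape, network$config$in_channels, 1L))))
  tape <- ag_tape()
  with_tape(tape, {
    enc <- encode_nodes(network, x, wrap_params(network), mcam_on = FALSE,
                        upto = layer)
    feat <- if (branch == "D") enc$down[[layer]] else enc$res[[layer]]
    ctr <- c(pmax(1L, dim(feat$value)[1:3] %/% 2L), 1L, 1L)
    probe <- ag_pick(feat, ctr)
    ag_backward(tape, probe)
  })
  g <- x$grad
  if (is.null(g)) stop("probe: no gradient reached the input")
  nz <- which(abs(g) > 0, arr.ind = TRUE)
  vapply(1:3, function(ax) diff(range(nz[, ax])) + 1L, integer(1))
}

# ---- ablation variants -------------------------------------------------------

#' Ablation variant configurations
#'
#' The four ablation arms: `BN` replaces the dual-branch encoder with the
#' residual U-Net backbone (no resampling branch, no MCAM); `SL`/`ML` select
#' single- or multi-layer supervision. `SNet+ML` is the published model.
#'
#' @param config Base [snet_config()].
#' @param variant One of `"BN+SL"`, `"BN+ML"`, `"SNet+SL"`, `"SNet+ML"`.
#' @return The modified configuration.
#' @export
make_variant <- function(config, variant) {
  known <- c("BN+SL", "BN+ML", "SNet+SL", "SNet+ML")
  if (!variant %in% known)
    stop("config error: unknown variant '", variant, "'; expected one of ",
         paste(known, collapse = ", "))
  parts <- strsplit(variant, "+", fixed = TRUE)[[1]]
  config$dual_branch <- parts[1] == "SNet"
  config$supervision <- if (parts[2] == "ML") "multi" else "single"
  config
}

# ---- checkpoints -------------------------------------------------------------

#' Save a network checkpoint
#'
#' Writes a single-file parameter archive plus a JSON sidecar carrying the
#' full configuration, so a checkpoint is self-describing.
#'
#' @param network An `snet_network`.
#' @param path Checkpoint file path (`.rds`); the sidecar gets `.json`
#'   appended.
#' @param extra Optional named list stored alongside (e.g. optimizer state).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(network, path, extra = NULL) {
  saveRDS(list(params = network$params, config = unclass(network$config),
               extra = extra), path)
  jsonlite::write_json(unclass(network$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#' @param path Path passed to [save_checkpoint()].
#' @return List with the restored `network` and any `extra` payload.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- obj$config
  class(cfg) <- "snet_config"
  list(network = structure(list(params = obj$params, config = cfg),
                           class = "snet_network"),
       extra = obj$extra)
}
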