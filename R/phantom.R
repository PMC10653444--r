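# Synthetic 3D phantoms with exact ground truth.
#
# Two geometries emulate the thin structures the network targets:
#   * ellipsoidal shells — closed walls of controllable thickness
#     (1-4 voxels), the heart-wall analogue;
#   * branching capsule trees with radii decaying towards one voxel, plus an
#     optional spherical sac — the intracranial-vessel/aneurysm analogue.
# Intensities follow a two-level foreground/background model with additive
# Gaussian noise and a smooth multiplicative-free bias field (sum of three
# seeded low-frequency cosine products), mimicking the contrast, noise and
# intensity inhomogeneity of clinical volumes. Every phantom is a pure
# function of (spec, shape, intensity model, seed).

#' Ellipsoidal shell specification
#'
#' The wall is the band of the ellipsoidal level set `rho(x)` with
#' `|rho(x) - 1| <= t / (2 * rbar)` where `rbar` is the geometric mean of the
#' semi-axes — an analytic, orientation-safe band whose measured thickness
#' tracks `wall_thickness`.
#'
#' @param center Shell center, voxel coordinates (length 3).
#' @param semi_axes Ellipsoid semi-axes in voxels (length 3).
#' @param wall_thickness Wall thickness in voxels (typical 1-4).
#' @param orientation Euler angles (radians, z-y-x convention), length 3.
#' @return Object of class `shell_spec`.
#' @export
shell_spec <- function(center, semi_axes, wall_thickness = 2,
                       orientation = c(0, 0, 0)) {
  if (any(semi_axes <= wall_thickness) || wall_thickness <= 0)
    stop("geometry error: need semi_axes > wall_thickness > 0")
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 wall_thickness = as.numeric(wall_thickness),
                 orientation = as.numeric(orientation)),
            class = "shell_spec")
}

#' Branching tube-tree specification
#'
#' A recursive tree of capsule segments: radius at generation `g` is
#' `root_radius * radius_decay^g`; branching stops once the radius would fall
#' below 0.5 voxel (so rasterized segments stay connected). An optional
#' aneurysm attaches a sphere at one tree node.
#'
#' @param root Root position, voxel coordinates.
#' @param root_radius Radius at the root segment (voxels).
#' @param branch_factor Children per node.
#' @param depth Number of branching generations.
#' @param radius_decay Per-generation radius multiplier in (0, 1).
#' @param segment_length Segment length in voxels.
#' @param aneurysm Optional `list(node = index, radius = r)` attaching a
#'   spherical sac at tree node `node` (1 = root).
#' @return Object of class `tube_spec`.
#' @export
tube_spec <- function(root, root_radius = 3, branch_factor = 2L, depth = 3L,
                      radius_decay = 0.7, segment_length = 12,
                      aneurysm = NULL) {
  if (root_radius < 0.5) stop("geometry error: root_radius below 0.5 voxel")
  if (radius_decay <= 0 || radius_decay >= 1)
    stop("geometry error: radius_decay must lie in (0, 1)")
  structure(list(root = as.numeric(root), root_radius = root_radius,
                 branch_factor = as.integer(branch_factor),
                 depth = as.integer(depth), radius_decay = radius_decay,
                 segment_length = segment_length, aneurysm = aneurysm),
            class = "tube_spec")
}

#' Intensity model
#'
#' @param fg_mean,bg_mean Foreground/background mean intensities (arbitrary
#'   units; must differ).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bias_amplitude Amplitude of the smooth bias field.
#' @param bias_scale Characteristic wavelength of the bias field, voxels.
#' @return Object of class `intensity_model`.
#' @export
intensity_model <- function(fg_mean = 1, bg_mean = 0, noise_sd = 0.1,
                            bias_amplitude = 0.2, bias_scale = 32) {
  if (fg_mean == bg_mean) stop("intensity model: fg_mean must differ from bg_mean")
  if (noise_sd < 0) stop("intensity model: noise_sd must be >= 0")
  structure(list(fg_mean = fg_mean, bg_mean = bg_mean, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, bias_scale = bias_scale),
            class = "intensity_model")
}

euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  rz %*% ry %*% rx
}

# voxel-center coordinate grid as an (n x 3) matrix
coord_grid <- function(shape) {
  cbind(rep(seq_len(shape[1]), times = shape[2] * shape[3]),
        rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
        rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}

shell_band_mask <- function(spec, shape, supersample = 1L) {
  s <- as.integer(supersample)
  rot <- euler_rotation(spec$orientation)
  rbar <- prod(spec$semi_axes)^(1 / 3)
  half_band <- spec$wall_thickness / (2 * rbar)
  if (s == 1L) {
    g <- coord_grid(shape)
    rel <- sweep(g, 2, spec$center, `-`) %*% rot
    rho <- sqrt((rel[, 1] / spec$semi_axes[1])^2 +
                (rel[, 2] / spec$semi_axes[2])^2 +
                (rel[, 3] / spec$semi_axes[3])^2)
    return(array(abs(rho - 1) <= half_band, shape))
  }
  # supersampled occupancy: fraction of s^3 sub-voxel centers inside the band
  sub <- (seq_len(s) - (s + 1) / 2) / s
  occ <- array(0, shape)
  for (ox in sub) for (oy in sub) for (oz in sub) {
    g <- coord_grid(shape)
    g[, 1] <- g[, 1] + ox; g[, 2] <- g[, 2] + oy; g[, 3] <- g[, 3] + oz
    rel <- sweep(g, 2, spec$center, `-`) %*% rot
    rho <- sqrt((rel[, 1] / spec$semi_axes[1])^2 +
                (rel[, 2] / spec$semi_axes[2])^2 +
                (rel[, 3] / spec$semi_axes[3])^2)
    occ <- occ + array(abs(rho - 1) <= half_band, shape)
  }
  occ / s^3
}

bias_field <- function(shape, model) {
  if (model$bias_amplitude == 0) return(array(0, shape))
  # three low-frequency cosine products; wavelengths >= bias_scale
  field <- array(0, shape)
  ax <- lapply(shape, seq_len)
  for (k in 1:3) {
    lam <- model$bias_scale * stats::runif(3, 1, 2)
    phi <- stats::runif(3, 0, 2 * pi)
    cx <- cos(2 * pi * ax[[1]] / lam[1] + phi[1])
    cy <- cos(2 * pi * ax[[2]] / lam[2] + phi[2])
    cz <- cos(2 * pi * ax[[3]] / lam[3] + phi[3])
    field <- field + outer(outer(cx, cy), cz)
  }
  model$bias_amplitude * field / 3
}

render_phantom <- function(mask, model, shape) {
  vol <- model$bg_mean + (model$fg_mean - model$bg_mean) * mask
  vol <- vol + bias_field(shape, model)
  if (model$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(shape), 0, model$noise_sd), shape)
  vol
}

with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Generate a thin-shell phantom
#'
#' @param spec A [shell_spec()].
#' @param shape Volume size (3 integers).
#' @param model An [intensity_model()].
#' @param seed Integer seed; identical inputs give bitwise-identical output.
#' @return Object of class `phantom_case`: list with `volume`, binary `mask`,
#'   `spacing` (mm), `seed` and `spec`.
#' @export
make_shell_phantom <- function(spec, shape, model = intensity_model(),
                               seed = 1L) {
  stopifnot(inherits(spec, "shell_spec"))
  shape <- as.integer(shape)
  rbar <- prod(spec$semi_axes)^(1 / 3)
  extent <- spec$semi_axes * (1 + spec$wall_thickness / (2 * rbar))
  if (any(spec$center - max(extent) < 3) || any(spec$center + max(extent) > shape - 2))
    stop("geometry error: shell (extent ", round(max(extent), 1),
         " voxels) exceeds volume bounds with the required 2-voxel margin")
  with_local_seed(seed, {
    mask <- shell_band_mask(spec, shape) * 1
    vol <- render_phantom(mask, model, shape)
    structure(list(volume = vol, mask = mask, spacing = c(1, 1, 1),
                   seed = seed, spec = spec), class = "phantom_case")
  })
}

# grow the capsule-segment tree; returns segments matrix and node positions
grow_tube_tree <- function(spec, shape) {
  segs <- NULL
  nodes <- matrix(spec$root, nrow = 1)
  clipped <- FALSE
  clamp <- function(p) {
    q <- pmin(pmax(p, 2), shape - 1)
    if (any(q != p)) clipped <<- TRUE
    q
  }
  recurse <- function(pos, dir, gen) {
    radius <- spec$root_radius * spec$radius_decay^gen
    if (radius < 0.5) return() # thinner than half a voxel: stop branching
    end <- clamp(pos + dir * spec$segment_length)
    segs <<- rbind(segs, c(pos, end, radius))
    nodes <<- rbind(nodes, end)
    if (gen >= spec$depth) return()
    for (b in seq_len(spec$branch_factor)) {
      # child direction: parent direction tilted by a random rotation
      theta <- stats::runif(1, pi / 8, pi / 3.5)
      phi <- stats::runif(1, 0, 2 * pi)
      perp1 <- c(dir[2] - dir[3], dir[3] - dir[1], dir[1] - dir[2])
      if (sum(perp1^2) < 1e-12) perp1 <- c(1, 0, 0)
      perp1 <- perp1 / sqrt(sum(perp1^2))
      perp2 <- c(dir[2] * perp1[3] - dir[3] * perp1[2],
                 dir[3] * perp1[1] - dir[1] * perp1[3],
                 dir[1] * perp1[2] - dir[2] * perp1[1])
      child <- cos(theta) * dir + sin(theta) * (cos(phi) * perp1 + sin(phi) * perp2)
      child <- child / sqrt(sum(child^2))
      recurse(end, child, gen + 1)
    }
  }
  root_dir <- stats::rnorm(3)
  root_dir <- root_dir / sqrt(sum(root_dir^2))
  recurse(spec$root, root_dir, 0)
  list(segs = segs, nodes = nodes, clipped = clipped)
}

#' Generate a branching tube-tree phantom
#'
#' Segments are rasterized as capsules (a voxel is foreground when its
#' center lies within the segment radius), which is an exact geometric
#' predicate with no marching artifacts. A tree whose branches would leave
#' the volume is clipped at the bounds with a warning; radii that decay
#' below 0.5 voxel simply stop branching.
#'
#' @inheritParams make_shell_phantom
#' @param spec A [tube_spec()].
#' @return A `phantom_case`.
#' @export
make_tube_phantom <- function(spec, shape, model = intensity_model(),
                              seed = 1L) {
  stopifnot(inherits(spec, "tube_spec"))
  shape <- as.integer(shape)
  if (any(spec$root < 2) || any(spec$root > shape - 1))
    stop("geometry error: root position outside the volume")
  with_local_seed(seed, {
    tree <- grow_tube_tree(spec, shape)
    if (tree$clipped)
      warning("tube tree exceeded the volume bounds; branches were clipped")
    segs <- tree$segs
    if (!is.null(spec$aneurysm)) {
      node <- tree$nodes[spec$aneurysm$node, ]
      # a sphere is a zero-length capsule
      segs <- rbind(segs, c(node, node, spec$aneurysm$radius))
    }
    mask <- array(as.numeric(cpp_rasterize_capsules(segs, shape)), shape)
    vol <- render_phantom(mask, model, shape)
    structure(list(volume = vol, mask = mask, spacing = c(1, 1, 1),
                   seed = seed, spec = spec), class = "phantom_case")
  })
}

# ---- NIfTI I/O ---------------------------------------------------------------

write_phantom_nifti <- function(case, image_path, mask_path) {
  img <- RNifti::asNifti(case$volume)
  RNifti::pixdim(img) <- case$spacing
  RNifti::writeNifti(img, image_path, datatype = "float")
  msk <- RNifti::asNifti(array(as.integer(case$mask), dim(case$mask)))
  RNifti::pixdim(msk) <- case$spacing
  RNifti::writeNifti(msk, mask_path, datatype = "uint8")
  invisible(NULL)
}

#' Read a NIfTI mask
#' @param path NIfTI file.
#' @return List with binary `mask` array and `spacing` (mm).
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(mask = array(as.numeric(img > 0.5), dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Read a NIfTI image volume
#' @param path NIfTI file.
#' @return List with `volume` array and `spacing` (mm).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(volume = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[1:3])
}

sample_range <- function(rng) {
  if (length(rng) == 1) rng else stats::runif(1, rng[1], rng[2])
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_cases` NIfTI image/mask pairs plus a JSON manifest recording
#' file paths, geometry specs, per-case seeds and spacing. Per-case seeds
#' are derived deterministically from the master seed, so re-running with
#' the same seed reproduces the files bit for bit.
#'
#' @param n_cases Number of cases (>= 1).
#' @param geometry `"shell"` or `"tube"`.
#' @param shape Volume size, 3 integers.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param spec_ranges Named list of parameter ranges sampled per case.
#'   For shells: `semi_axes` (range of the mean semi-axis), `axis_jitter`
#'   (relative anisotropy), `wall_thickness`. For tubes: `root_radius`,
#'   `depth`, `radius_decay`, `segment_length`, `sac_prob`, `sac_radius`.
#' @param model An [intensity_model()].
#' @return The manifest as a data frame (paths, seeds); also written as
#'   `manifest.json`.
#' @export
make_dataset <- function(n_cases, geometry = c("shell", "tube"), shape,
                         seed = 1L, out_dir,
                         spec_ranges = NULL, model = intensity_model()) {
  geometry <- match.arg(geometry)
  if (n_cases < 1) stop("make_dataset: n_cases must be >= 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", out_dir)
  shape <- as.integer(shape)
  defaults <- if (geometry == "shell")
    list(semi_axes = c(0.22, 0.28) * min(shape), axis_jitter = 0.1,
         wall_thickness = c(2, 2))
  else
    list(root_radius = c(2.5, 3.5), depth = c(3, 3), radius_decay = c(0.65, 0.75),
         segment_length = c(0.15, 0.22) * min(shape), sac_prob = 0.5,
         sac_radius = c(4, 6))
  sr <- utils::modifyList(defaults, spec_ranges %||% list())
  records <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- (seed + 7919L * i) %% .Machine$integer.max
    spec <- with_local_seed(case_seed + 1L, {
      if (geometry == "shell") {
        a <- sample_range(sr$semi_axes)
        jit <- stats::runif(3, 1 - sr$axis_jitter, 1 + sr$axis_jitter)
        shell_spec(center = shape / 2 + stats::runif(3, -2, 2),
                   semi_axes = a * jit,
                   wall_thickness = sample_range(sr$wall_thickness),
                   orientation = stats::runif(3, 0, pi))
      } else {
        an <- if (stats::runif(1) < sr$sac_prob)
          list(node = 2L, radius = sample_range(sr$sac_radius)) else NULL
        tube_spec(root = shape / 2 + stats::runif(3, -0.25, 0.25) * shape / 2,
                  root_radius = sample_range(sr$root_radius),
                  depth = as.integer(round(sample_range(sr$depth))),
                  radius_decay = sample_range(sr$radius_decay),
                  segment_length = sample_range(sr$segment_length),
                  aneurysm = an)
      }
    })
    case <- if (geometry == "shell")
      make_shell_phantom(spec, shape, model, case_seed)
    else
      suppressWarnings(make_tube_phantom(spec, shape, model, case_seed))
    img_path <- file.path(out_dir, sprintf("case%03d_image.nii.gz", i))
    msk_path <- file.path(out_dir, sprintf("case%03d_mask.nii.gz", i))
    write_phantom_nifti(case, img_path, msk_path)
    records[[i]] <- list(case = sprintf("case%03d", i), image = img_path,
                         mask = msk_path, seed = case_seed,
                         spacing = case$spacing, geometry = geometry,
                         spec = unclass(spec))
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(records, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest <- data.frame(case = vapply(records, `[[`, "", "case"),
                         image = vapply(records, `[[`, "", "image"),
                         mask = vapply(records, `[[`, "", "mask"),
                         seed = vapply(records, `[[`, 1, "seed"))
  attr(manifest, "records") <- records
  attr(manifest, "path") <- manifest_path
  manifest
}

#' Load a dataset manifest
#' @param path `manifest.json` written by [make_dataset()].
#' @return Data frame of cases with the full records attached as an
#'   attribute.
#' @export
read_manifest <- function(path) {
  records <- jsonlite::read_json(path)
  manifest <- data.frame(case = vapply(records, `[[`, "", "case"),
                         image = vapply(records, `[[`, "", "image"),
                         mask = vapply(records, `[[`, "", "mask"),
                         seed = vapply(records, function(r) as.numeric(r$seed), 1))
  attr(manifest, "records") <- records
  attr(manifest, "path") <- path
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
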