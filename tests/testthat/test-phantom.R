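# Shell and tube phantom generation: determinism, geometry, intensity model,
# and NIfTI round trips.

quiet_model <- intensity_model(fg_mean = 1, bg_mean = 0, noise_sd = 0,
                               bias_amplitude = 0)

test_that("phantoms are pure functions of (spec, shape, model, seed)", {
  spec <- shell_spec(center = c(32, 32, 32), semi_axes = c(10, 12, 9),
                     wall_thickness = 2, orientation = c(0.3, 0.6, 0.1))
  a <- make_shell_phantom(spec, c(64, 64, 64), intensity_model(), seed = 11L)
  b <- make_shell_phantom(spec, c(64, 64, 64), intensity_model(), seed = 11L)
  expect_identical(a$volume, b$volume)
  expect_identical(a$mask, b$mask)
  d <- make_shell_phantom(spec, c(64, 64, 64), intensity_model(), seed = 12L)
  expect_false(identical(a$volume, d$volume))

  tsp <- tube_spec(root = c(16, 16, 16), root_radius = 2.5, depth = 2L)
  t1 <- suppressWarnings(make_tube_phantom(tsp, c(48, 48, 48), intensity_model(), seed = 3L))
  t2 <- suppressWarnings(make_tube_phantom(tsp, c(48, 48, 48), intensity_model(), seed = 3L))
  expect_identical(t1$volume, t2$volume)
  expect_identical(t1$mask, t2$mask)
})

test_that("degenerate intensity model reproduces the mask exactly", {
  spec <- shell_spec(center = c(24, 24, 24), semi_axes = c(9, 9, 9),
                     wall_thickness = 2)
  ph <- make_shell_phantom(spec, c(48, 48, 48), quiet_model, seed = 1L)
  expect_identical(ph$volume, ph$mask)
  # mask/volume consistency: thresholding at (fg+bg)/2 recovers the mask
  m2 <- intensity_model(fg_mean = 120, bg_mean = 40, noise_sd = 0,
                        bias_amplitude = 0)
  ph2 <- make_shell_phantom(spec, c(48, 48, 48), m2, seed = 1L)
  expect_identical(array(as.numeric(ph2$volume > 80), dim(ph2$volume)),
                   ph$mask)
})

test_that("spherical shell voxel count matches the analytic area and the supersampled oracle", {
  spec <- shell_spec(center = c(32, 32, 32), semi_axes = c(10, 10, 10),
                     wall_thickness = 2)
  ph <- make_shell_phantom(spec, c(64, 64, 64), quiet_model, seed = 1L)
  count <- sum(ph$mask)
  expect_lt(abs(count - 4 * pi * 10^2 * 2) / (4 * pi * 10^2 * 2), 0.15)
  # band indicator integrated on a supersampled grid over the shell bounds
  half_band <- 2 / (2 * 10)
  oracle <- supersampled_count(c(28, 28, 28), function(x, y, z) {
    rho <- sqrt(sum(((c(x, y, z) + 18 - 32) / 10)^2)) # sub-box offset +18
    abs(rho - 1) <= half_band
  }, s = 4L)
  expect_lt(abs(count - oracle) / oracle, 0.10)
})

test_that("measured wall thickness tracks the specification within a voxel", {
  for (t_wall in c(2, 3)) {
    spec <- shell_spec(center = c(32, 32, 32), semi_axes = c(11, 10, 12),
                       wall_thickness = t_wall, orientation = c(0.4, 0.2, 0.9))
    ph <- make_shell_phantom(spec, c(64, 64, 64), quiet_model, seed = 1L)
    # max inradius of the band via distance-to-background
    dt <- snet3d:::cpp_edt(array(ph$mask == 0, dim(ph$mask)), c(1, 1, 1))
    # dt runs center-to-center, half a voxel beyond the boundary on each side
    measured <- 2 * (max(dt[ph$mask == 1]) - 0.5)
    expect_lt(abs(measured - t_wall), 1.01)
  }
})

test_that("shells exceeding the volume are rejected with a geometry error", {
  spec <- shell_spec(center = c(10, 10, 10), semi_axes = c(12, 12, 12),
                     wall_thickness = 2)
  expect_error(make_shell_phantom(spec, c(32, 32, 32), quiet_model, 1L),
               "geometry error")
  expect_error(shell_spec(center = c(0, 0, 0), semi_axes = c(3, 3, 3),
                          wall_thickness = 4), "geometry error")
})

test_that("a depth-0 tube is one capsule with the analytic voxel count", {
  spec <- tube_spec(root = c(24, 24, 24), root_radius = 1.5, depth = 0L,
                    segment_length = 20)
  ph <- make_tube_phantom(spec, c(48, 48, 48), quiet_model, seed = 8L)
  count <- sum(ph$mask)
  cylinder <- pi * 1.5^2 * 20
  expect_lt(abs(count - cylinder) / cylinder, 0.15)
  expect_equal(brute_n_components26(ph$mask), 1L)
})

test_that("an aneurysm sac adds exactly the sphere-minus-overlap voxels", {
  base <- tube_spec(root = c(24, 24, 12), root_radius = 2, depth = 1L,
                    segment_length = 14)
  with_sac <- base
  with_sac$aneurysm <- list(node = 2L, radius = 5)
  ph0 <- make_tube_phantom(base, c(48, 48, 48), quiet_model, seed = 4L)
  ph1 <- make_tube_phantom(with_sac, c(48, 48, 48), quiet_model, seed = 4L)
  increase <- sum(ph1$mask) - sum(ph0$mask)
  # recover the attachment node, then rasterize the sphere independently
  set.seed(4L)
  ctr <- snet3d:::grow_tube_tree(base, c(48, 48, 48))$nodes[2L, ]
  d <- dim(ph0$mask)
  sphere <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    sphere[i, j, k] <- sum((c(i, j, k) - ctr)^2) <= 25
  expected <- sum(sphere & ph0$mask == 0) # sphere volume minus tree overlap
  expect_equal(increase, expected)
  expect_lt(abs(sum(sphere) - (4 / 3) * pi * 125) / ((4 / 3) * pi * 125), 0.15)
})

test_that("tube trees form a single 26-connected component", {
  for (seed in c(1L, 23L)) {
    spec <- tube_spec(root = c(24, 24, 24), root_radius = 2.8, depth = 3L,
                      radius_decay = 0.7, segment_length = 9)
    ph <- suppressWarnings(make_tube_phantom(spec, c(48, 48, 48), quiet_model,
                                             seed = seed))
    expect_equal(brute_n_components26(ph$mask), 1L)
  }
})

test_that("branch radii stop at half a voxel rather than erroring", {
  spec <- tube_spec(root = c(24, 24, 24), root_radius = 1, depth = 6L,
                    radius_decay = 0.5, segment_length = 6)
  ph <- suppressWarnings(make_tube_phantom(spec, c(48, 48, 48), quiet_model, 1L))
  expect_gt(sum(ph$mask), 0)
})

test_that("make_dataset writes reproducible NIfTI pairs plus a manifest", {
  dir1 <- withr::local_tempdir()
  man1 <- make_dataset(3, "shell", shape = c(32, 32, 32), seed = 7L,
                       out_dir = dir1)
  files <- list.files(dir1)
  expect_equal(sum(grepl("\\.nii\\.gz$", files)), 6L)
  expect_true("manifest.json" %in% files)
  sums1 <- tools::md5sum(sort(list.files(dir1, full.names = TRUE,
                                         pattern = "nii.gz$")))
  man2 <- make_dataset(3, "shell", shape = c(32, 32, 32), seed = 7L,
                       out_dir = dir1)
  sums2 <- tools::md5sum(sort(list.files(dir1, full.names = TRUE,
                                         pattern = "nii.gz$")))
  expect_identical(unname(sums1), unname(sums2))

  # manifest round trip preserves the specs
  man_r <- read_manifest(file.path(dir1, "manifest.json"))
  expect_equal(man_r$case, man1$case)
  expect_equal(man_r$seed, man1$seed)
  rec <- attr(man_r, "records")[[1]]
  rec0 <- attr(man1, "records")[[1]]
  expect_equal(unlist(rec$spec$semi_axes), unlist(rec0$spec$semi_axes),
               tolerance = 1e-12)

  # masks on disk equal the in-memory regeneration from the recorded spec
  sp <- rec0$spec
  case <- make_shell_phantom(shell_spec(unlist(sp$center), unlist(sp$semi_axes),
                                        sp$wall_thickness, unlist(sp$orientation)),
                             c(32, 32, 32), intensity_model(), rec0$seed)
  on_disk <- read_mask_nifti(man1$mask[1])
  expect_identical(on_disk$mask, case$mask)
  expect_equal(on_disk$spacing, c(1, 1, 1))
})

test_that("unwritable output directories raise an I/O error", {
  expect_error(make_dataset(1, "shell", shape = c(32, 32, 32), seed = 1L,
                            out_dir = "/proc/nonexistent/nope"),
               "I/O error")
})
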