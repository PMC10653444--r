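# Volume and surface evaluation metrics against exhaustive oracles.

test_that("hard confusion counts equal per-voxel enumeration", {
  set.seed(21)
  g <- array(rbinom(5^3, 1, 0.5), c(5, 5, 5))
  expect_equal(unname(confusion_counts(g, g)[c("fp", "fn")]), c(0, 0))
  expect_equal(unname(confusion_counts(1 - g, g)[c("tp", "tn")]), c(0, 0))
  for (rep in 1:5) {
    p <- array(rbinom(5^3, 1, 0.5), c(5, 5, 5))
    expect_equal(unname(confusion_counts(p, g)),
                 unname(brute_confusion_counts(p, g)))
  }
  expect_error(confusion_counts(g * 2, g), "binary")
})

test_that("volume metrics reproduce counted toy cases", {
  # |A| = 4, |B| = 4, |A intersect B| = 3
  gt <- array(0, c(4, 4, 4)); gt[1:4] <- 1
  pred <- array(0, c(4, 4, 4)); pred[2:5] <- 1
  cts <- confusion_counts(pred, gt)
  expect_equal(dice(cts), 6 / 8)

  # pred volume 110, gt 100, full overlap
  gt2 <- array(0, c(11, 10, 10)); gt2[1:100] <- 1
  pred2 <- array(0, c(11, 10, 10)); pred2[1:110] <- 1
  cts2 <- confusion_counts(pred2, gt2)
  expect_equal(rve(cts2), 0.10)
  expect_equal(sensitivity(cts2), 1.0)
  expect_equal(specificity(cts2), (1100 - 100 - 10) / (1100 - 100))

  expect_equal(dice(confusion_counts(gt, gt)), 1)
  expect_equal(rve(confusion_counts(gt, gt)), 0)
  empty <- array(0, c(4, 4, 4))
  expect_warning(expect_true(is.na(rve(confusion_counts(pred, empty)))),
                 "empty ground truth")
})

test_that("surface extraction obeys the 6-neighbour erosion definition", {
  m <- array(0, c(5, 5, 5)); m[3, 3, 3] <- 1
  s <- surface_voxels(m)
  expect_equal(nrow(s$coords), 1L)
  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_equal(nrow(surface_voxels(cube)$coords), 26L)
  # a one-voxel-thick hollow shell is its own surface
  shell <- cube; shell[3, 3, 3] <- 1
  shell_mask <- array(0, c(7, 7, 7)); shell_mask[2:6, 2:6, 2:6] <- 1
  shell_mask[3:5, 3:5, 3:5] <- 0
  expect_equal(nrow(surface_voxels(shell_mask)$coords), sum(shell_mask))
  expect_error(surface_voxels(array(0, c(3, 3, 3))), "empty")
})

test_that("hd95 and assd equal exhaustive pairwise computation", {
  a <- array(0, c(8, 8, 8)); a[2, 2, 2] <- 1
  b <- array(0, c(8, 8, 8)); b[5, 2, 2] <- 1
  sa <- surface_voxels(a); sb <- surface_voxels(b)
  expect_equal(hd95(sa, sb), 3.0)
  expect_equal(assd(sa, sb), 3.0)
  expect_equal(hd95(sa, sa), 0)
  expect_equal(assd(sa, sa), 0)

  set.seed(13)
  for (rep in 1:8) {
    d <- sample(4:12, 3, replace = TRUE)
    ma <- array(rbinom(prod(d), 1, 0.2), d)
    mb <- array(rbinom(prod(d), 1, 0.2), d)
    if (!any(ma == 1) || !any(mb == 1)) next
    spacing <- c(1, 1, 1)
    sa <- surface_voxels(ma, spacing)
    sb <- surface_voxels(mb, spacing)
    ca <- brute_surface_coords(ma, spacing)
    cb <- brute_surface_coords(mb, spacing)
    expect_equal(nrow(sa$coords), nrow(ca))
    expect_equal(hd95(sa, sb), brute_hd95(ca, cb), tolerance = 1e-9)
    expect_equal(assd(sa, sb), brute_assd(ca, cb), tolerance = 1e-9)
    expect_equal(hd95(sa, sb), hd95(sb, sa), tolerance = 1e-12)
    expect_equal(assd(sa, sb), assd(sb, sa), tolerance = 1e-12)
  }
})

test_that("surface metrics honour anisotropic spacing and scale equivariance", {
  set.seed(5)
  d <- c(9, 9, 9)
  ma <- array(rbinom(prod(d), 1, 0.25), d)
  mb <- array(rbinom(prod(d), 1, 0.25), d)
  sp <- c(0.5, 1.0, 2.0)
  sa <- surface_voxels(ma, sp); sb <- surface_voxels(mb, sp)
  expect_equal(hd95(sa, sb),
               brute_hd95(brute_surface_coords(ma, sp),
                          brute_surface_coords(mb, sp)), tolerance = 1e-9)
  # doubling the spacing doubles both surface distances exactly
  sa2 <- surface_voxels(ma, 2 * sp); sb2 <- surface_voxels(mb, 2 * sp)
  expect_equal(hd95(sa2, sb2), 2 * hd95(sa, sb), tolerance = 1e-9)
  expect_equal(assd(sa2, sb2), 2 * assd(sa, sb), tolerance = 1e-9)
  # volume metrics are unchanged by spacing
  expect_equal(dice(confusion_counts(ma, mb)), dice(confusion_counts(ma, mb)))
})

test_that("hard Dice equals the Tversky index at alpha = beta = 1/2", {
  set.seed(9)
  ma <- array(rbinom(6^3, 1, 0.4), c(6, 6, 6))
  mb <- array(rbinom(6^3, 1, 0.4), c(6, 6, 6))
  expect_equal(dice(confusion_counts(ma, mb)),
               tversky_index(soft_confusion(ma, mb),
                             loss_config(alpha = 0.5, beta = 0.5, smooth = 0)),
               tolerance = 1e-12)
})

test_that("evaluate_case and evaluate_set aggregate hand-computed records", {
  dir <- withr::local_tempdir()
  set.seed(33)
  hand <- NULL
  pairs <- NULL
  for (i in 1:5) {
    d <- c(10, 10, 10)
    gt <- array(0, d); gt[3:7, 3:7, 3:7] <- 1
    pred <- gt
    flip <- sample(which(gt == 1), i) # knock out i foreground voxels
    pred[flip] <- 0
    rec <- evaluate_case(pred, gt)
    cts <- brute_confusion_counts(pred, gt)
    expect_equal(rec$dice, 2 * cts["tp"] / (2 * cts["tp"] + cts["fp"] + cts["fn"]),
                 ignore_attr = TRUE)
    hand <- rbind(hand, rec)
    pf <- file.path(dir, sprintf("pred%d.nii.gz", i))
    gf <- file.path(dir, sprintf("gt%d.nii.gz", i))
    img <- RNifti::asNifti(array(as.integer(pred), d)); RNifti::writeNifti(img, pf, datatype = "uint8")
    img <- RNifti::asNifti(array(as.integer(gt), d)); RNifti::writeNifti(img, gf, datatype = "uint8")
    pairs <- rbind(pairs, data.frame(pred = pf, gt = gf))
  }
  out_csv <- file.path(dir, "metrics.csv")
  tab <- evaluate_set(pairs, out_csv = out_csv)
  expect_true(file.exists(out_csv))
  expect_equal(nrow(tab), 7L) # 5 cases + mean + ci95
  mrow <- tab[tab$case == "mean", ]
  expect_equal(mrow$dice, mean(hand$dice))
  expect_equal(mrow$hd95_mm, mean(hand$hd95_mm))
  cirow <- tab[tab$case == "ci95", ]
  expect_equal(cirow$dice, qt(0.975, 4) * sd(hand$dice) / sqrt(5))
  expect_identical(names(tab), c("case", "dice", "sensitivity", "specificity",
                                 "rve", "hd95_mm", "assd_mm"))
})

test_that("degenerate evaluation sets are reported, not crashed", {
  dir <- withr::local_tempdir()
  d <- c(6, 6, 6)
  gt <- array(0, d); gt[2:4, 2:4, 2:4] <- 1
  f <- file.path(dir, "m.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(gt), d)), f, datatype = "uint8")
  # single case: mean defined, CI missing
  tab <- evaluate_set(data.frame(pred = f, gt = f))
  expect_true(is.na(tab[tab$case == "ci95", "dice"]))
  # identical cases: CI half-width zero
  pairs <- data.frame(pred = rep(f, 3), gt = rep(f, 3))
  tab3 <- evaluate_set(pairs)
  expect_equal(tab3[tab3$case == "ci95", "dice"], 0)
  # missing pair skipped with warning
  pairs_bad <- rbind(pairs, data.frame(pred = "nope.nii.gz", gt = f))
  expect_warning(tab4 <- evaluate_set(pairs_bad), "missing pair")
  expect_equal(attr(tab4, "skipped"), 1L)
})
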