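# Segmentation evaluation: four volume measures (Dice, sensitivity,
# specificity, relative volume error) computed from hard confusion counts,
# and two surface measures in physical millimetres (95th-percentile
# Hausdorff distance and average symmetric surface distance) computed from
# boundary voxels via an exact anisotropic Euclidean distance transform.

#' Hard confusion counts
#'
#' @param pred,gt Binary arrays of equal shape.
#' @return Named numeric vector `c(tp, fp, fn, tn)` summing to the voxel
#'   count.
#' @export
confusion_counts <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("confusion_counts: shapes differ")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusion_counts: inputs must be binary")
  tp <- sum(pred == 1 & gt == 1)
  fp <- sum(pred == 1 & gt == 0)
  fn <- sum(pred == 0 & gt == 1)
  c(tp = tp, fp = fp, fn = fn, tn = length(pred) - tp - fp - fn)
}

#' Volume-overlap metrics
#'
#' `dice = 2TP/(2TP+FP+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`, and the relative volume error
#' `rve = |V_pred - V_gt| / V_gt` with `V_pred = TP+FP`, `V_gt = TP+FN`
#' (voxel counts; equivalent to physical volumes under uniform spacing).
#' An empty ground truth makes `rve` (and `sensitivity`) undefined; they are
#' reported as `NA` with a warning.
#'
#' @param counts Output of [confusion_counts()].
#' @return Scalar metric value.
#' @name volume_metrics
NULL

#' @rdname volume_metrics
#' @export
dice <- function(counts) {
  den <- 2 * counts[["tp"]] + counts[["fp"]] + counts[["fn"]]
  if (den == 0) return(1) # both masks empty: perfect agreement convention
  2 * counts[["tp"]] / den
}

#' @rdname volume_metrics
#' @export
sensitivity <- function(counts) {
  den <- counts[["tp"]] + counts[["fn"]]
  if (den == 0) {
    warning("sensitivity undefined: empty ground truth")
    return(NA_real_)
  }
  counts[["tp"]] / den
}

#' @rdname volume_metrics
#' @export
specificity <- function(counts) {
  den <- counts[["tn"]] + counts[["fp"]]
  if (den == 0) return(NA_real_)
  counts[["tn"]] / den
}

#' @rdname volume_metrics
#' @export
rve <- function(counts) {
  v_gt <- counts[["tp"]] + counts[["fn"]]
  if (v_gt == 0) {
    warning("rve undefined: empty ground truth")
    return(NA_real_)
  }
  abs((counts[["tp"]] + counts[["fp"]]) - v_gt) / v_gt
}

#' Boundary voxels of a binary mask
#'
#' A surface voxel is a foreground voxel with at least one background
#' 6-neighbour (voxels on the array border count their outside as
#' background). Coordinates are returned in physical mm, scaled by the voxel
#' spacing.
#'
#' @param mask Binary 3D array; must contain at least one foreground voxel.
#' @param spacing Voxel spacing in mm, length 3.
#' @return Object of class `surface_set`: list with `coords` (n x 3 matrix,
#'   mm), the logical `voxels` array, and `spacing`.
#' @export
surface_voxels <- function(mask, spacing = c(1, 1, 1)) {
  if (!any(mask == 1)) stop("surface_voxels: mask is empty")
  d <- dim(mask)
  m <- array(mask == 1, d)
  interior <- array(TRUE, d)
  shift_all <- function(f) {
    # f(m) shifted along each axis; border treated as background
    out <- array(TRUE, d)
    for (ax in 1:3) {
      for (dir in c(-1L, 1L)) {
        shifted <- array(FALSE, d)
        idx_src <- idx_dst <- lapply(d, seq_len)
        rng <- seq_len(d[ax] - 1L)
        idx_dst[[ax]] <- if (dir == 1L) rng + 1L else rng
        idx_src[[ax]] <- if (dir == 1L) rng else rng + 1L
        shifted[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
          m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
        out <- out & shifted
      }
    }
    out
  }
  interior <- shift_all(m)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  coords <- sweep(idx, 2, spacing, `*`)
  structure(list(coords = coords, voxels = surf, spacing = spacing),
            class = "surface_set")
}

# directed surface distances d(a, B) for all a in A, via the exact EDT of B
directed_surface_distances <- function(a, b) {
  dt <- cpp_edt(b$voxels, as.numeric(b$spacing))
  idx <- which(a$voxels)
  dt[idx]
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' `HD95 = max(P95{d(a,B)}, P95{d(b,A)})` over the two directed surface
#' distance distributions — the max-of-directed-percentiles convention, with
#' the linear-interpolation percentile definition.
#'
#' @param a,b `surface_set` objects from [surface_voxels()].
#' @return Distance in mm.
#' @export
hd95 <- function(a, b) {
  stopifnot(inherits(a, "surface_set"), inherits(b, "surface_set"))
  max(stats::quantile(directed_surface_distances(a, b), 0.95, names = FALSE),
      stats::quantile(directed_surface_distances(b, a), 0.95, names = FALSE))
}

#' Average symmetric surface distance (mm)
#'
#' `ASSD = (sum_A d(a,B) + sum_B d(b,A)) / (|A| + |B|)`.
#'
#' @param a,b `surface_set` objects from [surface_voxels()].
#' @return Distance in mm.
#' @export
assd <- function(a, b) {
  stopifnot(inherits(a, "surface_set"), inherits(b, "surface_set"))
  da <- directed_surface_distances(a, b)
  db <- directed_surface_distances(b, a)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

#' Evaluate one prediction against its reference
#'
#' @param pred_mask,gt_mask Binary 3D arrays.
#' @param spacing Voxel spacing in mm.
#' @return One-row data frame with columns `dice`, `sensitivity`,
#'   `specificity`, `rve`, `hd95_mm`, `assd_mm`.
#' @export
evaluate_case <- function(pred_mask, gt_mask, spacing = c(1, 1, 1)) {
  counts <- confusion_counts(pred_mask, gt_mask)
  surf_ok <- any(pred_mask == 1) && any(gt_mask == 1)
  if (surf_ok) {
    sa <- surface_voxels(pred_mask, spacing)
    sb <- surface_voxels(gt_mask, spacing)
    h <- hd95(sa, sb)
    s <- assd(sa, sb)
  } else {
    warning("surface metrics undefined: empty prediction or reference mask")
    h <- NA_real_
    s <- NA_real_
  }
  data.frame(dice = dice(counts), sensitivity = sensitivity(counts),
             specificity = specificity(counts), rve = rve(counts),
             hd95_mm = h, assd_mm = s)
}

# t-interval half-width for the mean at the 95% level
ci95_halfwidth <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::qt(0.975, n - 1L) * stats::sd(x) / sqrt(n)
}

#' Evaluate a set of prediction/reference pairs
#'
#' Computes [evaluate_case()] for every pair and appends an aggregate row
#' holding the mean and the 95% t-interval half-width of each metric over
#' cases. With a single case the interval is undefined and reported missing.
#' Pairs whose files are absent are reported and skipped.
#'
#' @param pairs Data frame with columns `pred` and `gt` (NIfTI mask paths)
#'   and optionally `case`.
#' @param out_csv Optional path; when given the table is written as CSV.
#' @return Data frame: one row per case plus rows `mean` and `ci95`.
#' @export
evaluate_set <- function(pairs, out_csv = NULL) {
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(pairs))) {
    if (!file.exists(pairs$pred[i]) || !file.exists(pairs$gt[i])) {
      warning("missing pair skipped: ", pairs$pred[i], " / ", pairs$gt[i])
      skipped <- skipped + 1L
      next
    }
    pm <- read_mask_nifti(pairs$pred[i])
    gm <- read_mask_nifti(pairs$gt[i])
    rec <- evaluate_case(pm$mask, gm$mask, gm$spacing)
    rec$case <- if ("case" %in% names(pairs)) pairs$case[i]
                else basename(pairs$gt[i])
    rows[[length(rows) + 1L]] <- rec
  }
  if (length(rows) == 0) stop("evaluate_set: no evaluable pairs")
  tab <- do.call(rbind, rows)
  metrics <- c("dice", "sensitivity", "specificity", "rve", "hd95_mm", "assd_mm")
  agg_mean <- tab[1, ]
  agg_mean[metrics] <- vapply(metrics, function(m) mean(tab[[m]], na.rm = TRUE),
                              numeric(1))
  agg_mean$case <- "mean"
  agg_ci <- tab[1, ]
  agg_ci[metrics] <- vapply(metrics, function(m) ci95_halfwidth(tab[[m]]),
                            numeric(1))
  agg_ci$case <- "ci95"
  out <- rbind(tab, agg_mean, agg_ci)
  out <- out[, c("case", metrics)]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
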