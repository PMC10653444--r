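# Independent brute-force oracles. These deliberately use plain R loops and
# no package internals, so they cannot share a bug with the implementation
# they check.

# per-voxel soft confusion accumulation
brute_soft_confusion <- function(p, g) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(p)) {
    tp <- tp + g[i] * p[i]
    fp <- fp + (1 - g[i]) * p[i]
    fn <- fn + g[i] * (1 - p[i])
    tn <- tn + (1 - g[i]) * (1 - p[i])
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

brute_confusion_counts <- function(pred, gt) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1L
    else if (pred[i] == 1 && gt[i] == 0) fp <- fp + 1L
    else if (pred[i] == 0 && gt[i] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# boundary voxels under the 6-neighbour erosion definition, coords in mm
brute_surface_coords <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask[i, j, k] != 1) next
    nb <- c(
      if (i > 1) mask[i - 1, j, k] else 0, if (i < d[1]) mask[i + 1, j, k] else 0,
      if (j > 1) mask[i, j - 1, k] else 0, if (j < d[2]) mask[i, j + 1, k] else 0,
      if (k > 1) mask[i, j, k - 1] else 0, if (k < d[3]) mask[i, j, k + 1] else 0)
    if (any(nb == 0)) out <- rbind(out, c(i, j, k) * spacing)
  }
  out
}

# exhaustive O(|A||B|) directed surface distances
brute_directed_dists <- function(a_coords, b_coords) {
  apply(a_coords, 1, function(p)
    sqrt(min(colSums((t(b_coords) - p)^2))))
}

brute_hd95 <- function(a_coords, b_coords) {
  max(quantile(brute_directed_dists(a_coords, b_coords), 0.95, names = FALSE),
      quantile(brute_directed_dists(b_coords, a_coords), 0.95, names = FALSE))
}

brute_assd <- function(a_coords, b_coords) {
  da <- brute_directed_dists(a_coords, b_coords)
  db <- brute_directed_dists(b_coords, a_coords)
  (sum(da) + sum(db)) / (length(da) + length(db))
}

# 26-connected component count by breadth-first search
brute_n_components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask == 1, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    if (lab[v[1], v[2], v[3]] != 0L) next
    ncomp <- ncomp + 1L
    queue <- list(v)
    lab[v[1], v[2], v[3]] <- ncomp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (o in seq_len(nrow(offs))) {
        nb <- cur + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] == 1 && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- ncomp
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  ncomp
}

# supersampled volume integration of geometric predicates: fraction of s^3
# sub-voxel centers inside the solid, summed over a voxel box
supersampled_count <- function(shape, inside_fn, s = 4L) {
  sub <- (seq_len(s) - (s + 1) / 2) / s
  total <- 0
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) for (k in seq_len(shape[3])) {
    hits <- 0L
    for (ox in sub) for (oy in sub) for (oz in sub)
      if (inside_fn(i + ox, j + oy, k + oz)) hits <- hits + 1L
    total <- total + hits / s^3
  }
  total
}

# independent corner-aligned trilinear resampling of a (D,H,W,C,N) tensor
brute_trilinear <- function(x, out_size) {
  d <- dim(x)
  out <- array(0, c(out_size, d[4], d[5]))
  axw <- function(nin, nout, i) {
    if (nout == 1 || nin == 1) return(c(1, 1, 1, 0))
    s <- (i - 1) * (nin - 1) / (nout - 1)
    i0 <- min(floor(s), nin - 2)
    f <- s - i0
    c(i0 + 1, i0 + 2, 1 - f, f)
  }
  for (c_ in seq_len(d[4])) for (n_ in seq_len(d[5]))
    for (i in seq_len(out_size[1])) for (j in seq_len(out_size[2]))
      for (k in seq_len(out_size[3])) {
        a <- axw(d[1], out_size[1], i)
        b <- axw(d[2], out_size[2], j)
        cc <- axw(d[3], out_size[3], k)
        acc <- 0
        for (u in 1:2) for (v in 1:2) for (w_ in 1:2)
          acc <- acc + a[2 + u] * b[2 + v] * cc[2 + w_] *
            x[a[u], b[v], cc[w_], c_, n_]
        out[i, j, k, c_, n_] <- acc
      }
  out
}

# independent dense 3D convolution (stride 1, "same" padding pad = dil)
brute_conv3 <- function(x, w, b, dil = 1L) {
  d <- dim(x)
  cout <- dim(w)[5]
  y <- array(0, c(d[1:3], cout, d[5]))
  for (n_ in seq_len(d[5])) for (co in seq_len(cout))
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      acc <- b[co]
      for (ci in seq_len(d[4])) for (kd in 1:3) for (kh in 1:3) for (kw in 1:3) {
        ii <- i + dil * (kd - 2); jj <- j + dil * (kh - 2); kk <- k + dil * (kw - 2)
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && kk >= 1 && kk <= d[3])
          acc <- acc + x[ii, jj, kk, ci, n_] * w[kd, kh, kw, ci, co]
      }
      y[i, j, k, co, n_] <- acc
    }
  y
}

make_test_phantom_cases <- function(n, shape = c(32L, 32L, 32L), seed = 5L,
                                    geometry = "shell") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_dataset(n, geometry, shape = shape, seed = seed, out_dir = dir)
}
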