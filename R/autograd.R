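# Reverse-mode automatic differentiation over a define-by-run tape.
#
# Feature arrays ("tensors") are dense R double arrays of dimension
# (D, H, W, C, N): three spatial axes, channels, batch.  A node wraps one
# array together with the closure that maps its output gradient to the
# gradients of its parents.  Recording is active whenever a tape has been
# installed with `ag_tape()`; without a tape the ops still compute values,
# so inference pays no bookkeeping cost.

.snet <- new.env(parent = emptyenv())
.snet$tape <- NULL

ag_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

with_tape <- function(tape, expr) {
  old <- .snet$tape
  .snet$tape <- tape
  on.exit(.snet$tape <- old)
  force(expr)
}

ag_node <- function(value, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  t <- .snet$tape
  if (!is.null(t) && !is.null(backfn)) {
    if (t$n >= length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$n <- t$n + 1L
    t$nodes[[t$n]] <- nd
  }
  nd
}

ag_const <- function(value) ag_node(value)

is_ag_node <- function(x) is.environment(x) && !is.null(x$value)

#' @noRd
ag_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL # free intermediate gradients eagerly
  }
  invisible(NULL)
}

# ---- tensor helpers ---------------------------------------------------------

#' Reshape a 3D volume into the (D, H, W, C, N) tensor layout
#' @noRd
as_tensor <- function(vol) {
  d <- dim(vol)
  if (length(d) == 3L) dim(vol) <- c(d, 1L, 1L)
  if (length(dim(vol)) != 5L) stop("expected a 3D or 5D array")
  vol
}

tensor_spatial <- function(x) dim(x)[1:3]

# ---- primitive ops ----------------------------------------------------------

ag_conv3d <- function(x, w, b, stride = 1L, pad = 1L, dil = 1L) {
  v <- cpp_conv3d_fwd(x$value, w$value, b$value,
                      as.integer(stride), as.integer(pad), as.integer(dil))
  xv <- x$value; wv <- w$value
  ag_node(v, list(x, w, b), function(g) {
    gr <- cpp_conv3d_bwd(xv, wv, g, as.integer(stride), as.integer(pad),
                         as.integer(dil))
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_convt2 <- function(x, w, b) {
  v <- cpp_convt3d_fwd(x$value, w$value, b$value)
  xv <- x$value; wv <- w$value
  ag_node(v, list(x, w, b), function(g) {
    gr <- cpp_convt3d_bwd(xv, wv, g)
    list(gr$gx, gr$gw, gr$gb)
  })
}

ag_prelu <- function(x, a) {
  xv <- x$value
  av <- a$value[1L]
  v <- cpp_prelu_fwd(xv, av)
  ag_node(v, list(x, a), function(g) {
    gr <- cpp_prelu_bwd(xv, av, g)
    list(gr$gx, gr$ga)
  })
}

ag_add <- function(x, y) {
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_concat <- function(x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  if (any(dx[c(1:3, 5)] != dy[c(1:3, 5)]))
    stop("concat: spatial/batch dimensions disagree")
  v <- array(0, c(dx[1:3], dx[4] + dy[4], dx[5]))
  ix <- seq_len(dx[4])
  v[, , , ix, ] <- x$value
  v[, , , dx[4] + seq_len(dy[4]), ] <- y$value
  ag_node(v, list(x, y), function(g) {
    list(g[, , , ix, , drop = FALSE],
         g[, , , dx[4] + seq_len(dy[4]), , drop = FALSE])
  })
}

ag_interp <- function(x, out_size) {
  out_size <- as.integer(out_size)
  in_size <- dim(x$value)[1:3]
  if (all(in_size == out_size)) return(x) # identity resampling: pass through
  v <- cpp_interp3d_fwd(x$value, out_size)
  ag_node(v, list(x), function(g) list(cpp_interp3d_bwd(g, in_size)))
}

ag_sigmoid <- function(x) {
  v <- cpp_sigmoid_fwd(x$value)
  ag_node(v, list(x), function(g) list(cpp_sigmoid_bwd(v, g)))
}

# Inverted dropout: zero with probability p, scale survivors by 1/(1-p) so
# activations keep their expectation; masks come from the session RNG.
ag_dropout <- function(x, p) {
  if (p <= 0) return(x)
  dr <- cpp_dropout_fwd(x$value, p)
  mask <- dr$mask
  ag_node(dr$y, list(x), function(g) list(cpp_mul(g, mask)))
}

ag_pick <- function(x, idx) {
  # scalar read of one tensor element; used by the gradient-footprint probe
  xv <- x$value
  ag_node(xv[idx[1], idx[2], idx[3], idx[4], idx[5]], list(x), function(g) {
    gx <- array(0, dim(xv))
    gx[idx[1], idx[2], idx[3], idx[4], idx[5]] <- g
    list(gx)
  })
}

ag_sum_nodes <- function(nodes) {
  v <- sum(vapply(nodes, function(n) n$value, numeric(1)))
  ag_node(v, nodes, function(g) rep(list(g), length(nodes)))
}

# One supervision term: 1 - Tversky index of a soft prediction against a
# binary reference, differentiable in the prediction.
ag_tversky_term <- function(p, gt, alpha, beta, smooth) {
  cts <- cpp_soft_counts(p$value, gt)
  tp <- cts[["tp"]]
  den <- tp + alpha * cts[["fp"]] + beta * cts[["fn"]] + smooth
  ti <- if (den > 0) (tp + smooth) / den else 1
  ag_node(1 - ti, list(p), function(g) {
    list(cpp_tversky_grad(gt, tp, den, alpha, beta, smooth, g))
  })
}
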