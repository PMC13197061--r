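# A small reverse-mode automatic differentiation engine on dense matrices.
# The denoising network is expressed once in terms of these operations; when
# every operand is a plain matrix they compute eagerly with no tape (the
# inference path), and when any operand is a tracked node the result is
# recorded for the backward pass (the training path). Creation order of nodes
# is a topological order, so backpropagation is a single reverse sweep.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$n <- 0L
  e
}

is_adnode <- function(x) inherits(x, "adnode")

ad_value <- function(x) if (is_adnode(x)) x$val else x

# Register a new node on the tape. `parents` is a list of adnodes (constants
# excluded); `back` maps the incoming gradient to a list of parent gradients.
ad_node <- function(tape, val, parents, back) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- vapply(parents, function(p) p$id, integer(1))
  n$back <- back
  tape$n <- tape$n + 1L
  n$id <- tape$n
  n$tape <- tape
  tape$nodes[[n$id]] <- n
  class(n) <- "adnode"
  n
}

#' Create a tracked parameter node
#'
#' Wraps a matrix as a leaf on the tape so gradients with respect to it are
#' accumulated by [ad_backward()].
#' @param tape A tape from `ad_tape()`.
#' @param val Numeric matrix.
#' @return An `adnode`.
#' @keywords internal
ad_param <- function(tape, val) {
  ad_node(tape, val, list(), NULL)
}

tape_of <- function(...) {
  for (x in list(...)) if (is_adnode(x)) return(x$tape)
  NULL
}

# Reduce a gradient to the shape of a broadcast operand.
reduce_to <- function(g, dim_target) {
  if (is.null(dim(g))) g <- as.matrix(g)
  if (nrow(g) != dim_target[1]) g <- matrix(colSums(g), 1)
  if (ncol(g) != dim_target[2]) g <- matrix(rowSums(g), ncol = 1)
  g
}

# Broadcast b to the shape of a (row vector, column vector or scalar).
bcast <- function(b, d) {
  if (is.null(dim(b))) {
    if (length(b) == 1) return(matrix(b, d[1], d[2]))
    stop("cannot broadcast plain vector; supply a matrix")
  }
  if (all(dim(b) == d)) return(b)
  if (nrow(b) == 1 && ncol(b) == d[2]) return(matrix(b, d[1], d[2], byrow = TRUE))
  if (ncol(b) == 1 && nrow(b) == d[1]) return(matrix(b, d[1], d[2]))
  if (all(dim(b) == c(1, 1))) return(matrix(b[1], d[1], d[2]))
  stop("incompatible shapes for broadcasting")
}

dim2 <- function(x) if (is.null(dim(x))) c(1L, length(x)) else dim(x)

ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  val <- bcast(av, dim2(if (length(bv) > length(av)) bv else av)) +
         bcast(bv, dim2(if (length(bv) > length(av)) bv else av))
  t <- tape_of(a, b)
  if (is.null(t)) return(val)
  parents <- Filter(is_adnode, list(a, b))
  ad_node(t, val, parents, function(g) {
    out <- list()
    if (is_adnode(a)) out <- c(out, list(reduce_to(g, dim2(av))))
    if (is_adnode(b)) out <- c(out, list(reduce_to(g, dim2(bv))))
    out
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

ad_scale <- function(a, k) {
  av <- ad_value(a)
  val <- av * k
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) list(g * k))
}

ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  d <- dim2(if (length(bv) > length(av)) bv else av)
  ab <- bcast(av, d); bb <- bcast(bv, d)
  val <- ab * bb
  t <- tape_of(a, b)
  if (is.null(t)) return(val)
  parents <- Filter(is_adnode, list(a, b))
  ad_node(t, val, parents, function(g) {
    out <- list()
    if (is_adnode(a)) out <- c(out, list(reduce_to(g * bb, dim2(av))))
    if (is_adnode(b)) out <- c(out, list(reduce_to(g * ab, dim2(bv))))
    out
  })
}

ad_pow <- function(a, p) {
  av <- ad_value(a)
  val <- av^p
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) list(g * p * av^(p - 1)))
}

ad_mm <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  val <- av %*% bv
  t <- tape_of(a, b)
  if (is.null(t)) return(val)
  parents <- Filter(is_adnode, list(a, b))
  ad_node(t, val, parents, function(g) {
    out <- list()
    if (is_adnode(a)) out <- c(out, list(g %*% t(bv)))
    if (is_adnode(b)) out <- c(out, list(crossprod(av, g)))
    out
  })
}

ad_silu <- function(a) {
  av <- ad_value(a)
  s <- 1 / (1 + exp(-av))
  val <- av * s
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) list(g * (s + av * s * (1 - s))))
}

# Row gather: out = x[idx, ]. Backward scatter-adds, so the same op also
# serves as block pooling and row replication (idx with repeats).
ad_gather <- function(a, idx) {
  av <- ad_value(a)
  val <- av[idx, , drop = FALSE]
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(g, group = idx)
    da[as.integer(rownames(acc)), ] <- acc
    list(da)
  })
}

# Row scatter into a zero matrix of nrow_out rows: out[idx, ] = x. Serves as
# zero-padding up-pooling on block-stacked batches.
ad_scatter <- function(a, idx, nrow_out) {
  av <- ad_value(a)
  val <- matrix(0, nrow_out, ncol(av))
  val[idx, ] <- av
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) list(g[idx, , drop = FALSE]))
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  val <- do.call(cbind, vals)
  t <- do.call(tape_of, xs)
  if (is.null(t)) return(val)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  tracked <- which(vapply(xs, is_adnode, logical(1)))
  ad_node(t, val, xs[tracked], function(g) {
    lapply(tracked, function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ad_rbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  val <- do.call(rbind, vals)
  t <- do.call(tape_of, xs)
  if (is.null(t)) return(val)
  heights <- vapply(vals, nrow, integer(1))
  ends <- cumsum(heights)
  starts <- ends - heights + 1L
  tracked <- which(vapply(xs, is_adnode, logical(1)))
  ad_node(t, val, xs[tracked], function(g) {
    lapply(tracked, function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cols <- function(a, j) {
  av <- ad_value(a)
  val <- av[, j, drop = FALSE]
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    da[, j] <- da[, j] + g
    list(da)
  })
}

ad_rowmean <- function(a) {
  av <- ad_value(a)
  m <- ncol(av)
  val <- matrix(rowMeans(av), ncol = 1)
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) list(matrix(g, nrow(av), m) / m))
}

ad_softmax_rows <- function(a) {
  av <- ad_value(a)
  z <- av - apply(av, 1, max)
  e <- exp(z)
  val <- e / rowSums(e)
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) {
    list(val * (g - rowSums(g * val)))
  })
}

ad_t <- function(a) {
  av <- ad_value(a)
  val <- t(av)
  tp <- tape_of(a)
  if (is.null(tp)) return(val)
  ad_node(tp, val, list(a), function(g) list(t(g)))
}

ad_mean <- function(a) {
  av <- ad_value(a)
  val <- matrix(mean(av), 1, 1)
  t <- tape_of(a)
  if (is.null(t)) return(val)
  ad_node(t, val, list(a), function(g) {
    list(matrix(g[1] / length(av), nrow(av), ncol(av)))
  })
}

#' Reverse sweep over a tape
#'
#' Accumulates gradients of `loss` (a 1x1 node) with respect to every tracked
#' node; afterwards `ad_grad(node)` returns each gradient.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_adnode(loss))
  tape <- loss$tape
  tape$grad <- vector("list", tape$n)
  tape$grad[[loss$id]] <- matrix(1, 1, 1)
  for (id in seq(loss$id, 1L)) {
    g <- tape$grad[[id]]
    node <- tape$nodes[[id]]
    if (is.null(g) || is.null(node$back)) next
    pg <- node$back(g)
    for (k in seq_along(node$parents)) {
      pid <- node$parents[k]
      tape$grad[[pid]] <- if (is.null(tape$grad[[pid]])) pg[[k]]
                          else tape$grad[[pid]] + pg[[k]]
    }
  }
  invisible(NULL)
}

ad_grad <- function(node) {
  g <- node$tape$grad[[node$id]]
  if (is.null(g)) matrix(0, nrow(node$val), ncol(node$val)) else g
}

# ---- fused operations -------------------------------------------------------
# The two composites that dominate the denoiser (the 7-tap spherical
# convolution and the per-vertex channel normalization) are fused into single
# nodes with hand-derived backward passes to keep the tape short.

# out = [x[i1,] x[i2,] ... x[i7,]] %*% W + b ; idx7 = list of 7 row indices.
ad_sphconv <- function(x, W, b, idx7) {
  xv <- ad_value(x); Wv <- ad_value(W); bv <- ad_value(b)
  G <- do.call(cbind, lapply(idx7, function(i) xv[i, , drop = FALSE]))
  val <- G %*% Wv
  val <- val + matrix(bv, nrow(val), ncol(val), byrow = TRUE)
  t <- tape_of(x, W, b)
  if (is.null(t)) return(val)
  cin <- ncol(xv)
  parents <- Filter(is_adnode, list(x, W, b))
  ad_node(t, val, parents, function(g) {
    out <- list()
    if (is_adnode(x)) {
      dG <- g %*% t(Wv)
      stacked <- do.call(rbind, lapply(1:7, function(k)
        dG[, (k - 1) * cin + seq_len(cin), drop = FALSE]))
      acc <- rowsum(stacked, group = unlist(idx7, use.names = FALSE))
      dx <- matrix(0, nrow(xv), cin)
      dx[as.integer(rownames(acc)), ] <- acc
      out <- c(out, list(dx))
    }
    if (is_adnode(W)) out <- c(out, list(crossprod(G, g)))
    if (is_adnode(b)) out <- c(out, list(matrix(colSums(g), 1)))
    out
  })
}

# Per-row (vertex) normalization over channels with affine parameters:
# y = (x - mean_row) / sqrt(var_row + 1e-5); out = y * gain + bias.
ad_channelnorm <- function(x, gain, bias) {
  xv <- ad_value(x); gv <- ad_value(gain); bv <- ad_value(bias)
  m <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  sig <- sqrt(rowMeans(xc^2) + 1e-5)
  y <- xc / sig
  val <- y * matrix(gv, nrow(xv), m, byrow = TRUE) +
         matrix(bv, nrow(xv), m, byrow = TRUE)
  t <- tape_of(x, gain, bias)
  if (is.null(t)) return(val)
  parents <- Filter(is_adnode, list(x, gain, bias))
  ad_node(t, val, parents, function(g) {
    out <- list()
    dy <- g * matrix(gv, nrow(g), m, byrow = TRUE)
    if (is_adnode(x)) {
      dx <- (dy - rowMeans(dy) - y * rowMeans(dy * y)) / sig
      out <- c(out, list(dx))
    }
    if (is_adnode(gain)) out <- c(out, list(matrix(colSums(g * y), 1)))
    if (is_adnode(bias)) out <- c(out, list(matrix(colSums(g), 1)))
    out
  })
}
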