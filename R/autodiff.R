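# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value is a numeric matrix (scalars are 1x1). A node is an environment
# holding $val, $grad, and a $backward closure that pushes the node's gradient
# into its parents. Operations record nodes on the active tape in execution
# order; ad_backward() seeds the loss gradient and replays the tape in
# reverse. This is the substrate for the trainable encoder/decoder stack;
# no deep-learning framework is available in this environment.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Start recording an autodiff tape
#'
#' Discards any previous tape. All subsequent `ad_*` operations whose inputs
#' require gradients are recorded until the next call.
#' @return invisibly, the new (empty) tape environment.
#' @keywords internal
#' @export
ad_begin <- function() {
  tape <- new.env(parent = emptyenv())
  tape$head <- NULL      # linked list, newest node first: O(1) push
  .ad$tape <- tape
  invisible(tape)
}

ad_record <- function(node) {
  tape <- .ad$tape
  if (is.null(tape)) stop("no active tape; call ad_begin() first")
  tape$head <- list(node = node, prev = tape$head)
  node
}

new_node <- function(val, parents = list(), backward = NULL, requires = FALSE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backward <- backward
  node$requires <- requires
  class(node) <- "ad_node"
  node
}

#' Wrap a constant (no gradient) or a parameter (gradient target)
#' @param x numeric matrix, vector, or scalar.
#' @return an `ad_node`.
#' @keywords internal
#' @export
ad_const <- function(x) new_node(as_mat(x))

#' @rdname ad_const
#' @export
ad_param <- function(x) {
  n <- new_node(as_mat(x), requires = TRUE)
  n$grad <- matrix(0, nrow(n$val), ncol(n$val))
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), nrow = 1L)
}

as_node <- function(x) if (inherits(x, "ad_node")) x else ad_const(x)

#' Value of a node
#' @param x an `ad_node`.
#' @return its numeric matrix value.
#' @keywords internal
#' @export
ad_value <- function(x) x$val

acc_grad <- function(node, g) {
  if (node$requires)
    node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

make_op <- function(val, parents, backward) {
  requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  node <- new_node(val, parents, if (requires) backward else NULL, requires)
  if (requires) ad_record(node)
  node
}

#' Run backpropagation from a scalar loss node
#' @param loss a 1x1 `ad_node` on the active tape.
#' @keywords internal
#' @export
ad_backward <- function(loss) {
  stopifnot(inherits(loss, "ad_node"))
  if (!loss$requires) return(invisible(NULL))
  loss$grad <- matrix(1, nrow(loss$val), ncol(loss$val))
  cell <- .ad$tape$head
  while (!is.null(cell)) {            # newest-first = reverse execution order
    node <- cell$node
    if (!is.null(node$grad) && !is.null(node$backward))
      node$backward(node, node$grad)
    cell <- cell$prev
  }
  invisible(NULL)
}

# ---- arithmetic ------------------------------------------------------------

#' Autodiff operations
#'
#' Elementwise and matrix operations recorded on the tape. All values are
#' dense numeric matrices; scalars are 1x1.
#' @name ad_ops
#' @keywords internal
NULL

#' @rdname ad_ops
#' @param a,b input nodes (or numerics, auto-wrapped as constants).
#' @export
ad_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  stopifnot(identical(dim(a$val), dim(b$val)))
  make_op(a$val + b$val, list(a, b), function(node, g) {
    acc_grad(node$parents[[1]], g); acc_grad(node$parents[[2]], g)
  })
}

#' @rdname ad_ops
#' @param v a 1 x k row-vector node broadcast over the rows of `a`.
#' @export
ad_add_rowvec <- function(a, v) {
  a <- as_node(a); v <- as_node(v)
  stopifnot(nrow(v$val) == 1L, ncol(a$val) == ncol(v$val))
  make_op(sweep(a$val, 2L, v$val[1L, ], "+"), list(a, v), function(node, g) {
    acc_grad(node$parents[[1]], g)
    acc_grad(node$parents[[2]], matrix(colSums(g), nrow = 1L))
  })
}

#' @rdname ad_ops
#' @export
ad_sub <- function(a, b) ad_add(a, ad_scale(as_node(b), -1))

#' @rdname ad_ops
#' @param s a plain numeric scalar.
#' @export
ad_scale <- function(a, s) {
  a <- as_node(a)
  make_op(a$val * s, list(a), function(node, g)
    acc_grad(node$parents[[1]], g * s))
}

#' @rdname ad_ops
#' @export
ad_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  stopifnot(identical(dim(a$val), dim(b$val)))
  make_op(a$val * b$val, list(a, b), function(node, g) {
    acc_grad(node$parents[[1]], g * node$parents[[2]]$val)
    acc_grad(node$parents[[2]], g * node$parents[[1]]$val)
  })
}

#' @rdname ad_ops
#' @export
ad_matmul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  make_op(a$val %*% b$val, list(a, b), function(node, g) {
    acc_grad(node$parents[[1]], g %*% t(node$parents[[2]]$val))
    acc_grad(node$parents[[2]], t(node$parents[[1]]$val) %*% g)
  })
}

#' @rdname ad_ops
#' @export
ad_transpose <- function(a) {
  a <- as_node(a)
  make_op(t(a$val), list(a), function(node, g)
    acc_grad(node$parents[[1]], t(g)))
}

#' @rdname ad_ops
#' @export
ad_sum <- function(a) {
  a <- as_node(a)
  make_op(matrix(sum(a$val), 1L, 1L), list(a), function(node, g)
    acc_grad(node$parents[[1]],
             matrix(g[1L, 1L], nrow(node$parents[[1]]$val),
                    ncol(node$parents[[1]]$val))))
}

#' @rdname ad_ops
#' @export
ad_colsums <- function(a) {
  a <- as_node(a)
  make_op(matrix(colSums(a$val), nrow = 1L), list(a), function(node, g)
    acc_grad(node$parents[[1]],
             matrix(g[1L, ], nrow(node$parents[[1]]$val),
                    ncol(node$parents[[1]]$val), byrow = TRUE)))
}

# ---- nonlinearities --------------------------------------------------------

#' @rdname ad_ops
#' @export
ad_tanh <- function(a) {
  a <- as_node(a)
  y <- tanh(a$val)
  make_op(y, list(a), local({
    y_ <- y
    function(node, g) acc_grad(node$parents[[1]], g * (1 - y_^2))
  }))
}

#' @rdname ad_ops
#' @export
ad_sigmoid <- function(a) {
  a <- as_node(a)
  y <- 1 / (1 + exp(-a$val))
  make_op(y, list(a), local({
    y_ <- y
    function(node, g) acc_grad(node$parents[[1]], g * y_ * (1 - y_))
  }))
}

gelu_val <- function(x) x * stats::pnorm(x)

#' @rdname ad_ops
#' @export
ad_gelu <- function(a) {
  # exact (Gaussian-CDF) GELU: d/dx = Phi(x) + x phi(x)
  a <- as_node(a)
  make_op(gelu_val(a$val), list(a), function(node, g) {
    x <- node$parents[[1]]$val
    acc_grad(node$parents[[1]], g * (stats::pnorm(x) + x * stats::dnorm(x)))
  })
}

#' @rdname ad_ops
#' @export
ad_softmax_rows <- function(a) {
  a <- as_node(a)
  z <- a$val - apply(a$val, 1L, max)
  e <- exp(z)
  y <- e / rowSums(e)
  make_op(y, list(a), local({
    y_ <- y
    function(node, g) {
      dot <- rowSums(g * y_)
      acc_grad(node$parents[[1]], y_ * (g - dot))
    }
  }))
}

# ---- structural ops --------------------------------------------------------

#' @rdname ad_ops
#' @param idx integer row indices; 0 selects an all-zero row (padding).
#' @export
ad_gather_rows <- function(a, idx) {
  a <- as_node(a)
  idx <- as.integer(idx)
  k <- ncol(a$val)
  out <- matrix(0, length(idx), k)
  nz <- idx > 0L
  out[nz, ] <- a$val[idx[nz], , drop = FALSE]
  make_op(out, list(a), local({
    idx_ <- idx; nz_ <- nz
    function(node, g) {
      p <- node$parents[[1]]
      gp <- matrix(0, nrow(p$val), ncol(p$val))
      gs <- rowsum(g[nz_, , drop = FALSE], idx_[nz_])
      gp[as.integer(rownames(gs)), ] <- gs
      acc_grad(p, gp)
    }
  }))
}

#' @rdname ad_ops
#' @param from,to inclusive column bounds.
#' @export
ad_slice_cols <- function(a, from, to) {
  a <- as_node(a)
  make_op(a$val[, from:to, drop = FALSE], list(a), local({
    from_ <- from; to_ <- to
    function(node, g) {
      p <- node$parents[[1]]
      gp <- matrix(0, nrow(p$val), ncol(p$val))
      gp[, from_:to_] <- g
      acc_grad(p, gp)
    }
  }))
}

#' @rdname ad_ops
#' @param nodes list of nodes to concatenate.
#' @export
ad_cbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, function(n) n$val)
  widths <- vapply(vals, ncol, integer(1))
  make_op(do.call(cbind, vals), nodes, local({
    widths_ <- widths
    function(node, g) {
      at <- 0L
      for (i in seq_along(node$parents)) {
        w <- widths_[i]
        acc_grad(node$parents[[i]], g[, (at + 1L):(at + w), drop = FALSE])
        at <- at + w
      }
    }
  }))
}

#' @rdname ad_ops
#' @export
ad_rbind <- function(nodes) {
  nodes <- lapply(nodes, as_node)
  vals <- lapply(nodes, function(n) n$val)
  heights <- vapply(vals, nrow, integer(1))
  make_op(do.call(rbind, vals), nodes, local({
    heights_ <- heights
    function(node, g) {
      at <- 0L
      for (i in seq_along(node$parents)) {
        h <- heights_[i]
        acc_grad(node$parents[[i]], g[(at + 1L):(at + h), , drop = FALSE])
        at <- at + h
      }
    }
  }))
}

#' @rdname ad_ops
#' @param groups list of integer row-index vectors; output row g is the
#'   elementwise max over rows `groups[[g]]`.
#' @export
ad_max_pool_rows <- function(a, groups) {
  a <- as_node(a)
  k <- ncol(a$val)
  out <- matrix(0, length(groups), k)
  argmax <- matrix(0L, length(groups), k)
  for (gi in seq_along(groups)) {
    rows <- groups[[gi]]
    sub <- a$val[rows, , drop = FALSE]
    w <- apply(sub, 2L, which.max)
    argmax[gi, ] <- rows[w]
    out[gi, ] <- sub[cbind(w, seq_len(k))]
  }
  make_op(out, list(a), local({
    argmax_ <- argmax
    function(node, g) {
      p <- node$parents[[1]]
      gp <- matrix(0, nrow(p$val), ncol(p$val))
      for (gi in seq_len(nrow(g)))
        gp[cbind(argmax_[gi, ], seq_len(ncol(g)))] <-
          gp[cbind(argmax_[gi, ], seq_len(ncol(g)))] + g[gi, ]
      acc_grad(p, gp)
    }
  }))
}

#' @rdname ad_ops
#' @param gain,bias 1 x d row-vector nodes (learnable layer-norm affine).
#' @param eps variance floor.
#' @export
ad_layer_norm_rows <- function(a, gain, bias, eps = 1e-5) {
  a <- as_node(a); gain <- as_node(gain); bias <- as_node(bias)
  d <- ncol(a$val)
  mu <- rowMeans(a$val)
  xc <- a$val - mu
  var <- rowMeans(xc^2)
  inv <- 1 / sqrt(var + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, gain$val[1L, ], "*"), 2L, bias$val[1L, ], "+")
  make_op(y, list(a, gain, bias), local({
    xhat_ <- xhat; inv_ <- inv; d_ <- d
    function(node, g) {
      gn <- node$parents[[2]]$val[1L, ]
      gy <- sweep(g, 2L, gn, "*")
      m1 <- rowMeans(gy)
      m2 <- rowMeans(gy * xhat_)
      acc_grad(node$parents[[1]], inv_ * (gy - m1 - xhat_ * m2))
      acc_grad(node$parents[[2]], matrix(colSums(g * xhat_), nrow = 1L))
      acc_grad(node$parents[[3]], matrix(colSums(g), nrow = 1L))
    }
  }))
}

#' @rdname ad_ops
#' @export
ad_l2_normalize_rows <- function(a, eps = 1e-12) {
  a <- as_node(a)
  nrm <- sqrt(rowSums(a$val^2) + eps)
  y <- a$val / nrm
  make_op(y, list(a), local({
    y_ <- y; nrm_ <- nrm
    function(node, g) {
      dot <- rowSums(g * y_)
      acc_grad(node$parents[[1]], (g - y_ * dot) / nrm_)
    }
  }))
}

#' @rdname ad_ops
#' @param logits n x c node of unnormalized scores.
#' @param gold integer vector of gold class indices (1-based), length n.
#' @return 1x1 node: mean negative log-likelihood over the n rows.
#' @export
ad_cross_entropy_rows <- function(logits, gold) {
  logits <- as_node(logits)
  gold <- as.integer(gold)
  n <- nrow(logits$val)
  z <- logits$val - apply(logits$val, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), gold)]
  loss <- -mean(log(pmax(picked, 1e-300)))
  make_op(matrix(loss, 1L, 1L), list(logits), local({
    p_ <- p; gold_ <- gold; n_ <- n
    function(node, g) {
      gp <- p_
      gp[cbind(seq_len(n_), gold_)] <- gp[cbind(seq_len(n_), gold_)] - 1
      acc_grad(node$parents[[1]], g[1L, 1L] * gp / n_)
    }
  }))
}

#' @rdname ad_ops
#' @param xg 1 x 4H node: input projection plus bias for this timestep,
#'   gate order i, f, g, o.
#' @param hc 1 x 2H node: previous hidden and cell state, concatenated.
#' @param U H x 4H recurrent weight node.
#' @return for `ad_lstm_step`, a 1 x 2H node of the new `[h, c]`.
#' @export
ad_lstm_step <- function(xg, hc, U) {
  xg <- as_node(xg); hc <- as_node(hc); U <- as_node(U)
  H <- ncol(U$val)
  h2 <- H %/% 4L
  h_prev <- hc$val[, seq_len(h2), drop = FALSE]
  c_prev <- hc$val[, h2 + seq_len(h2), drop = FALSE]
  z <- xg$val + h_prev %*% U$val
  gi <- 1 / (1 + exp(-z[, seq_len(h2), drop = FALSE]))
  gf <- 1 / (1 + exp(-z[, h2 + seq_len(h2), drop = FALSE]))
  gg <- tanh(z[, 2L * h2 + seq_len(h2), drop = FALSE])
  go <- 1 / (1 + exp(-z[, 3L * h2 + seq_len(h2), drop = FALSE]))
  cc <- gf * c_prev + gi * gg
  tc <- tanh(cc)
  h <- go * tc
  make_op(cbind(h, cc), list(xg, hc, U), local({
    gi_ <- gi; gf_ <- gf; gg_ <- gg; go_ <- go; tc_ <- tc
    c_prev_ <- c_prev; h_prev_ <- h_prev; h2_ <- h2
    function(node, g) {
      dh <- g[, seq_len(h2_), drop = FALSE]
      dc <- g[, h2_ + seq_len(h2_), drop = FALSE] +
        dh * go_ * (1 - tc_^2)
      dz <- cbind(dc * gg_ * gi_ * (1 - gi_),          # i
                  dc * c_prev_ * gf_ * (1 - gf_),      # f
                  dc * gi_ * (1 - gg_^2),              # g
                  dh * tc_ * go_ * (1 - go_))          # o
      Uv <- node$parents[[3]]$val
      acc_grad(node$parents[[1]], dz)
      acc_grad(node$parents[[2]],
               cbind(dz %*% t(Uv), dc * gf_))
      acc_grad(node$parents[[3]], t(h_prev_) %*% dz)
    }
  }))
}

#' @rdname ad_ops
#' @param S m x m similarity node (already divided by the temperature).
#' @return 1x1 node: the instance-discrimination negative log-likelihood
#'   \eqn{\sum_i [\mathrm{logsumexp}_j S_{ji} - S_{ii}]}.
#' @export
ad_discrim_from_sim <- function(S) {
  S <- as_node(S)
  m <- nrow(S$val)
  zmax <- apply(S$val, 2L, max)
  e <- sweep(S$val, 2L, zmax, function(x, mx) exp(x - mx))
  colZ <- colSums(e)
  softmax_cols <- sweep(e, 2L, colZ, "/")
  loss <- sum(log(colZ) + zmax - diag(S$val))
  make_op(matrix(loss, 1L, 1L), list(S), local({
    sm_ <- softmax_cols; m_ <- m
    function(node, g) {
      gS <- sm_
      diag(gS) <- diag(gS) - 1
      acc_grad(node$parents[[1]], g[1L, 1L] * gS)
    }
  }))
}
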