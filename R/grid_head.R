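# Word-pair grid head: conditional layer normalization builds the N x N
# pair representation, distance and region embeddings enrich it, a single
# dilated convolution refines it, and an MLP classifies every cell.
# Grid tensors are carried as (N^2) x channels matrices in row-major
# (condition-word-major) cell order.

#' Grid head configuration
#'
#' @param d_h word-representation dimension entering the head.
#' @param d_d distance-embedding size (20 at full scale).
#' @param d_r region-embedding size (20 at full scale).
#' @param d_g grid channel size after the hybrid MLP (128 at full scale).
#' @param kernel dilated-convolution kernel size (odd; default 3).
#' @param dilation dilation rate (default 2).
#' @param eps variance floor inside the conditional layer norm.
#' @return object of class `grid_head_config`.
#' @export
grid_head_config <- function(d_h, d_d = 8L, d_r = 8L, d_g = 32L,
                             kernel = 3L, dilation = 2L, eps = 1e-5) {
  stopifnot(kernel %% 2L == 1L, dilation >= 1L, eps > 0)
  structure(list(d_h = as.integer(d_h), d_d = as.integer(d_d),
                 d_r = as.integer(d_r), d_g = as.integer(d_g),
                 kernel = as.integer(kernel), dilation = as.integer(dilation),
                 eps = eps),
            class = "grid_head_config")
}

# signed log-bucketing of the offset j - i, clamped at the extremes:
# 0 -> 1; positive offsets -> 2..8 by magnitude octave; negative -> 9..15
dist_bucket <- function(off) {
  mag <- pmin(floor(log2(pmax(abs(off), 1L))) + 1L, 7L)
  ifelse(off == 0L, 1L, ifelse(off > 0L, 1L + mag, 8L + mag))
}

n_dist_buckets <- 15L

#' Initialize grid-head parameters
#'
#' @param config a [grid_head_config()].
#' @param n_labels size of the relation set.
#' @param seed integer seed.
#' @return flat named list of matrices.
#' @export
init_grid_head_params <- function(config, n_labels, seed) {
  with_local_seed(seed, {
    dh <- config$d_h; dg <- config$d_g
    din <- dh + config$d_d + config$d_r
    k2 <- config$kernel^2
    p <- list(cln_wa = init_mat(dh, dh), cln_ba = matrix(1, 1L, dh),
              cln_wb = init_mat(dh, dh), cln_bb = matrix(0, 1L, dh),
              dist_emb = init_mat(n_dist_buckets, config$d_d),
              region_emb = init_mat(3L, config$d_r),
              hyb_w1 = init_mat(din, dg), hyb_b1 = matrix(0, 1L, dg),
              hyb_w2 = init_mat(dg, dg), hyb_b2 = matrix(0, 1L, dg),
              conv_b = matrix(0, 1L, dg),
              cls_w1 = init_mat(dg, dg), cls_b1 = matrix(0, 1L, dg),
              cls_w2 = init_mat(dg, n_labels), cls_b2 = matrix(0, 1L, n_labels))
    for (k in seq_len(k2))
      p[[sprintf("conv_k%d", k)]] <- init_mat(dg, dg, sd = 0.05)
    p
  })
}

#' Conditional layer normalization of one word pair
#'
#' Standard layer normalization of the input vector `h_j` whose gain and
#' bias are generated from the condition vector `h_i`:
#' `gamma = W_a h_i + b_a`, `lambda = W_b h_i + b_b`, and the output is
#' `gamma * (h_j - mu)/sqrt(sigma^2 + eps) + lambda` with `mu`, `sigma`
#' the mean and standard deviation over the coordinates of `h_j`.
#' With `W_a = 0, b_a = 1, W_b = 0, b_b = 0` this reduces to plain layer
#' normalization.
#'
#' @param h_i condition vector (length `d_h`).
#' @param h_j input vector (length `d_h`).
#' @param params list with `cln_wa`, `cln_ba`, `cln_wb`, `cln_bb` (as in
#'   [init_grid_head_params()]); vectors map through `h W + b`.
#' @param eps variance floor.
#' @return numeric vector of length `d_h`.
#' @export
conditional_layer_norm <- function(h_i, h_j, params, eps = 1e-5) {
  h_i <- matrix(as.numeric(h_i), nrow = 1L)
  h_j <- as.numeric(h_j)
  gamma <- h_i %*% params$cln_wa + params$cln_ba
  lambda <- h_i %*% params$cln_wb + params$cln_bb
  mu <- mean(h_j)
  sigma2 <- mean((h_j - mu)^2)
  as.numeric(gamma * ((h_j - mu) / sqrt(sigma2 + eps)) + lambda)
}

# node path: CLN over all n^2 ordered pairs at once
cln_grid_node <- function(H, nodes, config) {
  n <- nrow(H$val)
  d <- ncol(H$val)
  gamma <- ad_add_rowvec(ad_matmul(H, nodes$cln_wa), nodes$cln_ba)
  lambda <- ad_add_rowvec(ad_matmul(H, nodes$cln_wb), nodes$cln_bb)
  xhat <- ad_layer_norm_rows(H, ad_const(matrix(1, 1L, d)),
                             ad_const(matrix(0, 1L, d)), eps = config$eps)
  cond_idx <- rep(seq_len(n), each = n)    # i, row-major cell order
  input_idx <- rep(seq_len(n), times = n)  # j
  ad_add(ad_mul(ad_gather_rows(gamma, cond_idx),
                ad_gather_rows(xhat, input_idx)),
         ad_gather_rows(lambda, cond_idx))
}

# per-cell distance-bucket and region indices for an n x n grid (row-major)
grid_cell_indices <- function(n) {
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  list(dist = dist_bucket(j - i),
       region = ifelse(i < j, 1L, ifelse(i == j, 2L, 3L)))
}

# node path: [W ; D ; R] -> MLP -> G
hybrid_grid_node <- function(W, n, nodes) {
  idx <- grid_cell_indices(n)
  X <- ad_cbind(list(W,
                     ad_gather_rows(nodes$dist_emb, idx$dist),
                     ad_gather_rows(nodes$region_emb, idx$region)))
  z <- ad_gelu(ad_add_rowvec(ad_matmul(X, nodes$hyb_w1), nodes$hyb_b1))
  ad_add_rowvec(ad_matmul(z, nodes$hyb_w2), nodes$hyb_b2)
}

# gather index for one convolution tap: output cell (i,j) reads input cell
# (i+di, j+dj), 0 when outside the grid (zero padding)
conv_tap_index <- function(n, di, dj) {
  i <- rep(seq_len(n), each = n) + di
  j <- rep(seq_len(n), times = n) + dj
  ok <- i >= 1L & i <= n & j >= 1L & j <= n
  ifelse(ok, (i - 1L) * n + j, 0L)
}

# node path: single dilated convolution with GELU, shape-preserving
dilated_refine_node <- function(G, n, nodes, config) {
  half <- (config$kernel - 1L) %/% 2L
  offs <- seq.int(-half, half) * config$dilation
  acc <- NULL
  k <- 0L
  for (di in offs) for (dj in offs) {
    k <- k + 1L
    tap <- ad_matmul(ad_gather_rows(G, conv_tap_index(n, di, dj)),
                     nodes[[sprintf("conv_k%d", k)]])
    acc <- if (is.null(acc)) tap else ad_add(acc, tap)
  }
  ad_gelu(ad_add_rowvec(acc, nodes$conv_b))
}

# node path: per-cell relation logits
classify_logits_node <- function(S, nodes) {
  z <- ad_gelu(ad_add_rowvec(ad_matmul(S, nodes$cls_w1), nodes$cls_b1))
  ad_add_rowvec(ad_matmul(z, nodes$cls_w2), nodes$cls_b2)
}

# ---- numeric front-ends (no gradient) --------------------------------------

wrap_const_params <- function(params) lapply(params, ad_const)

#' Build the hybrid word-pair grid representation
#'
#' Concatenates, per cell (i, j), the CLN pair vector with a distance
#' embedding of the log-bucketed signed offset j - i (clamped at the
#' extreme buckets) and a region embedding (upper triangle / diagonal /
#' lower triangle), then projects to `d_g` channels with a one-hidden-layer
#' GELU perceptron.
#'
#' @param W numeric `(n^2) x d_h` CLN grid in row-major cell order.
#' @param n grid side length.
#' @param params grid-head parameters from [init_grid_head_params()].
#' @return numeric `(n^2) x d_g` matrix `G`.
#' @export
build_hybrid_grid <- function(W, n, params) {
  ad_value(hybrid_grid_node(ad_const(W), n, wrap_const_params(params)))
}

#' Refine the grid with a single dilated convolution
#'
#' A shape-preserving `kernel x kernel` convolution with the configured
#' dilation over the two spatial grid axes, zero padding, followed by GELU.
#'
#' @param G numeric `(n^2) x d_g` grid.
#' @param n grid side length.
#' @param params grid-head parameters.
#' @param config a [grid_head_config()].
#' @return numeric `(n^2) x d_g` matrix `S`.
#' @export
dilated_refine <- function(G, n, params, config) {
  ad_value(dilated_refine_node(ad_const(G), n, wrap_const_params(params),
                               config))
}

#' Classify every grid cell into relation labels
#'
#' @param S numeric `(n^2) x d_g` refined grid.
#' @param n grid side length.
#' @param params grid-head parameters.
#' @param rset the [relation_set()] classified over.
#' @return object of class `prediction_grid`: list with `n`, `probs`
#'   (`(n^2) x |R|`, rows summing to 1, row-major cell order), and the
#'   derived `argmax` relation_grid.
#' @export
classify_pairs <- function(S, n, params, rset) {
  logits <- ad_value(classify_logits_node(ad_const(S),
                                          wrap_const_params(params)))
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  probs <- e / rowSums(e)
  prediction_grid(probs, n, rset)
}

#' Construct a prediction grid from per-cell probabilities
#' @param probs `(n^2) x |R|` matrix, row-major cell order.
#' @param n grid side length.
#' @param rset the [relation_set()].
#' @return object of class `prediction_grid`.
#' @export
prediction_grid <- function(probs, n, rset) {
  am <- max.col(probs, ties.method = "first")
  cells <- matrix(am, n, n, byrow = TRUE)
  structure(list(n = n, probs = probs,
                 argmax = structure(list(n = n, cells = cells),
                                    class = "relation_grid")),
            class = "prediction_grid")
}

#' Mean per-cell cross-entropy against a gold relation grid
#'
#' `-(1/N^2) * sum_{ij} log y_ij[gold_ij]`: the average over all `N^2`
#' cells of the negative log probability assigned to the gold relation
#' label. Zero iff every cell predicts its gold label with probability 1.
#'
#' @param pred a `prediction_grid` (or bare `(n^2) x |R|` probability
#'   matrix in row-major cell order).
#' @param gold a `relation_grid` of gold label indices.
#' @return scalar loss, >= 0.
#' @export
bioner_loss <- function(pred, gold) {
  probs <- if (inherits(pred, "prediction_grid")) pred$probs else pred
  gold_vec <- as.vector(t(gold$cells))        # row-major cell order
  stopifnot(nrow(probs) == length(gold_vec))
  -mean(log(pmax(probs[cbind(seq_along(gold_vec), gold_vec)], 1e-300)))
}
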