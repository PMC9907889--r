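# Attention-map discrimination guidance: pool each guided head's attention
# map into "received attention" vectors (with and without the prefix
# columns), then push head diversity with an instance-discrimination loss
# treating every head as its own class.

#' Pool one attention map into received-attention vectors
#'
#' For key position k, the received attention is the sum of attention
#' weights it collects over all (unmasked) query rows. `p` covers all `L+P`
#' key columns (tokens plus prefix slots); `o` is its restriction to the
#' `L` non-prefix positions. With `P = 0`, `o` equals `p`.
#'
#' @param A numeric `L x (L+P)` attention map (rows sum to 1 over unmasked
#'   columns).
#' @param L number of token (non-prefix) key positions; defaults to
#'   `nrow(A)`.
#' @param mask optional logical vector of valid query rows; masked rows
#'   contribute nothing.
#' @return list with vectors `o` (length L) and `p` (length L+P).
#' @export
pool_received_attention <- function(A, L = nrow(A), mask = NULL) {
  if (!is.null(mask)) A <- A[mask, , drop = FALSE]
  p <- colSums(A)
  list(o = p[seq_len(L)], p = p)
}

#' Assemble the pooled per-head matrices O and P
#'
#' Stacks the guided heads' pooled vectors row-wise (layer-major, head-minor
#' order) and L2-normalizes each row to unit norm. A fully-masked (all-zero)
#' row is replaced by a uniform unit vector and flagged with a warning.
#'
#' @param stack attention-map stack: list with `maps` (list of `L x (L+P)`
#'   numeric matrices), `L`, and `P` (as produced by [encoder_encode()],
#'   with map nodes reduced to values).
#' @param tau temperature for the discrimination loss (default 2).
#' @param mask optional logical query-row mask shared by all maps.
#' @return object of class `head_vector_matrices`: list with `O` (m x L),
#'   `Pm` (m x (L+P)), both row-normalized, and `tau`.
#' @export
assemble_head_matrices <- function(stack, tau = 2, mask = NULL) {
  maps <- lapply(stack$maps, function(m) if (inherits(m, "ad_node")) m$val else m)
  m <- length(maps)
  L <- stack$L
  pooled <- lapply(maps, pool_received_attention, L = L, mask = mask)
  O <- do.call(rbind, lapply(pooled, `[[`, "o"))
  Pm <- do.call(rbind, lapply(pooled, `[[`, "p"))
  fix_rows <- function(M) {
    nrm <- sqrt(rowSums(M^2))
    zero <- nrm < 1e-12
    if (any(zero)) {
      warning(sprintf("%d fully-masked head row(s) replaced by uniform vectors",
                      sum(zero)))
      M[zero, ] <- 1
      nrm <- sqrt(rowSums(M^2))
    }
    M / nrm
  }
  structure(list(O = fix_rows(O), Pm = fix_rows(Pm), tau = tau, m = m),
            class = "head_vector_matrices")
}

#' Instance-discrimination loss over row-normalized head vectors
#'
#' Treats each row of `M` as its own class under the non-parametric softmax
#' \eqn{P(i|v) = \exp(v_i^T v/\tau) / \sum_j \exp(v_j^T v/\tau)} and returns
#' the summed negative log-likelihood of each row being assigned to itself.
#' Identical rows give the maximal value `m log m`; the loss shrinks as rows
#' spread apart on the unit sphere.
#'
#' @param M m x k matrix with unit-norm rows, m >= 2.
#' @param tau temperature, > 0.
#' @return scalar loss.
#' @export
instance_discrimination_loss <- function(M, tau = 2) {
  if (nrow(M) < 2L)
    stop("instance discrimination needs at least 2 head vectors")
  stopifnot(tau > 0)
  S <- (M %*% t(M)) / tau
  # loss_i = logsumexp_j(S[j, i]) - S[i, i]; columns are the class scores
  zmax <- apply(S, 2L, max)
  lse <- log(colSums(exp(sweep(S, 2L, zmax)))) + zmax
  sum(lse - diag(S))
}

#' Fused guidance loss over the prefix-exclusive and prefix-inclusive views
#'
#' `loss_o` is the discrimination loss on the token-only pooled matrix O,
#' `loss_p` on the prefix-inclusive matrix P; the fused guidance loss is
#' their plain mean. With `P = 0` the two views coincide and all three
#' values are equal.
#'
#' @param hv a `head_vector_matrices` from [assemble_head_matrices()].
#' @return list with `loss_o`, `loss_p`, `loss_pamdfga`.
#' @export
pamdfga_loss <- function(hv) {
  loss_o <- instance_discrimination_loss(hv$O, hv$tau)
  loss_p <- instance_discrimination_loss(hv$Pm, hv$tau)
  list(loss_o = loss_o, loss_p = loss_p,
       loss_pamdfga = (loss_p + loss_o) / 2)
}

#' Mean off-diagonal cosine similarity between head vectors
#'
#' The diversity diagnostic used to assess guidance: lower values mean the
#' guided heads attend to more distinct positions.
#'
#' @param M m x k matrix with unit-norm rows.
#' @return scalar in [-1, 1].
#' @export
head_cosine_similarity <- function(M) {
  S <- M %*% t(M)
  mean(S[row(S) != col(S)])
}

#' Export the per-head pairwise cosine-similarity matrix as CSV
#'
#' @param hv a `head_vector_matrices`.
#' @param path output CSV path.
#' @param which `"O"` (token-only view, default) or `"Pm"`.
#' @export
write_head_similarity_csv <- function(hv, path, which = c("O", "Pm")) {
  which <- match.arg(which)
  M <- hv[[which]]
  S <- M %*% t(M)
  utils::write.csv(S, path, row.names = FALSE)
  invisible(path)
}

# ---- node-based path used during training ----------------------------------

# Build the fused guidance loss as an autodiff node from live map nodes.
# Per-sentence maps (no padding): pooled by column sums, L2-normalized,
# similarity through the tape so gradients reach the attention weights.
guidance_loss_node <- function(stack, tau) {
  m <- length(stack$maps)
  if (m < 2L) stop("instance discrimination needs at least 2 guided heads")
  L <- stack$L
  p_rows <- lapply(stack$maps, ad_colsums)
  o_rows <- lapply(p_rows, function(p) ad_slice_cols(p, 1L, L))
  discrim <- function(rows) {
    M <- ad_l2_normalize_rows(ad_rbind(rows))
    S <- ad_scale(ad_matmul(M, ad_transpose(M)), 1 / tau)
    ad_discrim_from_sim(S)
  }
  loss_o <- discrim(o_rows)
  loss_p <- if (stack$P > 0L) discrim(p_rows) else loss_o
  ad_scale(ad_add(loss_p, loss_o), 0.5)
}
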