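#' Encoder configuration
#'
#' Dimensions of the prefix-augmented transformer encoder and its BiLSTM
#' contextualizer. Full scale in the original setting is 12 layers, 12 heads,
#' hidden size 768, prefix length 11, BiLSTM output 512, with attention
#' guidance on the last four layers; the toy defaults here are sized for CPU
#' tests with random initialization.
#'
#' @param layers number of transformer layers.
#' @param heads attention heads per layer; must divide `dim`.
#' @param dim hidden size d of the transformer.
#' @param prefix_len P, number of trainable prefix key/value slots per layer
#'   (0 disables the prefix, recovering standard self-attention).
#' @param d_h BiLSTM output dimension (split evenly across directions).
#' @param guided_layers layer indices whose attention maps feed the
#'   guidance loss; defaults to the last four (or all, if fewer).
#' @param ffn_mult feed-forward inner width as a multiple of `dim`.
#' @param max_pos positional capacity in pieces.
#' @param pool subword-to-word pooling rule, `"max"` (default) or `"mean"`.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(layers = 2L, heads = 2L, dim = 32L,
                           prefix_len = 4L, d_h = 32L,
                           guided_layers = NULL, ffn_mult = 2L,
                           max_pos = 160L, pool = c("max", "mean")) {
  pool <- match.arg(pool)
  layers <- as.integer(layers); heads <- as.integer(heads)
  dim <- as.integer(dim); prefix_len <- as.integer(prefix_len)
  d_h <- as.integer(d_h)
  stopifnot(layers >= 1L, heads >= 1L, dim %% heads == 0L,
            prefix_len >= 0L, d_h %% 2L == 0L)
  if (is.null(guided_layers))
    guided_layers <- seq.int(max(1L, layers - 3L), layers)
  guided_layers <- as.integer(guided_layers)
  stopifnot(all(guided_layers >= 1L), all(guided_layers <= layers))
  structure(list(layers = layers, heads = heads, dim = dim,
                 prefix_len = prefix_len, d_h = d_h,
                 guided_layers = guided_layers,
                 ffn_mult = as.integer(ffn_mult),
                 max_pos = as.integer(max_pos), pool = pool),
            class = "encoder_config")
}

init_mat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize the per-layer trainable prefix bank
#'
#' One independent pair of key and value prefix matrices per layer, each
#' `P x dim` (split across heads column-wise at attention time), drawn from
#' the same Gaussian initializer family as the encoder's embeddings.
#' `P = 0` yields an empty bank, which disables prefix guidance.
#'
#' @param config an [encoder_config()].
#' @param seed integer seed; identical seeds give bit-identical banks.
#' @return named list of matrices `prefix_k_l<i>` / `prefix_v_l<i>`.
#' @export
init_prefix_bank <- function(config, seed) {
  with_local_seed(seed, {
    bank <- list()
    for (l in seq_len(config$layers)) {
      bank[[sprintf("prefix_k_l%d", l)]] <-
        init_mat(config$prefix_len, config$dim)
      bank[[sprintf("prefix_v_l%d", l)]] <-
        init_mat(config$prefix_len, config$dim)
    }
    bank
  })
}

#' Initialize all encoder parameters (transformer + prefix bank + BiLSTM)
#'
#' @param config an [encoder_config()].
#' @param vocab_size size of the piece vocabulary.
#' @param seed integer seed.
#' @return flat named list of numeric matrices.
#' @export
init_encoder_params <- function(config, vocab_size, seed) {
  d <- config$dim; dff <- d * config$ffn_mult
  params <- with_local_seed(seed, {
    p <- list(emb = init_mat(vocab_size, d),
              pos = init_mat(config$max_pos, d))
    for (l in seq_len(config$layers)) {
      pre <- sprintf("l%d_", l)
      p[[paste0(pre, "wq")]] <- init_mat(d, d)
      p[[paste0(pre, "wk")]] <- init_mat(d, d)
      p[[paste0(pre, "wv")]] <- init_mat(d, d)
      p[[paste0(pre, "wo")]] <- init_mat(d, d)
      p[[paste0(pre, "attn_ln_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "attn_ln_b")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ffn_w1")]] <- init_mat(d, dff)
      p[[paste0(pre, "ffn_b1")]] <- matrix(0, 1L, dff)
      p[[paste0(pre, "ffn_w2")]] <- init_mat(dff, d)
      p[[paste0(pre, "ffn_b2")]] <- matrix(0, 1L, d)
      p[[paste0(pre, "ffn_ln_g")]] <- matrix(1, 1L, d)
      p[[paste0(pre, "ffn_ln_b")]] <- matrix(0, 1L, d)
    }
    h2 <- config$d_h %/% 2L
    for (dir in c("fwd", "bwd")) {
      p[[paste0("lstm_", dir, "_w")]] <- init_mat(d, 4L * h2, sd = 0.1)
      p[[paste0("lstm_", dir, "_u")]] <- init_mat(h2, 4L * h2, sd = 0.1)
      b <- matrix(0, 1L, 4L * h2)
      b[1L, (h2 + 1L):(2L * h2)] <- 1    # forget-gate bias
      p[[paste0("lstm_", dir, "_b")]] <- b
    }
    p
  })
  c(params, init_prefix_bank(config, seed + 1L))
}

#' Wrap a parameter store as autodiff nodes
#' @param params named list of matrices.
#' @return named list of `ad_param` nodes.
#' @keywords internal
#' @export
params_to_nodes <- function(params) lapply(params, ad_param)

#' Prefix-augmented multi-head self-attention for one layer
#'
#' Per head h, the attention weights are
#' `softmax(Q_h [K_h; phi_k^h]^T / sqrt(d_head))`, of shape `L x (L+P)`,
#' and the head output applies those weights to `[V_h; phi_v^h]`. Prefix
#' slots act as extra keys/values only — they never query. With `P = 0`
#' this is exactly standard scaled dot-product self-attention.
#'
#' @param H an `ad_node`, `L x dim` hidden states.
#' @param layer_nodes named list of this layer's parameter nodes
#'   (`wq`, `wk`, `wv`, `wo`, `attn_ln_g`, `attn_ln_b`, and the layer's
#'   `prefix_k` / `prefix_v`, which may have zero rows).
#' @param config an [encoder_config()].
#' @return list with `out` (`L x dim` node, after residual + layer norm)
#'   and `maps` (list of per-head `L x (L+P)` attention-weight nodes).
#' @export
prefix_self_attention <- function(H, layer_nodes, config) {
  d <- config$dim; h <- config$heads; dk <- d %/% h
  P <- nrow(layer_nodes$prefix_k$val)
  Q <- ad_matmul(H, layer_nodes$wq)
  K <- ad_matmul(H, layer_nodes$wk)
  V <- ad_matmul(H, layer_nodes$wv)
  maps <- vector("list", h)
  outs <- vector("list", h)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1L) * dk + 1L):(hh * dk)
    Qh <- ad_slice_cols(Q, cols[1L], cols[dk])
    Kh <- ad_slice_cols(K, cols[1L], cols[dk])
    Vh <- ad_slice_cols(V, cols[1L], cols[dk])
    if (P > 0L) {
      Kh <- ad_rbind(list(Kh, ad_slice_cols(layer_nodes$prefix_k,
                                            cols[1L], cols[dk])))
      Vh <- ad_rbind(list(Vh, ad_slice_cols(layer_nodes$prefix_v,
                                            cols[1L], cols[dk])))
    }
    logits <- ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dk))
    A <- ad_softmax_rows(logits)
    maps[[hh]] <- A
    outs[[hh]] <- ad_matmul(A, Vh)
  }
  attn <- ad_matmul(ad_cbind(outs), layer_nodes$wo)
  out <- ad_layer_norm_rows(ad_add(H, attn),
                            layer_nodes$attn_ln_g, layer_nodes$attn_ln_b)
  list(out = out, maps = maps)
}

transformer_ffn <- function(H, layer_nodes) {
  z <- ad_gelu(ad_add_rowvec(ad_matmul(H, layer_nodes$ffn_w1),
                             layer_nodes$ffn_b1))
  z <- ad_add_rowvec(ad_matmul(z, layer_nodes$ffn_w2), layer_nodes$ffn_b2)
  ad_layer_norm_rows(ad_add(H, z), layer_nodes$ffn_ln_g, layer_nodes$ffn_ln_b)
}

layer_node_slice <- function(nodes, l) {
  pre <- sprintf("l%d_", l)
  list(wq = nodes[[paste0(pre, "wq")]], wk = nodes[[paste0(pre, "wk")]],
       wv = nodes[[paste0(pre, "wv")]], wo = nodes[[paste0(pre, "wo")]],
       attn_ln_g = nodes[[paste0(pre, "attn_ln_g")]],
       attn_ln_b = nodes[[paste0(pre, "attn_ln_b")]],
       ffn_w1 = nodes[[paste0(pre, "ffn_w1")]],
       ffn_b1 = nodes[[paste0(pre, "ffn_b1")]],
       ffn_w2 = nodes[[paste0(pre, "ffn_w2")]],
       ffn_b2 = nodes[[paste0(pre, "ffn_b2")]],
       prefix_k = nodes[[sprintf("prefix_k_l%d", l)]],
       prefix_v = nodes[[sprintf("prefix_v_l%d", l)]],
       ffn_ln_g = nodes[[paste0(pre, "ffn_ln_g")]],
       ffn_ln_b = nodes[[paste0(pre, "ffn_ln_b")]])
}

#' Run the encoder over one piece sequence
#'
#' The sequence must begin with the start special token (`[CLS]` analogue).
#' Attention maps are collected post-softmax, pre-value, from the configured
#' guided layers only; prefixes are installed on every layer regardless.
#'
#' @param ids integer piece ids (specials included).
#' @param nodes parameter nodes from [params_to_nodes()].
#' @param config an [encoder_config()].
#' @return list with `hidden` (`L x dim` node) and `stack`, an attention-map
#'   stack: list of `L x (L+P)` nodes ordered layer-major then head, plus
#'   `L`, `P`, and a `layer`/`head` index data frame.
#' @export
encoder_encode <- function(ids, nodes, config) {
  L <- length(ids)
  if (L > config$max_pos)
    stop(sprintf(paste0("sequence of %d pieces exceeds positional capacity ",
                        "%d; truncate or split the sentence"),
                 L, config$max_pos))
  H <- ad_add(ad_gather_rows(nodes$emb, ids),
              ad_gather_rows(nodes$pos, seq_len(L)))
  maps <- list()
  meta_layer <- integer(); meta_head <- integer()
  for (l in seq_len(config$layers)) {
    ln <- layer_node_slice(nodes, l)
    att <- prefix_self_attention(H, ln, config)
    H <- transformer_ffn(att$out, ln)
    if (l %in% config$guided_layers) {
      maps <- c(maps, att$maps)
      meta_layer <- c(meta_layer, rep(l, config$heads))
      meta_head <- c(meta_head, seq_len(config$heads))
    }
  }
  list(hidden = H,
       stack = list(maps = maps, L = L, P = config$prefix_len,
                    index = data.frame(layer = meta_layer, head = meta_head)))
}

#' Pool subword-piece vectors into word vectors
#'
#' Elementwise max over each word's pieces by default (mean optionally);
#' special boundary pieces are excluded.
#'
#' @param H `L x d` node of piece vectors.
#' @param alignment alignment from [build_subword_alignment()].
#' @param pool `"max"` or `"mean"`.
#' @return `n x d` node, one row per word.
#' @export
pool_subwords <- function(H, alignment, pool = "max") {
  groups <- lapply(seq_len(nrow(alignment$ranges)), function(w)
    (alignment$ranges[w, 1L]:alignment$ranges[w, 2L]) + 1L)
  if (pool == "max") return(ad_max_pool_rows(H, groups))
  # mean pooling as a constant averaging matrix
  M <- matrix(0, length(groups), nrow(H$val))
  for (w in seq_along(groups)) M[w, groups[[w]]] <- 1 / length(groups[[w]])
  ad_matmul(ad_const(M), H)
}

run_lstm_dir <- function(X, W, U, b, reverse = FALSE) {
  n <- nrow(X$val)
  h2 <- ncol(U$val) %/% 4L
  xproj <- ad_add_rowvec(ad_matmul(X, W), b)
  hc <- ad_const(matrix(0, 1L, 2L * h2))
  outs <- vector("list", n)
  steps <- if (reverse) rev(seq_len(n)) else seq_len(n)
  for (t in steps) {
    hc <- ad_lstm_step(ad_gather_rows(xproj, t), hc, U)
    outs[[t]] <- ad_slice_cols(hc, 1L, h2)
  }
  ad_rbind(outs)
}

#' Bidirectional LSTM contextualizer
#'
#' Runs a forward and a backward LSTM over the word vectors and concatenates
#' per-step hidden states, yielding one `d_h`-dimensional representation per
#' word (half per direction). Deterministic given parameters and input.
#'
#' @param X `n x d` node of word vectors.
#' @param nodes parameter node list containing the `lstm_*` entries.
#' @return `n x d_h` node.
#' @export
bilstm_contextualize <- function(X, nodes) {
  fwd <- run_lstm_dir(X, nodes$lstm_fwd_w, nodes$lstm_fwd_u,
                      nodes$lstm_fwd_b, reverse = FALSE)
  bwd <- run_lstm_dir(X, nodes$lstm_bwd_w, nodes$lstm_bwd_u,
                      nodes$lstm_bwd_b, reverse = TRUE)
  ad_cbind(list(fwd, bwd))
}
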