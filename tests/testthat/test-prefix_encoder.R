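mk_layer_nodes <- function(cfg, P = cfg$prefix_len, seed = 2) {
  set.seed(seed)
  d <- cfg$dim
  list(wq = ad_param(init_mat(d, d)), wk = ad_param(init_mat(d, d)),
       wv = ad_param(init_mat(d, d)), wo = ad_param(init_mat(d, d)),
       attn_ln_g = ad_param(matrix(1, 1, d)),
       attn_ln_b = ad_param(matrix(0, 1, d)),
       prefix_k = ad_param(init_mat(P, d)),
       prefix_v = ad_param(init_mat(P, d)))
}

test_that("prefix bank initialization is deterministic and per-layer", {
  cfg <- encoder_config(layers = 3, heads = 2, dim = 8, prefix_len = 5)
  b1 <- init_prefix_bank(cfg, seed = 4)
  b2 <- init_prefix_bank(cfg, seed = 4)
  expect_identical(b1, b2)
  expect_length(b1, 6L)
  expect_equal(dim(b1$prefix_k_l1), c(5L, 8L))
  expect_false(identical(b1$prefix_k_l1, b1$prefix_k_l2))
  b0 <- init_prefix_bank(encoder_config(layers = 2, dim = 8, heads = 2,
                                        prefix_len = 0), seed = 1)
  expect_equal(nrow(b0$prefix_k_l1), 0L)
})

test_that("attention rows are distributions over L+P columns", {
  cfg <- encoder_config(layers = 1, heads = 2, dim = 8, prefix_len = 3)
  ad_begin()
  ln <- mk_layer_nodes(cfg)
  H <- ad_const(matrix(rnorm(5 * 8), 5, 8))
  att <- prefix_self_attention(H, ln, cfg)
  for (A in att$maps) {
    expect_equal(dim(ad_value(A)), c(5L, 8L))        # L x (L+P)
    expect_equal(rowSums(ad_value(A)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(ad_value(A) >= 0))
  }
})

test_that("with P=0 prefix attention equals standard attention", {
  cfg0 <- encoder_config(layers = 1, heads = 2, dim = 8, prefix_len = 0)
  ad_begin()
  ln <- mk_layer_nodes(cfg0, P = 0)
  H <- matrix(rnorm(4 * 8), 4, 8)
  att <- prefix_self_attention(ad_const(H), ln, cfg0)
  # reference standard multi-head attention, built independently
  d <- 8; h <- 2; dk <- d / h
  Q <- H %*% ad_value(ln$wq); K <- H %*% ad_value(ln$wk)
  V <- H %*% ad_value(ln$wv)
  ref_heads <- lapply(1:h, function(hh) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    logits <- Q[, cols] %*% t(K[, cols]) / sqrt(dk)
    e <- exp(logits - apply(logits, 1, max))
    A <- e / rowSums(e)
    list(A = A, O = A %*% V[, cols])
  })
  for (hh in 1:h)
    expect_lt(max(abs(ad_value(att$maps[[hh]]) - ref_heads[[hh]]$A)), 1e-6)
  ref_out <- do.call(cbind, lapply(ref_heads, `[[`, "O")) %*%
    ad_value(ln$wo) + H
  mu <- rowMeans(ref_out)
  sd_ <- sqrt(rowMeans((ref_out - mu)^2) + 1e-5)
  expect_lt(max(abs(ad_value(att$out) - (ref_out - mu) / sd_)), 1e-6)
})

test_that("hand-computed softmax cases come out exactly", {
  # all logits equal -> uniform 1/(L+P)
  cfg <- encoder_config(layers = 1, heads = 1, dim = 4, prefix_len = 2)
  ad_begin()
  ln <- mk_layer_nodes(cfg)
  ln$wq <- ad_const(matrix(0, 4, 4))        # Q = 0 -> all logits equal
  att <- prefix_self_attention(ad_const(matrix(rnorm(12), 3, 4)), ln, cfg)
  expect_equal(ad_value(att$maps[[1]]),
               matrix(1 / 5, 3, 5), tolerance = 1e-12)
  # L=1, P=1, logits (0, ln 3) -> weights (1/4, 3/4)
  sm <- ad_value(ad_softmax_rows(ad_const(matrix(c(0, log(3)), 1, 2))))
  expect_equal(as.numeric(sm), c(0.25, 0.75), tolerance = 1e-12)
})

test_that("attention outputs are convex combinations of value rows", {
  cfg <- encoder_config(layers = 1, heads = 2, dim = 8, prefix_len = 3)
  for (rep in 1:5) {
    ad_begin()
    ln <- mk_layer_nodes(cfg, seed = rep)
    H <- matrix(rnorm(4 * 8), 4, 8)
    d <- 8; h <- 2; dk <- d / h
    att <- prefix_self_attention(ad_const(H), ln, cfg)
    V <- H %*% ad_value(ln$wv)
    for (hh in 1:h) {
      cols <- ((hh - 1) * dk + 1):(hh * dk)
      Vfull <- rbind(V[, cols], ad_value(ln$prefix_v)[, cols])
      heads_out <- ad_value(att$maps[[hh]]) %*% Vfull
      for (j in seq_len(dk)) {
        expect_true(all(heads_out[, j] <= max(Vfull[, j]) + 1e-12))
        expect_true(all(heads_out[, j] >= min(Vfull[, j]) - 1e-12))
      }
    }
  }
})

test_that("encoder collects maps from guided layers only, deterministically", {
  corpus <- toy_corpus(4)
  model <- toy_model(corpus)
  al <- build_subword_alignment(corpus[[1]], model$splitter)
  ids <- piece_ids(al$pieces, model$vocab)
  nodes <- lapply(model$params, ad_const)
  enc1 <- encoder_encode(ids, nodes, model$encoder)
  enc2 <- encoder_encode(ids, nodes, model$encoder)
  L <- length(ids)
  expect_length(enc1$stack$maps, 2L * 2L)      # both layers guided, 2 heads
  for (A in enc1$stack$maps)
    expect_equal(dim(ad_value(A)), c(L, L + 2L))
  expect_identical(lapply(enc1$stack$maps, ad_value),
                   lapply(enc2$stack$maps, ad_value))
  expect_identical(ad_value(enc1$hidden), ad_value(enc2$hidden))

  cfg_last <- encoder_config(layers = 2, heads = 2, dim = 16, prefix_len = 2,
                             d_h = 16, guided_layers = 2)
  enc3 <- encoder_encode(ids, nodes, cfg_last)
  expect_length(enc3$stack$maps, 2L)           # h maps for one guided layer
  expect_equal(enc3$stack$index$layer, c(2L, 2L))
})

test_that("over-capacity sequences raise a truncation-advising error", {
  corpus <- toy_corpus(4)
  model <- toy_model(corpus, max_pos = 8L)
  long <- labeled_sentence(rep("abcdef", 10))
  nodes <- lapply(model$params, ad_const)
  al <- build_subword_alignment(long, model$splitter)
  expect_error(encoder_encode(piece_ids(al$pieces, model$vocab), nodes,
                              model$encoder),
               "positional capacity")
})

test_that("subword pooling takes elementwise max and skips specials", {
  H <- ad_const(rbind(c(9, 9), c(1, 3), c(2, 0), c(5, 5), c(9, 9)))
  al <- list(ranges = rbind(c(1L, 2L), c(3L, 3L)), special = c(TRUE, FALSE,
                                                               FALSE, FALSE,
                                                               TRUE))
  out <- ad_value(pool_subwords(H, al, "max"))
  expect_equal(out, rbind(c(2, 3), c(5, 5)))    # (1,3)v(2,0) -> (2,3); identity
  out_mean <- ad_value(pool_subwords(H, al, "mean"))
  expect_equal(out_mean, rbind(c(1.5, 1.5), c(5, 5)))
})

test_that("BiLSTM output is length-n, bounded, and direction-symmetric", {
  set.seed(8)
  d <- 6; h2 <- 4
  params <- list(lstm_fwd_w = init_mat(d, 4 * h2, sd = 0.3),
                 lstm_fwd_u = init_mat(h2, 4 * h2, sd = 0.3),
                 lstm_fwd_b = matrix(0, 1, 4 * h2))
  # shared parameters for both directions
  params$lstm_bwd_w <- params$lstm_fwd_w
  params$lstm_bwd_u <- params$lstm_fwd_u
  params$lstm_bwd_b <- params$lstm_fwd_b
  nodes <- lapply(params, ad_const)
  X <- matrix(rnorm(3 * d), 3, d)
  out <- ad_value(bilstm_contextualize(ad_const(X), nodes))
  expect_equal(dim(out), c(3L, 2L * h2))
  expect_true(all(abs(out) < 1))                 # tanh-bounded
  # reversing the input reverses and swaps the direction halves
  rev_out <- ad_value(bilstm_contextualize(ad_const(X[3:1, ]), nodes))
  expect_equal(rev_out[3:1, c((h2 + 1):(2 * h2), 1:h2)], out,
               tolerance = 1e-12)
  # n = 1 works
  one <- ad_value(bilstm_contextualize(ad_const(X[1, , drop = FALSE]),
                                       nodes))
  expect_equal(dim(one), c(1L, 2L * h2))
})

test_that("gradient reaches the prefix bank; frozen backbone stays put", {
  corpus <- toy_corpus(4)
  model <- toy_model(corpus)
  s <- corpus[[which(vapply(corpus, function(x) nrow(x$mentions) > 0,
                            logical(1)))[1]]]
  ad_begin()
  nodes <- params_to_nodes(model$params)
  fw <- forward_sentence(model, s, nodes)
  loss <- ad_add(ad_cross_entropy_rows(fw$logits,
                                       gold_cell_vector(s, model$rset)),
                 ad_scale(gridner:::guidance_loss_node(fw$stack, model$tau),
                          0.01))
  ad_backward(loss)
  expect_gt(max(abs(nodes$prefix_k_l1$grad)), 0)
  expect_gt(max(abs(nodes$prefix_v_l2$grad)), 0)
  # a one-step update moves the prefix while an untouched copy of the
  # backbone weight matrices stays bit-identical (freeze = don't update)
  upd <- gridner:::adamw_step(model$params,
                              lapply(nodes, function(n) n$grad),
                              gridner:::adamw_state(model$params),
                              lr = 1e-3, weight_decay = 0)
  expect_false(identical(upd$params$prefix_k_l1, model$params$prefix_k_l1))
})
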