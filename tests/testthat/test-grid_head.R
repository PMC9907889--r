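toy_head_params <- function(d_h = 6, d_g = 8, n_labels = 3, seed = 2) {
  init_grid_head_params(grid_head_config(d_h = d_h, d_d = 4, d_r = 4,
                                         d_g = d_g), n_labels, seed)
}

test_that("CLN with gamma=1, lambda=0 is standard layer normalization", {
  set.seed(1)
  d <- 8
  params <- list(cln_wa = matrix(0, d, d), cln_ba = matrix(1, 1, d),
                 cln_wb = matrix(0, d, d), cln_bb = matrix(0, 1, d))
  h_i <- rnorm(d); h_j <- rnorm(d)
  got <- conditional_layer_norm(h_i, h_j, params, eps = 1e-12)
  mu <- mean(h_j); sd_ <- sqrt(mean((h_j - mu)^2) + 1e-12)
  expect_lt(max(abs(got - (h_j - mu) / sd_)), 1e-6)
})

test_that("CLN hand example and degenerate input behave as defined", {
  d <- 2
  params <- list(cln_wa = matrix(0, d, d), cln_ba = matrix(1, 1, d),
                 cln_wb = matrix(0, d, d), cln_bb = matrix(0, 1, d))
  # h_j = (1,3): mu = 2, sigma = 1 -> (-1, 1)
  got <- conditional_layer_norm(c(0, 0), c(1, 3), params, eps = 1e-12)
  expect_equal(got, c(-1, 1), tolerance = 1e-6)
  # constant h_j: normalized part ~ 0, output ~ lambda
  params$cln_bb <- matrix(c(5, -5), 1, 2)
  got2 <- conditional_layer_norm(c(0, 0), c(4, 4), params)
  expect_equal(got2, c(5, -5), tolerance = 1e-6)
})

test_that("the CLN grid applies condition i to input j per cell", {
  set.seed(3)
  d <- 6; n <- 4
  params <- toy_head_params(d_h = d)
  H <- matrix(rnorm(n * d), n, d)
  cfg <- grid_head_config(d_h = d, d_d = 4, d_r = 4, d_g = 8)
  W <- ad_value(gridner:::cln_grid_node(ad_const(H),
                                        lapply(params, ad_const), cfg))
  expect_equal(dim(W), c(n * n, d))
  for (i in c(1, 3)) for (j in c(2, 4)) {
    row <- (i - 1) * n + j
    expect_equal(W[row, ],
                 conditional_layer_norm(H[i, ], H[j, ], params,
                                        eps = cfg$eps),
                 tolerance = 1e-10)
  }
})

test_that("hybrid grid shares distance vectors by offset and regions by triangle", {
  set.seed(4)
  n <- 5; d <- 6
  params <- toy_head_params(d_h = d)
  W <- matrix(rnorm(n * n * d), n * n, d)
  idx <- gridner:::grid_cell_indices(n)
  # same signed offset -> same distance bucket: (0,3) vs (1,4) (1-based (1,4),(2,5))
  cell <- function(i, j) (i - 1) * n + j
  expect_equal(idx$dist[cell(1, 4)], idx$dist[cell(2, 5)])
  expect_false(idx$dist[cell(1, 4)] == idx$dist[cell(4, 1)])
  expect_true(all(idx$region[idx$dist == 1 &
                               rep(1:n, each = n) == rep(1:n, times = n)] ==
                    2L))
  expect_equal(idx$region[cell(2, 4)], 1L)   # upper
  expect_equal(idx$region[cell(4, 2)], 3L)   # lower
  G <- build_hybrid_grid(W, n, params)
  expect_equal(dim(G), c(n * n, 8L))         # d_g regardless of inputs
})

test_that("extreme offsets clamp to the outer distance buckets", {
  b <- gridner:::dist_bucket(c(-500, -65, -64, -1, 0, 1, 64, 65, 500))
  expect_equal(b[5], 1L)
  expect_equal(b[c(6, 4)], c(2L, 9L))        # +-1
  expect_equal(b[7], b[8])                   # 64 and 65 share the top bucket
  expect_equal(b[7], b[9])                   # clamped beyond
  expect_equal(b[3], b[2])
  expect_true(all(b >= 1 & b <= gridner:::n_dist_buckets))
})

test_that("dilated refinement preserves shape; identity kernel gives GELU(G)", {
  set.seed(5)
  n <- 4; d_g <- 8
  cfg <- grid_head_config(d_h = 6, d_d = 4, d_r = 4, d_g = d_g)
  params <- toy_head_params(d_h = 6, d_g = d_g)
  G <- matrix(rnorm(n * n * d_g), n * n, d_g)
  S <- dilated_refine(G, n, params, cfg)
  expect_equal(dim(S), dim(G))

  # zero input, zero bias -> GELU(0) = 0
  expect_true(all(dilated_refine(G * 0, n, params, cfg) == 0))

  # kernel = identity at the center tap, zero elsewhere -> GELU(G)
  id_params <- params
  for (k in 1:9) id_params[[sprintf("conv_k%d", k)]] <- matrix(0, d_g, d_g)
  id_params$conv_k5 <- diag(d_g)             # center of the 3x3 kernel
  id_params$conv_b <- matrix(0, 1, d_g)
  expect_equal(dilated_refine(G, n, id_params, cfg), G * pnorm(G),
               tolerance = 1e-12)

  # n = 1: convolution sees only padding plus the center
  S1 <- dilated_refine(G[1, , drop = FALSE], 1, id_params, cfg)
  expect_equal(dim(S1), c(1L, d_g))
})

test_that("classifier emits per-cell distributions over the relation set", {
  set.seed(6)
  rset <- relation_set("Chemical")           # |R| = 3 for single-type corpora
  n <- 3; d_g <- 8
  params <- toy_head_params(d_g = d_g, n_labels = length(rset))
  S <- matrix(rnorm(n * n * d_g), n * n, d_g)
  pg <- classify_pairs(S, n, params, rset)
  expect_equal(dim(pg$probs), c(9L, 3L))
  expect_equal(rowSums(pg$probs), rep(1, 9), tolerance = 1e-9)
  # all-equal logits -> uniform 1/|R|
  u_params <- params
  u_params$cls_w2 <- matrix(0, d_g, 3)
  u_params$cls_b2 <- matrix(0, 1, 3)
  pu <- classify_pairs(S, n, u_params, rset)
  expect_equal(pu$probs, matrix(1 / 3, 9, 3), tolerance = 1e-12)
})

test_that("bioner_loss is the mean per-cell cross-entropy", {
  rset <- relation_set("C")
  s <- labeled_sentence(c("a", "b", "c"),
                        data.frame(start = 0, end = 1, type = "C"))
  gold <- encode_grid(s, rset)
  # perfect one-hot predictions -> 0
  perfect <- matrix(0, 9, 3)
  perfect[cbind(1:9, as.vector(t(gold$cells)))] <- 1
  expect_equal(bioner_loss(perfect, gold), 0)
  # uniform predictions -> log(3) whatever the gold grid
  expect_equal(bioner_loss(matrix(1 / 3, 9, 3), gold), log(3),
               tolerance = 1e-12)
  other <- encode_grid(labeled_sentence(c("a", "b", "c")), rset)
  expect_equal(bioner_loss(matrix(1 / 3, 9, 3), other), log(3),
               tolerance = 1e-12)
  # moving mass toward the gold label at one cell lowers the loss
  probs <- matrix(1 / 3, 9, 3)
  for (delta in c(0.1, 0.2, 0.3)) {
    shifted <- probs
    shifted[5, ] <- c(1 / 3 - delta / 2, 1 / 3 - delta / 2, 1 / 3 + delta)
    g5 <- gold
    g5$cells[2, 2] <- 3L
    expect_lt(bioner_loss(shifted, g5), bioner_loss(probs, g5))
  }
})

test_that("end-to-end gradient reaches every trainable component", {
  corpus <- toy_corpus(4)
  model <- toy_model(corpus)
  s <- corpus[[which(vapply(corpus, function(x) nrow(x$mentions) > 0,
                            logical(1)))[1]]]
  ad_begin()
  nodes <- params_to_nodes(model$params)
  fw <- gridner:::forward_sentence(model, s, nodes)
  loss <- ad_add(ad_cross_entropy_rows(fw$logits,
                                       gridner:::gold_cell_vector(s, model$rset)),
                 ad_scale(gridner:::guidance_loss_node(fw$stack, model$tau),
                          0.01))
  ad_backward(loss)
  touch <- c("emb", "pos", "l1_wq", "l2_wv", "prefix_k_l1", "prefix_v_l2",
             "lstm_fwd_w", "lstm_bwd_u", "cln_wa", "cln_wb", "dist_emb",
             "region_emb", "hyb_w1", "conv_k5", "conv_b", "cls_w1", "cls_w2")
  for (nm in touch)
    expect_gt(max(abs(nodes[[nm]]$grad)), 0)
})
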