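test_that("total loss is the exact weighted sum", {
  expect_equal(total_loss(1.0, 0.5, 0), 1.0)
  expect_equal(total_loss(1.0, 0.5, 0.1), 1.05)
  expect_error(total_loss(Inf, 0.5, 0.1), "finite")
  # gradient of the combination: d/dx [f + alpha g] = f' + alpha g'
  set.seed(1)
  x <- matrix(rnorm(4), 2, 2)
  alpha <- 0.1
  f_grad <- local({
    ad_begin()
    p <- ad_param(x)
    loss <- ad_add(ad_sum(ad_mul(p, p)),
                   ad_scale(ad_sum(ad_tanh(p)), alpha))
    ad_backward(loss)
    p$grad
  })
  num <- numeric_grad(function(v) sum(v * v) + alpha * sum(tanh(v)), x)
  expect_lt(max(abs(f_grad - num)), 1e-6)
})

test_that("entity-level scoring counts exact span+type matches only", {
  gold <- list(data.frame(start = 0, end = 2, type = "C"),
               data.frame(start = c(1, 4), end = c(2, 4),
                          type = c("C", "D")))
  # perfect prediction
  res <- evaluate_entities(gold, gold)
  expect_equal(c(res$precision, res$recall, res$f1), c(100, 100, 100))
  # off-by-one span is both a false positive and a false negative
  pred <- list(data.frame(start = 0, end = 1, type = "C"),
               gold[[2]])
  res2 <- evaluate_entities(pred, gold)
  expect_equal(res2$tp, 2L)
  expect_equal(res2$fp, 1L)
  expect_equal(res2$fn, 1L)
  # wrong type is also both
  pred3 <- list(data.frame(start = 0, end = 2, type = "D"), gold[[2]])
  expect_equal(evaluate_entities(pred3, gold)$tp, 2L)
  # empty predictions: P = 0 by convention, F1 = 0
  none <- list(data.frame(start = integer(), end = integer(),
                          type = character()),
               data.frame(start = integer(), end = integer(),
                          type = character()))
  res4 <- evaluate_entities(none, gold)
  expect_equal(res4$f1, 0)
})

test_that("harmonic F1 reproduces the published P/R/F1 arithmetic", {
  expect_equal(round(f1_score(91.74, 93.37), 2), 92.55)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(100, 100), 100)
})

test_that("micro scores agree with an independent tag-level oracle", {
  # oracle: score via BIO tags - write both sides to tags, re-extract runs
  # with an independent run-length scanner, and count multiset matches
  oracle <- function(pred, gold, n) {
    count_runs <- function(m) {
      if (is.null(m) || nrow(m) == 0) return(character())
      paste(m$start, m$end, m$type)
    }
    tp <- 0L; np <- 0L; ng <- 0L
    for (k in seq_along(pred)) {
      pk <- count_runs(pred[[k]]); gk <- count_runs(gold[[k]])
      tp <- tp + length(intersect(pk, gk))
      np <- np + length(pk); ng <- ng + length(gk)
    }
    p <- if (np) 100 * tp / np else 0
    r <- if (ng) 100 * tp / ng else 0
    list(p = p, r = r, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  set.seed(17)
  types <- c("Chemical", "Disease")
  for (rep in 1:300) {
    n <- sample(3:12, 1)
    gold <- list(random_flat_mentions(n, types))
    pred <- list(random_flat_mentions(n, types))
    got <- evaluate_entities(pred, gold)
    want <- oracle(pred, gold, n)
    expect_equal(got$precision, want$p)
    expect_equal(got$recall, want$r)
    expect_equal(got$f1, want$f1)
  }
})

test_that("a few optimizer steps reduce the joint loss on a toy corpus", {
  corpus <- toy_corpus(10)
  model <- toy_model(corpus)
  model <- train_model(model, corpus,
                       train_config(epochs = 6, batch_size = 4,
                                    alpha = 0.01, seed = 3))
  h <- attr(model, "history")
  expect_equal(nrow(h), 6L)
  expect_true(all(is.finite(h$loss_total)))
  expect_lt(h$loss_total[6], h$loss_total[1])
  # both loss components are logged (the ablation contract)
  expect_true(all(!is.na(h$loss_bioner)))
  expect_true(all(!is.na(h$loss_pamdfga)))
  h0 <- attr(train_model(toy_model(corpus), corpus,
                         train_config(epochs = 2, batch_size = 4,
                                      alpha = 0, seed = 3)), "history")
  expect_true(all(!is.na(h0$loss_pamdfga)))   # logged even when unused
})

test_that("fixed seed and config give bit-identical training metrics", {
  corpus <- toy_corpus(8)
  run <- function() {
    m <- train_model(toy_model(corpus, seed = 2), corpus,
                     train_config(epochs = 3, batch_size = 4,
                                  alpha = 0.01, seed = 5))
    attr(m, "history")
  }
  expect_identical(run(), run())
})

test_that("prediction decodes argmax grids; all-NONE means no mentions", {
  corpus <- toy_corpus(6)
  model <- toy_model(corpus)       # untrained: near-uniform heads
  out <- predict_entities(model, corpus, return_grids = TRUE)
  expect_length(out$mentions, length(corpus))
  expect_length(out$grids, length(corpus))
  for (k in seq_along(corpus)) {
    g <- out$grids[[k]]
    expect_equal(g$n, length(corpus[[k]]$tokens))
    if (all(g$cells == 1L)) expect_equal(nrow(out$mentions[[k]]), 0L)
  }
})

test_that("checkpoints round-trip through JSON", {
  corpus <- toy_corpus(5)
  model <- toy_model(corpus)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_identical(back$rset$labels, model$rset$labels)
  expect_identical(unname(back$vocab), unname(model$vocab))
  p1 <- predict_entities(model, corpus)$mentions
  p2 <- predict_entities(back, corpus)$mentions
  expect_identical(p1, p2)
})

test_that("repeated seeded runs report mean and spread", {
  corpus <- toy_corpus(8)
  res <- repeated_runs(corpus, seeds = 1:2,
                       model_args = list(
                         encoder = encoder_config(layers = 1, heads = 2,
                                                  dim = 16, prefix_len = 2,
                                                  d_h = 16),
                         head = grid_head_config(d_h = 16, d_d = 4,
                                                 d_r = 4, d_g = 16)),
                       config = train_config(epochs = 2, batch_size = 4,
                                             alpha = 0.01))
  expect_equal(nrow(res), 2L)
  expect_true(is.finite(attr(res, "mean")))
  expect_true(is.finite(attr(res, "sd")))
  expect_equal(attr(res, "max"), max(res$f1))
})

test_that("attention heatmaps render deterministically in all modes", {
  corpus <- toy_corpus(4)
  model <- toy_model(corpus)
  stack <- collect_attention(model, corpus[1])[[1]]
  for (mode in c("averaged", "single-head", "all-heads")) {
    path <- withr::local_tempfile(fileext = ".png")
    render_attention_heatmap(stack, path, mode = mode)
    expect_true(file.exists(path) && file.size(path) > 0)
  }
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_attention_heatmap(stack, p1, mode = "averaged")
  render_attention_heatmap(stack, p2, mode = "averaged")
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_error(render_attention_heatmap(stack, p1, mode = "single-head",
                                        layer = 99), "no collected map")
})

test_that("the CLI drives gen/encode/decode/eval end to end", {
  dir <- withr::local_tempdir()
  cfg <- file.path(dir, "gen.json")
  writeLines(jsonlite::toJSON(list(n_sentences = 12, mean_length = 8,
                                   max_length = 12, entity_density = 1,
                                   seed = 3), auto_unbox = TRUE), cfg)
  corpus_path <- file.path(dir, "corpus.conll")
  expect_message(gridner_cli(c("gen", "--config", cfg, "--out", corpus_path)),
                 "wrote 12 sentences")
  grids_path <- file.path(dir, "grids.jsonl")
  expect_message(gridner_cli(c("encode", "--in", corpus_path,
                               "--out", grids_path)), "encoded 12")
  dec_path <- file.path(dir, "decoded.conll")
  expect_message(gridner_cli(c("decode", "--in", grids_path,
                               "--corpus", corpus_path,
                               "--out", dec_path)), "decoded 12")
  out <- utils::capture.output(
    gridner_cli(c("eval", "--pred", dec_path, "--gold", corpus_path)))
  expect_true(any(grepl("^F1 100.00", out)))
})
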