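#' Training configuration
#'
#' Defaults follow the original setting: AdamW with learning rate 1e-3,
#' weight decay 0.1, linear decay with warm-up over the first 10% of steps,
#' batch size 8, temperature 2.0, and the guidance weight `alpha` searched
#' over \{0.1, 0.01, 0.001, 0.0001\} at full scale.
#'
#' @param epochs number of passes over the training corpus (>= 1).
#' @param batch_size sentences per optimizer step.
#' @param lr peak learning rate.
#' @param weight_decay decoupled weight decay, applied to weight matrices
#'   (biases and layer-norm vectors are exempt, the usual convention).
#' @param warmup fraction of total steps spent in linear warm-up.
#' @param alpha weight of the guidance loss in the total loss; 0 disables
#'   guidance (the ablation baseline).
#' @param seed integer seed driving shuffling (and nothing else).
#' @param eval_train if `TRUE`, compute training-set entity F1 every
#'   `eval_every` epochs.
#' @param eval_every epoch interval for the optional F1 evaluations.
#' @param f1_stop optional early-stopping threshold: training halts once
#'   the evaluated training F1 reaches this value (the learning-rate
#'   schedule still spans the configured `epochs`).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 8L, lr = 1e-3,
                         weight_decay = 0.1, warmup = 0.1, alpha = 0.01,
                         seed = 1L, eval_train = FALSE, eval_every = 1L,
                         f1_stop = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, lr > 0, weight_decay >= 0,
            warmup >= 0, warmup <= 1, alpha >= 0, eval_every >= 1L)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, warmup = warmup,
                 alpha = alpha, seed = as.integer(seed),
                 eval_train = isTRUE(eval_train),
                 eval_every = as.integer(eval_every),
                 f1_stop = f1_stop),
            class = "train_config")
}

#' Joint training objective
#'
#' `Loss_Total = Loss_BioNER + alpha * Loss_PAMDFGA`: the per-cell grid
#' cross-entropy plus the guidance loss scaled by `alpha`. With `alpha = 0`
#' this reduces to the unguided baseline.
#'
#' @param loss_bioner grid classification loss (finite scalar).
#' @param loss_pamdfga fused guidance loss (finite scalar).
#' @param alpha guidance weight.
#' @return scalar total loss.
#' @export
total_loss <- function(loss_bioner, loss_pamdfga, alpha) {
  stopifnot(is.finite(loss_bioner), is.finite(loss_pamdfga))
  loss_bioner + alpha * loss_pamdfga
}

# linear warm-up then linear decay to zero
lr_at_step <- function(step, total_steps, lr, warmup) {
  w <- max(1, round(total_steps * warmup))
  if (step <= w) return(lr * step / w)
  lr * max(0, (total_steps - step) / max(1, total_steps - w))
}

adamw_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (weight_decay > 0 && nrow(params[[nm]]) > 1L)  # exempt bias/LN rows
      upd <- upd + weight_decay * params[[nm]]
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Train a grid NER model
#'
#' Mini-batch AdamW training of the joint objective. The guidance loss is
#' pooled per sentence (each sentence's `L` is its own piece count; maps
#' are never padded) and averaged over the batch; the grid cross-entropy is
#' likewise the batch mean. Both components are logged per epoch together
#' with the combined loss, and optionally the training-set entity F1.
#' A non-finite loss aborts with diagnostics.
#'
#' @param model a [gridner_model()].
#' @param corpus training corpus.
#' @param config a [train_config()].
#' @param dev optional development corpus, evaluated each epoch.
#' @param verbose print one line per epoch.
#' @return the model with trained parameters; the per-epoch log is attached
#'   as attribute `history` (a data frame).
#' @export
train_model <- function(model, corpus, config = train_config(),
                        dev = NULL, verbose = FALSE) {
  stopifnot(length(corpus) >= 1L)
  n_batches <- ceiling(length(corpus) / config$batch_size)
  total_steps <- n_batches * config$epochs
  state <- adamw_state(model$params)
  history <- vector("list", config$epochs)
  with_local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(corpus))
      ep_bioner <- 0; ep_guid <- 0; ep_total <- 0
      for (b in seq_len(n_batches)) {
        take <- ord[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, length(corpus))]
        ad_begin()
        nodes <- params_to_nodes(model$params)
        ce_nodes <- list(); guid_nodes <- list()
        guid_vals <- numeric(length(take))
        for (si in seq_along(take)) {
          s <- corpus[[take[si]]]
          fw <- forward_sentence(model, s, nodes)
          ce_nodes[[si]] <- ad_cross_entropy_rows(
            fw$logits, gold_cell_vector(s, model$rset))
          if (config$alpha > 0) {
            guid_nodes[[si]] <- guidance_loss_node(fw$stack, model$tau)
            guid_vals[si] <- ad_value(guid_nodes[[si]])[1L, 1L]
          } else {
            # still logged for the ablation curves, but off the tape
            hv <- assemble_head_matrices(
              list(maps = lapply(fw$stack$maps, ad_value),
                   L = fw$stack$L, P = fw$stack$P), tau = model$tau)
            guid_vals[si] <- pamdfga_loss(hv)$loss_pamdfga
          }
        }
        bioner <- ad_scale(Reduce(ad_add, ce_nodes), 1 / length(take))
        loss <- bioner
        if (config$alpha > 0) {
          guid <- ad_scale(Reduce(ad_add, guid_nodes), 1 / length(take))
          loss <- ad_add(bioner, ad_scale(guid, config$alpha))
        }
        b_val <- ad_value(bioner)[1L, 1L]
        g_val <- mean(guid_vals)
        t_val <- total_loss(b_val, g_val, config$alpha)
        if (!is.finite(t_val))
          stop(sprintf(paste0("non-finite loss at epoch %d batch %d ",
                              "(bioner=%g, guidance=%g); training aborted"),
                       epoch, b, b_val, g_val))
        ad_backward(loss)
        grads <- lapply(nodes, function(n) n$grad)
        step <- (epoch - 1L) * n_batches + b
        upd <- adamw_step(model$params, grads, state,
                          lr_at_step(step, total_steps, config$lr,
                                     config$warmup),
                          config$weight_decay)
        model$params <- upd$params
        state <- upd$state
        ep_bioner <- ep_bioner + b_val
        ep_guid <- ep_guid + g_val
        ep_total <- ep_total + t_val
      }
      row <- data.frame(epoch = epoch,
                        loss_bioner = ep_bioner / n_batches,
                        loss_pamdfga = ep_guid / n_batches,
                        loss_total = ep_total / n_batches,
                        train_f1 = NA_real_, dev_f1 = NA_real_)
      if (config$eval_train &&
          (epoch %% config$eval_every == 0L || epoch == config$epochs)) {
        pred <- predict_entities(model, corpus)$mentions
        row$train_f1 <- evaluate_entities(pred, corpus)$f1
      }
      if (!is.null(dev)) {
        pred <- predict_entities(model, dev)$mentions
        row$dev_f1 <- evaluate_entities(pred, dev)$f1
      }
      history[[epoch]] <- row
      if (verbose)
        message(sprintf(
          "epoch %3d  bioner %.4f  pamdfga %.4f  total %.4f%s%s",
          epoch, row$loss_bioner, row$loss_pamdfga, row$loss_total,
          if (is.na(row$train_f1)) "" else sprintf("  train F1 %.2f",
                                                   row$train_f1),
          if (is.na(row$dev_f1)) "" else sprintf("  dev F1 %.2f",
                                                 row$dev_f1)))
      if (!is.null(config$f1_stop) && !is.na(row$train_f1) &&
          row$train_f1 >= config$f1_stop) break
    }
  })
  attr(model, "history") <- do.call(rbind, history)
  model
}

#' Entity-level micro-averaged precision, recall and F1
#'
#' Exact-match scoring: a predicted mention counts as a true positive iff
#' its span (start and end word indices) and its type both equal a gold
#' mention of the same sentence. Scores are percentages;
#' `F1 = 2 P R / (P + R)` when `P + R > 0`, else 0.
#'
#' @param pred list of predicted mention data frames (or labeled sentences),
#'   one per sentence.
#' @param gold matching list of gold mention data frames or sentences.
#' @return object of class `eval_result`: `precision`, `recall`, `f1`
#'   (percentages), plus raw `tp`, `fp`, `fn` counts.
#' @export
evaluate_entities <- function(pred, gold) {
  stopifnot(length(pred) == length(gold))
  as_m <- function(x) {
    m <- if (inherits(x, "labeled_sentence")) x$mentions else x
    if (is.null(m)) m <- data.frame(start = integer(), end = integer(),
                                    type = character())
    m
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in seq_along(pred)) {
    p <- as_m(pred[[k]]); g <- as_m(gold[[k]])
    pk <- if (nrow(p)) paste(p$start, p$end, p$type) else character()
    gk <- if (nrow(g)) paste(g$start, g$end, g$type) else character()
    tp <- tp + sum(pk %in% gk)
    fp <- fp + sum(!pk %in% gk)
    fn <- fn + sum(!gk %in% pk)
  }
  precision <- if (tp + fp > 0L) 100 * tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) 100 * tp / (tp + fn) else 0
  f1 <- f1_score(precision, recall)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "eval_result")
}

#' Harmonic-mean F1 from precision and recall
#' @param precision,recall percentages.
#' @return F1 percentage (0 when both are 0).
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("P %.2f  R %.2f  F1 %.2f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Summarize entity F1 over repeated seeded runs
#'
#' Trains one model per seed and reports per-run F1 plus mean, standard
#' deviation and maximum, the reporting convention of repeated-run tables.
#'
#' @param corpus training corpus.
#' @param eval_corpus corpus to evaluate on (defaults to `corpus`).
#' @param seeds integer vector of seeds (one run each).
#' @param model_args list of arguments to [gridner_model()] other than the
#'   corpus.
#' @param config a [train_config()]; its seed is replaced per run.
#' @return data frame of per-run F1 with attributes `mean`, `sd`, `max`.
#' @export
repeated_runs <- function(corpus, eval_corpus = corpus, seeds = 1:3,
                          model_args = list(), config = train_config()) {
  f1s <- vapply(seeds, function(sd_) {
    m <- do.call(gridner_model, c(list(corpus = corpus, seed = sd_),
                                  model_args))
    cfg <- config; cfg$seed <- sd_
    m <- train_model(m, corpus, cfg)
    pred <- predict_entities(m, eval_corpus)$mentions
    evaluate_entities(pred, eval_corpus)$f1
  }, numeric(1))
  out <- data.frame(seed = seeds, f1 = round(f1s, 2))
  attr(out, "mean") <- mean(f1s)
  attr(out, "sd") <- stats::sd(f1s)
  attr(out, "max") <- max(f1s)
  out
}

#' Mean off-diagonal head cosine similarity over a corpus
#'
#' The guidance diagnostic: pools every sentence's guided attention maps
#' into the token-view head matrix O and averages the off-diagonal cosine
#' similarity across sentences. Guided training should lower this value
#' relative to the unguided baseline.
#'
#' @param model a [gridner_model()].
#' @param corpus sentences to average over.
#' @return scalar mean cosine similarity.
#' @export
model_head_cosine <- function(model, corpus) {
  stacks <- collect_attention(model, corpus)
  mean(vapply(stacks, function(st) {
    hv <- assemble_head_matrices(st, tau = model$tau)
    head_cosine_similarity(hv$O)
  }, numeric(1)))
}
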