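#' Construct a word-pair grid NER model
#'
#' Assembles the full stack: subword splitter and piece vocabulary,
#' prefix-augmented transformer encoder, BiLSTM contextualizer, CLN pair
#' grid with distance/region embeddings, dilated convolution, and the
#' per-cell relation classifier. Parameters are randomly initialized
#' ("toy mode"); loading pretrained transformer weights is a config-level
#' concern and never required here.
#'
#' @param corpus training corpus (list of [labeled_sentence()]); supplies
#'   the piece vocabulary and the entity-type inventory.
#' @param encoder an [encoder_config()].
#' @param head a [grid_head_config()]; its `d_h` is forced to the
#'   encoder's `d_h`. If `NULL`, toy defaults are used.
#' @param types entity types; defaults to [corpus_types()] of `corpus`.
#' @param tau temperature of the guidance loss (default 2).
#' @param splitter subword splitter, default [chunk_splitter()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `gridner_model`.
#' @export
gridner_model <- function(corpus, encoder = encoder_config(),
                          head = NULL, types = NULL, tau = 2,
                          splitter = chunk_splitter(), seed = 1L) {
  if (is.null(types)) types <- corpus_types(corpus)
  if (length(types) == 0L)
    stop("no entity types: supply `types` or a corpus with mentions")
  rset <- relation_set(types)
  vocab <- build_vocab(corpus, splitter)
  if (is.null(head)) head <- grid_head_config(d_h = encoder$d_h)
  head$d_h <- encoder$d_h
  params <- c(init_encoder_params(encoder, attr(vocab, "size"), seed),
              init_grid_head_params(head, length(rset), seed + 2L))
  structure(list(encoder = encoder, head = head, rset = rset,
                 vocab = vocab, splitter = splitter, tau = tau,
                 params = params, seed = seed),
            class = "gridner_model")
}

#' @export
print.gridner_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(paste0("<gridner_model> %d transformer layer(s), %d head(s), ",
                     "d=%d, P=%d, d_h=%d, %d relation label(s), ",
                     "%d parameters\n"),
              x$encoder$layers, x$encoder$heads, x$encoder$dim,
              x$encoder$prefix_len, x$encoder$d_h, length(x$rset), n_par))
  invisible(x)
}

# Forward pass for one sentence on the active tape.
# Returns the relation logits node, the attention-map stack, and metadata.
forward_sentence <- function(model, sentence, nodes) {
  alignment <- build_subword_alignment(sentence, model$splitter)
  ids <- piece_ids(alignment$pieces, model$vocab)
  enc <- encoder_encode(ids, nodes, model$encoder)
  words <- pool_subwords(enc$hidden, alignment, model$encoder$pool)
  Hw <- bilstm_contextualize(words, nodes)
  n <- length(sentence$tokens)
  W <- cln_grid_node(Hw, nodes, model$head)
  G <- hybrid_grid_node(W, n, nodes)
  S <- dilated_refine_node(G, n, nodes, model$head)
  logits <- classify_logits_node(S, nodes)
  list(logits = logits, stack = enc$stack, n = n, alignment = alignment)
}

# gold label vector in row-major cell order
gold_cell_vector <- function(sentence, rset) {
  as.vector(t(encode_grid(sentence, rset)$cells))
}

#' Predict relation grids and entity mentions for a corpus
#'
#' Runs the forward pass (no gradients), takes the per-cell argmax to form
#' a predicted relation grid, and decodes it with [decode_grid()], using
#' the argmax probability of each THW cell for overlap resolution.
#'
#' @param model a trained [gridner_model()].
#' @param corpus list of [labeled_sentence()] (mentions may be empty).
#' @param return_grids also return the argmax `relation_grid`s.
#' @return list with `mentions` (one mention data frame per sentence) and,
#'   if requested, `grids`.
#' @export
predict_entities <- function(model, corpus, return_grids = FALSE) {
  nodes <- lapply(model$params, ad_const)
  mentions <- vector("list", length(corpus))
  grids <- if (return_grids) vector("list", length(corpus)) else NULL
  for (k in seq_along(corpus)) {
    fw <- forward_sentence(model, corpus[[k]], nodes)
    logits <- ad_value(fw$logits)
    z <- logits - apply(logits, 1L, max)
    e <- exp(z)
    probs <- e / rowSums(e)
    pg <- prediction_grid(probs, fw$n, model$rset)
    conf <- matrix(probs[cbind(seq_len(fw$n^2),
                               as.vector(t(pg$argmax$cells)))],
                   fw$n, fw$n, byrow = TRUE)
    mentions[[k]] <- decode_grid(pg$argmax, model$rset, thw_prob = conf)
    if (return_grids) grids[[k]] <- pg$argmax
  }
  out <- list(mentions = mentions)
  if (return_grids) out$grids <- grids
  out
}

#' Write predictions as a two-column CoNLL BIO file
#'
#' @param model a [gridner_model()].
#' @param corpus input sentences.
#' @param path output path.
#' @export
predict_to_conll <- function(model, corpus, path) {
  pred <- predict_entities(model, corpus)$mentions
  out <- mapply(function(s, m) labeled_sentence(s$tokens, m, id = s$id),
                corpus, pred, SIMPLIFY = FALSE)
  write_conll(out, path)
}

#' Collect attention-map stacks for a corpus (no gradients)
#'
#' @param model a [gridner_model()].
#' @param corpus input sentences.
#' @return list of per-sentence stacks; each stack's `maps` are plain
#'   numeric matrices and `tokens` carries the piece strings for axis
#'   labeling.
#' @export
collect_attention <- function(model, corpus) {
  nodes <- lapply(model$params, ad_const)
  lapply(corpus, function(s) {
    fw <- forward_sentence(model, s, nodes)
    stack <- fw$stack
    stack$maps <- lapply(stack$maps, ad_value)
    stack$tokens <- fw$alignment$pieces
    stack
  })
}

#' Save / load a model checkpoint as JSON
#'
#' Stores configuration, vocabulary, relation set, and all parameter
#' matrices in a single JSON file (text-only; toy scale).
#'
#' @param model a [gridner_model()].
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  rec <- list(
    encoder = unclass(model$encoder),
    head = unclass(model$head),
    types = model$rset$types,
    tau = model$tau,
    seed = model$seed,
    vocab = as.list(stats::setNames(as.integer(model$vocab),
                                    names(model$vocab))),
    params = lapply(model$params, function(m)
      list(dim = dim(m), data = as.numeric(m))))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param splitter subword splitter matching the one used at training time.
#' @export
load_checkpoint <- function(path, splitter = chunk_splitter()) {
  rec <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                  collapse = ""),
                            simplifyVector = TRUE)
  enc <- do.call(encoder_config,
                 rec$encoder[c("layers", "heads", "dim", "prefix_len", "d_h",
                               "guided_layers", "ffn_mult", "max_pos",
                               "pool")])
  head <- do.call(grid_head_config,
                  rec$head[c("d_h", "d_d", "d_r", "d_g", "kernel",
                             "dilation", "eps")])
  vocab <- unlist(rec$vocab)
  attr(vocab, "size") <- length(vocab)
  params <- lapply(rec$params, function(p)
    matrix(p$data, p$dim[1L], p$dim[2L]))
  structure(list(encoder = enc, head = head,
                 rset = relation_set(rec$types),
                 vocab = vocab, splitter = splitter, tau = rec$tau,
                 params = params, seed = rec$seed),
            class = "gridner_model")
}
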