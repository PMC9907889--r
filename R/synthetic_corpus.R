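#' Configuration for the synthetic biomedical corpus generator
#'
#' The generator emulates the statistical traits of biomedical NER corpora:
#' longish sentences that contain few entity words, multi-word alphanumeric
#' chemical names that a subword tokenizer fragments (the `"CD-832"` pattern:
#' letters, hyphen, digits as three words), single-word mentions, and a
#' single or multiple entity-type inventory per corpus.
#'
#' @param n_sentences number of sentences to generate.
#' @param mean_length mean sentence length in words (Poisson, truncated).
#' @param max_length hard maximum sentence length.
#' @param entity_density expected mentions per sentence (Poisson).
#' @param multi_token_fraction fraction of mentions spanning >= 2 words.
#' @param entity_types character vector of entity type names.
#' @param chemical_like_fraction fraction of mentions drawn as the
#'   letters/hyphen/digits chemical pattern (always multi-word, so the
#'   effective multi-word fraction is at least this value).
#' @param seed integer seed; the vocabulary and the corpus are both
#'   deterministic functions of it.
#' @return object of class `synthesis_config`.
#' @export
synthesis_config <- function(n_sentences = 1000L,
                             mean_length = 20,
                             max_length = 40L,
                             entity_density = 1.2,
                             multi_token_fraction = 0.5,
                             entity_types = "Chemical",
                             chemical_like_fraction = 0.3,
                             seed = 1L) {
  stopifnot(n_sentences >= 1L, mean_length >= 1, max_length >= 1L,
            entity_density >= 0,
            multi_token_fraction >= 0, multi_token_fraction <= 1,
            chemical_like_fraction >= 0, chemical_like_fraction <= 1,
            length(entity_types) >= 1L)
  structure(list(n_sentences = as.integer(n_sentences),
                 mean_length = mean_length,
                 max_length = as.integer(max_length),
                 entity_density = entity_density,
                 multi_token_fraction = multi_token_fraction,
                 entity_types = as.character(entity_types),
                 chemical_like_fraction = chemical_like_fraction,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

# run expr under a local RNG stream so generation never disturbs the caller's
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# pronounceable pseudo-words: filler is lowercase, entity words capitalized,
# so entity surface forms never collide with the filler vocabulary
make_pseudo_words <- function(k, syllables = 2L, capital = FALSE) {
  cons <- c("b","d","f","g","k","l","m","n","p","r","s","t","v","z")
  vow <- c("a","e","i","o","u")
  out <- character(k)
  seen <- character(0)
  i <- 0L
  while (i < k) {
    w <- paste0(vapply(seq_len(syllables), function(j)
      paste0(sample(cons, 1L), sample(vow, 1L)), character(1)), collapse = "")
    if (capital) w <- paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w)))
    if (!w %in% seen) { i <- i + 1L; out[i] <- w; seen <- c(seen, w) }
  }
  out
}

# one chemical-like surface: letters token, hyphen, digits ("XQ - 417" style)
draw_chemical_tokens <- function() {
  letters_part <- paste0(sample(LETTERS, sample(2:3, 1L), replace = TRUE),
                         collapse = "")
  digits_part <- paste0(sample(0:9, sample(2:4, 1L), replace = TRUE),
                        collapse = "")
  c(letters_part, "-", digits_part)
}

#' Generate a synthetic labeled corpus
#'
#' Deterministic given the config (identical config and seed give an
#' identical corpus). Non-entity tokens are drawn from a Zipf-weighted
#' synthetic vocabulary so token frequencies are realistically skewed;
#' entity surface forms are held out of that filler vocabulary, which makes
#' the toy recognition task solvable from surface form alone. Mentions are
#' placed by rejection sampling with a retry cap of 100 per sentence; a
#' density so high that placement fails is a hard error.
#'
#' @param config a [synthesis_config()].
#' @return list of [labeled_sentence()] objects.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  with_local_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n_filler <- 300L
  filler <- make_pseudo_words(n_filler, syllables = sample(2:3, 1L))
  zipf_w <- 1 / seq_len(n_filler)^1.1
  zipf_w <- zipf_w / sum(zipf_w)
  pools <- lapply(config$entity_types, function(t)
    make_pseudo_words(40L, syllables = 3L, capital = TRUE))
  names(pools) <- config$entity_types

  cf <- config$chemical_like_fraction
  mtf <- config$multi_token_fraction
  # chemical-like mentions are multi-word by construction; the remaining
  # mentions are multi-word with the probability that matches mtf overall
  p_multi_rest <- if (cf >= 1) 0 else max(0, (mtf - cf) / (1 - cf))

  out <- vector("list", config$n_sentences)
  for (sidx in seq_len(config$n_sentences)) {
    k <- stats::rpois(1L, config$entity_density)
    shapes <- vector("list", k)
    types <- character(k)
    for (m in seq_len(k)) {
      types[m] <- sample(config$entity_types, 1L)
      if (stats::runif(1) < cf) {
        shapes[[m]] <- draw_chemical_tokens()
      } else if (stats::runif(1) < p_multi_rest) {
        shapes[[m]] <- sample(pools[[types[m]]], sample(2:3, 1L))
      } else {
        shapes[[m]] <- sample(pools[[types[m]]], 1L)
      }
    }
    need <- sum(lengths(shapes))
    n <- stats::rpois(1L, config$mean_length)
    n <- max(n, need, 1L)
    n <- min(n, config$max_length)
    if (n < need)
      stop("entity_density too high for max_length: mentions cannot fit")
    placed <- NULL
    for (try in seq_len(100L)) {
      starts0 <- sort(sample.int(n, k))      # tentative 1-based starts
      ok <- TRUE
      pos <- integer(k)
      cursor <- 0L
      ord <- order(starts0)
      for (j in seq_len(k)) {
        m <- ord[j]
        s <- max(starts0[j], cursor + 1L)
        e <- s + length(shapes[[m]]) - 1L
        if (e > n) { ok <- FALSE; break }
        pos[m] <- s
        cursor <- e
      }
      if (ok) { placed <- pos; break }
    }
    if (is.null(placed) && k > 0L)
      stop("failed to place mentions after 100 retries; lower entity_density")
    tokens <- sample(filler, n, replace = TRUE, prob = zipf_w)
    starts <- integer(k); ends <- integer(k)
    for (m in seq_len(k)) {
      s <- placed[m]; e <- s + length(shapes[[m]]) - 1L
      tokens[s:e] <- shapes[[m]]
      starts[m] <- s - 1L; ends[m] <- e - 1L
    }
    mentions <- if (k > 0L)
      data.frame(start = starts, end = ends, type = types,
                 stringsAsFactors = FALSE)
    else NULL
    out[[sidx]] <- labeled_sentence(tokens, mentions,
                                    id = sprintf("syn%05d", sidx))
  }
  out
}
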