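# Independent oracles and fixture builders shared across test files.

init_mat <- function(nr, nc, sd = 0.02) matrix(rnorm(nr * nc, sd = sd), nr, nc)

# random flat mention set on n tokens: greedy left-to-right placement
random_flat_mentions <- function(n, types, p_entity = 0.35, max_len = 3L) {
  starts <- integer(); ends <- integer(); tset <- character()
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < p_entity) {
      len <- sample.int(min(max_len, n - i + 1L), 1L)
      starts <- c(starts, i - 1L)
      ends <- c(ends, i + len - 2L)
      tset <- c(tset, sample(types, 1L))
      i <- i + len + 1L       # gap so runs stay distinguishable
    } else i <- i + 1L
  }
  if (length(starts) == 0L) return(NULL)
  data.frame(start = starts, end = ends, type = tset,
             stringsAsFactors = FALSE)
}

random_sentence <- function(n, types, ...) {
  labeled_sentence(sprintf("w%02d", seq_len(n)),
                   random_flat_mentions(n, types, ...))
}

# brute-force grid decoder: enumerate every strictly-increasing index
# sequence from head s to tail e and test it as an NNW chain
brute_force_decode <- function(grid, rset) {
  n <- grid$n
  cells <- grid$cells
  path_exists <- function(s, e) {
    if (s == e) return(TRUE)
    inner <- setdiff(seq.int(s, e), c(s, e))
    for (k in 0:length(inner)) {
      combos <- if (k == 0L) list(integer())
      else if (length(inner) == 1L) list(inner)   # combn(scalar, 1) trap
      else utils::combn(inner, k, simplify = FALSE)
      for (mid in combos) {
        seqq <- c(s, mid, e)
        steps <- cbind(seqq[-length(seqq)], seqq[-1L])
        if (all(cells[steps] == 2L)) return(TRUE)
      }
    }
    FALSE
  }
  starts <- integer(); ends <- integer(); types <- character()
  for (e in seq_len(n)) for (s in seq_len(e)) {
    lab <- cells[e, s]
    if (lab > 2L && path_exists(s, e)) {
      starts <- c(starts, s - 1L); ends <- c(ends, e - 1L)
      types <- c(types, sub("^THW-", "", rset$labels[lab]))
    }
  }
  df <- data.frame(start = starts, end = ends, type = types,
                   stringsAsFactors = FALSE)
  df[order(df$start, df$end, df$type), , drop = FALSE]
}

mention_key <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(character())
  sort(paste(m$start, m$end, m$type))
}

# tiny corpus + model used by several neural-stack tests
toy_corpus <- function(n_sentences = 12L, seed = 7L) {
  generate_corpus(synthesis_config(
    n_sentences = n_sentences, mean_length = 8, max_length = 12,
    entity_density = 1, multi_token_fraction = 0.5,
    chemical_like_fraction = 0.3, seed = seed))
}

toy_model <- function(corpus, prefix_len = 2L, seed = 1L, ...) {
  gridner_model(corpus,
                encoder = encoder_config(layers = 2L, heads = 2L, dim = 16L,
                                         prefix_len = prefix_len, d_h = 16L,
                                         ...),
                head = grid_head_config(d_h = 16L, d_d = 4L, d_r = 4L,
                                        d_g = 16L),
                seed = seed)
}

# finite-difference gradient of f at params (a named list of matrices)
numeric_grad <- function(f, value, eps = 1e-6) {
  g <- value * 0
  for (i in seq_along(value)) {
    v1 <- value; v1[i] <- v1[i] + eps
    v2 <- value; v2[i] <- v2[i] - eps
    g[i] <- (f(v1) - f(v2)) / (2 * eps)
  }
  g
}
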