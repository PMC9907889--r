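#' Construct a labeled sentence
#'
#' The basic unit of all corpus I/O: a tokenized sentence together with its
#' gold entity mentions. Mentions use 0-based word indices with inclusive
#' ends, matching the tail-to-head cell addressing of the relation grid.
#' Only flat annotation is supported: mentions may neither overlap nor nest.
#'
#' @param tokens character vector of words (length >= 1, no empty strings).
#' @param mentions data frame with columns `start`, `end` (0-based, inclusive)
#'   and `type` (character), or `NULL` for an entity-free sentence.
#' @param id opaque sentence identifier.
#' @return an object of class `labeled_sentence`.
#' @export
labeled_sentence <- function(tokens, mentions = NULL, id = NULL) {
  tokens <- as.character(tokens)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) < 1L) stop("a sentence needs at least one non-empty token")
  mentions <- normalize_mentions(mentions)
  n <- length(tokens)
  if (nrow(mentions) > 0L) {
    if (any(mentions$start < 0L) || any(mentions$end >= n))
      stop("mention span outside [0, n)")
    if (any(mentions$start > mentions$end))
      stop("mention with start > end")
    check_flat(mentions)
  }
  structure(list(tokens = tokens, mentions = mentions, id = id),
            class = "labeled_sentence")
}

normalize_mentions <- function(mentions) {
  if (is.null(mentions) ||
      (is.data.frame(mentions) && nrow(mentions) == 0L) ||
      (is.list(mentions) && !is.data.frame(mentions) &&
         length(mentions) == 0L)) {
    return(data.frame(start = integer(), end = integer(),
                      type = character(), stringsAsFactors = FALSE))
  }
  if (is.list(mentions) && !is.data.frame(mentions)) {
    mentions <- do.call(rbind, lapply(mentions, function(m) {
      data.frame(start = as.integer(m[[1]]), end = as.integer(m[[2]]),
                 type = as.character(m[[3]]), stringsAsFactors = FALSE)
    }))
  }
  mentions <- mentions[, c("start", "end", "type")]
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  mentions$type <- as.character(mentions$type)
  mentions <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  rownames(mentions) <- NULL
  mentions
}

check_flat <- function(mentions) {
  if (nrow(mentions) < 2L) return(invisible(TRUE))
  m <- mentions[order(mentions$start), , drop = FALSE]
  if (any(m$start[-1L] <= m$end[-nrow(m)]))
    stop("mentions overlap or nest; only flat annotation is supported")
  invisible(TRUE)
}

#' @export
print.labeled_sentence <- function(x, ...) {
  cat("<labeled_sentence> ", paste(x$tokens, collapse = " "), "\n", sep = "")
  if (nrow(x$mentions) > 0L) {
    for (k in seq_len(nrow(x$mentions))) {
      m <- x$mentions[k, ]
      cat(sprintf("  [%d,%d] %s: %s\n", m$start, m$end, m$type,
                  paste(x$tokens[(m$start + 1L):(m$end + 1L)], collapse = " ")))
    }
  }
  invisible(x)
}

#' Recover entity spans from a BIO / BIOES tag sequence
#'
#' Ill-formed transitions (an `I-X` following `O`, or following `I-Y`/`B-Y`
#' of a different type) are repaired by treating the `I-X` as `B-X`, the
#' conventional IOB2 repair; the number of repairs is reported via the
#' `repairs` attribute so callers can log it. `E-`/`S-` prefixes (BIOES) are
#' accepted on input.
#'
#' @param tags character vector of per-token tags.
#' @return mention data frame (`start`, `end`, `type`; 0-based inclusive)
#'   with attribute `repairs` counting repaired transitions.
#' @export
spans_from_bio <- function(tags) {
  n <- length(tags)
  starts <- integer(); ends <- integer(); types <- character()
  cur_start <- -1L; cur_type <- NA_character_
  repairs <- 0L
  close_run <- function(last) {
    if (cur_start >= 0L) {
      starts[[length(starts) + 1L]] <<- cur_start
      ends[[length(ends) + 1L]] <<- last
      types[[length(types) + 1L]] <<- cur_type
    }
    cur_start <<- -1L; cur_type <<- NA_character_
  }
  for (i in seq_len(n)) {
    tag <- tags[[i]]
    if (tag == "O") {
      close_run(i - 2L)
      next
    }
    prefix <- substr(tag, 1L, 1L)
    if (!prefix %in% c("B", "I", "E", "S") || substr(tag, 2L, 2L) != "-")
      stop(sprintf("malformed tag '%s' at position %d", tag, i))
    type <- substr(tag, 3L, nchar(tag))
    if (prefix %in% c("B", "S")) {
      close_run(i - 2L)
      cur_start <- i - 1L; cur_type <- type
      if (prefix == "S") close_run(i - 1L)
    } else {            # I- or E-: continuation
      if (cur_start < 0L || !identical(cur_type, type)) {
        # dangling continuation: IOB2 repair, treat as B-
        repairs <- repairs + 1L
        close_run(i - 2L)
        cur_start <- i - 1L; cur_type <- type
      }
      if (prefix == "E") close_run(i - 1L)
    }
  }
  close_run(n - 1L)
  out <- normalize_mentions(data.frame(start = starts, end = ends, type = types,
                                       stringsAsFactors = FALSE))
  attr(out, "repairs") <- repairs
  out
}

#' Emit BIO tags for a set of flat mentions
#'
#' Exact inverse of [spans_from_bio()] on well-formed input.
#'
#' @param mentions mention data frame (`start`, `end`, `type`).
#' @param n sentence length in words.
#' @return character vector of `n` BIO tags.
#' @export
bio_from_spans <- function(mentions, n) {
  mentions <- normalize_mentions(mentions)
  check_flat(mentions)
  tags <- rep("O", n)
  for (k in seq_len(nrow(mentions))) {
    s <- mentions$start[k]; e <- mentions$end[k]; t <- mentions$type[k]
    if (s < 0L || e >= n) stop("mention span outside [0, n)")
    tags[s + 1L] <- paste0("B-", t)
    if (e > s) tags[(s + 2L):(e + 1L)] <- paste0("I-", t)
  }
  tags
}

#' Read a CoNLL-style BIO corpus
#'
#' Two-column format: token in the first column, tag in the last column,
#' extra middle columns ignored, blank lines separating sentences, UTF-8.
#' Unknown tag prefixes are a hard error naming the line; dangling `I-` tags
#' are repaired as `B-` with a warning summarizing the repair count.
#'
#' @param path file path.
#' @param scheme tag scheme on disk, `"BIO"` (default) or `"BIOES"`.
#' @return list of [labeled_sentence()] objects.
#' @export
read_conll <- function(path, scheme = c("BIO", "BIOES")) {
  scheme <- match.arg(scheme)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  toks <- character(); tags <- character(); tok_lines <- integer()
  n_repairs <- 0L
  flush_sentence <- function() {
    if (length(toks) == 0L) return(invisible(NULL))
    spans <- tryCatch(spans_from_bio(tags), error = function(e) {
      stop(sprintf("%s (sentence ending near line %d)", conditionMessage(e),
                   tok_lines[length(tok_lines)]), call. = FALSE)
    })
    n_repairs <<- n_repairs + attr(spans, "repairs")
    sentences[[length(sentences) + 1L]] <<-
      labeled_sentence(toks, spans, id = sprintf("s%04d", length(sentences) + 1L))
    toks <<- character(); tags <<- character(); tok_lines <<- integer()
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) { flush_sentence(); next }
    cols <- strsplit(line, "[ \t]+")[[1]]
    if (length(cols) < 2L)
      stop(sprintf("line %d: expected at least 2 columns, got %d", i, length(cols)))
    toks[[length(toks) + 1L]] <- cols[[1]]
    tags[[length(tags) + 1L]] <- cols[[length(cols)]]
    tok_lines[[length(tok_lines) + 1L]] <- i
  }
  flush_sentence()
  if (n_repairs > 0L)
    warning(sprintf("repaired %d dangling I- tag(s) as B- (IOB2 repair)", n_repairs))
  sentences
}

#' Write a corpus in two-column CoNLL BIO format
#'
#' @param corpus list of [labeled_sentence()] objects.
#' @param path output file path.
#' @export
write_conll <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in corpus) {
    tags <- bio_from_spans(s$mentions, length(s$tokens))
    writeLines(paste(s$tokens, tags), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read / write the JSON-lines corpus format
#'
#' Each line is `{"tokens": [...], "mentions": [[start, end, "type"], ...]}`
#' with 0-based inclusive spans.
#'
#' @param path file path.
#' @return list of [labeled_sentence()] objects.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    mentions <- lapply(rec$mentions, function(m)
      list(as.integer(m[[1]]), as.integer(m[[2]]), as.character(m[[3]])))
    labeled_sentence(unlist(rec$tokens), mentions,
                     id = if (!is.null(rec$id)) rec$id else sprintf("s%04d", i))
  })
}

#' @rdname read_jsonl
#' @param corpus list of [labeled_sentence()] objects.
#' @export
write_jsonl <- function(corpus, path) {
  out <- vapply(corpus, function(s) {
    mentions <- lapply(seq_len(nrow(s$mentions)), function(k)
      list(s$mentions$start[k], s$mentions$end[k], s$mentions$type[k]))
    jsonlite::toJSON(list(tokens = s$tokens, mentions = mentions),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Entity types declared by a corpus
#' @param corpus list of labeled sentences.
#' @return sorted character vector of types.
#' @export
corpus_types <- function(corpus) {
  sort(unique(unlist(lapply(corpus, function(s) s$mentions$type))))
}

# ---- subword tokenization and word/piece alignment -------------------------

#' A deterministic chunking subword splitter
#'
#' A stand-in for a WordPiece tokenizer at toy scale: a word is split into
#' chunks of at most `max_chars` characters; every chunk after the first is
#' prefixed with `"##"`, mirroring WordPiece's continuation marker (so
#' `"CD-832"`-style alphanumeric words become several pieces). Purely
#' rule-based and vocabulary-free, hence deterministic.
#'
#' @param max_chars maximum characters per piece (default 2).
#' @return a function mapping one word to a character vector of pieces.
#' @export
chunk_splitter <- function(max_chars = 2L) {
  force(max_chars)
  function(word) {
    nc <- nchar(word)
    if (nc == 0L) stop("cannot tokenize an empty word")
    if (nc <= max_chars) return(word)
    starts <- seq.int(1L, nc, by = max_chars)
    pieces <- substring(word, starts, pmin(starts + max_chars - 1L, nc))
    c(pieces[1L], paste0("##", pieces[-1L]))
  }
}

#' Align a sentence's words to encoder subword pieces
#'
#' Produces the piece sequence fed to the encoder — a start special token
#' (`[CLS]` analogue), each word's pieces in order, and an end special token
#' (`[SEP]` analogue) — and, per word, the 0-based range of piece positions
#' it occupies. Ranges are contiguous, non-overlapping, and partition all
#' non-special positions.
#'
#' @param sentence a [labeled_sentence()] or character vector of words.
#' @param splitter function word -> pieces, e.g. [chunk_splitter()].
#' @return list with `pieces` (character, specials included), `ranges`
#'   (n x 2 integer matrix of first/last piece index per word, 0-based),
#'   and `special` (logical per piece).
#' @export
build_subword_alignment <- function(sentence, splitter = chunk_splitter()) {
  words <- if (inherits(sentence, "labeled_sentence")) sentence$tokens else sentence
  if (any(!nzchar(words))) stop("cannot align an empty word")
  pieces <- c("[CLS]")
  ranges <- matrix(0L, nrow = length(words), ncol = 2L)
  for (w in seq_along(words)) {
    wp <- splitter(words[[w]])
    if (length(wp) < 1L) stop("splitter produced no pieces for a word")
    ranges[w, 1L] <- length(pieces)            # 0-based first index
    pieces <- c(pieces, wp)
    ranges[w, 2L] <- length(pieces) - 1L
  }
  pieces <- c(pieces, "[SEP]")
  special <- rep(FALSE, length(pieces))
  special[c(1L, length(pieces))] <- TRUE
  list(pieces = pieces, ranges = ranges, special = special)
}

#' Build a piece vocabulary from a corpus
#'
#' Maps every subword piece occurring in the corpus to an integer id.
#' Ids 1..4 are reserved for `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`.
#'
#' @param corpus list of labeled sentences.
#' @param splitter subword splitter, as in [build_subword_alignment()].
#' @return named integer vector piece -> id, with `attr(, "size")`.
#' @export
build_vocab <- function(corpus, splitter = chunk_splitter()) {
  pieces <- unique(unlist(lapply(corpus, function(s)
    unlist(lapply(s$tokens, splitter)))))
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")
  pieces <- setdiff(pieces, specials)
  vocab <- seq_len(length(specials) + length(pieces))
  names(vocab) <- c(specials, sort(pieces))
  attr(vocab, "size") <- length(vocab)
  vocab
}

#' Map pieces to vocabulary ids (unknown pieces to `[UNK]`)
#' @param pieces character vector of pieces.
#' @param vocab vocabulary from [build_vocab()].
#' @return integer ids.
#' @export
piece_ids <- function(pieces, vocab) {
  ids <- unname(vocab[pieces])
  ids[is.na(ids)] <- unname(vocab[["[UNK]"]])
  as.integer(ids)
}
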