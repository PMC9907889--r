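#' The relation label set over word pairs
#'
#' Ordered label set \eqn{\Re}: `NONE` at index 1, `NNW` at index 2, then one
#' `THW-<type>` label per entity type. NNW (Next-Neighboring-Word) marks two
#' successive words of one entity and lives strictly above the diagonal; a
#' THW (Tail-Head-Word) label points from an entity's last word to its first
#' and lives on or below the diagonal, carrying the type.
#'
#' @param types character vector of entity type names.
#' @return object of class `relation_set` with elements `labels` and `types`.
#' @export
relation_set <- function(types) {
  types <- as.character(types)
  if (anyDuplicated(types)) stop("duplicate entity types")
  structure(list(labels = c("NONE", "NNW", paste0("THW-", types)),
                 types = types),
            class = "relation_set")
}

#' @export
print.relation_set <- function(x, ...) {
  cat("<relation_set> ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.relation_set <- function(x) length(x$labels)

thw_index <- function(rset, type) {
  idx <- match(paste0("THW-", type), rset$labels)
  if (is.na(idx)) stop(sprintf("unknown entity type '%s'", type))
  idx
}

#' Encode a sentence's mentions as a word-pair relation grid
#'
#' For each mention with words \eqn{s..e} of type t: cells (k, k+1) for
#' \eqn{s \le k < e} get NNW, and cell (e, s) gets THW-t; every other cell is
#' NONE. A k-word mention hence contributes exactly k-1 NNW cells and one THW
#' cell; a single-word mention sits alone on the diagonal as THW-t, and a
#' sentence without entities encodes to the all-NONE grid.
#'
#' @param sentence a [labeled_sentence()].
#' @param rset a [relation_set()] covering the sentence's types.
#' @return object of class `relation_grid`: list with `n` and `cells`, an
#'   n x n integer matrix of indices into `rset$labels`.
#' @export
encode_grid <- function(sentence, rset) {
  n <- length(sentence$tokens)
  cells <- matrix(1L, n, n)                 # 1 = NONE
  m <- sentence$mentions
  check_flat(m)
  for (k in seq_len(nrow(m))) {
    s <- m$start[k]; e <- m$end[k]
    ti <- thw_index(rset, m$type[k])
    if (e > s)
      for (j in s:(e - 1L)) cells[j + 1L, j + 2L] <- 2L   # NNW at (k, k+1)
    cells[e + 1L, s + 1L] <- ti                            # THW at (tail, head)
  }
  structure(list(n = n, cells = cells), class = "relation_grid")
}

#' @export
print.relation_grid <- function(x, ...) {
  cat(sprintf("<relation_grid> n = %d, %d non-NONE cell(s)\n",
              x$n, sum(x$cells != 1L)))
  invisible(x)
}

#' Decode a relation grid back into entity mentions
#'
#' Emits a mention (s, e, t) iff cell (e, s) carries THW-t and either s = e
#' or a chain of NNW edges leads from s to e in the upper triangle (general
#' depth-first reachability over NNW edges i -> j, i < j, not just adjacent
#' steps). THW cells whose head-to-tail path does not exist are dropped and
#' counted. When decoded candidates overlap — possible only on arbitrary
#' predicted grids, never on encoded ones — the candidate whose THW cell has
#' the higher predicted probability wins; ties go to the smaller start, then
#' the longer span.
#'
#' @param grid a `relation_grid`.
#' @param rset the [relation_set()] the grid indexes into.
#' @param thw_prob optional n x n matrix of per-cell THW confidence used for
#'   overlap resolution (e.g. the classifier's probability of the argmax
#'   label); defaults to 1 everywhere.
#' @param flat if `TRUE` (default) resolve overlapping candidates to a flat
#'   mention set; if `FALSE` return all path-supported candidates.
#' @return mention data frame with attribute `dropped` counting unreachable
#'   THW cells.
#' @export
decode_grid <- function(grid, rset, thw_prob = NULL, flat = TRUE) {
  n <- grid$n
  cells <- grid$cells
  if (is.null(thw_prob)) thw_prob <- matrix(1, n, n)
  nnw <- cells == 2L & upper.tri(cells)
  # reach[s, e]: an NNW path s -> ... -> e exists (DFS over successors)
  reach <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (s in (n - 1L):1L) {
      succ <- which(nnw[s, ])
      for (j in succ) {
        reach[s, j] <- TRUE
        reach[s, ] <- reach[s, ] | reach[j, ]
      }
    }
  }
  starts <- integer(); ends <- integer(); types <- character(); probs <- numeric()
  dropped <- 0L
  for (e in seq_len(n)) {
    for (s in seq_len(e)) {                  # THW only at (e, s) with e >= s
      lab <- cells[e, s]
      if (lab <= 2L) next
      if (s == e || reach[s, e]) {
        starts <- c(starts, s - 1L); ends <- c(ends, e - 1L)
        types <- c(types, sub("^THW-", "", rset$labels[lab]))
        probs <- c(probs, thw_prob[e, s])
      } else dropped <- dropped + 1L
    }
  }
  cand <- data.frame(start = starts, end = ends, type = types,
                     stringsAsFactors = FALSE)
  if (flat && nrow(cand) > 1L) {
    ord <- order(-probs, cand$start, -(cand$end - cand$start))
    keep <- logical(nrow(cand))
    taken <- rep(FALSE, n)
    for (k in ord) {
      span <- (cand$start[k] + 1L):(cand$end[k] + 1L)
      if (!any(taken[span])) { keep[k] <- TRUE; taken[span] <- TRUE }
    }
    cand <- cand[keep, , drop = FALSE]
  }
  out <- normalize_mentions(cand)
  attr(out, "dropped") <- dropped
  out
}

#' Structural diagnostics for a relation grid
#'
#' Reports triangle violations (NNW on or below the diagonal, THW strictly
#' above it), THW cells with no supporting NNW path from head to tail, and
#' NNW edges not used by any path-supported THW candidate.
#'
#' @param grid a `relation_grid`.
#' @param rset the corresponding [relation_set()].
#' @return list with counts `triangle_violations`, `unreachable_thw`,
#'   `uncovered_nnw`.
#' @export
validate_grid <- function(grid, rset) {
  n <- grid$n
  cells <- grid$cells
  lower_or_diag <- !upper.tri(cells)
  triangle <- sum(cells == 2L & lower_or_diag) +
    sum(cells > 2L & upper.tri(cells))
  cand <- decode_grid(grid, rset, flat = FALSE)
  unreachable <- attr(cand, "dropped")
  nnw <- cells == 2L & upper.tri(cells)
  reach <- nnw_reachability(nnw, n)
  covered <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(cand))) {
    s <- cand$start[k]; e <- cand$end[k]
    if (e > s) {
      # NNW edge (i,j) lies on some head->tail path iff s reaches i (or i=s),
      # the edge exists, and j reaches e (or j=e)
      from_s <- reach[s + 1L, ]; from_s[s + 1L] <- TRUE
      to_e <- reach[, e + 1L]; to_e[e + 1L] <- TRUE
      for (i in which(from_s)) for (j in which(to_e))
        if (i < j && nnw[i, j]) covered[i, j] <- TRUE
    }
  }
  nnw_cells <- which(cells == 2L & upper.tri(cells))
  uncovered <- sum(!covered[nnw_cells])
  list(triangle_violations = triangle,
       unreachable_thw = unreachable,
       uncovered_nnw = uncovered)
}

nnw_reachability <- function(nnw, n) {
  reach <- matrix(FALSE, n, n)
  if (n >= 2L) {
    for (s in (n - 1L):1L) {
      for (j in which(nnw[s, ])) {
        reach[s, j] <- TRUE
        reach[s, ] <- reach[s, ] | reach[j, ]
      }
    }
  }
  reach
}

#' Serialize / deserialize a relation grid as JSON
#'
#' Only non-NONE cells are listed: `{"n": n, "cells": [[i, j, "label"], ...]}`
#' with 0-based cell coordinates.
#'
#' @param grid a `relation_grid`.
#' @param rset the corresponding [relation_set()].
#' @return for `grid_to_json`, a JSON string; for `grid_from_json`, a
#'   `relation_grid`.
#' @export
grid_to_json <- function(grid, rset) {
  idx <- which(grid$cells != 1L, arr.ind = TRUE)
  cells <- lapply(seq_len(nrow(idx)), function(k)
    list(idx[k, 1L] - 1L, idx[k, 2L] - 1L,
         rset$labels[grid$cells[idx[k, 1L], idx[k, 2L]]]))
  jsonlite::toJSON(list(n = grid$n, cells = cells), auto_unbox = TRUE)
}

#' @rdname grid_to_json
#' @param json JSON string produced by `grid_to_json`.
#' @export
grid_from_json <- function(json, rset) {
  rec <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  n <- as.integer(rec$n)
  cells <- matrix(1L, n, n)
  for (c3 in rec$cells) {
    lab <- match(as.character(c3[[3]]), rset$labels)
    if (is.na(lab)) stop(sprintf("unknown grid label '%s'", c3[[3]]))
    cells[as.integer(c3[[1]]) + 1L, as.integer(c3[[2]]) + 1L] <- lab
  }
  structure(list(n = n, cells = cells), class = "relation_grid")
}
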