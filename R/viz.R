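#' Render attention maps as heatmap images
#'
#' Deterministic base-graphics rendering of one sentence's attention-map
#' stack, token strings on both axes, darker cells meaning greater
#' attention. Three modes: one panel for a single head; a layer-by-head
#' panel lattice over all guided heads; or a single panel averaged over
#' all collected heads and layers. Prefix key columns are excluded so the
#' panels are token-by-token.
#'
#' @param stack one per-sentence stack from [collect_attention()] (numeric
#'   maps plus `tokens`, `L`, `P`, `index`).
#' @param path output PNG path.
#' @param mode `"single-head"`, `"all-heads"`, or `"averaged"`.
#' @param layer,head head selector for `"single-head"` mode (layer index as
#'   in the encoder config; head within layer).
#' @param cell_px approximate pixels per token cell.
#' @return invisibly, the path.
#' @export
render_attention_heatmap <- function(stack, path,
                                     mode = c("averaged", "single-head",
                                              "all-heads"),
                                     layer = NULL, head = 1L,
                                     cell_px = 24L) {
  mode <- match.arg(mode)
  L <- stack$L
  tok_part <- function(A) A[, seq_len(L), drop = FALSE]
  panels <- switch(
    mode,
    "averaged" = list(Reduce(`+`, lapply(stack$maps, tok_part)) /
                        length(stack$maps)),
    "single-head" = {
      if (is.null(layer)) layer <- max(stack$index$layer)
      sel <- which(stack$index$layer == layer & stack$index$head == head)
      if (length(sel) != 1L)
        stop("no collected map for that layer/head combination")
      list(tok_part(stack$maps[[sel]]))
    },
    "all-heads" = lapply(stack$maps, tok_part))
  n_panel <- length(panels)
  mfrow <- if (n_panel == 1L) c(1L, 1L)
           else c(length(unique(stack$index$layer)),
                  length(unique(stack$index$head)))
  px <- max(320L, L * cell_px)
  grDevices::png(path, width = px * mfrow[2L], height = px * mfrow[1L],
                 res = 96L)
  on.exit(grDevices::dev.off())
  shades <- grDevices::gray(seq(1, 0, length.out = 64L))  # dark = high
  graphics::par(mfrow = mfrow, mar = c(4.2, 4.2, 1.8, 0.6))
  for (k in seq_len(n_panel)) {
    A <- panels[[k]]
    # image() draws x right / y up; flip rows so queries read top-down
    graphics::image(seq_len(L), seq_len(L), t(A[L:1, , drop = FALSE]),
                    col = shades, axes = FALSE, xlab = "", ylab = "",
                    zlim = c(0, max(A)))
    graphics::axis(1L, at = seq_len(L), labels = stack$tokens,
                   las = 2L, cex.axis = 0.7)
    graphics::axis(2L, at = seq_len(L), labels = rev(stack$tokens),
                   las = 2L, cex.axis = 0.7)
    if (mode == "all-heads")
      graphics::title(sprintf("layer %d head %d", stack$index$layer[k],
                              stack$index$head[k]), cex.main = 0.9)
    else if (mode == "single-head")
      graphics::title(sprintf("layer %d head %d", layer, head))
  }
  invisible(path)
}
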