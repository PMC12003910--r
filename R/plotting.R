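#' Plot a scalp map of cluster-test statistics
#'
#' Draws the montage layout with electrodes colored by group-difference t
#' value (blue-white-red) and marks electrodes belonging to significant
#' permutation clusters with `+`.
#'
#' @param map A `map_stat` from [permutation_cluster_map()].
#' @param montage The montage used for the test.
#' @param main Plot title.
#' @param mark Which electrodes to mark: `"mask"` (significant at the
#'   cluster level) or `"mark_mask"` (the stricter display threshold).
#' @return Invisibly, the plotted t values.
#' @export
plot_map_stat <- function(map, montage, main = "group difference (t)",
                          mark = c("mask", "mark_mask")) {
  mark <- match.arg(mark)
  ch <- montage$channels[match(names(map$t), montage$channels$label), ]
  tval <- map$t
  lim <- max(abs(tval), 1, na.rm = TRUE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  col <- pal[pmin(101, pmax(1, round((tval + lim) / (2 * lim) * 100) + 1))]
  col[is.na(tval)] <- "grey80"
  graphics::plot(ch$x, ch$y, asp = 1, pch = 21, cex = 3, bg = col,
                 xlab = "", ylab = "", axes = FALSE, main = main,
                 xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3))
  graphics::symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE,
                    fg = "grey40")
  graphics::text(ch$x, ch$y - 0.13, ch$label, cex = 0.6, col = "grey30")
  hits <- map[[mark]]
  if (any(hits)) {
    graphics::points(ch$x[hits], ch$y[hits], pch = 3, cex = 1.6, lwd = 2)
  }
  invisible(tval)
}
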