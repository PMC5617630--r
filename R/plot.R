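#' Plot a tissue graph
#'
#' Draws the cell polygons (or centroid discs for abstract geometries such
#' as rings) colored by a per-cell value, with optional overlays: the
#' boundary annulus mask (hatched outline) and detected peaks (circles).
#'
#' @param x a `tissue_graph`.
#' @param values optional numeric per-cell vector to color by (e.g. auxin).
#' @param mask optional logical per-cell vector; `TRUE` cells get a thick
#'   outline.
#' @param peaks optional `peak_set`; peak cells are marked.
#' @param palette color palette name passed to [grDevices::hcl.colors()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tissue_graph <- function(x, values = NULL, mask = NULL, peaks = NULL,
                              palette = "viridis", ...) {
  cells <- x$cells
  cols <- if (is.null(values)) {
    rep("grey90", nrow(cells))
  } else {
    rng <- range(values)
    u <- if (diff(rng) == 0) rep(0.5, length(values)) else (values - rng[1]) / diff(rng)
    grDevices::hcl.colors(256, palette)[pmax(1L, ceiling(u * 255))]
  }
  graphics::plot(cells$x, cells$y, type = "n", asp = 1,
                 xlab = "x", ylab = "y", ...)
  if (!is.null(x$polygons)) {
    for (k in seq_along(x$polygons)) {
      graphics::polygon(x$polygons[[k]], col = cols[k], border = "grey40", lwd = 0.4)
    }
    if (!is.null(mask)) {
      for (k in which(mask)) {
        graphics::polygon(x$polygons[[k]], border = "red", lwd = 2)
      }
    }
  } else {
    cex <- 2.2
    graphics::points(cells$x, cells$y, pch = 21, bg = cols, col = "grey40", cex = cex)
    if (!is.null(mask)) {
      graphics::points(cells$x[mask], cells$y[mask], pch = 1, col = "red",
                       cex = cex + 0.6, lwd = 2)
    }
  }
  if (!is.null(peaks) && length(peaks$peak_idx)) {
    graphics::points(cells$x[peaks$peak_idx], cells$y[peaks$peak_idx],
                     pch = 21, bg = "white", col = "black", cex = 1.2, lwd = 1.5)
  }
  invisible(x)
}

#' Plot the final auxin field of a trajectory
#'
#' @param x a `tissue_trajectory`.
#' @param what which state variable to show.
#' @param t time point (nearest sample); default final.
#' @param ... passed on to [plot.tissue_graph()].
#' @return the tissue, invisibly.
#' @export
plot.tissue_trajectory <- function(x, what = c("A", "P_tot", "X"), t = NULL, ...) {
  what <- match.arg(what)
  st <- state_at(x, t)
  plot(x$tissue, values = st[[what]], ...)
}
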