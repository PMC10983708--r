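#' Bullseye plot of component loadings
#'
#' Draws the classic bullseye diagram: nine angular sectors (eight lobar
#' divisions plus BGT) crossed with four concentric depth rings (innermost =
#' periventricular), with the anterior/posterior corpus callosum as a split
#' central disc. Parcels are shaded by their pattern loading; by default
#' only loadings above `thr` are filled, mirroring the usual display rule.
#'
#' @param x a `wmh_pca` fit whose parcels follow [parcel_table()] naming.
#' @param components which components to draw (default: all).
#' @param thr display threshold; loadings `<= thr` are left blank. Use
#'   `thr = -Inf` to shade everything.
#' @param ... passed to `par`.
#' @return invisibly, the threshold table used.
#' @export
plot.wmh_pca <- function(x, components = seq_len(x$k), thr = 0.4, ...) {
  tab <- parcel_table()
  if (!all(rownames(x$loadings) %in% tab$name))
    stop("loadings are not named after bullseye parcels; nothing to draw")
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(components)),
                      mar = c(1, 1, 2, 1), ...)
  on.exit(graphics::par(op))
  regions <- region_names()
  pal <- grDevices::colorRampPalette(c("#fff5eb", "#fd8d3c", "#7f2704"))(64)
  shade <- function(l, lmax) pal[pmax(1, ceiling(64 * pmin(l / lmax, 1)))]
  lmax <- max(abs(x$loadings))

  for (cc in components) {
    L <- x$loadings[, cc]
    graphics::plot.new()
    graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
    graphics::title(sprintf("%s (%.0f%% var)", colnames(x$loadings)[cc],
                            100 * x$variance_explained[cc]))
    r0 <- 0.25                       # CC disc radius
    rr <- r0 + (1 - r0) * (0:4) / 4  # ring boundaries
    for (s in seq_along(regions)) {
      a0 <- 2 * pi * (s - 1) / 9; a1 <- 2 * pi * s / 9
      aa <- seq(a0, a1, length.out = 20)
      for (ly in 1:4) {
        nm <- paste0(regions[s], "_", ly)
        l <- L[nm]
        col <- if (!is.na(l) && l > thr) shade(l, lmax) else "white"
        xs <- c(rr[ly] * cos(aa), rev(rr[ly + 1] * cos(aa)))
        ys <- c(rr[ly] * sin(aa), rev(rr[ly + 1] * sin(aa)))
        graphics::polygon(xs, ys, col = col, border = "grey40")
      }
      rmid <- 1.08
      graphics::text(rmid * cos((a0 + a1) / 2), rmid * sin((a0 + a1) / 2),
                     regions[s], cex = 0.6)
    }
    # corpus callosum: anterior = upper half disc, posterior = lower half
    for (half in c("CC_anterior", "CC_posterior")) {
      aa <- if (half == "CC_anterior") seq(0, pi, length.out = 40)
            else seq(pi, 2 * pi, length.out = 40)
      l <- L[half]
      col <- if (!is.na(l) && l > thr) shade(l, lmax) else "white"
      graphics::polygon(c(r0 * cos(aa), 0), c(r0 * sin(aa), 0),
                        col = col, border = "grey40")
    }
  }
  invisible(threshold_loadings(x, thr))
}
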