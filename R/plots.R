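#' Plot a distance profile
#'
#' Query density (per 1000 anchors) against the signed offset, with the
#' matched-background profile overlaid when present.
#'
#' @param x a `distance_profile`
#' @param ... passed to [plot()]
#' @export
plot.distance_profile <- function(x, ...) {
  plot(x$offset, x$per_1000, type = "l", xlab = "offset (nt, 5' negative)",
       ylab = "sites per 1000 anchors", ...)
  if (!is.null(x$bg_per_1000))
    graphics::lines(x$offset, x$bg_per_1000, col = "grey60", lty = 2)
  graphics::abline(v = 0, col = "grey80")
  invisible(x)
}

#' Plot a scaled metagene profile
#' @param x a `metagene_profile`
#' @param ... passed to [plot()]
#' @export
plot.metagene_profile <- function(x, ...) {
  h <- x$histogram
  off <- c(utr5 = 0, cds = 1, utr3 = 2)
  plot(off[h$feature] + h$bin_mid, h$density, type = "h",
       xlab = "scaled position (5'UTR | CDS | 3'UTR)",
       ylab = "site density", xaxt = "n", ...)
  graphics::axis(1, at = c(0.5, 1.5, 2.5), labels = c("5'UTR", "CDS", "3'UTR"))
  graphics::abline(v = c(1, 2), col = "grey70")
  invisible(x)
}
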