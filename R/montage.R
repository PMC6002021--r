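#' Standard 64-channel 10/20-system montage
#'
#' A 2-D scalp projection (head radius 1, nose up) of a standard 64-label
#' extended 10/20 layout, built from the usual anterior-posterior rows.
#' Coordinates are schematic projections intended for channel-pair maps and
#' CSV export, not for source modeling.
#'
#' @return data.frame with columns label, x, y (64 rows).
#' @export
standardMontage <- function() {
  rows <- list(
    list(y = 0.90, labels = c("Fp1", "Fpz", "Fp2")),
    list(y = 0.72, labels = c("AF7", "AF3", "AFz", "AF4", "AF8")),
    list(y = 0.50, labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4",
                              "F6", "F8")),
    list(y = 0.26, labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2",
                              "FC4", "FC6", "FT8")),
    list(y = 0.00, labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4",
                              "C6", "T8")),
    list(y = -0.26, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2",
                               "CP4", "CP6", "TP8")),
    list(y = -0.50, labels = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2",
                               "P4", "P6", "P8", "P10")),
    list(y = -0.72, labels = c("PO7", "PO3", "POz", "PO4", "PO8")),
    list(y = -0.90, labels = c("O1", "Oz", "O2")),
    list(y = -1.00, labels = c("Iz")))
  out <- do.call(rbind, lapply(rows, function(r) {
    n <- length(r$labels)
    halfwidth <- sqrt(max(1.1 - r$y^2, 0.02))
    x <- if (n == 1) 0 else seq(-halfwidth, halfwidth, length.out = n)
    data.frame(label = r$labels, x = x, y = r$y,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Map top channel pairs onto scalp coordinates
#'
#' Joins a report's top channel pairs for one rating scale with a montage's
#' 2-D coordinates, producing an edge list ready for plotting or CSV export.
#'
#' @param report a [ContributionReport-class].
#' @param montage data.frame with columns label, x, y covering every label
#'   in the report (default [standardMontage()]).
#' @param scale rating scale to map (default: first in the report).
#' @return a [TopoSummary-class]; edges are ordered by decreasing magnitude
#'   and limited to the report's pair count.
#' @export
pairMap <- function(report, montage = standardMontage(),
                    scale = names(report@topPairs)[1]) {
  stopifnot(is(report, "ContributionReport"))
  tp <- report@topPairs[[scale]]
  if (is.null(tp)) stop("scale '", scale, "' not present in the report")
  labs <- unique(c(tp$channel1, tp$channel2))
  missing <- setdiff(labs, montage$label)
  if (length(missing))
    stop("montage error: no coordinates for label(s) ",
         paste(missing, collapse = ", "))
  i1 <- match(tp$channel1, montage$label)
  i2 <- match(tp$channel2, montage$label)
  edges <- data.frame(tp,
                      x1 = montage$x[i1], y1 = montage$y[i1],
                      x2 = montage$x[i2], y2 = montage$y[i2])
  edges <- edges[order(-edges$magnitude), , drop = FALSE]
  rownames(edges) <- NULL
  new("TopoSummary",
      coordinates = montage[montage$label %in% labs, , drop = FALSE],
      edges = edges, scale = scale)
}

#' Plot a channel-pair contribution map
#'
#' Draws the head outline, the montage positions and the top channel pairs
#' as edges with width proportional to contribution magnitude. Base
#' graphics; CSV output from [pairMap()] does not require plotting.
#'
#' @param topo a [TopoSummary-class].
#' @param montage full montage for context (default [standardMontage()]).
#' @param main plot title.
#' @return invisibly, the edge table.
#' @export
plotPairMap <- function(topo, montage = standardMontage(),
                        main = paste("Top channel pairs:", topo@scale)) {
  stopifnot(is(topo, "TopoSummary"))
  op <- graphics::par(mar = c(1, 1, 3, 1)); on.exit(graphics::par(op))
  plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1, axes = FALSE,
       xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(1.15 * cos(th), 1.15 * sin(th))
  graphics::lines(c(-0.1, 0, 0.1), c(1.14, 1.25, 1.14))  # nose
  e <- topo@edges
  if (nrow(e)) {
    w <- 0.5 + 3 * e$magnitude / max(e$magnitude)
    graphics::segments(e$x1, e$y1, e$x2, e$y2, lwd = w, col = "#00000080")
  }
  graphics::points(montage$x, montage$y, pch = 19, cex = 0.4,
                   col = "grey50")
  graphics::text(topo@coordinates$x, topo@coordinates$y,
                 topo@coordinates$label, cex = 0.7, pos = 3, offset = 0.2)
  invisible(e)
}
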