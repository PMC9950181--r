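#' Persistence curve of one homology dimension
#'
#' The finite intervals of the given dimension are expanded by multiplicity,
#' sorted by length `death - (birth - 1)` (ties broken by birth, then
#' deterministically), and indexed `j = 1..N`; the curve is the linear
#' interpolation of the points `(length_j, j)`.  Unlike a persistence diagram
#' the curve retains how many intervals of each persistence occur.
#' Infinite-death intervals are excluded: the length formula is undefined at
#' infinity, and in dimensions 1 and 2 of the networks this representation
#' targets all deaths are finite.
#'
#' @param intervals a `persistence_intervals` object.
#' @param dim homology dimension.
#' @return an object of class `persistence_curve` with a `points` data frame
#'   (`length`, `rank`).
#' @examples
#' ph <- network_persistence(hexagon_network())
#' persistence_curve(ph, 1)  # single point (2, 1)
#' @export
persistence_curve <- function(intervals, dim) {
  fin <- expand_intervals(intervals, dim = dim, finite_only = TRUE)
  len <- fin$death - (fin$birth - 1)
  ord <- order(len, fin$birth, method = "radix")
  structure(
    list(dim = as.integer(dim),
         points = data.frame(length = len[ord],
                             rank = seq_along(ord)),
         birth = fin$birth[ord], death = fin$death[ord]),
    class = "persistence_curve")
}

#' Barcode of one homology dimension
#'
#' One bar `[birth, death)` per finite interval occurrence, stacked in the
#' same order as the persistence curve (shortest first).
#'
#' @param intervals a `persistence_intervals` object.
#' @param dim homology dimension.
#' @return an object of class `persistence_barcode` with a `bars` data frame
#'   (`birth`, `death`, `rank`).
#' @export
barcode <- function(intervals, dim) {
  pc <- persistence_curve(intervals, dim)
  structure(
    list(dim = pc$dim,
         bars = data.frame(birth = pc$birth, death = pc$death,
                           rank = pc$points$rank)),
    class = "persistence_barcode")
}

#' Summary statistics of a persistence curve
#'
#' `max_length` is the final point's length, `count` the number of points and
#' `mean_slope` is `count / (max_length - min_length)` when that range is
#' positive and `Inf` otherwise.  A low mean slope corresponds to the flat,
#' horizontal curve profile characteristic of genealogical networks; a high
#' one to the vertical profile of other social networks.  The slope summary
#' is a statistic defined by this package, not a published formula.
#'
#' @param curve a `persistence_curve`.
#' @return a list with `max_length`, `count`, `mean_slope`.
#' @export
curve_summary <- function(curve) {
  stopifnot(inherits(curve, "persistence_curve"))
  pts <- curve$points
  if (nrow(pts) == 0L) stop("curve is empty")
  rng <- max(pts$length) - min(pts$length)
  list(max_length = max(pts$length),
       count = nrow(pts),
       mean_slope = if (rng > 0) nrow(pts) / rng else Inf)
}

#' @export
print.persistence_curve <- function(x, ...) {
  cat("Persistence curve, dimension ", x$dim, ": ", nrow(x$points),
      " point(s)", sep = "")
  if (nrow(x$points)) {
    cat(", lengths ", min(x$points$length), "..", max(x$points$length),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Plot persistence curves
#'
#' @param x a `persistence_curve`.
#' @param add overlay on the current plot (shared axes, as when comparing
#'   several networks).
#' @param col line colour.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.persistence_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  pts <- x$points
  if (nrow(pts) == 0L) {
    if (!add) plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "interval length", ylab = "rank", ...)
    return(invisible(x))
  }
  if (add) {
    lines(pts$length, pts$rank, col = col)
  } else {
    plot(pts$length, pts$rank, type = "l", col = col,
         xlab = "interval length", ylab = "rank", ...)
  }
  points(pts$length, pts$rank, pch = 16, cex = 0.4, col = col)
  invisible(x)
}

#' Plot a barcode
#'
#' @param x a `persistence_barcode`.
#' @param col bar colour.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.persistence_barcode <- function(x, col = "steelblue", ...) {
  b <- x$bars
  if (nrow(b) == 0L) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "threshold",
         ylab = "bar", ...)
    return(invisible(x))
  }
  plot(NA, xlim = c(min(b$birth), max(b$death)),
       ylim = c(0, nrow(b) + 1), xlab = "threshold", ylab = "bar", ...)
  segments(b$birth, b$rank, b$death, b$rank, col = col, lwd = 2)
  invisible(x)
}

#' Write a persistence curve as CSV
#'
#' @param curve a `persistence_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(curve$points, path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
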