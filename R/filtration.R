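#' Clique (flag) filtration of a network from its distance matrix
#'
#' For each integer threshold `delta`, the complex `G_delta` contains a
#' simplex for every vertex set whose pairwise geodesic distances are all at
#' most `delta`; the appearance value of a simplex is therefore the maximum
#' pairwise distance among its vertices.  Vertices appear at value 0, the
#' original edges at value 1, and the slices stabilise at the largest finite
#' distance `M` (the diameter for a connected network).  Vertices in different
#' components never co-occur in a simplex: unreachable distances are not
#' thresholded.
#'
#' Simplices are built up to dimension `max_simplex_dim` (at most 3, the
#' minimum needed for dimension-2 deaths; this cap is why persistence is
#' reported only to dimension 2).  When `t_max` is smaller than `M`, simplices
#' above the cap are not built and deaths beyond it are later reported as
#' censored at `t_max`.
#'
#' @param dm a distance matrix from [geodesic_distance_matrix()].
#' @param max_simplex_dim highest simplex dimension to build, 1-3.
#' @param t_max positive integer threshold cap, or `"diameter"` (the default)
#'   for the largest finite distance.
#' @return an object of class `flag_filtration` with the simplices per
#'   dimension, their appearance values, and the cap actually used.
#' @examples
#' fc <- build_clique_filtration(geodesic_distance_matrix(hexagon_network()))
#' simplex_counts_at(fc, 2)  # 6 vertices, 12 edges, 8 triangles
#' @export
build_clique_filtration <- function(dm, max_simplex_dim = 3L,
                                    t_max = "diameter") {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("dm must be a square distance matrix")
  }
  n <- nrow(dm)
  if (n == 0L) stop("distance matrix is empty")
  max_simplex_dim <- as.integer(max_simplex_dim)
  if (max_simplex_dim < 1L || max_simplex_dim > 3L) {
    stop("max_simplex_dim must be between 1 and 3")
  }
  M <- max_finite_distance(dm)
  if (identical(t_max, "diameter")) {
    cap <- as.integer(M)
  } else {
    cap <- as.integer(t_max)
    if (is.na(cap) || cap < 1L) stop("t_max must be a positive integer")
    cap <- min(cap, as.integer(M))
    cap <- max(cap, 1L)
  }
  dmi <- dm
  dmi[!is.finite(dmi)] <- -1
  storage.mode(dmi) <- "integer"
  raw <- flag_simplices_cpp(dmi, cap, max_simplex_dim)
  vnames <- rownames(dm)
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  simp <- list(
    list(verts = matrix(seq_len(n), ncol = 1L),
         value = rep(0L, n)),
    list(verts = raw$edge_v, value = as.integer(raw$edge_val)))
  if (max_simplex_dim >= 2L) {
    simp[[3L]] <- list(verts = raw$tri_v, value = as.integer(raw$tri_val))
  }
  if (max_simplex_dim >= 3L) {
    simp[[4L]] <- list(verts = raw$tet_v, value = as.integer(raw$tet_val))
  }
  structure(
    list(vertices = vnames, n = n, max_dim = max_simplex_dim,
         t_max = cap, diameter = as.integer(M), capped = cap < M,
         simplices = simp),
    class = "flag_filtration")
}

#' Simplex counts of a filtration slice
#'
#' Number of simplices per dimension present at threshold `delta`, i.e. with
#' appearance value at most `delta`.
#'
#' @param fc a `flag_filtration`.
#' @param delta integer threshold, `0 <= delta <= t_max`.
#' @return a named integer vector `dim0`, `dim1`, ...
#' @export
simplex_counts_at <- function(fc, delta) {
  stopifnot(inherits(fc, "flag_filtration"))
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 0L || delta > fc$t_max) {
    stop("delta must lie between 0 and the filtration cap (", fc$t_max, ")")
  }
  counts <- vapply(fc$simplices, function(s) sum(s$value <= delta), integer(1))
  names(counts) <- paste0("dim", seq_along(counts) - 1L)
  counts
}

#' @export
print.flag_filtration <- function(x, ...) {
  counts <- vapply(x$simplices, function(s) length(s$value), integer(1))
  cat("Clique filtration on", x$n, "vertices\n")
  cat("  simplices per dimension:",
      paste(sprintf("dim%d: %d", seq_along(counts) - 1L, counts),
            collapse = ", "), "\n")
  cat("  threshold cap t_max =", x$t_max,
      if (x$capped) paste0("(capped below the diameter ", x$diameter, ")")
      else "(= largest finite distance)", "\n")
  invisible(x)
}

#' Write a filtration as lower-star-style text
#'
#' One simplex per line, `value dim v0 v1 ...` with 0-based vertex indices,
#' in filtration order, for cross-checking against external persistence
#' engines.
#'
#' @param fc a `flag_filtration`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filtration_text <- function(fc, path) {
  stopifnot(inherits(fc, "flag_filtration"))
  ord <- filtration_order(fc)
  lines <- vapply(seq_len(nrow(ord$verts)), function(i) {
    vs <- ord$verts[i, seq_len(ord$dims[i] + 1L)] - 1L
    paste(c(ord$vals[i], ord$dims[i], vs), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Assemble all simplices into global filtration order:
# (appearance value, dimension, lexicographic vertex tuple).
filtration_order <- function(fc) {
  pieces_v <- list()
  pieces_d <- list()
  pieces_val <- list()
  for (d in seq_along(fc$simplices)) {
    s <- fc$simplices[[d]]
    k <- if (is.matrix(s$verts)) nrow(s$verts) else 0L
    if (k == 0L) next
    vm <- matrix(0L, nrow = k, ncol = 4L)
    vm[, seq_len(d)] <- s$verts
    pieces_v[[length(pieces_v) + 1L]] <- vm
    pieces_d[[length(pieces_d) + 1L]] <- rep(d - 1L, k)
    pieces_val[[length(pieces_val) + 1L]] <- s$value
  }
  verts <- do.call(rbind, pieces_v)
  dims <- unlist(pieces_d)
  vals <- unlist(pieces_val)
  o <- order(vals, dims, verts[, 1L], verts[, 2L], verts[, 3L], verts[, 4L],
             method = "radix")
  list(verts = verts[o, , drop = FALSE], dims = dims[o], vals = vals[o])
}
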