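#' Persistence diagram of one homology dimension
#'
#' A multiset of finite (birth, death) points with the diagonal implicit.
#' Essential (infinite-death) classes are stored as a count, not as points:
#' the bottleneck bijection maps only finite intervals to the diagonal, and
#' counts of essential classes are compared separately.
#'
#' @param intervals a `persistence_intervals` object (or compatible data
#'   frame).
#' @param dim homology dimension of the diagram.
#' @return an object of class `persistence_diagram` with elements `dim`,
#'   `points` (two-column matrix, one row per occurrence) and `essential`
#'   (count of infinite-death classes).
#' @export
persistence_diagram <- function(intervals, dim) {
  ess <- sum(intervals$multiplicity[intervals$dim == dim &
                                      is.infinite(intervals$death)])
  fin <- expand_intervals(intervals, dim = dim, finite_only = TRUE)
  pts <- cbind(birth = fin$birth, death = fin$death)
  if (nrow(pts) && any(pts[, 2L] <= pts[, 1L])) {
    stop("diagram points must satisfy death > birth")
  }
  structure(list(dim = as.integer(dim), points = pts,
                 essential = as.integer(ess)),
            class = "persistence_diagram")
}

#' Diagrams for several dimensions at once
#'
#' @param intervals a `persistence_intervals` object.
#' @param dims homology dimensions to extract.
#' @return a named list of `persistence_diagram` objects, keyed `"0"`, `"1"`,
#'   ...
#' @export
diagram_set <- function(intervals, dims = 0:2) {
  out <- lapply(dims, function(p) persistence_diagram(intervals, p))
  names(out) <- as.character(dims)
  out
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat("Persistence diagram, dimension ", x$dim, ": ",
      nrow(x$points), " finite point(s), ",
      x$essential, " essential class(es)\n", sep = "")
  invisible(x)
}

# L-infinity cost matrix between two point sets (m1 x m2).
linf_cost <- function(A, B) {
  if (nrow(A) == 0L || nrow(B) == 0L) {
    return(matrix(numeric(0), nrow(A), nrow(B)))
  }
  db <- abs(outer(A[, 1L], B[, 1L], "-"))
  dd <- abs(outer(A[, 2L], B[, 2L], "-"))
  pmax(db, dd)
}

# Perfect matching feasibility at threshold t in the augmented bipartite
# graph: left = A-points + B-ghosts, right = B-points + A-ghosts.  A point
# may match a point of the other diagram within cost t or its own diagonal
# projection within t; ghosts match each other at zero cost.  Kuhn's
# augmenting-path algorithm; returns NULL when infeasible, else for each left
# node the matched right node.
bottleneck_matching_at <- function(t, C, dA, dB) {
  m1 <- length(dA); m2 <- length(dB)
  nL <- m1 + m2; nR <- m2 + m1
  adj <- vector("list", nL)
  eps <- 1e-9 * max(1, t)
  for (i in seq_len(m1)) {
    js <- if (m2) which(C[i, ] <= t + eps) else integer(0)
    if (dA[i] <= t + eps) js <- c(js, m2 + i)
    adj[[i]] <- js
  }
  ghosts <- if (m1) m2 + seq_len(m1) else integer(0)
  for (j in seq_len(m2)) {
    js <- ghosts
    if (dB[j] <= t + eps) js <- c(j, js)
    adj[[m1 + j]] <- js
  }
  match_r <- integer(nR)            # right -> left (0 = free)
  visited <- logical(nR)
  try_augment <- function(u) {
    for (v in adj[[u]]) {
      if (visited[v]) next
      visited[v] <<- TRUE
      if (match_r[v] == 0L || try_augment(match_r[v])) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  for (u in seq_len(nL)) {
    visited <- logical(nR)
    if (!try_augment(u)) return(NULL)
  }
  match_l <- integer(nL)
  for (r in seq_len(nR)) if (match_r[r] > 0L) match_l[match_r[r]] <- r
  match_l
}

#' Bottleneck distance between two persistence diagrams
#'
#' Exact optimum over matchings that send each finite point either to a
#' finite point of the other diagram (L-infinity cost) or to its diagonal
#' projection (cost `(death - birth) / 2`).  Computed by binary search over
#' the finite candidate set of pairwise costs, testing feasibility with a
#' maximum bipartite matching at each threshold.  Essential classes are
#' excluded from the matching and compared by count only (reported in the
#' result).
#'
#' @param a,b `persistence_diagram` objects of the same dimension.
#' @return an object of class `bottleneck_result` with elements `value`,
#'   `matching` (data frame with one row per matched pair, diagonal matches
#'   flagged) and `essential_diff` (difference in essential counts).
#' @export
bottleneck_distance <- function(a, b) {
  stopifnot(inherits(a, "persistence_diagram"),
            inherits(b, "persistence_diagram"))
  if (a$dim != b$dim) {
    stop("diagrams have different homology dimensions (", a$dim, " vs ",
         b$dim, ")")
  }
  A <- a$points; B <- b$points
  m1 <- nrow(A); m2 <- nrow(B)
  dA <- if (m1) (A[, 2L] - A[, 1L]) / 2 else numeric(0)
  dB <- if (m2) (B[, 2L] - B[, 1L]) / 2 else numeric(0)
  C <- linf_cost(A, B)
  if (m1 + m2 == 0L) {
    return(structure(list(value = 0,
                          matching = empty_matching(),
                          essential_diff = a$essential - b$essential),
                     class = "bottleneck_result"))
  }
  cand <- sort(unique(c(0, dA, dB, as.vector(C))))
  lo <- 1L; hi <- length(cand); best <- NULL
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    m <- bottleneck_matching_at(cand[mid], C, dA, dB)
    if (!is.null(m)) {
      best <- list(t = cand[mid], m = m)
      hi <- mid - 1L
    } else {
      lo <- mid + 1L
    }
  }
  stopifnot(!is.null(best))   # always feasible at the largest candidate
  matching <- matching_table(best$m, m1, m2, C, dA, dB)
  structure(list(value = best$t, matching = matching,
                 essential_diff = a$essential - b$essential),
            class = "bottleneck_result")
}

empty_matching <- function() {
  data.frame(a = integer(0), b = integer(0), diagonal = logical(0),
             cost = numeric(0))
}

matching_table <- function(match_l, m1, m2, C, dA, dB) {
  rows <- list()
  for (i in seq_len(m1)) {
    r <- match_l[i]
    if (r <= m2) {
      rows[[length(rows) + 1L]] <-
        data.frame(a = i, b = r, diagonal = FALSE, cost = C[i, r])
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(a = i, b = NA_integer_, diagonal = TRUE, cost = dA[i])
    }
  }
  for (j in seq_len(m2)) {
    r <- match_l[m1 + j]
    if (r == j) {
      rows[[length(rows) + 1L]] <-
        data.frame(a = NA_integer_, b = j, diagonal = TRUE, cost = dB[j])
    }
    # ghost-to-ghost matches carry no cost and are omitted
  }
  if (!length(rows)) return(empty_matching())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.bottleneck_result <- function(x, ...) {
  cat("Bottleneck distance:", format(x$value), "\n")
  if (x$essential_diff != 0L) {
    cat("  (essential-class counts differ by", x$essential_diff,
        "- compared separately, not matched)\n")
  }
  invisible(x)
}

#' Brute-force bottleneck distance (test oracle)
#'
#' Exhaustive minimum over all point-to-point/diagonal matchings; refuses
#' instances with more than 8 off-diagonal points in total.  Independent of
#' the matching-based engine and used to validate it.
#'
#' @param a,b `persistence_diagram` objects (or two-column matrices of finite
#'   points).
#' @return the bottleneck value as a number.
#' @export
brute_force_bottleneck <- function(a, b) {
  A <- if (inherits(a, "persistence_diagram")) a$points else as.matrix(a)
  B <- if (inherits(b, "persistence_diagram")) b$points else as.matrix(b)
  m1 <- nrow(A); m2 <- nrow(B)
  if (m1 + m2 > 8L) {
    stop("brute_force_bottleneck refuses instances with more than 8 points")
  }
  if (m1 + m2 == 0L) return(0)
  dA <- if (m1) (A[, 2L] - A[, 1L]) / 2 else numeric(0)
  dB <- if (m2) (B[, 2L] - B[, 1L]) / 2 else numeric(0)
  C <- linf_cost(A, B)
  best <- Inf
  used <- logical(m2)
  rec <- function(i, curmax) {
    if (curmax >= best) return(invisible(NULL))
    if (i > m1) {
      tot <- curmax
      if (any(!used)) tot <- max(tot, dB[!used])
      if (tot < best) best <<- tot
      return(invisible(NULL))
    }
    rec(i + 1L, max(curmax, dA[i]))          # diagonal
    for (j in seq_len(m2)) {
      if (!used[j]) {
        used[j] <<- TRUE
        rec(i + 1L, max(curmax, C[i, j]))
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  best
}

#' Network-level bottleneck distance
#'
#' Maximum over homology dimensions 1 and 2 of the per-dimension bottleneck
#' value between finite points.  Dimension 0 is excluded: for simple graphs
#' its diagram is determined by the vertex and component counts alone.
#'
#' @param a,b named lists of `persistence_diagram` objects as returned by
#'   [diagram_set()]; both must carry dimensions 1 and 2.
#' @return a non-negative number.
#' @export
network_bottleneck_distance <- function(a, b) {
  for (d in c("1", "2")) {
    if (is.null(a[[d]]) || is.null(b[[d]])) {
      stop("both diagram sets must carry homology dimensions 1 and 2")
    }
  }
  max(bottleneck_distance(a[["1"]], b[["1"]])$value,
      bottleneck_distance(a[["2"]], b[["2"]])$value)
}

#' Pairwise network bottleneck distance matrix
#'
#' @param diagram_sets a list (length at least 2) of diagram sets from
#'   [diagram_set()].
#' @param labels optional names for the rows/columns.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(diagram_sets, labels = NULL) {
  n <- length(diagram_sets)
  if (n < 2L) stop("need at least two diagram sets")
  if (is.null(labels)) {
    labels <- names(diagram_sets)
    if (is.null(labels)) labels <- paste0("net", seq_len(n))
  }
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      D[i, j] <- D[j, i] <-
        network_bottleneck_distance(diagram_sets[[i]], diagram_sets[[j]])
    }
  }
  D
}

#' 2-D PCA embedding of a pairwise distance matrix
#'
#' Rows of the distance matrix are mean-centred and projected onto the two
#' principal axes with the most variance.  Axis signs are fixed by making
#' each axis's largest-magnitude loading positive, so the embedding is
#' deterministic.
#'
#' @param dist a square symmetric matrix, e.g. from
#'   [pairwise_distance_matrix()].
#' @return a data frame with columns `id`, `pc1`, `pc2`.
#' @export
pca_embed <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist)) {
    stop("dist must be a square matrix")
  }
  if (nrow(dist) < 2L) stop("need at least two inputs to embed")
  if (max(abs(dist - t(dist))) > 1e-8) stop("dist must be symmetric")
  p <- stats::prcomp(dist, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (ax in seq_len(k)) {
    load <- p$rotation[, ax]
    if (load[which.max(abs(load))] < 0) scores[, ax] <- -scores[, ax]
  }
  if (k < 2L) scores <- cbind(scores, 0)
  ids <- rownames(dist)
  if (is.null(ids)) ids <- paste0("net", seq_len(nrow(dist)))
  data.frame(id = ids, pc1 = scores[, 1L], pc2 = scores[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}
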