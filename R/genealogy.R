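#' Distance to union for every couple in a genealogical network
#'
#' For each union edge \{i, j\}, the geodesic distance between the partners
#' in the pre-union state of the network: the union edge itself and both
#' partners' parent-child edges to their common children are removed before
#' measuring ("before they form a union" the children do not yet exist;
#' without removing them any couple with a child would trivially sit at
#' distance 2).  Couples left in different components count as infinite.
#'
#' @param net a labelled \code{igraph} graph (edge attribute `relation`).
#' @return an object of class `union_distance_summary` with `finite`
#'   (integer multiset of distances) and `infinite` (count).
#' @export
distance_to_union <- function(net) {
  rel <- edge_labels(net)
  if (is.null(rel)) {
    stop("distance_to_union requires a labelled network ",
         "(edge attribute 'relation')")
  }
  uids <- which(rel == "union")
  if (length(uids) == 0L) stop("network has no union edges")
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  # parent-child adjacency: for each vertex, its pc neighbours
  pc <- which(rel == "parent_child")
  nV <- igraph::vcount(net)
  pc_nb <- vector("list", nV)
  for (e in pc) {
    a <- ends[e, 1L]; b <- ends[e, 2L]
    pc_nb[[a]] <- c(pc_nb[[a]], b)
    pc_nb[[b]] <- c(pc_nb[[b]], a)
  }
  finite <- integer(0)
  infinite <- 0L
  for (e in uids) {
    i <- ends[e, 1L]; j <- ends[e, 2L]
    kids <- intersect(pc_nb[[i]], pc_nb[[j]])
    drop <- e
    if (length(kids)) {
      pairs <- rbind(cbind(i, kids), cbind(j, kids))
      ids <- igraph::get_edge_ids(net, as.vector(t(pairs)))
      drop <- c(drop, ids[ids > 0L])
    }
    g2 <- igraph::delete_edges(net, unique(drop))
    d <- igraph::distances(g2, v = i, to = j, algorithm = "unweighted")[1L, 1L]
    if (is.finite(d)) finite <- c(finite, as.integer(d)) else {
      infinite <- infinite + 1L
    }
  }
  structure(list(finite = finite, infinite = infinite),
            class = "union_distance_summary")
}

#' @export
print.union_distance_summary <- function(x, ...) {
  cat("Distance to union for", length(x$finite) + x$infinite, "couple(s):",
      length(x$finite), "finite,", x$infinite, "infinite\n")
  if (length(x$finite)) {
    tab <- table(x$finite)
    cat("  finite distances:",
        paste(sprintf("%s x %d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Deterministic BFS parents from root over an adjacency list
# (neighbours visited in index order).  Returns parent index or NA.
bfs_parents <- function(adj, root, n) {
  par <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  par[root] <- 0L
  dist[root] <- 0L
  queue <- root
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        par[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(parent = par, dist = dist)
}

walk_to_root <- function(par, v) {
  path <- v
  while (par[v] > 0L) {
    v <- par[v]
    path <- c(path, v)
  }
  path
}

canonical_cycle_key <- function(cyc) {
  k <- length(cyc)
  rots <- vapply(seq_len(k), function(s) {
    paste(cyc[c(s:k, seq_len(s - 1L))], collapse = ",")
  }, character(1))
  rcyc <- rev(cyc)
  rots2 <- vapply(seq_len(k), function(s) {
    paste(rcyc[c(s:k, seq_len(s - 1L))], collapse = ",")
  }, character(1))
  min(c(rots, rots2))
}

#' Cycle basis of a network
#'
#' With `method = "minimum"` (the default), a minimum-weight cycle basis
#' under unit edge weights via Horton's candidate set: for every vertex `v`
#' and edge \{x, y\}, the candidate cycle is the closed walk formed by
#' shortest paths from `v` to `x` and `y` plus the edge, kept when it is a
#' simple cycle; candidates are scanned in order of increasing length and
#' greedily added when independent over GF(2).  A minimum basis makes the
#' cycle-length histogram well defined and reproducible.  For graphs too
#' large for the exact method a fundamental basis (BFS tree plus one cycle
#' per non-tree edge) is available; output flags which method was used.
#'
#' @param net a simple \code{igraph} graph.
#' @param method `"minimum"` or `"fundamental"`.
#' @return an object of class `cycle_basis`: a list with `cycles` (each a
#'   character vector of vertex names, first vertex not repeated) and
#'   `method`.  The basis size is `m - n + k` (edges - vertices +
#'   components).
#' @export
cycle_basis <- function(net, method = c("minimum", "fundamental")) {
  assert_simple(net)
  method <- match.arg(method)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  k <- igraph::components(net)$no
  dim_cycle_space <- m - n + k
  vnames <- igraph::V(net)$name
  if (dim_cycle_space == 0L) {
    return(structure(list(cycles = list(), method = method),
                     class = "cycle_basis"))
  }
  ends <- igraph::ends(net, igraph::E(net), names = FALSE)
  adj <- lapply(igraph::adjacent_vertices(net, igraph::V(net)),
                function(v) sort(as.integer(v)))
  cycles_idx <- if (method == "minimum") {
    horton_mcb(adj, ends, n, m, dim_cycle_space, net)
  } else {
    fundamental_basis(adj, ends, n)
  }
  structure(list(cycles = lapply(cycles_idx, function(ix) vnames[ix]),
                 method = method),
            class = "cycle_basis")
}

horton_mcb <- function(adj, ends, n, m, target, net) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  cand <- list()
  lens <- integer(0)
  for (v in seq_len(n)) {
    bp <- bfs_parents(adj, v, n)
    for (e in seq_len(m)) {
      x <- ends[e, 1L]; y <- ends[e, 2L]
      if (is.na(bp$dist[x]) || is.na(bp$dist[y])) next
      px <- walk_to_root(bp$parent, x)       # x ... v
      py <- walk_to_root(bp$parent, y)       # y ... v
      # simple cycle iff the two tree paths share only v
      if (length(intersect(px, py)) != 1L) next
      cyc <- c(rev(px), py[-length(py)])     # v ... x, y ... (v excluded)
      if (length(cyc) < 3L) next
      key <- canonical_cycle_key(cyc)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      cand[[length(cand) + 1L]] <- cyc
      lens <- c(lens, length(cyc))
    }
  }
  ord <- order(lens, vapply(cand, paste, character(1), collapse = ","),
               method = "radix")
  basis_cycles <- list()
  pivots <- integer(0)               # pivot edge id of each reduced vector
  reduced <- list()                  # reduced GF(2) edge vectors
  for (ci in ord) {
    cyc <- cand[[ci]]
    eid <- cycle_edge_ids(cyc, net)
    vec <- sort(eid)
    repeat {
      if (length(vec) == 0L) break
      hit <- match(vec[1L], pivots)
      if (is.na(hit)) break
      vec <- sort(setdiff(union(vec, reduced[[hit]]),
                          intersect(vec, reduced[[hit]])))
    }
    if (length(vec)) {
      basis_cycles[[length(basis_cycles) + 1L]] <- cyc
      pivots <- c(pivots, vec[1L])
      reduced[[length(reduced) + 1L]] <- vec
      if (length(basis_cycles) == target) break
    }
  }
  if (length(basis_cycles) != target) {
    stop("internal error: cycle basis incomplete (",
         length(basis_cycles), " of ", target, ")")
  }
  basis_cycles
}

fundamental_basis <- function(adj, ends, n) {
  # BFS forest; one cycle per non-tree edge through the nearest common
  # ancestor of its endpoints
  par <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  roots <- integer(0)
  for (v in seq_len(n)) {
    if (!is.na(dist[v])) next
    bp <- bfs_parents(adj, v, n)
    fill <- is.na(dist) & !is.na(bp$dist)
    par[fill] <- bp$parent[fill]
    dist[fill] <- bp$dist[fill]
    roots <- c(roots, v)
  }
  tree_edge <- function(a, b) {
    (!is.na(par[a]) && par[a] == b) || (!is.na(par[b]) && par[b] == a)
  }
  cycles <- list()
  for (e in seq_len(nrow(ends))) {
    x <- ends[e, 1L]; y <- ends[e, 2L]
    if (tree_edge(x, y)) next
    px <- walk_to_root(par, x)
    py <- walk_to_root(par, y)
    common <- intersect(px, py)
    anc <- common[which.min(match(common, px))]
    sx <- px[seq_len(match(anc, px))]        # x .. anc
    sy <- py[seq_len(match(anc, py))]        # y .. anc
    cyc <- c(rev(sx), sy[-length(sy)])       # anc .. x, y .. (anc excluded)
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

cycle_edge_ids <- function(cyc, net) {
  k <- length(cyc)
  if (is.character(cyc) && !all(cyc %in% igraph::V(net)$name)) {
    stop("cycle uses an edge absent from the network")
  }
  pairs <- rbind(cyc, cyc[c(2:k, 1L)])
  ids <- igraph::get_edge_ids(net, as.vector(pairs))
  if (any(ids == 0L)) stop("cycle uses an edge absent from the network")
  as.integer(ids)
}

#' @export
print.cycle_basis <- function(x, ...) {
  cat("Cycle basis (", x$method, " method): ", length(x$cycles),
      " cycle(s)\n", sep = "")
  if (length(x$cycles)) {
    cat("  lengths:", paste(sort(lengths(x$cycles)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cycle-basis length histogram
#'
#' Computes a cycle basis and tabulates the cycle lengths.  With
#' `exclude_familial = TRUE` (requires edge labels) basis cycles classified
#' `trivial` or `familial` are dropped first, leaving the nonfamilial cycle
#' lengths whose distribution separates genealogical from social networks.
#'
#' @param net a simple \code{igraph} graph.
#' @param exclude_familial drop trivial/familial cycles (labelled networks
#'   only).
#' @param method passed to [cycle_basis()].
#' @return a named integer vector: counts indexed by cycle length.
#' @export
cycle_basis_lengths <- function(net, exclude_familial = FALSE,
                                method = c("minimum", "fundamental")) {
  cb <- cycle_basis(net, method = match.arg(method))
  cycles <- cb$cycles
  if (exclude_familial) {
    if (is.null(edge_labels(net))) {
      stop("exclude_familial requires a labelled network")
    }
    cls <- vapply(cycles, classify_cycle, character(1), net = net)
    cycles <- cycles[!(cls %in% c("trivial", "familial"))]
  }
  if (length(cycles) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(lengths(cycles))
  stats::setNames(as.integer(tab), names(tab))
}

#' Classify a genealogical cycle
#'
#' Categories in precedence order:
#' \describe{
#'   \item{trivial}{length 3 with exactly one union edge - two parents and a
#'     child.}
#'   \item{familial}{length 4 with at most one union edge - two parents and
#'     two children, with or without the parents' union edge appearing in
#'     the cycle.}
#'   \item{common_ancestor}{all edges parent-child except at most one union
#'     edge closing the cycle at the descendant couple.}
#'   \item{union}{only union edges plus sibling-connecting parent-child
#'     pairs, i.e. every maximal run of consecutive parent-child edges has
#'     length exactly 2 (as in the double-cousin situation).}
#'   \item{hybrid}{any other combination.}
#' }
#' Classification is invariant under rotation and reversal of the vertex
#' sequence.
#'
#' @param cycle a character vector of vertex names forming a simple cycle
#'   (first vertex not repeated).
#' @param net a labelled \code{igraph} graph containing every cycle edge.
#' @return one of `"trivial"`, `"familial"`, `"common_ancestor"`, `"union"`,
#'   `"hybrid"`.
#' @export
classify_cycle <- function(cycle, net) {
  rel <- edge_labels(net)
  if (is.null(rel)) stop("classify_cycle requires a labelled network")
  len <- length(cycle)
  if (len < 3L) stop("a simple cycle has at least 3 vertices")
  if (anyDuplicated(cycle)) stop("cycle vertex sequence must be simple")
  ids <- cycle_edge_ids(cycle, net)
  labs <- rel[ids]
  if (anyNA(labs)) stop("cycle uses an unlabelled edge")
  n_union <- sum(labs == "union")
  if (len == 3L && n_union == 1L) return("trivial")
  if (len == 4L && n_union <= 1L) return("familial")
  if (n_union <= 1L) return("common_ancestor")
  # union cycle: parent-child edges only occur as sibling-connecting pairs
  is_pc <- labs == "parent_child"
  if (!any(is_pc)) return("union")
  runs <- cyclic_run_lengths(is_pc)
  if (all(runs == 2L)) return("union")
  "hybrid"
}

# Lengths of maximal cyclic runs of TRUE in a logical vector.
cyclic_run_lengths <- function(x) {
  n <- length(x)
  if (all(x)) return(n)
  # rotate so the vector starts just after a FALSE
  start <- which(!x)[1L]
  x <- x[c(seq.int(start, n), seq_len(start - 1L))]
  r <- rle(x)
  r$lengths[r$values]
}

#' Predicted persistence of a common-ancestor cycle
#'
#' The published prediction: a common-ancestor cycle whose distance to union
#' is `n` (equivalently, total individuals in the cycle) carries a
#' dimension-1 class of persistence `floor(n / 3)`.  Note that the computed
#' dimension-1 persistence of an isolated cycle graph `C_n` is
#' `ceiling(n / 3) - 1`, which differs from this prediction exactly when `n`
#' is divisible by 3; the package surfaces the discrepancy in its test suite
#' rather than reconciling it silently.
#'
#' @param n cycle size, at least 3.
#' @return `floor(n / 3)`.
#' @export
union_cycle_persistence_bound <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n must be an integer >= 3")
  n %/% 3L
}
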