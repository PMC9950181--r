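#' Read a network from an edge-list file
#'
#' Parses a whitespace- or tab-delimited edge list with two or three columns
#' (`u v` or `u v label`).  Lines starting with `#` (and trailing `#`
#' comments) are ignored.  Vertex identifiers are opaque strings; the internal
#' vertex order is the order of first appearance in the file, which makes
#' downstream computations reproducible across runs.  Duplicate records
#' collapse to a single edge.  Labels, when present, must cover every edge and
#' be one of `parent_child` or `union`; they are stored in the edge attribute
#' `relation`.
#'
#' @param path path to the edge-list file (UTF-8).
#' @return an undirected simple \code{igraph} graph, with an edge attribute
#'   `relation` when the file is labelled.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stripped <- trimws(sub("#.*$", "", raw))
  keep <- which(nzchar(stripped))
  toks <- strsplit(stripped[keep], "[ \t]+")
  nf <- lengths(toks)
  bad <- which(nf != 2L & nf != 3L)
  if (length(bad)) {
    stop("malformed edge record at line ", keep[bad[1L]],
         ": expected 2 or 3 fields, got ", nf[bad[1L]])
  }
  if (length(toks) == 0L) stop("edge-list file contains no records: ", path)
  u <- vapply(toks, `[`, character(1), 1L)
  v <- vapply(toks, `[`, character(1), 2L)
  lab <- rep(NA_character_, length(toks))
  has3 <- nf == 3L
  lab[has3] <- vapply(toks[has3], `[`, character(1), 3L)
  if (any(has3) && !all(has3)) {
    stop("edge labels, when present, must cover every record (line ",
         keep[which(!has3)[1L]], " is unlabelled)")
  }
  bad_lab <- which(has3 & !(lab %in% c("parent_child", "union")))
  if (length(bad_lab)) {
    stop("unknown edge label '", lab[bad_lab[1L]], "' at line ",
         keep[bad_lab[1L]], " (expected 'parent_child' or 'union')")
  }
  loops <- which(u == v)
  if (length(loops)) {
    stop("self-loop at line ", keep[loops[1L]],
         ": networks read from edge lists must be simple")
  }
  make_network(u, v, if (any(has3)) lab else NULL)
}

# Build a simple undirected graph from parallel endpoint vectors, vertices
# ordered by first appearance, duplicate unordered pairs collapsed.
make_network <- function(u, v, lab = NULL) {
  verts <- unique(as.vector(rbind(u, v)))
  a <- pmin(u, v)
  b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  if (!is.null(lab)) {
    agg <- tapply(lab, key, function(x) length(unique(x)))
    if (any(agg > 1L)) {
      dup <- names(agg)[agg > 1L][1L]
      stop("conflicting labels for duplicated edge ",
           gsub("\r", " -- ", dup, fixed = TRUE))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = u[first], to = v[first], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  if (!is.null(lab)) igraph::E(g)$relation <- lab[first]
  g
}

#' Write a network to an edge-list file
#'
#' Inverse of [read_edge_list()]: one `u v [label]` record per edge.
#'
#' @param net an \code{igraph} graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  rel <- igraph::edge_attr(net, "relation")
  lines <- if (is.null(rel)) {
    paste(el[, 1L], el[, 2L])
  } else {
    paste(el[, 1L], el[, 2L], rel)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

assert_simple <- function(net) {
  if (igraph::vcount(net) == 0L) stop("network has no vertices")
  if (any(igraph::which_loop(net)) || any(igraph::which_multiple(net))) {
    stop("operation requires a simple network ",
         "(collapse multigraphs with simplify_support())")
  }
  invisible(net)
}

#' All-pairs geodesic distance matrix
#'
#' Exact breadth-first-search hop distances between every pair of vertices.
#' Unreachable pairs are `Inf` (never a sentinel integer).
#'
#' @param net a simple \code{igraph} graph.
#' @return a symmetric numeric matrix with zero diagonal, dimnames set to the
#'   vertex names, and `Inf` between vertices in different components.
#' @seealso [max_finite_distance()]
#' @export
geodesic_distance_matrix <- function(net) {
  assert_simple(net)
  d <- igraph::distances(net, algorithm = "unweighted")
  d
}

#' Largest finite entry of a distance matrix
#'
#' The diameter of the network when it is connected; the largest
#' within-component distance otherwise.  Zero for a single vertex.
#'
#' @param dm a distance matrix from [geodesic_distance_matrix()].
#' @return a non-negative number.
#' @export
max_finite_distance <- function(dm) {
  max(dm[is.finite(dm)])
}

#' Connected components of a network
#'
#' @param net an \code{igraph} graph.
#' @return a list of character vectors, one per component, partitioning the
#'   vertex names.  The component count equals the number of infinite-death
#'   dimension-0 persistence intervals of the same network.
#' @export
connected_components <- function(net) {
  comp <- igraph::components(net)
  unname(split(igraph::V(net)$name, comp$membership))
}

#' Breadth-first subnetwork sample from a degree-1 seed
#'
#' Picks a vertex of degree 1 uniformly at random, then returns the induced
#' subnetwork on the `eta` vertices closest to it in BFS order.  Vertices at
#' equal distance are admitted in ascending identifier order, so the draw is
#' fully determined by the seed vertex.  Starting from a degree-1 vertex puts
#' both boundary and interior vertices of the original network in the sample.
#'
#' @param net a simple \code{igraph} graph with at least one degree-1 vertex.
#' @param eta number of vertices to keep; at most the size of the seed's
#'   component.
#' @param seed optional integer seed for the uniform choice of the degree-1
#'   vertex; when `NULL` the current RNG stream is used.
#' @return a connected induced subgraph containing the seed vertex, edge
#'   labels inherited.
#' @export
bfs_sample <- function(net, eta, seed = NULL) {
  assert_simple(net)
  eta <- as.integer(eta)
  if (eta < 1L) stop("eta must be a positive integer")
  deg <- igraph::degree(net)
  leaves <- igraph::V(net)$name[deg == 1L]
  if (length(leaves) == 0L) {
    stop("bfs_sample requires a vertex of degree 1 in the network")
  }
  root <- with_seed(seed, leaves[sample.int(length(leaves), 1L)])
  d <- igraph::distances(net, v = root, algorithm = "unweighted")[1L, ]
  reach <- names(d)[is.finite(d)]
  if (eta > length(reach)) {
    stop("eta (", eta, ") exceeds the size of the seed vertex's component (",
         length(reach), ")")
  }
  ord <- order(d[reach], reach, method = "radix")
  keep <- reach[ord][seq_len(eta)]
  igraph::induced_subgraph(net, keep)
}

#' Configuration-model null network
#'
#' Uniform stub matching: each vertex contributes as many stubs as its target
#' degree, the stub list is randomly permuted and paired off, so every perfect
#' matching of stubs is equally likely.  Self-loops and parallel edges are
#' kept (a loop counts twice towards its vertex's degree), so the realised
#' degree sequence equals the input exactly.
#'
#' @param degrees non-negative integer degree sequence with an even sum.
#' @param vertices optional character vector of vertex names.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return an \code{igraph} multigraph.
#' @seealso [simplify_support()] to collapse the result before distance or
#'   cycle computations.
#' @export
configuration_model <- function(degrees, vertices = NULL, seed = NULL) {
  degrees <- as.integer(degrees)
  if (any(is.na(degrees)) || any(degrees < 0L)) {
    stop("degrees must be non-negative integers")
  }
  if (sum(degrees) %% 2L != 0L) {
    stop("degree sum must be even for a configuration model")
  }
  n <- length(degrees)
  if (is.null(vertices)) vertices <- as.character(seq_len(n))
  stubs <- rep(seq_len(n), degrees)
  perm <- with_seed(seed, if (length(stubs)) sample(stubs) else integer(0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- vertices
  if (length(perm)) g <- igraph::add_edges(g, perm)
  g
}

#' Simple support of a multigraph
#'
#' Collapses parallel edges and removes self-loops, recording the original
#' parallel-edge multiplicity in the edge attribute `multiplicity`.  Distance
#' and cycle-basis computations operate on this simple support, since basis
#' cycles have length at least 3.
#'
#' @param net an \code{igraph} graph, possibly with loops and parallel edges.
#' @return a simple \code{igraph} graph with edge attribute `multiplicity`.
#' @export
simplify_support <- function(net) {
  igraph::E(net)$multiplicity <- 1L
  igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(multiplicity = "sum",
                                         relation = "first", "ignore"))
}

#' Read or write a network in GraphML format
#'
#' Interoperability wrappers around \code{igraph}'s GraphML support; the
#' `relation` edge attribute carries the genealogical labels.
#'
#' @param path file path.
#' @return for `read_graphml`, an \code{igraph} graph; for `write_graphml`,
#'   `path` invisibly.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  igraph::read_graph(path, format = "graphml")
}

#' @rdname read_graphml
#' @param net an \code{igraph} graph.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Edge labels of a genealogical network
#'
#' @param net an \code{igraph} graph.
#' @return the character vector of `relation` edge labels
#'   (`"parent_child"`/`"union"`), or `NULL` for an unlabelled network.
#' @export
edge_labels <- function(net) {
  igraph::edge_attr(net, "relation")
}
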