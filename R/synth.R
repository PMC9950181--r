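#' Canonical small networks
#'
#' `hexagon_network()` is the 6-cycle on vertices 1..6, the running worked
#' example of the package: its clique filtration passes through an
#' octahedron at threshold 2 and is complete at 3, giving one dimension-1
#' class `[1, 2)` and one dimension-2 class `[2, 3)`.  `cycle_network(m)`,
#' `path_network(n)` and `complete_network(n)` build the named graphs with
#' vertices `1..n`.
#'
#' @param m,n number of vertices (`m >= 3` for a cycle, `n >= 1` otherwise).
#' @return an \code{igraph} graph.
#' @export
hexagon_network <- function() {
  cycle_network(6L)
}

#' @rdname hexagon_network
#' @export
cycle_network <- function(m) {
  m <- as.integer(m)
  if (is.na(m) || m < 3L) stop("a cycle network needs at least 3 vertices")
  v <- as.character(seq_len(m))
  make_network(v, v[c(2:m, 1L)])
}

#' @rdname hexagon_network
#' @export
path_network <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("a path network needs at least 1 vertex")
  if (n == 1L) {
    g <- igraph::make_empty_graph(1L, directed = FALSE)
    igraph::V(g)$name <- "1"
    return(g)
  }
  v <- as.character(seq_len(n))
  make_network(v[-n], v[-1L])
}

#' @rdname hexagon_network
#' @export
complete_network <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("a complete network needs at least 1 vertex")
  if (n == 1L) return(path_network(1L))
  pairs <- utils::combn(as.character(seq_len(n)), 2L)
  make_network(pairs[1L, ], pairs[2L, ])
}

#' Tikopia persistence intervals (published table)
#'
#' The persistence-interval multiset of the Tikopia genealogical network
#' (288 individuals in its largest component, 8 components in total) as
#' printed in the source publication's interval table, shipped as a packaged
#' fixture in the interval-table interchange format.  Dimension 0 is
#' `[0, Inf) x 8` plus `[0, 1) x 286`; dimension 1 has 46 intervals, the
#' longest `[1, 7)`; dimension 2 has 38 intervals up to `[8, 9)`.
#'
#' @return a `persistence_intervals` object.
#' @export
tikopia_table1_fixture <- function() {
  read_intervals(system.file("extdata", "tikopia_table1_intervals.tsv",
                             package = "kintopo", mustWork = TRUE))
}

#' Parameters for the synthetic genealogy generator
#'
#' Defaults emulate the empirical regime of real genealogical corpora:
#' unions form at graph distances concentrated between 5 and 10 hops, a
#' Poisson offspring law with mean slightly above two children per couple,
#' and a modest rate of partners arriving from outside the recorded network.
#'
#' @param founder_couples number of unrelated founding couples.
#' @param generations number of offspring generations to simulate.
#' @param mean_children mean of the Poisson offspring draw per couple.
#' @param union_distance_range integer interval `c(lo, hi)`, `lo >= 3`,
#'   within which in-network partners are sought.
#' @param immigrant_rate probability an individual takes a partner from
#'   outside the network (a new founder-like spouse) even when in-range
#'   candidates exist.
#' @param seed integer seed driving the single pseudo-random stream of the
#'   simulation.
#' @return an object of class `genealogy_sim_params`.
#' @export
genealogy_sim_params <- function(founder_couples = 30L, generations = 5L,
                                 mean_children = 2.2,
                                 union_distance_range = c(5L, 10L),
                                 immigrant_rate = 0.15, seed = 1L) {
  founder_couples <- as.integer(founder_couples)
  generations <- as.integer(generations)
  lo <- as.integer(union_distance_range[1L])
  hi <- as.integer(union_distance_range[2L])
  if (founder_couples < 0L || generations < 0L) {
    stop("founder_couples and generations must be non-negative")
  }
  if (generations > 0L && founder_couples == 0L) {
    stop("cannot simulate generations without founder couples")
  }
  if (mean_children < 0) stop("mean_children must be non-negative")
  if (is.na(lo) || lo < 3L || is.na(hi) || hi < lo) {
    stop("union_distance_range must satisfy 3 <= lo <= hi")
  }
  if (immigrant_rate < 0 || immigrant_rate > 1) {
    stop("immigrant_rate must be a probability")
  }
  structure(list(founder_couples = founder_couples,
                 generations = generations,
                 mean_children = mean_children,
                 union_distance_range = c(lo, hi),
                 immigrant_rate = immigrant_rate,
                 seed = as.integer(seed)),
            class = "genealogy_sim_params")
}

#' @export
print.genealogy_sim_params <- function(x, ...) {
  cat("Genealogy simulation parameters:\n")
  cat("  founder couples:", x$founder_couples,
      "| generations:", x$generations, "\n")
  cat("  mean children:", x$mean_children,
      "| union distance range: [", x$union_distance_range[1L], ",",
      x$union_distance_range[2L], "]\n")
  cat("  immigrant rate:", x$immigrant_rate, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Simulate a genealogical network
#'
#' Generation-by-generation growth.  Founders are paired into couples; each
#' couple draws a Poisson number of children, connected to both parents by
#' parent-child edges.  Individuals of the new generation then pair up: each
#' still-unpaired person takes, uniformly at random, an unpaired
#' same-generation partner whose current graph distance (measured before
#' adding the union edge) lies in `union_distance_range`; with probability
#' `immigrant_rate`, or when no in-range candidate exists, a new spouse with
#' no prior network ties is created instead.  Unions are monogamous and
#' generations do not overlap.  The result is deterministic given the seed.
#'
#' Immigrant and founder couples have infinite distance to union; every
#' finite distance to union was in `union_distance_range` at the moment the
#' union formed, although unions formed later can shorten the realised
#' pre-union distance recovered by [distance_to_union()].
#'
#' @param params a `genealogy_sim_params` object.
#' @return a labelled \code{igraph} graph (edge attribute `relation`).
#' @export
simulate_genealogy <- function(params) {
  stopifnot(inherits(params, "genealogy_sim_params"))
  lo <- params$union_distance_range[1L]
  hi <- params$union_distance_range[2L]
  with_seed(params$seed, {
    from <- character(0); to <- character(0); rel <- character(0)
    verts <- character(0)
    add_vertex <- function(v) verts[[length(verts) + 1L]] <<- v
    add_edge <- function(a, b, r) {
      from[[length(from) + 1L]] <<- a
      to[[length(to) + 1L]] <<- b
      rel[[length(rel) + 1L]] <<- r
    }
    couples <- list()
    for (i in seq_len(params$founder_couples)) {
      a <- sprintf("F%03da", i); b <- sprintf("F%03db", i)
      add_vertex(a); add_vertex(b)
      add_edge(a, b, "union")
      couples[[length(couples) + 1L]] <- c(a, b)
    }
    kid_counter <- 0L
    imm_counter <- 0L
    for (g in seq_len(params$generations)) {
      children <- character(0)
      for (cp in couples) {
        nk <- stats::rpois(1L, params$mean_children)
        for (j in seq_len(nk)) {
          kid_counter <- kid_counter + 1L
          kid <- sprintf("G%d_%04d", g, kid_counter)
          add_vertex(kid)
          add_edge(cp[1L], kid, "parent_child")
          add_edge(cp[2L], kid, "parent_child")
          children <- c(children, kid)
        }
      }
      couples <- list()
      if (length(children) == 0L) next
      gcur <- igraph::graph_from_data_frame(
        data.frame(from = from, to = to, stringsAsFactors = FALSE),
        directed = FALSE,
        vertices = data.frame(name = verts, stringsAsFactors = FALSE))
      unpaired <- children[sample.int(length(children))]
      paired <- stats::setNames(rep(FALSE, length(unpaired)), unpaired)
      for (p in unpaired) {
        if (paired[[p]]) next
        partner <- NULL
        if (stats::runif(1L) >= params$immigrant_rate) {
          open <- names(paired)[!paired]
          open <- setdiff(open, p)
          if (length(open)) {
            d <- igraph::distances(gcur, v = p, to = open,
                                   algorithm = "unweighted")[1L, ]
            cands <- open[is.finite(d) & d >= lo & d <= hi]
            if (length(cands)) {
              partner <- cands[sample.int(length(cands), 1L)]
            }
          }
        }
        if (is.null(partner)) {
          imm_counter <- imm_counter + 1L
          partner <- sprintf("M%d_%04d", g, imm_counter)
          add_vertex(partner)
          gcur <- igraph::add_vertices(gcur, 1L, name = partner)
        } else {
          paired[[partner]] <- TRUE
        }
        paired[[p]] <- TRUE
        add_edge(p, partner, "union")
        gcur <- igraph::add_edges(gcur, c(p, partner))
        couples[[length(couples) + 1L]] <- c(p, partner)
      }
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = verts, stringsAsFactors = FALSE))
    igraph::E(g)$relation <- rel
    g
  })
}
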