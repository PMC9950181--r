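#' Persistent homology of a clique filtration
#'
#' Standard column reduction of the Z2 boundary matrix in filtration order
#' (appearance value, then dimension, then lexicographic vertex tuple; any
#' order gives the same interval multiset, this one makes runs reproducible).
#' Birth and death of an interval are the appearance values of the paired
#' simplices; unpaired simplices yield infinite-death (essential) intervals;
#' pairs with equal birth and death are dropped.
#'
#' For an unweighted connected network every dimension-0 interval is
#' `[0, 1)` except one essential `[0, Inf)` per component, and every
#' dimension-1 interval has birth 1.  When the filtration was built with a
#' `t_max` cap below the diameter, classes still alive at the cap are
#' reported with death `t_max` and flagged `censored`.
#'
#' @param fc a `flag_filtration` built with
#'   `max_simplex_dim >= max_hom_dim + 1`.
#' @param max_hom_dim highest homology dimension to report, 0-2.
#' @return an object of class `persistence_intervals`: a data frame with
#'   columns `dim`, `birth`, `death` (`Inf` for essential classes),
#'   `multiplicity` and `censored`.
#' @examples
#' hex <- hexagon_network()
#' ph <- compute_persistence(
#'   build_clique_filtration(geodesic_distance_matrix(hex)), max_hom_dim = 2)
#' ph  # [0,1) x 5, [0,Inf) x 1; [1,2) x 1; [2,3) x 1
#' @export
compute_persistence <- function(fc, max_hom_dim = 2L) {
  stopifnot(inherits(fc, "flag_filtration"))
  max_hom_dim <- as.integer(max_hom_dim)
  if (max_hom_dim < 0L || max_hom_dim > 2L) {
    stop("max_hom_dim must be 0, 1 or 2")
  }
  if (fc$max_dim < max_hom_dim + 1L) {
    stop("filtration was built with max_simplex_dim = ", fc$max_dim,
         " but homology dimension ", max_hom_dim,
         " needs simplices of dimension ", max_hom_dim + 1L)
  }
  ord <- filtration_order(fc)
  partner <- reduce_filtration_cpp(ord$verts, ord$dims, fc$n)

  births <- integer(0); deaths <- numeric(0); dims <- integer(0)
  cens <- logical(0)
  for (p in 0:max_hom_dim) {
    idx <- which(ord$dims == p)
    part <- partner[idx] + 1L                # 1-based, 0 -> unpaired
    b <- ord$vals[idx]
    d <- rep(Inf, length(idx))
    cns <- rep(FALSE, length(idx))
    paired_up <- part > 0L & ord$dims[pmax(part, 1L)] == p + 1L
    paired_down <- part > 0L & ord$dims[pmax(part, 1L)] == p - 1L
    d[paired_up] <- ord$vals[part[paired_up]]
    keep <- !paired_down
    if (fc$capped) {
      # classes still alive at the cap are censored there, except one
      # genuinely essential dimension-0 class per true component (known
      # from the unthresholded distance pattern, not rebuilt here: the
      # reduction sees every within-component pair of distance <= t_max,
      # and a component can still be split at the cap).
      open <- keep & !is.finite(d)
      if (p == 0L) {
        comp_of <- component_ids_from_values(fc)
        open_idx <- which(open)
        seen <- logical(max(comp_of))
        for (i in open_idx) {
          ci <- comp_of[ord$verts[idx[i], 1L]]
          if (!seen[ci]) {
            seen[ci] <- TRUE            # keep as essential
          } else {
            d[i] <- fc$t_max
            cns[i] <- TRUE
          }
        }
      } else {
        d[open] <- fc$t_max
        cns[open] <- TRUE
      }
    }
    keep <- keep & (b < d)
    births <- c(births, b[keep])
    deaths <- c(deaths, d[keep])
    dims <- c(dims, rep(p, sum(keep)))
    cens <- c(cens, cns[keep])
  }

  agg <- stats::aggregate(
    list(multiplicity = rep(1L, length(dims))),
    by = list(dim = dims, birth = births, death = deaths, censored = cens),
    FUN = sum)
  agg <- agg[order(agg$dim, agg$birth, agg$death), , drop = FALSE]
  rownames(agg) <- NULL
  agg <- agg[, c("dim", "birth", "death", "multiplicity", "censored")]
  structure(agg,
            class = c("persistence_intervals", "data.frame"),
            n_vertices = fc$n, t_max = fc$t_max, capped = fc$capped)
}

# Connected-component id per vertex, recovered from which vertex pairs ever
# share a simplex (i.e. have finite distance); uses the edges stored in the
# filtration, which under a cap still connect each capped component.
component_ids_from_values <- function(fc) {
  e <- fc$simplices[[2L]]$verts
  g <- igraph::make_empty_graph(n = fc$n, directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, t(e))
  igraph::components(g)$membership
}

#' Count essential (infinite-death) intervals
#'
#' In dimension 0 this equals the number of connected components of the
#' network: each component is one family/friend group that never merges.
#'
#' @param intervals a `persistence_intervals` object.
#' @param dim homology dimension.
#' @return an integer count (multiplicities included).
#' @export
essential_count <- function(intervals, dim) {
  stopifnot(inherits(intervals, "persistence_intervals") ||
              is.data.frame(intervals))
  sel <- intervals$dim == dim & is.infinite(intervals$death)
  sum(intervals$multiplicity[sel])
}

#' Expand intervals to one row per occurrence
#'
#' @param intervals a `persistence_intervals` data frame.
#' @param dim optional dimension filter.
#' @param finite_only drop infinite-death intervals.
#' @return a data frame with columns `dim`, `birth`, `death`, one row per
#'   interval occurrence.
#' @export
expand_intervals <- function(intervals, dim = NULL, finite_only = FALSE) {
  df <- as.data.frame(intervals)
  if (!is.null(dim)) df <- df[df$dim == dim, , drop = FALSE]
  if (finite_only) df <- df[is.finite(df$death), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(dim = integer(0), birth = numeric(0),
                      death = numeric(0)))
  }
  idx <- rep(seq_len(nrow(df)), df$multiplicity)
  out <- df[idx, c("dim", "birth", "death"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.persistence_intervals <- function(x, ...) {
  cat("Persistence intervals\n")
  for (p in sort(unique(x$dim))) {
    sub <- x[x$dim == p, , drop = FALSE]
    lab <- sprintf("[%g,%s)%s x %d", sub$birth,
                   ifelse(is.infinite(sub$death), "Inf",
                          sprintf("%g", sub$death)),
                   ifelse(sub$censored, "+", ""), sub$multiplicity)
    cat("  dim ", p, ": ", paste(lab, collapse = ", "), "\n", sep = "")
  }
  if (any(x$censored)) {
    cat("  ('+' marks deaths censored at the filtration cap)\n")
  }
  invisible(x)
}

#' Read a persistence-interval table
#'
#' Tab-delimited text with header columns `dim`, `birth`, `death`,
#' `multiplicity`; `death` may be the string `inf`.  This is the interchange
#' format shared by all tools in the package, so diagrams computed elsewhere
#' can be compared without recomputation.
#'
#' @param path path to the table.
#' @return a `persistence_intervals` object.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("interval table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("dim", "birth", "death", "multiplicity")
  if (!all(need %in% names(df))) {
    stop("interval table must have columns: ", paste(need, collapse = ", "))
  }
  death <- suppressWarnings(as.numeric(ifelse(
    tolower(trimws(as.character(df$death))) %in% c("inf", "infinity"),
    "Inf", as.character(df$death))))
  if (any(is.na(death))) stop("malformed death values in ", path)
  out <- data.frame(dim = as.integer(df$dim), birth = as.numeric(df$birth),
                    death = death,
                    multiplicity = as.integer(df$multiplicity),
                    censored = FALSE)
  if (any(out$birth >= out$death)) stop("intervals must satisfy birth < death")
  structure(out, class = c("persistence_intervals", "data.frame"))
}

#' Write a persistence-interval table
#'
#' @param intervals a `persistence_intervals` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  df <- as.data.frame(intervals)[, c("dim", "birth", "death", "multiplicity")]
  df$death <- ifelse(is.infinite(df$death), "inf",
                     format(df$death, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persistence intervals of a network, end to end
#'
#' Convenience wrapper: distance matrix, clique filtration, reduction.
#'
#' @param net a simple \code{igraph} graph.
#' @param max_hom_dim highest homology dimension, 0-2.
#' @param t_max threshold cap passed to [build_clique_filtration()].
#' @return a `persistence_intervals` object.
#' @export
network_persistence <- function(net, max_hom_dim = 2L, t_max = "diameter") {
  dm <- geodesic_distance_matrix(net)
  fc <- build_clique_filtration(dm, max_simplex_dim = max_hom_dim + 1L,
                                t_max = t_max)
  compute_persistence(fc, max_hom_dim = max_hom_dim)
}
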