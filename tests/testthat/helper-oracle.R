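# Independent oracle for persistent homology on small networks: dense GF(2)
# linear algebra on the boundary matrices of each filtration slice, interval
# multiplicities recovered from persistent Betti numbers by inclusion-
# exclusion.  Shares no code with the reduction engine in the package.

# Row-reduce a 0/1 matrix over GF(2); returns list(rank, basis) where basis
# holds a column basis of the column space.
gf2_rref <- function(M) {
  if (is.null(dim(M)) || any(dim(M) == 0L)) {
    return(list(rank = 0L, pivots = integer(0)))
  }
  M <- M %% 2L
  nr <- nrow(M); nc <- ncol(M)
  r <- 1L
  pivots <- integer(0)
  for (c in seq_len(nc)) {
    if (r > nr) break
    piv <- which(M[r:nr, c] == 1L)
    if (!length(piv)) next
    piv <- piv[1L] + r - 1L
    if (piv != r) M[c(r, piv), ] <- M[c(piv, r), ]
    hits <- which(M[, c] == 1L)
    hits <- hits[hits != r]
    if (length(hits)) M[hits, ] <- (M[hits, , drop = FALSE] +
                                      matrix(M[r, ], length(hits), nc,
                                             byrow = TRUE)) %% 2L
    pivots <- c(pivots, c)
    r <- r + 1L
  }
  list(rank = length(pivots), pivots = pivots)
}

gf2_rank <- function(M) gf2_rref(M)$rank

# Null-space basis (columns) of a GF(2) matrix with nc columns.
gf2_nullspace <- function(M) {
  nc <- ncol(M)
  if (is.null(nc) || nc == 0L) return(matrix(0L, 0L, 0L))
  if (nrow(M) == 0L) return(diag(1L, nc))
  M <- M %% 2L
  nr <- nrow(M)
  A <- M
  r <- 1L
  pivcol <- integer(0)
  for (c in seq_len(nc)) {
    if (r > nr) break
    piv <- which(A[r:nr, c] == 1L)
    if (!length(piv)) next
    piv <- piv[1L] + r - 1L
    if (piv != r) A[c(r, piv), ] <- A[c(piv, r), ]
    hits <- setdiff(which(A[, c] == 1L), r)
    if (length(hits)) A[hits, ] <- (A[hits, , drop = FALSE] +
                                      matrix(A[r, ], length(hits), nc,
                                             byrow = TRUE)) %% 2L
    pivcol <- c(pivcol, c)
    r <- r + 1L
  }
  free <- setdiff(seq_len(nc), pivcol)
  if (!length(free)) return(matrix(0L, nc, 0L))
  B <- matrix(0L, nc, length(free))
  for (fi in seq_along(free)) {
    f <- free[fi]
    B[f, fi] <- 1L
    for (ri in seq_along(pivcol)) {
      B[pivcol[ri], fi] <- A[ri, f]
    }
  }
  B %% 2L
}

# All simplices (as sorted index vectors) of the flag complex at threshold
# delta, dims 0..maxdim, from a distance matrix.
oracle_simplices <- function(dm, delta, maxdim) {
  n <- nrow(dm)
  out <- vector("list", maxdim + 1L)
  out[[1L]] <- as.list(seq_len(n))
  for (d in seq_len(maxdim)) {
    prev <- out[[d]]
    cur <- list()
    for (s in prev) {
      last <- s[length(s)]
      if (last >= n) next
      for (v in seq.int(last + 1L, n)) {
        dv <- dm[s, v]
        if (all(is.finite(dv)) && all(dv <= delta) && all(dv > 0)) {
          cur[[length(cur) + 1L]] <- c(s, v)
        }
      }
    }
    out[[d + 1L]] <- cur
  }
  out
}

simplex_key <- function(s) paste(s, collapse = ".")

# Dense GF(2) boundary matrix from p-simplices (columns) to (p-1)-simplices
# (rows), given the global (p-1)-simplex key index.
oracle_boundary <- function(psimp, faces_index, nfaces) {
  if (!length(psimp)) return(matrix(0L, nfaces, 0L))
  B <- matrix(0L, nfaces, length(psimp))
  for (j in seq_along(psimp)) {
    s <- psimp[[j]]
    for (drop in seq_along(s)) {
      B[faces_index[[simplex_key(s[-drop])]], j] <- 1L
    }
  }
  B
}

# Persistent Betti number beta_p^{i,j}: classes alive in G_i that survive to
# G_j.  dim(Z_p(G_i)) - dim(Z_p(G_i) intersect B_p(G_j)), with the
# intersection computed as dim Z + dim B - dim (Z + B) in the coordinates of
# the p-simplices of G_j.
oracle_persistence <- function(net, max_hom_dim = 1L) {
  dm <- kintopo::geodesic_distance_matrix(net)
  M <- kintopo::max_finite_distance(dm)
  maxdim <- max_hom_dim + 1L
  slices <- lapply(0:M, function(d) oracle_simplices(dm, d, maxdim))
  # global index of p-simplices at the final slice, per p
  final <- slices[[M + 1L]]
  idx <- lapply(final, function(ss) {
    e <- new.env(hash = TRUE, parent = emptyenv())
    for (k in seq_along(ss)) e[[simplex_key(ss[[k]])]] <- k
    e
  })
  # cycle-space basis Z_p at level i, embedded in final p-coordinates, and
  # boundary-space basis B_p at level j in final p-coordinates
  embed_cols <- function(cols, ss, p) {
    np <- length(final[[p + 1L]])
    if (!length(ss) || is.null(dim(cols)) || ncol(cols) == 0L) {
      return(matrix(0L, np, 0L))
    }
    out <- matrix(0L, np, ncol(cols))
    rows <- vapply(ss, function(s) idx[[p + 1L]][[simplex_key(s)]],
                   integer(1))
    out[rows, ] <- cols
    out
  }
  Z <- vector("list", max_hom_dim + 1L)   # [[p+1]][[i+1]]
  B <- vector("list", max_hom_dim + 1L)
  for (p in 0:max_hom_dim) {
    Z[[p + 1L]] <- vector("list", M + 1L)
    B[[p + 1L]] <- vector("list", M + 1L)
    for (i in 0:M) {
      ss <- slices[[i + 1L]]
      np <- length(ss[[p + 1L]])
      if (p == 0L) {
        zb <- diag(1L, max(np, 0L))           # every vertex chain is a cycle
        if (np == 0L) zb <- matrix(0L, 0L, 0L)
      } else {
        bd <- oracle_boundary(ss[[p + 1L]],
                              local({
                                e <- new.env(hash = TRUE,
                                             parent = emptyenv())
                                for (k in seq_along(ss[[p]]))
                                  e[[simplex_key(ss[[p]][[k]])]] <- k
                                e
                              }),
                              length(ss[[p]]))
        zb <- gf2_nullspace(bd)
      }
      Z[[p + 1L]][[i + 1L]] <- embed_cols(zb, ss[[p + 1L]], p)
      bd2 <- oracle_boundary(ss[[p + 2L]],
                             local({
                               e <- new.env(hash = TRUE, parent = emptyenv())
                               for (k in seq_along(ss[[p + 1L]]))
                                 e[[simplex_key(ss[[p + 1L]][[k]])]] <- k
                               e
                             }),
                             length(ss[[p + 1L]]))
      B[[p + 1L]][[i + 1L]] <- embed_cols(bd2, ss[[p + 1L]], p)
    }
  }
  beta <- function(p, i, j) {
    if (i < 0L || j < i) return(0L)
    Zi <- Z[[p + 1L]][[i + 1L]]
    Bj <- B[[p + 1L]][[j + 1L]]
    dZ <- gf2_rank(Zi)
    dB <- gf2_rank(Bj)
    dZB <- gf2_rank(cbind(Zi, Bj))
    dZ - (dZ + dB - dZB)
  }
  rows <- list()
  for (p in 0:max_hom_dim) {
    for (b in 0:M) {
      for (d in seq.int(b + 1L, M + 1L)) {
        if (d > M) next
        mult <- beta(p, b, d - 1L) - beta(p, b, d) -
          beta(p, b - 1L, d - 1L) + beta(p, b - 1L, d)
        if (mult > 0L) {
          rows[[length(rows) + 1L]] <-
            data.frame(dim = p, birth = b, death = d, multiplicity = mult)
        }
      }
      ess <- beta(p, b, M) - beta(p, b - 1L, M)
      if (ess > 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(dim = p, birth = b, death = Inf, multiplicity = ess)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$dim, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Canonical comparable form of an interval table.
interval_key <- function(df) {
  df <- as.data.frame(df)[, c("dim", "birth", "death", "multiplicity")]
  df <- df[order(df$dim, df$birth, df$death), , drop = FALSE]
  rownames(df) <- NULL
  df
}
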