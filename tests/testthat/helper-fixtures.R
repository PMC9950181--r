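# Small labelled-network motifs and random-object generators shared across
# the test files.  Everything is built in code; no stored fixtures beyond the
# packaged Tikopia interval table.

labeled_network <- function(from, to, relation) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  writeLines(paste(from, to, relation), f)
  read_edge_list(f)
}

# two parents, union edge, n children
nuclear_family <- function(n_children = 2L) {
  kids <- paste0("c", seq_len(n_children))
  labeled_network(
    from = c("p1", rep(c("p1", "p2"), n_children)),
    to = c("p2", rep(kids, each = 2L)),
    relation = c("union", rep("parent_child", 2L * n_children)))
}

# first cousins married: shared grandparent couple, two sibling parents
first_cousin_couple <- function() {
  labeled_network(
    from = c("g1", "g1", "g2", "g1", "g2", "a", "b", "s1"),
    to   = c("g2", "a", "a", "b", "b", "s1", "s2", "s2"),
    relation = c("union", rep("parent_child", 4L),
                 "parent_child", "parent_child", "union"))
}

# descendants of one ancestor forming a union (common-ancestor cycle motif)
common_ancestor_motif <- function() {
  labeled_network(
    from = c("top", "top", "m1", "m2", "x"),
    to   = c("m1", "m2", "x", "y", "y"),
    relation = c(rep("parent_child", 4L), "union"))
}

# double cousins: two sibling pairs intermarried (union cycle motif)
double_cousin_motif <- function() {
  labeled_network(
    from = c("pA", "pA", "pB", "pB", "a1", "a2"),
    to   = c("a1", "a2", "b1", "b2", "b1", "b2"),
    relation = c(rep("parent_child", 4L), "union", "union"))
}

random_simple_graph <- function(n, p = 0.35) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

random_connected_graph <- function(n, p = 0.35) {
  repeat {
    g <- random_simple_graph(n, p)
    if (igraph::is_connected(g)) return(g)
  }
}

random_tree <- function(n) {
  g <- igraph::sample_tree(n)
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

make_diagram <- function(pts, dim = 1L, essential = 0L) {
  pts <- matrix(as.numeric(pts), ncol = 2L,
                dimnames = list(NULL, c("birth", "death")))
  structure(list(dim = as.integer(dim), points = pts,
                 essential = as.integer(essential)),
            class = "persistence_diagram")
}

random_diagram <- function(max_pts = 4L, dim = 1L) {
  k <- sample(0:max_pts, 1L)
  if (k == 0L) return(make_diagram(matrix(numeric(0), 0L, 2L), dim))
  b <- round(runif(k, 0, 5), 2)
  d <- b + round(runif(k, 0.1, 5), 2)
  make_diagram(cbind(b, d), dim)
}

random_intervals <- function(max_rows = 6L, dim = 1L) {
  k <- sample(1:max_rows, 1L)
  b <- sample(1:4, k, replace = TRUE)
  d <- b + sample(1:5, k, replace = TRUE)
  structure(
    data.frame(dim = dim, birth = as.numeric(b), death = as.numeric(d),
               multiplicity = sample(1:3, k, replace = TRUE),
               censored = FALSE),
    class = c("persistence_intervals", "data.frame"))
}

write_temp_edges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
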