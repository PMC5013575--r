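# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# All-pairs shortest paths by Floyd-Warshall (package uses BFS via igraph).
fw_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Minimal least-squares superposition RMSD by Horn's closed-form quaternion
# method (package uses Kabsch/SVD). Returns the optimal RMSD only.
horn_rmsd <- function(p, q) {
  m <- nrow(p)
  pc <- sweep(p, 2, colMeans(p))
  qc <- sweep(q, 2, colMeans(q))
  s <- crossprod(qc, pc)  # s[a, b] = sum_i q_a p_b
  nmat <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],       -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],       -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(nmat, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(pc^2) + sum(qc^2) - 2 * lambda
  sqrt(max(0, ss) / m)
}

# Direct double-loop re-evaluation of the product-graph edge rule.
edge_rule_oracle <- function(pg) {
  ref <- pg$ref
  tgt <- pg$tgt
  v <- pg$vertices
  nv <- nrow(v)
  adj <- matrix(FALSE, nv, nv)
  for (u in seq_len(nv)) {
    for (w in seq_len(nv)) {
      if (u == w) next
      if (v$r[u] == v$r[w] || v$t[u] == v$t[w]) next
      if (pg$dimension == 2) {
        a <- ref$topo_dist[v$r[u], v$r[w]]
        b <- tgt$topo_dist[v$t[u], v$t[w]]
        if (is.finite(a) && is.finite(b) && abs(a - b) <= pg$threshold) {
          adj[u, w] <- TRUE
        }
      } else {
        a <- ref$geo_dist[v$r[u], v$r[w]]
        b <- tgt$geo_dist[v$t[u], v$t[w]]
        if (abs(a - b) <= pg$threshold) adj[u, w] <- TRUE
      }
    }
  }
  adj
}

# Maximum clique size via igraph (third, fully external cross-check).
igraph_clique_num <- function(adj) {
  if (nrow(adj) == 0L) return(0L)
  igraph::clique_num(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
}

# A two-fragment molecule (ethane-like pair of disconnected dimers) for
# exercising the Inf sentinel.
two_fragment_molecule <- function() {
  atoms <- tibble::tibble(
    serial = 1:4,
    name = paste0("C", 1:4),
    sybyl_type = "C.3",
    element = "C",
    x = c(0, 1.5, 10, 11.5), y = 0, z = 0
  )
  bonds <- tibble::tibble(a_serial = c(1L, 3L), b_serial = c(2L, 4L),
                          order_label = "1")
  new_molecule("FRAGMENTS", atoms, bonds)
}

# Propane-with-hydrogens fixture: 3 carbons in a chain, 2 hydrogens on the
# middle carbon, for the hydrogen-policy checks.
propane_with_h <- function() {
  atoms <- tibble::tibble(
    serial = 1:5,
    name = c("C1", "C2", "C3", "H1", "H2"),
    sybyl_type = c("C.3", "C.3", "C.3", "H", "H.spc"),
    element = c("C", "C", "C", "H", "H"),
    x = c(0, 1.5, 3, 1.5, 1.5), y = c(0, 0, 0, 1, -1), z = 0
  )
  bonds <- tibble::tibble(
    a_serial = c(1L, 2L, 2L, 2L), b_serial = c(2L, 3L, 4L, 5L),
    order_label = "1"
  )
  new_molecule("PROPANE", atoms, bonds)
}

expect_same_clique_size <- function(adj) {
  expect_identical(max_clique(adj)$size, brute_force_clique(adj)$size)
}
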