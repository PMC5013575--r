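test_that("self-comparison of a typed chain contains the identity clique", {
  spec <- fixture_spec(seed = 5, n_heavy = 3, topology = "chain",
                       type_alphabet = "C.3")
  g <- build_graph(make_molecule(spec))
  pg <- build_product_graph(g, g, dimension = 2, threshold = 0)
  expect_equal(nrow(pg$vertices), 9L)  # 3 x 3 type-matched pairs
  cl <- max_clique(pg)
  expect_equal(cl$size, 3L)
  # an edge never pairs a reference atom or target atom with itself twice
  idx <- which(pg$adjacency, arr.ind = TRUE)
  expect_true(all(pg$vertices$r[idx[, 1]] != pg$vertices$r[idx[, 2]]))
  expect_true(all(pg$vertices$t[idx[, 1]] != pg$vertices$t[idx[, 2]]))
  expect_false(any(diag(pg$adjacency)))
})

test_that("benzene vs benzene admits a 6-clique at 3D threshold zero", {
  g <- build_graph(benzene_molecule())
  pg <- build_product_graph(g, g, dimension = 3, threshold = 0)
  expect_equal(max_clique(pg)$size, 6L)
})

test_that("molecules sharing no SYBYL type give an empty, legal product graph", {
  a <- build_graph(make_molecule(fixture_spec(seed = 1, n_heavy = 5,
                                              type_alphabet = "C.3")))
  b <- build_graph(make_molecule(fixture_spec(seed = 2, n_heavy = 5,
                                              type_alphabet = "N.ar")))
  pg <- build_product_graph(a, b, dimension = 2, threshold = 2)
  expect_equal(nrow(pg$vertices), 0L)
  expect_equal(max_clique(pg)$size, 0L)
  expect_equal(brute_force_clique(pg)$size, 0L)
})

test_that("type compatibility is exact string equality", {
  mk <- function(types) {
    n <- length(types)
    new_molecule("M", tibble::tibble(
      serial = seq_len(n), name = paste0("A", seq_len(n)),
      sybyl_type = types, element = sub("\\..*$", "", types),
      x = seq_len(n) * 1.5, y = 0, z = 0
    ), tibble::tibble(a_serial = seq_len(n - 1),
                      b_serial = seq_len(n - 1) + 1L,
                      order_label = "1"))
  }
  pg <- build_product_graph(build_graph(mk(c("C.ar", "C.ar"))),
                            build_graph(mk(c("C.3", "C.2"))),
                            dimension = 2, threshold = 1)
  expect_equal(nrow(pg$vertices), 0L)  # C.ar never matches C.3/C.2
})

test_that("edge sets match a double-loop re-evaluation of the rule", {
  set.seed(77)
  for (i in 1:12) {
    sa <- fixture_spec(seed = 100 + i, n_heavy = c(3, 8),
                       type_alphabet = c("C.3", "N.3", "O.3"))
    sb <- fixture_spec(seed = 200 + i, n_heavy = c(3, 8),
                       type_alphabet = c("C.3", "N.3", "O.3"))
    ga <- build_graph(make_molecule(sa))
    gb <- build_graph(make_molecule(sb))
    dim <- if (i %% 2 == 0) 2 else 3
    thr <- if (dim == 2) sample(0:2, 1) else runif(1, 0, 1.5)
    pg <- build_product_graph(ga, gb, dimension = dim, threshold = thr)
    expect_equal(pg$adjacency, edge_rule_oracle(pg))
  }
})

test_that("comparisons touching disconnected pairs always fail, even Inf vs Inf", {
  g <- build_graph(two_fragment_molecule())
  pg <- build_product_graph(g, g, dimension = 2, threshold = 10)
  # vertices pairing atoms across fragments on both sides would need an
  # Inf-vs-Inf comparison: those edges must be absent
  v <- pg$vertices
  for (u in seq_len(nrow(v))) {
    for (w in seq_len(nrow(v))) {
      if (!pg$adjacency[u, w]) next
      expect_true(is.finite(g$topo_dist[v$r[u], v$r[w]]))
      expect_true(is.finite(g$topo_dist[v$t[u], v$t[w]]))
    }
  }
  # the conservative rule confines any one clique to a single fragment pair,
  # so the best mapping covers one 2-atom fragment only
  expect_equal(max_clique(pg)$size, 2L)
})

test_that("max_clique equals exhaustive enumeration and igraph on random graphs", {
  set.seed(1234)
  for (i in 1:120) {
    n <- sample(1:18, 1)
    p <- sample(c(0.3, 0.5, 0.7), 1)
    adj <- random_adjacency(n, p)
    s <- max_clique(adj)$size
    expect_identical(s, brute_force_clique(adj)$size)
    expect_identical(s, as.integer(igraph_clique_num(adj)))
    # returned members really form a clique
    cl <- max_clique(adj)$indices
    if (length(cl) > 1) {
      expect_true(all(adj[t(combn(cl, 2))]))
    }
  }
})

test_that("solver handles degenerate graphs", {
  expect_equal(max_clique(matrix(FALSE, 0, 0))$size, 0L)
  expect_equal(brute_force_clique(matrix(FALSE, 0, 0))$size, 0L)
  edgeless <- matrix(FALSE, 4, 4)
  expect_equal(max_clique(edgeless)$size, 1L)
  expect_equal(brute_force_clique(edgeless)$size, 1L)
  k6 <- !diag(6) > 0
  expect_equal(max_clique(k6)$size, 6L)
  expect_equal(brute_force_clique(k6)$size, 6L)
  # 5-cycle is triangle-free: maximum clique is an edge
  c5 <- matrix(FALSE, 5, 5)
  for (i in 1:5) {
    j <- i %% 5 + 1
    c5[i, j] <- c5[j, i] <- TRUE
  }
  expect_equal(max_clique(c5)$size, 2L)
  expect_error(brute_force_clique(matrix(FALSE, 25, 25)), "24 vertices")
})

test_that("max_clique is deterministic: identical member sets across calls", {
  set.seed(9)
  adj <- random_adjacency(15, 0.5)
  first <- max_clique(adj)
  for (i in 1:5) expect_identical(max_clique(adj), first)
})

test_that("threshold growth only adds edges; clique size is monotone", {
  ga <- build_graph(make_molecule(fixture_spec(seed = 31, n_heavy = 8)))
  gb <- build_graph(make_molecule(fixture_spec(seed = 32, n_heavy = 8)))
  prev_edges <- NULL
  prev_size <- -1L
  for (thr in 0:4) {
    pg <- build_product_graph(ga, gb, dimension = 2, threshold = thr)
    if (!is.null(prev_edges)) expect_true(all(pg$adjacency >= prev_edges))
    s <- max_clique(pg)$size
    expect_gte(s, prev_size)
    prev_edges <- pg$adjacency
    prev_size <- s
  }
})

test_that("swapping reference and target yields the same clique size", {
  for (seed in c(41, 42, 43)) {
    ga <- build_graph(make_molecule(fixture_spec(seed = seed, n_heavy = 7)))
    gb <- build_graph(make_molecule(fixture_spec(seed = seed + 50,
                                                 n_heavy = 7)))
    for (dim in c(2, 3)) {
      thr <- if (dim == 2) 1 else 0.8
      s_ab <- max_clique(build_product_graph(ga, gb, dim, thr))$size
      s_ba <- max_clique(build_product_graph(gb, ga, dim, thr))$size
      expect_identical(s_ab, s_ba)
    }
  }
})

test_that("3D product graphs are invariant under rigid motion; 2D under any coordinates", {
  set.seed(7)
  ga <- build_graph(make_molecule(fixture_spec(seed = 61, n_heavy = 7)))
  mb <- make_molecule(fixture_spec(seed = 62, n_heavy = 7))
  gb <- build_graph(mb)
  pg2 <- build_product_graph(ga, gb, 2, 1)
  pg3 <- build_product_graph(ga, gb, 3, 1)
  moved <- build_graph(rigid_transform(mb, random_rotation(), rnorm(3, sd = 8)))
  expect_equal(build_product_graph(ga, moved, 3, 1)$adjacency, pg3$adjacency)
  scrambled <- mb
  scrambled$atoms$x <- rnorm(7) * 10
  scrambled$atoms$y <- rnorm(7) * 10
  scrambled$atoms$z <- rnorm(7) * 10
  expect_equal(build_product_graph(ga, build_graph(scrambled), 2, 1)$adjacency,
               pg2$adjacency)
})
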