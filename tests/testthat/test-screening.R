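test_that("a molecule against itself scores Tanimoto 1 at threshold zero", {
  for (seed in c(10, 11, 12)) {
    g <- build_graph(make_molecule(fixture_spec(seed = seed,
                                                n_heavy = c(4, 9))))
    m2 <- score_pair(g, g, screen_config(dimension = 2, threshold_2d = 0))
    expect_identical(m2$tanimoto, 1)
    expect_identical(m2$c, g$n)
    m3 <- score_pair(g, g, screen_config(dimension = 3, threshold_3d = 0))
    expect_identical(m3$tanimoto, 1)
  }
})

test_that("benzene vs toluene at 2D threshold 0 maps the ring: c = 6, Tc = 6/7", {
  ref <- build_graph(benzene_molecule())
  tgt <- build_graph(toluene_molecule())
  m <- score_pair(ref, tgt, screen_config(dimension = 2, threshold_2d = 0))
  expect_identical(m$c, 6L)
  expect_equal(m$tanimoto, 6 / 7)
  # independent confirmation of the clique size on the same product graph
  pg <- build_product_graph(ref, tgt, 2, 0)
  expect_identical(as.integer(igraph_clique_num(pg$adjacency)), 6L)
  # all matched pairs are aromatic carbons; the methyl stays unmatched
  expect_true(all(m$pairs$ref_type == "C.ar"))
  expect_true(all(m$pairs$tgt_serial %in% 1:6))
})

test_that("disjoint type alphabets give Tanimoto 0 with an empty pair table", {
  a <- build_graph(make_molecule(fixture_spec(seed = 1, n_heavy = 5,
                                              type_alphabet = "C.3")))
  b <- build_graph(make_molecule(fixture_spec(seed = 2, n_heavy = 6,
                                              type_alphabet = "O.2")))
  m <- score_pair(a, b, screen_config())
  expect_identical(m$tanimoto, 0)
  expect_identical(m$c, 0L)
  expect_equal(nrow(m$pairs), 0L)
})

test_that("Tanimoto stays in [0, 1] and hits 1 only on full double cover", {
  set.seed(5)
  for (i in 1:20) {
    a <- build_graph(make_molecule(fixture_spec(seed = 300 + i,
                                                n_heavy = c(3, 8))))
    b <- build_graph(make_molecule(fixture_spec(seed = 400 + i,
                                                n_heavy = c(3, 8))))
    m <- score_pair(a, b, screen_config(dimension = 2, threshold_2d = 1))
    expect_gte(m$tanimoto, 0)
    expect_lte(m$tanimoto, 1)
    expect_identical(m$tanimoto == 1, m$c == m$n_ref && m$c == m$n_tgt)
  }
})

test_that("screening ranks the reference copy first and orders scores", {
  spec <- fixture_spec(seed = 21, n_heavy = c(5, 9))
  lib <- make_library(spec, 15)
  ref <- lib[[4]]
  rep <- screen_library(ref, lib, screen_config(dimension = 2,
                                                threshold_2d = 1,
                                                top_k = 10, workers = 1))
  expect_identical(rep$hits$name[1], ref$name)
  expect_identical(rep$hits$tanimoto[1], 1)
  expect_true(all(diff(rep$hits$tanimoto) <= 0))
  expect_identical(rep$hits$rank, seq_len(nrow(rep$hits)))
  expect_lte(length(unique(rep$hits$name)), 10L)
})

test_that("screen_library equals sequential per-pair scoring", {
  spec <- fixture_spec(seed = 33, n_heavy = c(4, 8))
  lib <- make_library(spec, 20)
  ref <- lib[[1]]
  cfg <- screen_config(dimension = 2, threshold_2d = 1, top_k = 50,
                       workers = 1)
  rep <- screen_library(ref, lib, cfg)
  rg <- build_graph(ref)
  serial <- vapply(lib, function(m) {
    score_pair(rg, build_graph(m), cfg)$tanimoto
  }, numeric(1))
  expected <- sort(serial, decreasing = TRUE)
  expect_equal(rep$hits$tanimoto, expected)
})

test_that("worker count does not change the report", {
  spec <- fixture_spec(seed = 55, n_heavy = c(4, 8))
  lib <- make_library(spec, 16)
  cfg1 <- screen_config(dimension = 2, threshold_2d = 1, workers = 1)
  cfg4 <- screen_config(dimension = 2, threshold_2d = 1, workers = 4)
  r1 <- screen_library(lib[[2]], lib, cfg1)
  r4 <- screen_library(lib[[2]], lib, cfg4)
  expect_identical(r1$hits, r4$hits)
})

test_that("permuting the library leaves ranked scores unchanged", {
  spec <- fixture_spec(seed = 71, n_heavy = c(4, 8))
  lib <- make_library(spec, 12)
  cfg <- screen_config(dimension = 2, threshold_2d = 1, workers = 1)
  base <- screen_library(lib[[1]], lib, cfg)
  set.seed(2)
  perm <- sample(seq_along(lib))
  shuffled <- lib[perm]
  for (i in seq_along(shuffled)) shuffled[[i]]$record_index <- i - 1L
  again <- screen_library(lib[[1]], shuffled, cfg)
  expect_equal(again$hits$tanimoto, base$hits$tanimoto)
  expect_setequal(again$hits$name, base$hits$name)
})

test_that("2D reports ignore coordinates entirely", {
  spec <- fixture_spec(seed = 81, n_heavy = c(4, 8))
  lib <- make_library(spec, 10)
  cfg <- screen_config(dimension = 2, threshold_2d = 1, workers = 1)
  base <- screen_library(lib[[1]], lib, cfg)
  set.seed(3)
  scrambled <- lapply(lib, function(m) {
    n <- nrow(m$atoms)
    m$atoms$x <- round(rnorm(n, sd = 10), 4)
    m$atoms$y <- round(rnorm(n, sd = 10), 4)
    m$atoms$z <- round(rnorm(n, sd = 10), 4)
    m
  })
  again <- screen_library(scrambled[[1]], scrambled, cfg)
  expect_identical(dplyr::select(again$hits, -"pairs"),
                   dplyr::select(base$hits, -"pairs"))
})

test_that("3D conformer records group under one name, best conformers kept", {
  spec <- fixture_spec(seed = 91, n_heavy = 6, topology = "chain",
                       jitter_sigma = 0.3, conformers = 3L)
  lib <- make_library(spec, 5)
  expect_length(lib, 15L)
  ref <- lib[[1]]
  cfg <- screen_config(dimension = 3, threshold_3d = 0.5, top_k = 3,
                       conformers_per_molecule = 2L, workers = 1)
  rep <- screen_library(ref, lib, cfg)
  expect_lte(length(unique(rep$hits$name)), 3L)
  expect_true(all(table(rep$hits$name) <= 2L))
  # each compound's retained conformers are its best-scoring records
  cfg_all <- screen_config(dimension = 3, threshold_3d = 0.5, top_k = 100,
                           conformers_per_molecule = 3L, workers = 1)
  all_rep <- screen_library(ref, lib, cfg_all)
  for (nm in unique(rep$hits$name)) {
    kept <- sort(rep$hits$tanimoto[rep$hits$name == nm], decreasing = TRUE)
    full <- sort(all_rep$hits$tanimoto[all_rep$hits$name == nm],
                 decreasing = TRUE)
    expect_equal(kept, full[seq_along(kept)])
  }
})

test_that("a record that cannot form a graph is skipped, not fatal", {
  lib <- make_library(fixture_spec(seed = 17, n_heavy = 5), 4)
  only_h <- new_molecule("ALLH", tibble::tibble(
    serial = 1:2, name = c("H1", "H2"), sybyl_type = "H", element = "H",
    x = c(0, 1), y = 0, z = 0
  ), tibble::tibble(a_serial = 1L, b_serial = 2L, order_label = "1"))
  only_h$record_index <- 4L
  lib <- c(lib, list(only_h))
  expect_warning(
    rep <- screen_library(lib[[1]], lib, screen_config(workers = 1)),
    "skipped"
  )
  expect_identical(rep$skipped_records, 4L)
  expect_identical(rep$n_records, 5L)
  expect_false("ALLH" %in% rep$hits$name)
})

test_that("config validation rejects nonsense", {
  expect_error(screen_config(dimension = 4))
  expect_error(screen_config(threshold_2d = -1))
  expect_error(screen_config(threshold_2d = 0.5))
  expect_error(screen_config(threshold_3d = -0.1))
  expect_error(screen_config(top_k = 0))
})

test_that("tidy/glance/autoplot expose the report as tabular results", {
  lib <- make_library(fixture_spec(seed = 23, n_heavy = c(4, 7)), 8)
  rep <- screen_library(lib[[1]], lib,
                        screen_config(dimension = 2, threshold_2d = 1,
                                      workers = 1))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_false("pairs" %in% names(td))
  expect_true(all(c("rank", "name", "tanimoto") %in% names(td)))
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$best_tanimoto, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
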