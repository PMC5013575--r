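# Deterministic synthetic molecules: every module is testable without any
# external compound database. Generation is a pure function of the spec
# seed; the session RNG state is saved and restored around each draw.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic per-item sub-seed, kept inside 32-bit integer range
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483587)
}

#' Specification for the synthetic-molecule generator
#'
#' @param seed integer; the generator is a pure function of the spec, so the
#'   same seed always reproduces the same molecules.
#' @param n_heavy heavy-atom count, a single value or a `c(min, max)` range
#'   sampled per molecule.
#' @param topology one of `"chain"`, `"tree"`, `"ring"`,
#'   `"ring+substituent"`, or `"random"` (sampled per molecule).
#' @param type_alphabet SYBYL types the heavy atoms are drawn from.
#' @param jitter_sigma Gaussian coordinate noise in Angstroms added on top
#'   of the unit-bond-length embedding (default 0.05, i.e. small geometric
#'   distortion around idealised geometry).
#' @param conformers conformers per molecule in [make_library()] (records
#'   sharing the molecule name with re-drawn geometry).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_heavy = c(4L, 10L),
                         topology = "random",
                         type_alphabet = c("C.3", "C.ar", "N.3", "O.3"),
                         jitter_sigma = 0.05,
                         conformers = 1L) {
  topologies <- c("chain", "tree", "ring", "ring+substituent", "random")
  stopifnot(length(seed) == 1L, topology %in% topologies,
            length(n_heavy) %in% c(1L, 2L), all(n_heavy >= 1L),
            length(type_alphabet) >= 1L, jitter_sigma >= 0, conformers >= 1L)
  if (length(n_heavy) == 1L) n_heavy <- c(n_heavy, n_heavy)
  structure(
    list(seed = as.integer(seed), n_heavy = as.integer(n_heavy),
         topology = topology, type_alphabet = type_alphabet,
         jitter_sigma = jitter_sigma, conformers = as.integer(conformers)),
    class = "fixture_spec"
  )
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# Bond list for a topology; atoms are 1..n. Ring needs n >= 3.
fixture_edges <- function(topology, n) {
  if (topology == "random") {
    candidates <- c("chain", "tree",
                    if (n >= 3L) "ring",
                    if (n >= 4L) "ring+substituent")
    topology <- sample(candidates, 1L)
  }
  edges <- switch(topology,
    chain = if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
            else cbind(integer(0), integer(0)),
    tree = if (n > 1L) {
      parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
      cbind(parent, 2:n)
    } else cbind(integer(0), integer(0)),
    ring = {
      if (n < 3L) stop("a ring needs at least 3 atoms", call. = FALSE)
      cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
    },
    `ring+substituent` = {
      if (n < 4L) stop("ring+substituent needs at least 4 atoms",
                       call. = FALSE)
      r <- max(3L, ceiling(2 * n / 3))
      ring <- cbind(seq_len(r), c(seq_len(r)[-1L], 1L))
      tail_len <- n - r
      tail <- if (tail_len > 0L) {
        cbind(c(1L, if (tail_len > 1L) (r + 1L):(n - 1L)),
              (r + 1L):n)
      } else cbind(integer(0), integer(0))
      rbind(ring, tail)
    },
    stop("unknown topology '", topology, "'", call. = FALSE)
  )
  list(topology = topology, edges = edges)
}

# Unit-bond-length embedding: rings as regular polygons, acyclic parts as
# random-direction walks from the parent atom.
fixture_coords <- function(topology, edges, n, jitter_sigma) {
  xyz <- matrix(0, n, 3L)
  if (startsWith(topology, "ring")) {
    # ring atoms are 1..k where edge (k, 1) closes the cycle
    k <- edges[edges[, 2L] == 1L, 1L][[1L]]
    radius <- 1 / (2 * sin(pi / k))
    ang <- 2 * pi * (seq_len(k) - 1L) / k
    xyz[seq_len(k), ] <- cbind(radius * cos(ang), radius * sin(ang), 0)
    if (n > k) {
      for (i in (k + 1L):n) {
        parent <- edges[edges[, 2L] == i, 1L]
        xyz[i, ] <- xyz[parent, ] + random_unit_vector()
      }
    }
  } else {
    if (n > 1L) {
      for (e in seq_len(nrow(edges))) {
        parent <- edges[e, 1L]
        child <- edges[e, 2L]
        xyz[child, ] <- xyz[parent, ] + random_unit_vector()
      }
    }
  }
  if (jitter_sigma > 0) {
    xyz <- xyz + matrix(stats::rnorm(3 * n, sd = jitter_sigma), n, 3L)
  }
  round(xyz, 4L)  # match the MOL2 write precision, so round trips are exact
}

build_fixture_molecule <- function(spec, name, record_index = 0L,
                                   redraw_coords_only = FALSE) {
  n <- if (spec$n_heavy[1L] == spec$n_heavy[2L]) spec$n_heavy[1L] else
    sample(spec$n_heavy[1L]:spec$n_heavy[2L], 1L)
  fe <- fixture_edges(spec$topology, n)
  types <- sample(spec$type_alphabet, n, replace = TRUE)
  xyz <- fixture_coords(fe$topology, fe$edges, n, spec$jitter_sigma)
  atoms <- tibble::tibble(
    serial = seq_len(n),
    name = paste0(sybyl_element(types), seq_len(n)),
    sybyl_type = types,
    element = sybyl_element(types),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
  )
  bonds <- tibble::tibble(
    a_serial = as.integer(fe$edges[, 1L]),
    b_serial = as.integer(fe$edges[, 2L]),
    order_label = rep("1", nrow(fe$edges))
  )
  new_molecule(name, atoms, bonds, record_index = record_index)
}

#' Generate one synthetic molecule
#'
#' Connected bond topology per the spec, atom types drawn from the spec's
#' alphabet, 3D coordinates from a unit-bond-length embedding plus Gaussian
#' jitter, rounded to the MOL2 write precision so read/write round trips
#' are exact.
#'
#' @param spec a [fixture_spec()].
#' @param name molecule name (default derived from the seed).
#' @return A `mol2_molecule`.
#' @export
#' @examples
#' m <- make_molecule(fixture_spec(seed = 7, n_heavy = 6, topology = "ring"))
#' nrow(m$bonds)  # ring: as many bonds as atoms
make_molecule <- function(spec, name = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.null(name)) name <- sprintf("SYN%08d", spec$seed)
  with_seed(spec$seed, build_fixture_molecule(spec, name))
}

#' Generate a synthetic screening library
#'
#' `n_molecules` compounds named `SYN<i>`, each with `spec$conformers`
#' records (same topology and types, independently re-drawn geometry),
#' conformer records adjacent and in file order.
#'
#' @param spec a [fixture_spec()].
#' @param n_molecules number of distinct compounds.
#' @return List of `mol2_molecule` with sequential `record_index`.
#' @export
make_library <- function(spec, n_molecules) {
  stopifnot(inherits(spec, "fixture_spec"), n_molecules >= 1L)
  out <- vector("list", n_molecules * spec$conformers)
  k <- 0L
  for (i in seq_len(n_molecules)) {
    base_seed <- derive_seed(spec$seed, i)
    # topology/types fixed per compound: conformers differ in geometry only
    base <- with_seed(base_seed,
                      build_fixture_molecule(spec, sprintf("SYN%05d", i)))
    for (j in seq_len(spec$conformers)) {
      k <- k + 1L
      m <- base
      if (j > 1L) {
        n <- nrow(base$atoms)
        edges <- cbind(match(base$bonds$a_serial, base$atoms$serial),
                       match(base$bonds$b_serial, base$atoms$serial))
        topo <- if (any(edges[, 2L] == 1L)) "ring" else "chain"
        xyz <- with_seed(derive_seed(base_seed, j),
                         fixture_coords(topo, edges, n, spec$jitter_sigma))
        m$atoms$x <- xyz[, 1L]
        m$atoms$y <- xyz[, 2L]
        m$atoms$z <- xyz[, 3L]
      }
      m$record_index <- k - 1L
      out[[k]] <- m
    }
  }
  out
}

#' Generate a molecule pair with a planted common substructure
#'
#' Builds two molecules sharing an identical core -- same chain topology,
#' same SYBYL types, same coordinates -- of `core_size` atoms, then
#' decorates each with atoms whose types are absent from the partner
#' molecule (`F`/`Cl` tails on the first, `Br`/`I` on the second).
#' Decoration atoms can never enter the product graph, so at threshold 0
#' (either dimension) the planted core is provably the maximum common
#' substructure: the expected clique size is exactly `core_size`.
#'
#' @param spec a [fixture_spec()]; `n_heavy` bounds the total size of each
#'   molecule (must admit `core_size`), and the core types are drawn from
#'   `type_alphabet`, which must not contain the decoration types.
#' @param core_size planted common-substructure size.
#' @return List with `a`, `b` (`mol2_molecule`) and `expected_c`
#'   (= `core_size`).
#' @export
make_known_mcs_pair <- function(spec, core_size) {
  stopifnot(inherits(spec, "fixture_spec"), core_size >= 1L)
  decor_a <- c("F", "Cl")
  decor_b <- c("Br", "I")
  if (any(c(decor_a, decor_b) %in% spec$type_alphabet)) {
    stop("type_alphabet must not contain the decoration types ",
         "(F, Cl, Br, I): planted-core uniqueness would not be guaranteed",
         call. = FALSE)
  }
  if (core_size > spec$n_heavy[2L]) {
    stop("core_size exceeds the spec's heavy-atom bound", call. = FALSE)
  }

  with_seed(spec$seed, {
    core_types <- sample(spec$type_alphabet, core_size, replace = TRUE)
    core_xyz <- fixture_coords("chain",
                               if (core_size > 1L)
                                 cbind(seq_len(core_size - 1L),
                                       seq_len(core_size - 1L) + 1L)
                               else cbind(integer(0), integer(0)),
                               core_size, spec$jitter_sigma)

    decorate <- function(decor_types, mol_name) {
      n_range <- core_size:spec$n_heavy[2L]
      n_total <- if (length(n_range) == 1L) n_range else sample(n_range, 1L)
      n_extra <- n_total - core_size
      types <- c(core_types, sample(decor_types, n_extra, replace = TRUE))
      xyz <- core_xyz
      edges <- if (core_size > 1L) {
        cbind(seq_len(core_size - 1L), seq_len(core_size - 1L) + 1L)
      } else cbind(integer(0), integer(0))
      if (n_extra > 0L) {
        for (i in seq_len(n_extra)) {
          attach_to <- sample.int(core_size, 1L)
          idx <- core_size + i
          edges <- rbind(edges, c(attach_to, idx))
          xyz <- rbind(xyz, round(xyz[attach_to, ] + random_unit_vector(), 4L))
        }
      }
      n <- core_size + n_extra
      atoms <- tibble::tibble(
        serial = seq_len(n),
        name = paste0(sybyl_element(types), seq_len(n)),
        sybyl_type = types,
        element = sybyl_element(types),
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
      )
      bonds <- tibble::tibble(
        a_serial = as.integer(edges[, 1L]),
        b_serial = as.integer(edges[, 2L]),
        order_label = rep("1", nrow(edges))
      )
      new_molecule(mol_name, atoms, bonds)
    }

    list(
      a = decorate(decor_a, "PLANT_A"),
      b = decorate(decor_b, "PLANT_B"),
      expected_c = as.integer(core_size)
    )
  })
}

#' Benzene with idealised geometry
#'
#' Six aromatic carbons on a regular hexagon (C-C 1.397 Angstroms), six
#' aromatic bonds. Hydrogens are omitted; screening drops them by default
#' anyway.
#'
#' @return A `mol2_molecule`.
#' @export
benzene_molecule <- function() {
  ang <- 2 * pi * (0:5) / 6
  r <- 1.397
  atoms <- tibble::tibble(
    serial = 1:6,
    name = paste0("C", 1:6),
    sybyl_type = "C.ar",
    element = "C",
    x = round(r * cos(ang), 4L),
    y = round(r * sin(ang), 4L),
    z = 0
  )
  bonds <- tibble::tibble(
    a_serial = 1:6, b_serial = c(2:6, 1L), order_label = "ar"
  )
  new_molecule("BENZENE", atoms, bonds)
}

#' Toluene heavy-atom skeleton
#'
#' The benzene ring plus one sp3 methyl carbon bonded to ring atom 1
#' (C-C 1.51 Angstroms). Seven heavy atoms.
#'
#' @return A `mol2_molecule`.
#' @export
toluene_molecule <- function() {
  b <- benzene_molecule()
  ring <- b$atoms
  methyl_dir <- c(ring$x[1L], ring$y[1L], 0) / sqrt(ring$x[1L]^2 + ring$y[1L]^2)
  methyl <- tibble::tibble(
    serial = 7L, name = "C7", sybyl_type = "C.3", element = "C",
    x = round(ring$x[1L] + 1.51 * methyl_dir[1L], 4L),
    y = round(ring$y[1L] + 1.51 * methyl_dir[2L], 4L),
    z = 0
  )
  atoms <- dplyr::bind_rows(ring, methyl)
  bonds <- dplyr::bind_rows(
    b$bonds,
    tibble::tibble(a_serial = 1L, b_serial = 7L, order_label = "1")
  )
  new_molecule("TOLUENE", atoms, bonds)
}

#' A random Erdos-Renyi adjacency matrix
#'
#' Symmetric logical adjacency for solver testing: each of the
#' `choose(n, 2)` undirected edges is present independently with
#' probability `p`.
#'
#' @param n vertex count.
#' @param p edge probability.
#' @return `n` x `n` logical matrix, zero diagonal.
#' @export
random_adjacency <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  if (n >= 2L) {
    up <- which(upper.tri(adj))
    adj[up] <- stats::runif(length(up)) < p
    adj <- adj | t(adj)
  }
  adj
}
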