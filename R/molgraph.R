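#' Build the graph-theoretic view of a molecule
#'
#' Reduces a molecule to the objects the product graph is built from: the
#' kept (heavy-atom) selection, the boolean adjacency over kept atoms, the
#' all-pairs topological distance matrix in covalent-bond counts, and the
#' Euclidean distance matrix in Angstroms. Hydrogens (element `"H"`, which
#' covers SYBYL `"H"`, `"H.spc"`, `"H.t3p"`) are dropped unless
#' `include_h = TRUE`; dummy atoms (`"Du"`, `"Du.C"`, `"LP"`) are always
#' dropped, as are bonds incident to dropped atoms.
#'
#' Topological distances come from breadth-first traversal of the remaining
#' bond graph (unit edge weights); disconnected pairs hold `Inf`. The
#' returned object is treated as immutable: screening builds the reference
#' graph once and reuses it across the whole library.
#'
#' @param mol a `mol2_molecule`.
#' @param include_h keep hydrogen atoms? Default `FALSE` (the usual
#'   screening setting: heavy atoms only).
#' @return An object of class `mol_graph` with fields `source`, `kept`
#'   (row indices into `mol$atoms`), `n`, `serials`, `types`, `adjacency`,
#'   `topo_dist`, `geo_dist`.
#' @export
#' @examples
#' g <- build_graph(benzene_molecule())
#' max(g$topo_dist)  # opposite ring atoms are 3 bonds apart
build_graph <- function(mol, include_h = FALSE) {
  stopifnot(inherits(mol, "mol2_molecule"))
  el <- mol$atoms$element
  drop <- el %in% c("Du", "LP")
  if (!include_h) drop <- drop | el == "H"
  kept <- which(!drop)
  n <- length(kept)
  if (n == 0L) {
    stop(sprintf("molecule '%s' has no atoms left after hydrogen/dummy removal",
                 mol$name), call. = FALSE)
  }

  serials <- mol$atoms$serial[kept]
  idx_of_serial <- stats::setNames(seq_len(n), serials)

  adj <- matrix(FALSE, n, n)
  b <- mol$bonds
  if (nrow(b)) {
    ai <- idx_of_serial[as.character(b$a_serial)]
    bi <- idx_of_serial[as.character(b$b_serial)]
    ok <- !is.na(ai) & !is.na(bi)
    adj[cbind(ai[ok], bi[ok])] <- TRUE
    adj[cbind(bi[ok], ai[ok])] <- TRUE
  }

  topo <- if (n == 1L) {
    matrix(0, 1L, 1L)
  } else {
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::distances(ig)  # unit weights: BFS distances in bond counts
  }
  dimnames(topo) <- NULL

  xyz <- as.matrix(mol$atoms[kept, c("x", "y", "z")])
  geo <- as.matrix(stats::dist(xyz))
  dimnames(geo) <- NULL

  structure(
    list(
      source = mol,
      kept = kept,
      n = n,
      serials = serials,
      types = mol$atoms$sybyl_type[kept],
      atom_names = mol$atoms$name[kept],
      coords = xyz,
      adjacency = adj,
      topo_dist = topo,
      geo_dist = geo
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  n_inf <- sum(!is.finite(x$topo_dist)) / 2
  cat(sprintf("<mol_graph> %s: %d kept atoms, %d bonds%s\n",
              x$source$name, x$n, sum(x$adjacency) / 2,
              if (n_inf > 0) sprintf(", %d disconnected pairs", n_inf) else ""))
  invisible(x)
}

#' Apply a rigid transform to a molecule
#'
#' Maps every atom coordinate through `x -> R x + t`. Connectivity, typing
#' and serials are untouched, so topological properties are invariant and
#' geometric distances are preserved exactly (up to floating point).
#'
#' @param mol a `mol2_molecule`.
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (Angstroms).
#' @return The transformed `mol2_molecule`.
#' @export
rigid_transform <- function(mol, rotation, translation = c(0, 0, 0)) {
  stopifnot(inherits(mol, "mol2_molecule"),
            is.matrix(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
  new_xyz <- sweep(xyz %*% t(rotation), 2L, translation, `+`)
  out <- mol
  out$atoms$x <- new_xyz[, 1L]
  out$atoms$y <- new_xyz[, 2L]
  out$atoms$z <- new_xyz[, 3L]
  out
}

#' A uniformly random rotation matrix
#'
#' QR-based draw from the Haar measure on SO(3); used by tests and the
#' acceptance script to exercise rigid-motion invariance.
#'
#' @return 3x3 rotation matrix, determinant +1.
#' @export
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3L, 3L))
  q <- qr.Q(qr_dec)
  d <- sign(diag(qr.R(qr_dec)))
  d[d == 0] <- 1
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
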