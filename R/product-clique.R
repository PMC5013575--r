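#' Build a 2D or 3D product graph between two molecular graphs
#'
#' The product graph is the substrate of common-substructure detection: its
#' vertices are the type-compatible atom pairs (one atom from the reference,
#' one from the target, with exactly equal SYBYL type strings -- `"C.ar"`
#' never matches `"C.3"`), and its edges connect two pairs whose internal
#' relations agree. Cliques of this graph are exactly the consistent
#' atom-to-atom mappings, so its maximum clique is the maximum common
#' substructure under the chosen metric.
#'
#' The edge rule between vertices `(i, i')` and `(j, j')` requires `i != j`
#' and `i' != j'` (the mapping must be injective) and:
#' * dimension 2: both topological distances finite and
#'   `|topo_ref(i, j) - topo_tgt(i', j')| <= threshold`, in covalent-bond
#'   counts (the maximum allowed shortest path difference). A comparison
#'   touching a disconnected pair fails, even against another disconnected
#'   pair.
#' * dimension 3: `|geo_ref(i, j) - geo_tgt(i', j')| <= threshold`, in
#'   Angstroms (the maximum allowed spatial distance difference).
#'
#' @param ref,tgt `mol_graph` objects built under the same hydrogen policy.
#' @param dimension 2 (topological) or 3 (geometric).
#' @param threshold non-negative; bonds for dimension 2, Angstroms for 3.
#' @return An object of class `product_graph`: `vertices` tibble
#'   (`r`, `t` indices into the kept atoms, plus `type`), logical
#'   `adjacency`, `dimension`, `threshold`, and the two source graphs.
#'   An empty product graph (no type-matched pair) is legal and yields
#'   similarity 0 downstream.
#' @export
build_product_graph <- function(ref, tgt, dimension = 2, threshold = 0) {
  stopifnot(inherits(ref, "mol_graph"), inherits(tgt, "mol_graph"),
            dimension %in% c(2, 3), is.numeric(threshold),
            length(threshold) == 1L, threshold >= 0)

  compat <- outer(ref$types, tgt$types, `==`)
  hit <- which(compat, arr.ind = TRUE)
  # row-major over (r, t): deterministic vertex order
  ord <- order(hit[, 1L], hit[, 2L])
  r_idx <- hit[ord, 1L]
  t_idx <- hit[ord, 2L]
  nv <- length(r_idx)

  vertices <- tibble::tibble(
    r = as.integer(r_idx),
    t = as.integer(t_idx),
    type = ref$types[r_idx]
  )

  if (nv == 0L) {
    adj <- matrix(FALSE, 0L, 0L)
  } else {
    if (dimension == 2) {
      a <- ref$topo_dist[r_idx, r_idx, drop = FALSE]
      b <- tgt$topo_dist[t_idx, t_idx, drop = FALSE]
      ok <- is.finite(a) & is.finite(b) & abs(a - b) <= threshold
    } else {
      a <- ref$geo_dist[r_idx, r_idx, drop = FALSE]
      b <- tgt$geo_dist[t_idx, t_idx, drop = FALSE]
      ok <- abs(a - b) <= threshold
    }
    distinct <- outer(r_idx, r_idx, `!=`) & outer(t_idx, t_idx, `!=`)
    adj <- ok & distinct
    diag(adj) <- FALSE
    dimnames(adj) <- NULL
  }

  structure(
    list(
      vertices = vertices,
      adjacency = adj,
      dimension = as.integer(dimension),
      threshold = threshold,
      ref = ref,
      tgt = tgt
    ),
    class = "product_graph"
  )
}

#' @export
print.product_graph <- function(x, ...) {
  cat(sprintf(
    "<product_graph> %dD, threshold %g: %d vertices, %d edges\n",
    x$dimension, x$threshold, nrow(x$vertices), sum(x$adjacency) / 2))
  invisible(x)
}

as_clique <- function(indices, g = NULL) {
  indices <- sort(as.integer(indices))
  pairs <- if (!is.null(g) && inherits(g, "product_graph")) {
    g$vertices[indices, , drop = FALSE]
  } else {
    NULL
  }
  structure(list(indices = indices, size = length(indices), pairs = pairs),
            class = "mcs_clique")
}

#' @export
print.mcs_clique <- function(x, ...) {
  cat(sprintf("<mcs_clique> size %d\n", x$size))
  invisible(x)
}

clique_adjacency <- function(g) {
  if (inherits(g, "product_graph")) g$adjacency
  else if (is.matrix(g)) {
    storage.mode(g) <- "logical"
    g
  } else stop("expected a product_graph or a logical adjacency matrix",
              call. = FALSE)
}

#' Exact maximum clique
#'
#' Finds a maximum clique with a colouring-bounded branch-and-bound
#' (compiled): vertices are explored in degree-descending order, candidates
#' are greedily coloured at every node and a branch is cut when the current
#' clique plus the colour count cannot beat the incumbent. The search is
#' exact and deterministic -- the same input always returns the same member
#' set (the first maximum clique met in the fixed search order).
#'
#' @param g a `product_graph`, or a symmetric logical adjacency matrix
#'   (useful for testing the solver on arbitrary graphs).
#' @return An `mcs_clique`: sorted vertex `indices`, `size`, and (for
#'   product graphs) the `pairs` tibble of matched atoms.
#' @export
#' @examples
#' pg <- build_product_graph(build_graph(benzene_molecule()),
#'                           build_graph(benzene_molecule()),
#'                           dimension = 2, threshold = 0)
#' max_clique(pg)$size  # 6: the ring maps onto itself
max_clique <- function(g) {
  adj <- clique_adjacency(g)
  as_clique(.max_clique_cpp(adj), g)
}

#' Exact maximum clique by exhaustive search (test oracle)
#'
#' Plain recursive enumeration of cliques with only the trivial
#' size-remaining prune -- no colouring, no ordering heuristics -- kept
#' deliberately independent of [max_clique()] so the two can cross-validate.
#' Guarded to at most 24 vertices.
#'
#' @inheritParams max_clique
#' @return An `mcs_clique`.
#' @export
brute_force_clique <- function(g) {
  adj <- clique_adjacency(g)
  n <- nrow(adj)
  if (n > 24L) {
    stop("brute_force_clique is guarded to <= 24 vertices (got ", n, ")",
         call. = FALSE)
  }
  best <- integer(0)
  cur <- integer(0)
  recurse <- function(cand) {
    if (!length(cand)) {
      if (length(cur) > length(best)) best <<- cur
      return(invisible(NULL))
    }
    while (length(cand)) {
      if (length(cur) + length(cand) <= length(best)) return(invisible(NULL))
      v <- cand[[1L]]
      cand <- cand[-1L]
      cur <<- c(cur, v)
      recurse(cand[adj[v, cand]])
      cur <<- cur[-length(cur)]
    }
  }
  recurse(seq_len(n))
  as_clique(best, g)
}
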