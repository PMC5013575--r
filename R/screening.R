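#' Screening configuration
#'
#' Bundles every option of a screening run. Exactly one of the two
#' thresholds is active, selected by `dimension`.
#'
#' @param dimension 2 for topological screening, 3 for geometric.
#' @param threshold_2d maximum allowed shortest path difference, in covalent
#'   bonds (non-negative integer; default 1).
#' @param threshold_3d maximum allowed spatial distance difference, in
#'   Angstroms (non-negative; default 1.0).
#' @param top_k number of highest-ranking molecules kept in the output
#'   (default 100, the number a screener typically inspects visually).
#' @param conformers_per_molecule in 3D runs, how many conformers of each
#'   compound to keep in the final output (default 1). Conformers are
#'   library records sharing one molecule name. Ignored in 2D, where the
#'   score is conformation-independent.
#' @param include_h consider hydrogen atoms when building molecular and
#'   product graphs? Default `FALSE` (faster, and the usual setting).
#' @param workers CPU cores for the library loop. `NULL` (default) uses all
#'   available cores. Output is identical for every value: work is
#'   partitioned over records and merged in record order before ranking.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(dimension = 2,
                          threshold_2d = 1L,
                          threshold_3d = 1.0,
                          top_k = 100L,
                          conformers_per_molecule = 1L,
                          include_h = FALSE,
                          workers = NULL) {
  stopifnot(dimension %in% c(2, 3),
            is.numeric(threshold_2d), threshold_2d >= 0,
            abs(threshold_2d - round(threshold_2d)) < 1e-9,
            is.numeric(threshold_3d), threshold_3d >= 0,
            is.numeric(top_k), top_k >= 1,
            is.numeric(conformers_per_molecule), conformers_per_molecule >= 1,
            is.logical(include_h))
  if (is.null(workers)) workers <- parallel::detectCores()
  stopifnot(is.numeric(workers), workers >= 1)
  structure(
    list(
      dimension = as.integer(dimension),
      threshold_2d = as.integer(round(threshold_2d)),
      threshold_3d = as.numeric(threshold_3d),
      top_k = as.integer(top_k),
      conformers_per_molecule = as.integer(conformers_per_molecule),
      include_h = include_h,
      workers = as.integer(workers)
    ),
    class = "screen_config"
  )
}

active_threshold <- function(config) {
  if (config$dimension == 2) config$threshold_2d else config$threshold_3d
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "<screen_config> %dD, threshold %s, top_k %d, conformers %d, %s, %d worker(s)\n",
    x$dimension,
    if (x$dimension == 2) paste(x$threshold_2d, "bond(s)")
    else paste(x$threshold_3d, "Angstrom"),
    x$top_k, x$conformers_per_molecule,
    if (x$include_h) "with H" else "heavy atoms only", x$workers))
  invisible(x)
}

#' Score one reference/target pair
#'
#' Builds the product graph under the configured dimension and threshold,
#' solves its maximum clique, and converts the common-substructure size
#' `c` into the graph Tanimoto coefficient
#' `Tc = c / (n_ref + n_tgt - c)` over the kept (heavy) atom counts.
#' `Tc` is 1 exactly when the mapping covers both molecules entirely, and 0
#' when no atom pair matches.
#'
#' @param ref,tgt `mol_graph` objects built under the same `include_h`
#'   policy as `config`.
#' @param config a [screen_config()].
#' @return An object of class `match_result`: `pairs` tibble (`ref_serial`,
#'   `ref_type`, `tgt_serial`, `tgt_type`, plus atom names), `c`, `n_ref`,
#'   `n_tgt`, `tanimoto`.
#' @export
#' @examples
#' ref <- build_graph(benzene_molecule())
#' tgt <- build_graph(toluene_molecule())
#' score_pair(ref, tgt, screen_config(dimension = 2, threshold_2d = 0))
score_pair <- function(ref, tgt, config = screen_config()) {
  stopifnot(inherits(ref, "mol_graph"), inherits(tgt, "mol_graph"),
            inherits(config, "screen_config"))
  pg <- build_product_graph(ref, tgt, config$dimension,
                            active_threshold(config))
  cl <- max_clique(pg)
  match_from_clique(cl, ref, tgt)
}

match_from_clique <- function(cl, ref, tgt) {
  c_size <- cl$size
  pairs <- if (c_size > 0L) {
    tibble::tibble(
      ref_serial = ref$serials[cl$pairs$r],
      ref_name = ref$atom_names[cl$pairs$r],
      ref_type = ref$types[cl$pairs$r],
      tgt_serial = tgt$serials[cl$pairs$t],
      tgt_name = tgt$atom_names[cl$pairs$t],
      tgt_type = tgt$types[cl$pairs$t]
    )
  } else {
    tibble::tibble(
      ref_serial = integer(), ref_name = character(), ref_type = character(),
      tgt_serial = integer(), tgt_name = character(), tgt_type = character()
    )
  }
  tanimoto <- if (c_size == 0L) 0 else c_size / (ref$n + tgt$n - c_size)
  structure(
    list(pairs = pairs, c = c_size, n_ref = ref$n, n_tgt = tgt$n,
         tanimoto = tanimoto),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> c = %d of (%d, %d) atoms, Tanimoto %.4f\n",
              x$c, x$n_ref, x$n_tgt, x$tanimoto))
  invisible(x)
}

#' Screen a library against a reference ligand
#'
#' Scores every record of the library against the reference, groups records
#' sharing a molecule name as conformers of one compound, and ranks
#' compounds by decreasing Tanimoto coefficient.
#'
#' In 2D the score does not depend on the conformation, so each compound
#' keeps a single entry (its lowest record index). In 3D each compound is
#' represented by its best-scoring conformers, up to
#' `conformers_per_molecule`, and the compound's score is the maximum over
#' its conformers. The `top_k` best compounds survive; within the report
#' the retained rows are sorted by Tanimoto descending with ties broken by
#' ascending record index, and `rank` numbers the rows.
#'
#' The record loop runs on `config$workers` cores; partial results are
#' merged in record order before any ranking, so the report is identical
#' for every worker count. A record that fails to yield a usable graph
#' (e.g. it is reduced to zero atoms by hydrogen removal) is skipped with a
#' warning and counted in the report, never fatal.
#'
#' @param ref a `mol2_molecule` (the reference ligand).
#' @param library non-empty list of `mol2_molecule`, e.g. from
#'   [read_mol2()].
#' @param config a [screen_config()].
#' @return An object of class `screen_report`: `hits` tibble (`rank`,
#'   `name`, `record_index`, `tanimoto`, `c`, `n_ref`, `n_tgt`, list-column
#'   `pairs`), the `config`, `reference_name`, `n_records`, and
#'   `skipped_records`.
#' @export
screen_library <- function(ref, library, config = screen_config()) {
  stopifnot(inherits(ref, "mol2_molecule"), length(library) >= 1L)
  if (inherits(library, "mol2_molecule")) library <- list(library)
  ref_graph <- build_graph(ref, include_h = config$include_h)

  score_one <- function(i) {
    mol <- library[[i]]
    tryCatch({
      g <- build_graph(mol, include_h = config$include_h)
      m <- score_pair(ref_graph, g, config)
      list(ok = TRUE, i = i, name = mol$name,
           record_index = mol$record_index, match = m)
    }, error = function(e) {
      list(ok = FALSE, i = i,
           name = if (inherits(mol, "mol2_molecule")) mol$name else NA_character_,
           msg = conditionMessage(e))
    })
  }

  idx <- seq_along(library)
  results <- if (config$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, score_one, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, score_one)
  }
  results <- results[order(vapply(results, `[[`, 1L, "i"))]  # record order

  ok <- vapply(results, `[[`, logical(1), "ok")
  skipped <- which(!ok)
  for (s in skipped) {
    warning(sprintf("record %d ('%s') skipped: %s", s - 1L,
                    results[[s]]$name, results[[s]]$msg), call. = FALSE)
  }
  scored <- results[ok]
  if (length(scored) == 0L) {
    stop("no library record could be scored", call. = FALSE)
  }

  all_rows <- tibble::tibble(
    name = vapply(scored, `[[`, character(1), "name"),
    record_index = vapply(scored, `[[`, integer(1), "record_index"),
    tanimoto = vapply(scored, function(r) r$match$tanimoto, numeric(1)),
    c = vapply(scored, function(r) r$match$c, integer(1)),
    n_ref = vapply(scored, function(r) r$match$n_ref, integer(1)),
    n_tgt = vapply(scored, function(r) r$match$n_tgt, integer(1)),
    pairs = lapply(scored, function(r) r$match$pairs)
  )

  keep_per_name <- if (config$dimension == 3L) config$conformers_per_molecule
                   else 1L
  rows <- all_rows |>
    dplyr::arrange(dplyr::desc(.data$tanimoto), .data$record_index) |>
    dplyr::group_by(.data$name) |>
    dplyr::slice_head(n = keep_per_name) |>
    dplyr::ungroup()

  # compound ranking: best conformer score per name, record-order tie-break
  name_best <- rows |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(best = max(.data$tanimoto),
                     first_record = min(.data$record_index),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$best), .data$first_record)
  keep_names <- name_best$name[seq_len(min(config$top_k, nrow(name_best)))]

  hits <- rows |>
    dplyr::filter(.data$name %in% keep_names) |>
    dplyr::arrange(dplyr::desc(.data$tanimoto), .data$record_index) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1L)

  # 3D: matched-atom RMSD after Kabsch superposition, per retained hit
  by_record <- vapply(library, `[[`, integer(1), "record_index")
  hits$rmsd <- vapply(seq_len(nrow(hits)), function(i) {
    if (config$dimension != 3L || hits$c[[i]] == 0L) return(NA_real_)
    tgt <- library[[match(hits$record_index[[i]], by_record)]]
    superpose_matched(ref, tgt, hits$pairs[[i]])$rmsd
  }, numeric(1))

  structure(
    list(
      hits = hits,
      config = config,
      reference_name = ref$name,
      n_records = length(library),
      skipped_records = as.integer(skipped - 1L)  # 0-based record indices
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, n = 10L, ...) {
  cat(sprintf(
    "<screen_report> reference '%s', %d record(s) screened (%d skipped), %d hit(s)\n",
    x$reference_name, x$n_records, length(x$skipped_records), nrow(x$hits)))
  print(utils::head(dplyr::select(x$hits, -"pairs"), n))
  invisible(x)
}
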