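#' Least-squares superposition over matched atom pairs
#'
#' Kabsch fit: finds the rotation and translation minimising the sum of
#' squared distances between the matched target atoms (moved) and the
#' matched reference atoms (fixed), then reports the RMSD of the matched
#' pairs after the move. The rotation comes from the SVD of the paired
#' covariance with the usual reflection guard (determinant forced to +1).
#' With fewer than 3 pairs the rotation is underdetermined, so the fit
#' degrades to a pure translation of centroids (documented degenerate
#' mode). Zero pairs is a contract error.
#'
#' @param ref,tgt `mol2_molecule` objects.
#' @param pairs tibble (or data frame) with columns `ref_serial` and
#'   `tgt_serial`, e.g. the `pairs` of a `match_result`.
#' @return Object of class `superposition`: `rotation` (3x3, det +1),
#'   `translation` (length 3), `rmsd` (Angstroms over the matched pairs
#'   after the transform), `n_pairs`.
#' @export
superpose_matched <- function(ref, tgt, pairs) {
  stopifnot(inherits(ref, "mol2_molecule"), inherits(tgt, "mol2_molecule"))
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0L) {
    stop("superposition needs at least one matched pair", call. = FALSE)
  }
  p <- atom_coords(ref, pairs$ref_serial)   # fixed
  q <- atom_coords(tgt, pairs$tgt_serial)   # moving
  m <- nrow(p)

  cp <- colMeans(p)
  cq <- colMeans(q)

  if (m < 3L) {
    rot <- diag(3)
  } else {
    h <- crossprod(sweep(q, 2L, cq), sweep(p, 2L, cp))
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  trans <- cp - as.vector(rot %*% cq)
  moved <- sweep(q %*% t(rot), 2L, trans, `+`)
  rmsd <- sqrt(mean(rowSums((moved - p)^2)))

  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd, n_pairs = m),
    class = "superposition"
  )
}

atom_coords <- function(mol, serials) {
  i <- match(serials, mol$atoms$serial)
  if (anyNA(i)) {
    stop("pair references serial(s) absent from '", mol$name, "': ",
         paste(serials[is.na(i)], collapse = ", "), call. = FALSE)
  }
  as.matrix(mol$atoms[i, c("x", "y", "z")])
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pair(s), RMSD %.4f Angstrom\n",
              x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to a whole molecule
#'
#' @param mol a `mol2_molecule` (normally the hit target).
#' @param sp a [superpose_matched()] result.
#' @return The molecule with all atoms moved by the fitted rigid transform.
#' @export
apply_superposition <- function(mol, sp) {
  stopifnot(inherits(sp, "superposition"))
  rigid_transform(mol, sp$rotation, sp$translation)
}

#' Write the ranked similarity list
#'
#' One line per hit: molecule name, a tab, and the Tanimoto coefficient
#' printed with 4 decimals, in descending score order -- nothing else.
#'
#' @param report a `screen_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(report, path) {
  stopifnot(inherits(report, "screen_report"), nrow(report$hits) >= 1L)
  lines <- sprintf("%s\t%.4f", report$hits$name, report$hits$tanimoto)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}

#' Read a ranked similarity list back
#'
#' @param path file written by [write_ranked_list()].
#' @return Tibble with `name` and `tanimoto` (as printed, 4 decimals).
#' @export
read_ranked_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    name = vapply(parts, `[[`, character(1), 1L),
    tanimoto = as.numeric(vapply(parts, `[[`, character(1), 2L))
  )
}

match_comment_lines <- function(match) {
  p <- match$pairs
  sprintf("# %d %s %d %s", p$ref_serial, p$ref_type, p$tgt_serial, p$tgt_type)
}

#' Write an aligned reference/target MOL2 file
#'
#' Writes one MOL2 document holding the reference record first and the hit
#' target second, preceded by a comment section: one `#` line per matched
#' atom pair (`<ref_serial> <ref_type> <tgt_serial> <tgt_type>`, in clique
#' order), plus a `# target_record` line carrying the hit's record index so
#' a run directory can be reloaded. For 3D hits the supplied superposition
#' is applied to the whole target molecule (a viewer needs all atoms
#' moved, not only the matched ones); for 2D hits the target coordinates
#' pass through unchanged.
#'
#' @param ref reference `mol2_molecule`.
#' @param hit_tgt target `mol2_molecule` (the library record).
#' @param match the hit's `match_result`.
#' @param superposition optional [superpose_matched()] result; required
#'   when the screening dimension is 3.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_mol2 <- function(ref, hit_tgt, match, superposition = NULL,
                               path) {
  stopifnot(inherits(ref, "mol2_molecule"),
            inherits(hit_tgt, "mol2_molecule"),
            inherits(match, "match_result"))
  tgt_out <- if (!is.null(superposition)) {
    apply_superposition(hit_tgt, superposition)
  } else {
    hit_tgt
  }
  comments <- c(
    sprintf("# target_record %d", hit_tgt$record_index),
    match_comment_lines(match)
  )
  write_mol2(list(ref, tgt_out), comment_lines = comments, path = path)
  invisible(path)
}

parse_aligned_comments <- function(comment_lines) {
  rec_line <- grep("^# target_record ", comment_lines, value = TRUE)
  record_index <- if (length(rec_line)) {
    as.integer(sub("^# target_record ", "", rec_line[[1L]]))
  } else NA_integer_
  pair_lines <- grep("^# [0-9]+ \\S+ [0-9]+ \\S+$", comment_lines,
                     value = TRUE)
  toks <- strsplit(sub("^# ", "", pair_lines), " ", fixed = TRUE)
  pairs <- tibble::tibble(
    ref_serial = vapply(toks, function(t) as.integer(t[[1L]]), integer(1)),
    ref_type = vapply(toks, `[[`, character(1), 2L),
    tgt_serial = vapply(toks, function(t) as.integer(t[[3L]]), integer(1)),
    tgt_type = vapply(toks, `[[`, character(1), 4L)
  )
  list(record_index = record_index, pairs = pairs)
}
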