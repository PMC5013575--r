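#' Molecule container for Tripos MOL2 records
#'
#' A molecule is an S3 list with a `name` (line 1 of the `@<TRIPOS>MOLECULE`
#' record, preserved verbatim), an `atoms` tibble, a `bonds` tibble and the
#' 0-based `record_index` of the record in its source file.
#'
#' The `atoms` tibble has columns `serial` (the 1-based atom id as printed in
#' the file -- never renumbered by any function in this package), `name`,
#' `sybyl_type` (e.g. `"C.ar"`, `"N.3"`, `"Br"`), `element` (the text before
#' the first `"."` of the SYBYL type) and coordinates `x`, `y`, `z` in
#' Angstroms. The `bonds` tibble has `a_serial`, `b_serial` and the MOL2 bond
#' `order_label` (`"1"`, `"2"`, `"ar"`, `"am"`, ...).
#'
#' @param name molecule name, a single string.
#' @param atoms tibble as described above.
#' @param bonds tibble as described above (may have zero rows).
#' @param record_index 0-based position of the record in its source file.
#' @return An object of class `mol2_molecule`.
#' @export
new_molecule <- function(name, atoms, bonds, record_index = 0L) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  stopifnot(
    is.character(name), length(name) == 1L,
    all(c("serial", "name", "sybyl_type", "element", "x", "y", "z") %in%
          names(atoms)),
    all(c("a_serial", "b_serial", "order_label") %in% names(bonds))
  )
  if (anyDuplicated(atoms$serial)) {
    stop("atom serials must be unique within a molecule", call. = FALSE)
  }
  if (any(!nzchar(atoms$sybyl_type))) {
    stop("every atom needs a non-empty SYBYL type", call. = FALSE)
  }
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  validate_bonds(atoms, bonds)
  structure(
    list(
      name = name,
      atoms = atoms,
      bonds = bonds,
      record_index = as.integer(record_index)
    ),
    class = "mol2_molecule"
  )
}

validate_bonds <- function(atoms, bonds) {
  if (nrow(bonds) == 0L) return(invisible(TRUE))
  if (any(bonds$a_serial == bonds$b_serial)) {
    stop("bond connecting an atom to itself", call. = FALSE)
  }
  known <- atoms$serial
  bad <- !(bonds$a_serial %in% known) | !(bonds$b_serial %in% known)
  if (any(bad)) {
    stop(
      "bond references a missing atom serial: ",
      paste(bonds$a_serial[bad], bonds$b_serial[bad], sep = "-",
            collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(pmin(bonds$a_serial, bonds$b_serial),
               pmax(bonds$a_serial, bonds$b_serial))
  if (anyDuplicated(key)) {
    stop("duplicate undirected bond in record", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.mol2_molecule <- function(x, ...) {
  cat(sprintf("<mol2_molecule> %s: %d atoms, %d bonds (record %d)\n",
              x$name, nrow(x$atoms), nrow(x$bonds), x$record_index))
  invisible(x)
}

#' @export
format.mol2_molecule <- function(x, ...) {
  sprintf("%s (%d atoms)", x$name, nrow(x$atoms))
}

sybyl_element <- function(sybyl_type) sub("\\..*$", "", sybyl_type)

# Normalise read_mol2() input to a character vector of lines. Accepts a file
# path, a single string containing newlines, or an already-split vector.
# CRLF and trailing blank lines are tolerated.
mol2_lines <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    lines <- readLines(path_or_text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(path_or_text, "\n", fixed = TRUE))
  }
  sub("\r$", "", lines)
}

#' Read a Tripos MOL2 file
#'
#' Parses one or more `@<TRIPOS>MOLECULE` records into a list of
#' [new_molecule()] objects, in file order. Atom serials are taken from the
#' file verbatim. Only the MOLECULE, ATOM and BOND record types are
#' interpreted; any other record type (SUBSTRUCTURE, ...) is skipped.
#' Optional ATOM columns (substructure id/name, partial charge) are dropped.
#' `"#"`-prefixed comment lines are collected into the `"comment_lines"`
#' attribute of the result.
#'
#' @param path_or_text a file path, a single string holding a whole MOL2
#'   document, or a character vector of lines.
#' @return List of `mol2_molecule`, with attribute `comment_lines`.
#' @export
#' @examples
#' doc <- write_mol2(list(benzene_molecule()))
#' mols <- read_mol2(doc)
#' mols[[1]]
read_mol2 <- function(path_or_text) {
  lines <- mol2_lines(path_or_text)
  comments <- lines[startsWith(lines, "#")]
  is_marker <- startsWith(lines, "@<TRIPOS>")
  section <- toupper(sub("^@<TRIPOS>", "", lines[is_marker]))
  marker_pos <- which(is_marker)
  mol_starts <- marker_pos[section == "MOLECULE"]
  if (length(mol_starts) == 0L) {
    stop("no @<TRIPOS>MOLECULE record found: empty input", call. = FALSE)
  }

  parse_record <- function(rec_idx, from, to) {
    block <- lines[from:to]
    mk <- which(startsWith(block, "@<TRIPOS>"))
    sec_name <- toupper(sub("^@<TRIPOS>", "", block[mk]))
    sec_end <- c(mk[-1] - 1L, length(block))

    section_body <- function(wanted) {
      i <- match(wanted, sec_name)
      if (is.na(i)) return(character(0))
      body <- if (mk[i] + 1L > sec_end[i]) character(0) else
        block[(mk[i] + 1L):sec_end[i]]
      body <- body[!startsWith(body, "#")]
      body[nzchar(trimws(body))]
    }

    mol_body <- section_body("MOLECULE")
    if (length(mol_body) < 2L) {
      stop(sprintf("record %d: MOLECULE section needs a name and a counts line",
                   rec_idx), call. = FALSE)
    }
    name <- trimws(mol_body[[1L]])
    counts <- suppressWarnings(as.integer(strsplit(trimws(mol_body[[2L]]),
                                                   "\\s+")[[1L]]))
    n_atoms_decl <- counts[1L]
    n_bonds_decl <- if (length(counts) >= 2L) counts[2L] else 0L

    atom_lines <- section_body("ATOM")
    atoms <- parse_atom_lines(atom_lines, rec_idx)
    bond_lines <- section_body("BOND")
    bonds <- parse_bond_lines(bond_lines, rec_idx)

    if (!is.na(n_atoms_decl) && n_atoms_decl != nrow(atoms)) {
      stop(sprintf("record %d: counts line declares %d atoms but %d parsed",
                   rec_idx, n_atoms_decl, nrow(atoms)), call. = FALSE)
    }
    if (!is.na(n_bonds_decl) && n_bonds_decl != nrow(bonds)) {
      stop(sprintf("record %d: counts line declares %d bonds but %d parsed",
                   rec_idx, n_bonds_decl, nrow(bonds)), call. = FALSE)
    }
    new_molecule(name, atoms, bonds, record_index = rec_idx)
  }

  ends <- c(mol_starts[-1] - 1L, length(lines))
  out <- vector("list", length(mol_starts))
  for (k in seq_along(mol_starts)) {
    out[[k]] <- tryCatch(
      parse_record(k - 1L, mol_starts[k], ends[k]),
      error = function(e) {
        stop(sprintf("record %d: %s", k - 1L, conditionMessage(e)),
             call. = FALSE)
      }
    )
  }
  attr(out, "comment_lines") <- comments
  out
}

parse_atom_lines <- function(atom_lines, rec_idx) {
  if (length(atom_lines) == 0L) {
    return(tibble::tibble(
      serial = integer(), name = character(), sybyl_type = character(),
      element = character(), x = double(), y = double(), z = double()
    ))
  }
  toks <- strsplit(trimws(atom_lines), "\\s+")
  n_tok <- lengths(toks)
  bad <- which(n_tok < 6L)
  if (length(bad)) {
    stop(sprintf("malformed ATOM line %d ('%s')", bad[1L],
                 atom_lines[bad[1L]]), call. = FALSE)
  }
  m <- t(vapply(toks, function(tk) tk[1:6], character(6)))
  serial <- suppressWarnings(as.integer(m[, 1L]))
  xyz <- suppressWarnings(apply(m[, 3:5, drop = FALSE], 2L, as.numeric))
  xyz <- matrix(xyz, ncol = 3L)
  bad <- which(is.na(serial) | rowSums(is.na(xyz)) > 0)
  if (length(bad)) {
    stop(sprintf("malformed ATOM line %d ('%s')", bad[1L],
                 atom_lines[bad[1L]]), call. = FALSE)
  }
  if (any(serial < 1L)) {
    stop("ATOM serials must be positive", call. = FALSE)
  }
  tibble::tibble(
    serial = serial,
    name = m[, 2L],
    sybyl_type = m[, 6L],
    element = sybyl_element(m[, 6L]),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
  )
}

parse_bond_lines <- function(bond_lines, rec_idx) {
  if (length(bond_lines) == 0L) {
    return(tibble::tibble(a_serial = integer(), b_serial = integer(),
                          order_label = character()))
  }
  toks <- strsplit(trimws(bond_lines), "\\s+")
  bad <- which(lengths(toks) < 4L)
  if (length(bad)) {
    stop(sprintf("malformed BOND line %d ('%s')", bad[1L],
                 bond_lines[bad[1L]]), call. = FALSE)
  }
  m <- t(vapply(toks, function(tk) tk[1:4], character(4)))
  a <- suppressWarnings(as.integer(m[, 2L]))
  b <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(a) | is.na(b))
  if (length(bad)) {
    stop(sprintf("malformed BOND line %d ('%s')", bad[1L],
                 bond_lines[bad[1L]]), call. = FALSE)
  }
  tibble::tibble(a_serial = a, b_serial = b, order_label = m[, 4L])
}

#' Write molecules as a Tripos MOL2 document
#'
#' Serialises a list of molecules into a multi-record MOL2 document.
#' Coordinates are printed with 4 decimal places, so a read/write/read round
#' trip is the identity on molecules whose coordinates carry at most that
#' precision (everything this package's generator produces). Optional
#' comment lines are emitted `"#"`-prefixed before the first record; the
#' aligned-structure writer uses them to list matched atom pairs.
#'
#' @param molecules non-empty list of `mol2_molecule` (a bare molecule is
#'   accepted and wrapped).
#' @param comment_lines optional character vector; lines not already starting
#'   with `"#"` are prefixed.
#' @param path optional file path; when given the document is also written
#'   there.
#' @return The document as a single string, invisibly when `path` is given.
#' @export
write_mol2 <- function(molecules, comment_lines = NULL, path = NULL) {
  if (inherits(molecules, "mol2_molecule")) molecules <- list(molecules)
  stopifnot(length(molecules) >= 1L)
  header <- if (length(comment_lines)) {
    ifelse(startsWith(comment_lines, "#"), comment_lines,
           paste0("# ", comment_lines))
  } else character(0)
  body <- unlist(lapply(molecules, format_mol2_record))
  doc <- paste(c(header, body), collapse = "\n")
  doc <- paste0(doc, "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # binary: keep LF endings everywhere
    on.exit(close(con))
    writeChar(doc, con, eos = NULL)
    return(invisible(doc))
  }
  doc
}

format_mol2_record <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  atom_lines <- sprintf("%7d %-8s %9.4f %9.4f %9.4f %-8s %3d %-6s %9.4f",
                        a$serial, a$name, a$x, a$y, a$z, a$sybyl_type,
                        1L, "UNL1", 0)
  bond_lines <- if (nrow(b)) {
    sprintf("%6d %5d %5d %-4s", seq_len(nrow(b)), b$a_serial, b$b_serial,
            b$order_label)
  } else character(0)
  c(
    "@<TRIPOS>MOLECULE",
    mol$name,
    sprintf("%5d %5d %5d %5d %5d", nrow(a), nrow(b), 0L, 0L, 0L),
    "SMALL",
    "NO_CHARGES",
    "@<TRIPOS>ATOM",
    atom_lines,
    "@<TRIPOS>BOND",
    bond_lines
  )
}

#' Comment lines of a MOL2 document
#'
#' @param path_or_text as in [read_mol2()].
#' @return Character vector of `"#"`-prefixed lines, possibly empty.
#' @export
mol2_comments <- function(path_or_text) {
  lines <- mol2_lines(path_or_text)
  lines[startsWith(lines, "#")]
}

#' Atom table of a molecule as a tibble
#'
#' Convenience accessor so molecules drop into dplyr pipelines.
#'
#' @param x a `mol2_molecule`.
#' @param ... unused.
#' @export
as_tibble.mol2_molecule <- function(x, ...) {
  tibble::add_column(x$atoms, molecule = x$name, .before = 1L)
}
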