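# Run-directory management: a completed screen is written as a ranked list,
# one aligned MOL2 per hit, and a flat key-value manifest sufficient to
# reload the run. Output files are byte-stable across repeated runs and
# worker counts; only the log carries timestamps.

ranked_list_file <- "ranked_list.txt"
manifest_file <- "manifest.txt"
log_file <- "run.log"

fmt_num <- function(x) {
  if (is.na(x)) "NA" else sprintf("%.17g", x)
}

#' Write a completed screening run to a directory
#'
#' Creates `ranked_list.txt` (see [write_ranked_list()]), one
#' `<rank>_<name>.mol2` aligned file per hit (see [write_aligned_mol2()];
#' for 3D runs the target is superposed onto the reference over the matched
#' atoms first, and the matched-atom RMSD is recorded in the file's comment
#' section), and `manifest.txt`, a flat `key: value` file echoing the
#' configuration and inputs so the directory can be reloaded with
#' [load_run()].
#'
#' @param report a `screen_report`.
#' @param ref the reference `mol2_molecule` used for the run.
#' @param library the screened library (list of `mol2_molecule`).
#' @param out_dir output directory, created if needed.
#' @param reference_path,library_path provenance strings for the manifest.
#' @return `out_dir`, invisibly.
#' @export
save_run <- function(report, ref, library, out_dir,
                     reference_path = "", library_path = "") {
  stopifnot(inherits(report, "screen_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ranked_list(report, file.path(out_dir, ranked_list_file))

  by_record <- vapply(library, `[[`, integer(1), "record_index")
  hits <- report$hits
  for (i in seq_len(nrow(hits))) {
    tgt <- library[[match(hits$record_index[[i]], by_record)]]
    match_res <- structure(
      list(pairs = hits$pairs[[i]], c = hits$c[[i]],
           n_ref = hits$n_ref[[i]], n_tgt = hits$n_tgt[[i]],
           tanimoto = hits$tanimoto[[i]]),
      class = "match_result"
    )
    sp <- NULL
    if (report$config$dimension == 3L && match_res$c > 0L) {
      sp <- superpose_matched(ref, tgt, match_res$pairs)
    }
    path <- file.path(out_dir,
                      sprintf("%d_%s.mol2", hits$rank[[i]], hits$name[[i]]))
    tgt_out <- if (!is.null(sp)) apply_superposition(tgt, sp) else tgt
    rmsd <- if (!is.null(hits$rmsd)) hits$rmsd[[i]] else
      if (is.null(sp)) NA_real_ else sp$rmsd
    comments <- c(
      sprintf("# target_record %d", tgt$record_index),
      sprintf("# rmsd %s", fmt_num(rmsd)),
      match_comment_lines(match_res)
    )
    write_mol2(list(ref, tgt_out), comment_lines = comments, path = path)
  }

  cfg <- report$config
  manifest <- c(
    sprintf("reference_name: %s", report$reference_name),
    sprintf("reference_path: %s", reference_path),
    sprintf("library_path: %s", library_path),
    sprintf("n_records: %d", report$n_records),
    sprintf("skipped_records: %s",
            paste(report$skipped_records, collapse = ",")),
    sprintf("dimension: %d", cfg$dimension),
    sprintf("threshold_2d: %d", cfg$threshold_2d),
    sprintf("threshold_3d: %s", fmt_num(cfg$threshold_3d)),
    sprintf("top_k: %d", cfg$top_k),
    sprintf("conformers_per_molecule: %d", cfg$conformers_per_molecule),
    sprintf("include_h: %s", cfg$include_h),
    sprintf("workers: %d", cfg$workers)
  )
  con <- file(file.path(out_dir, manifest_file), open = "wb")
  writeChar(paste0(paste(manifest, collapse = "\n"), "\n"), con, eos = NULL)
  close(con)
  invisible(out_dir)
}

read_manifest <- function(dir) {
  path <- file.path(dir, manifest_file)
  if (!file.exists(path)) {
    stop("not a loadable run directory: missing ", manifest_file,
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  key <- sub(":.*$", "", lines)
  val <- sub("^[^:]*: ?", "", lines)
  stats::setNames(as.list(val), key)
}

#' Reload a screening run from its output directory
#'
#' Reconstructs the `screen_report` from the manifest, the ranked list and
#' the aligned MOL2 files: hit names and ranks come from the file names,
#' matched pairs from the `#` comment sections, and the Tanimoto
#' coefficients are recomputed exactly from the clique size and the two
#' kept-atom counts (re-derived under the manifest's hydrogen policy), so a
#' freshly saved run reloads to a report equal to the in-memory one.
#'
#' @param dir a directory written by [save_run()] or [run_screen()].
#' @return A `screen_report`.
#' @export
load_run <- function(dir) {
  man <- read_manifest(dir)
  if (!file.exists(file.path(dir, ranked_list_file))) {
    stop("not a loadable run directory: missing ", ranked_list_file,
         call. = FALSE)
  }
  needed <- c("dimension", "threshold_2d", "threshold_3d", "top_k",
              "conformers_per_molecule", "include_h", "workers",
              "reference_name", "n_records")
  missing_keys <- setdiff(needed, names(man))
  if (length(missing_keys)) {
    stop("corrupt manifest: missing ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  config <- screen_config(
    dimension = as.integer(man$dimension),
    threshold_2d = as.integer(man$threshold_2d),
    threshold_3d = as.numeric(man$threshold_3d),
    top_k = as.integer(man$top_k),
    conformers_per_molecule = as.integer(man$conformers_per_molecule),
    include_h = as.logical(man$include_h),
    workers = as.integer(man$workers)
  )

  files <- list.files(dir, pattern = "^[0-9]+_.*\\.mol2$")
  ranks <- as.integer(sub("_.*$", "", files))
  files <- files[order(ranks)]
  ranks <- sort(ranks)

  rows <- lapply(seq_along(files), function(k) {
    path <- file.path(dir, files[[k]])
    mols <- read_mol2(path)
    if (length(mols) != 2L) {
      stop("aligned file ", files[[k]], " does not hold 2 records",
           call. = FALSE)
    }
    info <- parse_aligned_comments(attr(mols, "comment_lines"))
    rmsd_line <- grep("^# rmsd ", attr(mols, "comment_lines"), value = TRUE)
    rmsd <- if (length(rmsd_line)) {
      suppressWarnings(as.numeric(sub("^# rmsd ", "", rmsd_line[[1L]])))
    } else NA_real_
    ref <- mols[[1L]]
    tgt <- mols[[2L]]
    rg <- build_graph(ref, include_h = config$include_h)
    tg <- build_graph(tgt, include_h = config$include_h)
    p <- info$pairs
    pairs <- tibble::tibble(
      ref_serial = p$ref_serial,
      ref_name = ref$atoms$name[match(p$ref_serial, ref$atoms$serial)],
      ref_type = p$ref_type,
      tgt_serial = p$tgt_serial,
      tgt_name = tgt$atoms$name[match(p$tgt_serial, tgt$atoms$serial)],
      tgt_type = p$tgt_type
    )
    c_size <- nrow(pairs)
    tibble::tibble(
      rank = ranks[[k]],
      name = tgt$name,
      record_index = info$record_index,
      tanimoto = if (c_size == 0L) 0 else c_size / (rg$n + tg$n - c_size),
      c = c_size,
      n_ref = rg$n,
      n_tgt = tg$n,
      pairs = list(pairs),
      rmsd = rmsd
    )
  })
  hits <- dplyr::arrange(dplyr::bind_rows(rows), .data$rank)

  skipped <- if (is.null(man$skipped_records) ||
                 !nzchar(man$skipped_records)) {
    integer(0)
  } else {
    as.integer(strsplit(man$skipped_records, ",", fixed = TRUE)[[1L]])
  }

  structure(
    list(
      hits = hits,
      config = config,
      reference_name = man$reference_name,
      n_records = as.integer(man$n_records),
      skipped_records = skipped
    ),
    class = "screen_report"
  )
}

cli_option_list <- function() {
  list(
    optparse::make_option(c("-R", "--reference"), type = "character",
                          help = "Reference ligand (MOL2)"),
    optparse::make_option(c("-T", "--library"), type = "character",
                          help = "Target library (multi-record MOL2)"),
    optparse::make_option(c("-d", "--dimension"), type = "integer",
                          default = 2L, help = "2 or 3 [default %default]"),
    optparse::make_option("--spd", type = "integer", default = NULL,
                          help = "2D: max shortest path difference, bonds [default 1]"),
    optparse::make_option("--tol", type = "double", default = NULL,
                          help = "3D: max spatial distance difference, Angstroms [default 1.0]"),
    optparse::make_option("--top-k", type = "integer", default = 100L,
                          dest = "top_k",
                          help = "Highest-ranking molecules to output [default %default]"),
    optparse::make_option("--conformers", type = "integer", default = 1L,
                          help = "3D: conformers per molecule in the output [default %default]"),
    optparse::make_option("--include-h", action = "store_true",
                          default = FALSE, dest = "include_h",
                          help = "Consider hydrogen atoms [default: off]"),
    optparse::make_option("--workers", type = "integer", default = NULL,
                          help = "CPU cores [default: all available]"),
    optparse::make_option("--out-dir", type = "character",
                          default = "screen_run", dest = "out_dir",
                          help = "Output directory [default %default]")
  )
}

cli_fail <- function(msg) {
  message("error: ", msg)
  2L
}

#' Command-line screening entry point
#'
#' Thin argument-parsing front end over [read_mol2()], [screen_library()]
#' and [save_run()], suitable for `Rscript` wrappers (one ships in
#' `inst/cli/cliquescreen.R`). Validates that the reference and library
#' files exist and parse as MOL2 and that the flags are mutually
#' consistent (`--spd` is 2D-only, `--tol` and `--conformers` 3D-only)
#' before screening; on success populates the output directory with the
#' ranked list, the aligned MOL2 files, the manifest and a log.
#'
#' @param argv character vector of command-line arguments, e.g.
#'   `c("-R", "ref.mol2", "-T", "lib.mol2", "-d", "2")`.
#' @return Exit status, invisibly: 0 on success, 2 on any usage, input or
#'   validation error (the message names the offending path or record).
#' @export
run_screen <- function(argv = commandArgs(trailingOnly = TRUE)) {
  opts <- tryCatch(
    optparse::parse_args(
      optparse::OptionParser(option_list = cli_option_list(),
                             prog = "cliquescreen"),
      args = argv
    ),
    error = function(e) e
  )
  if (inherits(opts, "error")) {
    return(invisible(cli_fail(conditionMessage(opts))))
  }

  if (is.null(opts$reference)) {
    return(invisible(cli_fail("--reference is required")))
  }
  if (is.null(opts$library)) {
    return(invisible(cli_fail("--library is required")))
  }
  if (!opts$dimension %in% c(2L, 3L)) {
    return(invisible(cli_fail("--dimension must be 2 or 3")))
  }
  if (opts$dimension == 2L && !is.null(opts$tol)) {
    return(invisible(cli_fail("--tol applies to 3D screening only (-d 3)")))
  }
  if (opts$dimension == 3L && !is.null(opts$spd)) {
    return(invisible(cli_fail("--spd applies to 2D screening only (-d 2)")))
  }
  if (opts$dimension == 2L && opts$conformers != 1L) {
    return(invisible(cli_fail("--conformers applies to 3D screening only")))
  }
  for (p in c(opts$reference, opts$library)) {
    if (!file.exists(p)) {
      return(invisible(cli_fail(sprintf("file not found: %s", p))))
    }
  }

  parse_or_fail <- function(path) {
    tryCatch(read_mol2(path), error = function(e) e)
  }
  ref_mols <- parse_or_fail(opts$reference)
  if (inherits(ref_mols, "error")) {
    return(invisible(cli_fail(sprintf("invalid mol2 '%s': %s",
                                      opts$reference,
                                      conditionMessage(ref_mols)))))
  }
  lib_mols <- parse_or_fail(opts$library)
  if (inherits(lib_mols, "error")) {
    return(invisible(cli_fail(sprintf("invalid mol2 '%s': %s", opts$library,
                                      conditionMessage(lib_mols)))))
  }

  config <- screen_config(
    dimension = opts$dimension,
    threshold_2d = if (is.null(opts$spd)) 1L else opts$spd,
    threshold_3d = if (is.null(opts$tol)) 1.0 else opts$tol,
    top_k = opts$top_k,
    conformers_per_molecule = opts$conformers,
    include_h = opts$include_h,
    workers = opts$workers
  )

  t0 <- Sys.time()
  report <- tryCatch(
    withCallingHandlers(
      screen_library(ref_mols[[1L]], lib_mols, config),
      warning = function(w) {
        message("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    ),
    error = function(e) e
  )
  if (inherits(report, "error")) {
    return(invisible(cli_fail(conditionMessage(report))))
  }

  save_run(report, ref_mols[[1L]], lib_mols, opts$out_dir,
           reference_path = opts$reference, library_path = opts$library)

  log_lines <- c(
    sprintf("started: %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("reference: %s", opts$reference),
    sprintf("library: %s (%d records, %d skipped)", opts$library,
            report$n_records, length(report$skipped_records)),
    sprintf("hits written: %d", nrow(report$hits))
  )
  writeLines(log_lines, file.path(opts$out_dir, log_file))
  message(sprintf("screened %d record(s); %d hit(s) written to %s",
                  report$n_records, nrow(report$hits), opts$out_dir))
  invisible(0L)
}
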