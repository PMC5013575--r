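#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screening report
#'
#' One row per hit: rank, molecule name, conformer record index, Tanimoto
#' coefficient, common-substructure size `c`, the two kept-atom counts and
#' (3D runs) the matched-atom RMSD. The per-hit atom-pair tables are
#' dropped; reach them through `x$hits$pairs`.
#'
#' @param x a `screen_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.screen_report <- function(x, ...) {
  dplyr::select(x$hits, -"pairs")
}

#' One-row summary of a screening run
#'
#' @param x a `screen_report`.
#' @param ... unused.
#' @return Tibble with the run's headline numbers: records screened and
#'   skipped, hits kept, best and median Tanimoto, dimension and active
#'   threshold.
#' @export
glance.screen_report <- function(x, ...) {
  tibble::tibble(
    reference = x$reference_name,
    n_records = x$n_records,
    n_skipped = length(x$skipped_records),
    n_hits = nrow(x$hits),
    best_tanimoto = max(x$hits$tanimoto),
    median_tanimoto = stats::median(x$hits$tanimoto),
    dimension = x$config$dimension,
    threshold = active_threshold(x$config)
  )
}

#' Plot the similarity ranking of a screening run
#'
#' Lollipop chart of Tanimoto coefficient against rank, the usual first
#' look at a virtual-screening hit list.
#'
#' @param object a `screen_report`.
#' @param max_hits show at most this many top hits (default 50).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.screen_report <- function(object, max_hits = 50L, ...) {
  d <- utils::head(dplyr::select(object$hits, -"pairs"), max_hits)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$tanimoto)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$rank, yend = 0),
                          colour = "grey70") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "rank", y = "Tanimoto coefficient",
      title = sprintf("Similarity ranking vs '%s' (%dD)",
                      object$reference_name, object$config$dimension)
    ) +
    ggplot2::theme_minimal()
}

#' Tidy a single pair comparison
#'
#' @param x a `match_result` from [score_pair()].
#' @param ... unused.
#' @return The matched atom-pair tibble with the Tanimoto coefficient
#'   attached as a column.
#' @export
tidy.match_result <- function(x, ...) {
  tibble::add_column(x$pairs, tanimoto = x$tanimoto)
}

#' @rdname tidy.match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(c = x$c, n_ref = x$n_ref, n_tgt = x$n_tgt,
                 tanimoto = x$tanimoto)
}
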