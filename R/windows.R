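#' Windowed fragment-density profile of one record
#'
#' Bins a record into windows of `width` bp starting every `step` bp
#' (default `step = width`: tumbling, non-overlapping windows; the trailing
#' short window is kept). A fragment is assigned to the window containing
#' its start coordinate; `mean_cut_position` averages the cut coordinates
#' falling in the window (NA when none).
#'
#' @param fragments Fragment tibble for one record (typically the selected
#'   fragments of a digest).
#' @param cuts Integer vector of cut coordinates, or a cut tibble with a
#'   `position` column; may be `NULL` (no mean positions).
#' @param record_length Record length in bp.
#' @param width Window width in bp (default 100 kb).
#' @param step Window step in bp; `step < width` gives sliding windows.
#' @param record_id Label copied into the output.
#' @return A `window_profile` tibble: `record`, `start`, `end`,
#'   `n_fragments`, `mean_cut_position`.
#' @export
window_profile <- function(fragments, cuts = NULL, record_length,
                           width = 100000, step = width,
                           record_id = fragments[["record"]][1] %||% "record") {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  if (length(record_id) == 0 || is.na(record_id)) record_id <- "record"
  if (!is.null(cuts) && is.data.frame(cuts)) cuts <- cuts$position
  starts <- seq(0, max(record_length - 1, 0), by = step)
  bins <- purrr::map(starts, function(s) {
    e <- min(s + width, record_length)
    in_bin_frag <- fragments$start >= s & fragments$start < e
    in_bin_cut <- if (is.null(cuts)) logical(0) else cuts >= s & cuts < e
    tibble::tibble(
      record = record_id,
      start = s,
      end = e,
      n_fragments = sum(in_bin_frag),
      mean_cut_position = if (any(in_bin_cut)) mean(cuts[in_bin_cut]) else NA_real_
    )
  }) |>
    dplyr::bind_rows()
  structure(bins, class = c("window_profile", class(bins)))
}

#' Windowed fragment-density profiles for a whole genome digest
#'
#' Convenience wrapper: digests every record, applies size (and end)
#' selection, and profiles each record with [window_profile()].
#'
#' @inheritParams digest_genome
#' @param width,step Window width and step in bp.
#' @return A `window_profile` tibble over all records.
#' @export
genome_windows <- function(genome, enzymes, min_len = 100, max_len = 600,
                           end_rule = NULL, width = 100000, step = width,
                           boundary_mode = c("cut_offset", "site_start"),
                           terminal_policy = c("include", "exclude"),
                           catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  terminal_policy <- match.arg(terminal_policy)
  enz <- resolve_enzymes(enzymes, catalog)
  if (is.null(end_rule)) {
    end_rule <- if (nrow(enz) == 2) "different_enzymes" else "any"
  }
  out <- purrr::map2(genome$record, genome$sequence, function(id, seq) {
    cuts <- cut_positions(seq, enz, boundary_mode, catalog)
    frags <- enumerate_fragments(cuts, nchar(seq), terminal_policy)
    sel <- select_fragments(frags, min_len, max_len, end_rule)
    window_profile(sel, cuts$position, nchar(seq), width, step, record_id = id)
  }) |>
    dplyr::bind_rows()
  structure(out, class = c("window_profile", class(out)))
}

#' Average per-window fragment count of a chromosome
#'
#' The per-chromosome horizontal reference line of a fragment-density plot.
#'
#' @param bins A `window_profile` tibble (one record).
#' @return Arithmetic mean of `n_fragments` over the windows.
#' @export
chromosome_mean_count <- function(bins) {
  if (nrow(bins) == 0) stop("no windows", call. = FALSE)
  mean(bins$n_fragments)
}

#' Plot a windowed fragment-density profile
#'
#' Fragment count per window along the record, with a dashed horizontal
#' line at the per-record average count.
#'
#' @param object A `window_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_profile
#' @export
autoplot.window_profile <- function(object, ...) {
  means <- dplyr::summarise(tibble::as_tibble(object),
                            mean_count = mean(.data$n_fragments),
                            .by = "record")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$n_fragments)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$mean_count),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~record, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "fragments per window")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
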