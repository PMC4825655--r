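#' Run a grid of digests over enzymes (or pairs) and genomes
#'
#' One digest summary per cell, in the row/column order given. A genome
#' that fails to load marks its column missing (NA) with a warning rather
#' than aborting the grid.
#'
#' @param genomes Named list of genome tibbles, or a named character vector
#'   of FASTA paths.
#' @param rows Enzyme selections, one per matrix row: a list whose elements
#'   are length-1 or length-2 character vectors of enzyme names, or a
#'   character vector with pairs written `"A+B"`.
#' @param ... Conventions passed to [digest_genome()] (`min_len`, `max_len`,
#'   `boundary_mode`, `terminal_policy`, `denominator_mode`, `catalog`).
#' @return A long `coverage_matrix` tibble: `pair`, `genome_id`, the four
#'   fragment metrics, `genome_length`, `igc_percent`. Conventions are
#'   stored in the `"conventions"` attribute. Reshape with
#'   [coverage_wide()], summarise with [summarize_rows()], compare with
#'   [ratio_to_reference()].
#' @export
build_matrix <- function(genomes, rows, ...) {
  if (is.character(genomes)) {
    if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
      names(genomes) <- sub("\\.(fa|fasta)(\\.gz)?$", "", basename(genomes))
    }
    paths <- genomes
    genomes <- purrr::map(paths, function(p) {
      tryCatch(read_genome(p), error = function(e) {
        warning("failed to load genome '", p, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    })
  }
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  if (is.character(rows)) rows <- strsplit(rows, "+", fixed = TRUE)
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    names(rows) <- vapply(rows, paste0, character(1), collapse = "+")
  }

  cells <- purrr::map(names(rows), function(rn) {
    purrr::map(names(genomes), function(gn) {
      g <- genomes[[gn]]
      if (is.null(g)) {
        return(tibble::tibble(pair = rn, genome_id = gn,
                              n_fragments_total = NA_integer_,
                              len_fragments_total = NA_real_,
                              n_fragments_selected = NA_integer_,
                              len_fragments_selected = NA_real_,
                              genome_length = NA_real_,
                              igc_percent = NA_real_))
      }
      s <- suppressWarnings(
        digest_genome(g, rows[[rn]], genome_id = gn, ...)
      )
      dplyr::mutate(tibble::as_tibble(glance(s)), pair = rn, .before = 1) |>
        dplyr::select(-"enzymes")
    }) |>
      dplyr::bind_rows()
  }) |>
    dplyr::bind_rows()

  conv <- list(...)
  structure(cells, class = c("coverage_matrix", class(cells)),
            conventions = conv)
}

#' Reshape a long coverage matrix to table form
#'
#' @param x Long coverage tibble (from [build_matrix()] or
#'   [read_coverage_matrix()]).
#' @param value Column to spread, default `"igc_percent"`.
#' @return Wide tibble: one row per enzyme (pair), one column per genome.
#' @export
coverage_wide <- function(x, value = "igc_percent") {
  tidyr::pivot_wider(tibble::as_tibble(x)[, c("pair", "genome_id", value)],
                     names_from = "genome_id", values_from = dplyr::all_of(value))
}

#' Read a wide coverage table from TSV
#'
#' Expects a first column `pair` and one column per genome; `#` lines are
#' comments. Returns the long `coverage_matrix` form used by
#' [summarize_rows()] and [ratio_to_reference()].
#'
#' @param path TSV path.
#' @return Long `coverage_matrix` tibble with `pair`, `genome_id`,
#'   `igc_percent`.
#' @export
read_coverage_matrix <- function(path) {
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  stopifnot(names(wide)[1] == "pair")
  long <- tidyr::pivot_longer(wide, -"pair", names_to = "genome_id",
                              values_to = "igc_percent")
  structure(long, class = c("coverage_matrix", class(long)))
}

#' Row summaries of a coverage matrix
#'
#' Mean and sample standard deviation (n-1 denominator, matching the
#' printed coverage tables) of each row's non-missing values, plus optional
#' means over declared genome subsets (e.g. plants only).
#'
#' @param x Long coverage tibble with `pair` and `genome_id` columns.
#' @param value Value column to summarise, default `"igc_percent"`.
#' @param groups Named list of genome-id subsets; each adds a
#'   `mean_<name>` column.
#' @return Tibble with `pair`, `n`, `mean`, `sd`, and group-mean columns.
#' @export
summarize_rows <- function(x, value = "igc_percent", groups = NULL) {
  x <- tibble::as_tibble(x)
  v <- rlang::sym(value)
  out <- dplyr::summarise(
    x,
    n = sum(!is.na(!!v)),
    mean = mean(!!v, na.rm = TRUE),
    sd = stats::sd(!!v, na.rm = TRUE),
    .by = "pair"
  )
  out$mean[is.nan(out$mean)] <- NA_real_
  for (g in names(groups)) {
    gm <- dplyr::summarise(
      dplyr::filter(x, .data$genome_id %in% groups[[g]]),
      !!rlang::sym(paste0("mean_", g)) := mean(!!v, na.rm = TRUE),
      .by = "pair"
    )
    out <- dplyr::left_join(out, gm, by = "pair")
  }
  out
}

#' Ratio of each row to a reference row
#'
#' Per-genome ratio of a row's value to the reference row's value in the
#' same genome, and the mean of those per-genome ratios. Genomes where the
#' reference is zero are flagged missing (NA) and excluded from the mean.
#'
#' @param x Long coverage tibble with `pair` and `genome_id` columns.
#' @param reference Row label of the reference (e.g. `"PstI+MspI"`).
#' @param value Value column, default `"igc_percent"`.
#' @return List with `ratios` (long tibble `pair`, `genome_id`, `ratio`)
#'   and `mean_ratio` (tibble `pair`, `mean_ratio`).
#' @export
ratio_to_reference <- function(x, reference, value = "igc_percent") {
  x <- tibble::as_tibble(x)
  if (!reference %in% x$pair) {
    stop("reference row '", reference, "' not present", call. = FALSE)
  }
  ref <- x[x$pair == reference, c("genome_id", value)]
  names(ref)[2] <- ".ref"
  if (all(ref$.ref == 0, na.rm = TRUE)) {
    stop("reference row '", reference, "' is all zero", call. = FALSE)
  }
  joined <- dplyr::left_join(x[, c("pair", "genome_id", value)], ref,
                             by = "genome_id")
  joined$ratio <- ifelse(is.na(joined$.ref) | joined$.ref == 0, NA_real_,
                         joined[[value]] / joined$.ref)
  ratios <- joined[, c("pair", "genome_id", "ratio")]
  means <- dplyr::summarise(ratios, mean_ratio = mean(.data$ratio, na.rm = TRUE),
                            .by = "pair")
  list(ratios = tibble::as_tibble(ratios), mean_ratio = means)
}

#' Heatmap of a coverage matrix
#'
#' @param object Long `coverage_matrix` tibble.
#' @param value Value column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_matrix
#' @export
autoplot.coverage_matrix <- function(object, value = "igc_percent", ...) {
  df <- tibble::as_tibble(object)
  df$pair <- factor(df$pair, levels = rev(unique(df$pair)))
  df$genome_id <- factor(df$genome_id, levels = unique(df$genome_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_id, y = .data$pair,
                                   fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "IgC (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Sweep digestion conventions over a genome
#'
#' Runs the same digest under every combination of `boundary_mode` and
#' `terminal_policy`. Useful for calibrating against published fragment
#' counts when the original convention is unstated: exact equality is
#' expected under the matching convention and the differences between
#' conventions are a few fragments per record.
#'
#' @inheritParams digest_genome
#' @return Tibble with one row per convention combination plus the digest
#'   summary columns.
#' @export
sweep_conventions <- function(genome, enzymes, min_len = 100, max_len = 600,
                              end_rule = NULL,
                              denominator_mode = "all_bases",
                              genome_id = "genome",
                              catalog = enzyme_catalog()) {
  grid <- tidyr::expand_grid(boundary_mode = c("cut_offset", "site_start"),
                             terminal_policy = c("include", "exclude"))
  purrr::pmap(grid, function(boundary_mode, terminal_policy) {
    s <- suppressWarnings(digest_genome(
      genome, enzymes, min_len, max_len, end_rule,
      boundary_mode = boundary_mode, terminal_policy = terminal_policy,
      denominator_mode = denominator_mode, genome_id = genome_id,
      catalog = catalog
    ))
    dplyr::mutate(tibble::as_tibble(glance(s)),
                  boundary_mode = boundary_mode,
                  terminal_policy = terminal_policy, .before = 1)
  }) |>
    dplyr::bind_rows()
}
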