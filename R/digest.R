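# Label used for fragment ends created by a chromosome end rather than a cut.
CHROM_END <- "CHROM_END"

#' Cut coordinates for a single or double digest of one sequence
#'
#' Converts recognition-site matches into inter-base cut coordinates.
#' In `cut_offset` mode (default) the coordinate is the physical top-strand
#' cut: site start + cut offset for forward-orientation sites and
#' site start + (site length - cut offset) for reverse-orientation sites of
#' non-palindromic enzymes. In `site_start` mode the coordinate is the site
#' start itself. Coordinates claimed by both enzymes of a pair carry both
#' labels.
#'
#' @param sequence A single base string.
#' @param enzymes One or two enzymes (names or an enzyme data frame).
#' @param boundary_mode `"cut_offset"` (physical cut) or `"site_start"`.
#' @param catalog Catalog used to resolve enzyme names.
#' @return Tibble with `position` (0-based, sorted, unique) and `enzymes`,
#'   a list-column of the responsible enzyme names.
#' @export
#' @examples
#' cut_positions("CATGCATGCATG", "CviAII")
cut_positions <- function(sequence, enzymes,
                          boundary_mode = c("cut_offset", "site_start"),
                          catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  enz <- dplyr::distinct(resolve_enzymes(enzymes, catalog))
  if (!nrow(enz) %in% c(1L, 2L)) {
    stop("digests use one or two enzymes, got ", nrow(enz), call. = FALSE)
  }
  per_enzyme <- purrr::map(seq_len(nrow(enz)), function(i) {
    sites <- scan_sites_stranded(sequence, enz[i, , drop = FALSE], catalog)
    len <- enz$site_length[i]
    off <- enz$cut_offset[i]
    pos <- if (boundary_mode == "site_start") {
      sites$position
    } else {
      sites$position + ifelse(sites$strand == "+", off, len - off)
    }
    tibble::tibble(position = unique(pos), enzyme = enz$name[i])
  })
  dplyr::bind_rows(per_enzyme) |>
    dplyr::summarise(enzymes = list(sort(unique(.data$enzyme))),
                     .by = "position") |>
    dplyr::arrange(.data$position)
}

#' Enumerate end-labeled fragments between cut coordinates
#'
#' Fragments are the half-open intervals between consecutive cuts. Each side
#' is labeled with the enzyme(s) that produced the cut; with
#' `terminal_policy = "include"` the leading and trailing intervals are also
#' emitted with `CHROM_END` on the outer side. Multiple labels on a shared
#' cut are joined with `,`. Zero-length intervals (a cut at position 0 or at
#' the record end) are suppressed, so fragment lengths are >= 1 and, under
#' the `include` policy, sum exactly to the record length.
#'
#' @param cuts Cut tibble from [cut_positions()] (sorted, deduplicated), or
#'   an integer vector of cut coordinates.
#' @param record_length Length of the record in bp.
#' @param terminal_policy `"include"` or `"exclude"` terminal fragments.
#' @return Tibble with `start`, `end`, `length`, `left_end`, `right_end`.
#' @export
enumerate_fragments <- function(cuts, record_length,
                                terminal_policy = c("include", "exclude")) {
  terminal_policy <- match.arg(terminal_policy)
  if (is.numeric(cuts)) {
    pos <- as.integer(sort(unique(cuts)))
    cuts <- tibble::tibble(position = pos,
                           enzymes = rep(list("cut"), length(pos)))
  }
  if (nrow(cuts) > 0 && max(cuts$position) > record_length) {
    stop("cut position ", max(cuts$position), " beyond record length ",
         record_length, call. = FALSE)
  }
  labels <- vapply(cuts$enzymes, paste0, character(1), collapse = ",")
  bounds <- c(0L, cuts$position, record_length)
  lefts <- c(CHROM_END, labels)
  rights <- c(labels, CHROM_END)
  out <- tibble::tibble(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    left_end = lefts,
    right_end = rights
  )
  out <- dplyr::mutate(out, length = .data$end - .data$start) |>
    dplyr::filter(.data$length > 0)
  if (terminal_policy == "exclude") {
    out <- dplyr::filter(out, .data$left_end != CHROM_END,
                         .data$right_end != CHROM_END)
  }
  dplyr::select(out, "start", "end", "length", "left_end", "right_end")
}

# TRUE when two distinct enzymes can be assigned to the two ends.
# CHROM_END never qualifies; labels are comma-joined sets.
ends_differ <- function(left_end, right_end) {
  purrr::map2_lgl(strsplit(left_end, ",", fixed = TRUE),
                  strsplit(right_end, ",", fixed = TRUE), function(l, r) {
    l <- setdiff(l, CHROM_END)
    r <- setdiff(r, CHROM_END)
    length(l) > 0 && length(r) > 0 && length(union(l, r)) >= 2
  })
}

#' Size-select (and end-select) digestion fragments
#'
#' Keeps fragments with `min_len <= length <= max_len` (bounds inclusive).
#' With `end_rule = "different_enzymes"` (double digests) a fragment is kept
#' only if two distinct enzymes can be assigned to its two ends — the
#' adapter-ligation rule; chromosome ends never qualify. `"any"` is the
#' single-digest rule.
#'
#' @param fragments Fragment tibble from [enumerate_fragments()] or
#'   [digest_fragments()].
#' @param min_len,max_len Inclusive size-selection window in bp.
#' @param end_rule `"any"` or `"different_enzymes"`.
#' @return The selected subset, same columns as the input.
#' @export
select_fragments <- function(fragments, min_len = 100, max_len = 600,
                             end_rule = c("any", "different_enzymes")) {
  end_rule <- match.arg(end_rule)
  if (min_len > max_len) {
    stop("min_len (", min_len, ") > max_len (", max_len, ")", call. = FALSE)
  }
  out <- dplyr::filter(fragments, .data$length >= min_len,
                       .data$length <= max_len)
  if (end_rule == "different_enzymes" && nrow(out) > 0) {
    out <- dplyr::filter(out, ends_differ(.data$left_end, .data$right_end))
  }
  out
}

#' Digest every record of a genome into end-labeled fragments
#'
#' @param genome Genome tibble.
#' @param enzymes One or two enzymes (names or enzyme data frame).
#' @param boundary_mode,terminal_policy See [cut_positions()] and
#'   [enumerate_fragments()].
#' @param catalog Catalog used to resolve enzyme names.
#' @return Fragment tibble with a leading `record` column; fragments never
#'   span record boundaries.
#' @export
digest_fragments <- function(genome, enzymes,
                             boundary_mode = c("cut_offset", "site_start"),
                             terminal_policy = c("include", "exclude"),
                             catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  terminal_policy <- match.arg(terminal_policy)
  purrr::map2(genome$record, genome$sequence, function(id, seq) {
    cuts <- cut_positions(seq, enzymes, boundary_mode, catalog)
    frags <- enumerate_fragments(cuts, nchar(seq), terminal_policy)
    dplyr::mutate(frags, record = id, .before = 1)
  }) |>
    dplyr::bind_rows()
}

#' Cut coordinates for every record of a genome
#'
#' @inheritParams digest_fragments
#' @return Tibble with `record`, `position`, and comma-joined `enzymes`.
#' @export
genome_cuts <- function(genome, enzymes,
                        boundary_mode = c("cut_offset", "site_start"),
                        catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  purrr::map2(genome$record, genome$sequence, function(id, seq) {
    cuts <- cut_positions(seq, enzymes, boundary_mode, catalog)
    tibble::tibble(record = id, position = cuts$position,
                   enzymes = vapply(cuts$enzymes, paste0, character(1),
                                    collapse = ","))
  }) |>
    dplyr::bind_rows()
}

#' Export fragments as BED6
#'
#' Name is `left_label|right_label`, score the fragment length, strand `.`.
#'
#' @param fragments Fragment tibble with a `record` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  stopifnot("record" %in% names(fragments))
  bed <- tibble::tibble(
    chrom = fragments$record,
    start = fragments$start,
    end = fragments$end,
    name = paste0(fragments$left_end, "|", fragments$right_end),
    score = fragments$length,
    strand = "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
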