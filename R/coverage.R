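#' In-silico genome coverage (IgC)
#'
#' IgC is the percentage of a sequenced genome covered by the digestion
#' fragments that pass selection: `100 * selected_length_bp /
#' genome_length_bp`. Values are kept at full precision; use
#' [format_igc()] for 1-decimal table output.
#'
#' @param selected_length_bp Total length (bp) of selected fragments.
#' @param genome_length_bp Genome length (bp); must be positive.
#' @return IgC percentage (numeric, full precision).
#' @export
#' @examples
#' igc(17, 25)
igc <- function(selected_length_bp, genome_length_bp) {
  if (any(genome_length_bp <= 0)) {
    stop("genome_length_bp must be positive", call. = FALSE)
  }
  100 * selected_length_bp / genome_length_bp
}

#' Format IgC for tabular output
#'
#' Half-up rounding to one decimal, the presentation convention of the
#' coverage tables. Internal computation stays full precision.
#'
#' @param x Numeric IgC values.
#' @param digits Decimal places.
#' @return Numeric values rounded half-up.
#' @export
format_igc <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Digest a genome and summarise the fragment metrics
#'
#' Runs a single or double digest over every record, records the four
#' fragment metrics — total fragment count, total fragment length, selected
#' (in-window) fragment count, selected fragment length — summed over all
#' records, and computes IgC. Double digests (two enzymes) select only
#' fragments with two different enzyme ends; single digests keep any ends.
#'
#' @param genome Genome tibble from [read_genome()]/[as_genome()].
#' @param enzymes One or two enzymes (names or an enzyme data frame).
#' @param min_len,max_len Inclusive size-selection window in bp.
#' @param end_rule `"any"`, `"different_enzymes"`, or `NULL` to choose by
#'   the number of enzymes (any for one, different_enzymes for two).
#' @param boundary_mode `"cut_offset"` or `"site_start"`.
#' @param terminal_policy `"include"` or `"exclude"` terminal fragments in
#'   the totals.
#' @param denominator_mode IgC denominator, `"all_bases"` or `"acgt_only"`.
#' @param genome_id Label for the genome in the output.
#' @param catalog Catalog used to resolve enzyme names.
#' @return A one-row `digest_summary` tibble with columns `genome_id`,
#'   `enzymes`, `n_fragments_total`, `len_fragments_total`,
#'   `n_fragments_selected`, `len_fragments_selected`, `genome_length`,
#'   `igc_percent`; the per-record breakdown is attached and available via
#'   [tidy()][generics::tidy].
#' @export
digest_genome <- function(genome, enzymes, min_len = 100, max_len = 600,
                          end_rule = NULL,
                          boundary_mode = c("cut_offset", "site_start"),
                          terminal_policy = c("include", "exclude"),
                          denominator_mode = c("all_bases", "acgt_only"),
                          genome_id = "genome",
                          catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  terminal_policy <- match.arg(terminal_policy)
  denominator_mode <- match.arg(denominator_mode)
  enz <- resolve_enzymes(enzymes, catalog)
  if (!nrow(enz) %in% c(1L, 2L)) {
    stop("digests use one or two enzymes", call. = FALSE)
  }
  if (nrow(enz) == 2 && enz$name[1] == enz$name[2]) {
    warning("enzyme paired with itself: the different-ends rule selects ",
            "no fragments, IgC is 0 by construction", call. = FALSE)
  }
  if (is.null(end_rule)) {
    end_rule <- if (nrow(enz) == 2) "different_enzymes" else "any"
  }
  end_rule <- match.arg(end_rule, c("any", "different_enzymes"))

  per_record <- purrr::map2(genome$record, genome$sequence, function(id, seq) {
    cuts <- cut_positions(seq, enz, boundary_mode, catalog)
    frags <- enumerate_fragments(cuts, nchar(seq), terminal_policy)
    sel <- select_fragments(frags, min_len, max_len, end_rule)
    tibble::tibble(
      record = id,
      n_fragments_total = nrow(frags),
      len_fragments_total = sum(frags$length),
      n_fragments_selected = nrow(sel),
      len_fragments_selected = sum(sel$length)
    )
  }) |>
    dplyr::bind_rows()

  glen <- genome_length(genome, denominator_mode)
  out <- tibble::tibble(
    genome_id = genome_id,
    enzymes = paste0(enz$name, collapse = "+"),
    n_fragments_total = sum(per_record$n_fragments_total),
    len_fragments_total = sum(per_record$len_fragments_total),
    n_fragments_selected = sum(per_record$n_fragments_selected),
    len_fragments_selected = sum(per_record$len_fragments_selected),
    genome_length = glen,
    igc_percent = if (glen > 0) igc(sum(per_record$len_fragments_selected), glen) else 0
  )
  structure(out,
            class = c("digest_summary", class(out)),
            per_record = per_record,
            conventions = list(min_len = min_len, max_len = max_len,
                               end_rule = end_rule,
                               boundary_mode = boundary_mode,
                               terminal_policy = terminal_policy,
                               denominator_mode = denominator_mode))
}

#' @rdname digest_genome
#' @param enzyme A single enzyme (name or one-row data frame).
#' @param ... Passed to [digest_genome()].
#' @export
digest_genome_single <- function(genome, enzyme, ...) {
  enz <- resolve_enzymes(enzyme, catalog = list(...)$catalog %||% enzyme_catalog())
  if (nrow(enz) != 1) stop("digest_genome_single takes one enzyme", call. = FALSE)
  digest_genome(genome, enz, end_rule = "any", ...)
}

#' @rdname digest_genome
#' @param enzyme_a,enzyme_b The two enzymes of the pair.
#' @export
digest_genome_pair <- function(genome, enzyme_a, enzyme_b, ...) {
  catalog <- list(...)$catalog %||% enzyme_catalog()
  enz <- dplyr::bind_rows(resolve_enzymes(enzyme_a, catalog),
                          resolve_enzymes(enzyme_b, catalog))
  if (nrow(enz) != 2) stop("digest_genome_pair takes two enzymes", call. = FALSE)
  digest_genome(genome, enz, end_rule = "different_enzymes", ...)
}

#' Per-record breakdown of a digest summary
#'
#' @param x A `digest_summary` from [digest_genome()].
#' @param ... Unused.
#' @return Tibble of the four fragment metrics per record.
#' @method tidy digest_summary
#' @export
tidy.digest_summary <- function(x, ...) {
  attr(x, "per_record")
}

#' One-row genome-level summary of a digest
#'
#' @param x A `digest_summary` from [digest_genome()].
#' @param ... Unused.
#' @return The summary as a plain one-row tibble.
#' @method glance digest_summary
#' @export
glance.digest_summary <- function(x, ...) {
  out <- x
  attr(out, "per_record") <- NULL
  attr(out, "conventions") <- NULL
  class(out) <- setdiff(class(out), "digest_summary")
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

`%||%` <- function(a, b) if (is.null(a)) b else a
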