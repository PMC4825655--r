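# IUPAC degeneracy map. Genome letters outside A/C/G/T (including N) are
# never matched, so pattern classes expand to plain ACGT only.
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

#' Built-in restriction enzyme catalog
#'
#' Returns the bundled table of restriction enzymes with their IUPAC
#' recognition sequences and top-strand cut offsets (standard REBASE
#' definitions). The offset counts bases from the site start to the cut,
#' so PstI (`CTGCA^G`) has offset 5 and MluCI (`^AATT`) offset 0.
#' Methylation sensitivity and incubation temperature are metadata only;
#' they do not affect digestion.
#'
#' @return A tibble with columns `name`, `recognition`, `cut_offset`,
#'   `site_length`, `methylation_sensitive`, `incubation_temp_c`.
#' @seealso [read_enzyme_tsv()] to load user-defined enzymes.
#' @export
#' @examples
#' enzyme_catalog()
enzyme_catalog <- function() {
  tab <- tibble::tribble(
    ~name,       ~recognition, ~cut_offset, ~methylation_sensitive, ~incubation_temp_c,
    "CviAII",    "CATG",       1L,          TRUE,                   25,
    "NlaIII",    "CATG",       4L,          TRUE,                   37,
    "CviKI-1",   "RGCY",       2L,          FALSE,                  37,
    "MluCI",     "AATT",       0L,          FALSE,                  37,
    "MseI",      "TTAA",       1L,          TRUE,                   37,
    "HinfI",     "GANTC",      1L,          TRUE,                   37,
    "DdeI",      "CTNAG",      1L,          TRUE,                   37,
    "BfaI",      "CTAG",       1L,          TRUE,                   37,
    "TfiI",      "GAWTC",      1L,          TRUE,                   65,
    "HpyCH4IV",  "ACGT",       1L,          TRUE,                   37,
    "MspI",      "CCGG",       1L,          FALSE,                  37,
    "ApeKI",     "GCWGC",      1L,          TRUE,                   75,
    "AvaII",     "GGWCC",      1L,          TRUE,                   37,
    "PstI",      "CTGCAG",     5L,          TRUE,                   37,
    "TaqI",      "TCGA",       1L,          TRUE,                   65,
    "EcoRI",     "GAATTC",     1L,          FALSE,                  37,
    "AluI",      "AGCT",       2L,          TRUE,                   37,
    "RsaI",      "GTAC",       2L,          TRUE,                   37,
    "HaeIII",    "GGCC",       2L,          TRUE,                   37,
    "HhaI",      "GCGC",       3L,          TRUE,                   37,
    "HindIII",   "AAGCTT",     1L,          TRUE,                   37,
    "BamHI",     "GGATCC",     1L,          TRUE,                   37,
    "EcoRV",     "GATATC",     3L,          TRUE,                   37,
    "NotI",      "GCGGCCGC",   2L,          TRUE,                   37,
    "SbfI",      "CCTGCAGG",   6L,          TRUE,                   37
  )
  dplyr::mutate(tab, site_length = nchar(.data$recognition)) |>
    dplyr::relocate("site_length", .after = "cut_offset")
}

#' Read a user enzyme table from TSV
#'
#' Columns: `name`, `recognition`, `cut_offset`, and optionally
#' `methylation_sensitive` and `incubation_temp_c`. Lines starting with `#`
#' are comments. Every row is validated (IUPAC alphabet, cut offset within
#' the site).
#'
#' @param path Path to a tab-separated enzyme file.
#' @return A validated enzyme tibble in the same shape as [enzyme_catalog()].
#' @export
read_enzyme_tsv <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("name", "recognition", "cut_offset")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("enzyme TSV '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  offs <- suppressWarnings(as.integer(raw$cut_offset))
  bad <- which(is.na(offs))
  if (length(bad) > 0) {
    stop("enzyme TSV '", path, "': non-integer cut_offset in data row ",
         bad[1], " (enzyme '", raw$name[bad[1]], "')", call. = FALSE)
  }
  tab <- tibble::tibble(
    name = raw$name,
    recognition = toupper(raw$recognition),
    cut_offset = offs,
    site_length = nchar(raw$recognition),
    methylation_sensitive =
      if ("methylation_sensitive" %in% names(raw))
        as.logical(raw$methylation_sensitive) else NA,
    incubation_temp_c =
      if ("incubation_temp_c" %in% names(raw))
        suppressWarnings(as.numeric(raw$incubation_temp_c)) else NA_real_
  )
  if (anyDuplicated(tab$name)) {
    stop("enzyme TSV '", path, "': duplicated enzyme name(s)", call. = FALSE)
  }
  validate_enzymes(tab, context = paste0("enzyme TSV '", path, "'"))
}

# Validate an enzyme tibble: IUPAC alphabet and 0 <= cut_offset <= site length.
validate_enzymes <- function(enzymes, context = "enzyme table") {
  stopifnot(is.data.frame(enzymes))
  for (i in seq_len(nrow(enzymes))) {
    rec <- enzymes$recognition[i]
    letters_i <- strsplit(rec, "")[[1]]
    bad <- setdiff(letters_i, names(IUPAC_CODES))
    if (length(bad) > 0) {
      stop(context, ", enzyme '", enzymes$name[i],
           "': invalid IUPAC letter(s) ", paste(unique(bad), collapse = ", "),
           " in recognition sequence '", rec, "'", call. = FALSE)
    }
    off <- enzymes$cut_offset[i]
    if (is.na(off) || off < 0 || off > nchar(rec)) {
      stop(context, ", enzyme '", enzymes$name[i],
           "': cut_offset ", off, " outside [0, ", nchar(rec), "]",
           call. = FALSE)
    }
  }
  enzymes
}

#' Resolve enzyme selections against a catalog
#'
#' Accepts enzyme names (looked up in `catalog`) or a data frame of enzyme
#' definitions, and returns a validated enzyme tibble.
#'
#' @param x Character vector of enzyme names, or an enzyme data frame with
#'   `name`, `recognition`, `cut_offset` columns.
#' @param catalog Catalog to resolve names against; defaults to the built-in
#'   [enzyme_catalog()].
#' @return A validated enzyme tibble.
#' @export
resolve_enzymes <- function(x, catalog = enzyme_catalog()) {
  if (is.data.frame(x)) {
    if (!"site_length" %in% names(x)) x$site_length <- nchar(x$recognition)
    if (!"methylation_sensitive" %in% names(x)) x$methylation_sensitive <- NA
    if (!"incubation_temp_c" %in% names(x)) x$incubation_temp_c <- NA_real_
    return(validate_enzymes(tibble::as_tibble(x)))
  }
  stopifnot(is.character(x))
  unknown <- setdiff(x, catalog$name)
  if (length(unknown) > 0) {
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "),
         "; supply them via read_enzyme_tsv() or a data frame", call. = FALSE)
  }
  catalog[match(x, catalog$name), , drop = FALSE]
}

#' Expand an IUPAC pattern to plain ACGT strings
#'
#' @param pattern IUPAC string over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @return Character vector with one element per concrete ACGT word; length
#'   equals the product of per-position degeneracies.
#' @export
#' @examples
#' expand_iupac("GANTC")
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) > 0)
  letters_p <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters_p, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC letter(s) in '", pattern, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  sets <- IUPAC_CODES[letters_p]
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste0, collapse = ""))
}

# Regex with one ACGT character class per pattern position. Ambiguity codes
# in the *genome* (N runs, soft gaps) therefore never match, even pattern N.
iupac_regex <- function(pattern) {
  letters_p <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(letters_p, names(IUPAC_CODES))
  if (length(bad) > 0) {
    stop("invalid IUPAC letter(s) in '", pattern, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  paste0(vapply(IUPAC_CODES[letters_p], function(s) {
    if (length(s) == 1) s else paste0("[", paste0(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Reverse complement of an IUPAC pattern (degeneracy-aware).
revcomp_iupac <- function(pattern) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

# TRUE when the recognition site reads the same on both strands, in which
# case a single forward scan covers the double-stranded molecule.
is_palindromic <- function(pattern) {
  identical(toupper(pattern), revcomp_iupac(pattern))
}

# 0-based start positions of all (possibly overlapping) matches of an IUPAC
# pattern on one strand of `sequence`.
match_starts <- function(sequence, pattern) {
  if (nchar(sequence) == 0) return(integer(0))
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

#' Locate recognition sites on a sequence
#'
#' Scans the forward strand for the enzyme's recognition pattern; for
#' non-palindromic sites the reverse-complement pattern is also scanned on
#' the forward strand and positions are merged and deduplicated. Overlapping
#' matches are all reported. Genome letters outside A/C/G/T (assembly-gap N
#' runs in particular) match no pattern position, including pattern N, so
#' gaps never create sites. Matching is case-insensitive.
#'
#' @param sequence A single base string.
#' @param enzyme Enzyme name or one-row enzyme data frame.
#' @param catalog Catalog used to resolve `enzyme` when given by name.
#' @return Sorted integer vector of 0-based site start positions.
#' @export
#' @examples
#' scan_sites("CATGCATG", "CviAII")
scan_sites <- function(sequence, enzyme, catalog = enzyme_catalog()) {
  scan_sites_stranded(sequence, enzyme, catalog)$position |>
    unique() |>
    sort()
}

# Site starts with orientation: "+" for the recognition pattern itself, "-"
# for its reverse complement (non-palindromic enzymes only).
scan_sites_stranded <- function(sequence, enzyme, catalog = enzyme_catalog()) {
  enz <- resolve_enzymes_one(enzyme, catalog)
  seq_up <- toupper(sequence)
  fwd <- match_starts(seq_up, enz$recognition)
  if (is_palindromic(enz$recognition)) {
    return(tibble::tibble(position = fwd, strand = rep("+", length(fwd))))
  }
  rev <- match_starts(seq_up, revcomp_iupac(enz$recognition))
  out <- tibble::tibble(
    position = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev)))
  )
  dplyr::arrange(dplyr::distinct(out), .data$position, .data$strand)
}

resolve_enzymes_one <- function(enzyme, catalog = enzyme_catalog()) {
  enz <- resolve_enzymes(enzyme, catalog)
  if (nrow(enz) != 1) stop("expected exactly one enzyme", call. = FALSE)
  enz
}
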