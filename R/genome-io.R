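#' Read a genome assembly from FASTA
#'
#' Loads a (possibly gzipped) multi-record FASTA file into a genome tibble.
#' Sequences are uppercased; record order is preserved; the record id is the
#' first whitespace-delimited token of the header.
#'
#' @param path Path to a `.fa`/`.fasta` file, optionally `.gz`.
#' @return A genome tibble with columns `record` (id), `sequence`, `length`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  first <- readChar(con, 1L, useBytes = TRUE)
  close(con)
  if (length(first) == 0 || !nzchar(first)) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  if (first != ">") {
    stop("not FASTA (first byte is not '>'): ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  as_genome(stats::setNames(toupper(as.character(seqs)), ids))
}

#' Build a genome tibble from named sequences
#'
#' @param sequences Named character vector of base strings (names become
#'   record ids) or a data frame with `record` and `sequence` columns.
#' @return A genome tibble (`record`, `sequence`, `length`).
#' @export
as_genome <- function(sequences) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("record", "sequence") %in% names(sequences)))
    out <- tibble::tibble(record = sequences$record,
                          sequence = toupper(sequences$sequence))
  } else {
    stopifnot(is.character(sequences))
    if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
      stop("sequences must be named (record ids)", call. = FALSE)
    }
    out <- tibble::tibble(record = names(sequences),
                          sequence = toupper(unname(sequences)))
  }
  if (anyDuplicated(out$record)) {
    stop("duplicated record id(s) in genome", call. = FALSE)
  }
  dplyr::mutate(out, length = nchar(.data$sequence))
}

#' Write a genome tibble to FASTA
#'
#' @param genome Genome tibble from [read_genome()] or [as_genome()].
#' @param path Output path; `.gz` suffix writes gzip.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(genome$sequence, genome$record))
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Total genome length
#'
#' The IgC denominator. `all_bases` counts every letter including assembly
#' gaps (the reported sequence length, the default); `acgt_only` excludes
#' ambiguity codes for gap-heavy assemblies.
#'
#' @param genome Genome tibble.
#' @param denominator_mode `"all_bases"` or `"acgt_only"`.
#' @return Integer-valued total length in bp.
#' @export
genome_length <- function(genome, denominator_mode = c("all_bases", "acgt_only")) {
  denominator_mode <- match.arg(denominator_mode)
  if (nrow(genome) == 0) return(0)
  if (denominator_mode == "all_bases") {
    sum(nchar(genome$sequence))
  } else {
    sum(vapply(genome$sequence, function(s) {
      sum(stringr::str_count(s, c("A", "C", "G", "T")))
    }, numeric(1), USE.NAMES = FALSE))
  }
}
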