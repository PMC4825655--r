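# Shared fixtures and independent brute-force oracles.

TOY12 <- "CATGCATGCATG"
TOY25 <- "CCCATGCCCCCAATTCCCCCATGCC"

# Position-by-position site scan: substring membership in the IUPAC
# expansion, both orientations, never via the regex scanner.
brute_scan <- function(sequence, recognition) {
  sequence <- toupper(sequence)
  pats <- expand_iupac(recognition)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(recognition)))
  pats <- unique(c(pats, expand_iupac(rc)))
  len <- nchar(recognition)
  n <- nchar(sequence)
  if (n < len) return(integer(0))
  starts <- 0:(n - len)
  hits <- vapply(starts, function(p) {
    substr(sequence, p + 1, p + len) %in% pats
  }, logical(1))
  starts[hits]
}

# Random ACGT(+N) sequence without going through the package generator.
rand_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}

# Oracle fragment slicing: cut coordinates -> lengths, independent of
# enumerate_fragments (plain diff on boundary vector).
brute_fragment_lengths <- function(cut_pos, record_length, include_terminals = TRUE) {
  cut_pos <- sort(unique(cut_pos))
  bounds <- if (include_terminals) {
    unique(c(0, cut_pos, record_length))
  } else {
    cut_pos
  }
  d <- diff(bounds)
  d[d > 0]
}

local_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
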