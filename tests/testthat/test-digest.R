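test_that("cut coordinates follow site start plus offset", {
  cp <- cut_positions(TOY12, "CviAII")
  expect_equal(cp$position, c(1L, 5L, 9L))
  expect_true(all(vapply(cp$enzymes, identical, logical(1), "CviAII")))
  # site_start mode places boundaries at recognition starts instead
  expect_equal(cut_positions(TOY12, "CviAII", boundary_mode = "site_start")$position,
               c(0L, 4L, 8L))
})

test_that("pair digests take the labeled union of cut sets", {
  cp <- cut_positions(TOY25, c("CviAII", "MluCI"))
  expect_equal(cp$position, c(3L, 11L, 20L))
  expect_equal(cp$enzymes, list("CviAII", "MluCI", "CviAII"))

  single_a <- cut_positions(TOY25, "CviAII")$position
  single_b <- cut_positions(TOY25, "MluCI")$position
  expect_equal(cp$position, sort(unique(c(single_a, single_b))))
  expect_gte(nrow(cp), length(single_a))
})

test_that("a coordinate claimed by both enzymes carries both labels", {
  ab <- data.frame(name = c("A", "B"), recognition = c("AACG", "ACGT"),
                   cut_offset = c(2L, 1L))
  # no reverse-complement occurrence here: one shared cut
  cp <- cut_positions("TAACGTC", ab)
  expect_equal(cp$position, 3L)
  expect_equal(cp$enzymes[[1]], c("A", "B"))
  # with a trailing T the reverse-complement CGTT of AACG also cuts (at 5)
  cp2 <- cut_positions("TAACGTT", ab)
  expect_equal(cp2$position, c(3L, 5L))
  expect_equal(cp2$enzymes[[1]], c("A", "B"))
  expect_equal(cp2$enzymes[[2]], "A")
})

test_that("fragment enumeration tiles the record and labels ends", {
  fr <- enumerate_fragments(cut_positions(TOY12, "CviAII"), 12)
  expect_equal(fr$length, c(1, 4, 4, 3))
  expect_equal(fr$left_end[1], "CHROM_END")
  expect_equal(fr$right_end[4], "CHROM_END")
  expect_equal(sum(fr$length), 12)

  fr25 <- enumerate_fragments(cut_positions(TOY25, c("CviAII", "MluCI")), 25)
  expect_equal(nrow(fr25), 4)
  internal <- fr25[fr25$left_end != "CHROM_END" & fr25$right_end != "CHROM_END", ]
  expect_equal(internal$start, c(3, 11))
  expect_equal(internal$length, c(8, 9))
  expect_equal(internal$left_end, c("CviAII", "MluCI"))
  expect_equal(internal$right_end, c("MluCI", "CviAII"))
})

test_that("no cuts yield one whole-record fragment (include) or none (exclude)", {
  none <- cut_positions("AAAAAAAAAA", "CviAII")
  expect_equal(nrow(none), 0)
  fr <- enumerate_fragments(none, 10, "include")
  expect_equal(fr$length, 10)
  expect_equal(fr$left_end, "CHROM_END")
  expect_equal(fr$right_end, "CHROM_END")
  expect_equal(nrow(enumerate_fragments(none, 10, "exclude")), 0)
  expect_error(enumerate_fragments(c(3, 15), 10), "beyond record length")
})

test_that("length conservation holds for arbitrary cut sets", {
  set.seed(11)
  for (i in 1:25) {
    L <- sample(5:200, 1)
    cuts <- sort(unique(sample(0:L, sample(0:6, 1))))
    fr <- enumerate_fragments(cuts, L, "include")
    expect_equal(sum(fr$length), L)
    expect_true(all(fr$length >= 1))
    # tiling without overlap
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])
  }
})

test_that("size selection uses inclusive bounds and the different-ends rule", {
  fr <- enumerate_fragments(cut_positions(TOY12, "CviAII"), 12)
  sel <- select_fragments(fr, 2, 4, "any")
  expect_equal(nrow(sel), 3)
  expect_equal(sum(sel$length), 11)

  fr25 <- enumerate_fragments(cut_positions(TOY25, c("CviAII", "MluCI")), 25)
  sel25 <- select_fragments(fr25, 5, 10, "different_enzymes")
  expect_equal(nrow(sel25), 2)
  expect_equal(sum(sel25$length), 17)

  lens <- tibble::tibble(start = 0, end = c(99, 100, 600, 601),
                         length = c(99, 100, 600, 601),
                         left_end = "A", right_end = "B")
  kept <- select_fragments(lens, 100, 600, "any")
  expect_equal(kept$length, c(100, 600))

  # a single-enzyme digest can never satisfy different ends
  expect_equal(nrow(select_fragments(fr, 1, 100, "different_enzymes")), 0)
  expect_error(select_fragments(fr, 10, 5), "min_len")
})

test_that("different-ends admits any assignment of two distinct enzymes", {
  frag <- function(l, r) tibble::tibble(start = 0, end = 150, length = 150,
                                        left_end = l, right_end = r)
  keep <- function(l, r) nrow(select_fragments(frag(l, r), 100, 600,
                                               "different_enzymes")) == 1
  expect_true(keep("A", "B"))
  expect_false(keep("A", "A"))
  expect_true(keep("A,B", "A"))   # assign B left, A right
  expect_true(keep("A,B", "A,B"))
  expect_false(keep("CHROM_END", "B"))
  expect_false(keep("A", "CHROM_END"))
})

test_that("widening the size window never removes a fragment", {
  set.seed(3)
  s <- rand_seq(4000)
  fr <- enumerate_fragments(cut_positions(s, "CviAII"), nchar(s))
  narrow <- select_fragments(fr, 150, 300)
  wide <- select_fragments(fr, 100, 600)
  expect_true(all(paste(narrow$start, narrow$end) %in% paste(wide$start, wide$end)))
})

test_that("fragment sets match brute-force slicing on random sequences", {
  set.seed(19)
  for (i in 1:10) {
    s <- rand_seq(800, c("A", "C", "G", "T", "N"))
    for (enzyme in c("CviAII", "HinfI", "MspI")) {
      sites <- brute_scan(s, enzyme_catalog()$recognition[enzyme_catalog()$name == enzyme])
      off <- enzyme_catalog()$cut_offset[enzyme_catalog()$name == enzyme]
      oracle <- brute_fragment_lengths(sites + off, nchar(s))
      fr <- enumerate_fragments(cut_positions(s, enzyme), nchar(s))
      expect_equal(fr$length, oracle, info = paste(enzyme, i))
    }
  }
})

test_that("per-record digestion never crosses record boundaries", {
  g <- as_genome(c(r1 = TOY12, r2 = TOY25))
  fr <- digest_fragments(g, "CviAII")
  expect_setequal(unique(fr$record), c("r1", "r2"))
  by_rec <- split(fr, fr$record)
  expect_equal(sum(by_rec$r1$length), 12)
  expect_equal(sum(by_rec$r2$length), 25)
})

test_that("fragments export as BED6 with labeled names", {
  g <- as_genome(c(r1 = TOY25))
  fr <- digest_fragments(g, c("CviAII", "MluCI"))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_fragments_bed(fr, bed)
  lines <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name",
                                              "score", "strand"),
                           show_col_types = FALSE)
  expect_equal(nrow(lines), nrow(fr))
  expect_equal(lines$name[2], "CviAII|MluCI")
  expect_equal(lines$score, fr$length)
})
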