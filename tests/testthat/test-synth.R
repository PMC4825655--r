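test_that("the same spec always yields a byte-identical genome", {
  spec <- synthesis_spec(n_records = 2, record_length = 5000, gc = 0.5, seed = 7)
  g1 <- random_genome(spec)
  g2 <- random_genome(spec)
  expect_identical(g1$sequence, g2$sequence)
  fa1 <- withr::local_tempfile(fileext = ".fa")
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g1, fa1)
  write_genome(g2, fa2)
  expect_identical(readLines(fa1), readLines(fa2))
  # record sub-seeds: adding a record does not reshuffle earlier ones
  g3 <- random_genome(synthesis_spec(n_records = 3, record_length = 5000,
                                     gc = 0.5, seed = 7))
  expect_identical(g3$sequence[1:2], g1$sequence)
})

test_that("planted sites are exactly the sites found, background rejected clean", {
  plants <- tibble::tibble(record = 1L, pos = as.integer(seq(100, 5800, by = 300)),
                           motif = "CATG")
  spec <- synthesis_spec(n_records = 1, record_length = 10000, gc = 0.5,
                         plants = plants, seed = 11)
  g <- random_genome(spec)
  expect_equal(scan_sites(g$sequence[1], "CviAII"), sort(plants$pos))
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  write_plants_tsv(g, sidecar)
  back <- readr::read_tsv(sidecar, show_col_types = FALSE)
  expect_equal(back$pos, plants$pos)
})

test_that("background composition tracks the requested GC fraction", {
  spec <- synthesis_spec(n_records = 1, record_length = 100000, gc = 0.7, seed = 1)
  g <- random_genome(spec)
  n <- 100000
  gc_obs <- sum(stringr::str_count(g$sequence[1], c("G", "C"))) / n
  # binomial bound: 3 SD around 0.7
  expect_lt(abs(gc_obs - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("gap runs become N and reduce or preserve site counts", {
  plants <- tibble::tibble(record = 1L, pos = c(100L, 500L, 900L), motif = "CATG")
  spec_nogap <- synthesis_spec(record_length = 2000, plants = plants, seed = 3)
  spec_gap <- synthesis_spec(record_length = 2000, plants = plants,
                             gaps = tibble::tibble(record = 1L, start = 200L,
                                                   length = 200L),
                             seed = 3)
  expect_error(
    synthesis_spec(record_length = 2000, plants = plants,
                   gaps = tibble::tibble(record = 1L, start = 498L, length = 60L)),
    "overlapping"
  )
  # avoid = character(0) leaves random background sites for the gap to erase
  g0 <- random_genome(spec_nogap, avoid = character(0))
  g1 <- random_genome(spec_gap, avoid = character(0))
  expect_equal(substr(g1$sequence[1], 201, 400), strrep("N", 200))
  expect_lte(length(scan_sites(g1$sequence[1], "CviAII")),
             length(scan_sites(g0$sequence[1], "CviAII")))
})

test_that("spec validation rejects out-of-range plants and overlaps", {
  expect_error(synthesis_spec(record_length = 100,
                              plants = tibble::tibble(record = 1L, pos = 98L,
                                                      motif = "CATG")),
               "outside")
  expect_error(synthesis_spec(record_length = 100,
                              plants = tibble::tibble(record = 1L,
                                                      pos = c(10L, 12L),
                                                      motif = "CATG")),
               "overlapping")
  expect_error(synthesis_spec(record_length = 100,
                              plants = tibble::tibble(record = 1L, pos = 10L,
                                                      motif = "CNTG")),
               "plain ACGT")
})

test_that("single-digest summaries equal the planted-coordinate oracle", {
  plants <- tibble::tibble(record = 1L, pos = as.integer(seq(2000, 7700, by = 300)),
                           motif = "CATG")  # 20 plants inside a 6-kb island
  spec <- synthesis_spec(record_length = 10000, plants = plants, seed = 21)
  g <- random_genome(spec)
  for (tp in c("include", "exclude")) {
    for (bm in c("cut_offset", "site_start")) {
      want <- expected_digest(spec, "CviAII", boundary_mode = bm,
                              terminal_policy = tp, genome = g)
      got <- digest_genome_single(g, "CviAII", boundary_mode = bm,
                                  terminal_policy = tp)
      expect_equal(got$n_fragments_total, want$n_fragments_total, info = paste(tp, bm))
      expect_equal(got$len_fragments_total, want$len_fragments_total)
      expect_equal(got$n_fragments_selected, want$n_fragments_selected)
      expect_equal(got$len_fragments_selected, want$len_fragments_selected)
      expect_equal(got$igc_percent, want$igc_percent)
    }
  }
  # 19 internal ~300 bp fragments are selected
  want <- expected_digest(spec, "CviAII", genome = g)
  expect_equal(want$n_fragments_selected, 19)
})

test_that("pair digests with alternating planted enzymes match the oracle", {
  pos <- as.integer(seq(1000, 8750, by = 250))
  plants <- tibble::tibble(record = 1L, pos = pos,
                           motif = rep(c("CATG", "AATT"), length.out = length(pos)))
  spec <- synthesis_spec(record_length = 10000, plants = plants, seed = 33)
  g <- random_genome(spec)
  want <- expected_digest(spec, c("CviAII", "MluCI"), genome = g)
  got <- digest_genome_pair(g, "CviAII", "MluCI")
  expect_equal(got$n_fragments_selected, want$n_fragments_selected)
  expect_equal(got$igc_percent, want$igc_percent)
  # every internal fragment alternates enzymes, hence is selected
  expect_equal(want$n_fragments_selected, length(pos) - 1)

  # zero plants, terminals excluded: all metrics vanish
  empty <- synthesis_spec(record_length = 4000, seed = 2)
  want0 <- expected_digest(empty, c("CviAII", "MluCI"),
                           terminal_policy = "exclude",
                           genome = random_genome(empty, avoid = c("CATG", "AATT")))
  expect_equal(want0$n_fragments_total, 0)
  expect_equal(want0$igc_percent, 0)
})

test_that("the oracle refuses a background that is not motif-free", {
  spec <- synthesis_spec(record_length = 3000,
                         plants = tibble::tibble(record = 1L, pos = 500L,
                                                 motif = "CATG"),
                         seed = 5)
  dirty <- random_genome(spec, avoid = character(0))  # no rejection applied
  # a 3-kb random sequence almost surely contains extra CATG occurrences
  expect_error(expected_digest(spec, "CviAII", genome = dirty), "oracle invalid")
})
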