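#' Specification for a seeded synthetic genome
#'
#' Describes a reproducible FASTA fixture: i.i.d. background bases at a
#' target GC fraction, recognition motifs planted at known coordinates, and
#' N-gap runs emulating assembly gaps. Coordinates are 0-based; `record`
#' indexes records starting at 1.
#'
#' @param n_records Number of records.
#' @param record_length Length of each record in bp (scalar or one per
#'   record).
#' @param gc Background GC fraction in `[0, 1]`.
#' @param plants Tibble/data frame with `record`, `pos`, `motif`: plain
#'   ACGT motifs overwritten onto the background. Planted intervals must
#'   not overlap each other or gaps.
#' @param gaps Tibble/data frame with `record`, `start`, `length`: runs
#'   overwritten with `N`.
#' @param seed Integer seed; each record derives its own sub-seed so adding
#'   records does not reshuffle earlier ones.
#' @return A `synthesis_spec` list.
#' @export
synthesis_spec <- function(n_records = 1, record_length = 10000, gc = 0.5,
                           plants = NULL, gaps = NULL, seed = 1) {
  stopifnot(n_records >= 1, gc >= 0, gc <= 1)
  record_length <- rep_len(as.integer(record_length), n_records)
  plants <- if (is.null(plants)) {
    tibble::tibble(record = integer(), pos = integer(), motif = character())
  } else tibble::as_tibble(plants)
  gaps <- if (is.null(gaps)) {
    tibble::tibble(record = integer(), start = integer(), length = integer())
  } else tibble::as_tibble(gaps)

  if (nrow(plants) > 0) {
    if (any(grepl("[^ACGT]", plants$motif))) {
      stop("planted motifs must be plain ACGT", call. = FALSE)
    }
    ends <- plants$pos + nchar(plants$motif)
    if (any(plants$record < 1 | plants$record > n_records) ||
        any(plants$pos < 0) || any(ends > record_length[plants$record])) {
      stop("planted motif outside its record", call. = FALSE)
    }
  }
  if (nrow(gaps) > 0) {
    if (any(gaps$record < 1 | gaps$record > n_records) ||
        any(gaps$start < 0) ||
        any(gaps$start + gaps$length > record_length[gaps$record])) {
      stop("gap run outside its record", call. = FALSE)
    }
  }
  iv <- dplyr::bind_rows(
    tibble::tibble(record = plants$record, start = plants$pos,
                   end = plants$pos + nchar(plants$motif), kind = "plant"),
    tibble::tibble(record = gaps$record, start = gaps$start,
                   end = gaps$start + gaps$length, kind = "gap")
  )
  if (nrow(iv) > 1) {
    iv <- dplyr::arrange(iv, .data$record, .data$start)
    same <- iv$record[-1] == iv$record[-nrow(iv)]
    overlap <- iv$start[-1] < iv$end[-nrow(iv)]
    # gap-gap overlaps merge harmlessly; plant overlaps invalidate the oracle
    bad <- same & overlap &
      !(iv$kind[-1] == "gap" & iv$kind[-nrow(iv)] == "gap")
    if (any(bad)) {
      stop("overlapping planted/gap intervals", call. = FALSE)
    }
  }
  structure(list(n_records = n_records, record_length = record_length,
                 gc = gc, plants = plants, gaps = gaps,
                 seed = as.integer(seed)),
            class = "synthesis_spec")
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

record_seed <- function(seed, i) as.integer((seed + i * 9973L) %% 2147483647L)

#' Generate a synthetic genome from a specification
#'
#' Background bases are drawn i.i.d. at the spec's GC fraction, planted
#' motifs are overwritten at their coordinates, then gap runs are set to
#' `N`. Background freedom from the `avoid` motifs (both orientations) is
#' enforced by rejection: any match not identical to a planted interval has
#' its background bases resampled until the sequence is clean, so
#' [scan_sites()] finds exactly the planted occurrences and
#' [expected_digest()] is an exact oracle. The same spec always yields a
#' byte-identical genome.
#'
#' @param spec A [synthesis_spec()].
#' @param avoid IUPAC motifs the background must not contain; defaults to
#'   the planted motifs.
#' @return A genome tibble (records `synth_1`, `synth_2`, ...) with the
#'   plant table attached as attribute `"plants"`.
#' @export
random_genome <- function(spec, avoid = unique(spec$plants$motif)) {
  stopifnot(inherits(spec, "synthesis_spec"))
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
             G = spec$gc / 2, T = (1 - spec$gc) / 2)
  avoid <- unique(toupper(avoid))

  seqs <- vapply(seq_len(spec$n_records), function(i) {
    len <- spec$record_length[i]
    plants_i <- spec$plants[spec$plants$record == i, , drop = FALSE]
    gaps_i <- spec$gaps[spec$gaps$record == i, , drop = FALSE]
    with_local_seed(record_seed(spec$seed, i), {
      chars <- sample(names(probs), len, replace = TRUE, prob = probs)
      for (j in seq_len(nrow(plants_i))) {
        m <- strsplit(plants_i$motif[j], "")[[1]]
        chars[plants_i$pos[j] + seq_along(m)] <- m
      }
      gap_mask <- rep(FALSE, len)
      for (j in seq_len(nrow(gaps_i))) {
        idx <- gaps_i$start[j] + seq_len(gaps_i$length[j])
        chars[idx] <- "N"
        gap_mask[idx] <- TRUE
      }
      plant_mask <- rep(FALSE, len)
      for (j in seq_len(nrow(plants_i))) {
        plant_mask[plants_i$pos[j] + seq_len(nchar(plants_i$motif[j]))] <- TRUE
      }
      planted_iv <- if (nrow(plants_i) > 0) {
        paste0(plants_i$pos, ":", plants_i$pos + nchar(plants_i$motif))
      } else character(0)

      for (iter in seq_len(1000)) {
        seq_str <- paste0(chars, collapse = "")
        unwanted <- integer(0)
        for (motif in avoid) {
          pats <- unique(c(motif, revcomp_iupac(motif)))
          for (pat in pats) {
            for (p in match_starts(seq_str, pat)) {
              key <- paste0(p, ":", p + nchar(pat))
              if (!key %in% planted_iv) {
                unwanted <- c(unwanted, p + seq_len(nchar(pat)))
              }
            }
          }
        }
        unwanted <- unique(unwanted)
        resample <- unwanted[!plant_mask[unwanted] & !gap_mask[unwanted]]
        if (length(unwanted) == 0) break
        if (length(resample) == 0) {
          stop("avoid-motif occurrence inside planted/gap bases; ",
               "cannot keep the background motif-free", call. = FALSE)
        }
        chars[resample] <- sample(names(probs), length(resample),
                                  replace = TRUE, prob = probs)
        if (iter == 1000) stop("background rejection did not converge",
                               call. = FALSE)
      }
      paste0(chars, collapse = "")
    })
  }, character(1))

  g <- as_genome(stats::setNames(seqs, paste0("synth_", seq_along(seqs))))
  attr(g, "plants") <- spec$plants
  attr(g, "spec") <- spec
  g
}

#' Write the planted-coordinate sidecar of a synthetic genome
#'
#' @param genome A genome from [random_genome()].
#' @param path Output TSV path (`record`, `pos`, `motif`).
#' @return `path`, invisibly.
#' @export
write_plants_tsv <- function(genome, path) {
  plants <- attr(genome, "plants")
  if (is.null(plants)) stop("genome has no planted-coordinate table", call. = FALSE)
  readr::write_tsv(plants, path)
  invisible(path)
}

#' Oracle digest summary computed from planted coordinates
#'
#' Computes the digest summary of a synthetic genome purely from the
#' specification's planted coordinates by direct interval arithmetic —
#' independently of the scanning/digestion code paths — for use as a test
#' oracle. Valid only when the background is guaranteed free of the
#' enzymes' motifs (generate with [random_genome()] and an `avoid` set
#' covering the enzymes under test); pass the generated `genome` to have
#' this checked.
#'
#' @param spec The [synthesis_spec()] used to generate the genome.
#' @param enzymes One or two enzymes (names or enzyme data frame).
#' @param min_len,max_len Inclusive size-selection window.
#' @param end_rule `"any"`, `"different_enzymes"`, or `NULL` for the
#'   enzyme-count default.
#' @param boundary_mode,terminal_policy,denominator_mode Digest conventions.
#' @param genome Optional genome generated from `spec`; if given, the
#'   background is verified motif-free (exactly the planted occurrences).
#' @param catalog Catalog used to resolve enzyme names.
#' @return A one-row tibble with the same summary columns as
#'   [digest_genome()].
#' @export
expected_digest <- function(spec, enzymes, min_len = 100, max_len = 600,
                            end_rule = NULL,
                            boundary_mode = c("cut_offset", "site_start"),
                            terminal_policy = c("include", "exclude"),
                            denominator_mode = c("all_bases", "acgt_only"),
                            genome = NULL,
                            catalog = enzyme_catalog()) {
  boundary_mode <- match.arg(boundary_mode)
  terminal_policy <- match.arg(terminal_policy)
  denominator_mode <- match.arg(denominator_mode)
  enz <- resolve_enzymes(enzymes, catalog)
  if (is.null(end_rule)) {
    end_rule <- if (nrow(enz) == 2) "different_enzymes" else "any"
  }
  end_rule <- match.arg(end_rule, c("any", "different_enzymes"))

  expansions <- lapply(enz$recognition, expand_iupac)

  if (!is.null(genome)) {
    for (i in seq_len(nrow(enz))) {
      for (r in seq_len(spec$n_records)) {
        found <- scan_sites(genome$sequence[r], enz[i, , drop = FALSE], catalog)
        keep <- spec$plants$record == r & spec$plants$motif %in% expansions[[i]]
        planted <- sort(spec$plants$pos[keep])
        if (!identical(as.integer(found), as.integer(planted))) {
          stop("background is not motif-free for enzyme '", enz$name[i],
               "' in record ", r, "; oracle invalid", call. = FALSE)
        }
      }
    }
  }

  totals <- c(n_total = 0, len_total = 0, n_sel = 0, len_sel = 0)
  for (r in seq_len(spec$n_records)) {
    len_r <- spec$record_length[r]
    cuts <- list()
    for (i in seq_len(nrow(enz))) {
      keep <- spec$plants$record == r & spec$plants$motif %in% expansions[[i]]
      pos <- spec$plants$pos[keep]
      cc <- if (boundary_mode == "cut_offset") pos + enz$cut_offset[i] else pos
      for (p in cc) {
        key <- as.character(p)
        cuts[[key]] <- sort(unique(c(cuts[[key]], enz$name[i])))
      }
    }
    cpos <- sort(as.integer(names(cuts)))
    labels <- lapply(as.character(cpos), function(k) cuts[[k]])
    bounds <- c(0L, cpos, len_r)
    lefts <- c(list(CHROM_END), labels)
    rights <- c(labels, list(CHROM_END))
    for (k in seq_len(length(bounds) - 1)) {
      flen <- bounds[k + 1] - bounds[k]
      if (flen <= 0) next
      terminal <- identical(lefts[[k]], CHROM_END) ||
        identical(rights[[k]], CHROM_END)
      if (terminal && terminal_policy == "exclude") next
      totals["n_total"] <- totals["n_total"] + 1
      totals["len_total"] <- totals["len_total"] + flen
      in_window <- flen >= min_len && flen <= max_len
      ok_ends <- if (end_rule == "any") TRUE else {
        l <- setdiff(lefts[[k]], CHROM_END)
        rr <- setdiff(rights[[k]], CHROM_END)
        length(l) > 0 && length(rr) > 0 && length(union(l, rr)) >= 2
      }
      if (in_window && ok_ends) {
        totals["n_sel"] <- totals["n_sel"] + 1
        totals["len_sel"] <- totals["len_sel"] + flen
      }
    }
  }

  glen <- if (denominator_mode == "all_bases") {
    sum(spec$record_length)
  } else {
    sum(spec$record_length) - sum(spec$gaps$length)
  }
  tibble::tibble(
    genome_id = "synthetic",
    enzymes = paste0(enz$name, collapse = "+"),
    n_fragments_total = unname(totals["n_total"]),
    len_fragments_total = unname(totals["len_total"]),
    n_fragments_selected = unname(totals["n_sel"]),
    len_fragments_selected = unname(totals["len_sel"]),
    genome_length = glen,
    igc_percent = if (glen > 0) 100 * unname(totals["len_sel"]) / glen else 0
  )
}
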