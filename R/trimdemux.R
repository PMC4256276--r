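# Demultiplexing and trimming. Reads are assigned to libraries by exact,
# case-insensitive match of their first 6 bases; the intron 3'-end tag is
# located by exact substring search anywhere in the read (the 6 random
# nucleotides between index and tag are skipped implicitly); everything
# through the tag is discarded, the fixed low-quality tail is dropped, and
# the remaining 15-16 nt genomic flank is kept.

TRIM_CATEGORIES <- c("accepted", "no_index", "no_tag", "multiple_tag",
                     "too_short", "too_long", "contains_N")

#' Demultiplex reads by their 6-nt library index
#'
#' @param sequences Character vector of read sequences.
#' @param index_table Tibble with columns `library` and `barcode`
#'   (distinct 6-nt barcodes).
#' @return Character vector of library identifiers, `NA` where the first six
#'   bases match no barcode exactly.
#' @examples
#' demultiplex(c("ATCACGTTTT", "NNNNNNTTTT"), default_libraries())
#' @export
demultiplex <- function(sequences, index_table) {
  index_table <- as_tibble(index_table)
  bc <- toupper(index_table$barcode)
  if (anyDuplicated(bc)) abort("duplicate barcodes in index table")
  if (any(nchar(bc) != 6)) abort("barcodes must be 6 nt")
  index_table$library[match(toupper(substr(sequences, 1, 6)), bc)]
}

#' Locate the intron 3'-end tag within reads
#'
#' Exact substring search, including overlapping occurrences. A read with
#' exactly one occurrence yields its 0-based half-open interval; none or
#' more than one yield status `"none"` / `"ambiguous"`.
#'
#' @param sequences Character vector of read sequences.
#' @param tag Tag sequence (>= 8 nt).
#' @return Tibble `start, end, status` (0-based half-open; `NA` coordinates
#'   unless status is `"unique"`).
#' @export
find_tag <- function(sequences, tag) {
  tag <- toupper(tag)
  if (nchar(tag) < 8) abort("tag must be at least 8 nt")
  up <- toupper(sequences)
  first <- stringr::str_locate(up, stringr::fixed(tag))[, "start"]
  # second (possibly overlapping) occurrence: search again past first start
  rest <- ifelse(is.na(first), NA_character_,
                 substr(up, first + 1L, nchar(up)))
  second <- stringr::str_locate(rest, stringr::fixed(tag))[, "start"]
  status <- dplyr::case_when(
    is.na(first) ~ "none",
    !is.na(second) ~ "ambiguous",
    TRUE ~ "unique"
  )
  tibble(
    start = ifelse(status == "unique", first - 1L, NA_integer_),
    end = ifelse(status == "unique", first - 1L + nchar(tag), NA_integer_),
    status = status
  )
}

#' Trim reads to their genomic flank
#'
#' Takes the sequence after the tag, removes the final `tail` low-quality
#' bases, and accepts the remainder iff its length falls within `bounds` and
#' it contains no `N` (an `N` can never exact-match the reference, so such
#' reads are rejected at trim rather than blurring mapping QC).
#'
#' @param sequences Character vector of read sequences.
#' @param tag_interval Tibble from [find_tag()] (columns `start, end,
#'   status`).
#' @param bounds Acceptable flank length range, default `c(15, 16)`.
#' @param tail Number of terminal bases to drop, default 5.
#' @return Tibble `flank, category` where `category` is `"accepted"` or a
#'   rejection reason (`no_tag`, `multiple_tag`, `too_short`, `too_long`,
#'   `contains_N`).
#' @export
trim_flank <- function(sequences, tag_interval, bounds = c(15L, 16L), tail = 5L) {
  up <- toupper(sequences)
  post <- ifelse(tag_interval$status == "unique",
                 substr(up, tag_interval$end + 1L, nchar(up)),
                 NA_character_)
  keep_len <- nchar(post) - tail
  flank <- ifelse(!is.na(post) & keep_len > 0, substr(post, 1L, keep_len), "")
  category <- dplyr::case_when(
    tag_interval$status == "none" ~ "no_tag",
    tag_interval$status == "ambiguous" ~ "multiple_tag",
    keep_len < bounds[1] ~ "too_short",
    keep_len > bounds[2] ~ "too_long",
    grepl("N", flank, fixed = TRUE) ~ "contains_N",
    TRUE ~ "accepted"
  )
  tibble(flank = ifelse(category == "accepted", flank, NA_character_),
         category = category)
}

#' Demultiplex and trim a whole library set
#'
#' Applies [demultiplex()], [find_tag()] and [trim_flank()] to every read and
#' partitions the input into accepted flanks and rejection categories.
#'
#' @param reads A read tibble (`id, sequence`, e.g. from [read_fastq()] or
#'   the simulator) or a FASTQ path.
#' @param index_table Tibble `library, barcode`.
#' @param tag Intron 3'-end tag sequence.
#' @inheritParams trim_flank
#' @return A list with `flanks` — tibble `source_id, library, flank` of
#'   accepted reads — and `report` — tibble `category, count` over all of
#'   [TRIM_CATEGORIES()][run_trim], summing to the number of input reads.
#' @examples
#' cfg <- sim_config(seed = 1, chrom_length = 2000, plasmid_length = 1000,
#'                   libraries = default_libraries()[1, ] |>
#'                     dplyr::mutate(n_sites = 10L, reads = 100L))
#' sim <- simulate_rigseq(cfg)
#' run_trim(sim$reads, cfg$libraries, cfg$tag)$report
#' @export
run_trim <- function(reads, index_table, tag, bounds = c(15L, 16L), tail = 5L) {
  if (is.character(reads) && length(reads) == 1) {
    reads <- read_fastq(reads)
  }
  reads <- as_tibble(reads)

  if (nrow(reads) == 0) {
    return(list(
      flanks = tibble(source_id = character(0), library = character(0),
                      flank = character(0)),
      report = tibble(category = TRIM_CATEGORIES, count = 0L)
    ))
  }

  lib <- demultiplex(reads$sequence, index_table)
  ti <- find_tag(reads$sequence, tag)
  tf <- trim_flank(reads$sequence, ti, bounds = bounds, tail = tail)

  category <- ifelse(is.na(lib), "no_index", tf$category)
  accepted <- category == "accepted"

  report <- tibble(category = TRIM_CATEGORIES) |>
    left_join(
      tibble(category = category) |> count(.data$category, name = "count"),
      by = "category"
    ) |>
    mutate(count = dplyr::coalesce(.data$count, 0L))

  list(
    flanks = tibble(
      source_id = reads$id[accepted],
      library = lib[accepted],
      flank = tf$flank[accepted]
    ),
    report = report
  )
}
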