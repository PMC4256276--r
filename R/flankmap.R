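# Exact-match mapping of 15-16 nt flanks to the reference, both strands,
# with circular wrap — the short-read equivalent of running an aligner at
# zero mismatches over a seed spanning the whole read. The index stores every
# plus-strand window; minus-strand matches are found by querying the reverse
# complement of the flank, which is equivalent to indexing both strands.

#' Index every 15/16-mer window of a reference
#'
#' @param replicons Replicon tibble.
#' @param k Integer vector of window sizes to index (default `c(15, 16)`,
#'   the post-trim flank lengths).
#' @return An object of class `rigseq_index`: the plus-strand window table
#'   (`kmer, replicon, start, k`; `L` windows per circular replicon and
#'   `L - k + 1` per linear one) plus replicon metadata.
#' @export
index_reference <- function(replicons, k = c(15L, 16L)) {
  if (any(k < 1) || any(k > min(replicons$length))) {
    abort("window size k outside the usable range for these replicons")
  }
  windows <- purrr::map_dfr(seq_len(nrow(replicons)), function(i) {
    r <- replicons[i, ]
    purrr::map_dfr(as.integer(k), function(kk) {
      starts <- if (r$circular) 0:(r$length - 1L) else 0:(r$length - kk)
      tibble(
        kmer = substr_circ(r$sequence, starts, kk, circular = r$circular),
        replicon = r$name,
        start = starts,
        k = kk
      )
    })
  })
  structure(
    list(
      windows = windows,
      replicons = replicons[, c("name", "length", "circular", "role")],
      k = sort(as.integer(k))
    ),
    class = "rigseq_index"
  )
}

#' @export
print.rigseq_index <- function(x, ...) {
  cat(sprintf("<rigseq reference index: %d windows (k = %s) over %d replicon(s)>\n",
              nrow(x$windows), paste(x$k, collapse = "/"), nrow(x$replicons)))
  invisible(x)
}

# All occurrences of each distinct query across both strands.
# Returns one row per (query, occurrence).
query_occurrences <- function(queries, index) {
  q <- tibble(flank = unique(queries)) |>
    mutate(.rc = revcomp(.data$flank), .len = nchar(.data$flank))
  fwd <- inner_join(q, index$windows,
                    by = join_by("flank" == "kmer", ".len" == "k")) |>
    mutate(strand = "+")
  rev <- inner_join(q, index$windows,
                    by = join_by(".rc" == "kmer", ".len" == "k")) |>
    mutate(strand = "-")
  bind_rows(fwd, rev)[, c("flank", "replicon", "strand", "start")]
}

#' Map flanks to the reference by exact matching
#'
#' Each flank is matched in full, with zero mismatches, against both strands
#' of every replicon (circular replicons wrap). One genomic occurrence gives
#' status `unique`; several give `ambiguous`, reporting the lexicographically
#' smallest `(replicon, strand, start)` occurrence for reproducibility; none
#' gives `unmapped`.
#'
#' @param flanks Tibble `source_id, library, flank` from [run_trim()].
#' @param index A [index_reference()] object.
#' @return Tibble `source_id, library, flank, replicon, role, strand, start,
#'   length, n_hits, status`. `start` is the 0-based plus-strand offset of
#'   the match (`NA` when unmapped).
#' @export
map_flanks <- function(flanks, index) {
  stopifnot(inherits(index, "rigseq_index"))
  flanks <- as_tibble(flanks)
  if (any(!nchar(flanks$flank) %in% index$k)) {
    abort("flank length outside the indexed k range")
  }
  occ <- query_occurrences(flanks$flank, index)
  per_query <- occ |>
    arrange(.data$flank, .data$replicon, .data$strand, .data$start) |>
    group_by(.data$flank) |>
    summarise(
      replicon = first(.data$replicon),
      strand = first(.data$strand),
      start = first(.data$start),
      n_hits = n(),
      .groups = "drop"
    )
  flanks |>
    left_join(per_query, by = "flank") |>
    left_join(index$replicons[, c("name", "role")],
              by = join_by("replicon" == "name")) |>
    mutate(
      n_hits = dplyr::coalesce(.data$n_hits, 0L),
      length = nchar(.data$flank),
      status = dplyr::case_when(
        n_hits == 0L ~ "unmapped",
        n_hits == 1L ~ "unique",
        TRUE ~ "ambiguous"
      )
    ) |>
    select("source_id", "library", "flank", "replicon", "role",
           "strand", "start", "length", "n_hits", "status")
}

#' Per-library replicon preference summary
#'
#' Chromosome and donor-plasmid fractions are computed over uniquely mapped
#' flanks (the denominator used for "X% of reads were chromosomal"
#' statements); the `unmapped_ambiguous` fraction is over all demultiplexed
#' flanks of the library.
#'
#' @param mapped Tibble from [map_flanks()].
#' @return Tibble `library, n_flanks, n_unique, chromosome, donor_plasmid,
#'   unmapped_ambiguous` (fractions are `NA` for empty libraries).
#' @export
replicon_summary <- function(mapped) {
  as_tibble(mapped) |>
    group_by(.data$library) |>
    summarise(
      n_flanks = n(),
      n_unique = sum(.data$status == "unique"),
      n_uchrom = sum(.data$status == "unique" & .data$role == "chromosome"),
      n_uplasmid = sum(.data$status == "unique" & .data$role == "donor_plasmid"),
      n_other = sum(.data$status != "unique"),
      .groups = "drop"
    ) |>
    mutate(
      chromosome = if_else(.data$n_unique > 0,
                           .data$n_uchrom / .data$n_unique, NA_real_),
      donor_plasmid = if_else(.data$n_unique > 0,
                              .data$n_uplasmid / .data$n_unique, NA_real_),
      unmapped_ambiguous = if_else(.data$n_flanks > 0,
                                   .data$n_other / .data$n_flanks, NA_real_)
    ) |>
    select("library", "n_flanks", "n_unique", "chromosome",
           "donor_plasmid", "unmapped_ambiguous")
}
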