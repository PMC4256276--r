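# Sequence utilities for relaxase nick-site biochemistry: oligo arithmetic,
# exact-match in-silico PCR, primer-extension product lengths (a nick in the
# template terminates extension), and ungapped similarity scans against an
# oriT nic window to flag candidate off-target cleavage sites.

#' Bundled oligonucleotide set
#'
#' The published primers and substrate oligos of the
#' conjugation/retrotransposition assays this package models:
#' library-amplification, mutagenesis, oriT substrate and cleavage-mapping
#' oligonucleotides.
#'
#' @return Tibble `oligo_id, sequence, application`.
#' @examples
#' oligo_length(rigseq_oligos())
#' @export
rigseq_oligos <- function() {
  path <- system.file("extdata", "oligonucleotides.tsv", package = "rigseq")
  readr::read_tsv(path, col_types = "ccc")
}

#' Oligo length in nucleotides
#'
#' @param x A character vector of sequences, or an oligo tibble with columns
#'   `oligo_id` and `sequence` (then a named vector is returned).
#' @return Integer length(s); empty sequences raise an error.
#' @examples
#' oligo_length("ACGT")
#' @export
oligo_length <- function(x) {
  if (is.data.frame(x)) {
    return(setNames(oligo_length(x$sequence), x$oligo_id))
  }
  if (any(!nzchar(x))) abort("empty oligo sequence")
  check_dna(x, allow_n = TRUE, what = "oligo")
  nchar(x)
}

# Plus-strand occurrences (0-based starts) of an exact pattern, with
# circular wrap. Implemented by substring comparison over the doubled
# sequence so it stays independent of the Biostrings matcher used as the
# test oracle.
pattern_starts <- function(template, pattern, circular = FALSE) {
  L <- nchar(template)
  k <- nchar(pattern)
  if (k > L) return(integer(0))
  starts <- if (circular) 0:(L - 1L) else 0:(L - k)
  hits <- substr_circ(template, starts, k, circular = TRUE) == pattern
  starts[hits]
}

#' Exact-match in-silico PCR
#'
#' Locates `fwd` on the plus strand and the reverse complement of `rev`
#' downstream of it (and the strand-swapped orientation), reporting every
#' amplicon. Amplicon length includes both primer footprints; circular
#' templates are searched across the origin, in which case products may wrap.
#'
#' @param template A one-row replicon tibble, or a plain DNA string.
#' @param fwd,rev Primer sequences, 5'->3', at least 12 nt.
#' @param circular Used when `template` is a plain string (replicon tibbles
#'   carry their own flag).
#' @return Tibble `orientation, fwd_start, rev_end, length, amplicon`
#'   (0-based `fwd_start`; `rev_end` exclusive, may exceed the template
#'   length for origin-spanning products). Empty when no product forms.
#' @examples
#' insilico_pcr(paste0("ACGTACGTACGTACG", strrep("T", 10), "GGGTTTCCCAAAGGG"),
#'              "ACGTACGTACGTACG", revcomp("GGGTTTCCCAAAGGG"))
#' @export
insilico_pcr <- function(template, fwd, rev, circular = FALSE) {
  if (is.data.frame(template)) {
    circular <- template$circular[1]
    template <- template$sequence[1]
  }
  template <- toupper(template)
  fwd <- toupper(fwd)
  rev <- toupper(rev)
  if (nchar(fwd) < 12 || nchar(rev) < 12) {
    abort("primers must be at least 12 nt")
  }
  L <- nchar(template)

  one_orientation <- function(p_left, p_right, orientation) {
    left <- pattern_starts(template, p_left, circular)
    right <- pattern_starts(template, revcomp(p_right), circular)
    if (length(left) == 0 || length(right) == 0) return(NULL)
    pairs <- tidyr::expand_grid(fwd_start = left, r_start = right) |>
      mutate(rev_end = .data$r_start + nchar(p_right))
    if (circular) {
      # on a circle every pair yields a product going the forward way round
      pairs <- pairs |>
        mutate(rev_end = if_else(.data$rev_end <= .data$fwd_start,
                                 .data$rev_end + L, .data$rev_end)) |>
        filter(.data$rev_end - .data$fwd_start <= L)
    } else {
      pairs <- pairs |> filter(.data$r_start >= .data$fwd_start)
    }
    if (nrow(pairs) == 0) return(NULL)
    pairs |>
      mutate(
        orientation = orientation,
        length = .data$rev_end - .data$fwd_start,
        amplicon = substr_circ(template, .data$fwd_start, .data$length,
                               circular = TRUE)
      ) |>
      select("orientation", "fwd_start", "rev_end", "length", "amplicon")
  }

  out <- bind_rows(
    one_orientation(fwd, rev, "fwd/rev"),
    one_orientation(rev, fwd, "rev/fwd")
  )
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(orientation = character(0), fwd_start = integer(0),
                  rev_end = integer(0), length = integer(0),
                  amplicon = character(0)))
  }
  arrange(out, .data$orientation, .data$fwd_start, .data$length)
}

#' Primer-extension product length
#'
#' Extension proceeds from the primer 3' end along the single-stranded
#' template and terminates at a nick in the template backbone; the product
#' covers every position strictly 5' of the nick on the synthesized strand,
#' so its length is the distance from the primer 5' start to the nick. This
#' is the arithmetic that turns a 96-nt nicked substrate into a 61-nt band
#' when the nick sits 61 nt downstream of the primer start.
#'
#' @param primer_start 0-based offset of the primer 5' end in the direction
#'   of synthesis.
#' @param primer_len Primer length in nt.
#' @param nick_offset Offset(s) of the nick, same frame; must not fall
#'   upstream of the primer 3' end.
#' @return Integer product length(s) in nt, one per nick.
#' @examples
#' primer_extension_product(0, 15, 61)
#' @export
primer_extension_product <- function(primer_start, primer_len, nick_offset) {
  if (any(nick_offset < primer_start + primer_len)) {
    abort("nick upstream of the primer 3' end: no extension product")
  }
  as.integer(nick_offset - primer_start)
}

#' Scan a sequence for windows similar to an oriT nic site
#'
#' Ungapped sliding comparison of a fixed nic window against every offset of
#' both query strands, reporting windows with at least `min_identities`
#' matching positions — the screen used to flag candidate relaxase
#' off-target cleavage sites (the published glnP off-target site shares 9 of
#' 15 positions with the cognate oriT nic window).
#'
#' @param query DNA string (>= window length).
#' @param nic_window The nic-site window to compare against (e.g. a 15-mer).
#'   The cognate nic sequence is construct-specific and must be supplied.
#' @param min_identities Minimum identical positions to report (default 9).
#' @return Tibble `offset, strand, identities, window` sorted by decreasing
#'   identities then offset. `offset` is the 0-based plus-strand start of
#'   the window on the query, for both strands.
#' @export
orit_similarity_scan <- function(query, nic_window, min_identities = 9L) {
  query <- toupper(query)
  nic_window <- toupper(nic_window)
  w <- nchar(nic_window)
  nq <- nchar(query)
  if (nq < w) abort("query shorter than the nic window")
  nic_chars <- strsplit(nic_window, "", fixed = TRUE)[[1]]

  scan_one <- function(seqstr) {
    qc <- strsplit(seqstr, "", fixed = TRUE)[[1]]
    n_off <- nq - w + 1L
    ids <- integer(n_off)
    for (j in seq_len(w)) {
      ids <- ids + (qc[j:(j + n_off - 1L)] == nic_chars[j])
    }
    tibble(scan_offset = 0:(n_off - 1L), identities = ids)
  }

  hits <- bind_rows(
    scan_one(query) |> mutate(strand = "+", offset = .data$scan_offset),
    scan_one(revcomp(query)) |>
      mutate(strand = "-", offset = nq - w - .data$scan_offset)
  ) |>
    filter(.data$identities >= min_identities) |>
    mutate(window = ifelse(
      .data$strand == "+",
      substring(query, .data$offset + 1L, .data$offset + w),
      revcomp(substring(query, .data$offset + 1L, .data$offset + w))
    )) |>
    arrange(dplyr::desc(.data$identities), .data$offset) |>
    select("offset", "strand", "identities", "window")
  hits
}
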