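# Insertion events: mapped flanks collapsed onto the boundary the intron
# invaded. The sequenced flank is the 3' exon side of the insertion, so a
# plus-strand flank starting at s places the boundary at s (the intron sits
# between s-1 and s on the plus strand); a minus-strand flank occupying the
# plus-strand interval [s, e) places the boundary at e, with event strand -.
# Events on opposite strands at the same boundary are distinct.

event_boundary <- function(strand, start, length, replicon_length, circular) {
  b <- ifelse(strand == "+", start, start + length)
  ifelse(circular, b %% replicon_length, b)
}

#' Collapse mapped flanks into unique insertion events
#'
#' @param mapped Tibble from [map_flanks()].
#' @param index The [index_reference()] object used for mapping (supplies
#'   replicon lengths/circularity for the boundary arithmetic).
#' @param mode `"unique-only"` (default) counts only uniquely mapped flanks;
#'   `"best-first"` also counts ambiguous flanks at their deterministic
#'   smallest-coordinate placement, emulating a single-report best-alignment
#'   mapper.
#' @return Tibble `library, replicon, role, boundary, strand, read_count`,
#'   one row per unique `(library, replicon, boundary, strand)`.
#' @export
collapse_events <- function(mapped, index, mode = c("unique-only", "best-first")) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "rigseq_index"))
  keep <- if (mode == "unique-only") "unique" else c("unique", "ambiguous")
  m <- as_tibble(mapped) |>
    filter(.data$status %in% keep) |>
    left_join(index$replicons[, c("name", "length", "circular")],
              by = join_by("replicon" == "name"), suffix = c("", ".rep"))
  if (nrow(m) == 0) {
    return(tibble(library = character(0), replicon = character(0),
                  role = character(0), boundary = integer(0),
                  strand = character(0), read_count = integer(0)))
  }
  m |>
    mutate(boundary = event_boundary(.data$strand, .data$start, .data$length,
                                     .data$length.rep, .data$circular)) |>
    count(.data$library, .data$replicon, .data$role, .data$boundary,
          .data$strand, name = "read_count") |>
    arrange(.data$library, .data$replicon, .data$boundary, .data$strand)
}

#' Annotate events with relative frequencies
#'
#' The relative retrotransposition frequency of a chromosomal event is its
#' read count divided by the library's total uniquely mapped chromosomal
#' reads. Donor-plasmid events are normalized separately within the plasmid
#' (flagged by `freq_scope`).
#'
#' @param events Tibble from [collapse_events()].
#' @return `events` with columns `rel_freq` and `freq_scope` added.
#'   Libraries with zero reads in a scope get `NA` frequencies with a
#'   warning.
#' @export
relative_frequencies <- function(events) {
  out <- as_tibble(events) |>
    group_by(.data$library, .data$role) |>
    mutate(
      rel_freq = .data$read_count / sum(.data$read_count),
      freq_scope = .data$role
    ) |>
    ungroup()
  if (any(!is.finite(out$rel_freq))) {
    warn("zero read total in at least one (library, replicon role); frequencies set to NA")
    out$rel_freq[!is.finite(out$rel_freq)] <- NA_real_
  }
  out
}

#' Reservoir-subsampling normalization of unique-site counts
#'
#' Libraries of different depth cannot be compared by their raw unique-site
#' counts, so equal-size read subsets are drawn and the number of unique
#' insertion points per subset is averaged. Each of the `K` subsets is an
#' independent single-pass reservoir sample (Algorithm R) of `S` chromosomal
#' reads without replacement, seeded as `seed + subset_index`.
#'
#' @param mapped Tibble from [map_flanks()]; only uniquely mapped chromosomal
#'   reads enter the pool.
#' @param index The [index_reference()] object (boundary arithmetic).
#' @param K Number of subsets (published analysis used 1000; desk-scale
#'   default 100).
#' @param S Subset size in reads (published analysis used 250000). Must not
#'   exceed the library pool; no silent scaling.
#' @param seed Integer base seed.
#' @param library Optional library to restrict to (default: `mapped` must
#'   contain a single library).
#' @return An object of class `rigseq_subsample`: per-subset unique-site
#'   counts with `K`, `S`, `seed`, `mean` and `sd`.
#' @export
subsample_unique_counts <- function(mapped, index, K = 100L, S, seed = 1L,
                                    library = NULL) {
  m <- as_tibble(mapped)
  if (!is.null(library)) m <- m[m$library == library, ]
  if (dplyr::n_distinct(m$library) > 1) {
    abort("mapped contains several libraries; pass `library`")
  }
  m <- m |> filter(.data$status == "unique", .data$role == "chromosome")
  n <- nrow(m)
  if (S > n) {
    abort(sprintf("subset size S = %d exceeds the %d chromosomal reads available", S, n))
  }
  rep_meta <- index$replicons
  i <- match(m$replicon, rep_meta$name)
  key <- paste(
    m$replicon,
    event_boundary(m$strand, m$start, m$length,
                   rep_meta$length[i], rep_meta$circular[i]),
    m$strand
  )
  counts <- integer(K)
  for (j in seq_len(K)) {
    idx <- withr::with_seed(seed + j, reservoir_sample(n, S))
    counts[j] <- dplyr::n_distinct(key[idx])
  }
  structure(
    list(counts = counts, K = as.integer(K), S = as.integer(S),
         seed = as.integer(seed), n_reads = n,
         total_unique = dplyr::n_distinct(key),
         mean = mean(counts), sd = stats::sd(counts)),
    class = "rigseq_subsample"
  )
}

#' @export
print.rigseq_subsample <- function(x, ...) {
  cat(sprintf(
    "<rigseq subsample: K = %d subsets of S = %d reads (pool %d); mean unique sites %.2f (sd %.2f, total %d)>\n",
    x$K, x$S, x$n_reads, x$mean, x$sd, x$total_unique
  ))
  invisible(x)
}
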