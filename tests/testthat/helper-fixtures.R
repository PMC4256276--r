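# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own matching/enumeration code paths: mapping is cross-checked
# with Biostrings::matchPattern, subsampling expectations with exhaustive
# subset enumeration, and sequence arithmetic with plain substring loops.

tiny_libraries <- function(n_sites = c(20L, 60L), reads = c(2000L, 2000L)) {
  libs <- default_libraries()[seq_along(n_sites), ]
  libs$n_sites <- as.integer(n_sites)
  libs$reads <- as.integer(reads)
  libs
}

tiny_config <- function(seed = 1L, chrom_length = 20000L, plasmid_length = 4000L,
                        libraries = tiny_libraries(), n_sites_plasmid = 15L, ...) {
  sim_config(seed = seed, chrom_length = chrom_length,
             plasmid_length = plasmid_length, libraries = libraries,
             n_sites_plasmid = n_sites_plasmid, ...)
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Brute-force both-strand exact scan of one flank against a replicon table,
# circular wrap included. Returns tibble(replicon, strand, start).
oracle_scan_flank <- function(flank, replicons) {
  k <- nchar(flank)
  hits <- list()
  for (i in seq_len(nrow(replicons))) {
    r <- replicons[i, ]
    subject <- if (r$circular) {
      paste0(r$sequence, substr(r$sequence, 1, k - 1))
    } else {
      r$sequence
    }
    for (st in c("+", "-")) {
      pat <- if (st == "+") flank else revcomp(flank)
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subject))
      starts <- Biostrings::start(m) - 1L
      starts <- starts[starts < r$length]
      if (length(starts) > 0) {
        hits[[length(hits) + 1]] <-
          tibble::tibble(replicon = r$name, strand = st, start = starts)
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(replicon = character(0), strand = character(0),
                          start = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(hits), replicon, strand, start)
}

# Exact expected number of unique keys in a size-S subset drawn without
# replacement, by enumerating all C(n, S) subsets.
enum_mean_unique <- function(keys, S) {
  n <- length(keys)
  subsets <- utils::combn(n, S)
  mean(apply(subsets, 2, function(idx) length(unique(keys[idx]))))
}

# Event-strand window around a planted truth event, read straight off the
# reference with plain string ops (independent of extract_windows).
oracle_truth_window <- function(reference, truth_row, w_up = 12, w_down = 6) {
  r <- reference[reference$name == truth_row$replicon, ]
  L <- r$length
  b <- truth_row$coordinate
  doubled <- paste0(r$sequence, r$sequence)
  grab <- function(s0, len) substr(doubled, (s0 %% L) + 1, (s0 %% L) + len)
  if (truth_row$strand == "+") {
    grab(b - w_up, w_up + w_down)
  } else {
    revcomp(grab(b - w_down, w_up + w_down))
  }
}
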