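# Low-level sequence helpers shared across modules. Coordinates are 0-based
# half-open internally; circular coordinates are reduced modulo the replicon
# length at the point of use.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over `A/C/G/T/N` (case-insensitive; the
#' result is uppercase). `N` maps to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp(c("AAAC", "ACGT"))
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  if (any(is.na(x))) abort("revcomp() does not accept NA sequences")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, toupper(x))
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside %s", what,
      if (allow_n) "A/C/G/T/N" else "A/C/G/T"
    ))
  }
  invisible(x)
}

# Circular-aware substring: extract `len[i]` bases starting at 0-based offset
# `start0[i]`. Offsets may be negative or >= L for circular sequences; linear
# sequences reject out-of-range windows.
substr_circ <- function(seq, start0, len, circular = TRUE) {
  L <- nchar(seq)
  if (any(len > L)) abort("window longer than the replicon")
  if (!circular) {
    if (any(start0 < 0 | start0 + len > L)) {
      abort("window out of range on a linear replicon")
    }
    return(substring(seq, start0 + 1, start0 + len))
  }
  s <- start0 %% L
  doubled <- paste0(seq, substring(seq, 1, max(len)))
  substring(doubled, s + 1, s + len)
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_dna_vec <- function(n_seq, len) {
  if (n_seq == 0) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n_seq * len, replace = TRUE), nrow = n_seq)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Symmetric Dirichlet draw via normalised gammas.
rdirichlet_sym <- function(n, concentration) {
  g <- rgamma(n, shape = concentration, rate = 1)
  # guard against an all-zero draw at very small concentrations
  while (sum(g) == 0) g <- rgamma(n, shape = concentration, rate = 1)
  g / sum(g)
}

# Minimal IUPAC code covering a set of bases.
iupac_code <- function(bases) {
  if (length(bases) == 0) return("N")
  key <- paste(sort(unique(bases)), collapse = "")
  map <- Biostrings::IUPAC_CODE_MAP
  inv <- setNames(names(map), vapply(strsplit(map, ""), function(b) paste(sort(b), collapse = ""), ""))
  code <- inv[[key]]
  if (is.null(code) || is.na(code)) "N" else code
}

iupac_expand <- function(code) {
  strsplit(Biostrings::IUPAC_CODE_MAP[[toupper(code)]], "")[[1]]
}

# Single-pass reservoir sample (Algorithm R) of `size` items from 1..n,
# without replacement, driven by the current RNG stream.
reservoir_sample <- function(n, size) {
  if (size > n) abort("reservoir size exceeds population")
  res <- seq_len(size)
  if (n > size) {
    i <- (size + 1L):n
    j <- floor(runif(length(i)) * i) + 1L
    hit <- which(j <= size)
    for (t in hit) res[j[t]] <- i[t]
  }
  res
}

# Position labels used throughout the profile module: -W_up..-1, +1..+W_down,
# no position 0 (the insertion boundary sits between -1 and +1).
position_labels <- function(w_up, w_down) {
  p <- c(-rev(seq_len(w_up)), seq_len(w_down))
  ifelse(p < 0, as.character(p), paste0("+", p))
}

position_values <- function(w_up, w_down) {
  c(-rev(seq_len(w_up)), seq_len(w_down))
}
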