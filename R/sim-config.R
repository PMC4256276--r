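# Simulation configuration. The defaults ARE the study conditions the
# simulator emulates: three libraries (relaxase absent; relaxase from the
# conjugative element pRS01; relaxase alone from an expression plasmid) whose
# chromosomal site counts (154/461/912), chromosomal read fractions
# (5.2%/30.4%/86.9%) and insertion-site base biases (C at -6 ~90%, T at +5
# ~25%) match the published RIG-Seq libraries.

#' Default intron 3'-end tag used by the simulator
#'
#' The amplicon design places a short fragment of the intron 3' end between
#' the random hexamer and the genomic flank; trimming keys on this tag. The
#' real fragment sequence is construct-specific, so the simulator ships a
#' fixed 20-nt synthetic tag; all detection logic is sequence-agnostic and
#' accepts any tag of at least 8 nt.
#'
#' @return A 20-nt DNA string.
#' @export
rigseq_tag <- function() "CTGATTAGCGTACCGTTCAG"

#' Default library design table
#'
#' One row per sequencing library: 6-nt barcode, relaxase status, number of
#' chromosomal insertion sites to plant, fraction of reads that are
#' chromosomal (the rest come from the donor plasmid), Dirichlet
#' concentration controlling how flat the per-site frequency spectrum is
#' (flatter when relaxase is present), and reads per library.
#'
#' @return A tibble with columns `library`, `barcode`, `relaxase`,
#'   `n_sites`, `chrom_read_fraction`, `freq_concentration`, `reads`.
#' @export
default_libraries <- function() {
  tibble(
    library = c("D-C", "D-pRS01", "D-pLtrB"),
    barcode = c("ATCACG", "TTAGGC", "CAGATC"),
    relaxase = c(FALSE, TRUE, TRUE),
    n_sites = c(154L, 461L, 912L),
    chrom_read_fraction = c(0.052, 0.304, 0.869),
    freq_concentration = c(2, 4, 4),
    reads = c(50000L, 50000L, 50000L)
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic RIG-Seq generator. All randomness
#' in the simulator derives from `seed`, making whole runs bit-reproducible.
#'
#' @param seed Integer seed; every simulator stage derives its stream from it.
#' @param chrom_length,plasmid_length Replicon lengths in nt (>= 1000).
#' @param libraries Library design table, see [default_libraries()].
#' @param p_C6 Probability that a planted site carries C at position -6 on
#'   the event strand (default 0.90).
#' @param p_T5 Probability of T at position +5 (default 0.25; low T+5 marks
#'   the single-strand, endonuclease-independent retrotransposition pathway).
#' @param tag Intron 3'-end tag planted in every read (>= 8 nt).
#' @param flank_len_range Pre-trim genomic flank length range; the default
#'   `c(20, 21)` yields 15-16 nt flanks after the 5-nt low-quality tail is
#'   removed.
#' @param lowqual_tail Number of terminal low-quality bases (Q2) per read.
#' @param n_sites_plasmid Donor-plasmid insertion sites planted per library.
#' @param min_site_spacing Minimum distance between any two planted
#'   boundaries, so site edits and profile windows never collide.
#' @return An object of class `rigseq_sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 7, chrom_length = 5000, plasmid_length = 2000)
#' @export
sim_config <- function(seed = 1L,
                       chrom_length = 100000L,
                       plasmid_length = 12000L,
                       libraries = default_libraries(),
                       p_C6 = 0.90,
                       p_T5 = 0.25,
                       tag = rigseq_tag(),
                       flank_len_range = c(20L, 21L),
                       lowqual_tail = 5L,
                       n_sites_plasmid = 50L,
                       min_site_spacing = 30L) {
  libraries <- as_tibble(libraries)
  need <- c("library", "barcode", "relaxase", "n_sites",
            "chrom_read_fraction", "freq_concentration", "reads")
  missing_cols <- setdiff(need, names(libraries))
  if (length(missing_cols) > 0) {
    abort(paste("libraries table lacks columns:", paste(missing_cols, collapse = ", ")))
  }
  libraries$barcode <- toupper(libraries$barcode)

  if (chrom_length < 1000 || plasmid_length < 1000) {
    abort("replicon lengths must be at least 1000 nt")
  }
  if (p_C6 < 0 || p_C6 > 1 || p_T5 < 0 || p_T5 > 1) {
    abort("p_C6 and p_T5 must be probabilities in [0, 1]")
  }
  if (any(libraries$chrom_read_fraction < 0 | libraries$chrom_read_fraction > 1)) {
    abort("chrom_read_fraction must lie in [0, 1]")
  }
  if (any(libraries$n_sites <= 0) || any(libraries$reads <= 0) ||
      n_sites_plasmid <= 0) {
    abort("site and read counts must be positive")
  }
  if (any(libraries$freq_concentration <= 0)) {
    abort("freq_concentration must be positive")
  }
  if (anyDuplicated(libraries$barcode) || any(nchar(libraries$barcode) != 6)) {
    abort("library barcodes must be distinct 6-nt sequences")
  }
  check_dna(libraries$barcode, what = "barcode")
  if (nchar(tag) < 8) {
    abort("tag shorter than 8 nt gives unreliable detection")
  }
  check_dna(tag, what = "tag")
  if (length(flank_len_range) != 2 || flank_len_range[1] > flank_len_range[2]) {
    abort("flank_len_range must be c(min, max) with min <= max")
  }
  if (flank_len_range[1] < lowqual_tail + 15) {
    abort("flank_len_range min must be at least lowqual_tail + 15")
  }

  structure(
    list(
      seed = as.integer(seed),
      chrom_length = as.integer(chrom_length),
      plasmid_length = as.integer(plasmid_length),
      libraries = libraries,
      p_C6 = p_C6, p_T5 = p_T5,
      tag = toupper(tag),
      flank_len_range = as.integer(flank_len_range),
      lowqual_tail = as.integer(lowqual_tail),
      n_sites_plasmid = as.integer(n_sites_plasmid),
      min_site_spacing = as.integer(min_site_spacing)
    ),
    class = "rigseq_sim_config"
  )
}

#' @export
print.rigseq_sim_config <- function(x, ...) {
  cat("<rigseq simulation config>\n")
  cat(sprintf("  seed %d | chromosome %d nt | donor plasmid %d nt\n",
              x$seed, x$chrom_length, x$plasmid_length))
  cat(sprintf("  p(C-6) = %.2f, p(T+5) = %.2f, tag %s\n", x$p_C6, x$p_T5, x$tag))
  print(x$libraries)
  invisible(x)
}

config_library_row <- function(config, library) {
  i <- match(library, config$libraries$library)
  if (is.na(i)) abort(sprintf("library '%s' not in config", library))
  config$libraries[i, ]
}

# Per-stage seeds derived from the master seed; kept small so seed + offsets
# stay well inside 32-bit integer range.
stage_seed <- function(config, stage, lib_index = 0L) {
  offsets <- c(reference = 0L, plant = 1L, reads = 2L)
  config$seed + 17L * lib_index + offsets[[stage]]
}
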