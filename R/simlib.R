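# Synthetic RIG-Seq library generator. The generator is first-class code: it
# defines the ground truth (SimTruth) against which pipeline recovery is
# scored, and emulates the amplicon structure of the assay:
#   [6-nt library index][6 random nt][intron 3'-end tag][genomic 3' flank]
# with a low-quality 5-nt tail on the flank.

#' Build simulated reference replicons
#'
#' Generates one circular chromosome and one circular donor plasmid with
#' i.i.d. uniform base composition. These stand in for the real host
#' chromosome and intron donor plasmid; both are synthetic sequences.
#'
#' @param config A [sim_config()].
#' @return A two-row replicon tibble (roles `chromosome`, `donor_plasmid`).
#'   The chromosome carries oriC (offset 0) and Ter (mid-replicon) landmarks.
#' @examples
#' build_reference(sim_config(seed = 7, chrom_length = 1000, plasmid_length = 1000))
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "rigseq_sim_config"))
  withr::with_seed(stage_seed(config, "reference"), {
    chrom <- random_dna(config$chrom_length)
    plasmid <- random_dna(config$plasmid_length)
  })
  bind_rows(
    replicon(
      "sim_chromosome", chrom, circular = TRUE, role = "chromosome",
      landmarks = tibble(
        label = c("oriC", "Ter"),
        offset = c(0L, as.integer(config$chrom_length %/% 2))
      )
    ),
    replicon("sim_donor_plasmid", plasmid, circular = TRUE, role = "donor_plasmid")
  )
}

# Greedy draw of `n` boundaries on [0, L) with circular min-distance
# `min_sep` from each other and from `taken`: walk a random permutation of
# all positions, blocking the neighbourhood of each accepted site.
# Deterministic under the current RNG stream; errors when the replicon jams
# before `n` sites are placed.
draw_separated_sites <- function(n, L, min_sep, taken = integer(0)) {
  blocked <- logical(L)
  block <- function(p) {
    span <- (p + seq(-min_sep + 1L, min_sep - 1L)) %% L
    blocked[span + 1L] <<- TRUE
  }
  for (p in as.integer(taken)) block(p)
  kept <- integer(n)
  got <- 0L
  for (p in sample.int(L) - 1L) {
    if (blocked[p + 1L]) next
    got <- got + 1L
    kept[got] <- p
    if (got == n) break
    block(p)
  }
  if (got < n) {
    abort(sprintf(
      "coordinate collision: could not place %d sites with spacing %d on a %d-nt replicon",
      n, min_sep, L
    ))
  }
  kept
}

# Apply a single-base edit list (0-based offsets) to one sequence.
apply_edits <- function(sequence, offsets0, bases) {
  if (length(offsets0) == 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  chars[offsets0 + 1L] <- bases
  paste(chars, collapse = "")
}

# Draw per-site event-strand bases at -6 and +5, translate them to
# plus-strand edits around each boundary, and return the edit list.
site_edits <- function(boundary, strand, L, p_C6, p_T5) {
  n <- length(boundary)
  base_m6 <- ifelse(runif(n) < p_C6, "C",
                    sample(c("A", "G", "T"), n, replace = TRUE))
  base_p5 <- ifelse(runif(n) < p_T5, "T",
                    sample(c("A", "C", "G"), n, replace = TRUE))
  plus <- strand == "+"
  comp <- setNames(c("T", "G", "C", "A"), DNA_ALPHABET)
  tibble(
    offset = c(
      ifelse(plus, boundary - 6L, boundary + 5L) %% L,  # event-strand -6
      ifelse(plus, boundary + 4L, boundary - 5L) %% L   # event-strand +5
    ),
    base = c(
      ifelse(plus, base_m6, comp[base_m6]),
      ifelse(plus, base_p5, comp[base_p5])
    )
  )
}

#' Plant ground-truth insertion sites for one library
#'
#' Draws distinct chromosomal boundaries (`n_sites` from the library's config
#' row) and donor-plasmid boundaries (`n_sites_plasmid`), assigns each a
#' random strand, edits the reference so the event-strand base at -6 is C
#' with probability `p_C6` and at +5 is T with probability `p_T5`, and draws
#' per-site relative frequencies from a symmetric Dirichlet whose
#' concentration is the library's `freq_concentration` (flatter spectra for
#' relaxase-positive libraries).
#'
#' @param reference Replicon tibble from [build_reference()].
#' @param config A [sim_config()].
#' @param library Library identifier (row of `config$libraries`).
#' @param exclude Optional tibble with columns `replicon`, `coordinate` of
#'   boundaries already planted (other libraries), kept at `min_site_spacing`.
#' @return A list with elements `reference` (edited replicon tibble) and
#'   `truth`: a tibble `library, replicon, role, coordinate, strand,
#'   true_frequency` where frequencies sum to 1 within (library, role).
#' @export
plant_sites <- function(reference, config, library, exclude = NULL) {
  stopifnot(inherits(config, "rigseq_sim_config"))
  row <- config_library_row(config, library)
  lib_index <- match(library, config$libraries$library)
  if (row$n_sites > config$chrom_length / 10) {
    abort("n_sites exceeds chrom_length/10")
  }

  plan <- tibble(
    role = c("chromosome", "donor_plasmid"),
    n = c(row$n_sites, config$n_sites_plasmid)
  )

  withr::with_seed(stage_seed(config, "plant", lib_index), {
    truth <- purrr::pmap_dfr(plan, function(role, n) {
      rep_row <- reference[reference$role == role, ]
      taken <- integer(0)
      if (!is.null(exclude)) {
        taken <- exclude$coordinate[exclude$replicon == rep_row$name]
      }
      b <- draw_separated_sites(n, rep_row$length, config$min_site_spacing, taken)
      tibble(
        library = library,
        replicon = rep_row$name,
        role = role,
        coordinate = b,
        strand = sample(c("+", "-"), n, replace = TRUE),
        true_frequency = rdirichlet_sym(n, row$freq_concentration)
      )
    })

    for (nm in unique(truth$replicon)) {
      i <- match(nm, reference$name)
      tr <- truth[truth$replicon == nm, ]
      ed <- site_edits(tr$coordinate, tr$strand, reference$length[i],
                       config$p_C6, config$p_T5)
      reference$sequence[i] <- apply_edits(reference$sequence[i], ed$offset, ed$base)
    }
  })

  list(reference = reference, truth = truth)
}

#' Synthesize RIG-Seq reads for one library
#'
#' Each read is `[barcode][6 random nt][tag][genomic flank]`: the flank is
#' the 20-21 nt of reference sequence downstream of the insertion boundary on
#' the event strand (wrapping circular origins), the event of origin is drawn
#' multinomially from the library's true frequencies, and reads come from the
#' chromosome with probability `chrom_read_fraction` (donor plasmid
#' otherwise). Qualities are constant Q37 except the terminal
#' `lowqual_tail` bases at Q2 (Phred+33).
#'
#' @param truth Truth tibble from [plant_sites()] (one library).
#' @param reference Edited replicon tibble (after all planting).
#' @param config A [sim_config()].
#' @param library Library identifier.
#' @param n_reads Number of reads; defaults to the library's `reads` field.
#' @return A tibble `id, sequence, quality, library, replicon, coordinate,
#'   strand, flank_len` — the last four columns are ground-truth provenance
#'   and are not consumed by the analysis pipeline.
#' @export
synthesize_reads <- function(truth, reference, config, library, n_reads = NULL) {
  stopifnot(inherits(config, "rigseq_sim_config"))
  row <- config_library_row(config, library)
  lib_index <- match(library, config$libraries$library)
  n <- as.integer(n_reads %||% row$reads)
  tr <- truth[truth$library == library, ]
  if (nrow(tr) == 0) abort(sprintf("no planted events for library '%s'", library))

  withr::with_seed(stage_seed(config, "reads", lib_index), {
    from_chrom <- runif(n) < row$chrom_read_fraction
    ev <- integer(n)
    for (ro in c("chromosome", "donor_plasmid")) {
      sel <- if (ro == "chromosome") from_chrom else !from_chrom
      pool <- which(tr$role == ro)
      if (any(sel)) {
        if (length(pool) == 0) abort(sprintf("no %s events to draw reads from", ro))
        ev[sel] <- sample(pool, sum(sel), replace = TRUE,
                          prob = tr$true_frequency[pool])
      }
    }
    flank_len <- sample(seq(config$flank_len_range[1], config$flank_len_range[2]),
                        n, replace = TRUE)
    hexamer <- random_dna_vec(n, 6L)
  })

  b <- tr$coordinate[ev]
  strand <- tr$strand[ev]
  rep_name <- tr$replicon[ev]

  flank <- character(n)
  for (nm in unique(rep_name)) {
    i <- match(nm, reference$name)
    sel <- rep_name == nm
    L <- reference$length[i]
    plus <- strand[sel] == "+"
    start0 <- ifelse(plus, b[sel], b[sel] - flank_len[sel])
    raw <- substr_circ(reference$sequence[i], start0, flank_len[sel],
                       circular = reference$circular[i])
    raw[!plus] <- revcomp(raw[!plus])
    flank[sel] <- raw
  }

  seqs <- paste0(row$barcode, hexamer, config$tag, flank)
  qual <- paste0(
    strrep(rawToChar(as.raw(33 + 37)), nchar(seqs) - config$lowqual_tail),
    strrep(rawToChar(as.raw(33 + 2)), config$lowqual_tail)
  )
  tibble(
    id = sprintf("%s_read%06d", gsub("[^A-Za-z0-9]", "", library), seq_len(n)),
    sequence = seqs,
    quality = qual,
    library = library,
    replicon = rep_name,
    coordinate = b,
    strand = strand,
    flank_len = flank_len
  )
}

#' Run the full simulator
#'
#' Builds the reference, plants every configured library's sites on it (sites
#' of different libraries never come closer than `min_site_spacing`), and
#' synthesizes all libraries' reads against the fully edited reference.
#'
#' @param config A [sim_config()].
#' @return A list with `reference` (edited replicon tibble), `truth`
#'   (all libraries) and `reads` (all libraries, simulator output tibble).
#' @examples
#' cfg <- sim_config(seed = 1, chrom_length = 5000, plasmid_length = 2000,
#'                   libraries = default_libraries()[1, ] |>
#'                     dplyr::mutate(n_sites = 20L, reads = 500L))
#' sim <- simulate_rigseq(cfg)
#' @export
simulate_rigseq <- function(config) {
  stopifnot(inherits(config, "rigseq_sim_config"))
  reference <- build_reference(config)
  truth <- NULL
  for (lib in config$libraries$library) {
    planted <- plant_sites(reference, config, lib, exclude = truth)
    reference <- planted$reference
    truth <- bind_rows(truth, planted$truth)
  }
  reads <- purrr::map_dfr(
    config$libraries$library,
    function(lib) synthesize_reads(truth, reference, config, lib)
  )
  list(reference = reference, truth = truth, reads = reads)
}
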