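#' Construct a replicon table
#'
#' A replicon is one reference DNA molecule (a chromosome or a plasmid).
#' Replicons are carried as rows of a tibble so that a reference — typically a
#' chromosome plus the intron donor plasmid — is just a two-row data frame
#' that pipes through the rest of the package.
#'
#' @param name Replicon identifier.
#' @param sequence DNA string over `A/C/G/T` (uppercased on input; simulated
#'   and bundled references contain no `N`).
#' @param circular Is the molecule circular? Flank extraction, mapping and
#'   window extraction wrap around the origin of circular replicons.
#' @param role One of `"chromosome"`, `"donor_plasmid"`, `"other"`. The role
#'   drives replicon-preference summaries and the chromosomal normalization
#'   of event frequencies.
#' @param landmarks Optional tibble with columns `label` and `offset`
#'   (0-based), e.g. oriC/Ter positions for plotting chromosome tracks.
#' @return A one-row tibble with columns `name`, `sequence`, `length`,
#'   `circular`, `role` and a `landmarks` list-column.
#' @examples
#' replicon("toy", "ACGTACGTAC", circular = TRUE, role = "chromosome")
#' @export
replicon <- function(name, sequence, circular = TRUE,
                     role = c("other", "chromosome", "donor_plasmid"),
                     landmarks = NULL) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) abort("replicon sequence must be non-empty")
  check_dna(sequence, allow_n = FALSE, what = sprintf("replicon '%s'", name))
  L <- nchar(sequence)
  if (is.null(landmarks)) {
    landmarks <- tibble(label = character(0), offset = integer(0))
  }
  landmarks <- as_tibble(landmarks)
  if (nrow(landmarks) > 0 &&
      any(landmarks$offset < 0 | landmarks$offset >= L)) {
    abort("landmark offsets must lie in [0, replicon length)")
  }
  tibble(
    name = name, sequence = sequence, length = L,
    circular = circular, role = role, landmarks = list(landmarks)
  )
}

replicon_by_name <- function(replicons, name) {
  i <- match(name, replicons$name)
  if (is.na(i)) abort(sprintf("unknown replicon '%s'", name))
  replicons[i, ]
}

#' Read a reference FASTA into a replicon table
#'
#' Wraps [Biostrings::readDNAStringSet()]. Roles and circularity are not part
#' of FASTA, so they are supplied per record (recycled if scalar).
#'
#' @param path FASTA file.
#' @param circular Logical, recycled over records.
#' @param role Character, recycled over records.
#' @return A replicon tibble (see [replicon()]).
#' @export
read_reference_fasta <- function(path, circular = TRUE, role = "other") {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  circular <- rep_len(circular, length(ss))
  role <- rep_len(role, length(ss))
  purrr::pmap_dfr(
    list(nm, as.character(ss), circular, role),
    function(n, s, ci, ro) replicon(n, s, circular = ci, role = ro)
  )
}

#' Write a replicon table as FASTA
#'
#' @param replicons Replicon tibble.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(replicons, path) {
  ss <- Biostrings::DNAStringSet(setNames(replicons$sequence, replicons$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
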