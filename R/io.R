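# FASTQ I/O. Parsing is delegated to Biostrings; a lightweight structural
# check runs first so that malformed input is reported with the offending
# record named (Biostrings' own errors do not identify records).

validate_fastq_structure <- function(path) {
  lines <- readr::read_lines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    rec <- n %/% 4 + 1
    abort(sprintf("malformed FASTQ '%s': truncated record %d", path, rec))
  }
  if (n == 0) return(invisible(TRUE))
  rec_i <- seq_len(n %/% 4)
  hdr <- lines[(rec_i - 1) * 4 + 1]
  sq <- lines[(rec_i - 1) * 4 + 2]
  sep <- lines[(rec_i - 1) * 4 + 3]
  ql <- lines[(rec_i - 1) * 4 + 4]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+") |
                 nchar(sq) != nchar(ql) | nchar(sq) == 0)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(sprintf(
      "malformed FASTQ '%s': record %d ('%s') has an invalid header, separator or sequence/quality length",
      path, i, sub("^@", "", hdr[i])
    ))
  }
  invisible(TRUE)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return A tibble `id, sequence, quality`. Malformed files raise an error
#'   naming the first bad record.
#' @export
read_fastq <- function(path) {
  validate_fastq_structure(path)
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss)),
    quality = unname(as.character(S4Vectors::mcols(ss)$qualities %||%
                                    Biostrings::BStringSet(rep("", length(ss)))))
  )
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Write the simulator's ground truth as TSV
#'
#' Columns: `library, replicon, coordinate` (0-based boundary), `strand,
#' true_frequency`.
#'
#' @param truth Truth tibble from [plant_sites()]/[simulate_rigseq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(
    truth[, c("library", "replicon", "coordinate", "strand", "true_frequency")],
    path
  )
  invisible(path)
}
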