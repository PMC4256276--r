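# Genome-track export. Events become point features (BED, 0-based
# half-open) and a binned relative-frequency signal (bedGraph); summed
# bedGraph mass per library equals the summed relative frequencies.

#' Write BED and bedGraph tracks for chromosomal events
#'
#' One file pair per library: a BED of point intervals `[boundary,
#' boundary + 1)` with score `min(1000, round(1000 * rel_freq))`, and a
#' bedGraph of relative frequency summed within fixed-size bins.
#'
#' @param events Tibble from [relative_frequencies()].
#' @param dir Output directory (created if needed).
#' @param bin_size bedGraph bin width in nt (default 1000).
#' @return A list with `files` (tibble `library, bed, bedgraph`) and `bins`
#'   (tibble `library, replicon, bin_start, bin_end, value`), invisibly.
#' @export
write_tracks <- function(events, dir, bin_size = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- as_tibble(events) |> filter(.data$role == "chromosome")

  bins <- ev |>
    mutate(bin_start = (.data$boundary %/% bin_size) * bin_size) |>
    group_by(.data$library, .data$replicon, .data$bin_start) |>
    summarise(value = sum(.data$rel_freq), .groups = "drop") |>
    mutate(bin_end = .data$bin_start + bin_size) |>
    select("library", "replicon", "bin_start", "bin_end", "value")

  files <- purrr::map_dfr(unique(ev$library), function(lib) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lib)
    bed_path <- file.path(dir, paste0(safe, "_events.bed"))
    bg_path <- file.path(dir, paste0(safe, "_relfreq.bedgraph"))

    e <- ev |> filter(.data$library == lib) |>
      arrange(.data$replicon, .data$boundary, .data$strand)
    bed <- sprintf(
      "%s\t%d\t%d\t%s\t%d\t%s",
      e$replicon, e$boundary, e$boundary + 1L,
      paste0(safe, "_site", seq_len(nrow(e))),
      pmin(1000L, as.integer(round(1000 * e$rel_freq))),
      e$strand
    )
    readr::write_lines(bed, bed_path)

    b <- bins |> filter(.data$library == lib) |>
      arrange(.data$replicon, .data$bin_start)
    readr::write_lines(
      c(sprintf("track type=bedGraph name=\"%s relative frequency\"", lib),
        sprintf("%s\t%d\t%d\t%.10g", b$replicon, b$bin_start, b$bin_end, b$value)),
      bg_path
    )
    tibble(library = lib, bed = bed_path, bedgraph = bg_path)
  })

  invisible(list(files = files, bins = bins))
}
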