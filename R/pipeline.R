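# Pipeline orchestration: simulate -> trim -> map -> count -> profile, with
# a machine-readable run manifest. Stage outputs are plain TSV/FASTA/FASTQ
# and are byte-identical across re-runs with the same seed.

#' Assemble a pipeline configuration
#'
#' @param simulate A [sim_config()], or `NULL` to analyse an existing FASTQ.
#' @param fastq,reference Paths to input FASTQ and reference FASTA, used when
#'   `simulate` is `NULL`. The reference FASTA is loaded with the first
#'   record as the chromosome and the second as the donor plasmid.
#' @param index_table Tibble `library, barcode`; defaults to the simulation
#'   libraries (or [default_libraries()]).
#' @param tag Intron 3'-end tag.
#' @param trim_bounds,trim_tail Flank length bounds and low-quality tail.
#' @param map_mode `"unique-only"` or `"best-first"` (see
#'   [collapse_events()]).
#' @param K,S Subsampling parameters; `S = NULL` uses the largest size all
#'   libraries support, `K = 0` skips subsampling.
#' @param bin_size bedGraph bin width.
#' @param cutoff,w_up,w_down Profile parameters (see [build_profile()]).
#' @param profile_weighted Weight profile columns by relative frequency.
#' @param seed Seed recorded in the manifest and used for subsampling.
#' @return An object of class `rigseq_config`.
#' @export
rigseq_config <- function(simulate = sim_config(),
                          fastq = NULL, reference = NULL,
                          index_table = NULL,
                          tag = NULL,
                          trim_bounds = c(15L, 16L), trim_tail = 5L,
                          map_mode = "unique-only",
                          K = 100L, S = NULL, bin_size = 1000L,
                          cutoff = 5e-3, w_up = 12L, w_down = 6L,
                          profile_weighted = TRUE,
                          seed = 1L) {
  if (is.null(index_table)) {
    index_table <- if (!is.null(simulate)) simulate$libraries else default_libraries()
  }
  if (is.null(tag)) {
    tag <- if (!is.null(simulate)) simulate$tag else rigseq_tag()
  }
  structure(
    list(simulate = simulate, fastq = fastq, reference = reference,
         index_table = as_tibble(index_table), tag = toupper(tag),
         trim_bounds = as.integer(trim_bounds), trim_tail = as.integer(trim_tail),
         map_mode = map_mode, K = as.integer(K), S = S,
         bin_size = as.integer(bin_size),
         cutoff = cutoff, w_up = as.integer(w_up), w_down = as.integer(w_down),
         profile_weighted = profile_weighted,
         seed = as.integer(seed)),
    class = "rigseq_config"
  )
}

#' Validate a pipeline configuration
#'
#' @param config A [rigseq_config()].
#' @return A character vector of violations; empty means the configuration
#'   is runnable.
#' @export
validate_config <- function(config) {
  v <- character(0)
  if (is.null(config$tag) || !nzchar(config$tag)) {
    v <- c(v, "missing tag")
  } else if (nchar(config$tag) < 8) {
    v <- c(v, "tag shorter than 8 nt")
  }
  if (is.null(config$simulate)) {
    if (is.null(config$fastq) || !file.exists(config$fastq)) {
      v <- c(v, "input FASTQ missing or not found")
    }
    if (is.null(config$reference) || !file.exists(config$reference)) {
      v <- c(v, "reference FASTA missing or not found")
    }
  }
  bc <- config$index_table$barcode
  if (anyDuplicated(toupper(bc))) v <- c(v, "duplicate barcodes in index table")
  if (any(nchar(bc) != 6)) v <- c(v, "barcodes must be 6 nt")
  if (config$K > 0 && !is.null(config$S) && !is.null(config$simulate)) {
    if (config$S > min(config$simulate$libraries$reads)) {
      v <- c(v, "subset size S exceeds the smallest library")
    }
  }
  if (config$w_up < 6 || config$w_down < 5) {
    v <- c(v, "profile window must cover positions -6 and +5")
  }
  v
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> trim -> map -> count -> profile, writing
#' every stage's outputs under `outdir` together with a JSON run manifest
#' (tool version, configuration snapshot, per-stage counts and output
#' checksums). Re-running with the same configuration and seed reproduces
#' byte-identical TSV outputs.
#'
#' @param config A [rigseq_config()]; validated before anything runs.
#' @param outdir Output directory (created if needed).
#' @return A list with the in-memory stage results (`reference`, `truth`,
#'   `trim`, `mapped`, `summary`, `events`, `subsamples`, `profiles`,
#'   `key_stats`) and the `manifest`.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "rigseq_config"))
  violations <- validate_config(config)
  if (length(violations) > 0) {
    abort(paste0("invalid configuration: ", paste(violations, collapse = "; ")))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()
  outputs <- character(0)
  log_line <- function(stage, msg) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)))
    })
  }

  # -- simulate / load ------------------------------------------------------
  truth <- NULL
  res <- run_stage("simulate", {
    if (!is.null(config$simulate)) {
      sim <- simulate_rigseq(config$simulate)
      write_reference_fasta(sim$reference, file.path(outdir, "reference.fasta"))
      write_fastq(sim$reads, file.path(outdir, "reads.fastq"))
      write_truth_tsv(sim$truth, file.path(outdir, "truth.tsv"))
      truth <<- sim$truth
      log_line("simulate", sprintf("%d reads, %d truth events", nrow(sim$reads), nrow(sim$truth)))
      list(reads = sim$reads[, c("id", "sequence", "quality")],
           reference = sim$reference)
    } else {
      # the FASTQ itself is parsed (and validated) by the trim stage
      list(reads = config$fastq,
           reference = read_reference_fasta(
             config$reference,
             circular = TRUE,
             role = c("chromosome", "donor_plasmid")
           ))
    }
  })
  reads <- res$reads
  reference <- res$reference
  stage_counts$simulate <- list(reads = if (is.data.frame(reads)) nrow(reads) else NA)
  outputs <- c(outputs, file.path(outdir, c("reference.fasta", "reads.fastq", "truth.tsv")))

  # -- trim -----------------------------------------------------------------
  trim <- run_stage("trim", run_trim(reads, config$index_table, config$tag,
                                     bounds = config$trim_bounds,
                                     tail = config$trim_tail))
  readr::write_tsv(trim$flanks, file.path(outdir, "flanks.tsv"))
  readr::write_tsv(trim$report, file.path(outdir, "trim_report.tsv"))
  stage_counts$trim <- list(
    input = sum(trim$report$count),
    accepted = trim$report$count[trim$report$category == "accepted"]
  )
  log_line("trim", sprintf("%d/%d reads accepted",
                           stage_counts$trim$accepted, stage_counts$trim$input))
  outputs <- c(outputs, file.path(outdir, c("flanks.tsv", "trim_report.tsv")))

  # -- map ------------------------------------------------------------------
  index <- run_stage("map", index_reference(
    reference, k = seq(config$trim_bounds[1], config$trim_bounds[2])
  ))
  mapped <- run_stage("map", map_flanks(trim$flanks, index))
  readr::write_tsv(select(mapped, -"flank"), file.path(outdir, "mapped.tsv"))
  summary_tbl <- replicon_summary(mapped)
  readr::write_tsv(summary_tbl, file.path(outdir, "replicon_summary.tsv"))
  stage_counts$map <- list(input = nrow(mapped),
                           unique = sum(mapped$status == "unique"))
  log_line("map", sprintf("%d/%d flanks uniquely mapped", stage_counts$map$unique, nrow(mapped)))
  outputs <- c(outputs, file.path(outdir, c("mapped.tsv", "replicon_summary.tsv")))

  # -- count ----------------------------------------------------------------
  events <- run_stage("count", {
    collapse_events(mapped, index, mode = config$map_mode) |>
      relative_frequencies()
  })
  readr::write_tsv(events, file.path(outdir, "events.tsv"))
  tracks <- write_tracks(events, file.path(outdir, "tracks"), bin_size = config$bin_size)
  subsamples <- NULL
  if (config$K > 0) {
    subsamples <- run_stage("count", {
      purrr::map(setNames(nm = unique(mapped$library)), function(lib) {
        pool <- sum(mapped$library == lib & mapped$status == "unique" &
                      mapped$role == "chromosome")
        S <- config$S %||% min(pool, 10000L)
        if (pool == 0 || S > pool) return(NULL)
        subsample_unique_counts(mapped, index, K = config$K, S = S,
                                seed = config$seed, library = lib)
      })
    })
    sub_tbl <- purrr::imap_dfr(purrr::compact(subsamples), function(s, lib) {
      tibble(library = lib, K = s$K, S = s$S, seed = s$seed,
             mean_unique = s$mean, sd_unique = s$sd, total_unique = s$total_unique)
    })
    readr::write_tsv(sub_tbl, file.path(outdir, "subsample_summary.tsv"))
    outputs <- c(outputs, file.path(outdir, "subsample_summary.tsv"))
  }
  stage_counts$count <- list(events = nrow(events))
  log_line("count", sprintf("%d unique insertion events", nrow(events)))
  outputs <- c(outputs, file.path(outdir, "events.tsv"), tracks$files$bed, tracks$files$bedgraph)

  # -- profile --------------------------------------------------------------
  profiles <- run_stage("profile", {
    purrr::map(setNames(nm = unique(events$library)), function(lib) {
      ev <- events |> filter(.data$library == lib, .data$role == "chromosome")
      if (nrow(ev) == 0) return(NULL)
      win <- extract_windows(ev, reference, w_up = config$w_up, w_down = config$w_down)
      build_profile(win, w_up = config$w_up, w_down = config$w_down,
                    cutoff = config$cutoff, weighted = config$profile_weighted)
    })
  })
  profiles <- purrr::compact(profiles)
  key_stats <- purrr::imap_dfr(profiles, function(p, lib) {
    mutate(key_position_stats(p), library = lib, .before = 1)
  })
  for (lib in names(profiles)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", lib)
    readr::write_tsv(tidy(profiles[[lib]]),
                     file.path(outdir, sprintf("profile_%s.tsv", safe)))
    outputs <- c(outputs, file.path(outdir, sprintf("profile_%s.tsv", safe)))
  }
  readr::write_tsv(key_stats, file.path(outdir, "key_position_stats.tsv"))
  outputs <- c(outputs, file.path(outdir, "key_position_stats.tsv"))
  stage_counts$profile <- list(libraries = length(profiles))
  log_line("profile", sprintf("%d library profiles", length(profiles)))

  # -- manifest -------------------------------------------------------------
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    tool = "rigseq",
    version = as.character(utils::packageVersion("rigseq")),
    seed = config$seed,
    config = list(
      tag = config$tag, trim_bounds = config$trim_bounds,
      trim_tail = config$trim_tail, map_mode = config$map_mode,
      K = config$K, S = config$S, bin_size = config$bin_size,
      cutoff = config$cutoff, w_up = config$w_up, w_down = config$w_down,
      simulated = !is.null(config$simulate)
    ),
    stages = stage_counts,
    outputs = lapply(setNames(nm = basename(outputs)), function(f) {
      unname(tools::md5sum(outputs[basename(outputs) == f][1]))
    })
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(reference = reference, truth = truth, trim = trim, mapped = mapped,
       summary = summary_tbl, events = events, subsamples = subsamples,
       profiles = profiles, key_stats = key_stats, manifest = manifest)
}
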