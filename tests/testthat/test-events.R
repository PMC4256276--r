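# Event collapsing, relative frequencies, reservoir subsampling, tracks.

toy_index <- function(L = 500, seed = 51) {
  index_reference(dplyr::bind_rows(
    replicon("chrom", random_seq(L, seed = seed), circular = TRUE, role = "chromosome"),
    replicon("plasmid", random_seq(300, seed = seed + 1), circular = TRUE,
             role = "donor_plasmid")
  ))
}

mk_mapped <- function(strand, start, length = 16L, lib = "L",
                      replicon = "chrom", role = "chromosome",
                      status = "unique") {
  tibble::tibble(
    source_id = paste0("r", seq_along(strand)), library = lib, flank = "X",
    replicon = replicon, role = role, strand = strand, start = start,
    length = length, n_hits = 1L, status = status
  )
}

test_that("collapsing follows the 3'-flank boundary convention", {
  idx <- toy_index()
  # three + strand reads starting at 100 -> one event at boundary 100
  ev <- collapse_events(mk_mapped(rep("+", 3), rep(100L, 3)), idx)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$boundary, 100)
  expect_equal(ev$read_count, 3)

  # a + read at 100 and a - read over [84, 100) share the boundary, not the event
  ev2 <- collapse_events(mk_mapped(c("+", "-"), c(100L, 84L)), idx)
  expect_equal(nrow(ev2), 2)
  expect_equal(sort(ev2$boundary), c(100, 100))
  expect_setequal(ev2$strand, c("+", "-"))

  # minus-strand boundary wraps on circular replicons
  ev3 <- collapse_events(mk_mapped("-", 490L), idx)
  expect_equal(ev3$boundary, (490 + 16) %% 500)

  expect_equal(nrow(collapse_events(mk_mapped(character(0), integer(0)), idx)), 0)

  # best-first mode also counts ambiguous flanks at their reported placement
  amb <- mk_mapped(c("+", "+"), c(10L, 10L), status = c("unique", "ambiguous"))
  expect_equal(collapse_events(amb, idx)$read_count, 1)
  expect_equal(collapse_events(amb, idx, mode = "best-first")$read_count, 2)
})

test_that("relative frequencies normalize within library and replicon role", {
  idx <- toy_index()
  mapped <- dplyr::bind_rows(
    mk_mapped(rep("+", 3), rep(100L, 3)),
    mk_mapped("+", 200L),
    mk_mapped(rep("+", 2), rep(50L, 2), replicon = "plasmid", role = "donor_plasmid")
  )
  ev <- relative_frequencies(collapse_events(mapped, idx))
  chrom <- ev[ev$role == "chromosome", ]
  expect_equal(sort(chrom$rel_freq), c(0.25, 0.75))
  expect_equal(sum(chrom$rel_freq), 1, tolerance = 1e-9)
  expect_equal(ev$rel_freq[ev$role == "donor_plasmid"], 1)
  expect_equal(ev$freq_scope[ev$role == "donor_plasmid"], "donor_plasmid")

  single <- relative_frequencies(collapse_events(mk_mapped("+", 10L), idx))
  expect_equal(single$rel_freq, 1)

  # exact arithmetic on a fixed multinomial draw
  counts <- withr::with_seed(1, as.integer(stats::rmultinom(1, 500, rep(1 / 20, 20))))
  mapped20 <- mk_mapped(rep("+", sum(counts)),
                        rep(seq(0, by = 20, length.out = 20), counts))
  ev20 <- relative_frequencies(collapse_events(mapped20, idx))
  expect_equal(sort(ev20$rel_freq), sort(counts[counts > 0] / sum(counts)))

  zero <- tibble::tibble(library = "L", replicon = "chrom", role = "chromosome",
                         boundary = 1L, strand = "+", read_count = 0L)
  expect_warning(rf <- relative_frequencies(zero), "zero")
  expect_true(is.na(rf$rel_freq))
})

test_that("exhaustive subsets reproduce the total unique-site count", {
  idx <- toy_index()
  mapped <- mk_mapped(rep("+", 6), c(10L, 10L, 20L, 30L, 30L, 30L))
  s <- subsample_unique_counts(mapped, idx, K = 5, S = 6, seed = 1)
  expect_true(all(s$counts == 3))
  expect_equal(s$sd, 0)
  expect_error(subsample_unique_counts(mapped, idx, K = 2, S = 7, seed = 1),
               "exceeds")
})

test_that("subsampling matches exact enumeration on toy libraries", {
  idx <- toy_index()
  # 3 reads at 2 sites (counts 2,1), S = 2: exact mean = 5/3
  mapped <- mk_mapped(rep("+", 3), c(10L, 10L, 20L))
  expect_equal(enum_mean_unique(c(1, 1, 2), 2), 5 / 3)
  s <- subsample_unique_counts(mapped, idx, K = 10000, S = 2, seed = 7)
  expect_lt(abs(s$mean - 5 / 3), 3 * s$sd / sqrt(s$K))

  # a 12-read library with an uneven site spectrum, S grid
  starts <- c(rep(10L, 5), rep(20L, 3), rep(30L, 2), 40L, 50L)
  mapped12 <- mk_mapped(rep("+", 12), starts)
  keys <- as.integer(factor(starts))
  means <- vapply(c(3L, 6L, 9L), function(S) {
    s <- subsample_unique_counts(mapped12, idx, K = 2000, S = S, seed = 11)
    expect_lt(abs(s$mean - enum_mean_unique(keys, S)),
              3 * s$sd / sqrt(s$K))
    s$mean
  }, numeric(1))
  # mean unique count is non-decreasing in S
  expect_true(all(diff(means) >= 0))
})

test_that("subsampling metadata and tidiers expose K, S and counts", {
  idx <- toy_index()
  mapped <- mk_mapped(rep("+", 10), rep(c(10L, 20L), 5))
  s <- subsample_unique_counts(mapped, idx, K = 25, S = 4, seed = 3)
  expect_equal(glance(s)$K, 25)
  expect_equal(glance(s)$S, 4)
  expect_equal(nrow(tidy(s)), 25)
  expect_equal(tidy(s)$unique_sites, s$counts)
  # reproducible under the same seed
  s2 <- subsample_unique_counts(mapped, idx, K = 25, S = 4, seed = 3)
  expect_identical(s$counts, s2$counts)
  expect_s3_class(autoplot(s), "ggplot")
  ev <- relative_frequencies(collapse_events(mapped, idx))
  expect_s3_class(plot_insertion_map(ev), "ggplot")
})

test_that("relaxase-style libraries keep more unique sites at fixed depth", {
  libs <- tiny_libraries(n_sites = c(20L, 80L), reads = c(4000L, 4000L))
  libs$chrom_read_fraction <- c(0.9, 0.9)
  libs$freq_concentration <- c(2, 4)
  cfg <- tiny_config(seed = 61, libraries = libs)
  sim <- simulate_rigseq(cfg)
  tr <- run_trim(sim$reads, cfg$libraries, cfg$tag)
  idx <- index_reference(sim$reference)
  mapped <- map_flanks(tr$flanks, idx)
  s_off <- subsample_unique_counts(mapped, idx, K = 50, S = 1000, seed = 1,
                                   library = "D-C")
  s_on <- subsample_unique_counts(mapped, idx, K = 50, S = 1000, seed = 1,
                                  library = "D-pRS01")
  expect_gt(s_on$mean, s_off$mean)
})

test_that("tracks conserve relative-frequency mass and use point intervals", {
  idx <- toy_index()
  mapped <- dplyr::bind_rows(
    mk_mapped(rep("+", 3), rep(100L, 3)),
    mk_mapped("+", 120L),
    mk_mapped("+", 400L)
  )
  ev <- relative_frequencies(collapse_events(mapped, idx))
  dir <- withr::local_tempdir()
  tracks <- write_tracks(ev, dir, bin_size = 100L)

  bed <- readr::read_tsv(tracks$files$bed[1],
                         col_names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         col_types = "ciicic")
  expect_equal(bed$start, c(100, 120, 400))
  expect_equal(bed$end, bed$start + 1)
  expect_equal(bed$score, c(600L, 200L, 200L))

  # two events fall in bin [100, 200): bedGraph value is their summed rel_freq
  b100 <- tracks$bins[tracks$bins$bin_start == 100, ]
  expect_equal(b100$value, 0.8)
  expect_equal(sum(tracks$bins$value), 1, tolerance = 1e-9)

  # the written bedGraph round-trips through a standard genome-track parser
  gr <- rtracklayer::import(tracks$files$bedgraph[1], format = "bedGraph")
  expect_equal(sum(gr$score), 1, tolerance = 1e-6)
})
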