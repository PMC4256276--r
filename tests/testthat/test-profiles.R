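# Insertion-site windows, profiles, consensus and homing comparison.

test_that("windows follow the -W..-1/+1..+W convention on both strands", {
  seq30 <- "ACGTTGCAGGATCCTAGGCATCGATTGCAA"
  ref <- replicon("chrom", seq30, circular = TRUE, role = "chromosome")
  ev <- function(b, strand) {
    tibble::tibble(library = "L", replicon = "chrom", role = "chromosome",
                   boundary = b, strand = strand, read_count = 1L,
                   rel_freq = 1, freq_scope = "chromosome")
  }

  # + strand at b = 12: upstream is reference[0, 12)
  w <- extract_windows(ev(12L, "+"), ref)
  expect_equal(substr(w$window, 1, 12), substr(seq30, 1, 12))
  expect_equal(substr(w$window, 13, 18), substr(seq30, 13, 18))

  # - strand at the same boundary mirrors by reverse complement
  wm <- extract_windows(ev(12L, "-"), ref)
  expect_equal(wm$window, revcomp(substr(seq30, 12 - 6 + 1, 12 + 12)))

  # wrap: b = 2 on circular L = 30 reads upstream offsets 20..29, 0, 1
  ww <- extract_windows(ev(2L, "+"), ref)
  expect_equal(substr(ww$window, 1, 12),
               paste0(substr(seq30, 21, 30), substr(seq30, 1, 2)))

  lin <- replicon("lin", substr(seq30, 1, 20), circular = FALSE, role = "chromosome")
  expect_error(extract_windows(ev(2L, "+") |>
                                 dplyr::mutate(replicon = "lin"), lin),
               "out of range")
})

mk_windows <- function(strings, weights = rep(1, length(strings))) {
  tibble::tibble(library = "L", replicon = "chrom",
                 boundary = seq_along(strings), strand = "+",
                 window = strings, weight = weights)
}

test_that("profiles are weighted column distributions that sum to one", {
  win <- mk_windows(
    c(paste0("AAAAAACAAAAA", "AAAAAA"),   # C at -6
      paste0("AAAAAATAAAAA", "AAAAAA")),  # T at -6
    weights = c(0.75, 0.25)
  )
  p <- build_profile(win, cutoff = 0)
  expect_equal(unname(p$matrix[c("C", "T"), "-6"]), c(0.75, 0.25))
  expect_equal(unname(colSums(p$matrix)), rep(1, 18), tolerance = 1e-9)

  # cutoff excludes light windows; excluding all is an error
  p2 <- build_profile(win, cutoff = 0.5)
  expect_equal(p2$n_sites, 1)
  expect_equal(unname(p2$matrix["C", "-6"]), 1)
  expect_error(build_profile(win, cutoff = 0.9), "cutoff")

  # equal weights make weighted and unweighted profiles identical
  eq <- mk_windows(vapply(1:20, function(i) random_seq(18, seed = i),
                          character(1)),
                   weights = rep(1 / 20, 20))
  expect_equal(build_profile(eq, cutoff = 0, weighted = TRUE)$matrix,
               build_profile(eq, cutoff = 0, weighted = FALSE)$matrix)
})

test_that("key-position statistics read C-6/T+5 and flag the endonuclease signature", {
  allC <- mk_windows(rep(paste0("AAAAAACAAAAA", "AAAATA"), 10))
  ks <- key_position_stats(build_profile(allC, cutoff = 0))
  expect_equal(ks$freq_C_minus6, 1.0)
  expect_equal(ks$freq_T_plus5, 1.0)
  expect_true(ks$endo_compatible)

  # 96/100 T at +5 crosses the > 0.95 double-strand-pathway threshold; 60 does not
  t5 <- function(n_t) mk_windows(c(
    rep(paste0(strrep("A", 12), "AAAATA"), n_t),
    rep(paste0(strrep("A", 12), "AAAAGA"), 100 - n_t)
  ))
  expect_true(key_position_stats(build_profile(t5(96), cutoff = 0))$endo_compatible)
  expect_false(key_position_stats(build_profile(t5(60), cutoff = 0))$endo_compatible)

  narrow <- build_profile(mk_windows(rep("AAAA", 5)), w_up = 2, w_down = 2,
                          cutoff = 0)
  expect_error(key_position_stats(narrow), "outside")
})

test_that("consensus uses majority calls and minimal IUPAC covers", {
  one_col <- function(bases, weights) {
    build_profile(mk_windows(bases, weights), w_up = 0L, w_down = 1L, cutoff = 0)
  }
  expect_equal(consensus(one_col(c("C", "C", "C", "C", "C", "C", "C", "C", "C", "A"),
                                 rep(0.1, 10))), "C")
  expect_equal(consensus(one_col(c("A", "A", "A", "A", "G", "G", "G", "G", "C", "T"),
                                 rep(0.1, 10))), "R")
  expect_equal(consensus(one_col(c("A", "A", "A", "C", "C", "C", "G", "G", "G", "T"),
                                 rep(0.1, 10))), "V")
})

test_that("homing comparison reports matches and Shannon information", {
  # deterministic profile identical to the model consensus: all match, 2 bits
  site <- "AAGTGGCAACGGACGATA"
  cmp <- compare_to_homing(build_profile(mk_windows(rep(site, 3)), cutoff = 0),
                           homing_site_model(site))
  expect_true(all(cmp$match))
  expect_equal(cmp$information, rep(2, 18))
  expect_equal(cmp$position, c(-12:-1, 1:6))

  # uniform columns carry 0 bits (constant-letter windows, one per base)
  uni <- build_profile(mk_windows(strrep(c("A", "C", "G", "T"), 18L)), cutoff = 0)
  cmp_u <- compare_to_homing(uni, homing_site_model())
  expect_equal(cmp_u$information, rep(0, 18))

  # {C: 0.9, A/G/T: 0.1/3 each}: information = 2 - H = 1.3725082 bits
  mix <- build_profile(mk_windows(strrep(c(rep("C", 27), "A", "G", "T"), 18L)),
                       cutoff = 0)
  cmp_m <- compare_to_homing(mix, homing_site_model(strrep("C", 18)))
  expect_equal(cmp_m$information, rep(1.3725082, 18), tolerance = 1e-6)
  expect_equal(cmp_m$modal_base, rep("C", 18))
  expect_true(all(cmp_m$match))

  # degenerate model codes cover their expansion
  d <- build_profile(mk_windows(strrep(rep("G", 4), 18L)), cutoff = 0)
  expect_true(all(compare_to_homing(d, homing_site_model(strrep("R", 18)))$match))
  expect_false(any(compare_to_homing(d, homing_site_model(strrep("Y", 18)))$match))
})

test_that("narrow homing models must still contain the key positions", {
  expect_error(homing_site_model("ACGT", w_up = 2L, w_down = 2L), "key positions")
  expect_error(homing_site_model("ACGTACGT", w_up = 12L, w_down = 6L), "length")
})

test_that("profiles recover the planted p_C6/p_T5 across parameter settings", {
  for (p in c(0.25, 0.5, 0.9)) {
    for (n_sites in c(50L, 500L)) {
      libs <- tiny_libraries(n_sites = c(n_sites, 2L), reads = c(10L, 10L))
      cfg <- tiny_config(seed = round(1000 * p) + n_sites,
                         chrom_length = 50000L, libraries = libs,
                         p_C6 = p, p_T5 = p)
      planted <- plant_sites(build_reference(cfg), cfg, "D-C")
      truth <- planted$truth[planted$truth$role == "chromosome", ]
      ev <- truth |>
        dplyr::rename(boundary = coordinate, rel_freq = true_frequency)
      prof <- build_profile(extract_windows(ev, planted$reference),
                            cutoff = 0, weighted = FALSE)
      ks <- key_position_stats(prof)
      se3 <- 3 * sqrt(p * (1 - p) / n_sites)
      expect_lt(abs(ks$freq_C_minus6 - p), se3 + 1e-9)
      expect_lt(abs(ks$freq_T_plus5 - p), se3 + 1e-9)
    }
  }
})

test_that("profiles are invariant under a global strand flip of the data", {
  cfg <- tiny_config(seed = 77, libraries = tiny_libraries(n_sites = c(40L, 2L),
                                                           reads = c(10L, 10L)))
  planted <- plant_sites(build_reference(cfg), cfg, "D-C")
  truth <- planted$truth[planted$truth$role == "chromosome", ]
  ev <- truth |> dplyr::rename(boundary = coordinate, rel_freq = true_frequency)
  p1 <- build_profile(extract_windows(ev, planted$reference), cutoff = 0)

  # reverse-complement the reference and mirror every event
  ref <- planted$reference
  L <- ref$length[ref$role == "chromosome"]
  flipped_ref <- ref
  flipped_ref$sequence <- revcomp(ref$sequence)
  ev2 <- ev |>
    dplyr::mutate(boundary = (L - boundary) %% L,
                  strand = ifelse(strand == "+", "-", "+"))
  p2 <- build_profile(extract_windows(ev2, flipped_ref), cutoff = 0)
  expect_equal(p1$matrix, p2$matrix)
})

test_that("profile tidiers and plots expose the matrix faithfully", {
  win <- mk_windows(vapply(1:10, function(i) random_seq(18, seed = 100 + i),
                           character(1)))
  p <- build_profile(win, cutoff = 0)
  td <- tidy(p)
  expect_equal(nrow(td), 18 * 4)
  expect_equal(td$freq[td$label == "-6" & td$base == "C"],
               unname(p$matrix["C", "-6"]))
  g <- glance(p)
  expect_equal(g$n_sites, 10)
  expect_s3_class(autoplot(p), "ggplot")
})
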