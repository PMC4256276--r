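# Insertion-site sequence profiles. Windows around each boundary are read on
# the event strand with the field's numbering: positions -W_up..-1 upstream,
# +1..+W_down downstream, no position 0 (the intron sits between -1 and +1).
# The upstream (5'-exon) sequence comes from the reference — the sequenced
# read carries only the 3' flank, so the reference is the only source of
# upstream composition. Columns can be weighted by relative retrotransposition
# frequency (with the published 5e-3 cutoff) or unweighted over the whole
# site set; both modes are standard outputs.

#' Extract insertion-site windows around events
#'
#' For a plus-strand event at boundary `b` the window is
#' `reference[b - w_up, b + w_down)`; minus-strand events take the reverse
#' complement mirror, `revcomp(reference[b - w_down, b + w_up))`. Circular
#' replicons wrap; linear replicons too short for the window raise an error.
#'
#' @param events Tibble from [relative_frequencies()] (needs `replicon,
#'   boundary, strand, rel_freq`).
#' @param reference Replicon tibble.
#' @param w_up,w_down Window extent upstream/downstream of the boundary
#'   (default 12/6, spanning the intron-binding sites IBS2/IBS1 upstream and
#'   the delta-prime/+5 region downstream).
#' @return Tibble `library, replicon, boundary, strand, window, weight`.
#' @export
extract_windows <- function(events, reference, w_up = 12L, w_down = 6L) {
  ev <- as_tibble(events)
  out <- purrr::map_dfr(unique(ev$replicon), function(nm) {
    r <- replicon_by_name(reference, nm)
    e <- ev |> filter(.data$replicon == nm)
    plus <- e$strand == "+"
    start0 <- ifelse(plus, e$boundary - w_up, e$boundary - w_down)
    win <- substr_circ(r$sequence, start0, w_up + w_down, circular = r$circular)
    win[!plus] <- revcomp(win[!plus])
    e |>
      mutate(window = win, weight = .data$rel_freq) |>
      select("library", "replicon", "boundary", "strand", "window", "weight")
  })
  out[order(match(out$library, unique(ev$library))), ]
}

#' Build a position-frequency profile from site windows
#'
#' Windows whose weight falls below `cutoff` are excluded (the published
#' weighted analysis used a relative-frequency cutoff of 5.0e-3); each
#' retained window contributes its weight (or 1 in unweighted mode) to the
#' base observed at each position, and columns are normalized to sum to 1.
#'
#' @param windows Tibble from [extract_windows()].
#' @param w_up,w_down Window extent (must match the extraction).
#' @param cutoff Minimum weight for inclusion (default `5e-3`; use 0 for the
#'   whole-site-set analysis).
#' @param weighted If `FALSE`, all retained windows weigh 1.
#' @return An object of class `rigseq_profile`: a 4 x (w_up + w_down) matrix
#'   of base frequencies (rows A/C/G/T, columns labelled `-w_up`..`+w_down`)
#'   with `n_sites`, `total_weight`, `cutoff` and `weighted` metadata.
#' @export
build_profile <- function(windows, w_up = 12L, w_down = 6L,
                          cutoff = 5e-3, weighted = TRUE) {
  win <- as_tibble(windows) |> filter(.data$weight >= cutoff)
  if (nrow(win) == 0) {
    abort("no windows at or above the relative-frequency cutoff; profile would be empty")
  }
  width <- w_up + w_down
  if (any(nchar(win$window) != width)) {
    abort("window strings do not match w_up + w_down")
  }
  w <- if (weighted) win$weight else rep(1, nrow(win))
  chars <- matrix(unlist(strsplit(win$window, "", fixed = TRUE)),
                  nrow = nrow(win), byrow = TRUE)
  counts <- vapply(DNA_ALPHABET, function(b) colSums((chars == b) * w),
                   numeric(width))
  mat <- t(matrix(counts, nrow = width)) / sum(w)  # rows = bases, cols = positions
  dimnames(mat) <- list(DNA_ALPHABET, position_labels(w_up, w_down))
  structure(
    list(matrix = mat, w_up = as.integer(w_up), w_down = as.integer(w_down),
         n_sites = nrow(win), total_weight = sum(win$weight),
         cutoff = cutoff, weighted = weighted),
    class = "rigseq_profile"
  )
}

#' @export
print.rigseq_profile <- function(x, ...) {
  cat(sprintf(
    "<rigseq insertion-site profile: %d sites, window -%d..+%d, %s%s>\n",
    x$n_sites, x$w_up, x$w_down,
    if (x$weighted) "frequency-weighted" else "unweighted",
    if (x$cutoff > 0) sprintf(", cutoff %.1e", x$cutoff) else ""
  ))
  print(round(x$matrix, 3))
  invisible(x)
}

profile_column <- function(profile, position) {
  lab <- if (position < 0) as.character(position) else paste0("+", position)
  if (!lab %in% colnames(profile$matrix)) {
    abort(sprintf("position %s outside the profile window", lab))
  }
  profile$matrix[, lab]
}

#' Key-position statistics of an insertion-site profile
#'
#' Reads the C frequency at -6 (the most conserved insertion-site residue)
#' and the T frequency at +5. A T+5 frequency above 0.95 is the signature of
#' endonuclease-dependent double-strand-DNA invasion, so the result carries
#' an `endo_compatible` flag at that threshold; low T+5 marks the
#' single-strand pathway.
#'
#' @param profile A [build_profile()] object whose window covers -6 and +5.
#' @return A one-row tibble `freq_C_minus6, freq_T_plus5, endo_compatible,
#'   n_sites`.
#' @export
key_position_stats <- function(profile) {
  fc <- unname(profile_column(profile, -6L)["C"])
  ft <- unname(profile_column(profile, 5L)["T"])
  tibble(
    freq_C_minus6 = fc,
    freq_T_plus5 = ft,
    endo_compatible = ft > 0.95,
    n_sites = profile$n_sites
  )
}

#' Consensus string of a profile
#'
#' Per column: the base itself if its frequency reaches `threshold`,
#' otherwise the minimal IUPAC degenerate code covering every base at or
#' above `secondary`, otherwise `N`.
#'
#' @param profile A [build_profile()] object.
#' @param threshold Single-base call threshold (default 0.5).
#' @param secondary Frequency needed to enter a degenerate code
#'   (default 0.25).
#' @return A single consensus string, one character per window position.
#' @export
consensus <- function(profile, threshold = 0.5, secondary = 0.25) {
  cols <- seq_len(ncol(profile$matrix))
  chars <- vapply(cols, function(j) {
    col <- profile$matrix[, j]
    top <- names(col)[which.max(col)]
    if (max(col) >= threshold) return(top)
    iupac_code(names(col)[col >= secondary])
  }, character(1))
  paste(chars, collapse = "")
}

#' Compare a profile to a homing-site model
#'
#' Per position: the profile's modal base, the model consensus character,
#' whether the modal base is covered by the (possibly degenerate) model
#' character, and the Shannon information content `2 - H` in bits — the
#' logo-ready table.
#'
#' @param profile A [build_profile()] object.
#' @param model A [homing_site_model()]; positions outside the shared span
#'   are dropped.
#' @return Tibble `position, label, modal_base, modal_freq, model_base,
#'   match, information`.
#' @export
compare_to_homing <- function(profile, model = homing_site_model()) {
  pos_p <- position_values(profile$w_up, profile$w_down)
  pos_m <- position_values(model$w_up, model$w_down)
  shared <- intersect(pos_p, pos_m)
  if (length(shared) == 0) abort("profile window does not overlap the model span")
  purrr::map_dfr(shared, function(p) {
    col <- profile$matrix[, match(p, pos_p)]
    mchar <- substr(model$consensus, match(p, pos_m), match(p, pos_m))
    h <- -sum(ifelse(col > 0, col * log2(col), 0))
    tibble(
      position = p,
      label = colnames(profile$matrix)[match(p, pos_p)],
      modal_base = names(col)[which.max(col)],
      modal_freq = max(col),
      model_base = mchar,
      match = names(col)[which.max(col)] %in% iupac_expand(mchar),
      information = 2 - h
    )
  })
}
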