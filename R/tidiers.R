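# broom-style tidiers for the package's result objects.

#' Tidy an insertion-site profile
#'
#' @param x A [build_profile()] object.
#' @param ... Unused.
#' @return A long tibble `position, label, base, freq`, one row per
#'   (position, base).
#' @export
tidy.rigseq_profile <- function(x, ...) {
  pos <- position_values(x$w_up, x$w_down)
  labs <- colnames(x$matrix)
  purrr::map_dfr(seq_along(pos), function(j) {
    tibble(position = pos[j], label = labs[j],
           base = rownames(x$matrix), freq = unname(x$matrix[, j]))
  })
}

#' Glance at an insertion-site profile
#'
#' @param x A [build_profile()] object.
#' @param ... Unused.
#' @return One-row tibble with site counts, window extent, weighting mode
#'   and the key-position statistics.
#' @export
glance.rigseq_profile <- function(x, ...) {
  ks <- key_position_stats(x)
  tibble(
    n_sites = x$n_sites, total_weight = x$total_weight,
    w_up = x$w_up, w_down = x$w_down,
    weighted = x$weighted, cutoff = x$cutoff,
    freq_C_minus6 = ks$freq_C_minus6, freq_T_plus5 = ks$freq_T_plus5
  )
}

#' Tidy a subsampling result
#'
#' @param x A [subsample_unique_counts()] object.
#' @param ... Unused.
#' @return Tibble `subset, unique_sites`, one row per subset.
#' @export
tidy.rigseq_subsample <- function(x, ...) {
  tibble(subset = seq_len(x$K), unique_sites = x$counts)
}

#' Glance at a subsampling result
#'
#' @param x A [subsample_unique_counts()] object.
#' @param ... Unused.
#' @return One-row tibble `K, S, n_reads, total_unique, mean_unique,
#'   sd_unique, seed`.
#' @export
glance.rigseq_subsample <- function(x, ...) {
  tibble(K = x$K, S = x$S, n_reads = x$n_reads,
         total_unique = x$total_unique,
         mean_unique = x$mean, sd_unique = x$sd, seed = x$seed)
}
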