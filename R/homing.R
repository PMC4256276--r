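#' Homing-site model
#'
#' The homing site of the Ll.LtrB intron spans the intron-binding sequences
#' IBS2/IBS1 upstream of the insertion boundary and the delta-prime region
#' downstream; its key residues are C at -6 and T at +5 (T+5 being required
#' for the endonuclease-dependent double-strand pathway). The default
#' consensus string shipped here is an illustrative synthetic stand-in with
#' those key residues in place — all scoring is relative to whatever model
#' string the user supplies, so substituting the exact construct sequence is
#' a one-argument change.
#'
#' @param consensus Consensus string over the modelled window (IUPAC codes
#'   allowed), read left to right from `-w_up` to `+w_down` with no
#'   position 0.
#' @param w_up,w_down Window extent; `w_up + w_down` must equal
#'   `nchar(consensus)` and the window must contain positions -6 and +5.
#' @return An object of class `rigseq_homing_model`.
#' @examples
#' homing_site_model()
#' @export
homing_site_model <- function(consensus = "AAGTGGCAACGGACGATA",
                              w_up = 12L, w_down = 6L) {
  consensus <- toupper(consensus)
  if (nchar(consensus) != w_up + w_down) {
    abort("consensus length must equal w_up + w_down")
  }
  if (w_up < 6 || w_down < 5) {
    abort("model window must contain the key positions -6 and +5")
  }
  if (!all(strsplit(consensus, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP))) {
    abort("consensus must use IUPAC nucleotide codes")
  }
  structure(
    list(consensus = consensus, w_up = as.integer(w_up),
         w_down = as.integer(w_down)),
    class = "rigseq_homing_model"
  )
}

#' @export
print.rigseq_homing_model <- function(x, ...) {
  cat(sprintf("<homing-site model -%d..+%d: %s>\n", x$w_up, x$w_down, x$consensus))
  invisible(x)
}
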