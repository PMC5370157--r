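#' Deterministic global pairwise alignment
#'
#' Needleman-Wunsch with affine gap costs (Gotoh). A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`; set `gap_open == gap_extend` for
#' linear costs. Traceback ties are resolved preferring diagonal, then a
#' gap in `b`, then a gap in `a`, so the alignment is fully deterministic.
#'
#' @param a,b Ungapped nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters. Defaults
#'   are match +1, mismatch -1, gap open -2, gap extend -1.
#' @param free_ends Logical of length 1 or 2: may the terminal overhang of
#'   `a` (first element) and of `b` (second) stay unaligned for free? Both
#'   `TRUE` gives overlap alignment (a fragment inside a longer template);
#'   `c(FALSE, TRUE)` keeps `a` fully aligned while `b`'s flanks are free
#'   (a primer inside a padded binding site).
#' @return List with gapped strings `a` and `b` (equal length) and the
#'   alignment `score`.
#' @export
nw_align <- function(a, b, match = 1, mismatch = -1,
                     gap_open = -2, gap_extend = -1, free_ends = FALSE) {
  stopifnot(nzchar(a), nzchar(b))
  free_ends <- rep_len(as.logical(free_ends), 2)
  nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend,
               free_ends[1], free_ends[2])
}

# Global identity between two ungapped sequences: identical columns divided
# by total alignment length of the global alignment (linear gap -2).
global_identity <- function(a, b) {
  aln <- nw_align(a, b, match = 1, mismatch = -1,
                  gap_open = -2, gap_extend = -2, free_ends = FALSE)
  ca <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  sum(ca == cb & ca != "-") / length(ca)
}
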