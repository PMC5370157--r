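#' Prescreen shotgun reads for rRNA-like sequences
#'
#' Cheap shared-k-mer screen that reduces a metagenome to a draft set of
#' rRNA-candidate reads before the main program. A read is kept iff the
#' maximum, over representatives and over its two strands, of the fraction
#' of its distinct k-mers found in a representative is at least
#' `min_shared`. Metatranscriptome and amplicon datasets skip this step
#' entirely (rRNA already dominates them).
#'
#' @param reads Data frame with `id`, `seq`.
#' @param representatives Data frame with `id`, `seq` (ungapped), e.g. from
#'   [build_representatives()].
#' @param k Word size, default 11 (must be >= 6).
#' @param min_shared Minimum shared-k-mer fraction, default 0.10.
#' @return List with `kept` (subset of `reads`, original order) and `hits`
#'   (data frame: `read_id`, `rep_id` of the best hit, `strand`,
#'   `fraction`, `kept`).
#' @export
screen_reads <- function(reads, representatives, k = 11, min_shared = 0.10) {
  stopifnot(k >= 6)
  if (nrow(representatives) == 0L)
    stop("screen_reads: empty representative set")
  rep_sets <- lapply(representatives$seq, distinct_kmers, k = k)
  n_reads <- nrow(reads)
  hits <- data.frame(read_id = character(n_reads), rep_id = NA_character_,
                     strand = NA_character_, fraction = 0,
                     kept = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n_reads)) {
    fwd <- distinct_kmers(reads$seq[i], k)
    rev <- distinct_kmers(revcomp(reads$seq[i]), k)
    best_frac <- 0; best_rep <- NA_character_; best_strand <- NA_character_
    if (length(fwd) > 0) {
      for (r in seq_along(rep_sets)) {
        f <- sum(fwd %in% rep_sets[[r]]) / length(fwd)
        if (f > best_frac) {
          best_frac <- f; best_rep <- representatives$id[r]; best_strand <- "+"
        }
        f <- sum(rev %in% rep_sets[[r]]) / length(rev)
        if (f > best_frac) {
          best_frac <- f; best_rep <- representatives$id[r]; best_strand <- "-"
        }
      }
    }
    hits$read_id[i] <- reads$id[i]
    hits$rep_id[i] <- best_rep
    hits$strand[i] <- best_strand
    hits$fraction[i] <- best_frac
    hits$kept[i] <- best_frac >= min_shared
  }
  list(kept = reads[hits$kept, , drop = FALSE], hits = hits)
}
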