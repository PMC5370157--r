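#' Construct a reference alignment object
#'
#' The central container for a gapped rRNA reference database: rows sharing
#' one column space, an optional taxonomy (id -> lineage), and an optional
#' anchor row (the full-length marker sequence primer positions are
#' expressed against).
#'
#' @param ids Character vector of row ids (unique).
#' @param gapped Character vector of gapped sequences, all the same length;
#'   `-` is the gap character.
#' @param taxonomy Named list mapping row id -> character vector lineage.
#'   Every non-anchor row must have an entry when taxonomy is supplied.
#' @param anchor_id Id of the anchor row, if present.
#' @return An object of class `ref_alignment` with elements `ids`,
#'   `gapped` (named by id), `width`, `taxonomy`, `anchor_id`.
#' @export
ref_alignment <- function(ids, gapped, taxonomy = NULL, anchor_id = NULL) {
  stopifnot(length(ids) == length(gapped), length(ids) > 0)
  if (anyDuplicated(ids))
    stop("ref_alignment: duplicate row id(s)")
  widths <- nchar(gapped)
  if (length(unique(widths)) != 1L)
    stop("ref_alignment: rows differ in length (e.g. '",
         ids[widths != widths[1]][1], "')")
  if (!is.null(anchor_id) && !anchor_id %in% ids)
    stop("ref_alignment: anchor_id '", anchor_id, "' not among rows")
  if (!is.null(taxonomy)) {
    need <- setdiff(ids, anchor_id)
    missing <- setdiff(need, names(taxonomy))
    if (length(missing) > 0)
      stop("ref_alignment: no taxonomy for: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  gapped <- stats::setNames(gapped, ids)
  structure(list(ids = ids, gapped = gapped, width = widths[1],
                 taxonomy = taxonomy, anchor_id = anchor_id),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat("ref_alignment:", length(x$ids), "rows x", x$width, "columns\n")
  if (!is.null(x$anchor_id)) cat("  anchor:", x$anchor_id, "\n")
  if (!is.null(x$taxonomy)) cat("  taxonomy entries:", length(x$taxonomy), "\n")
  invisible(x)
}

# Ungapped sequence of one alignment row.
template_ungapped <- function(aln, id) degap(unname(aln$gapped[[id]]))

#' Build a representative set by greedy identity clustering
#'
#' Greedy incremental clustering in descending length order (ties broken by
#' id): each sequence joins the first existing representative it matches at
#' global identity >= `identity`, otherwise it founds a new representative.
#' Identity is identical columns over global-alignment length
#' (Needleman-Wunsch, match +1, mismatch -1, linear gap -2). Used to shrink
#' a reference database to the small query set the prescreen needs.
#'
#' @param refs Data frame with `id`, `seq` (ungapped).
#' @param identity Identity threshold in (0, 1]; default 0.75.
#' @return The representative subset of `refs`, in founding order.
#' @export
build_representatives <- function(refs, identity = 0.75) {
  stopifnot(identity > 0, identity <= 1)
  if (nrow(refs) == 0L) return(refs)
  ord <- order(-nchar(refs$seq), refs$id)
  refs <- refs[ord, , drop = FALSE]
  rep_idx <- integer(0)
  for (i in seq_len(nrow(refs))) {
    placed <- FALSE
    for (r in rep_idx) {
      if (global_identity(refs$seq[i], refs$seq[r]) >= identity) {
        placed <- TRUE
        break
      }
    }
    if (!placed) rep_idx <- c(rep_idx, i)
  }
  out <- refs[rep_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map ungapped anchor positions to alignment columns
#'
#' Enumerates the non-gap columns of the anchor row so that every base of
#' the anchor sequence gets a unique alignment column, and vice versa.
#'
#' @param aln A [ref_alignment()].
#' @param anchor_id Row id of the anchor; defaults to `aln$anchor_id`.
#' @return List with `col_of_pos` (integer vector, position p -> column)
#'   and `pos_of_col` (integer vector of length `aln$width`, column ->
#'   position or `NA` for gap columns).
#' @export
map_anchor <- function(aln, anchor_id = aln$anchor_id) {
  if (is.null(anchor_id) || !anchor_id %in% aln$ids)
    stop("map_anchor: anchor row '", anchor_id, "' not found")
  chars <- strsplit(unname(aln$gapped[[anchor_id]]), "", fixed = TRUE)[[1]]
  col_of_pos <- which(chars != "-")
  if (length(col_of_pos) == 0L)
    stop("map_anchor: anchor row '", anchor_id, "' is all gaps")
  pos_of_col <- rep(NA_integer_, aln$width)
  pos_of_col[col_of_pos] <- seq_along(col_of_pos)
  list(col_of_pos = col_of_pos, pos_of_col = pos_of_col)
}

#' Extend reference sequences with terminal primer regions
#'
#' Many curated SSU databases lack the 8F / 1492R primer regions because
#' the deposited amplicons were generated with that pair. This utility
#' attaches a forward extension primer to the 5' end of every sequence and
#' the reverse complement of a reverse extension primer to the 3' end, so
#' primers binding in those regions can be evaluated after re-alignment.
#'
#' @param refs Data frame with `id`, `seq` (ungapped).
#' @param fwd_ext 5' extension, default the classic 8F primer.
#' @param rev_ext 3' extension (given 5'->3' on the minus strand), default
#'   1492R; its reverse complement is appended.
#' @return `refs` with extended `seq`; ids, count and order preserved.
#' @export
extend_database <- function(refs,
                            fwd_ext = "AGAGTTTGATCCTGGCTCAG",
                            rev_ext = "GGTTACCTTGTTACGACTT") {
  if (!nzchar(fwd_ext) || !nzchar(rev_ext))
    stop("extend_database: extension primers must be non-empty")
  if (nrow(refs) == 0L) return(refs)
  refs$seq <- paste0(normalize_seq(fwd_ext), refs$seq,
                     revcomp(normalize_seq(rev_ext)))
  refs
}
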