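#' Anchor a primer on the reference marker sequence
#'
#' Expands the primer, then slides every non-degenerate variant (its
#' reverse complement for R-orientation primers) along the ungapped anchor
#' sequence and takes the placement with the fewest mismatches. At least
#' one variant must place with at most `max_mismatch` mismatches, otherwise
#' the primer cannot be evaluated against this reference and an error names
#' it. The matched anchor positions give the primer a fixed interval of
#' alignment columns through the anchor map.
#'
#' @param primer One row of [parse_primers()] output (fields `name`,
#'   `raw_seq`, `orientation`), or a list with those fields.
#' @param anchor_seq Ungapped anchor sequence (e.g. a full-length 16S
#'   gene).
#' @param anchor_map From [map_anchor()] for the alignment the reads are
#'   projected into.
#' @param pad Pad bases added on each side at site extraction; 3 to 5,
#'   default 4.
#' @param max_mismatch Placement validation threshold, default 2.
#' @return A `primer_spec`: `name`, `raw_seq`, `orientation`, `variants`,
#'   `anchor_interval` (`c(start, end)`, 1-based anchor positions),
#'   `anchor_cols` (alignment column of each primer base, plus-strand
#'   order), `pad`.
#' @export
anchor_primer <- function(primer, anchor_seq, anchor_map, pad = 4,
                          max_mismatch = 2) {
  stopifnot(pad >= 3, pad <= 5)
  variants <- expand_degenerate(primer$raw_seq)
  plus_variants <- if (primer$orientation == "R")
    vapply(variants, revcomp, character(1)) else variants
  anchor_seq <- normalize_seq(anchor_seq)
  best <- NULL
  for (v in seq_along(plus_variants)) {
    pl <- best_ungapped_placement(plus_variants[v], anchor_seq)
    if (is.null(best) || pl$mismatches < best$mismatches ||
        (pl$mismatches == best$mismatches && pl$start < best$start)) {
      best <- pl
      best$variant <- v
    }
  }
  if (is.null(best) || best$mismatches > max_mismatch)
    stop("anchor_primer: primer '", primer$name,
         "' has no binding site on the reference sequence (best placement ",
         if (is.null(best)) "none" else paste0(best$mismatches, " mismatches"),
         ")")
  L <- nchar(variants[1])
  interval <- c(best$start, best$start + L - 1L)
  cols <- anchor_map$col_of_pos[interval[1]:interval[2]]
  structure(list(name = primer$name, raw_seq = primer$raw_seq,
                 orientation = primer$orientation, variants = variants,
                 anchor_interval = interval, anchor_cols = cols,
                 pad = pad, anchor_mismatches = best$mismatches),
            class = "primer_spec")
}

#' @export
print.primer_spec <- function(x, ...) {
  cat("primer_spec ", x$name, " (", x$orientation, "): ",
      length(x$variants), " variant(s), anchor positions ",
      x$anchor_interval[1], "-", x$anchor_interval[2], "\n", sep = "")
  invisible(x)
}

# Best ungapped placement of a pattern in a text: smallest Hamming
# distance, leftmost on ties.
best_ungapped_placement <- function(pattern, text) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tc <- strsplit(text, "", fixed = TRUE)[[1]]
  L <- length(pc); n <- length(tc)
  if (n < L) return(NULL)
  n_off <- n - L + 1L
  idx <- outer(seq_len(n_off) - 1L, seq_len(L), "+")
  mism <- rowSums(matrix(tc[idx], nrow = n_off) !=
                    matrix(pc, nrow = n_off, ncol = L, byrow = TRUE))
  best <- which.min(mism) # leftmost on ties
  list(start = best, mismatches = unname(mism[best]))
}

#' Extract a primer binding site from a projected read
#'
#' Collects the read's actual bases across the primer's anchored column
#' window, with up to `pad` flanking bases on each side (the pads absorb
#' base slips left over from the multiple alignment when the primer is
#' re-aligned to the site). Primer positions outside the read's aligned
#' span are marked uncovered; a site with no covered primer position
#' yields `NULL` and no evaluation record.
#'
#' @param proj From [nast_project()].
#' @param primer A `primer_spec` from [anchor_primer()].
#' @param pad Flank bases per side; defaults to the primer's `pad`.
#' @return `NULL`, or a list with `primer_len`, `covered` (logical per
#'   primer position, plus-strand order), `frag` (the read bases across
#'   the window, plus strand), `span` (`c(first, last)` covered alignment
#'   columns of the site).
#' @export
extract_binding_site <- function(proj, primer, pad = primer$pad) {
  cols <- primer$anchor_cols
  P <- length(cols)
  chars <- strsplit(proj$gapped, "", fixed = TRUE)[[1]]
  covered <- cols >= proj$start_col & cols <= proj$end_col
  if (!any(covered)) return(NULL)
  in_span <- function(j) j >= proj$start_col & j <= proj$end_col
  base_at <- function(j) chars[j][chars[j] != "-" & in_span(j)]
  # left pad: last `pad` read bases in columns before the first primer col
  left_cols <- seq_len(cols[1] - 1L)
  left <- base_at(left_cols)
  left <- if (length(left) > pad) left[(length(left) - pad + 1L):length(left)] else left
  # core: read bases at primer columns and in the gap columns between them
  core <- character(0)
  for (i in seq_len(P)) {
    core <- c(core, base_at(cols[i]))
    if (i < P && cols[i + 1L] > cols[i] + 1L)
      core <- c(core, base_at(seq.int(cols[i] + 1L, cols[i + 1L] - 1L)))
  }
  # right pad
  right_cols <- if (cols[P] < length(chars)) seq.int(cols[P] + 1L, length(chars)) else integer(0)
  right <- base_at(right_cols)
  right <- if (length(right) > pad) right[seq_len(pad)] else right
  frag <- paste(c(left, core, right), collapse = "")
  if (!nzchar(frag)) return(NULL)
  list(primer_len = P, covered = covered, frag = frag,
       span = c(max(proj$start_col, cols[1]), min(proj$end_col, cols[P])))
}

#' Type one primer variant against an extracted binding site
#'
#' Re-aligns the non-degenerate variant to the padded site by global
#' alignment with free ends (so the pads can absorb terminal slips). For
#' R-orientation primers, the plus-strand site is reverse-complemented
#' first, so primer coordinates always run 5' to 3' and the 3'-terminal
#' window is well defined. Emits one symbol per primer position: `=` for a
#' match, the uppercase read base for a substitution, `d` for a primer
#' base absent from the read (deletion), lowercase read bases appended
#' after a position for extra read bases (insertion), and `.` for primer
#' positions not covered by the read (missing fragment). A site whose
#' re-aligned identity over covered positions falls below `min_identity`
#' is judged poorly aligned and dropped (`NULL` with a `reason`
#' attribute).
#'
#' @param site From [extract_binding_site()].
#' @param variant One non-degenerate primer sequence (5'->3').
#' @param orientation `"F"` or `"R"`.
#' @param min_identity Poor-alignment drop threshold over covered primer
#'   positions, default 0.5.
#' @return `NULL` if dropped, else a list with `match_string`, `symbols`
#'   (per-position strings), `n_mismatch_total`, `n_mismatch_last4`,
#'   `completeness`, `degree` (`"matched"` / `"mismatched"`), `identity`.
#' @export
evaluate_site <- function(site, variant, orientation, min_identity = 0.5) {
  P <- site$primer_len
  stopifnot(nchar(variant) == P)
  covered_p <- if (orientation == "R") rev(site$covered) else site$covered
  frag_p <- if (orientation == "R") revcomp(site$frag) else site$frag
  cov_idx <- which(covered_p)
  pa <- cov_idx[1]; pb <- cov_idx[length(cov_idx)]
  sub_variant <- substr(variant, pa, pb)
  # the variant must be fully aligned (its 3' end cannot dangle for free);
  # only the site's flanks are free. Gap open -3 (not -2) so a terminal
  # substitution is never re-read as an equal-scoring gap-plus-pad-match slip
  aln <- nw_align(sub_variant, frag_p, gap_open = -3, gap_extend = -1,
                  free_ends = c(FALSE, TRUE))
  va <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  fa <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  symbols <- as.list(rep(".", P))
  vpos <- pa - 1L
  for (i in seq_along(va)) {
    if (va[i] != "-" && fa[i] != "-") {
      vpos <- vpos + 1L
      symbols[[vpos]] <- if (va[i] == fa[i]) "=" else toupper(fa[i])
    } else if (va[i] != "-" && fa[i] == "-") {
      vpos <- vpos + 1L
      symbols[[vpos]] <- "d"
    } else { # site base not used by the variant
      if (vpos >= pa && vpos < pb) # internal insertion; pads ignored
        symbols[[vpos]] <- paste0(symbols[[vpos]], tolower(fa[i]))
    }
  }
  counts <- count_match_symbols(symbols, P)
  identity <- counts$n_match / length(cov_idx)
  if (identity < min_identity)
    return(dropped_site("poor_alignment"))
  completeness <- (P - counts$n_missing) / P
  degree <- if (completeness == 1 &&
                (counts$n_total == 0 ||
                 (counts$n_total == 1 && counts$n_last4 == 0)))
    "matched" else "mismatched"
  list(match_string = paste(unlist(symbols), collapse = ""),
       symbols = unlist(symbols),
       n_mismatch_total = counts$n_total,
       n_mismatch_last4 = counts$n_last4,
       completeness = completeness,
       degree = degree,
       identity = identity)
}

# Tally a per-position symbol list: substitutions count one each;
# insertions and deletions count one per event (a maximal run of 'd'
# positions, or the inserted bases attached after one position); the
# last-4 window is the 4 primer positions nearest the 3' end, and an indel
# event counts there if it touches any of them.
count_match_symbols <- function(symbols, P) {
  first <- substr(unlist(symbols), 1L, 1L)
  has_ins <- nchar(unlist(symbols)) > 1L
  n_match <- sum(first == "=")
  n_missing <- sum(first == ".")
  subst <- first %in% c("A", "C", "G", "T", "N")
  del <- first == "d"
  del_runs <- rle(del)
  del_starts <- cumsum(c(1L, del_runs$lengths))[seq_along(del_runs$lengths)]
  del_events <- which(del_runs$values)
  last4 <- seq.int(max(1L, P - 3L), P)
  n_del_last4 <- 0L
  for (e in del_events) {
    run_pos <- seq.int(del_starts[e], del_starts[e] + del_runs$lengths[e] - 1L)
    if (any(run_pos %in% last4)) n_del_last4 <- n_del_last4 + 1L
  }
  ins_pos <- which(has_ins)
  n_ins_last4 <- sum(ins_pos >= max(1L, P - 4L))
  n_total <- sum(subst) + length(del_events) + length(ins_pos)
  n_last4 <- sum(subst & seq_len(P) %in% last4) + n_del_last4 + n_ins_last4
  list(n_match = n_match, n_missing = n_missing,
       n_subst = sum(subst), n_del_events = length(del_events),
       n_ins_events = length(ins_pos),
       n_total = n_total, n_last4 = n_last4)
}

#' Select the best variant evaluation for a site
#'
#' A degenerate primer is judged by its best non-degenerate variant: the
#' lexicographic minimum of (total mismatches, last-4 mismatches, variant
#' index), so adding variants can never worsen the result.
#'
#' @param evals Non-empty list of [evaluate_site()] results, in variant
#'   order; each must carry a `variant_index` element.
#' @return The chosen evaluation.
#' @export
select_best_variant <- function(evals) {
  if (length(evals) == 0L) stop("select_best_variant: no evaluations")
  key <- vapply(evals, function(e)
    e$n_mismatch_total * 1e6 + e$n_mismatch_last4 * 1e3 + e$variant_index,
    numeric(1))
  evals[[which.min(key)]]
}

#' Evaluate one projected read against one primer
#'
#' Extracts the binding site, types every non-degenerate variant against
#' it, drops poorly aligned ones, and keeps the best by
#' [select_best_variant()].
#'
#' @param proj From [nast_project()].
#' @param primer A `primer_spec` from [anchor_primer()].
#' @param lineage Taxonomy to record (character vector or `;`-joined
#'   string).
#' @param pad,min_identity See [extract_binding_site()] and
#'   [evaluate_site()].
#' @return A one-row data frame (the site evaluation), or a dropped-site
#'   sentinel (see [is_dropped()]) whose `reason` is `"no_overlap"` or
#'   `"poor_alignment"`.
#' @export
evaluate_read_primer <- function(proj, primer, lineage = NA_character_,
                                 pad = primer$pad, min_identity = 0.5) {
  site <- extract_binding_site(proj, primer, pad)
  if (is.null(site)) return(dropped_site("no_overlap"))
  evals <- list()
  for (v in seq_along(primer$variants)) {
    e <- evaluate_site(site, primer$variants[v], primer$orientation,
                       min_identity = min_identity)
    if (!is_dropped(e)) {
      e$variant_index <- v
      evals[[length(evals) + 1L]] <- e
    }
  }
  if (length(evals) == 0L) return(dropped_site("poor_alignment"))
  best <- select_best_variant(evals)
  data.frame(read_id = proj$read_id,
             primer_name = primer$name,
             variant_used = primer$variants[best$variant_index],
             match_string = best$match_string,
             site_start = site$span[1], site_end = site$span[2],
             n_mismatch_total = best$n_mismatch_total,
             n_mismatch_last4 = best$n_mismatch_last4,
             degree = best$degree,
             completeness = best$completeness,
             lineage = if (is.character(lineage) && length(lineage) > 1)
               paste(lineage, collapse = ";") else as.character(lineage),
             score = best$n_mismatch_total * 100 + best$n_mismatch_last4,
             stringsAsFactors = FALSE)
}

# Sentinel for a site that yields no evaluation record, carrying the drop
# reason ("no_overlap" or "poor_alignment").
dropped_site <- function(reason)
  structure(list(reason = reason), class = "dropped_site")

#' Test whether a site evaluation was dropped
#'
#' @param x Result of [evaluate_site()] or [evaluate_read_primer()].
#' @return `TRUE` for a dropped site (the drop reason is in `x$reason`).
#' @export
is_dropped <- function(x) inherits(x, "dropped_site")
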