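#' Precompute the distinct k-mer sets of every template
#'
#' The search score compares a read's k-mers against each template's
#' ungapped sequence; building the template sets once per run avoids
#' recomputing them per read.
#'
#' @param templates A [ref_alignment()].
#' @param k Word size, default 8.
#' @return List of integer k-mer code vectors, named by template id, with
#'   attribute `k`.
#' @export
template_kmer_index <- function(templates, k = 8) {
  idx <- lapply(templates$ids, function(id)
    distinct_kmers(template_ungapped(templates, id), k))
  names(idx) <- templates$ids
  attr(idx, "k") <- k
  idx
}

#' k-mer search score of a query against a template database
#'
#' The search score is `100 x (distinct query k-mers present in the
#' template's ungapped sequence) / (distinct query k-mers)`, i.e. a 0-100
#' similarity. The best-scoring template is returned; ties are broken by
#' template id (alphabetical).
#'
#' @param query Ungapped nucleotide string, length >= `k`.
#' @param templates A [ref_alignment()].
#' @param k Word size, default 8.
#' @param index Optional prebuilt [template_kmer_index()] for `templates`.
#' @return List with `template_id` and `score`.
#' @export
kmer_search <- function(query, templates, k = 8, index = NULL) {
  if (nchar(query) < k)
    stop("kmer_search: query shorter than k = ", k)
  if (is.null(index)) index <- template_kmer_index(templates, k)
  qk <- distinct_kmers(query, k)
  if (length(qk) == 0L) {
    ord <- order(names(index))
    return(list(template_id = names(index)[ord[1]], score = 0))
  }
  scores <- vapply(index, function(tk) 100 * sum(qk %in% tk) / length(qk),
                   numeric(1))
  best <- which(scores == max(scores))
  best <- best[order(names(index)[best])][1]
  list(template_id = names(index)[best], score = unname(scores[best]))
}

#' Orient a read and attribute it to a gene
#'
#' Computes the k-mer search score of the read and of its reverse
#' complement against the SSU reference (and, in metatranscriptome mode,
#' the LSU reference as well, giving four scores). The global maximum fixes
#' the strand, the gene and the best template. The read is accepted iff
#' that maximum reaches `cutoff`; if both (all four) scores fall below it,
#' the read is not considered part of an rRNA gene.
#'
#' @param read One-row data frame (or list) with `id` and `seq`.
#' @param ssu SSU [ref_alignment()].
#' @param lsu Optional LSU [ref_alignment()].
#' @param cutoff Minimum search score on the 0-100 scale; default 30.
#' @param k Word size, default 8.
#' @param ssu_index,lsu_index Optional prebuilt [template_kmer_index()]s.
#' @return List with `id`, `seq` (oriented, i.e. reverse-complemented when
#'   `strand == "-"`), `strand`, `gene` (`"SSU"`, `"LSU"` or `"none"`),
#'   `scores` (named numeric), `template_id`, `score`, `accepted`.
#' @export
orient_and_assign <- function(read, ssu, lsu = NULL, cutoff = 30, k = 8,
                              ssu_index = NULL, lsu_index = NULL) {
  stopifnot(cutoff >= 0)
  if (is.null(ssu_index)) ssu_index <- template_kmer_index(ssu, k)
  seq_fwd <- read$seq
  seq_rev <- revcomp(seq_fwd)
  cand <- list(
    list(gene = "SSU", strand = "+", hit = kmer_search(seq_fwd, ssu, k, ssu_index)),
    list(gene = "SSU", strand = "-", hit = kmer_search(seq_rev, ssu, k, ssu_index))
  )
  if (!is.null(lsu)) {
    if (is.null(lsu_index)) lsu_index <- template_kmer_index(lsu, k)
    cand <- c(cand, list(
      list(gene = "LSU", strand = "+", hit = kmer_search(seq_fwd, lsu, k, lsu_index)),
      list(gene = "LSU", strand = "-", hit = kmer_search(seq_rev, lsu, k, lsu_index))
    ))
  }
  scores <- vapply(cand, function(x) x$hit$score, numeric(1))
  names(scores) <- vapply(cand, function(x)
    paste0(x$gene, "_", ifelse(x$strand == "+", "fwd", "rev")), character(1))
  # ties: SSU before LSU, then the lexicographically smaller oriented
  # sequence (a strand-symmetric rule, so orienting the reverse
  # complement flips the strand and nothing else), then '+'
  oseq <- vapply(cand, function(x)
    if (x$strand == "+") seq_fwd else seq_rev, character(1))
  gene_rank <- vapply(cand, function(x)
    if (x$gene == "SSU") 0L else 1L, integer(1))
  strand_rank <- vapply(cand, function(x)
    if (x$strand == "+") 0L else 1L, integer(1))
  best <- order(-scores, gene_rank, oseq, strand_rank)[1]
  top <- cand[[best]]
  accepted <- unname(scores[best] >= cutoff)
  list(id = read$id,
       seq = if (top$strand == "+") seq_fwd else seq_rev,
       strand = top$strand,
       gene = if (accepted) top$gene else "none",
       scores = scores,
       template_id = top$hit$template_id,
       score = unname(scores[best]),
       accepted = accepted)
}

#' Project an oriented read into the reference column space
#'
#' Template-based (NAST-style) projection: the oriented read is globally
#' aligned (free end gaps) to its best template's ungapped sequence, and
#' the pairwise alignment is threaded through the template's gap pattern so
#' every read base lands in a fixed alignment column. Read insertions
#' relative to the template fill the template's gap columns left to right;
#' insertions that exceed the available gap columns are recorded as
#' rejected-insertion bases (read position, base) and omitted from the
#' gapped string, so the read is always exactly reconstructible.
#'
#' @param oread Result of [orient_and_assign()]; must be accepted.
#' @param templates The [ref_alignment()] searched.
#' @return List with `read_id`, `gapped` (string of alignment width),
#'   `start_col`, `end_col` (1-based inclusive span of aligned bases),
#'   `template_id`, and `rejected` (data frame `pos`, `base` in oriented
#'   read coordinates).
#' @export
nast_project <- function(oread, templates) {
  if (!isTRUE(oread$accepted))
    stop("nast_project: read '", oread$id, "' was not accepted")
  tmpl_id <- oread$template_id
  tchars <- strsplit(unname(templates$gapped[[tmpl_id]]), "", fixed = TRUE)[[1]]
  col_of_tpos <- which(tchars != "-")
  tlen <- length(col_of_tpos)
  aln <- nw_align(oread$seq, paste(tchars[col_of_tpos], collapse = ""),
                  free_ends = TRUE)
  ra <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  ta <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  out <- rep("-", templates$width)
  rejected_pos <- integer(0)
  rejected_base <- character(0)
  tpos <- 0L; rpos <- 0L; i <- 1L
  while (i <= length(ra)) {
    if (ta[i] != "-") {
      tpos <- tpos + 1L
      if (ra[i] != "-") {
        rpos <- rpos + 1L
        out[col_of_tpos[tpos]] <- ra[i]
      }
      i <- i + 1L
    } else {
      # run of read bases inserted relative to the template
      ins_bases <- character(0); ins_rpos <- integer(0)
      while (i <= length(ra) && ta[i] == "-") {
        rpos <- rpos + 1L
        ins_bases <- c(ins_bases, ra[i])
        ins_rpos <- c(ins_rpos, rpos)
        i <- i + 1L
      }
      lo <- if (tpos == 0L) 1L else col_of_tpos[tpos] + 1L
      hi <- if (tpos == tlen) templates$width else col_of_tpos[tpos + 1L] - 1L
      gap_cols <- if (lo <= hi) seq.int(lo, hi) else integer(0)
      n_fit <- min(length(ins_bases), length(gap_cols))
      if (n_fit > 0)
        out[gap_cols[seq_len(n_fit)]] <- ins_bases[seq_len(n_fit)]
      if (length(ins_bases) > n_fit) {
        extra <- seq.int(n_fit + 1L, length(ins_bases))
        rejected_pos <- c(rejected_pos, ins_rpos[extra])
        rejected_base <- c(rejected_base, ins_bases[extra])
      }
    }
  }
  filled <- which(out != "-")
  if (length(filled) == 0L)
    stop("nast_project: read '", oread$id, "' projected to no columns")
  list(read_id = oread$id,
       gapped = paste(out, collapse = ""),
       start_col = filled[1],
       end_col = filled[length(filled)],
       template_id = tmpl_id,
       rejected = data.frame(pos = rejected_pos, base = rejected_base,
                             stringsAsFactors = FALSE))
}

#' Reconstruct an oriented read from its projection
#'
#' Inverse of [nast_project()]: degaps the projected string and re-inserts
#' the rejected-insertion bases at their recorded read positions. Used to
#' verify projection conservation.
#'
#' @param proj Result of [nast_project()].
#' @return The oriented read sequence.
#' @export
unproject <- function(proj) {
  chars <- strsplit(degap(proj$gapped), "", fixed = TRUE)[[1]]
  if (nrow(proj$rejected) > 0) {
    rej <- proj$rejected[order(proj$rejected$pos), , drop = FALSE]
    for (i in seq_len(nrow(rej))) {
      p <- rej$pos[i]
      chars <- append(chars, rej$base[i], after = p - 1L)
    }
  }
  paste(chars, collapse = "")
}
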