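#' Build a reference alignment for a mock community
#'
#' Convenience assembler for the simulator's output: the members' rRNA
#' genes (ungapped, equal length, hence trivially one column space) become
#' the reference rows, one member's gene is appended again as the anchor
#' row, and the member lineages become the taxonomy.
#'
#' @param spec A [community_spec()].
#' @param anchor_member Index of the member whose gene serves as anchor,
#'   default 3 (the first bacterial member of the default community).
#' @return A [ref_alignment()] with taxonomy and anchor.
#' @export
mock_reference <- function(spec, anchor_member = 3L) {
  members <- spec$members
  tax <- stats::setNames(strsplit(members$lineage, ";", fixed = TRUE),
                         members$id)
  ref_alignment(c(members$id, "anchor"),
                c(members$rrna, members$rrna[anchor_member]),
                taxonomy = tax, anchor_id = "anchor")
}

#' Prescreen stage: reduce a metagenome to rRNA-like candidates
#'
#' Thin wrapper over [screen_reads()] that also reports counts in and
#' out. Refuses to run in metatranscriptome mode, where rRNA already
#' dominates and the screen is skipped by design.
#'
#' @param reads Data frame with `id`, `seq`.
#' @param representatives Representative set (see
#'   [build_representatives()]).
#' @param k,min_shared Screen parameters, see [screen_reads()].
#' @param mode `"metagenome"` (default) or `"metatranscriptome"`.
#' @return List with `kept`, `hits`, `log` (named counts).
#' @export
run_prescreen <- function(reads, representatives, k = 11, min_shared = 0.10,
                          mode = c("metagenome", "metatranscriptome")) {
  mode <- match.arg(mode)
  if (mode == "metatranscriptome")
    stop("run_prescreen: the prescreen is skipped for metatranscriptomes; ",
         "run the main stage directly")
  res <- screen_reads(reads, representatives, k = k, min_shared = min_shared)
  res$log <- c(input = nrow(reads), kept = nrow(res$kept),
               discarded = nrow(reads) - nrow(res$kept))
  res
}

#' Main stage: orient, classify, project and evaluate primers
#'
#' The two-stage core of the pipeline. Stage I: every read and its
#' reverse complement are scored against the SSU reference (and the LSU
#' reference in metatranscriptome mode, four scores per read); reads below
#' the search-score cutoff are dropped; surviving SSU reads are classified
#' with the bootstrap classifier and gated at the domain rank; accepted,
#' classified reads are projected into the reference column space.
#' Stage II: for every primer, each projected read's binding site is
#' extracted with pad bases, re-aligned to every non-degenerate variant,
#' typed per position, and the best variant kept. Every drop is counted in
#' the run log.
#'
#' @param reads Data frame with `id`, `seq` (draft reads from the
#'   prescreen, or raw reads in metatranscriptome mode).
#' @param ssu SSU [ref_alignment()] with taxonomy and anchor row.
#' @param primers Primer table from [parse_primers()] (columns `name`,
#'   `raw_seq`, `orientation`).
#' @param lsu Optional LSU [ref_alignment()] with taxonomy
#'   (metatranscriptome mode).
#' @param mode `"metagenome"` or `"metatranscriptome"`.
#' @param search_cutoff Search-score cutoff on the 0-100 scale, default
#'   30.
#' @param bootstrap_cutoff Bootstrap cutoff, or `NULL` for the automatic
#'   60 / 50 (below 250 bases) rule.
#' @param pad Pad bases per side at site extraction (3-5), default 4.
#' @param min_identity Poor-alignment drop threshold, default 0.5.
#' @param k_search Search word size, default 8.
#' @param seed Run seed (drives the bootstrap resampling).
#' @return List with `assignments` (per-read orientation, gene, score,
#'   lineage, bootstrap, passed), `lsu_assignments` (metatranscriptome
#'   mode), `projections`, `evaluations` (named list of site-evaluation
#'   data frames, one per primer), `stats` (named list of
#'   [compute_stat_tables()] reports), `primer_specs`, and `log`.
#' @export
run_pipeline <- function(reads, ssu, primers, lsu = NULL,
                         mode = c("metagenome", "metatranscriptome"),
                         search_cutoff = 30, bootstrap_cutoff = NULL,
                         pad = 4, min_identity = 0.5, k_search = 8,
                         seed = 1) {
  mode <- match.arg(mode)
  if (mode == "metagenome") lsu <- NULL # four-score attribution is MT-only
  if (is.null(ssu$anchor_id))
    stop("run_pipeline: SSU reference has no anchor row")

  # anchor all primers before touching any read
  anchor_map <- map_anchor(ssu)
  anchor_seq <- template_ungapped(ssu, ssu$anchor_id)
  primer_specs <- lapply(seq_len(nrow(primers)), function(i)
    anchor_primer(primers[i, ], anchor_seq, anchor_map, pad = pad))
  names(primer_specs) <- primers$name

  ssu_index <- template_kmer_index(ssu, k_search)
  lsu_index <- if (!is.null(lsu)) template_kmer_index(lsu, k_search)

  oriented <- lapply(seq_len(nrow(reads)), function(i)
    orient_and_assign(reads[i, ], ssu, lsu = lsu, cutoff = search_cutoff,
                      k = k_search, ssu_index = ssu_index,
                      lsu_index = lsu_index))
  accepted <- vapply(oriented, `[[`, logical(1), "accepted")
  genes <- vapply(oriented, `[[`, character(1), "gene")
  log <- c(input = nrow(reads),
           orientation_fail = sum(!accepted),
           ssu = sum(genes == "SSU"),
           lsu = sum(genes == "LSU"))

  model <- train_classifier(ssu, k = k_search)
  lsu_model <- if (!is.null(lsu) && !is.null(lsu$taxonomy))
    train_classifier(lsu, k = k_search)

  classify_gene <- function(keep, mdl) {
    if (sum(keep) == 0 || is.null(mdl))
      return(data.frame(read_id = character(0), genus = character(0),
                        passed = logical(0)))
    oreads <- data.frame(
      id = vapply(oriented[keep], `[[`, character(1), "id"),
      seq = vapply(oriented[keep], `[[`, character(1), "seq"),
      stringsAsFactors = FALSE)
    cls <- classify_reads(mdl, oreads, cutoff = bootstrap_cutoff, seed = seed)
    cls$gene <- if (identical(mdl, model)) "SSU" else "LSU"
    cls
  }
  ssu_cls <- classify_gene(accepted & genes == "SSU", model)
  lsu_cls <- classify_gene(accepted & genes == "LSU", lsu_model)
  log["bootstrap_fail"] <- sum(!ssu_cls$passed)
  log["classified"] <- sum(ssu_cls$passed)

  keep_ids <- ssu_cls$read_id[ssu_cls$passed]
  okeep <- oriented[vapply(oriented, function(o)
    o$id %in% keep_ids && o$gene == "SSU", logical(1))]
  projections <- lapply(okeep, nast_project, templates = ssu)
  names(projections) <- vapply(projections, `[[`, character(1), "read_id")

  lineage_of <- stats::setNames(
    vapply(seq_len(nrow(ssu_cls)), function(i)
      paste(ssu_cls$lineage[[i]], collapse = ";"), character(1)),
    ssu_cls$read_id)

  evaluations <- list(); stats <- list()
  for (pn in names(primer_specs)) {
    spec <- primer_specs[[pn]]
    rows <- list(); n_no_overlap <- 0L; n_poor <- 0L
    for (proj in projections) {
      ev <- evaluate_read_primer(proj, spec,
                                 lineage = lineage_of[[proj$read_id]],
                                 pad = pad, min_identity = min_identity)
      if (is_dropped(ev)) {
        if (ev$reason == "poor_alignment")
          n_poor <- n_poor + 1L else n_no_overlap <- n_no_overlap + 1L
      } else rows[[length(rows) + 1L]] <- ev
    }
    evals <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(read_id = character(0), primer_name = character(0),
                 variant_used = character(0), match_string = character(0),
                 site_start = integer(0), site_end = integer(0),
                 n_mismatch_total = integer(0), n_mismatch_last4 = integer(0),
                 degree = character(0), completeness = numeric(0),
                 lineage = character(0), score = numeric(0))
    evaluations[[pn]] <- evals
    stats[[pn]] <- compute_stat_tables(evals)
    log[paste0(pn, "_sites")] <- nrow(evals)
    log[paste0(pn, "_no_overlap")] <- n_no_overlap
    log[paste0(pn, "_poor_alignment")] <- n_poor
  }

  list(assignments = ssu_cls, lsu_assignments = lsu_cls,
       oriented = oriented, projections = projections,
       evaluations = evaluations, stats = stats,
       primer_specs = primer_specs, log = log)
}

#' Write all pipeline outputs to a directory
#'
#' Emits `<primer>.Match_type` and `<primer>.Stat` for every primer plus
#' a `taxonomy.tsv` (and `taxonomy_lsu.tsv` when present).
#'
#' @param result From [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pn in names(result$evaluations)) {
    write_match_type(result$evaluations[[pn]],
                     file.path(dir, paste0(pn, ".Match_type")))
    write_stat(result$stats[[pn]], file.path(dir, paste0(pn, ".Stat")))
  }
  if (nrow(result$assignments) > 0)
    write_taxonomy(result$assignments, file.path(dir, "taxonomy.tsv"))
  if (!is.null(result$lsu_assignments) && nrow(result$lsu_assignments) > 0)
    write_taxonomy(result$lsu_assignments,
                   file.path(dir, "taxonomy_lsu.tsv"))
  invisible(dir)
}
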