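# Split a match-type string into per-primer-position symbols: '=', an
# uppercase base (substitution), 'd' (deletion) or '.' (missing) opens a
# position; lowercase bases (insertion) attach to the preceding position.
parse_match_string <- function(s) {
  m <- gregexpr("[=ACGTNd.][acgtn]*", s)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(s, gregexpr("[=ACGTNd.][acgtn]*", s))[[1]]
}

# Event counts of one match-type string: substitutions one each,
# insertions/deletions one per event, missing one per position.
mismatch_event_counts <- function(s) {
  sym <- parse_match_string(s)
  first <- substr(sym, 1L, 1L)
  del_runs <- rle(first == "d")
  c(substitution = sum(first %in% c("A", "C", "G", "T", "N")),
    insertion = sum(nchar(sym) > 1L),
    deletion = sum(del_runs$values),
    missing = sum(first == "."))
}

#' Write the per-read match-type table for one primer
#'
#' One row per evaluated read: id, match-type string, binding-site column
#' span, mismatch counts (total and within the last 4 positions near the
#' 3' end), matched degree, completeness, taxonomy and the variant-
#' selection score. TSV with a header line, rows in read-id order.
#'
#' @param evals Data frame of site evaluations for one primer (from
#'   [run_pipeline()] or [evaluate_read_primer()] rows).
#' @param path Output path, conventionally `<primer>.Match_type`.
#' @return `path`, invisibly.
#' @export
write_match_type <- function(evals, path) {
  cols <- c("read_id", "match_string", "site_start", "site_end",
            "n_mismatch_total", "n_mismatch_last4", "degree",
            "completeness", "lineage", "score")
  if (nrow(evals) > 0) {
    stopifnot(length(unique(evals$primer_name)) == 1L)
    evals <- evals[order(evals$read_id), cols, drop = FALSE]
  } else {
    evals <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  }
  utils::write.table(evals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a match-type table back
#'
#' Inverse of [write_match_type()].
#'
#' @param path Path to a `.Match_type` file.
#' @return Data frame of site evaluations.
#' @export
read_match_type <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(read_id = "character",
                                   match_string = "character",
                                   degree = "character",
                                   lineage = "character"),
                    stringsAsFactors = FALSE)
}

#' Compute the six summary tables for one primer
#'
#' The per-primer statistics: (1) matched vs mismatched sequence counts
#' among complete sites, (2) the distribution of completeness over all
#' sites, (3) the most frequent mismatch type, (4) the most common
#' match-type string, (5) mismatch counts by type at every primer
#' position, and (6) coverage over taxonomy levels. Only sites with
#' completeness 1 enter tables 1 and 6; tables 3-5 use every site with at
#' least one covered position. All taxa appear in table 6, with no
#' abundance floor, so rare groups stay visible.
#'
#' @param evals Data frame of site evaluations for one primer.
#' @param tax_ranks Number of taxonomy ranks for table 6, default the
#'   deepest lineage present.
#' @return List of class `stat_report` with elements `table1` ... `table6`.
#' @export
compute_stat_tables <- function(evals, tax_ranks = NULL) {
  if (nrow(evals) > 0) stopifnot(length(unique(evals$primer_name)) == 1L)
  complete <- evals[evals$completeness == 1, , drop = FALSE]
  table1 <- data.frame(degree = c("matched", "mismatched"),
                       count = c(sum(complete$degree == "matched"),
                                 sum(complete$degree == "mismatched")))
  comp_tab <- table(evals$completeness)
  table2 <- data.frame(completeness = as.numeric(names(comp_tab)),
                       count = as.integer(comp_tab))
  table2 <- table2[order(-table2$completeness), , drop = FALSE]
  rownames(table2) <- NULL

  ev_counts <- if (nrow(evals) > 0)
    rowSums(vapply(evals$match_string, mismatch_event_counts, numeric(4)))
  else c(substitution = 0, insertion = 0, deletion = 0, missing = 0)
  table3 <- data.frame(type = names(ev_counts), count = as.numeric(ev_counts))
  table3$most_frequent <- table3$count == max(table3$count) & table3$count > 0

  if (nrow(evals) > 0) {
    ms_tab <- sort(table(evals$match_string), decreasing = TRUE)
    top <- names(ms_tab)[ms_tab == max(ms_tab)]
    top <- sort(top)[1]
    table4 <- data.frame(match_string = top,
                         count = as.integer(ms_tab[[top]]))
  } else {
    table4 <- data.frame(match_string = character(0), count = integer(0))
  }

  P <- if (nrow(evals) > 0)
    length(parse_match_string(evals$match_string[1])) else 0L
  table5 <- matrix(0L, nrow = P, ncol = 4,
                   dimnames = list(NULL, c("substitution", "insertion",
                                           "deletion", "missing")))
  if (nrow(evals) > 0) {
    for (s in evals$match_string) {
      sym <- parse_match_string(s)
      first <- substr(sym, 1L, 1L)
      table5[, "substitution"] <- table5[, "substitution"] +
        (first %in% c("A", "C", "G", "T", "N"))
      table5[, "insertion"] <- table5[, "insertion"] + (nchar(sym) > 1L)
      # one deletion event, charged to the first position of its run
      is_del <- first == "d"
      starts <- is_del & !c(FALSE, is_del[-length(is_del)])
      table5[, "deletion"] <- table5[, "deletion"] + starts
      table5[, "missing"] <- table5[, "missing"] + (first == ".")
    }
  }
  table5 <- as.data.frame(table5)
  table5 <- cbind(position = seq_len(P), table5)

  lineages <- strsplit(complete$lineage, ";", fixed = TRUE)
  if (is.null(tax_ranks))
    tax_ranks <- if (length(lineages) > 0) max(lengths(lineages)) else 0L
  rows <- list()
  for (r in seq_len(tax_ranks)) {
    has_rank <- lengths(lineages) >= r
    taxon <- vapply(lineages[has_rank], function(l)
      paste(l[seq_len(r)], collapse = ";"), character(1))
    deg <- complete$degree[has_rank]
    for (tx in sort(unique(taxon))) {
      n_complete <- sum(taxon == tx)
      n_matched <- sum(taxon == tx & deg == "matched")
      rows[[length(rows) + 1L]] <- data.frame(
        rank = r, taxon = tx, n_complete = n_complete,
        n_matched = n_matched,
        coverage_pct = 100 * n_matched / n_complete)
    }
  }
  table6 <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(rank = integer(0), taxon = character(0),
               n_complete = integer(0), n_matched = integer(0),
               coverage_pct = numeric(0))
  structure(list(table1 = table1, table2 = table2, table3 = table3,
                 table4 = table4, table5 = table5, table6 = table6),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  cat("stat_report:", sum(x$table1$count), "complete site(s),",
      nrow(x$table6), "taxon-rank rows\n")
  invisible(x)
}

#' Write a summary statistics file
#'
#' Serializes a [compute_stat_tables()] report as a plain-text `.Stat`
#' file: six titled TSV tables separated by blank lines.
#'
#' @param stat A `stat_report`.
#' @param path Output path, conventionally `<primer>.Stat`.
#' @return `path`, invisibly.
#' @export
write_stat <- function(stat, path) {
  titles <- c("Table 1: Match and mismatch sequence count",
              "Table 2: Distribution of completeness",
              "Table 3: Most frequent mismatch type",
              "Table 4: Most common match type",
              "Table 5: Count of each mismatch in every position",
              "Table 6: Coverage over taxonomy levels")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in 1:6) {
    writeLines(titles[i], con)
    utils::write.table(stat[[paste0("table", i)]], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Goodness of fit of an observed community to expected proportions
#'
#' Pearson's chi-squared goodness-of-fit statistic
#' `sum((O - E)^2 / E)` with `E = N * p`, degrees of freedom one less
#' than the number of categories, and its upper-tail p value. Used to
#' compare the pipeline-recovered genus composition of a mock community
#' with the truth.
#'
#' @param observed Named integer vector of taxon counts.
#' @param expected Named numeric vector of expected proportions over the
#'   same taxa (normalized internally).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
compare_composition <- function(observed, expected) {
  stopifnot(length(observed) == length(expected), sum(observed) > 0)
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    stopifnot(setequal(names(observed), names(expected)))
    expected <- expected[names(observed)]
  }
  expected <- expected / sum(expected)
  zero <- expected == 0
  if (any(zero & observed > 0))
    stop("compare_composition: observed count for a taxon with expected ",
         "proportion 0: ", paste(names(observed)[zero & observed > 0],
                                 collapse = ", "))
  observed <- observed[!zero]
  expected <- expected[!zero]
  E <- sum(observed) * expected
  chi2 <- sum((observed - E)^2 / E)
  df <- length(observed) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}
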