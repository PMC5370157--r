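#' Train the k-mer naive-Bayes taxonomy classifier
#'
#' Wang-style classifier trained at the lowest rank (genus) of the
#' reference taxonomy: for each genus, the probability that a k-mer occurs
#' in one of its sequences is estimated as `(count + 0.5) / (N + 1)`,
#' where `count` is the number of the genus's training sequences containing
#' the k-mer and `N` the number of training sequences in the genus. A query
#' is scored by the joint log-probability of its distinct k-mers.
#'
#' @param refs A [ref_alignment()] with taxonomy (rows are degapped
#'   internally); the anchor row, having no taxonomy, is excluded.
#' @param k Word size, default 8.
#' @return Classifier model (list with the per-genus log-probability
#'   matrix, genus lineages, `k`).
#' @export
train_classifier <- function(refs, k = 8) {
  if (is.null(refs$taxonomy))
    stop("train_classifier: reference alignment has no taxonomy")
  train_ids <- setdiff(refs$ids, refs$anchor_id)
  missing <- setdiff(train_ids, names(refs$taxonomy))
  if (length(missing) > 0)
    stop("train_classifier: taxonomy missing for: ",
         paste(utils::head(missing, 5), collapse = ", "))
  lineages <- refs$taxonomy[train_ids]
  genus_of <- vapply(lineages, function(l) l[length(l)], character(1))
  genera <- sort(unique(genus_of))
  n_kmers <- 4^k
  # count, per genus, how many training sequences contain each k-mer
  counts <- matrix(0L, nrow = length(genera), ncol = n_kmers,
                   dimnames = list(genera, NULL))
  n_seq <- stats::setNames(integer(length(genera)), genera)
  for (id in train_ids) {
    g <- genus_of[[id]]
    km <- distinct_kmers(template_ungapped(refs, id), k)
    counts[g, km + 1L] <- counts[g, km + 1L] + 1L
    n_seq[g] <- n_seq[g] + 1L
  }
  logp <- log((counts + 0.5) / (n_seq + 1))
  genus_lineage <- list()
  for (id in train_ids) genus_lineage[[genus_of[[id]]]] <- lineages[[id]]
  structure(list(logp = logp, genera = genera,
                 genus_lineage = genus_lineage, k = k),
            class = "nb_classifier")
}

#' @export
print.nb_classifier <- function(x, ...) {
  cat("nb_classifier:", length(x$genera), "genera, k =", x$k, "\n")
  invisible(x)
}

# Genus index (row of logp) with the highest joint log-probability for a
# set of k-mer codes; ties broken by genus order (alphabetical).
nb_best_genus <- function(model, codes) {
  scores <- model$logp[, codes + 1L, drop = FALSE]
  which.max(rowSums(scores))
}

#' Classify a read with bootstrap confidence
#'
#' Scores the read's distinct k-mers against every genus, takes the best,
#' then bootstraps: `n_boot` resamples of `ceiling(m / 8)` of the read's
#' `m` k-mers (with replacement) are reclassified, and the bootstrap value
#' at each rank is the percentage of resamples agreeing with the winning
#' lineage at that rank. The read passes iff its domain is one of
#' Bacteria / Archaea / Eukarya (Eukaryota) and the domain-level bootstrap
#' is at least the cutoff. The default cutoff of 60 switches automatically
#' to 50 for reads shorter than 250 bases.
#'
#' @param model From [train_classifier()].
#' @param read_seq Ungapped nucleotide string (oriented).
#' @param cutoff Bootstrap cutoff percentage, or `NULL` for the automatic
#'   60 / 50 rule.
#' @param n_boot Number of bootstrap resamples, default 100.
#' @param seed Integer seed making the resampling deterministic.
#' @return List with `lineage`, `bootstrap` (integer percent per rank),
#'   `genus`, `cutoff` (the one applied) and `passed`.
#' @export
classify_bootstrap <- function(model, read_seq, cutoff = NULL,
                               n_boot = 100, seed = 1) {
  k <- model$k
  if (nchar(read_seq) < k)
    stop("classify_bootstrap: read shorter than k = ", k)
  if (is.null(cutoff))
    cutoff <- if (nchar(read_seq) < 250) 50 else 60
  codes <- distinct_kmers(read_seq, k)
  if (length(codes) == 0L)
    stop("classify_bootstrap: read has no valid k-mers")
  best <- nb_best_genus(model, codes)
  lineage <- model$genus_lineage[[model$genera[best]]]
  n_ranks <- length(lineage)
  m <- length(codes)
  n_sub <- ceiling(m / 8)
  # per-k-mer log-probability matrix of this read; every bootstrap
  # resample is then one matrix product with a resample-count matrix
  S <- model$logp[, codes + 1L, drop = FALSE]
  boot_g <- with_seed(seed, {
    idx <- sample.int(m, n_sub * n_boot, replace = TRUE)
    counts <- matrix(tabulate(idx + rep(seq_len(n_boot) - 1L, each = n_sub) * m,
                              nbins = m * n_boot), nrow = m)
    # ties (resamples carrying no discriminating k-mer) are broken at
    # random so uninformative reads cannot accumulate spurious agreement
    max.col(t(S %*% counts), ties.method = "random")
  })
  # rank r agrees only if all ranks above it agree too
  agree_of_genus <- vapply(seq_along(model$genera), function(g) {
    bl <- model$genus_lineage[[model$genera[g]]]
    upto <- min(n_ranks, length(bl))
    out <- rep(FALSE, n_ranks)
    if (upto > 0)
      out[seq_len(upto)] <- cumprod(bl[seq_len(upto)] ==
                                      lineage[seq_len(upto)]) == 1
    out
  }, logical(n_ranks))
  agree_of_genus <- matrix(agree_of_genus, nrow = n_ranks)
  bootstrap <- as.integer(round(100 *
    rowMeans(agree_of_genus[, boot_g, drop = FALSE])))
  domain_ok <- lineage[1] %in% c("Bacteria", "Archaea", "Eukarya", "Eukaryota")
  list(lineage = lineage, bootstrap = bootstrap,
       genus = model$genera[best], cutoff = cutoff,
       passed = domain_ok && bootstrap[1] >= cutoff)
}

#' Classify a set of reads
#'
#' Vectorized wrapper around [classify_bootstrap()]; each read gets a seed
#' derived deterministically from the run seed and its index.
#'
#' @param model From [train_classifier()].
#' @param reads Data frame with `id`, `seq` (oriented).
#' @param cutoff Bootstrap cutoff, or `NULL` for the automatic 60/50 rule.
#' @param n_boot Bootstrap resamples per read.
#' @param seed Run seed.
#' @return Data frame with `read_id`, list-columns `lineage` and
#'   `bootstrap`, `genus`, `passed`.
#' @export
classify_reads <- function(model, reads, cutoff = NULL, n_boot = 100,
                           seed = 1) {
  res <- lapply(seq_len(nrow(reads)), function(i) {
    classify_bootstrap(model, reads$seq[i], cutoff = cutoff,
                       n_boot = n_boot, seed = (seed + 7L * i) %% .Machine$integer.max)
  })
  data.frame(read_id = reads$id,
             lineage = I(lapply(res, `[[`, "lineage")),
             bootstrap = I(lapply(res, `[[`, "bootstrap")),
             genus = vapply(res, `[[`, character(1), "genus"),
             passed = vapply(res, `[[`, logical(1), "passed"),
             stringsAsFactors = FALSE)
}
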