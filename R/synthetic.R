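# Run expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Simulate a family of related rRNA-like gene sequences
#'
#' Draws a random ancestor sequence, implants the given plus-strand motifs
#' (e.g. universal-primer binding sites) at fixed positions, and evolves
#' one descendant per taxon by independent substitutions at rate
#' `divergence` per site. Motif positions are conserved -- the biological
#' picture being that universal primers target conserved regions -- unless
#' a taxon appears in a motif's `mismatch_in` with a position to mutate,
#' which engineers a controlled primer-template mismatch for that taxon.
#'
#' @param n_taxa Number of taxa (one sequence each).
#' @param gene_length Gene length in bases, default 1500 (16S-like).
#' @param divergence Per-site substitution probability between the
#'   ancestor and each taxon, default 0.10.
#' @param motifs List of lists with `seq` (plus-strand motif) and `pos`
#'   (1-based start on the gene); optionally `mismatch_in` (taxon indices)
#'   and `mismatch_offset` (0-based offset of the position to mutate, in
#'   plus-strand motif coordinates).
#' @param seed Integer seed.
#' @return Data frame with `id` (`taxon01` ...) and `seq`; the ancestor
#'   and the conserved-position mask are attached as attributes.
#' @export
simulate_rrna_family <- function(n_taxa, gene_length = 1500,
                                 divergence = 0.10, motifs = list(),
                                 seed = 1) {
  stopifnot(n_taxa >= 1, divergence >= 0, divergence < 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anc <- strsplit(random_dna(gene_length), "", fixed = TRUE)[[1]]
    conserved <- rep(FALSE, gene_length)
    for (m in motifs) {
      mc <- strsplit(normalize_seq(m$seq), "", fixed = TRUE)[[1]]
      idx <- seq.int(m$pos, m$pos + length(mc) - 1L)
      stopifnot(idx[length(idx)] <= gene_length)
      anc[idx] <- mc
      conserved[idx] <- TRUE
    }
    ids <- sprintf("taxon%02d", seq_len(n_taxa))
    seqs <- character(n_taxa)
    for (t in seq_len(n_taxa)) {
      s <- anc
      mut <- which(stats::runif(gene_length) < divergence & !conserved)
      for (i in mut) s[i] <- sample(setdiff(bases, s[i]), 1)
      for (m in motifs) {
        if (!is.null(m$mismatch_in) && t %in% m$mismatch_in) {
          i <- m$pos + m$mismatch_offset
          s[i] <- sample(setdiff(bases, s[i]), 1)
        }
      }
      seqs[t] <- paste(s, collapse = "")
    }
    out <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
    attr(out, "ancestor") <- paste(anc, collapse = "")
    attr(out, "conserved") <- conserved
    out
  })
}

#' Define a mock shotgun community
#'
#' Bundles the members (taxon lineage, genome length, embedded rRNA gene,
#' relative abundance) with the read-simulation parameters: fixed read
#' length, per-genome fold coverage (scaled by relative abundance), and an
#' error model -- `"exact"` (error free) or `"uniform"` (i.i.d.
#' substitutions at `error_rate`).
#'
#' @param members Data frame with columns `id`, `lineage` (`;`-separated
#'   string), `genome_length`, `abundance`, `rrna` (ungapped gene
#'   sequence).
#' @param read_length Read length in bases.
#' @param coverage Fold coverage per genome.
#' @param error_model `"exact"` or `"uniform"`.
#' @param error_rate Substitution probability per base for the uniform
#'   model.
#' @param seed Integer seed.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(members, read_length = 400, coverage = 6,
                           error_model = c("exact", "uniform"),
                           error_rate = 0, seed = 1) {
  error_model <- match.arg(error_model)
  stopifnot(all(c("id", "lineage", "genome_length", "abundance", "rrna")
                %in% names(members)),
            all(members$abundance > 0),
            coverage > 0,
            read_length <= min(members$genome_length),
            error_rate >= 0, error_rate < 1)
  if (any(nchar(members$rrna) > members$genome_length))
    stop("community_spec: rRNA gene longer than its genome")
  structure(list(members = members, read_length = read_length,
                 coverage = coverage, error_model = error_model,
                 error_rate = error_rate, seed = seed),
            class = "community_spec")
}

#' The default 13-organism mock community
#'
#' Mirrors the validation design the pipeline is tested against: 13
#' organisms -- two Archaea, nine Bacteria and two Eukarya -- with equal
#' abundance, 400-base reads, 6-fold per-genome coverage and an exact
#' (error-free) read model. Genomes are 20 kb with one embedded SSU-like
#' gene of 1.5 kb; genus-level lineages are synthetic. Both default
#' primers' plus-strand binding sites are implanted as conserved motifs at
#' their familiar 16S coordinates (515 and 787).
#'
#' @param seed Integer seed.
#' @param genome_length Genome length per member, default 20000.
#' @param divergence Between-genus divergence of the rRNA genes, default
#'   0.10.
#' @param f_site,r_site Plus-strand motifs implanted at positions 515 and
#'   787; defaults are one non-degenerate variant of each of the common
#'   V4 primers.
#' @param mismatch_genus Optional member index whose forward-primer site
#'   receives an engineered mismatch at the primer's 3'-terminal base.
#' @return A `community_spec`.
#' @export
default_mock_community <- function(seed = 1, genome_length = 20000,
                                   divergence = 0.10,
                                   f_site = "GTGCCAGCAGCCGCGGTAA",
                                   r_site = revcomp("GGACTACCAGGGTATCTAAT"),
                                   mismatch_genus = NULL) {
  motifs <- list(
    list(seq = f_site, pos = 515L,
         mismatch_in = mismatch_genus,
         mismatch_offset = nchar(f_site) - 1L), # primer 3'-terminal base
    list(seq = r_site, pos = 787L))
  fam <- simulate_rrna_family(13, gene_length = 1500,
                              divergence = divergence, motifs = motifs,
                              seed = seed)
  domains <- c(rep("Archaea", 2), rep("Bacteria", 9), rep("Eukarya", 2))
  phyla <- c("Euryarchaeota", "Crenarchaeota",
             "Proteobacteria", "Proteobacteria", "Firmicutes", "Firmicutes",
             "Actinobacteria", "Bacteroidetes", "Cyanobacteria",
             "Acidobacteria", "Planctomycetes",
             "Ascomycota", "Basidiomycota")
  genera <- sprintf("Genus%02d", 1:13)
  members <- data.frame(
    id = sprintf("org%02d", 1:13),
    lineage = paste(domains, phyla, genera, sep = ";"),
    genome_length = genome_length,
    abundance = 1,
    rrna = fam$seq,
    stringsAsFactors = FALSE)
  community_spec(members, read_length = 400, coverage = 6,
                 error_model = "exact", seed = seed)
}

#' Generate mock genomes with embedded rRNA genes
#'
#' Each genome is i.i.d. uniform ACGT background with the member's rRNA
#' gene inserted (replacing background) at a random position recorded in
#' the truth table.
#'
#' @param spec A [community_spec()].
#' @return List with `genomes` (data frame `id`, `seq`) and `truth` (data
#'   frame `genome_id`, `start`, `end`, `feature`, `taxon`): one `rRNA`
#'   row per gene plus the flanking `background` rows.
#' @export
generate_mock_genomes <- function(spec) {
  # offset stream: backgrounds must not replay the draws that built the
  # rRNA gene family under the same community seed
  with_seed((spec$seed + 104729L) %% .Machine$integer.max, {
    members <- spec$members
    genomes <- list(); truth <- list()
    for (i in seq_len(nrow(members))) {
      L <- members$genome_length[i]
      gene <- members$rrna[i]
      gl <- nchar(gene)
      bg <- strsplit(random_dna(L), "", fixed = TRUE)[[1]]
      start <- sample.int(L - gl + 1L, 1)
      bg[seq.int(start, start + gl - 1L)] <-
        strsplit(gene, "", fixed = TRUE)[[1]]
      genomes[[i]] <- data.frame(id = members$id[i],
                                 seq = paste(bg, collapse = ""),
                                 stringsAsFactors = FALSE)
      rows <- data.frame(
        genome_id = members$id[i],
        start = c(if (start > 1) 1L else integer(0), start,
                  if (start + gl <= L) start + gl else integer(0)),
        end = c(if (start > 1) start - 1L else integer(0),
                start + gl - 1L,
                if (start + gl <= L) L else integer(0)),
        feature = c(if (start > 1) "background" else character(0), "rRNA",
                    if (start + gl <= L) "background" else character(0)),
        taxon = members$lineage[i],
        stringsAsFactors = FALSE)
      truth[[i]] <- rows
    }
    list(genomes = do.call(rbind, genomes), truth = do.call(rbind, truth))
  })
}

#' Simulate shotgun reads from mock genomes
#'
#' Draws `ceiling(coverage x abundance x L / read_length)` reads per
#' genome, uniformly positioned, with a random strand. The exact error
#' model introduces no errors; the uniform model substitutes bases
#' i.i.d. at `error_rate`. The per-read truth records the origin interval,
#' strand, and the fraction of the read overlapping the embedded rRNA
#' gene.
#'
#' @param mock Result of [generate_mock_genomes()].
#' @param spec The same [community_spec()].
#' @param seed Seed for read sampling; defaults to `spec$seed + 1`.
#' @return List with `reads` (data frame `id`, `seq`) and `truth` (data
#'   frame `read_id`, `genome_id`, `start`, `end`, `strand`,
#'   `rrna_overlap`, `taxon`).
#' @export
simulate_reads <- function(mock, spec, seed = spec$seed + 1L) {
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    members <- spec$members
    rl <- spec$read_length
    reads <- list(); truth <- list()
    for (i in seq_len(nrow(members))) {
      gid <- members$id[i]
      gseq <- mock$genomes$seq[mock$genomes$id == gid]
      L <- nchar(gseq)
      n_reads <- ceiling(spec$coverage * members$abundance[i] * L / rl)
      rr <- mock$truth[mock$truth$genome_id == gid &
                         mock$truth$feature == "rRNA", ]
      starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE)
      strands <- sample(c("+", "-"), n_reads, replace = TRUE)
      for (j in seq_len(n_reads)) {
        s <- starts[j]; e <- s + rl - 1L
        seq <- substr(gseq, s, e)
        if (spec$error_model == "uniform" && spec$error_rate > 0) {
          ch <- strsplit(seq, "", fixed = TRUE)[[1]]
          mut <- which(stats::runif(rl) < spec$error_rate)
          for (p in mut) ch[p] <- sample(setdiff(bases, ch[p]), 1)
          seq <- paste(ch, collapse = "")
        }
        if (strands[j] == "-") seq <- revcomp(seq)
        ov <- max(0L, min(e, rr$end[1]) - max(s, rr$start[1]) + 1L)
        rid <- sprintf("%s_r%04d", gid, j)
        reads[[length(reads) + 1L]] <-
          data.frame(id = rid, seq = seq, stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = rid, genome_id = gid, start = s, end = e,
          strand = strands[j], rrna_overlap = ov / rl,
          taxon = members$lineage[i], stringsAsFactors = FALSE)
      }
    }
    list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
  })
}
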