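test_that("search score is 100 for a template copy and 0 for disjoint k-mers", {
  t1 <- random_seq(500, seed = 30)
  aln <- ref_alignment(c("t1", "t2"), c(t1, random_seq(500, seed = 31)))
  hit <- kmer_search(t1, aln)
  expect_identical(hit$template_id, "t1")
  expect_equal(hit$score, 100)
  # two-letter alphabet arrangement shares no 8-mers with random templates
  none <- kmer_search(strrep("AC", 50), aln)
  expect_equal(none$score, 0)
  expect_error(kmer_search("ACG", aln), "shorter than k")
})

test_that("search score and template choice match an exhaustive k-mer oracle", {
  set.seed(32)
  templates <- vapply(1:5, function(i) random_seq(600), character(1))
  aln <- ref_alignment(sprintf("t%d", 1:5), templates)
  idx <- template_kmer_index(aln, 8)
  str_kmers <- function(s, k) unique(substring(s, 1:(nchar(s) - k + 1),
                                               k:nchar(s)))
  for (q in 1:20) {
    base <- sample(5, 1)
    s <- sample(1:400, 1)
    query <- paste0(substr(templates[base], s, s + 99), random_seq(50))
    got <- kmer_search(query, aln, index = idx)
    qk <- str_kmers(query, 8)
    scores <- vapply(templates, function(tt)
      100 * length(intersect(qk, str_kmers(tt, 8))) / length(qk), numeric(1))
    expect_equal(got$score, max(scores))
    expect_identical(got$template_id, sprintf("t%d", which.max(scores)))
  }
})

test_that("orientation picks the strand of the matching sequence, symmetric under revcomp", {
  t1 <- random_seq(900, seed = 33)
  aln <- ref_alignment(c("t1"), t1)
  read <- list(id = "r", seq = substr(t1, 200, 520))
  o <- orient_and_assign(read, aln, cutoff = 30)
  expect_identical(o$strand, "+")
  expect_identical(o$gene, "SSU")
  expect_true(o$accepted)

  o2 <- orient_and_assign(list(id = "r", seq = revcomp(read$seq)), aln,
                          cutoff = 30)
  expect_identical(o2$strand, "-")
  expect_equal(o2$score, o$score)
  expect_identical(o2$template_id, o$template_id)
  expect_identical(o2$seq, read$seq) # oriented back to plus strand
})

test_that("shuffled random reads fail the recommended cutoff of 30", {
  t1 <- random_seq(900, seed = 34)
  aln <- ref_alignment(c("t1"), t1)
  set.seed(35)
  for (i in 1:10) {
    shuf <- paste(sample(strsplit(substr(t1, 1, 300), "")[[1]]),
                  collapse = "")
    o <- orient_and_assign(list(id = "s", seq = shuf), aln, cutoff = 30)
    expect_true(all(o$scores < 30))
    expect_false(o$accepted)
    expect_identical(o$gene, "none")
  }
})

test_that("search score never decreases when template-matching bases are appended", {
  t1 <- random_seq(800, seed = 36)
  aln <- ref_alignment(c("t1"), t1)
  idx <- template_kmer_index(aln, 8)
  set.seed(37)
  for (i in 1:10) {
    start <- sample(1:300, 1)
    prev <- -1
    for (len in c(40, 80, 160, 320)) {
      sc <- kmer_search(substr(t1, start, start + len - 1), aln,
                        index = idx)$score
      expect_gte(sc, prev)
      prev <- sc
    }
  }
})

test_that("projection reproduces the template row and handles indels", {
  rows <- c(t1 = "AC-GTACGTTACG-TACGATGCAC--GTAC",
            t2 = "ACTGTACGTTACGATACGATGCACGT--AC")
  aln <- ref_alignment(names(rows), unname(rows))
  t1u <- rrnaprimer:::degap(rows[["t1"]])

  o <- orient_and_assign(list(id = "r1", seq = t1u), aln, cutoff = 30)
  p <- nast_project(o, aln)
  expect_identical(p$gapped, unname(rows[["t1"]]))
  expect_equal(nrow(p$rejected), 0)
  expect_identical(unproject(p), t1u)

  # one internal deletion -> one extra gap inside the span
  del <- paste0(substr(t1u, 1, 9), substr(t1u, 11, nchar(t1u)))
  pd <- nast_project(orient_and_assign(list(id = "r2", seq = del), aln,
                                       cutoff = 10), aln)
  gaps_in_span <- function(pp) {
    ch <- strsplit(pp$gapped, "")[[1]]
    sum(ch[pp$start_col:pp$end_col] == "-")
  }
  expect_equal(gaps_in_span(pd), gaps_in_span(p) + 1)
  expect_identical(unproject(pd), del)

  # insertion too large for the gap columns -> rejected but conserved
  ins <- paste0(substr(t1u, 1, 9), "GGGGG", substr(t1u, 10, nchar(t1u)))
  pi <- nast_project(orient_and_assign(list(id = "r3", seq = ins), aln,
                                       cutoff = 10), aln)
  expect_gt(nrow(pi$rejected), 0)
  expect_identical(unproject(pi), ins)

  expect_error(nast_project(orient_and_assign(
    list(id = "r4", seq = strrep("AC", 40)), aln, cutoff = 30), aln),
    "not accepted")
})

test_that("column-restricted identity tracks the simulated substitution rate", {
  t1 <- random_seq(1200, seed = 38)
  aln <- ref_alignment(c("t1"), t1)
  rate <- 0.05
  set.seed(39)
  idents <- replicate(40, {
    s <- sample(1:(1200 - 400), 1)
    ch <- strsplit(substr(t1, s, s + 399), "")[[1]]
    mut <- which(runif(400) < rate)
    for (p in mut) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    read <- paste(ch, collapse = "")
    o <- orient_and_assign(list(id = "m", seq = read), aln, cutoff = 10)
    p <- nast_project(o, aln)
    tch <- strsplit(t1, "")[[1]]
    rch <- strsplit(p$gapped, "")[[1]]
    span <- p$start_col:p$end_col
    mean(rch[span] == tch[span])
  })
  expect_lt(abs(mean(idents) - (1 - rate)), 0.02)
})
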