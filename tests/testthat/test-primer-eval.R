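test_that("degenerate expansion covers both syntaxes, deterministically", {
  v1 <- expand_degenerate("GTGCCAGC(A/C)GCCGCGGTAA")
  expect_identical(v1, c("GTGCCAGCAGCCGCGGTAA", "GTGCCAGCCGCCGCGGTAA"))
  v2 <- expand_degenerate("GGACTACC(A/C/G)GGGTATCTAAT")
  expect_length(v2, 3)
  expect_identical(substr(v2, 9, 9), c("A", "C", "G"))
  expect_identical(expand_degenerate("GGACTACCVGGGTATCTAAT"), v2)
  expect_identical(expand_degenerate("ACGT"), "ACGT")
  expect_error(expand_degenerate("ACQT"), "invalid")
})

test_that("reverse complement handles IUPAC codes and is an involution", {
  expect_identical(revcomp("ACGT"), "ACGT")
  expect_identical(revcomp("GGAC"), "GTCC")
  expect_identical(revcomp("V"), "B")
  set.seed(60)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                        "B", "D", "H", "V", "N"), 25, TRUE), collapse = "")
    expect_identical(revcomp(revcomp(x)), x)
  }
  expect_error(revcomp("ACXT"), "invalid")
})

test_that("primers anchor at the position an exact substring search finds", {
  ref <- fixture_mini_ref()
  am <- map_anchor(ref)
  anchor_seq <- rrnaprimer:::template_ungapped(ref, "anchor")
  pr <- fixture_primers()

  psF <- anchor_primer(pr[1, ], anchor_seq, am)
  # oracle: exact substring search for the A-variant
  oracle_start <- regexpr("GTGCCAGCAGCCGCGGTAA", anchor_seq, fixed = TRUE)
  expect_equal(psF$anchor_interval[1], as.integer(oracle_start))
  expect_equal(diff(psF$anchor_interval) + 1, 19)

  psR <- anchor_primer(pr[2, ], anchor_seq, am)
  oracle_r <- regexpr(revcomp("GGACTACCAGGGTATCTAAT"), anchor_seq,
                      fixed = TRUE)
  expect_equal(psR$anchor_interval[1], as.integer(oracle_r))

  alien <- data.frame(name = "bad", raw_seq = strrep("AC", 10),
                      orientation = "F")
  expect_error(anchor_primer(alien[1, ], anchor_seq, am), "bad")
})

test_that("binding sites extract with coverage flags; non-overlap yields nothing", {
  ref <- fixture_mini_ref()
  am <- map_anchor(ref)
  ps <- anchor_primer(fixture_primers()[1, ],
                      rrnaprimer:::template_ungapped(ref, "anchor"), am)
  full <- rrnaprimer:::template_ungapped(ref, "t1")
  o <- orient_and_assign(list(id = "r", seq = full), ref, cutoff = 30)
  p <- nast_project(o, ref)
  site <- extract_binding_site(p, ps)
  expect_true(all(site$covered))
  expect_equal(site$primer_len, 19)

  # read ending 4 primer positions into the site (site starts at col 31)
  part <- substr(full, 1, 34)
  pp <- nast_project(orient_and_assign(list(id = "r2", seq = part), ref,
                                       cutoff = 10), ref)
  s2 <- extract_binding_site(pp, ps)
  expect_equal(sum(s2$covered), 4)

  # read entirely upstream
  up <- substr(full, 1, 25)
  pu <- nast_project(orient_and_assign(list(id = "r3", seq = up), ref,
                                       cutoff = 10), ref)
  expect_null(extract_binding_site(pu, ps))
})

test_that("match typing applies the matched-degree rule symbol by symbol", {
  site <- function(frag, covered = rep(TRUE, 5))
    list(primer_len = 5, covered = covered, frag = frag, span = c(1, 5))
  perfect <- evaluate_site(site("ACGGT"), "ACGGT", "F")
  expect_identical(perfect$match_string, "=====")
  expect_identical(perfect$degree, "matched")

  # substitution at position 4 of 5 (inside the last-4 window)
  sub4 <- evaluate_site(site("ACGAT"), "ACGGT", "F")
  expect_identical(sub4$match_string, "===A=")
  expect_equal(sub4$n_mismatch_total, 1)
  expect_equal(sub4$n_mismatch_last4, 1)
  expect_identical(sub4$degree, "mismatched")

  # one substitution outside the last 4 of a 9-mer -> still matched
  site9 <- list(primer_len = 9, covered = rep(TRUE, 9),
                frag = "AAGGTTTTT", span = c(1, 9))
  out4 <- evaluate_site(site9, "ACGGTTTTT", "F")
  expect_equal(out4$n_mismatch_total, 1)
  expect_equal(out4$n_mismatch_last4, 0)
  expect_identical(out4$degree, "matched")

  # deletion: primer base absent from the read
  del <- evaluate_site(site("ACGT"), "ACGGT", "F")
  expect_true(grepl("d", del$match_string))
  expect_equal(del$n_mismatch_total, 1)

  # missing positions come from the coverage flags
  partial <- evaluate_site(site("ACG", covered = c(TRUE, TRUE, TRUE,
                                                   FALSE, FALSE)),
                           "ACGGT", "F")
  expect_identical(partial$match_string, "===..")
  expect_equal(partial$completeness, 3 / 5)

  # garbage site is dropped as poorly aligned
  bad <- evaluate_site(site("TTACA"), "ACGGT", "F")
  expect_true(is_dropped(bad))
  expect_identical(bad$reason, "poor_alignment")
})

test_that("best-variant selection prefers fewer mismatches, then 3' cleanliness", {
  site <- list(primer_len = 5, covered = rep(TRUE, 5), frag = "ACGGT",
               span = c(1, 5))
  pr <- list(variants = c("ATGGT", "ACGGT"), orientation = "F")
  evals <- lapply(seq_along(pr$variants), function(v) {
    e <- evaluate_site(site, pr$variants[v], "F")
    e$variant_index <- v
    e
  })
  best <- select_best_variant(evals)
  expect_equal(best$variant_index, 2)
  expect_identical(best$degree, "matched")

  # both variants one mismatch; pick the one clean in the last 4
  site2 <- list(primer_len = 6, covered = rep(TRUE, 6), frag = "AACGGT",
                span = c(1, 6))
  evals2 <- lapply(list(c(v = "AACGGA", i = 1), c(v = "ATCGGT", i = 2)),
                   function(x) {
    e <- evaluate_site(site2, x[["v"]], "F")
    e$variant_index <- as.integer(x[["i"]])
    e
  })
  expect_equal(select_best_variant(evals2)$variant_index, 2)
  expect_error(select_best_variant(list()), "no evaluations")

  # monotonicity: an added variant can only improve the selection key
  key <- function(e) c(e$n_mismatch_total, e$n_mismatch_last4)
  b1 <- select_best_variant(evals2[1])
  b2 <- select_best_variant(evals2)
  expect_true(key(b2)[1] < key(b1)[1] ||
                (key(b2)[1] == key(b1)[1] && key(b2)[2] <= key(b1)[2]))
})

test_that("F and R evaluations agree on mirrored reads", {
  set.seed(61)
  f_site <- "GTGCCAGCAGCCGCGGTAA"
  anc <- paste0(random_seq(40), f_site, random_seq(40))
  # mutate one site base to create a substitution
  mut <- anc
  substr(mut, 45, 45) <- "T"

  refF <- ref_alignment(c("t", "anchor"), c(anc, anc),
                        taxonomy = list(t = c("Bacteria", "P", "G")),
                        anchor_id = "anchor")
  amF <- map_anchor(refF)
  psF <- anchor_primer(data.frame(name = "pF", raw_seq = f_site,
                                  orientation = "F")[1, ], anc, amF)
  oF <- orient_and_assign(list(id = "x", seq = mut), refF, cutoff = 10)
  eF <- evaluate_read_primer(nast_project(oF, refF), psF)

  anc_rc <- revcomp(anc)
  refR <- ref_alignment(c("t", "anchor"), c(anc_rc, anc_rc),
                        taxonomy = list(t = c("Bacteria", "P", "G")),
                        anchor_id = "anchor")
  amR <- map_anchor(refR)
  psR <- anchor_primer(data.frame(name = "pR", raw_seq = f_site,
                                  orientation = "R")[1, ], anc_rc, amR)
  oR <- orient_and_assign(list(id = "x", seq = revcomp(mut)), refR,
                          cutoff = 10)
  eR <- evaluate_read_primer(nast_project(oR, refR), psR)

  expect_identical(eF$match_string, eR$match_string)
  expect_equal(eF$n_mismatch_total, eR$n_mismatch_total)
  expect_equal(eF$n_mismatch_last4, eR$n_mismatch_last4)
  expect_identical(eF$degree, eR$degree)
})
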