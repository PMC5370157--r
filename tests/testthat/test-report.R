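mk_eval <- function(read_id, match_string, completeness = 1,
                    degree = "matched", lineage = "Bacteria;P1;G1",
                    n_total = 0, n_last4 = 0) {
  data.frame(read_id = read_id, primer_name = "P", variant_used = "ACGT",
             match_string = match_string, site_start = 10L, site_end = 20L,
             n_mismatch_total = n_total, n_mismatch_last4 = n_last4,
             degree = degree, completeness = completeness,
             lineage = lineage, score = n_total * 100 + n_last4,
             stringsAsFactors = FALSE)
}

test_that("match-type files round-trip every field", {
  evals <- rbind(
    mk_eval("r1", "====="),
    mk_eval("r2", "==A==", degree = "mismatched", n_total = 1),
    mk_eval("r3", "===..", completeness = 3 / 5, degree = "mismatched"))
  path <- withr::local_tempfile(fileext = ".Match_type")
  write_match_type(evals, path)
  back <- read_match_type(path)
  cols <- c("read_id", "match_string", "site_start", "site_end",
            "n_mismatch_total", "n_mismatch_last4", "degree",
            "completeness", "lineage", "score")
  expect_equal(back[, cols], evals[order(evals$read_id), cols],
               ignore_attr = TRUE)

  empty <- withr::local_tempfile(fileext = ".Match_type")
  write_match_type(evals[0, ], empty)
  expect_equal(nrow(read_match_type(empty)), 0)
  expect_equal(length(readLines(empty)), 1) # header only
})

test_that("summary tables follow their definitions on a hand-built case", {
  evals <- rbind(
    mk_eval("r1", "====="), mk_eval("r2", "====="), mk_eval("r3", "====="),
    mk_eval("r4", "==A==", degree = "mismatched", n_total = 1),
    mk_eval("r5", "=T===", degree = "mismatched", n_total = 1),
    mk_eval("r6", "==AT=", degree = "mismatched", n_total = 2, n_last4 = 1),
    mk_eval("r7", "===..", completeness = 3 / 5, degree = "mismatched"))
  st <- compute_stat_tables(evals)
  # 6 complete sites: 3 matched, 3 mismatched
  expect_equal(st$table1$count[st$table1$degree == "matched"], 3)
  expect_equal(st$table1$count[st$table1$degree == "mismatched"], 3)
  expect_equal(sum(st$table1$count), sum(evals$completeness == 1))
  # completeness distribution has both values
  expect_setequal(st$table2$completeness, c(1, 3 / 5))
  # substitutions are the most frequent mismatch type
  expect_identical(st$table3$type[st$table3$most_frequent], "substitution")
  # most common match string
  expect_identical(st$table4$match_string, "=====")
  expect_equal(st$table4$count, 3)
  # table5 column sums equal total event counts
  expect_equal(sum(st$table5$substitution), 4)
  expect_equal(sum(st$table5$missing), 2)
  expect_equal(st$table5$substitution[3], 2)
  # table6 uses only complete records
  g1 <- st$table6[st$table6$rank == 3, ]
  expect_equal(g1$n_complete, 6)
  expect_equal(g1$n_matched, 3)
  expect_equal(g1$coverage_pct, 50)
})

test_that("summary tables equal an independent recount on randomized inputs", {
  set.seed(70)
  P <- 12
  rand_string <- function() {
    n_miss <- sample(0:4, 1)
    sym <- c(sample(c("=", "=", "=", "A", "C", "G", "T", "d"),
                    P - n_miss, TRUE), rep(".", n_miss))
    paste(sym, collapse = "")
  }
  evals <- do.call(rbind, lapply(1:60, function(i) {
    ms <- rand_string()
    o <- oracle_recount(ms, P)
    mk_eval(sprintf("r%02d", i), ms, completeness = o$completeness,
            degree = if (o$completeness == 1 &&
                         (o$n_total == 0 ||
                          (o$n_total == 1 && o$n_last4 == 0)))
              "matched" else "mismatched",
            lineage = sample(c("Bacteria;P1;G1", "Bacteria;P2;G2",
                               "Archaea;P3;G3"), 1),
            n_total = o$n_total, n_last4 = o$n_last4)
  }))
  st <- compute_stat_tables(evals)
  complete <- evals[evals$completeness == 1, ]
  expect_equal(sum(st$table1$count), nrow(complete))
  expect_equal(st$table1$count[st$table1$degree == "matched"],
               sum(complete$degree == "matched"))
  expect_equal(sum(st$table2$count), nrow(evals))
  # per-position substitution counts, recomputed directly
  for (pos in c(1, 5, 12)) {
    ora <- sum(substr(evals$match_string, pos, pos) %in%
                 c("A", "C", "G", "T"))
    expect_equal(st$table5$substitution[pos], ora)
  }
  # taxa partition the complete records at every rank
  for (r in unique(st$table6$rank))
    expect_equal(sum(st$table6$n_complete[st$table6$rank == r]),
                 nrow(complete))
  expect_true(all(st$table6$coverage_pct >= 0 & st$table6$coverage_pct <= 100))
})

test_that("stat files serialize all six tables", {
  evals <- rbind(mk_eval("r1", "====="),
                 mk_eval("r2", "==A==", degree = "mismatched", n_total = 1))
  st <- compute_stat_tables(evals)
  path <- withr::local_tempfile(fileext = ".Stat")
  write_stat(st, path)
  txt <- readLines(path)
  for (i in 1:6) expect_true(any(grepl(paste0("^Table ", i, ":"), txt)))
})

test_that("goodness of fit matches closed forms and the stats oracle", {
  obs <- c(a = 30, b = 20, c = 50)
  expect_equal(compare_composition(obs, c(a = 0.3, b = 0.2, c = 0.5))$chi2, 0)
  expect_equal(compare_composition(obs, c(a = 0.3, b = 0.2, c = 0.5))$p_value, 1)

  two <- compare_composition(c(a = 10, b = 0), c(a = 0.5, b = 0.5))
  expect_equal(two$chi2, 10)

  set.seed(71)
  o <- c(x = 40, y = 25, z = 35)
  p <- c(x = 0.4, y = 0.35, z = 0.25)
  got <- compare_composition(o, p)
  ref <- suppressWarnings(stats::chisq.test(o, p = p))
  expect_equal(got$chi2, unname(ref$statistic))
  expect_equal(got$p_value, unname(ref$p.value))

  expect_error(compare_composition(c(a = 5, b = 1), c(a = 1, b = 0)),
               "proportion 0")
})
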