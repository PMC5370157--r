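# Shared fixtures, built in code. Expensive ones (full mock-community
# pipeline runs) are computed once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# the two V4 primers used throughout
fixture_primers <- function() {
  data.frame(name = c("F515", "R806"),
             raw_seq = c("GTGCCAGC(A/C)GCCGCGGTAA",
                         "GGACTACC(A/C/G)GGGTATCTAAT"),
             orientation = c("F", "R"),
             stringsAsFactors = FALSE)
}

# small ungapped reference with both primer sites embedded exactly:
# anchor + one bacterial row; primer F515 site at 31-49
fixture_mini_ref <- function() {
  set.seed(301)
  f_site <- "GTGCCAGCAGCCGCGGTAA"
  r_site <- revcomp("GGACTACCAGGGTATCTAAT")
  anc <- paste0(random_seq(30), f_site, random_seq(20), r_site,
                random_seq(20))
  ref_alignment(c("t1", "anchor"), c(anc, anc),
                taxonomy = list(t1 = c("Bacteria", "P1", "G1")),
                anchor_id = "anchor")
}

# the default 13-member mock community simulated and run end to end;
# default cutoffs mirror the mock-validation run (search 10, bootstrap 80),
# NULL bootstrap_cutoff means the automatic 60/50 rule
fixture_mock_run <- function(seed = 11, mismatch_genus = NULL,
                             search_cutoff = 10, bootstrap_cutoff = 80) {
  key <- paste0("mock_run_", seed, "_",
                paste(mismatch_genus, collapse = "-"), "_",
                search_cutoff, "_", paste(bootstrap_cutoff, collapse = ""))
  cached(key, function() {
    spec <- default_mock_community(seed = seed,
                                   mismatch_genus = mismatch_genus)
    mock <- generate_mock_genomes(spec)
    sim <- simulate_reads(mock, spec)
    ref <- mock_reference(spec)
    scr <- run_prescreen(sim$reads,
                         data.frame(id = spec$members$id,
                                    seq = spec$members$rrna))
    res <- run_pipeline(scr$kept, ref, fixture_primers(),
                        search_cutoff = search_cutoff,
                        bootstrap_cutoff = bootstrap_cutoff,
                        seed = 5)
    list(spec = spec, mock = mock, sim = sim, ref = ref, screen = scr,
         result = res)
  })
}

# test-local recount of a match-type string, independent of the package's
# internal tally: substitutions one each, indels one per event, missing
# per position; last-4 window on primer coordinates
oracle_recount <- function(match_string, P) {
  syms <- regmatches(match_string,
                     gregexpr("[=ACGTNd.][acgtn]*", match_string))[[1]]
  stopifnot(length(syms) == P)
  first <- substr(syms, 1, 1)
  is_sub <- first %in% c("A", "C", "G", "T", "N")
  is_del <- first == "d"
  is_ins <- nchar(syms) > 1
  del_ev_start <- which(is_del & !c(FALSE, is_del[-P]))
  del_ev_end <- which(is_del & !c(is_del[-1], FALSE))
  last4 <- seq(max(1, P - 3), P)
  n_total <- sum(is_sub) + length(del_ev_start) + sum(is_ins)
  n_last4 <- sum(is_sub & seq_len(P) %in% last4) +
    sum(del_ev_end >= max(1, P - 3)) +
    sum(which(is_ins) >= max(1, P - 4))
  list(n_total = n_total, n_last4 = n_last4,
       completeness = (P - sum(first == ".")) / P)
}

# genus label (last rank) of a ;-joined lineage string
genus_of <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts[length(parts)]
}
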