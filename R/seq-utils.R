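#' @useDynLib rrnaprimer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# IUPAC nucleotide code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# IUPAC complement (covers the degenerate codes: e.g. V <-> B)
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-", `.` = "."
)

#' Reverse complement of a nucleotide sequence
#'
#' Complements every base, including degenerate IUPAC codes (`R` <-> `Y`,
#' `V` <-> `B`, ...), and reverses the sequence. Gap characters are
#' preserved.
#'
#' @param seq A single nucleotide string; IUPAC codes allowed, case
#'   insensitive.
#' @return The reverse-complemented string, uppercase.
#' @examples
#' revcomp("GGAC")   # "GTCC"
#' revcomp("ACGT")   # "ACGT" (palindrome)
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  comp <- IUPAC_COMPLEMENT[chars]
  if (anyNA(comp)) {
    bad <- unique(chars[is.na(comp)])
    stop("revcomp: invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(comp)), collapse = "")
}

#' Expand a degenerate primer into its non-degenerate variants
#'
#' Accepts both parenthesized alternatives, e.g. `"GTGCCAGC(A/C)GCCGCGGTAA"`,
#' and IUPAC degeneracy codes (`R`, `Y`, `V`, `N`, ...), possibly mixed.
#' The expansion is the cartesian product over positions; variant order is
#' deterministic (alternatives in written order, IUPAC sets in alphabetical
#' order, leftmost position varying slowest).
#'
#' @param raw_seq Primer string with optional `(X/Y/...)` groups and IUPAC
#'   codes.
#' @return Character vector of non-degenerate variants (no duplicates).
#' @examples
#' expand_degenerate("GTGCCAGC(A/C)GCCGCGGTAA")  # 2 variants
#' expand_degenerate("GGACTACCVGGGTATCTAAT")     # 3 variants (V = A/C/G)
#' @export
expand_degenerate <- function(raw_seq) {
  sets <- parse_primer_positions(raw_seq)
  n_var <- prod(lengths(sets))
  if (n_var > 10000)
    stop("expand_degenerate: primer expands to ", n_var, " variants; refusing")
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)[, rev(seq_along(sets)), drop = FALSE]
  variants <- do.call(paste0, grid)
  unique(variants)
}

# Parse a primer string into a list of per-position allowed-base sets.
# Shared by expand_degenerate() and primer input validation.
parse_primer_positions <- function(raw_seq) {
  stopifnot(is.character(raw_seq), length(raw_seq) == 1L, nzchar(raw_seq))
  s <- toupper(gsub("[[:space:]]", "", raw_seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      close <- i
      while (close <= length(chars) && chars[close] != ")") close <- close + 1L
      if (close > length(chars))
        stop("primer '", raw_seq, "': unbalanced parenthesis")
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      if (length(alts) == 0L)
        stop("primer '", raw_seq, "': empty alternative group")
      if (!all(alts %in% names(IUPAC_SETS)))
        stop("primer '", raw_seq, "': invalid symbol in alternative group (",
             inner, ")")
      # written order preserved; alternatives may themselves be IUPAC codes
      expanded <- unique(unlist(IUPAC_SETS[alts], use.names = FALSE))
      sets[[length(sets) + 1L]] <- expanded
      i <- close + 1L
    } else if (ch %in% names(IUPAC_SETS)) {
      sets[[length(sets) + 1L]] <- IUPAC_SETS[[ch]]
      i <- i + 1L
    } else {
      stop("primer '", raw_seq, "': invalid nucleotide symbol '", ch, "'")
    }
  }
  if (length(sets) == 0L) stop("primer '", raw_seq, "': no positions")
  sets
}

# Integer encoding of all k-mers of a sequence (A=0 C=1 G=2 T=3, base 4).
# k-mers containing any non-ACGT character are dropped. Returns the codes
# in sequence order, possibly with duplicates.
kmer_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T")) - 1L
  valid <- !is.na(v)
  v[!valid] <- 0L
  idx <- seq_len(n - k + 1L)
  m <- outer(idx, 0:(k - 1L), "+")
  pow <- 4^((k - 1L):0)
  codes <- as.integer(matrix(v[m], nrow = length(idx)) %*% pow)
  ok <- rowSums(matrix(valid[m], nrow = length(idx))) == k
  codes[ok]
}

# Distinct k-mer codes of a sequence.
distinct_kmers <- function(seq, k) unique(kmer_codes(seq, k))

# Strip gap characters ('-' and '.') from a gapped sequence.
degap <- function(seq) gsub("[-.]", "", seq)
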