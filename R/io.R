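#' Read shotgun reads or reference sequences
#'
#' Parses FASTA or FASTQ into a data frame of sequence records. Sequences
#' are uppercased and RNA `U` is normalized to `T` on read. Qualities are
#' parsed (as their ASCII string) but are not used anywhere downstream.
#'
#' @param path Path to the sequence file.
#' @param format `"fasta"` or `"fastq"`.
#' @return A data frame with columns `id` (character, unique) and `seq`
#'   (uppercase DNA), plus `qual` for FASTQ input.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_sequences: no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = format,
                               with.qualities = (format == "fastq")),
    error = function(e) stop("read_sequences: parse error in '", path,
                             "': ", conditionMessage(e))
  )
  ids <- sub("\\s.*$", "", names(set))
  if (length(set) == 0L)
    return(data.frame(id = character(0), seq = character(0)))
  if (anyDuplicated(ids))
    stop("read_sequences: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids)))
    stop("read_sequences: empty id at record ", which(!nzchar(ids))[1])
  seqs <- normalize_seq(as.character(set))
  bad <- grepl("[^ACGTUNRYSWKMBDHV]", seqs)
  if (any(bad))
    stop("read_sequences: invalid characters in record ", which(bad)[1],
         " ('", ids[which(bad)[1]], "')")
  if (any(!nzchar(seqs)))
    stop("read_sequences: empty sequence in record ", which(!nzchar(seqs))[1])
  out <- data.frame(id = ids, seq = unname(seqs), stringsAsFactors = FALSE)
  if (format == "fastq") {
    qual <- as.character(S4Vectors::mcols(set)$qualities)
    if (any(nchar(qual) != nchar(out$seq)))
      stop("read_sequences: quality length mismatch at record ",
           which(nchar(qual) != nchar(out$seq))[1])
    out$qual <- qual
  }
  out
}

normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Write sequences as FASTA
#'
#' @param records Data frame with `id` and `seq` columns (gapped or
#'   ungapped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gapped reference alignment
#'
#' Reads aligned FASTA in which `-` and `.` are both accepted as gap
#' characters (SILVA-style files mix the two); gaps are normalized to `-`
#' internally. All rows must share one length, the alignment width.
#'
#' @param path Path to an aligned FASTA file.
#' @param taxonomy Optional taxonomy, as returned by [read_taxonomy()], to
#'   attach to the alignment.
#' @param anchor_id Optional id of the anchor (reference marker) row.
#' @return A `ref_alignment` object; see [ref_alignment()].
#' @export
read_alignment <- function(path, taxonomy = NULL, anchor_id = NULL) {
  set <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- normalize_seq(as.character(set))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    off <- ids[widths != widths[1]][1]
    stop("read_alignment: rows differ in length (e.g. '", off, "')")
  }
  ref_alignment(ids, unname(seqs), taxonomy = taxonomy, anchor_id = anchor_id)
}

#' Parse a primer list
#'
#' One primer per line: name, sequence, orientation (`F` or `R`), separated
#' by tabs or whitespace. Sequences may use parenthesized alternatives
#' (`"(A/C)"`) and/or IUPAC degeneracy codes; both are validated here and
#' preserved verbatim in `raw_seq`.
#'
#' @param path Path to the primer list file.
#' @return Data frame with columns `name`, `raw_seq`, `orientation`.
#' @export
parse_primers <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(name = character(0), raw_seq = character(0),
                      orientation = character(0)))
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(fields) != 3L)
      stop("parse_primers: line ", i, ": expected 'name sequence orientation'")
    name <- fields[1]; raw <- fields[2]; ori <- toupper(fields[3])
    if (!ori %in% c("F", "R"))
      stop("parse_primers: line ", i, ": orientation must be F or R")
    tryCatch(parse_primer_positions(raw),
             error = function(e) stop("parse_primers: line ", i, ": ",
                                      conditionMessage(e)))
    data.frame(name = name, raw_seq = raw, orientation = ori,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (anyDuplicated(out$name))
    stop("parse_primers: duplicate primer name(s): ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "))
  out
}

#' Read a taxonomy table
#'
#' Two-column lines: sequence id, then a `;`-separated lineage from domain
#' downward (mothur dialect). A trailing `;` and per-rank bootstrap
#' confidences in parentheses, e.g. `Archaea(100)`, are stripped. Blank
#' lines are skipped.
#'
#' @param path Path to the taxonomy file.
#' @return Named list: for each sequence id, a character vector of rank
#'   labels.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(fields) < 2L)
      stop("read_taxonomy: line ", i, ": id with no lineage")
    id <- fields[1]
    lineage <- strsplit(fields[2], ";", fixed = TRUE)[[1]]
    lineage <- sub("\\([0-9.]+\\)$", "", lineage)
    lineage <- lineage[nzchar(lineage)]
    if (length(lineage) == 0L)
      stop("read_taxonomy: line ", i, ": id with no lineage")
    out[[id]] <- lineage
  }
  out
}

#' Write a taxonomy assignment table
#'
#' One row per read: id, lineage with per-rank bootstrap percentages in
#' parentheses, and the pass flag from the domain-level bootstrap gate.
#'
#' @param assignments Data frame from [classify_reads()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(assignments, path) {
  lin <- vapply(seq_len(nrow(assignments)), function(i) {
    l <- assignments$lineage[[i]]
    b <- assignments$bootstrap[[i]]
    paste0(paste0(l, "(", b, ")", collapse = ";"), ";")
  }, character(1))
  df <- data.frame(read_id = assignments$read_id, taxonomy = lin,
                   passed = assignments$passed)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
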