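#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are upper-cased and `U` is mapped to `T` so that RNA-style
#' records can be used directly as DNA barcodes. Record identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgu", ">b", "ACGT"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_seq(as.character(raw))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Four-line FASTQ records with Phred+33 quality encoding. Records with a
#' quality string whose length differs from the sequence, truncated trailing
#' records, and files that look Phred+64 encoded (any decoded score above 41)
#' are rejected with an informative error rather than silently dropped.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `id`, `sequence` (upper-cased) and
#'   `quality` (raw Phred+33 string). Decode scores with [qualityScores()].
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ record at end of ", path,
         " (", length(lines), " lines; not a multiple of 4)")
  }
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- !startsWith(hdr, "@")
  if (any(bad_hdr)) {
    stop("malformed FASTQ header at line ", (which(bad_hdr)[1] - 1L) * 4L + 1L)
  }
  if (any(!startsWith(plus, "+"))) {
    stop("malformed FASTQ separator at line ",
         (which(!startsWith(plus, "+"))[1] - 1L) * 4L + 3L)
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  if (anyDuplicated(ids)) {
    stop("duplicate read ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mism <- nchar(seq) != nchar(qual)
  if (any(mism)) {
    stop("sequence/quality length mismatch for read(s): ",
         paste(ids[mism], collapse = ", "))
  }
  allq <- utf8ToInt(paste(qual, collapse = "")) - 33L
  if (any(allq < 0L)) stop("quality characters below Phred+33 range in ", path)
  if (any(allq > 41L)) {
    stop("quality scores above 41 detected; input looks Phred+64 encoded. ",
         "Only Phred+33 FASTQ is accepted.")
  }
  data.frame(id = ids, sequence = normalize_seq(seq), quality = qual,
             stringsAsFactors = FALSE)
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param x A read table from [readFastq()] or a character vector of
#'   Phred+33 quality strings.
#' @return A list of integer vectors, one per read.
#' @export
qualityScores <- function(x) {
  if (is.data.frame(x)) x <- x$quality
  phred_scores(x)
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads Data frame with `id`, `sequence`, `quality` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality), con)
  }
  invisible(path)
}

# Shared TSV reader: single header row, tab-separated, '#' lines are comments.
read_tsv <- function(path, required) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(basename(path), " is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a table as TSV
#'
#' Tab-separated, one header row, no quoting. Columns listed in
#' `percent_cols` are rendered with exactly two decimals, rounding half away
#' from zero; all other numeric columns are written as-is.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param percent_cols Character vector of column names holding percentages.
#' @return Invisibly, `path`.
#' @export
writeTsv <- function(df, path, percent_cols = character()) {
  out <- df
  for (cl in intersect(percent_cols, names(out))) {
    out[[cl]] <- fmt_pct(as.numeric(out[[cl]]))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a demultiplexing sample sheet
#'
#' Columns: `sample_id`, `group`, `fwd_tag`, `rev_tag`, `fwd_primer`,
#' `rev_primer`. Tags must be exactly 8 nt; `(fwd_tag, rev_tag)` pairs and
#' sample ids must be unique. Primers may contain IUPAC ambiguity codes.
#'
#' @param path Path to a TSV sample sheet ('#' lines are comments).
#' @return A validated data frame.
#' @export
readSampleSheet <- function(path) {
  sheet <- read_tsv(path, c("sample_id", "group", "fwd_tag", "rev_tag",
                            "fwd_primer", "rev_primer"))
  validateSampleSheet(sheet)
}

#' Validate a sample sheet data frame
#'
#' @param sheet Data frame with the sample-sheet columns.
#' @return The sheet, invisibly validated (tags upper-cased).
#' @export
validateSampleSheet <- function(sheet) {
  for (cl in c("fwd_tag", "rev_tag", "fwd_primer", "rev_primer")) {
    sheet[[cl]] <- toupper(sheet[[cl]])
  }
  badlen <- nchar(sheet$fwd_tag) != 8L | nchar(sheet$rev_tag) != 8L
  if (any(badlen)) {
    stop("tags must be exactly 8 nt; offending sample(s): ",
         paste(sheet$sample_id[badlen], collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  if (anyDuplicated(paste(sheet$fwd_tag, sheet$rev_tag))) {
    stop("duplicate (fwd_tag, rev_tag) pair in sample sheet")
  }
  sheet
}

#' Read a taxonomy map
#'
#' Columns: `seq_id`, `family`, `genus`, `species`. `genus`/`species` may be
#' empty to denote coarser knowledge, but a non-empty `species` requires a
#' non-empty `genus`, and a non-empty `genus` requires a non-empty `family`.
#'
#' @param path Path to a TSV taxonomy map.
#' @return A validated data frame.
#' @export
readTaxonomy <- function(path) {
  tax <- read_tsv(path, c("seq_id", "family", "genus", "species"))
  for (cl in c("family", "genus", "species")) {
    tax[[cl]] <- ifelse(is.na(tax[[cl]]), "", trimws(tax[[cl]]))
  }
  if (anyDuplicated(tax$seq_id)) stop("duplicate seq_id in taxonomy map")
  bad <- (nzchar(tax$species) & !nzchar(tax$genus)) |
         (nzchar(tax$genus) & !nzchar(tax$family))
  if (any(bad)) {
    stop("taxonomy rank gaps (species without genus, or genus without family) ",
         "for: ", paste(tax$seq_id[bad], collapse = ", "))
  }
  tax
}

#' Read a microhistology diet table
#'
#' Columns: `group` (bird group), `taxon`, `rank`, `fm_percent` (percentage of
#' identifiable epidermis fragments attributed to the taxon).
#'
#' @param path Path to a TSV file.
#' @return A data frame.
#' @export
readMicrohistology <- function(path) {
  df <- read_tsv(path, c("group", "taxon", "rank", "fm_percent"))
  df$fm_percent <- as.numeric(df$fm_percent)
  df
}
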