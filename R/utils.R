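# Internal helpers shared across modules.

#' @import methods
#' @importFrom stats uniroot setNames as.dist hclust cophenetic rmultinom
#'   aggregate runif rbinom
#' @importFrom utils read.delim write.table
#' @importClassesFrom Biostrings DNAStringSet
NULL

# Round half away from zero at `digits` decimals (table rendering convention;
# base round() is round-half-even).
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Render a percentage with exactly two decimals.
fmt_pct <- function(x) {
  sprintf("%.2f", round_half_away(x, 2))
}

# Uppercase and map U -> T; input character vector.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

# Reverse-complement of plain character sequences, IUPAC-aware.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a character string (for quality strings of reverse-complemented reads).
rev_chr <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE)
}

# Phred+33 quality string -> integer scores.
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# Integer scores -> Phred+33 string.
phred_string <- function(scores) {
  intToUtf8(pmin(scores, 41L) + 33L)
}

# Translate an IUPAC nucleotide string into a regular expression where each
# ambiguity code becomes a character class of the bases it covers.
iupac_regex <- function(x) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad)) {
    stop("non-IUPAC characters in primer: ", paste(unique(bad), collapse = ", "))
  }
  paste(vapply(chars, function(ch) {
    bases <- map[[ch]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1)), collapse = "")
}

# Number of mismatching positions between two equal-length strings (fast raw
# comparison; no alignment).
hamming_chr <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Default alignment scoring used throughout: match +1, mismatch -2,
# gap open 5, gap extend 2 (penalties).
default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_opening = 5, gap_extension = 2)
}

.substitution_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE
  )
}
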