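#' Global pairwise alignment of two barcode sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used to put
#' two barcode sequences of near-equal length into a common coordinate system
#' before distance computation. End gaps are penalized (no free end gaps).
#' Scoring defaults: match +1, mismatch -2, gap open -5, gap extend -2.
#'
#' @param seqA,seqB Ungapped nucleotide strings (or `DNAString`).
#' @param scoring A list with elements `match`, `mismatch`, `gap_opening`,
#'   `gap_extension` (penalties positive), as from the package default.
#' @return A list of class `aligned_pair` with elements `seqA`, `seqB`
#'   (equal-length gapped strings), `score`, and `comparable_sites` (columns
#'   where both characters are in `{A,C,G,T}`).
#' @examples
#' alignPair("ACGT", "AGT")
#' @export
alignPair <- function(seqA, seqB, scoring = default_scoring()) {
  a <- as.character(seqA); b <- as.character(seqB)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension
  )
  ga <- as.character(Biostrings::pattern(aln))
  gb <- as.character(Biostrings::subject(aln))
  structure(
    list(seqA = ga, seqB = gb, score = Biostrings::score(aln),
         comparable_sites = count_comparable(ga, gb)),
    class = "aligned_pair"
  )
}

# Columns where both characters are unambiguous bases.
count_comparable <- function(ga, gb) {
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  sum(ca %in% acgt & cb %in% acgt)
}

# Identity of a set of query sequences against one centroid under global
# alignment with end gaps penalized: matches / alignment columns.
# Returns a numeric vector parallel to `queries`.
global_identity <- function(queries, centroid, scoring = default_scoring()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(centroid),
    type = "global", substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension
  )
  # alignment columns including end gaps: every column either pairs two
  # bases or gaps one of them, so columns = la + lb - aligned_pairs
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- nchar(queries) + nchar(centroid) - pairs
  Biostrings::nmatch(aln) / cols
}
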