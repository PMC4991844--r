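#' @title Local plant barcode reference library
#'
#' @description
#' Barcode sequences with three-rank taxonomy (family, genus, species) and a
#' partition of records into groups of exactly identical sequences. Species
#' that share a barcode sequence fall into one group and can only be
#' distinguished at the finest rank common to the group's members; the group
#' table records that assignable rank.
#'
#' @slot sequences [Biostrings::DNAStringSet] of normalized barcode
#'   sequences, named by `seq_id`.
#' @slot taxonomy Data frame (`seq_id`, `family`, `genus`, `species`) with
#'   one row per sequence, in sequence order.
#' @slot groups Data frame (`seq_id`, `group_id`) partitioning the records
#'   by exact sequence identity.
#'
#' @aliases ReferenceLibrary-class
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary", slots = c(
  sequences = "DNAStringSet",
  taxonomy = "data.frame",
  groups = "data.frame"
))

setValidity("ReferenceLibrary", function(object) {
  errs <- character()
  ids <- names(object@sequences)
  if (is.null(ids)) ids <- character()
  if (!identical(unname(ids), as.character(object@taxonomy$seq_id))) {
    errs <- c(errs, "taxonomy rows must match sequence names in order")
  }
  if (!setequal(ids, object@groups$seq_id) ||
      nrow(object@groups) != length(ids)) {
    errs <- c(errs, "groups must partition the records")
  }
  if (length(errs)) errs else TRUE
})

#' Build a reference library from sequences and taxonomy
#'
#' Sequences are normalized (upper-cased, `U` mapped to `T`, residual IUPAC
#' ambiguity codes mapped to `N`). Records whose `N` fraction exceeds 5% are
#' rejected with a warning. Identical sequences are collapsed into groups by
#' exact string equality only; a sequence that is a strict prefix of another
#' (a trimming-length artifact) is *not* collapsed, but a warning is issued.
#'
#' @param fasta A [Biostrings::DNAStringSet], named character vector, or path
#'   to a FASTA file.
#' @param taxonomy A taxonomy data frame (`seq_id`, `family`, `genus`,
#'   `species`) or path to a taxonomy TSV ([readTaxonomy()]).
#' @return A [ReferenceLibrary-class] object.
#' @export
buildLibrary <- function(fasta, taxonomy) {
  if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    fasta <- readFasta(fasta)
  }
  seqs <- normalize_seq(as.character(fasta))
  names(seqs) <- names(fasta)
  if (is.character(taxonomy)) taxonomy <- readTaxonomy(taxonomy)
  missing <- setdiff(names(seqs), taxonomy$seq_id)
  if (length(missing)) {
    stop("sequence id(s) missing from taxonomy: ",
         paste(missing, collapse = ", "))
  }
  # map residual ambiguity codes to N, then apply the N-fraction rule
  seqs <- vapply(seqs, function(s) {
    gsub("[^ACGTN]", "N", s)
  }, character(1))
  n_frac <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr("N", s, fixed = TRUE))) / nchar(s)
  }, numeric(1))
  reject <- n_frac > 0.05
  if (any(reject)) {
    warning("rejecting ", sum(reject), " record(s) with > 5% N: ",
            paste(names(seqs)[reject], collapse = ", "))
    seqs <- seqs[!reject]
  }
  # warn on strict-prefix pairs (possible trimming-length artifacts)
  if (length(seqs) >= 2L) {
    srt <- sort(unique(unname(seqs)))
    pref <- startsWith(srt[-1], srt[-length(srt)]) &
      nchar(srt[-1]) > nchar(srt[-length(srt)])
    if (any(pref)) {
      warning(sum(pref), " sequence pair(s) differ only by terminal length; ",
              "not collapsed")
    }
  }
  tax <- taxonomy[match(names(seqs), taxonomy$seq_id), , drop = FALSE]
  rownames(tax) <- NULL
  group_id <- match(unname(seqs), unique(unname(seqs)))
  groups <- data.frame(
    seq_id = names(seqs),
    group_id = sprintf("g%03d", group_id),
    stringsAsFactors = FALSE
  )
  dss <- Biostrings::DNAStringSet(unname(seqs))
  names(dss) <- names(seqs)
  new("ReferenceLibrary", sequences = dss, taxonomy = tax, groups = groups)
}

#' @describeIn ReferenceLibrary-class Sequences in the library.
#' @param x A `ReferenceLibrary`.
#' @export
refSequences <- function(x) x@sequences

#' @describeIn ReferenceLibrary-class Taxonomy table of the library.
#' @export
refTaxonomy <- function(x) x@taxonomy

#' @describeIn ReferenceLibrary-class Identical-sequence groups with their
#'   assignable rank and taxon (one row per group).
#' @export
seqGroups <- function(x) {
  if (!nrow(x@groups)) {
    return(data.frame(group_id = character(), seq_ids = character(),
                      n_records = integer(), rank = character(),
                      taxon = character(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(x@groups$seq_id, x@groups$group_id), function(ids) {
    res <- resolutionOf(x@taxonomy[x@taxonomy$seq_id %in% ids, , drop = FALSE])
    data.frame(seq_ids = paste(ids, collapse = ","), n_records = length(ids),
               rank = res$rank, taxon = res$taxon, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df <- cbind(data.frame(group_id = rownames(df), stringsAsFactors = FALSE), df)
  rownames(df) <- NULL
  df[order(df$group_id), , drop = FALSE]
}

#' Assignable rank of a group of taxonomically labeled records
#'
#' The finest rank at which a group of records sharing one barcode sequence
#' can be identified: species if the group holds one species; genus if more
#' than one species but a single genus; family if more than one genus but a
#' single family; `"above-family"` otherwise. Merging two groups can never
#' yield a finer rank.
#'
#' @param records Data frame with `family`, `genus`, `species` columns (the
#'   taxonomy rows of the group's members).
#' @return A list with `rank` and `taxon` (the name at that rank).
#' @export
resolutionOf <- function(records) {
  if (!nrow(records)) stop("group is empty")
  spp <- unique(records$species[nzchar(records$species)])
  gen <- unique(records$genus[nzchar(records$genus)])
  fam <- unique(records$family[nzchar(records$family)])
  if (length(spp) == 1L && all(records$species == spp)) {
    return(list(rank = "species", taxon = spp))
  }
  if (length(gen) == 1L) return(list(rank = "genus", taxon = gen))
  if (length(fam) == 1L) return(list(rank = "family", taxon = fam))
  list(rank = "above-family", taxon = NA_character_)
}

#' Per-family species and unique-sequence counts
#'
#' @param x A [ReferenceLibrary-class].
#' @return Data frame (`family`, `n_species`, `n_sequences`) sorted by
#'   family; `n_sequences` counts distinct sequences within the family.
#' @export
familyCounts <- function(x) {
  tax <- x@taxonomy
  seqs <- as.character(x@sequences)
  fams <- sort(unique(tax$family[nzchar(tax$family)]))
  out <- lapply(fams, function(f) {
    sel <- tax$family == f
    data.frame(
      family = f,
      n_species = length(unique(tax$species[sel & nzchar(tax$species)])),
      n_sequences = length(unique(seqs[sel])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' @describeIn ReferenceLibrary-class Display a summary.
#' @param object A `ReferenceLibrary`.
#' @export
setMethod("show", "ReferenceLibrary", function(object) {
  tax <- object@taxonomy
  cat("ReferenceLibrary with", length(object@sequences), "sequences,",
      length(unique(tax$species[nzchar(tax$species)])), "species,",
      length(unique(tax$family[nzchar(tax$family)])), "families,",
      length(unique(object@groups$group_id)), "identical-sequence groups\n")
  invisible(NULL)
})

#' Write a reference library archive
#'
#' Writes the normalized FASTA, the identical-sequence group table
#' (`group_id`, `seq_ids`, `rank`, `taxon`) and the per-family counts table.
#'
#' @param x A [ReferenceLibrary-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeLibrary <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(x@sequences, file.path(dir, "reference.fasta"))
  writeTsv(x@taxonomy, file.path(dir, "taxonomy.tsv"))
  writeTsv(seqGroups(x), file.path(dir, "groups.tsv"))
  writeTsv(familyCounts(x), file.path(dir, "family_counts.tsv"))
  invisible(dir)
}
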