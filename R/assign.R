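#' Karlin-Altschul parameters for an ungapped match/mismatch scheme
#'
#' Computes the scale `lambda` and the search-space constant `K` for local
#' alignment e-values under uniform base frequencies. `lambda` is the
#' positive root of \eqn{\frac{1}{4} e^{\lambda m} + \frac{3}{4}
#' e^{\lambda s} = 1} (match score `m`, mismatch score `s`); a positive root
#' exists only when the expected pair score is negative. `K` is evaluated by
#' the standard series: with \eqn{S_k} the k-step random walk of pair
#' scores, \eqn{\sigma = \sum_{k\ge1} k^{-1}\left(E[e^{\lambda S_k};
#' S_k<0] + P(S_k \ge 0)\right)} and
#' \deqn{K = \frac{\delta\,\lambda\,e^{-2\sigma}}{H\,(1-e^{-\lambda\delta})},}
#' where \eqn{\delta} is the greatest common divisor of the scores and `H`
#' the relative entropy of the aligned-pair distribution. The series is
#' truncated when terms fall below 1e-12 (the walk has negative drift, so
#' terms decay geometrically). For match +1 / mismatch -2 this yields
#' `lambda` = 1.33, `K` = 0.62.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0 for a root to exist).
#' @return A list with `lambda`, `K`, and `H`.
#' @export
calibrateEvalueParams <- function(match = 1, mismatch = -2) {
  if (match <= 0) stop("match score must be positive")
  e_score <- 0.25 * match + 0.75 * mismatch
  if (e_score >= 0) {
    stop("expected pair score is non-negative (", signif(e_score, 3),
         "); no positive lambda exists for this scheme")
  }
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-9, 10), tol = 1e-14)$root
  H <- lambda * (0.25 * exp(lambda * match) * match +
                 0.75 * exp(lambda * mismatch) * mismatch)
  delta <- .gcd(abs(match), abs(mismatch))
  # distribution of the walk S_k by convolution on an integer lattice
  lo <- -200L; hi <- 200L
  supp <- lo:hi
  step <- rep(0, length(supp))
  step[match(c(mismatch, match), supp)] <- c(0.75, 0.25)
  dist <- step
  sigma <- 0
  for (k in 1:400) {
    if (k > 1L) {
      nd <- rep(0, length(supp))
      for (s in c(mismatch, match)) {
        p <- step[match(s, supp)]
        src <- supp - s
        keep <- src >= lo & src <= hi
        nd[keep] <- nd[keep] + dist[match(src[keep], supp)] * p
      }
      dist <- nd
    }
    neg <- supp < 0
    term <- sum(dist[neg] * exp(lambda * supp[neg])) + sum(dist[!neg])
    sigma <- sigma + term / k
    if (term / k < 1e-12) break
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

.gcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Local-alignment search of a query against the reference library
#'
#' Smith-Waterman local alignment of the query against every reference
#' sequence, on both strands, keeping the best-scoring alignment per
#' reference. Identity is matches over alignment columns; coverage is the
#' fraction of query bases inside the local alignment (subject coverage is
#' also reported for audit). The e-value is `K * m * n * exp(-lambda *
#' score)` with `m` the query length and `n` the summed reference length.
#'
#' @param query A nucleotide string (the OTU representative).
#' @param library A [ReferenceLibrary-class].
#' @param config A [RunConfig-class] (not used by the search itself; kept for
#'   interface symmetry).
#' @param scoring Alignment scoring scheme.
#' @param params Optional precomputed [calibrateEvalueParams()] result.
#' @return A data frame of hits sorted by score descending then `seq_id`:
#'   `seq_id`, `score`, `identity`, `coverage`, `subject_coverage`,
#'   `evalue`, `strand`.
#' @export
searchLibrary <- function(query, library, config = runConfig(),
                          scoring = default_scoring(), params = NULL) {
  refs <- refSequences(library)
  if (!length(refs)) stop("reference library is empty")
  query <- normalize_seq(as.character(query))
  if (is.null(params)) {
    params <- calibrateEvalueParams(scoring$match, scoring$mismatch)
  }
  m <- nchar(query)
  n_total <- sum(Biostrings::width(refs))
  submat <- .substitution_matrix(scoring)
  one_strand <- function(q) {
    aln <- Biostrings::pairwiseAlignment(
      refs, Biostrings::DNAString(q), type = "local",
      substitutionMatrix = submat,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension
    )
    # 'subject' is the query here; coverage is over query bases
    qaln <- Biostrings::subject(aln)
    paln <- Biostrings::pattern(aln)
    qspan <- Biostrings::end(qaln) - Biostrings::start(qaln) + 1L
    sspan <- Biostrings::end(paln) - Biostrings::start(paln) + 1L
    data.frame(
      seq_id = names(refs),
      score = Biostrings::score(aln),
      identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
      coverage = qspan / m,
      subject_coverage = sspan / Biostrings::width(refs),
      stringsAsFactors = FALSE
    )
  }
  fw <- one_strand(query)
  rv <- one_strand(revcomp_chr(query))
  take_fw <- fw$score >= rv$score
  hits <- fw
  hits[!take_fw, ] <- rv[!take_fw, ]
  hits$strand <- ifelse(take_fw, "+", "-")
  hits$evalue <- params$K * m * n_total * exp(-params$lambda * hits$score)
  hits <- hits[order(-hits$score, hits$seq_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Assign a taxon to an OTU from its hit list
#'
#' Hits are filtered with strict thresholds (`coverage > minAssignCoverage`,
#' `identity > minAssignIdentity`, `evalue < maxEvalue`). If none pass, the
#' OTU is unassigned. Otherwise all filtered hits tied at the maximum score
#' are mapped to taxa, and the assignment is the lowest rank whose single
#' taxon contains all of them: species when the tie-set holds one species;
#' else genus, then family; when even the family is not unique the OTU is
#' unassigned with an `above_family` flag.
#'
#' @param hits Hit data frame from [searchLibrary()].
#' @param library A [ReferenceLibrary-class] (source of the taxonomy).
#' @param config A [RunConfig-class].
#' @return A list with `rank` (`"species"`, `"genus"`, `"family"` or
#'   `"unassigned"`), `taxon` (`NA` when unassigned), `n_tied_species`,
#'   `above_family` (logical flag), and `supporting_hits`.
#' @export
assignTaxon <- function(hits, library, config = runConfig()) {
  tax <- refTaxonomy(library)
  unknown <- setdiff(hits$seq_id, tax$seq_id)
  if (length(unknown)) {
    stop("hit(s) reference seq_id(s) absent from taxonomy: ",
         paste(unknown, collapse = ", "))
  }
  pass <- hits[hits$coverage > config@minAssignCoverage &
               hits$identity > config@minAssignIdentity &
               hits$evalue < config@maxEvalue, , drop = FALSE]
  if (!nrow(pass)) {
    return(list(rank = "unassigned", taxon = NA_character_,
                n_tied_species = 0L, above_family = FALSE,
                supporting_hits = pass))
  }
  top <- pass[pass$score == max(pass$score), , drop = FALSE]
  rows <- tax[match(top$seq_id, tax$seq_id), , drop = FALSE]
  spp <- unique(rows$species[nzchar(rows$species)])
  gen <- unique(rows$genus[nzchar(rows$genus)])
  fam <- unique(rows$family[nzchar(rows$family)])
  n_sp <- length(spp)
  if (n_sp == 1L && all(nzchar(rows$species))) {
    res <- list(rank = "species", taxon = spp)
  } else if (length(gen) == 1L && all(nzchar(rows$genus))) {
    res <- list(rank = "genus", taxon = gen)
  } else if (length(fam) == 1L) {
    res <- list(rank = "family", taxon = fam)
  } else {
    return(list(rank = "unassigned", taxon = NA_character_,
                n_tied_species = n_sp, above_family = TRUE,
                supporting_hits = top))
  }
  c(res, list(n_tied_species = n_sp, above_family = FALSE,
              supporting_hits = top))
}

#' Assign every OTU representative against the reference library
#'
#' @param otus An [OtuTable-class].
#' @param library A [ReferenceLibrary-class].
#' @param config A [RunConfig-class].
#' @param scoring Alignment scoring scheme.
#' @return A data frame with one row per OTU: `otu_id`, `rank`, `taxon`,
#'   `n_tied_species`, `best_identity`, `best_coverage`, `best_evalue`,
#'   `strand`.
#' @export
assignOtus <- function(otus, library, config = runConfig(),
                       scoring = default_scoring()) {
  params <- calibrateEvalueParams(scoring$match, scoring$mismatch)
  reps <- as.character(otuRepresentatives(otus))
  rows <- lapply(names(reps), function(oid) {
    hits <- searchLibrary(reps[[oid]], library, config, scoring, params)
    a <- assignTaxon(hits, library, config)
    best <- if (nrow(a$supporting_hits)) a$supporting_hits[1, ] else
      data.frame(identity = NA_real_, coverage = NA_real_,
                 evalue = NA_real_, strand = NA_character_)
    data.frame(
      otu_id = oid, rank = a$rank, taxon = a$taxon,
      n_tied_species = a$n_tied_species,
      best_identity = best$identity, best_coverage = best$coverage,
      best_evalue = best$evalue, strand = best$strand,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
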