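#' Merge paired-end reads by ungapped overlap
#'
#' The reverse read is reverse-complemented and the best ungapped overlap
#' with the forward read is sought (the overlap maximizing matches minus
#' mismatches). A pair is merged when that overlap spans at least
#' `mergeMinOverlap` bases with a mismatch fraction of at most
#' `mergeMaxMismatchFrac`; otherwise it is rejected. In the overlap, each
#' position takes the higher-quality base call; the posterior quality is the
#' maximum of the two scores when the calls agree and their difference when
#' they conflict, capped at 41.
#'
#' @param fwd,rev Read tables from [readFastq()] (positionally paired).
#' @param config A [RunConfig-class].
#' @return A list with `merged` (read table; ids from the forward reads) and
#'   `rejects` (data frame `id`, `reason`).
#' @export
mergePairs <- function(fwd, rev, config = runConfig()) {
  if (nrow(fwd) != nrow(rev)) {
    stop("forward and reverse files hold different read counts (",
         nrow(fwd), " vs ", nrow(rev), ")")
  }
  min_ov <- config@mergeMinOverlap
  max_mm <- config@mergeMaxMismatchFrac
  rc_seq <- revcomp_chr(rev$sequence)
  rc_qual <- rev_chr(rev$quality)
  n <- nrow(fwd)
  merged_seq <- character(n); merged_qual <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    f <- charToRaw(fwd$sequence[i]); r <- charToRaw(rc_seq[i])
    qf <- utf8ToInt(fwd$quality[i]) - 33L
    qr <- utf8ToInt(rc_qual[i]) - 33L
    nf <- length(f); nr <- length(r)
    best_l <- 0L; best_score <- -Inf; best_mm <- 0L
    max_ov <- min(nf, nr)
    if (max_ov >= min_ov) for (l in seq.int(min_ov, max_ov)) {
      mm <- sum(f[(nf - l + 1L):nf] != r[seq_len(l)])
      sc <- l - 2L * mm
      if (mm / l <= max_mm && sc > best_score) {
        best_score <- sc; best_l <- l; best_mm <- mm
      }
    }
    if (best_l == 0L) next
    l <- best_l
    fo <- (nf - l + 1L):nf; ro <- seq_len(l)
    agree <- f[fo] == r[ro]
    take_f <- qf[fo] >= qr[ro]
    ov_base <- ifelse(take_f, as.integer(f[fo]), as.integer(r[ro]))
    ov_q <- ifelse(agree, pmax(qf[fo], qr[ro]), abs(qf[fo] - qr[ro]))
    ov_q <- pmin(ov_q, 41L)
    merged_seq[i] <- paste0(
      substr(fwd$sequence[i], 1L, nf - l),
      rawToChar(as.raw(ov_base)),
      substr(rc_seq[i], l + 1L, nr)
    )
    merged_qual[i] <- paste0(
      substr(fwd$quality[i], 1L, nf - l),
      phred_string(ov_q),
      substr(rc_qual[i], l + 1L, nr)
    )
    ok[i] <- TRUE
  }
  list(
    merged = data.frame(id = fwd$id[ok], sequence = merged_seq[ok],
                        quality = merged_qual[ok], stringsAsFactors = FALSE),
    rejects = data.frame(id = fwd$id[!ok],
                         reason = rep("no_overlap", sum(!ok)),
                         stringsAsFactors = FALSE)
  )
}

#' Demultiplex merged reads by 8-nt tags and primers
#'
#' A read is assigned to a sample if and only if it begins with that sample's
#' `fwd_tag + fwd_primer` and ends with `revcomp(rev_primer) +
#' revcomp(rev_tag)`, matched exactly (IUPAC ambiguity codes in primers match
#' their degeneracy sets; tags match literally). Reads containing `N`
#' anywhere are discarded before matching. Reads matching no sample, or more
#' than one sample (possible only with a malformed sheet), are discarded and
#' counted. Tags and primers are trimmed from assigned reads.
#'
#' @param reads Merged read table (`id`, `sequence`, `quality`).
#' @param sheet Sample sheet ([readSampleSheet()]).
#' @return A list with `assigned` (read table plus `sample` and `group`
#'   columns, trimmed to the insert) and `discards` (named counts:
#'   `contains_n`, `tag_primer_mismatch`, `ambiguous`).
#' @export
demultiplexReads <- function(reads, sheet) {
  sheet <- validateSampleSheet(sheet)
  n <- nrow(reads)
  has_n <- grepl("N", reads$sequence, fixed = TRUE)
  pool <- reads[!has_n, , drop = FALSE]
  patterns <- vapply(seq_len(nrow(sheet)), function(i) {
    paste0("^", sheet$fwd_tag[i], iupac_regex(sheet$fwd_primer[i]),
           "(.*)",
           iupac_regex(revcomp_chr(sheet$rev_primer[i])),
           revcomp_chr(sheet$rev_tag[i]), "$")
  }, character(1))
  match_mat <- vapply(patterns, function(p) grepl(p, pool$sequence),
                      logical(nrow(pool)))
  if (nrow(pool) == 1L) match_mat <- matrix(match_mat, nrow = 1L)
  hits <- rowSums(match_mat)
  assigned_idx <- which(hits == 1L)
  sample_of <- apply(match_mat[assigned_idx, , drop = FALSE], 1L, which)
  lead <- nchar(sheet$fwd_tag) + nchar(sheet$fwd_primer)
  trail <- nchar(sheet$rev_primer) + nchar(sheet$rev_tag)
  out <- pool[assigned_idx, , drop = FALSE]
  if (nrow(out)) {
    s <- sample_of
    len <- nchar(out$sequence)
    out$sequence <- substr(out$sequence, lead[s] + 1L, len - trail[s])
    out$quality <- substr(out$quality, lead[s] + 1L, len - trail[s])
    out$sample <- sheet$sample_id[s]
    out$group <- sheet$group[s]
  } else {
    out$sample <- character(0)
    out$group <- character(0)
  }
  rownames(out) <- NULL
  list(
    assigned = out,
    discards = c(
      contains_n = sum(has_n),
      tag_primer_mismatch = sum(hits == 0L),
      ambiguous = sum(hits > 1L)
    )
  )
}

#' Quality and length filtering
#'
#' Keeps a read when its length is at least `minLen` (a read of exactly
#' `minLen` is kept) *and* it passes the quality rule selected by
#' `qualMode`: mean Phred score at least `minQual` (default), per-base
#' minimum at least `minQual`, or expected errors at most
#' `maxExpectedErrors`.
#'
#' @param reads Read table with quality strings (an error otherwise).
#' @param config A [RunConfig-class].
#' @return A list with `kept` (read table) and `discards` (named counts
#'   `too_short`, `low_quality`).
#' @export
qualityFilter <- function(reads, config = runConfig()) {
  if (nrow(reads) && (is.null(reads$quality) || anyNA(reads$quality) ||
                      any(!nzchar(reads$quality)))) {
    stop("reads without quality scores; the pipeline requires FASTQ input")
  }
  len <- nchar(reads$sequence)
  short <- len < config@minLen
  scores <- phred_scores(reads$quality)
  qual_ok <- switch(config@qualMode,
    mean = vapply(scores, mean, numeric(1)) >= config@minQual,
    min = vapply(scores, min, numeric(1)) >= config@minQual,
    ee = vapply(scores, function(q) sum(10^(-q / 10)), numeric(1)) <=
      config@maxExpectedErrors
  )
  keep <- !short & qual_ok
  list(
    kept = reads[keep, , drop = FALSE],
    discards = c(too_short = sum(short),
                 low_quality = sum(!short & !qual_ok))
  )
}

#' Dereplicate reads into unique sequences
#'
#' Exact-sequence grouping with per-sample read counts, sorted by total
#' abundance descending, ties broken lexicographically by sequence.
#'
#' @param reads Read table with a `sample` column.
#' @return A list of class `unique_seqs` with `sequence` (character),
#'   `abundance` (integer, `sum(counts)` per row) and `counts` (matrix
#'   uniques x samples).
#' @export
dereplicate <- function(reads) {
  samples <- sort(unique(reads$sample))
  if (!nrow(reads)) {
    return(structure(list(sequence = character(), abundance = integer(),
                          counts = matrix(0L, 0, 0)), class = "unique_seqs"))
  }
  tab <- table(factor(reads$sequence), factor(reads$sample, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  ab <- rowSums(counts)
  ord <- order(-ab, rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  structure(list(sequence = rownames(counts),
                 abundance = as.integer(rowSums(counts)),
                 counts = counts),
            class = "unique_seqs")
}

#' @title OTU table with representative sequences
#'
#' @description
#' The result of greedy centroid clustering: representative sequences (the
#' highest-abundance member of each cluster), a per-sample read count
#' matrix, and the member unique sequences of each cluster with their
#' identity to the representative.
#'
#' @slot representatives [Biostrings::DNAStringSet] named by OTU id.
#' @slot counts Integer matrix, OTUs x samples.
#' @slot members List (per OTU) of data frames with `sequence`, `abundance`,
#'   `identity`.
#'
#' @aliases OtuTable-class
#' @exportClass OtuTable
setClass("OtuTable", slots = c(
  representatives = "DNAStringSet",
  counts = "matrix",
  members = "list"
))

setValidity("OtuTable", function(object) {
  errs <- character()
  if (length(object@representatives) != nrow(object@counts)) {
    errs <- c(errs, "one count row per representative required")
  }
  if (length(object@members) != length(object@representatives)) {
    errs <- c(errs, "one member table per representative required")
  }
  if (length(errs)) errs else TRUE
})

#' @describeIn OtuTable-class OTU x sample count matrix.
#' @param x An `OtuTable`.
#' @export
otuCounts <- function(x) x@counts

#' @describeIn OtuTable-class Representative sequences.
#' @export
otuRepresentatives <- function(x) x@representatives

#' @describeIn OtuTable-class Member unique sequences per OTU.
#' @export
otuMembers <- function(x) x@members

#' @describeIn OtuTable-class Display a summary.
#' @param object An `OtuTable`.
#' @export
setMethod("show", "OtuTable", function(object) {
  cat("OtuTable with", length(object@representatives), "OTUs x",
      ncol(object@counts), "samples;", sum(object@counts), "reads\n")
  invisible(NULL)
})

#' Greedy centroid clustering of unique sequences into OTUs
#'
#' Unique sequences are scanned in dereplication order (abundance
#' descending). Each sequence joins the first existing centroid to which its
#' identity is at least `otuIdentity`, where identity is matches divided by
#' alignment columns (end gaps included); otherwise it founds a new
#' centroid. For equal-length pairs the ungapped substitution identity is
#' used (merged substitution-error amplicons have equal lengths); unequal
#' lengths are resolved by global alignment with end gaps penalized.
#' Centroids are the most abundant variants. Per-sample abundances are
#' summed over members.
#'
#' @param uniques A `unique_seqs` object from [dereplicate()].
#' @param config A [RunConfig-class].
#' @return An [OtuTable-class]; OTU ids are `OTU_1`, `OTU_2`, ... in founding
#'   order.
#' @export
clusterOtus <- function(uniques, config = runConfig()) {
  t_id <- config@otuIdentity
  n <- length(uniques$sequence)
  if (n == 0L) {
    return(new("OtuTable",
               representatives = Biostrings::DNAStringSet(character()),
               counts = matrix(0L, 0, 0), members = list()))
  }
  centroids <- character()
  membership <- integer(n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    s <- uniques$sequence[i]
    placed <- FALSE
    if (length(centroids)) {
      for (ci in seq_along(centroids)) {
        cs <- centroids[ci]
        # identity is at most min(lengths)/max(lengths): matches cannot
        # exceed the shorter sequence and columns cover the longer one
        ls <- nchar(s); lc <- nchar(cs)
        if (min(ls, lc) / max(ls, lc) < t_id) next
        # equal lengths: ungapped substitution identity (merged amplicons
        # differ by substitutions); unequal lengths: gapped alignment
        idty <- if (ls == lc) {
          1 - hamming_chr(s, cs) / ls
        } else {
          global_identity(s, cs)
        }
        if (idty >= t_id) {
          membership[i] <- ci
          identity[i] <- idty
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      centroids <- c(centroids, s)
      membership[i] <- length(centroids)
      identity[i] <- 1
    }
  }
  k <- length(centroids)
  otu_ids <- paste0("OTU_", seq_len(k))
  counts <- matrix(0L, nrow = k, ncol = ncol(uniques$counts),
                   dimnames = list(otu_ids, colnames(uniques$counts)))
  members <- vector("list", k)
  for (ci in seq_len(k)) {
    idx <- which(membership == ci)
    counts[ci, ] <- as.integer(colSums(uniques$counts[idx, , drop = FALSE]))
    members[[ci]] <- data.frame(
      sequence = uniques$sequence[idx],
      abundance = uniques$abundance[idx],
      identity = identity[idx],
      stringsAsFactors = FALSE
    )
  }
  reps <- Biostrings::DNAStringSet(centroids)
  names(reps) <- otu_ids
  new("OtuTable", representatives = reps, counts = counts, members = members)
}

#' Audit OTU membership identities
#'
#' Recomputes the identity of every member to its representative and checks
#' the clustering invariant `identity >= otuIdentity`.
#'
#' @param otus An [OtuTable-class].
#' @param config A [RunConfig-class].
#' @return Number of violating members (0 when the invariant holds).
#' @export
otuAudit <- function(otus, config = runConfig()) {
  reps <- as.character(otus@representatives)
  bad <- 0L
  for (ci in seq_along(reps)) {
    m <- otus@members[[ci]]
    if (!nrow(m)) next
    idty <- global_identity(m$sequence, reps[ci])
    # equal-length members may sit above the gapped optimum via the
    # substitution-only path; take the better of the two
    same_len <- nchar(m$sequence) == nchar(reps[ci])
    if (any(same_len)) {
      ham <- vapply(m$sequence[same_len], function(s) {
        1 - hamming_chr(s, reps[ci]) / nchar(s)
      }, numeric(1))
      idty[same_len] <- pmax(idty[same_len], ham)
    }
    bad <- bad + sum(idty < config@otuIdentity)
  }
  bad
}

#' Run the full amplicon pipeline
#'
#' Merges read pairs, demultiplexes by tags and primers, quality- and
#' length-filters, dereplicates, and clusters into OTUs, asserting read
#' conservation at every stage (`reads_in == reads_out + sum(discards)`).
#' No chimera removal is performed.
#'
#' @param fwd,rev Paths to paired FASTQ files, or read tables.
#' @param sheet Sample sheet (path or data frame).
#' @param config A [RunConfig-class].
#' @return A list with `otus` ([OtuTable-class]), `sample_groups` (named
#'   character: sample -> group), `accounting` (per-sample stage counts:
#'   `sample`, `pair_end`, `retained`, `uniques`, `otus`), and `stages`
#'   (global stage totals and discard categories).
#' @export
runPipeline <- function(fwd, rev, sheet, config = runConfig()) {
  if (is.character(fwd)) fwd <- readFastq(fwd)
  if (is.character(rev)) rev <- readFastq(rev)
  if (is.character(sheet)) sheet <- readSampleSheet(sheet)
  n_pairs <- nrow(fwd)

  mg <- mergePairs(fwd, rev, config)
  stopifnot(n_pairs == nrow(mg$merged) + nrow(mg$rejects))

  dm <- demultiplexReads(mg$merged, sheet)
  stopifnot(nrow(mg$merged) == nrow(dm$assigned) + sum(dm$discards))

  qf <- qualityFilter(dm$assigned, config)
  stopifnot(nrow(dm$assigned) == nrow(qf$kept) + sum(qf$discards))

  uq <- dereplicate(qf$kept)
  stopifnot(nrow(qf$kept) == sum(uq$abundance))

  otus <- clusterOtus(uq, config)
  stopifnot(sum(uq$abundance) == sum(otus@counts))

  samples <- sheet$sample_id
  per_sample <- data.frame(
    sample = samples,
    pair_end = vapply(samples, function(s) sum(dm$assigned$sample == s),
                      integer(1)),
    retained = vapply(samples, function(s) sum(qf$kept$sample == s),
                      integer(1)),
    uniques = vapply(samples, function(s) {
      if (!ncol(uq$counts) || !s %in% colnames(uq$counts)) return(0L)
      sum(uq$counts[, s] > 0L)
    }, integer(1)),
    otus = vapply(samples, function(s) {
      if (!ncol(otus@counts) || !s %in% colnames(otus@counts)) return(0L)
      sum(otus@counts[, s] > 0L)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(per_sample) <- NULL
  list(
    otus = otus,
    sample_groups = setNames(sheet$group, sheet$sample_id),
    accounting = per_sample,
    stages = list(
      pairs_in = n_pairs,
      merged = nrow(mg$merged),
      merge_rejected = nrow(mg$rejects),
      demultiplexed = nrow(dm$assigned),
      demux_discards = dm$discards,
      retained = nrow(qf$kept),
      filter_discards = qf$discards,
      uniques = length(uq$sequence),
      otus = length(otus@representatives)
    )
  )
}
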