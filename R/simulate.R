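# Synthetic reference libraries with controlled divergence structure and
# tagged, error-bearing paired reads drawn from known diet proportions.

# Apply `n` random substitutions to a sequence with a 2:1
# transition:transversion ratio (K2P-like).
mutate_seq <- function(seq, n) {
  if (n == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  if (n > length(chars)) {
    stop("substitution budget (", n, ") exceeds sequence length")
  }
  pos <- sample.int(length(chars), n)
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  transversions <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  for (p in pos) {
    b <- chars[p]
    chars[p] <- if (runif(1) < 2 / 3) {
      transitions[[b]]
    } else {
      sample(transversions[[b]], 1L)
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a reference library with a balanced taxonomy
#'
#' A root barcode sequence is drawn uniformly over `{A,C,G,T}` and evolved
#' down a balanced family/genus/species tree, applying a fixed number of
#' random substitutions (transition:transversion 2:1) on each branch.
#' Optionally plants identical-sequence groups to exercise genus- and
#' family-level assignment: `sharedGenusGroup` makes all species of the
#' first genus share one sequence, `sharedFamilyGroup` makes the first
#' species of every genus in the last family share one sequence.
#'
#' @param n_families,genera_per_family,species_per_genus Tree shape.
#' @param seq_len Barcode length in bases (>= 150).
#' @param species_subs Substitutions on each terminal (species) branch.
#' @param genus_subs Substitutions on each genus branch.
#' @param family_subs Substitutions on each family branch (default
#'   `2 * genus_subs`).
#' @param shared_genus_group,shared_family_group Plant identical-sequence
#'   groups (see above).
#' @param seed Integer seed; the same seed reproduces the library exactly.
#' @return A [ReferenceLibrary-class]. Species are named `"Gff.g spN"`, so
#'   the genus is the first word of the binomial.
#' @export
simulateReference <- function(n_families = 2, genera_per_family = 2,
                              species_per_genus = 2, seq_len = 200,
                              species_subs = 4, genus_subs = 8,
                              family_subs = 2 * genus_subs,
                              shared_genus_group = FALSE,
                              shared_family_group = FALSE, seed = 1L) {
  if (seq_len < 150) stop("seq_len must be >= 150")
  stopifnot(species_subs >= 0, genus_subs >= 0, family_subs >= 0)
  set.seed(seed)
  root <- paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE),
                collapse = "")
  seqs <- character(); tax <- list()
  for (f in seq_len(n_families)) {
    fam_name <- sprintf("Familia%02d", f)
    fam_seq <- mutate_seq(root, family_subs)
    for (g in seq_len(genera_per_family)) {
      gen_name <- sprintf("G%02d.%d", f, g)
      gen_seq <- mutate_seq(fam_seq, genus_subs)
      for (s in seq_len(species_per_genus)) {
        sp_name <- sprintf("%s sp%d", gen_name, s)
        sp_seq <- mutate_seq(gen_seq, species_subs)
        id <- sprintf("%s_1", gsub(" ", "_", sp_name))
        seqs[[id]] <- sp_seq
        tax[[id]] <- data.frame(seq_id = id, family = fam_name,
                                genus = gen_name, species = sp_name,
                                stringsAsFactors = FALSE)
      }
    }
  }
  taxonomy <- do.call(rbind, tax)
  rownames(taxonomy) <- NULL
  if (shared_genus_group) {
    first_genus <- taxonomy$genus[1]
    ids <- taxonomy$seq_id[taxonomy$genus == first_genus]
    seqs[ids] <- seqs[[ids[1]]]
  }
  if (shared_family_group) {
    last_family <- taxonomy$family[nrow(taxonomy)]
    sel <- taxonomy[taxonomy$family == last_family, , drop = FALSE]
    ids <- vapply(split(sel$seq_id, sel$genus), `[[`, character(1), 1L)
    seqs[ids] <- seqs[[ids[1]]]
  }
  buildLibrary(setNames(as.character(seqs), names(seqs)), taxonomy)
}

#' Simulate a demultiplexing sample sheet
#'
#' Generates 8-nt tags with pairwise Hamming distance at least 3 (so a
#' single sequencing error cannot move a read between samples under the
#' perfect-match rule) and uses the trnL c/h primer pair by default.
#'
#' @param n_samples Number of samples.
#' @param groups Group label per sample (recycled).
#' @param fwd_primer,rev_primer Primer sequences.
#' @param seed Integer seed.
#' @return A sample sheet data frame.
#' @export
simulateSampleSheet <- function(n_samples, groups = "G1",
                                fwd_primer = "CGAAATCGGTAGACGCTACG",
                                rev_primer = "CCATTGAGTCTCTGCACCTATC",
                                seed = 1L) {
  set.seed(seed)
  tags <- character()
  while (length(tags) < 2L * n_samples) {
    cand <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                  collapse = "")
    if (all(vapply(tags, function(t) hamming_chr(t, cand) >= 3L, logical(1)))) {
      tags <- c(tags, cand)
    }
  }
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    group = rep_len(groups, n_samples),
    fwd_tag = tags[seq_len(n_samples)],
    rev_tag = tags[n_samples + seq_len(n_samples)],
    fwd_primer = fwd_primer,
    rev_primer = rev_primer,
    stringsAsFactors = FALSE
  )
}

#' Simulate tagged paired-end amplicon reads from known diet proportions
#'
#' Per sample, source taxa are drawn multinomially from the given
#' proportions; each read's template is the barcode of a reference sequence
#' of that taxon, flanked by the sample's tag+primer on the forward side
#' and reverse-complemented primer+tag on the reverse side. Overlapping
#' read pairs are emitted with i.i.d. substitution errors at `error_rate`
#' (no indels) and Phred qualities from the quality model (`"constant"`:
#' Q35; `"degraded"`: mean Q25, two-state).
#'
#' @param library A [ReferenceLibrary-class].
#' @param sheet Sample sheet.
#' @param proportions Named numeric vector of per-taxon (species)
#'   proportions summing to 1, or a list with one such vector per sample.
#' @param n_reads Reads per sample.
#' @param read_len Read length (both mates).
#' @param error_rate Per-base substitution error probability.
#' @param quality_model `"constant"` or `"degraded"`.
#' @param n_ambiguous Number of reads per sample that receive a single `N`
#'   (to exercise the demultiplexing discard rule); default 0.
#' @param seed Integer seed.
#' @return A list with `fwd`, `rev` (read tables), and `truth` (a list with
#'   `proportions` per sample, `provenance` data frame mapping read id to
#'   sample and source `seq_id`, and the generator `params`).
#' @export
simulateReads <- function(library, sheet, proportions, n_reads = 2000,
                          read_len = 150, error_rate = 0,
                          quality_model = c("constant", "degraded"),
                          n_ambiguous = 0, seed = 1L) {
  quality_model <- match.arg(quality_model)
  set.seed(seed)
  tax <- refTaxonomy(library)
  seqs <- as.character(refSequences(library))
  if (!is.list(proportions)) {
    proportions <- setNames(rep(list(proportions), nrow(sheet)),
                            sheet$sample_id)
  }
  fwd <- list(); rev <- list(); prov <- list()
  bases <- c("A", "C", "G", "T")
  # vectorized i.i.d. substitution errors over a character vector of reads
  add_errors <- function(reads) {
    if (error_rate == 0 || !length(reads)) return(reads)
    n_err <- rbinom(length(reads), nchar(reads), error_rate)
    for (i in which(n_err > 0L)) {
      pos <- sample.int(nchar(reads[i]), n_err[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
      }
    }
    reads
  }
  qual_string <- function(len) {
    if (quality_model == "constant") {
      strrep(rawToChar(as.raw(35L + 33L)), len)
    } else {
      # two-state: high (Q32) / low (Q11) at 2:1, mean = 25
      q <- sample(c(32L, 11L), len, replace = TRUE, prob = c(2, 1))
      phred_string(q)
    }
  }
  for (si in seq_len(nrow(sheet))) {
    smp <- sheet$sample_id[si]
    props <- proportions[[smp]]
    if (abs(sum(props) - 1) > 1e-8) {
      stop("proportions for sample ", smp, " do not sum to 1")
    }
    taxa <- names(props)
    missing <- taxa[!taxa %in% tax$species]
    if (length(missing)) {
      stop("taxon not in library: ", paste(missing, collapse = ", "))
    }
    draw <- as.integer(rmultinom(1, n_reads, props))
    sources <- rep(taxa, draw)
    sources <- sources[sample.int(length(sources))]
    # one reference per read for its taxon
    src <- vapply(sources, function(taxon) {
      cand <- tax$seq_id[tax$species == taxon]
      if (length(cand) == 1L) cand else sample(cand, 1L)
    }, character(1), USE.NAMES = FALSE)
    lead <- paste0(sheet$fwd_tag[si], toupper(sheet$fwd_primer[si]))
    trail <- paste0(revcomp_chr(toupper(sheet$rev_primer[si])),
                    revcomp_chr(sheet$rev_tag[si]))
    mol <- setNames(paste0(lead, seqs[unique(src)], trail), unique(src))
    too_long <- nchar(mol) > 2L * read_len - 1L
    if (any(too_long)) {
      stop("template too long for read length (molecule ",
           max(nchar(mol)), " nt, reads ", read_len, " nt)")
    }
    rc_mol <- setNames(revcomp_chr(mol), names(mol))
    f <- add_errors(substr(mol[src], 1L, read_len))
    r <- add_errors(substr(rc_mol[src], 1L, read_len))
    flag <- character(length(sources))
    if (n_ambiguous > 0 && length(sources)) {
      amb_idx <- sample.int(length(sources),
                            min(n_ambiguous, length(sources)))
      for (i in amb_idx) {
        p <- sample.int(read_len, 1L)
        substr(f[i], p, p) <- "N"
      }
      flag[amb_idx] <- "N"
    }
    ids <- sprintf("%s_r%06d", smp, seq_along(sources))
    fwd[[si]] <- data.frame(id = ids, sequence = unname(f),
                            stringsAsFactors = FALSE)
    rev[[si]] <- data.frame(id = ids, sequence = unname(r),
                            stringsAsFactors = FALSE)
    prov[[si]] <- data.frame(id = ids, sample = smp, seq_id = src,
                             taxon = sources, flag = flag,
                             stringsAsFactors = FALSE)
  }
  fwd_df <- do.call(rbind, fwd)
  rev_df <- do.call(rbind, rev)
  fwd_df$quality <- vapply(nchar(fwd_df$sequence), qual_string, character(1))
  rev_df$quality <- vapply(nchar(rev_df$sequence), qual_string, character(1))
  prov_df <- do.call(rbind, prov)
  rownames(fwd_df) <- rownames(rev_df) <- rownames(prov_df) <- NULL
  list(
    fwd = fwd_df, rev = rev_df,
    truth = list(
      proportions = proportions,
      provenance = prov_df,
      params = list(n_reads = n_reads, read_len = read_len,
                    error_rate = error_rate, quality_model = quality_model,
                    seed = seed)
    )
  )
}

#' Compare recovered diet proportions with the simulation truth
#'
#' Computes the absolute error `|fs/100 - true proportion|` per taxon per
#' group (true group proportions are the mean of the member samples'
#' proportions; samples carry equal read counts). `fs` is renormalized over
#' assigned reads; when unassigned reads were present this is flagged.
#'
#' @param truth The `truth` element of [simulateReads()].
#' @param diet A diet table from [dietTable()].
#' @param sample_groups Named character vector mapping sample to group.
#' @return A list with `errors` (data frame `group`, `taxon`, `true`,
#'   `recovered`, `abs_error` in proportion units), `max_abs_error`,
#'   `mean_abs_error`, and `renormalized` (TRUE when unassigned reads were
#'   excluded from the Fs denominator).
#' @export
recoveryReport <- function(truth, diet, sample_groups) {
  groups <- unique(unname(sample_groups))
  un <- attr(diet, "unassigned_reads")
  rows <- list()
  for (g in groups) {
    smp <- names(sample_groups)[sample_groups == g]
    pr <- truth$proportions[names(truth$proportions) %in% smp]
    taxa <- unique(unlist(lapply(pr, names)))
    true_p <- vapply(taxa, function(tx) {
      mean(vapply(pr, function(p) if (tx %in% names(p)) p[[tx]] else 0,
                  numeric(1)))
    }, numeric(1))
    for (tx in union(taxa, diet$taxon[diet$group == g])) {
      rec <- diet$fs[diet$group == g & diet$taxon == tx]
      rec <- if (length(rec)) rec[1] / 100 else 0
      tr <- if (tx %in% names(true_p)) true_p[[tx]] else 0
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, taxon = tx, true = tr, recovered = rec,
        abs_error = abs(rec - tr), stringsAsFactors = FALSE
      )
    }
  }
  errors <- do.call(rbind, rows)
  list(
    errors = errors,
    max_abs_error = max(errors$abs_error),
    mean_abs_error = mean(errors$abs_error),
    renormalized = !is.null(un) && any(un > 0)
  )
}
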