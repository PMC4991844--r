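#' Inter- and intra-specific divergence summary for a taxon group
#'
#' Summarizes K2P distances within one genus or family: maximal, minimal and
#' mean (with population standard deviation) distance over inter-specific
#' pairs (pairs whose species labels differ, both members in the group), and
#' the maximal intra-specific distance (same-species pairs). Saturated pairs
#' are excluded from the statistics and counted separately.
#'
#' @param k2p A `k2p_matrix` from [pairwiseK2P()].
#' @param taxonomy Taxonomy data frame (`seq_id`, `family`, `genus`,
#'   `species`) covering the matrix labels.
#' @param group Genus or family name.
#' @param level `"genus"` or `"family"`.
#' @return A one-row data frame with columns `group`, `level`, `n_species`,
#'   `n_pairs`, `max`, `min`, `mean`, `sd`, `intra_max`, `n_intra_pairs`,
#'   `n_saturated`. When the group holds a single species the inter-specific
#'   columns are `NA` (with a warning) and only intra statistics are filled.
#' @export
divergenceSummary <- function(k2p, taxonomy, group, level = c("genus", "family")) {
  level <- match.arg(level)
  if (!group %in% taxonomy[[level]]) {
    stop("group '", group, "' absent from taxonomy at level ", level)
  }
  tax <- taxonomy[taxonomy[[level]] == group & taxonomy$seq_id %in% k2p$labels, ]
  if (any(!nzchar(tax$species))) {
    warning("dropping ", sum(!nzchar(tax$species)),
            " record(s) without species label in group ", group)
    tax <- tax[nzchar(tax$species), ]
  }
  ids <- tax$seq_id
  sp <- setNames(tax$species, tax$seq_id)
  n_species <- length(unique(sp))
  inter <- numeric(); intra <- numeric(); n_sat <- 0L
  if (length(ids) >= 2L) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in seq(i + 1L, length(ids))) {
        dij <- k2p$d[ids[i], ids[j]]
        if (k2p$saturated[ids[i], ids[j]]) {
          n_sat <- n_sat + 1L
          next
        }
        if (sp[[ids[i]]] == sp[[ids[j]]]) {
          intra <- c(intra, dij)
        } else {
          inter <- c(inter, dij)
        }
      }
    }
  }
  if (!length(inter)) {
    warning("no inter-specific pairs in group ", group,
            " (", n_species, " species); inter statistics undefined")
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  data.frame(
    group = group, level = level, n_species = n_species,
    n_pairs = length(inter),
    max = if (length(inter)) max(inter) else NA_real_,
    min = if (length(inter)) min(inter) else NA_real_,
    mean = if (length(inter)) mean(inter) else NA_real_,
    sd = if (length(inter)) pop_sd(inter) else NA_real_,
    intra_max = if (length(intra)) max(intra) else NA_real_,
    n_intra_pairs = length(intra),
    n_saturated = n_sat,
    stringsAsFactors = FALSE
  )
}

#' Barcoding-gap test
#'
#' A group shows a barcoding gap when its minimal inter-specific distance
#' strictly exceeds its maximal intra-specific distance.
#'
#' @param summary A one-row data frame from [divergenceSummary()], or the
#'   minimal inter-specific distance (with `intra_max` supplied).
#' @param intra_max Maximal intra-specific distance when `summary` is numeric.
#' @return `TRUE`, `FALSE`, or `NA` when the intra-specific side is
#'   undefined (no same-species pairs): indeterminate, not `FALSE`.
#' @examples
#' barcodingGap(0.02, 0.01)  # TRUE
#' barcodingGap(0.00, 0.00)  # FALSE (strict)
#' @export
barcodingGap <- function(summary, intra_max = NULL) {
  if (is.data.frame(summary)) {
    min_inter <- summary$min[1]
    intra_max <- summary$intra_max[1]
  } else {
    min_inter <- summary
  }
  if (is.null(intra_max) || is.na(intra_max) || is.na(min_inter)) {
    return(NA)
  }
  min_inter > intra_max
}

#' UPGMA tree from a distance matrix
#'
#' Agglomerative average-linkage clustering; each internal node sits at half
#' the distance between the merged clusters, so the tree is ultrametric.
#' Saturated or missing distances are refused rather than replaced by an
#' arbitrary large value.
#'
#' @param d A `k2p_matrix`, a symmetric numeric matrix, or a `dist`.
#' @return A rooted ultrametric [ape::phylo] tree (serializable with
#'   [ape::write.tree()]).
#' @examples
#' d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' upgmaTree(d)
#' @export
upgmaTree <- function(d) {
  if (inherits(d, "k2p_matrix")) {
    if (any(d$saturated)) {
      stop("distance matrix contains saturated pairs; cannot build UPGMA tree")
    }
    d <- d$d
  }
  dd <- as.dist(d)
  if (anyNA(dd)) stop("distance matrix contains undefined distances")
  if (attr(dd, "Size") < 2L) stop("need at least 2 leaves")
  ape::as.phylo(hclust(dd, method = "average"))
}

#' Species monophyly resolution rate (Rf)
#'
#' Percentage of species recovered as monophyletic on a tree. Only species
#' represented by at least two leaves enter the calculation; singletons are
#' excluded from numerator and denominator (counting them as trivially
#' monophyletic would inflate the rate).
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param species Named character vector mapping every tip label to a species
#'   name, or a taxonomy data frame with `seq_id` and `species` columns.
#' @return A list of class `rf` with `rf` (percent, `NA` when no species has
#'   two leaves), `n_evaluated`, and `monophyletic` (named logical).
#' @export
resolutionRate <- function(tree, species) {
  if (is.data.frame(species)) {
    species <- setNames(species$species, species$seq_id)
  }
  unmapped <- setdiff(tree$tip.label, names(species))
  if (length(unmapped)) {
    stop("tips without species mapping: ", paste(unmapped, collapse = ", "))
  }
  sp <- species[tree$tip.label]
  counts <- table(sp)
  eligible <- names(counts)[counts >= 2L]
  if (!length(eligible)) {
    warning("no species with >= 2 leaves; Rf undefined")
    return(structure(list(rf = NA_real_, n_evaluated = 0L,
                          monophyletic = logical()), class = "rf"))
  }
  mono <- vapply(eligible, function(s) {
    ape::is.monophyletic(tree, tips = tree$tip.label[sp == s])
  }, logical(1))
  structure(list(rf = 100 * mean(mono), n_evaluated = length(eligible),
                 monophyletic = mono), class = "rf")
}

#' @export
print.rf <- function(x, ...) {
  cat("Rf:", if (is.na(x$rf)) "undefined" else sprintf("%.1f%%", x$rf),
      "over", x$n_evaluated, "species with >= 2 sequences\n")
  invisible(x)
}

#' Assemble a marker evaluation report
#'
#' @param gene Marker gene name (e.g. `"trnL"`).
#' @param amplification_success Fraction of species with a recovered
#'   sequence, in `[0, 1]`.
#' @param rf Resolution rate percent (or `NA`), as from [resolutionRate()].
#' @param summaries Data frame of stacked [divergenceSummary()] rows.
#' @param gap_ok Named logical vector (per group) of [barcodingGap()] results.
#' @return A list of class `marker_report`.
#' @export
markerReport <- function(gene, amplification_success, rf = NA_real_,
                         summaries = NULL, gap_ok = logical()) {
  stopifnot(amplification_success >= 0, amplification_success <= 1)
  if (!is.na(rf)) stopifnot(rf >= 0, rf <= 100)
  structure(list(gene = gene, amplification_success = amplification_success,
                 rf = rf, summaries = summaries, gap_ok = gap_ok),
            class = "marker_report")
}

#' Rank candidate barcode markers
#'
#' Lexicographic ranking of marker reports: (1) amplification success,
#' descending; (2) number of taxon groups in which the marker attains the
#' largest mean inter-specific divergence among the compared markers
#' (ties share the credit); (3) number of groups with a barcoding gap;
#' remaining ties broken alphabetically by gene name. The ranking is a total
#' order and deterministic.
#'
#' @param reports List of [markerReport()] objects.
#' @return A data frame (one row per marker, best first) with the
#'   per-criterion audit columns `gene`, `rank`, `amplification_success`,
#'   `n_best_mean_groups`, `n_gap_groups`, `rf`.
#' @export
rankMarkers <- function(reports) {
  if (!length(reports)) stop("need at least one marker report")
  genes <- vapply(reports, `[[`, character(1), "gene")
  amp <- vapply(reports, `[[`, numeric(1), "amplification_success")
  rf <- vapply(reports, function(r) as.numeric(r$rf), numeric(1))
  # mean inter-specific divergence per (group, level) per marker
  group_means <- lapply(reports, function(r) {
    s <- r$summaries
    if (is.null(s) || !nrow(s)) return(setNames(numeric(), character()))
    setNames(s$mean, paste(s$level, s$group))
  })
  all_groups <- unique(unlist(lapply(group_means, names)))
  best_count <- integer(length(reports))
  for (g in all_groups) {
    means <- vapply(group_means, function(m) {
      if (g %in% names(m)) m[[g]] else NA_real_
    }, numeric(1))
    if (all(is.na(means))) next
    top <- which(!is.na(means) & means == max(means, na.rm = TRUE))
    best_count[top] <- best_count[top] + 1L
  }
  gap_count <- vapply(reports, function(r) sum(r$gap_ok %in% TRUE), integer(1))
  ord <- order(-amp, -best_count, -gap_count, genes)
  data.frame(
    gene = genes[ord], rank = seq_along(ord),
    amplification_success = amp[ord],
    n_best_mean_groups = best_count[ord],
    n_gap_groups = gap_count[ord],
    rf = rf[ord],
    stringsAsFactors = FALSE
  )
}
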