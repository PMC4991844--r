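# Diet composition tables (Fs), per-sample occurrence, and the rank-aware
# comparison between metabarcoding and microhistology.

# Parse a diet-table taxon label: strip a "(except ...)" residual clause and
# a trailing " spp."/" sp." marker. Returns the base name and residual flag.
parse_taxon_label <- function(label) {
  residual <- grepl("\\(except .*\\)", label)
  base <- trimws(sub("\\s*\\(except .*\\)", "", label))
  base <- sub("\\s+spp?\\.$", "", base)
  list(base = base, residual = residual)
}

# Resolve a taxon label to (family, genus, species) using its stated rank and
# the reference taxonomy. Unknown names resolve partially (string-only,
# flagged by NA lineage fields). Labels printed at genus rank that are
# actually family names (e.g. "Asteraceae sp.") are lifted to family.
taxon_lineage <- function(label, rank, taxonomy = NULL) {
  base <- parse_taxon_label(label)$base
  fam <- NA_character_; gen <- NA_character_; spe <- NA_character_
  lookup_family <- function(genus) {
    if (is.null(taxonomy)) return(NA_character_)
    hit <- taxonomy$family[taxonomy$genus == genus & nzchar(taxonomy$genus)]
    if (length(hit)) hit[1] else NA_character_
  }
  is_known_family <- !is.null(taxonomy) && base %in% taxonomy$family
  if (rank == "species") {
    spe <- base
    gen <- strsplit(base, " ")[[1]][1]
    fam <- lookup_family(gen)
  } else if (rank == "genus" && !is_known_family) {
    gen <- base
    fam <- lookup_family(gen)
  } else {
    fam <- base
  }
  list(base = base, rank = if (rank == "genus" && is_known_family) "family" else rank,
       family = fam, genus = gen, species = spe)
}

#' Aggregate OTU assignments into a per-group diet table
#'
#' Reads per taxon are summed over the OTUs assigned to that taxon across
#' the samples of each bird group; `fs` is the percentage of the group's
#' *assigned* reads (unassigned OTUs are excluded from the denominator and
#' reported separately in the attribute `unassigned_reads`). When a
#' genus-level assignment coexists with species-level assignments of the
#' same genus (or a family-level one with finer taxa of that family), the
#' coarser row is labelled `"X spp. (except Y, Z)"`, so coarse and fine rows
#' partition the reads. Microhistology percentages (`fm`) are merged by
#' exact label per group when supplied; microhistology-only taxa appear with
#' zero reads.
#'
#' @param assignments Assignment data frame from [assignOtus()].
#' @param otus An [OtuTable-class] (or an OTU x sample count matrix).
#' @param sample_groups Named character vector mapping sample to bird group.
#' @param taxonomy Optional taxonomy data frame for lineage-aware residual
#'   labelling of family-level rows.
#' @param microhistology Optional microhistology table ([readMicrohistology()]).
#' @return A data frame with columns `group`, `taxon`, `rank`, `n_reads`,
#'   `fs`, `fm`, `presence_fraction`, ordered by group then reads
#'   descending. Within each group `fs` sums to 100 (up to rounding).
#' @export
dietTable <- function(assignments, otus, sample_groups, taxonomy = NULL,
                      microhistology = NULL) {
  counts <- if (is(otus, "OtuTable")) otuCounts(otus) else otus
  unmapped <- setdiff(colnames(counts), names(sample_groups))
  if (length(unmapped)) {
    stop("sample(s) without group mapping: ", paste(unmapped, collapse = ", "))
  }
  assigned <- assignments[assignments$rank != "unassigned", , drop = FALSE]
  groups <- unique(unname(sample_groups[colnames(counts)]))
  # residual labelling over the union of assigned taxa
  key <- paste(assigned$rank, assigned$taxon)
  taxa <- assigned[!duplicated(key), c("rank", "taxon")]
  lineages <- lapply(seq_len(nrow(taxa)), function(i) {
    taxon_lineage(taxa$taxon[i], taxa$rank[i], taxonomy)
  })
  label_of <- setNames(taxa$taxon, paste(taxa$rank, taxa$taxon))
  for (i in seq_len(nrow(taxa))) {
    li <- lineages[[i]]
    if (li$rank == "genus") {
      finer <- vapply(lineages, function(lj) {
        lj$rank == "species" && !is.na(lj$genus) && lj$genus == li$base
      }, logical(1))
    } else if (li$rank == "family") {
      finer <- vapply(lineages, function(lj) {
        lj$rank %in% c("species", "genus") && !is.na(lj$family) &&
          lj$family == li$base
      }, logical(1))
    } else next
    if (any(finer)) {
      except <- sort(vapply(lineages[finer], `[[`, character(1), "base"))
      label_of[[paste(taxa$rank[i], taxa$taxon[i])]] <-
        paste0(li$base, " spp. (except ", paste(except, collapse = ", "), ")")
    }
  }
  unassigned_reads <- setNames(numeric(length(groups)), groups)
  rows <- list()
  for (g in groups) {
    smp <- colnames(counts)[sample_groups[colnames(counts)] == g]
    gc <- counts[, smp, drop = FALSE]
    zero_samples <- smp[colSums(gc[rownames(gc) %in% assigned$otu_id, ,
                                   drop = FALSE]) == 0]
    if (length(zero_samples)) {
      warning("sample(s) with zero assigned reads in group ", g, ": ",
              paste(zero_samples, collapse = ", "))
    }
    un_idx <- assignments$otu_id[assignments$rank == "unassigned"]
    unassigned_reads[g] <- sum(gc[rownames(gc) %in% un_idx, , drop = FALSE])
    total <- 0
    tx_reads <- list(); tx_pres <- list()
    for (i in seq_len(nrow(taxa))) {
      oids <- assigned$otu_id[assigned$rank == taxa$rank[i] &
                              assigned$taxon == taxa$taxon[i]]
      sub <- gc[rownames(gc) %in% oids, , drop = FALSE]
      nr <- sum(sub)
      tx_reads[[i]] <- nr
      tx_pres[[i]] <- mean(colSums(sub) > 0)
      total <- total + nr
    }
    for (i in seq_len(nrow(taxa))) {
      nr <- tx_reads[[i]]
      if (nr == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g,
        taxon = label_of[[paste(taxa$rank[i], taxa$taxon[i])]],
        rank = taxa$rank[i],
        n_reads = nr,
        fs = 100 * nr / total,
        fm = 0,
        presence_fraction = tx_pres[[i]],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), taxon = character(), rank = character(),
               n_reads = numeric(), fs = numeric(), fm = numeric(),
               presence_fraction = numeric(), stringsAsFactors = FALSE)
  if (!is.null(microhistology)) {
    for (i in seq_len(nrow(microhistology))) {
      g <- microhistology$group[i]; tx <- microhistology$taxon[i]
      sel <- out$group == g & out$taxon == tx
      if (any(sel)) {
        out$fm[sel] <- microhistology$fm_percent[i]
      } else if (g %in% groups) {
        out <- rbind(out, data.frame(
          group = g, taxon = tx, rank = microhistology$rank[i],
          n_reads = 0, fs = 0, fm = microhistology$fm_percent[i],
          presence_fraction = 0, stringsAsFactors = FALSE
        ))
      }
    }
  }
  out <- out[order(out$group, -out$n_reads, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned_reads") <- unassigned_reads
  out
}

#' Per-sample taxon incidence
#'
#' A taxon is present in a sample when at least one read of an OTU assigned
#' to it occurs there. Taxa with zero reads overall are absent.
#'
#' @param assignments Assignment data frame from [assignOtus()].
#' @param otus An [OtuTable-class] or count matrix.
#' @return A list with `incidence` (logical matrix, taxa x samples) and
#'   `fraction` (named numeric: fraction of samples containing each taxon).
#' @export
presenceTable <- function(assignments, otus) {
  counts <- if (is(otus, "OtuTable")) otuCounts(otus) else otus
  assigned <- assignments[assignments$rank != "unassigned", , drop = FALSE]
  taxa <- unique(assigned$taxon)
  inc <- matrix(FALSE, length(taxa), ncol(counts),
                dimnames = list(taxa, colnames(counts)))
  for (tx in taxa) {
    oids <- assigned$otu_id[assigned$taxon == tx]
    inc[tx, ] <- colSums(counts[rownames(counts) %in% oids, , drop = FALSE]) > 0
  }
  inc <- inc[rowSums(inc) > 0, , drop = FALSE]
  list(incidence = inc, fraction = rowMeans(inc))
}

#' Rank-aware comparison of metabarcoding and microhistology detections
#'
#' Taxa detected by the two methods are matched in two passes: exact label
#' match first, then a rank-aware pass in which a genus-level record in one
#' method matches a congeneric species-level record in the other, and a
#' family-level record matches any finer record of that family. Matching is
#' one-to-one; candidate pairs are considered in a label-sorted order that
#' makes the procedure symmetric under swapping the two methods. Records
#' whose names are absent from the reference taxonomy are matched by string
#' only and flagged.
#'
#' @param diet A diet table ([dietTable()]) or a data frame with `group`,
#'   `taxon`, `rank` and either `n_reads` or `fs` (> 0 means detected).
#' @param microhistology Microhistology table with `group`, `taxon`, `rank`,
#'   `fm_percent` (> 0 means detected).
#' @param taxonomy Optional taxonomy data frame for lineage resolution.
#' @return A list of class `method_comparison` with element `union` (matching
#'   over taxa pooled across groups) and `per_group` (one entry per group);
#'   each holds `shared` (data frame of matched pairs with the ranks each
#'   method achieved and which was finer), `metabarcoding_only`,
#'   `microhistology_only`, and `string_only_flagged`.
#' @export
compareMethods <- function(diet, microhistology, taxonomy = NULL) {
  det_meta <- diet[(if ("n_reads" %in% names(diet)) diet$n_reads else diet$fs) > 0,
                   c("group", "taxon", "rank"), drop = FALSE]
  det_micro <- microhistology[microhistology$fm_percent > 0,
                              c("group", "taxon", "rank"), drop = FALSE]
  groups <- union(unique(det_meta$group), unique(det_micro$group))
  per_group <- lapply(groups, function(g) {
    match_detections(det_meta[det_meta$group == g, , drop = FALSE],
                     det_micro[det_micro$group == g, , drop = FALSE],
                     taxonomy)
  })
  names(per_group) <- groups
  uni <- match_detections(det_meta[!duplicated(det_meta$taxon), , drop = FALSE],
                          det_micro[!duplicated(det_micro$taxon), , drop = FALSE],
                          taxonomy)
  structure(list(union = uni, per_group = per_group),
            class = "method_comparison")
}

# One-to-one matching of two detection tables (taxon, rank).
match_detections <- function(meta, micro, taxonomy = NULL) {
  rank_depth <- c(species = 3L, genus = 2L, family = 1L)
  la <- lapply(seq_len(nrow(meta)), function(i) {
    taxon_lineage(meta$taxon[i], meta$rank[i], taxonomy)
  })
  lb <- lapply(seq_len(nrow(micro)), function(i) {
    taxon_lineage(micro$taxon[i], micro$rank[i], taxonomy)
  })
  pair_matches <- function(x, y) {
    if (x$rank == y$rank) return(identical(x$base, y$base))
    fine <- if (rank_depth[[x$rank]] > rank_depth[[y$rank]]) x else y
    coarse <- if (rank_depth[[x$rank]] > rank_depth[[y$rank]]) y else x
    if (coarse$rank == "genus") {
      return(!is.na(fine$genus) && fine$genus == coarse$base)
    }
    if (coarse$rank == "family") {
      return(!is.na(fine$family) && fine$family == coarse$base)
    }
    FALSE
  }
  free_a <- rep(TRUE, nrow(meta)); free_b <- rep(TRUE, nrow(micro))
  pairs <- expand.grid(a = seq_len(nrow(meta)), b = seq_len(nrow(micro)))
  if (nrow(pairs)) {
    keys <- cbind(pmin(meta$taxon[pairs$a], micro$taxon[pairs$b]),
                  pmax(meta$taxon[pairs$a], micro$taxon[pairs$b]))
    pairs <- pairs[order(keys[, 1], keys[, 2]), , drop = FALSE]
  }
  shared <- list()
  for (phase in c("exact", "rank")) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$a[r]; j <- pairs$b[r]
      if (!free_a[i] || !free_b[j]) next
      hit <- if (phase == "exact") {
        meta$taxon[i] == micro$taxon[j]
      } else {
        pair_matches(la[[i]], lb[[j]])
      }
      if (hit) {
        free_a[i] <- FALSE; free_b[j] <- FALSE
        finer <- if (rank_depth[[la[[i]]$rank]] > rank_depth[[lb[[j]]$rank]]) {
          "metabarcoding"
        } else if (rank_depth[[la[[i]]$rank]] < rank_depth[[lb[[j]]$rank]]) {
          "microhistology"
        } else "equal"
        shared[[length(shared) + 1L]] <- data.frame(
          metabarcoding_taxon = meta$taxon[i],
          metabarcoding_rank = la[[i]]$rank,
          microhistology_taxon = micro$taxon[j],
          microhistology_rank = lb[[j]]$rank,
          finer_method = finer,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  flagged <- c(
    meta$taxon[vapply(la, function(l) is.na(l$family), logical(1))],
    micro$taxon[vapply(lb, function(l) is.na(l$family), logical(1))]
  )
  list(
    shared = if (length(shared)) do.call(rbind, shared) else
      data.frame(metabarcoding_taxon = character(),
                 metabarcoding_rank = character(),
                 microhistology_taxon = character(),
                 microhistology_rank = character(),
                 finer_method = character(), stringsAsFactors = FALSE),
    metabarcoding_only = sort(meta$taxon[free_a]),
    microhistology_only = sort(micro$taxon[free_b]),
    string_only_flagged = sort(unique(flagged))
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  u <- x$union
  cat("Method comparison (union over groups):\n")
  cat("  shared:              ", nrow(u$shared), "\n")
  cat("  metabarcoding only:  ", length(u$metabarcoding_only), "\n")
  cat("  microhistology only: ", length(u$microhistology_only), "\n")
  invisible(x)
}

#' Diet share of higher taxa
#'
#' Sums `fs` percentages over all diet-table rows whose lineage falls inside
#' each family (or genus) of interest, per group.
#'
#' @param diet A diet table ([dietTable()] output or compatible data frame
#'   with `group`, `taxon`, `rank`, `fs`).
#' @param taxonomy Taxonomy data frame used to resolve lineages.
#' @param level `"family"` or `"genus"`.
#' @return A data frame `group`, `taxon`, `fs_total`.
#' @export
taxonShares <- function(diet, taxonomy, level = c("family", "genus")) {
  level <- match.arg(level)
  lin <- lapply(seq_len(nrow(diet)), function(i) {
    taxon_lineage(diet$taxon[i], diet$rank[i], taxonomy)
  })
  higher <- vapply(lin, function(l) {
    v <- l[[level]]
    if (is.null(v) || is.na(v)) NA_character_ else v
  }, character(1))
  keep <- !is.na(higher)
  agg <- aggregate(list(fs_total = diet$fs[keep]),
                   by = list(group = diet$group[keep], taxon = higher[keep]),
                   FUN = sum)
  agg[order(agg$group, -agg$fs_total), , drop = FALSE]
}
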