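#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P substitutions-per-site estimate from an aligned pair,
#' with pairwise deletion: only columns where both characters are unambiguous
#' bases (`A`, `C`, `G`, `T`) are compared. With `P` the transition
#' proportion and `Q` the transversion proportion over comparable sites,
#' \deqn{d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).}
#' When either logarithm argument is non-positive the distance is saturated:
#' `distance` is `NA` and `saturated` is `TRUE` (no large-distance
#' substitution is made).
#'
#' @param seqA,seqB Equal-length gapped nucleotide strings (e.g. from
#'   [alignPair()]), or an `aligned_pair` object passed as `seqA`.
#' @return A list of class `k2p` with `distance`, `P`, `Q`,
#'   `comparable_sites`, `transitions`, `transversions`, `saturated`.
#' @examples
#' p <- alignPair("ACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGT")
#' k2pDistance(p)$distance  # 0
#' @export
k2pDistance <- function(seqA, seqB = NULL) {
  if (inherits(seqA, "aligned_pair")) {
    seqB <- seqA$seqB
    seqA <- seqA$seqA
  }
  if (nchar(seqA) != nchar(seqB)) {
    stop("aligned sequences must have equal length")
  }
  ca <- strsplit(toupper(seqA), "")[[1]]
  cb <- strsplit(toupper(seqB), "")[[1]]
  acgt <- c("A", "C", "G", "T")
  cmp <- ca %in% acgt & cb %in% acgt
  n <- sum(cmp)
  if (n == 0L) {
    stop("no comparable sites between the two sequences; distance undefined")
  }
  a <- ca[cmp]; b <- cb[cmp]
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  ts <- sum(transition)
  tv <- sum(diff) - ts
  P <- ts / n
  Q <- tv / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  saturated <- arg1 <= 0 || arg2 <= 0
  d <- if (saturated) NA_real_ else -0.5 * log(arg1) - 0.25 * log(arg2)
  structure(
    list(distance = d, P = P, Q = Q, comparable_sites = n,
         transitions = ts, transversions = tv, saturated = saturated),
    class = "k2p"
  )
}

#' All-pairs K2P distance matrix
#'
#' Aligns every pair of sequences globally (unless `aligned = TRUE`, in which
#' case sequences must already share a common gapped length) and evaluates
#' the K2P distance per pair with pairwise deletion of gap/ambiguous columns.
#' Saturated pairs are `NA` in `d` and flagged in `saturated`.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param aligned If `TRUE`, sequences are taken as columns of a common
#'   alignment; otherwise each pair is aligned with [alignPair()].
#' @param scoring Alignment scoring (ignored when `aligned = TRUE`).
#' @return A list of class `k2p_matrix` with `labels` and symmetric matrices
#'   `d`, `P`, `Q`, `saturated` (zero / `FALSE` diagonals).
#' @export
pairwiseK2P <- function(seqs, aligned = FALSE, scoring = default_scoring()) {
  labels <- names(seqs)
  seqs <- as.character(seqs)  # drops names on some inputs; restore below
  names(seqs) <- labels
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("sequences must carry unique names")
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  P <- d; Q <- d
  sat <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        pair <- if (aligned) {
          list(seqA = seqs[[i]], seqB = seqs[[j]])
        } else {
          alignPair(seqs[[i]], seqs[[j]], scoring)
        }
        k <- tryCatch(k2pDistance(pair$seqA, pair$seqB), error = function(e) {
          stop("pair (", labels[i], ", ", labels[j], "): ", conditionMessage(e))
        })
        d[i, j] <- d[j, i] <- k$distance
        P[i, j] <- P[j, i] <- k$P
        Q[i, j] <- Q[j, i] <- k$Q
        sat[i, j] <- sat[j, i] <- k$saturated
      }
    }
  }
  structure(list(labels = labels, d = d, P = P, Q = Q, saturated = sat),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("K2P distance matrix over", length(x$labels), "sequences",
      if (any(x$saturated)) "(contains saturated pairs)" else "", "\n")
  print(round(x$d, 4))
  invisible(x)
}
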