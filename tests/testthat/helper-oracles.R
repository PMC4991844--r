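# Independent oracles used to cross-check alignment-based operations on tiny
# instances. These are deliberately separate implementations (plain dynamic
# programming over score matrices) from the package's alignment machinery.

# Global (Needleman-Wunsch) affine-gap alignment score; end gaps penalized.
# A gap of length L costs gap_open + L * gap_ext.
oracle_global_score <- function(a, b, match = 1, mismatch = -2,
                                gap_open = 5, gap_ext = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (consumes b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -gap_open - i * gap_ext
  for (j in seq_len(m)) Y[1, j + 1] <- -gap_open - j * gap_ext
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Local (Smith-Waterman) affine-gap best score.
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_ext = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Random nucleotide string.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute exactly n positions of a sequence (never back to the original base).
substitute_n <- function(seq, n, positions = NULL) {
  chars <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(chars), n)
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# Build a k2p_matrix-shaped object from a plain distance matrix (for tests of
# consumers that only need d / saturated / labels).
fake_k2p <- function(d) {
  structure(list(labels = rownames(d), d = d,
                 P = d * 0, Q = d * 0,
                 saturated = matrix(FALSE, nrow(d), ncol(d),
                                    dimnames = dimnames(d))),
            class = "k2p_matrix")
}

# Random ultrametric distance matrix built from a random rooted tree with
# non-decreasing merge heights.
random_ultrametric <- function(n) {
  heights <- sort(runif(n - 1, 0.05, 1))
  d <- matrix(0, n, n)
  active <- as.list(seq_len(n))
  for (h in heights) {
    pick <- sample(length(active), 2)
    c1 <- active[[pick[1]]]; c2 <- active[[pick[2]]]
    for (i in c1) for (j in c2) d[i, j] <- d[j, i] <- 2 * h
    active <- c(active[-pick], list(c(c1, c2)))
  }
  dimnames(d) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  d
}

# Shared microhistology / metabarcoding fixture paths.
fixture_path <- function(name) {
  system.file("extdata", name, package = "gooseDiet", mustWork = TRUE)
}
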