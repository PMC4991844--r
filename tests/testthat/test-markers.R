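make_tax <- function(ids, species, genus = "Carex", family = "Cyperaceae") {
  data.frame(seq_id = ids, family = family, genus = genus, species = species,
             stringsAsFactors = FALSE)
}

test_that("divergence summaries enumerate inter- and intra-specific pairs", {
  # 2 species, 1 sequence each: a single inter-specific pair
  d <- matrix(c(0, 0.027, 0.027, 0), 2,
              dimnames = list(c("x1", "x2"), c("x1", "x2")))
  tax <- make_tax(c("x1", "x2"), c("Carex a", "Carex b"))
  s <- divergenceSummary(fake_k2p(d), tax, "Carex", "genus")
  expect_equal(s$max, 0.027)
  expect_equal(s$min, 0.027)
  expect_equal(s$mean, 0.027)
  expect_equal(s$sd, 0)
  expect_true(is.na(s$intra_max))

  # all sequences one species: inter stats undefined, intra returned
  tax1 <- make_tax(c("x1", "x2"), c("Carex a", "Carex a"))
  expect_warning(s1 <- divergenceSummary(fake_k2p(d), tax1, "Carex", "genus"),
                 "no inter-specific pairs")
  expect_true(is.na(s1$mean))
  expect_equal(s1$intra_max, 0.027)

  expect_error(divergenceSummary(fake_k2p(d), tax, "Poa", "genus"), "absent")
})

test_that("divergence summary equals brute-force pair enumeration", {
  set.seed(31)
  ids <- paste0("s", 1:6)
  species <- rep(c("Carex a", "Carex b", "Carex c"), each = 2)
  d <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (i in 1:5) for (j in (i + 1):6) {
    d[i, j] <- d[j, i] <- round(runif(1, 0.001, 0.2), 4)
  }
  s <- divergenceSummary(fake_k2p(d), make_tax(ids, species), "Carex", "genus")
  inter <- c(); intra <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    if (species[i] == species[j]) intra <- c(intra, d[i, j])
    else inter <- c(inter, d[i, j])
  }
  expect_equal(s$n_pairs, 12L)  # 3 genera pairs * 2 * 2 sequences
  expect_equal(s$max, max(inter))
  expect_equal(s$min, min(inter))
  expect_equal(s$mean, mean(inter))
  expect_equal(s$sd, sqrt(mean((inter - mean(inter))^2)))
  expect_equal(s$intra_max, max(intra))
})

test_that("the barcoding gap requires strictly larger inter-specific distance", {
  expect_true(barcodingGap(0.02, 0.01))
  expect_false(barcodingGap(0.00, 0.00))
  expect_true(is.na(barcodingGap(0.02, NA)))
})

test_that("UPGMA reproduces hand-computed merge heights", {
  d <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgmaTree(d)
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(max(depth), 0.2)

  d3 <- matrix(c(0, 2, 6,
                 2, 0, 6,
                 6, 6, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- upgmaTree(d3)
  cd <- cophenetic(tr3)
  expect_equal(cd["A", "B"], 2)
  expect_equal(cd["A", "C"], 6)
  expect_equal(cd["B", "C"], 6)
  # cherry at height 1, root at height 3
  depths <- sort(unique(round(ape::node.depth.edgelength(tr3), 10)))
  expect_equal(max(depths), 3)
})

test_that("UPGMA reproduces ultrametric matrices exactly and is always ultrametric", {
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    d <- random_ultrametric(n)
    tr <- upgmaTree(d)
    cd <- cophenetic(tr)[rownames(d), colnames(d)]
    expect_equal(unname(cd), unname(d), tolerance = 1e-12)
    expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  }
  # arbitrary (non-ultrametric) input still yields an ultrametric tree
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.01, 1)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_true(ape::is.ultrametric(upgmaTree(d), tol = 1e-10))
  }
})

test_that("UPGMA refuses saturated or undefined distances", {
  d <- matrix(c(0, NA, NA, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(upgmaTree(d), "undefined")
  k <- fake_k2p(matrix(c(0, .1, .1, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  k$saturated[1, 2] <- k$saturated[2, 1] <- TRUE
  expect_error(upgmaTree(k), "saturated")
  expect_error(upgmaTree(matrix(0, 1, 1, dimnames = list("a", "a"))),
               "2 leaves")
})

test_that("Rf counts monophyletic species among those with two or more leaves", {
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  sorted <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  expect_equal(resolutionRate(sorted, sp)$rf, 100)
  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  expect_equal(resolutionRate(mixed, sp)$rf, 0)

  # 4 species, 3 monophyletic and 1 interleaved -> 75; singletons excluded
  tr <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,",
    "((c1:1,d1:1):1,((c2:1,d2:1):1,e1:1):1):1);"))
  sp4 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
           c1 = "C", c2 = "C", d1 = "D", d2 = "D", e1 = "E")
  r <- resolutionRate(tr, sp4)
  expect_equal(r$n_evaluated, 4L)
  expect_equal(r$rf, 50)  # A and B monophyletic; C and D interleaved

  # 4 species, 3 monophyletic and one split across the root -> 75
  tr75 <- ape::read.tree(text = paste0(
    "((d2:1,((a1:1,a2:1):1,(b1:1,b2:1):1):1):1,((c1:1,c2:1):1,d1:1):1);"))
  sp75 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B",
            c1 = "C", c2 = "C", d1 = "D", d2 = "D")
  expect_equal(resolutionRate(tr75, sp75)$rf, 75)

  single <- c(a1 = "A", b1 = "B")
  t2 <- ape::read.tree(text = "(a1:1,b1:1);")
  expect_warning(r2 <- resolutionRate(t2, single), "undefined")
  expect_true(is.na(r2$rf))
})

test_that("Rf is invariant under leaf order", {
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C")
  t1 <- ape::read.tree(text = "(((a1:1,a2:1):1,(b1:1,c1:1):1):1,(b2:1,c2:1):1);")
  t2 <- ape::read.tree(text = "((b2:1,c2:1):1,((b1:1,c1:1):1,(a2:1,a1:1):1):1);")
  expect_equal(resolutionRate(t1, sp)$rf, resolutionRate(t2, sp)$rf)
})

test_that("marker ranking is deterministic and orders by the stated criteria", {
  sm <- function(group, mean) {
    data.frame(group = group, level = "genus", mean = mean,
               stringsAsFactors = FALSE)
  }
  trnl <- markerReport("trnL", 1.00, rf = 90,
                       summaries = rbind(sm("Carex", 0.027), sm("Poa", 0.05)),
                       gap_ok = c(Carex = TRUE, Poa = TRUE))
  matk <- markerReport("matK", 0.43, rf = 95,
                       summaries = rbind(sm("Carex", 0.09), sm("Poa", 0.09)),
                       gap_ok = c(Carex = TRUE, Poa = TRUE))
  ranked <- rankMarkers(list(matk, trnl))
  expect_identical(ranked$gene, c("trnL", "matK"))  # success dominates

  # identical on all criteria -> alphabetical
  a <- markerReport("rbcL", 0.9)
  b <- markerReport("atpF", 0.9)
  expect_identical(rankMarkers(list(a, b))$gene, c("atpF", "rbcL"))
  expect_identical(rankMarkers(list(b, a))$gene, c("atpF", "rbcL"))

  expect_identical(rankMarkers(list(trnl))$gene, "trnL")

  # total order: every permutation of three reports gives the same ranking
  c3 <- markerReport("psbK", 0.9, summaries = sm("Carex", 0.5),
                     gap_ok = c(Carex = TRUE))
  perms <- list(list(a, b, c3), list(c3, a, b), list(b, c3, a))
  rankings <- lapply(perms, function(p) rankMarkers(p)$gene)
  expect_true(all(vapply(rankings, identical, logical(1), rankings[[1]])))
})
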