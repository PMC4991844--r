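small_lib <- function(seqs, tax) buildLibrary(seqs, tax)

test_that("lambda solves the Karlin-Altschul equation for the scoring scheme", {
  p <- calibrateEvalueParams(1, -2)
  # root of (1/4)e^l + (3/4)e^(-2l) = 1; closed form e^l = (3 + sqrt(21))/2
  expect_equal(p$lambda, log((3 + sqrt(21)) / 2), tolerance = 1e-10)
  expect_equal(0.25 * exp(p$lambda) + 0.75 * exp(-2 * p$lambda), 1,
               tolerance = 1e-10)
  # published ungapped constants for the +1/-2 nucleotide scheme
  expect_equal(p$lambda, 1.33, tolerance = 0.005)
  expect_equal(p$K, 0.621, tolerance = 0.005)

  p11 <- calibrateEvalueParams(1, -1)
  expect_equal(p11$lambda, log(3), tolerance = 1e-10)
  expect_true(is.finite(p11$K) && p11$K > 0)

  expect_error(calibrateEvalueParams(1, 1), "no positive lambda")
  expect_error(calibrateEvalueParams(-1, -2), "match score")
})

test_that("e-values decrease in score and scale linearly with database size", {
  set.seed(61)
  refs <- setNames(vapply(1:3, function(i) random_seq(150), character(1)),
                   paste0("ref", 1:3))
  tax <- data.frame(seq_id = names(refs), family = "F", genus = "G",
                    species = paste("G sp", 1:3), stringsAsFactors = FALSE)
  lib <- small_lib(refs, tax)
  hits <- searchLibrary(refs[[1]], lib)
  expect_true(all(diff(hits$score) <= 0))
  expect_true(all(diff(hits$evalue) >= 0))

  # doubling total reference length doubles every e-value
  lib2 <- small_lib(c(refs, setNames(refs, paste0("dup", 1:3))),
                    rbind(tax, transform(tax, seq_id = paste0("dup", 1:3))))
  hits2 <- searchLibrary(refs[[1]], lib2)
  m <- merge(hits, hits2, by = "seq_id")
  expect_equal(m$evalue.y / m$evalue.x, rep(2, nrow(m)))
})

test_that("search finds identical, substituted, and reverse-complement queries", {
  set.seed(62)
  ref <- random_seq(150)
  other <- random_seq(150)
  lib <- small_lib(
    setNames(c(ref, other), c("self", "other")),
    data.frame(seq_id = c("self", "other"), family = "F", genus = "G",
               species = c("G a", "G b"), stringsAsFactors = FALSE)
  )
  h <- searchLibrary(ref, lib)
  top <- h[h$seq_id == "self", ]
  expect_equal(top$identity, 1)
  expect_equal(top$coverage, 1)
  expect_identical(top$strand, "+")

  q100 <- substr(ref, 1, 100)
  h1 <- searchLibrary(substitute_n(q100, 1, positions = 50), lib)
  expect_equal(h1$identity[h1$seq_id == "self"], 0.99)

  hr <- searchLibrary(revcomp_chr(ref), lib)
  expect_equal(hr$identity[hr$seq_id == "self"], 1)
  expect_identical(hr$strand[hr$seq_id == "self"], "-")
})

test_that("local alignment scores match an independent DP oracle", {
  set.seed(63)
  for (rep in 1:10) {
    refs <- setNames(vapply(1:3, function(i) random_seq(sample(30:60, 1)),
                            character(1)), paste0("r", 1:3))
    tax <- data.frame(seq_id = names(refs), family = "F", genus = "G",
                      species = paste("G sp", 1:3), stringsAsFactors = FALSE)
    lib <- small_lib(refs, tax)
    q <- random_seq(sample(30:60, 1))
    hits <- searchLibrary(q, lib)
    for (id in names(refs)) {
      expected <- max(oracle_local_score(refs[[id]], q),
                      oracle_local_score(refs[[id]], revcomp_chr(q)))
      expect_equal(hits$score[hits$seq_id == id], expected, info = id)
    }
  }
})

test_that("assignment resolves species, genus, and family by the LCA rule", {
  set.seed(64)
  base <- random_seq(160)
  carex <- substitute_n(base, 40)
  # five congeneric species share one sequence; three confamilial genera
  # share another; one species is unique
  seqs <- c(setNames(rep(base, 5), paste0("pot", 1:5)),
            setNames(rep(substitute_n(base, 80), 3), paste0("poa", 1:3)),
            carex = carex)
  tax <- rbind(
    do.call(rbind, lapply(1:5, function(i) {
      data.frame(seq_id = paste0("pot", i), family = "Potamogetonaceae",
                 genus = "Potamogeton", species = paste("Potamogeton sp", i),
                 stringsAsFactors = FALSE)
    })),
    data.frame(seq_id = paste0("poa", 1:3), family = "Poaceae",
               genus = c("Beckmannia", "Phalaris", "Polypogon"),
               species = c("Beckmannia syzigachne", "Phalaris arundinacea",
                           "Polypogon fugax"), stringsAsFactors = FALSE),
    data.frame(seq_id = "carex", family = "Cyperaceae", genus = "Carex",
               species = "Carex heterolepis", stringsAsFactors = FALSE)
  )
  lib <- small_lib(seqs, tax)
  cfg <- runConfig()

  a1 <- assignTaxon(searchLibrary(base, lib), lib, cfg)
  expect_identical(a1$rank, "genus")
  expect_identical(a1$taxon, "Potamogeton")
  expect_equal(a1$n_tied_species, 5L)

  a2 <- assignTaxon(searchLibrary(seqs[["poa1"]], lib), lib, cfg)
  expect_identical(a2$rank, "family")
  expect_identical(a2$taxon, "Poaceae")

  a3 <- assignTaxon(searchLibrary(carex, lib), lib, cfg)
  expect_identical(a3$rank, "species")
  expect_identical(a3$taxon, "Carex heterolepis")

  # a query far from everything stays unassigned
  a4 <- assignTaxon(searchLibrary(random_seq(160), lib), lib, cfg)
  expect_identical(a4$rank, "unassigned")
})

test_that("assignment thresholds are strict and order-invariant", {
  hits <- data.frame(
    seq_id = c("a", "b", "c"),
    score = c(100, 100, 90),
    identity = c(0.99, 0.99, 0.985),
    coverage = c(1, 1, 1),
    subject_coverage = 1,
    evalue = 1e-60,
    strand = "+",
    stringsAsFactors = FALSE
  )
  tax <- data.frame(seq_id = c("a", "b", "c"), family = "F",
                    genus = c("G1", "G1", "G2"),
                    species = paste("S", 1:3), stringsAsFactors = FALSE)
  lib <- small_lib(setNames(rep(strrep("ACGT", 40), 3), c("a", "b", "c")), tax)
  cfg <- runConfig()
  a <- assignTaxon(hits, lib, cfg)
  expect_identical(a$rank, "genus")  # tie-set {a, b}; c excluded by score
  expect_identical(a$taxon, "G1")
  # permuting equally scoring hits changes nothing
  for (perm in list(c(2, 1, 3), c(3, 1, 2))) {
    expect_identical(assignTaxon(hits[perm, ], lib, cfg)[c("rank", "taxon")],
                     a[c("rank", "taxon")])
  }
  # identity exactly at the threshold fails the strict rule
  hits_eq <- transform(hits, identity = 0.98)
  expect_identical(assignTaxon(hits_eq, lib, cfg)$rank, "unassigned")
  # e-value exactly at the threshold fails too
  hits_ev <- transform(hits, evalue = cfg@maxEvalue)
  expect_identical(assignTaxon(hits_ev, lib, cfg)$rank, "unassigned")
  # hit naming an unknown reference is an error
  bad <- transform(hits, seq_id = c("a", "zz", "c"))
  expect_error(assignTaxon(bad, lib, cfg), "absent from taxonomy")
})

test_that("species assignments are correct on clean synthetic reads", {
  lib <- simulateReference(n_families = 2, genera_per_family = 2,
                           species_per_genus = 2, seq_len = 170,
                           species_subs = 8, genus_subs = 12, seed = 65)
  sheet <- simulateSampleSheet(1, seed = 65)
  species <- refTaxonomy(lib)$species
  props <- setNames(rep(1 / 4, 4), species[c(1, 3, 5, 7)])
  sim <- simulateReads(lib, sheet, props, n_reads = 120, read_len = 150,
                       error_rate = 0, seed = 65)
  res <- runPipeline(sim$fwd, sim$rev, sheet, runConfig())
  asn <- assignOtus(res$otus, lib)
  sp_level <- asn[asn$rank == "species", ]
  expect_setequal(sp_level$taxon, names(props))
  expect_equal(nrow(asn[asn$rank == "unassigned", ]), 0L)
})
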