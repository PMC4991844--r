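fixture_tax <- function() readTaxonomy(fixture_path("shengjin_plant_taxonomy.tsv"))
fixture_meta <- function() {
  read.delim(fixture_path("goose_diet_metabarcoding.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}
fixture_micro <- function() {
  readMicrohistology(fixture_path("goose_diet_microhistology.tsv"))
}

# a small assignment + count fixture: two samples in one group
toy_diet <- function() {
  asn <- data.frame(
    otu_id = paste0("OTU_", 1:3),
    rank = c("species", "species", "unassigned"),
    taxon = c("Carex heterolepis", "Poa annua", NA),
    stringsAsFactors = FALSE
  )
  counts <- matrix(c(60, 15, 15, 10, 3, 2), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
  list(asn = asn, counts = counts,
       groups = c(s1 = "GWFG", s2 = "GWFG"))
}

test_that("diet fractions are percentages of assigned reads", {
  td <- toy_diet()
  dt <- dietTable(td$asn, td$counts, td$groups)
  expect_equal(sum(dt$fs), 100)
  expect_equal(dt$fs[dt$taxon == "Carex heterolepis"], 75)
  expect_equal(dt$fs[dt$taxon == "Poa annua"], 25)
  expect_equal(attr(dt, "unassigned_reads")[["GWFG"]], 5)
  # presence fractions count samples with at least one read
  expect_equal(dt$presence_fraction, c(1, 1))
})

test_that("a single-taxon group has fs 100 and scaling leaves fs unchanged", {
  asn <- data.frame(otu_id = "OTU_1", rank = "species", taxon = "Poa annua",
                    stringsAsFactors = FALSE)
  counts <- matrix(7, 1, 1, dimnames = list("OTU_1", "s1"))
  dt <- dietTable(asn, counts, c(s1 = "BG"))
  expect_equal(dt$fs, 100)

  td <- toy_diet()
  dt1 <- dietTable(td$asn, td$counts, td$groups)
  dt10 <- dietTable(td$asn, td$counts * 10, td$groups)
  expect_equal(dt1$fs, dt10$fs)
})

test_that("genus rows coexisting with congeneric species become residual rows", {
  asn <- data.frame(
    otu_id = paste0("OTU_", 1:3),
    rank = c("species", "genus", "genus"),
    taxon = c("Carex heterolepis", "Carex", "Polygonum"),
    stringsAsFactors = FALSE
  )
  counts <- matrix(c(50, 30, 20), 3, 1,
                   dimnames = list(paste0("OTU_", 1:3), "s1"))
  dt <- dietTable(asn, counts, c(s1 = "GWFG"), fixture_tax())
  expect_true("Carex spp. (except Carex heterolepis)" %in% dt$taxon)
  expect_true("Polygonum" %in% dt$taxon)  # no congeneric species present
  expect_equal(sum(dt$fs), 100)
})

test_that("zero-assigned samples warn and contribute zero", {
  td <- toy_diet()
  counts <- td$counts
  counts[, "s2"] <- 0
  expect_warning(dt <- dietTable(td$asn, counts, td$groups), "zero assigned")
  expect_equal(sum(dt$n_reads), 75)
})

test_that("per-sample incidence reflects read support", {
  td <- toy_diet()
  counts <- td$counts
  counts["OTU_2", "s2"] <- 0
  pt <- presenceTable(td$asn, counts)
  expect_equal(unname(pt$fraction["Carex heterolepis"]), 1)
  expect_equal(unname(pt$fraction["Poa annua"]), 0.5)
  # taxa with zero reads overall are absent from the table
  counts["OTU_2", ] <- 0
  pt0 <- presenceTable(td$asn, counts)
  expect_false("Poa annua" %in% rownames(pt0$incidence))
})

test_that("read conservation holds per group", {
  td <- toy_diet()
  dt <- dietTable(td$asn, td$counts, td$groups)
  assigned_total <- sum(td$counts[1:2, ])
  expect_equal(sum(dt$n_reads), assigned_total)
})

test_that("the published goose diet tables reproduce the printed summaries", {
  meta <- fixture_meta()
  micro <- fixture_micro()
  tax <- fixture_tax()
  # detection counts as printed: 12 items for GWFG, 4 for BG
  expect_equal(sum(meta$group == "GWFG"), 12L)
  expect_equal(sum(meta$group == "BG"), 4L)
  # Fs within each group sums to ~100
  expect_equal(sum(meta$fs_percent[meta$group == "GWFG"]), 100,
               tolerance = 0.02 / 100)
  # family share: Poaceae taxa carry ~73% of GWFG reads, Carex ~26%
  diet <- data.frame(group = meta$group, taxon = meta$taxon, rank = meta$rank,
                     fs = meta$fs_percent, stringsAsFactors = FALSE)
  fam <- taxonShares(diet, tax, "family")
  expect_equal(fam$fs_total[fam$group == "GWFG" & fam$taxon == "Poaceae"],
               73.19, tolerance = 1e-8)
  gen <- taxonShares(diet, tax, "genus")
  expect_equal(gen$fs_total[gen$group == "GWFG" & gen$taxon == "Carex"],
               26.52, tolerance = 1e-8)
  expect_equal(gen$fs_total[gen$group == "BG" & gen$taxon == "Carex"],
               99.72, tolerance = 1e-8)
})

test_that("rank-aware matching recovers the published method differences", {
  meta <- fixture_meta()
  micro <- fixture_micro()
  tax <- fixture_tax()
  diet <- data.frame(group = meta$group, taxon = meta$taxon, rank = meta$rank,
                     n_reads = meta$n_reads, stringsAsFactors = FALSE)
  cmp <- compareMethods(diet, micro, tax)
  # two taxa seen only under the microscope
  expect_setequal(cmp$union$microhistology_only,
                  c("Carex thunbergii", "Fabaceae sp."))
  # the genus-level microscopy record matches the congeneric species
  sh <- cmp$union$shared
  alo <- sh[sh$microhistology_taxon == "Alopecurus", ]
  expect_identical(alo$metabarcoding_taxon, "Alopecurus aequalis")
  expect_identical(alo$finer_method, "metabarcoding")
  # metabarcoding-only: the remaining six items
  expect_length(cmp$union$metabarcoding_only, 6L)
  # 15 distinct food-item labels across both methods as printed; the
  # rank-aware view merges Alopecurus with Alopecurus aequalis, leaving 14
  expect_length(union(diet$taxon, micro$taxon), 15L)
  expect_equal(nrow(sh) + length(cmp$union$metabarcoding_only) +
                 length(cmp$union$microhistology_only), 14L)
})

test_that("identical detections leave no method-only taxa and swapping is symmetric", {
  det <- data.frame(group = "G", taxon = c("Poa annua", "Carex heterolepis"),
                    rank = "species", n_reads = c(10, 5),
                    stringsAsFactors = FALSE)
  micro <- data.frame(group = "G", taxon = det$taxon, rank = "species",
                      fm_percent = c(50, 50), stringsAsFactors = FALSE)
  cmp <- compareMethods(det, micro)
  expect_length(cmp$union$microhistology_only, 0L)
  expect_length(cmp$union$metabarcoding_only, 0L)

  # swapping the two methods swaps the "only" sets exactly
  meta <- fixture_meta()
  tax <- fixture_tax()
  diet <- data.frame(group = meta$group, taxon = meta$taxon, rank = meta$rank,
                     n_reads = meta$n_reads, stringsAsFactors = FALSE)
  micro2 <- fixture_micro()
  fwd <- compareMethods(diet, micro2, tax)
  swapped_diet <- data.frame(group = micro2$group, taxon = micro2$taxon,
                             rank = micro2$rank, n_reads = micro2$fm_percent,
                             stringsAsFactors = FALSE)
  swapped_micro <- data.frame(group = meta$group, taxon = meta$taxon,
                              rank = meta$rank,
                              fm_percent = meta$n_reads,
                              stringsAsFactors = FALSE)
  rev <- compareMethods(swapped_diet, swapped_micro, tax)
  expect_setequal(rev$union$metabarcoding_only, fwd$union$microhistology_only)
  expect_setequal(rev$union$microhistology_only, fwd$union$metabarcoding_only)
})

test_that("species-level vs genus-level counterparts share with rank detail", {
  det <- data.frame(group = "G", taxon = "Carex heterolepis", rank = "species",
                    n_reads = 10, stringsAsFactors = FALSE)
  micro <- data.frame(group = "G", taxon = "Carex", rank = "genus",
                      fm_percent = 40, stringsAsFactors = FALSE)
  cmp <- compareMethods(det, micro)
  expect_equal(nrow(cmp$union$shared), 1L)
  expect_identical(cmp$union$shared$finer_method, "metabarcoding")
})
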