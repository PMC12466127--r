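## small hand-built table: 10 tumor specimens, 2 regions
hand_table <- function() {
  tab <- data.frame(
    specimen = sprintf("S%02d", 1:10),
    patient = sprintf("P%02d", 1:10),
    section = "S1", compartment = "tumor",
    stringsAsFactors = FALSE)
  tab$regA <- c(rep("chr1:150C>G", 3), rep("WT", 6), "NS")
  tab$regB <- c(rep("NS", 4), rep("WT", 6))
  tab
}

test_that("callability counts non-NS tumor cells per region", {
  tab <- hand_table()
  res <- region_callability(tab)
  expect_equal(res$per_region$fraction,
               c(9 / 10, 6 / 10))
  expect_equal(res$n_above_threshold, 1)

  all_called <- tab
  all_called$regA <- "WT"; all_called$regB <- "WT"
  expect_true(all(region_callability(all_called)$per_region$fraction == 1))
})

test_that("mutation frequency excludes NS from the denominator", {
  tab <- hand_table()
  ## regA: 3 MUT, 6 WT, 1 NS -> 3/9 = 1/3
  res <- mutation_frequencies(tab)
  expect_equal(res$per_region$frequency[1], 1 / 3)
  expect_equal(res$per_region$frequency[2], 0)
  expect_equal(res$burden$fraction, 3 / 10)

  all_wt <- tab
  all_wt$regA <- "WT"; all_wt$regB <- "WT"
  res2 <- mutation_frequencies(all_wt)
  expect_true(all(res2$per_region$frequency == 0))
  expect_equal(res2$burden$fraction, 0)

  ## a fully NS region is reported as missing, not 0
  one_ns <- tab
  one_ns$regB <- "NS"
  expect_true(is.na(mutation_frequencies(one_ns)$per_region$frequency[2]))
})

test_that("co-occurrence requires two mutated regions per patient", {
  tab <- hand_table()
  expect_equal(nrow(co_occurrence(tab)$patients), 0)
  tab$regB[2] <- "chr1:400A>T"
  res <- co_occurrence(tab)
  expect_equal(res$patients$patient, "P02")
  m <- res$comutation_matrix
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m["regA", "regB"], 1L)
})

test_that("known-SNP filtering is allele-aware and conserves counts", {
  muts <- snv_records(rep("chr1", 3), c(100L, 200L, 300L),
                      c("A", "C", "G"), c("G", "T", "A"),
                      paste0("p", 1:3))
  expect_equal(nrow(filter_known_snps(muts, data.frame())$somatic), 3)

  snps <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                     ref = c("A", "C"), alt = c("G", "A"),
                     stringsAsFactors = FALSE)
  res <- filter_known_snps(muts, snps)
  ## pos 100 matches exactly -> flagged; pos 200 has a different alt ->
  ## somatic (a position-only rule would flag both)
  expect_equal(res$flagged$pos, 100L)
  expect_equal(sort(res$somatic$pos), c(200L, 300L))
  expect_equal(nrow(res$somatic) + nrow(res$flagged), nrow(muts))
  pos_only <- muts$pos %in% snps$pos
  expect_false(sum(pos_only) == nrow(res$flagged))
})

test_that("germline decoys from the generator are flagged exactly", {
  g <- generate_genome(2, 1e5, seed = 101)
  coh <- generate_cohorts(g, seed = 1)
  ann <- generate_annotations(coh$truth, g, seed = 1)
  snv <- generate_snvs(g, ann$truth, n_germline_decoys = 2, seed = 6)
  res <- filter_known_snps(snv$snvs, snv$known_snps)
  expect_equal(nrow(res$flagged), 2)
  expect_true(all(res$flagged$origin == "germline"))
  expect_true(all(res$somatic$origin == "somatic"))
})

test_that("multifocal concordance uses all-sections-identical, strict flag", {
  tab <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(specimen = sprintf("P%d_S%d", i, 1:2),
               patient = sprintf("P%d", i), section = c("S1", "S2"),
               compartment = "tumor", stringsAsFactors = FALSE)
  }))
  tab$regA <- "WT"
  tab$regA[tab$specimen == "P1_S1"] <- "chr1:150C>G"   # one discordant
  res <- multifocal_concordance(tab)
  expect_equal(res$per_region$concordance, 0.75)
  expect_equal(res$n_above_threshold, 0)  # 0.75 is not "over 75%"

  tab$regA[tab$specimen == "P1_S2"] <- "chr1:150C>G"   # now identical
  expect_equal(multifocal_concordance(tab)$per_region$concordance, 1.0)

  ## different alleles in the two sections are discordant
  tab$regA[tab$specimen == "P1_S2"] <- "chr1:151A>T"
  expect_equal(multifocal_concordance(tab)$per_region$concordance, 0.75)

  single <- hand_table()
  expect_warning(res0 <- multifocal_concordance(single), "no patient")
  expect_equal(nrow(res0$per_region), 0)
})

test_that("peritumoral exclusivity reports offending specimens", {
  tab <- hand_table()
  expect_error(peritumoral_exclusivity(tab), "no peritumoral")

  peri <- data.frame(specimen = c("P01_PT", "P02_PT"),
                     patient = c("P01", "P02"), section = "PT",
                     compartment = "peritumoral", regA = "WT",
                     regB = "WT", stringsAsFactors = FALSE)
  res <- peritumoral_exclusivity(rbind(tab, peri))
  expect_true(res$tumor_exclusive)
  expect_equal(nrow(res$per_patient), 2)  # P01 and P02 are tumor-mutated

  peri$regA[1] <- "chr1:150C>G"
  res2 <- peritumoral_exclusivity(rbind(tab, peri))
  expect_false(res2$tumor_exclusive)
  expect_equal(res2$per_patient$offending_specimens[
    res2$per_patient$patient == "P01"], "P01_PT")
})

test_that("cohort statistics are invariant under row permutation", {
  sim <- generate_genotype_table(seed = 5)
  tab <- sim$table
  set.seed(99)
  shuffled <- tab[sample.int(nrow(tab)), , drop = FALSE]
  rownames(shuffled) <- NULL
  expect_equal(region_callability(tab), region_callability(shuffled))
  expect_equal(mutation_frequencies(tab), mutation_frequencies(shuffled))
  expect_equal(multifocal_concordance(tab),
               multifocal_concordance(shuffled))
  expect_setequal(co_occurrence(tab)$patients$patient,
                  co_occurrence(shuffled)$patients$patient)
})

test_that("the planted validation cohort is recovered exactly", {
  sim <- generate_genotype_table(seed = 5)
  truth <- sim$truth
  tab <- sim$table

  callab <- region_callability(tab)
  expect_equal(callab$per_region$fraction, truth$callability)
  expect_equal(callab$n_above_threshold, 4L)

  freqs <- mutation_frequencies(tab)
  expect_equal(freqs$per_region$frequency, truth$frequency)
  expect_equal(freqs$burden$fraction, truth$burden)
  expect_equal(freqs$burden$n_mutated, truth$n_mutated_patients)
  expect_gt(freqs$burden$fraction, 0.46)

  cooc <- co_occurrence(tab)
  expect_equal(nrow(cooc$patients), truth$n_cooccurring)
  expect_setequal(cooc$patients$patient, truth$cooccurring_patients)

  conc <- multifocal_concordance(tab)
  expect_equal(conc$per_region$concordance, truth$concordance)
  expect_equal(conc$n_above_threshold, 4L)

  peri <- peritumoral_exclusivity(tab)
  expect_true(peri$tumor_exclusive)
  expect_equal(sum(tab$compartment == "peritumoral"), 9)

  ## planted violation is caught and named
  bad <- generate_genotype_table(seed = 5, peritumoral_violation = TRUE)
  res <- peritumoral_exclusivity(bad$table)
  expect_false(res$tumor_exclusive)
  expect_true(any(nzchar(res$per_patient$offending_specimens)))
})

test_that("genotype tables round-trip through TSV", {
  sim <- generate_genotype_table(seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(sim$table, path)
  back <- read_genotype_table(path)
  expect_equal(back, sim$table)
})
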