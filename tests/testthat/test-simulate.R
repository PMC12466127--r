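test_that("genome generation is deterministic with controlled composition", {
  g1 <- generate_genome(2, 5e4, gc = 0.5, seed = 8)
  g2 <- generate_genome(2, 5e4, gc = 0.5, seed = 8)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(2, 5e4, gc = 0.5, seed = 9)))

  ## binomial bound: observed GC within 3 SD of the target
  n <- 1e5
  g <- generate_genome(1, n, gc = 0.5, seed = 4)
  gc_obs <- sum(strsplit(g[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.5 * n), 3 * sqrt(n * 0.25))

  g0 <- generate_genome(1, 1e4, gc = 0, seed = 4)
  expect_false(grepl("[GC]", g0[[1]]))
})

test_that("FASTA output of the same seed is byte-identical", {
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(generate_genome(1, 2e4, seed = 77), p1)
  write_genome(generate_genome(1, 2e4, seed = 77), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("cohort generation respects planted membership rules", {
  g <- generate_genome(2, 1e5, seed = 101)
  sim <- generate_cohorts(g, dropout = 0, seed = 1)
  truth <- sim$truth$regions
  key <- function(d) paste(d$chrom, d$start, d$end)
  shared <- key(truth[truth$status == "shared", ])
  a_spec <- key(truth[truth$status == "A_specific", ])
  for (s in sim$cohort_a$samples) {
    expect_true(all(shared %in% key(s)))       # shared in every sample
    expect_true(all(a_spec %in% key(s)))       # no dropout
  }
  for (s in sim$cohort_b$samples) {
    expect_false(any(a_spec %in% key(s)))      # never in the other group
  }

  none_a <- generate_cohorts(g, n_specific_a = 0, seed = 2)
  calls <- call_specific_regions(none_a$cohort_a, none_a$cohort_b)
  expect_equal(sum(calls$status == "A_specific"), 0)
})

test_that("a promoter-only class mix classifies every region as promoter", {
  g <- generate_genome(2, 1e5, seed = 101)
  coh <- generate_cohorts(g, seed = 1)
  mix <- list(A = c(promoter = 1), B = c(promoter = 1),
              shared = c(promoter = 1))
  ann <- generate_annotations(coh$truth, g, class_mix = mix,
                              n_candidates = 0, seed = 1)
  expect_true(all(ann$truth$classes$class == "promoter"))
})

test_that("the 1 Mb gene-neighborhood boundary is respected", {
  ## element midpoint at 500,000; genes at exactly 1 Mb and 1 Mb + 1 bp
  genes <- data.frame(chrom = "chr1",
                      start = c(1500000L, 1500001L),
                      end = c(1500000L, 1500001L) + 1000L,
                      strand = ".", name = c("AT_EDGE", "PAST_EDGE"),
                      stringsAsFactors = FALSE)
  prof <- list(EE_X = list(
    element = data.frame(chrom = "chr1", start = 499800L, end = 500200L,
                         strand = ".", id = "EE_X",
                         stringsAsFactors = FALSE),
    snvs = snv_records("chr1", 500000L, "A", "G", "p1"),
    n_patients = 1L,
    hotspots = cluster_hotspots(snv_records("chr1", 500000L, "A", "G",
                                            "p1"))))
  ranked <- prioritize_candidates(prof, genes, top_n = 1)
  expect_equal(ranked$nearby_curated, "AT_EDGE")
  expect_equal(ranked$n_nearby_curated, 1)
})

test_that("SNV planting validates positions and supports degenerate inputs", {
  g <- generate_genome(2, 1e5, seed = 101)
  coh <- generate_cohorts(g, seed = 1)
  ann <- generate_annotations(coh$truth, g, seed = 1)

  bad_plan <- data.frame(element_id = ann$truth$candidates[1],
                         pos = 1L, n_patients = 1L,
                         stringsAsFactors = FALSE)
  expect_error(generate_snvs(g, ann$truth, plan = bad_plan, seed = 1),
               "outside its element")

  none <- generate_snvs(g, ann$truth, n_patients = 0, seed = 1)
  expect_equal(nrow(none$snvs), 0)
  expect_equal(nrow(none$known_snps), 0)
})

test_that("planted recurrence and hotspot geometry come out as specified", {
  g <- generate_genome(2, 1e5, seed = 101)
  coh <- generate_cohorts(g, seed = 1)
  ## enhancer-rich mix so that three candidate enhancers exist
  mix <- list(A = c(promoter = 0.3, insulator = 0.2, enhancer = 0.3),
              B = c(promoter = 0.3, insulator = 0.2, enhancer = 0.3),
              shared = c(promoter = 0.3, insulator = 0.2,
                         enhancer = 0.3))
  ann <- generate_annotations(coh$truth, g, class_mix = mix, seed = 1)
  snv <- generate_snvs(g, ann$truth, seed = 1)
  plan <- snv$truth$snv_plan
  som <- snv$snvs[snv$snvs$origin == "somatic", ]
  for (i in seq_len(nrow(plan))) {
    carriers <- som$patient[som$chrom == plan$chrom[i] &
                              som$pos == plan$pos[i]]
    expect_equal(length(unique(carriers)), plan$n_patients[i])
  }
  ## hotspot offsets {0, 5} on the recurrent candidate: one cluster
  rec_el <- plan$element_id[plan$n_patients == 3]
  in_el <- som[som$element_id %in% rec_el & !is.na(som$element_id), ]
  cl <- cluster_hotspots(in_el, gap = 7)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$pos_max - cl$pos_min, 5)
})

test_that("an all-wild-type plan produces zero burden and no co-occurrence", {
  sim <- generate_genotype_table(frequencies = rep(0, 5),
                                 callability = rep(1, 5),
                                 concordance = rep(1, 5),
                                 n_cooccurring = 0,
                                 n_mutated_patients = 0,
                                 n_peritumoral = 0, seed = 5)
  freqs <- mutation_frequencies(sim$table)
  expect_true(all(freqs$per_region$frequency == 0))
  expect_equal(freqs$burden$fraction, 0)
  expect_equal(nrow(co_occurrence(sim$table)$patients), 0)
  expect_true(all(region_callability(sim$table)$per_region$fraction == 1))
})

test_that("infeasible genotype plans are rejected", {
  ## concordance demands discordant mutations a zero-frequency region
  ## cannot host
  expect_error(
    generate_genotype_table(frequencies = c(0, 0.2, 0.2, 0.2, 0.2),
                            concordance = c(0.5, 0.9, 0.9, 0.9, 0.9),
                            seed = 5),
    "infeasible")
  ## more mutated patients than mutations
  expect_error(
    generate_genotype_table(frequencies = rep(0.01, 5),
                            n_mutated_patients = 40, n_cooccurring = 0,
                            seed = 5),
    "infeasible")
})

test_that("generators are pure functions of (parameters, seed)", {
  g <- generate_genome(2, 1e5, seed = 101)
  c1 <- generate_cohorts(g, seed = 3)
  c2 <- generate_cohorts(g, seed = 3)
  expect_identical(c1, c2)
  t1 <- generate_genotype_table(seed = 5)
  t2 <- generate_genotype_table(seed = 5)
  expect_identical(t1, t2)
  ## the global RNG stream is left untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_genotype_table(seed = 5))
  expect_identical(runif(3), before)
})

test_that("ground truth round-trips through the JSON sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(seed = 2, preset = "small", dir = dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$regions$status, sim$truth$regions$status)
  expect_equal(truth$genotype$burden, sim$truth$genotype$burden)
  expect_equal(truth$pwm_plan$tf, sim$truth$pwm_plan$tf)
  expect_setequal(truth$candidates, sim$truth$candidates)
})
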