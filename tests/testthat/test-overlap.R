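make_elements <- function(n, width = 400L, gap = 600L) {
  start <- as.integer(seq(1000, by = width + gap, length.out = n))
  data.frame(chrom = "chr1", start = start, end = start + width,
             strand = ".", id = sprintf("EE_%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

test_that("SNVs map to the planted elements and nowhere else", {
  els <- make_elements(40)
  inside <- function(i, off) els$start[i] + off  # 1-based pos via off >= 1
  snvs <- snv_records(
    rep("chr1", 5),
    c(inside(3, 10), inside(3, 18), inside(7, 50), inside(12, 1),
      inside(12, 399)),
    c("A", "C", "G", "T", "A"), c("G", "T", "A", "C", "C"),
    c("p1", "p2", "p1", "p3", "p4"))
  res <- map_snvs_to_elements(snvs, els)
  expect_length(res$profiles, 3)
  expect_setequal(names(res$profiles), c("EE_03", "EE_07", "EE_12"))
  expect_equal(res$profiles$EE_03$n_patients, 2)
  expect_equal(nrow(res$spillover), 0)
})

test_that("empty SNV input yields no profiles; spill-over conserves counts", {
  els <- make_elements(5)
  none <- snv_records(character(0), integer(0), character(0),
                      character(0), character(0))
  expect_length(map_snvs_to_elements(none, els)$profiles, 0)

  snvs <- snv_records(c("chr1", "chr1", "chr2"),
                      c(els$start[2] + 5L, 99000L, 50L),
                      c("A", "A", "A"), c("G", "G", "G"),
                      c("p1", "p2", "p3"))
  res <- map_snvs_to_elements(snvs, els)
  n_in_profiles <- sum(vapply(res$profiles, function(p) nrow(p$snvs), 0))
  expect_equal(n_in_profiles + nrow(res$spillover), nrow(snvs))
})

test_that("a VCF position equal to an element's BED start is not assigned", {
  els <- make_elements(1)
  at_start <- snv_records("chr1", els$start[1], "A", "G", "p1")
  res <- map_snvs_to_elements(at_start, els)
  expect_length(res$profiles, 0)
  expect_equal(nrow(res$spillover), 1)
  ## one past the start is the element's first base
  first_base <- snv_records("chr1", els$start[1] + 1L, "A", "G", "p1")
  expect_length(map_snvs_to_elements(first_base, els)$profiles, 1)
})

test_that("ref alleles disagreeing with the genome raise a named error", {
  g <- c(chr1 = paste(rep("A", 5000), collapse = ""))
  els <- data.frame(chrom = "chr1", start = 1000L, end = 1400L,
                    strand = ".", id = "EE_01", stringsAsFactors = FALSE)
  bad <- snv_records("chr1", 1100L, "C", "G", "p9")
  expect_error(map_snvs_to_elements(bad, els, genome = g),
               "chr1:1100C>G.*p9")
})

test_that("hotspot clustering is single linkage with the 7 bp gap rule", {
  single <- snv_records("chr1", 100L, "A", "G", "p1")
  expect_equal(nrow(cluster_hotspots(single)), 1)

  two_near <- snv_records(c("chr1", "chr1"), c(100L, 107L), c("A", "A"),
                          c("G", "G"), c("p1", "p2"))
  expect_equal(nrow(cluster_hotspots(two_near, gap = 7)), 1)
  two_far <- snv_records(c("chr1", "chr1"), c(100L, 108L), c("A", "A"),
                         c("G", "G"), c("p1", "p2"))
  expect_equal(nrow(cluster_hotspots(two_far, gap = 7)), 2)

  chain <- snv_records(rep("chr1", 3), c(1L, 8L, 15L), rep("A", 3),
                       rep("G", 3), paste0("p", 1:3))
  cl <- cluster_hotspots(chain, gap = 7)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_snvs, 3)
})

test_that("cluster counts match the graph-components oracle and are monotone in gap", {
  set.seed(21)
  for (i in 1:15) {
    pos <- sort(sample(1:500, sample(3:12, 1)))
    snvs <- snv_records(rep("chr1", length(pos)), pos,
                        rep("A", length(pos)), rep("G", length(pos)),
                        paste0("p", seq_along(pos)))
    counts <- vapply(c(0, 3, 7, 15, 50), function(gp) {
      got <- nrow(cluster_hotspots(snvs, gap = gp))
      expect_equal(got, oracle_hotspot_count(pos, gp))
      got
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    ## gap 0: one cluster per distinct position
    expect_equal(counts[1], length(unique(pos)))
  }
})

fake_profile <- function(id, n_patients, n_snvs, chrom = "chr1",
                         start = 1000L, end = 1400L) {
  snvs <- snv_records(rep(chrom, n_snvs),
                      start + seq_len(n_snvs) * 3L,
                      rep("A", n_snvs), rep("G", n_snvs),
                      paste0("pt", rep_len(seq_len(n_patients), n_snvs)))
  list(element = data.frame(chrom = chrom, start = start, end = end,
                            strand = ".", id = id,
                            stringsAsFactors = FALSE),
       snvs = snvs, n_patients = n_patients,
       hotspots = cluster_hotspots(snvs))
}

test_that("patient recurrence dominates raw SNV count in prioritization", {
  genes <- data.frame(chrom = "chr1", start = 5000L, end = 8000L,
                      strand = ".", name = "GENE1",
                      stringsAsFactors = FALSE)
  pa <- fake_profile("EE_A", n_patients = 3, n_snvs = 3)
  pb <- fake_profile("EE_B", n_patients = 1, n_snvs = 5)
  ranked <- prioritize_candidates(list(EE_A = pa, EE_B = pb), genes,
                                  top_n = 2)
  expect_equal(ranked$element_id, c("EE_A", "EE_B"))
  expect_equal(ranked$rank, 1:2)

  single <- prioritize_candidates(list(EE_B = pb), genes, top_n = 3)
  expect_equal(single$rank, 1)
})

test_that("prioritization equals a brute-force sort by the declared key", {
  set.seed(2)
  genes <- data.frame(chrom = "chr1",
                      start = as.integer(seq(2000, 90000, length.out = 6)),
                      end = as.integer(seq(2000, 90000, length.out = 6)) + 500L,
                      strand = ".", name = paste0("G", 1:6),
                      stringsAsFactors = FALSE)
  profiles <- lapply(1:10, function(i) {
    fake_profile(sprintf("EE_%02d", i), sample(1:4, 1), sample(1:6, 1),
                 start = 1000L * i, end = 1000L * i + 400L)
  })
  names(profiles) <- vapply(profiles, function(p) p$element$id, "")
  inter <- data.frame(element_id = c("EE_02", "EE_05"),
                      gene = c("G1", "G2"),
                      confidence = c("high", "low"),
                      stringsAsFactors = FALSE)
  ranked <- prioritize_candidates(profiles, genes, curated = genes$name,
                                  interactions = inter, top_n = 10,
                                  neighborhood_bp = 20000)
  ## independent sort oracle over the same feature tuples
  feats <- do.call(rbind, lapply(profiles, function(p) {
    mid <- (p$element$start + p$element$end) %/% 2
    d <- ifelse(genes$chrom == p$element$chrom,
                ifelse(mid < genes$start, genes$start - mid,
                       ifelse(mid >= genes$end, mid - (genes$end - 1), 0)),
                Inf)
    data.frame(id = p$element$id, np = p$n_patients, ns = nrow(p$snvs),
               ng = sum(d <= 20000),
               hi = p$element$id %in% "EE_02",
               stringsAsFactors = FALSE)
  }))
  oracle_order <- feats$id[order(-feats$np, -feats$ns, -feats$ng,
                                 -as.integer(feats$hi), feats$id)]
  expect_equal(ranked$element_id, oracle_order)
  ## total order: a permutation prefix of the inputs
  expect_setequal(ranked$element_id, names(profiles))
})

test_that("VCF round trip preserves SNV records and skips non-SNVs", {
  path <- withr::local_tempfile(fileext = ".vcf")
  snvs <- snv_records(c("chr2", "chr1"), c(500L, 100L), c("A", "C"),
                      c("T", "G"), "p1")
  write_snv_vcf(snvs, path)
  ## splice in an indel record that must be skipped
  lines <- readLines(path)
  writeLines(c(lines, "chr3\t900\t.\tAT\tA\t.\tPASS\t."), path)
  back <- read_snv_vcf(path, patient = "p1")
  expect_equal(nrow(back), 2)
  expect_equal(attr(back, "n_skipped"), 1)
  expect_equal(back$pos, c(100L, 500L))
  expect_equal(back$ref, c("C", "A"))
})
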