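#' Generate a complete synthetic study
#'
#' Composes all generators into one bundle containing every input the
#' pipeline consumes plus the planted ground truth. Two presets:
#' \describe{
#'   \item{`paper_like`}{a study scaled to exercise every stage at
#'     realistic proportions: a 2 x 1.2 Mb genome (long enough to place
#'     genes beyond the +/- 1 Mb neighborhood), 9 vs 12 samples, 400 /
#'     480 / 300 planted A-specific / B-specific / shared regions with
#'     group class mixes matching the element-class proportions of the
#'     two tumor types, 39 whole-genome patients, planted gain and loss
#'     motifs among 8 background motifs, and a 54-patient genotype
#'     table.}
#'   \item{`small`}{the bare generator defaults (2 x 100 kb genome,
#'     20 / 30 / 50 regions) for fast unit-level work.}
#' }
#'
#' @param seed Master seed; per-generator sub-seeds are derived from it.
#' @param preset `"paper_like"` (default) or `"small"`.
#' @param dropout Peak dropout fraction passed to [generate_cohorts()].
#' @param dir Optional directory: when given, all inputs are written as
#'   standard files (FASTA, per-sample BED + sample sheet, track BEDs,
#'   gene BED, curated TSV, interactions TSV, per-patient VCFs,
#'   known-SNP TSV, JASPAR-style PFM text, genotype TSV) together with a
#'   `ground_truth.json` sidecar.
#' @return List: `genome`, `cohort_a`, `cohort_b`, `tracks`, `genes`,
#'   `curated`, `interactions`, `snvs`, `known_snps`, `pfms`, `genotype`
#'   (list `table`, `mutations`), `truth`, `params`.
#' @export
simulate_study <- function(seed, preset = c("paper_like", "small"),
                           dropout = 0, dir = NULL) {
  preset <- match.arg(preset)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 7L))
  p <- if (preset == "paper_like") {
    list(n_chroms = 2L, length_bp = 1200000L,
         n_specific_a = 400L, n_specific_b = 480L, n_shared = 300L,
         width_range = c(300L, 700L), min_gap = 200L)
  } else {
    list(n_chroms = 2L, length_bp = 100000L,
         n_specific_a = 20L, n_specific_b = 30L, n_shared = 50L,
         width_range = c(300L, 800L), min_gap = 50L)
  }
  genome <- generate_genome(p$n_chroms, p$length_bp, gc = 0.41,
                            seed = sub[1])
  coh <- generate_cohorts(genome, n_a = 9L, n_b = 12L,
                          n_specific_a = p$n_specific_a,
                          n_specific_b = p$n_specific_b,
                          n_shared = p$n_shared, dropout = dropout,
                          width_range = p$width_range,
                          min_gap = p$min_gap, seed = sub[2])
  ann <- generate_annotations(coh$truth, genome, seed = sub[3])
  snv <- generate_snvs(genome, ann$truth, n_patients = 39L,
                       seed = sub[4])
  pwm <- generate_pwms(snv$truth, genome, seed = sub[5])
  truth <- pwm$truth

  ## validation target regions: +/- 50 bp around each planted SNV site
  sp <- truth$snv_plan
  tgt <- unique(sp[, c("element_id", "chrom", "pos")])
  tgt <- tgt[order(tgt$chrom, tgt$pos), , drop = FALSE]
  ## sites < 50 bp apart belong to one target amplicon
  keep <- rep(TRUE, nrow(tgt))
  if (nrow(tgt) > 1) {
    for (i in 2:nrow(tgt)) {
      if (tgt$chrom[i] == tgt$chrom[i - 1] &&
          tgt$pos[i] - tgt$pos[i - 1] < 50) keep[i] <- FALSE
    }
  }
  tgt <- tgt[keep, , drop = FALSE]
  val_regions <- data.frame(
    id = sprintf("TGT-%02d", seq_len(nrow(tgt))),
    chrom = tgt$chrom,
    start = as.integer(tgt$pos - 100L),  # midpoint == the discovery site
    end = as.integer(tgt$pos + 100L),
    stringsAsFactors = FALSE
  )
  n_val <- nrow(val_regions)
  geno_plan <- list(
    frequencies = rep_len(c(0.30, 0.15, 0.0, 0.12, 0.18), n_val),
    callability = rep_len(c(0.50, 0.95, 0.90, 0.90, 0.88), n_val),
    concordance = rep_len(c(0.60, 0.90, 1.00, 0.82, 0.78), n_val)
  )
  ## patient-level targets capped by the mutations the plan provides
  n_spec <- 54L + 11L
  m_tot <- sum(round_half_up(geno_plan$frequencies *
                               round_half_up(geno_plan$callability *
                                               n_spec)))
  n_cooc <- min(7L, m_tot %/% 2L)
  n_mut <- min(25L, m_tot - n_cooc)
  geno <- generate_genotype_table(
    regions = val_regions, genome = genome,
    frequencies = geno_plan$frequencies,
    callability = geno_plan$callability,
    concordance = geno_plan$concordance,
    n_cooccurring = n_cooc, n_mutated_patients = n_mut,
    seed = sub[6]
  )
  truth$genotype <- geno$truth

  sim <- list(genome = genome, cohort_a = coh$cohort_a,
              cohort_b = coh$cohort_b, tracks = ann$tracks,
              genes = ann$genes, curated = ann$curated,
              interactions = ann$interactions, snvs = snv$snvs,
              known_snps = snv$known_snps, pfms = pwm$pfms,
              genotype = geno[c("table", "mutations")], truth = truth,
              params = list(seed = seed, preset = preset,
                            dropout = dropout))
  if (!is.null(dir)) write_study(sim, dir)
  sim
}

#' Write a simulated study bundle to standard file formats
#'
#' @param sim A [simulate_study()] bundle.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  peak_dir <- file.path(dir, "peaks")
  dir.create(peak_dir, showWarnings = FALSE)
  sheet <- list()
  for (coh in list(sim$cohort_a, sim$cohort_b)) {
    for (sid in names(coh$samples)) {
      path <- file.path(peak_dir, paste0(sid, ".bed"))
      write_bed(coh$samples[[sid]], path)
      sheet[[length(sheet) + 1L]] <- data.frame(
        sample = sid, group = coh$group, path = path,
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, sheet),
                     file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tk in names(sim$tracks)) {
    write_bed(sim$tracks[[tk]], file.path(dir, paste0(tk, ".bed")))
  }
  write_bed(sim$genes, file.path(dir, "genes.bed"))
  writeLines(sim$curated, file.path(dir, "curated_genes.tsv"))
  utils::write.table(sim$interactions, file.path(dir, "interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vcf_dir <- file.path(dir, "vcf")
  dir.create(vcf_dir, showWarnings = FALSE)
  for (pt in unique(sim$snvs$patient)) {
    write_snv_vcf(sim$snvs[sim$snvs$patient == pt, , drop = FALSE],
                  file.path(vcf_dir, paste0(pt, ".vcf")))
  }
  utils::write.table(sim$known_snps, file.path(dir, "known_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_jaspar(sim$pfms, file.path(dir, "motifs.txt"))
  write_genotype_table(sim$genotype$table,
                       file.path(dir, "genotypes.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a study bundle back from the files written by [write_study()]
#'
#' Reconstructs the in-memory input bundle through the package's file
#' readers (FASTA, BED, VCF, JASPAR-style PFM text, TSV), so a
#' round-trip through disk exercises every parser.
#'
#' @param dir Directory written by [write_study()].
#' @return An input bundle equivalent to the one [simulate_study()]
#'   returns (the `truth` element is the deserialized JSON sidecar).
#' @export
read_study_inputs <- function(dir) {
  genome <- read_genome(file.path(dir, "genome.fa"))
  sheet <- utils::read.table(file.path(dir, "sample_sheet.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  cohorts <- lapply(split(sheet, sheet$group), function(g) {
    paths <- stats::setNames(g$path, g$sample)
    read_peak_cohort(g$group[1], paths)
  })
  groups <- unique(sheet$group)
  tracks <- read_annotation_tracks(file.path(dir, "promoter.bed"),
                                   file.path(dir, "insulator.bed"),
                                   file.path(dir, "enhancer.bed"))
  genes <- read_bed(file.path(dir, "genes.bed"))
  curated <- readLines(file.path(dir, "curated_genes.tsv"))
  interactions <- utils::read.table(file.path(dir, "interactions.tsv"),
                                    header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE)
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  snvs <- do.call(rbind, lapply(vcfs, function(v) {
    read_snv_vcf(v, sub("\\.vcf$", "", basename(v)))
  }))
  known_snps <- utils::read.table(file.path(dir, "known_snps.tsv"),
                                  header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  pfms <- read_jaspar(file.path(dir, "motifs.txt"))
  genotype <- read_genotype_table(file.path(dir, "genotypes.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(genome = genome, cohort_a = cohorts[[groups[1]]],
       cohort_b = cohorts[[groups[2]]], tracks = tracks, genes = genes,
       curated = curated, interactions = interactions, snvs = snvs,
       known_snps = known_snps, pfms = pfms,
       genotype = list(table = genotype), truth = truth)
}
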