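#' Pipeline configuration
#'
#' All tunables of the pipeline with their defaults. Fractions are in
#' `[0, 1]`; `f_max < f_min` is enforced before any compute.
#'
#' @param f_min Recurrence to call a region active in a group (0.5).
#' @param f_max Maximum other-group recurrence for a specific call (0.1).
#' @param class_priority Track priority for element classification.
#' @param flank Window half-width for TF scanning, bp (7: 15 bp window).
#' @param hotspot_gap Single-linkage hotspot gap, bp (7).
#' @param neighborhood_bp Gene-neighborhood half-width, bp (1e6).
#' @param top_k Ranked TF shortlist size (5).
#' @param top_n Candidate enhancers to report (3).
#' @param site_threshold Relative score for a binding-site call (0.80).
#' @param delta_min Minimum `|delta|` for gain/loss calls (0.05).
#' @param callability_threshold High-quality region flag (0.85).
#' @param concordance_threshold Multifocal concordance flag (0.75).
#' @param pseudocount PWM pseudocount per cell (0.25).
#' @param background PWM background base frequencies (uniform).
#' @param alpha_strict,alpha_ns Enrichment significance tiers.
#' @param seed Seed recorded in the report and used by any stage that
#'   needs randomness.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(f_min = 0.5, f_max = 0.1,
                            class_priority = c("promoter", "insulator",
                                               "enhancer"),
                            flank = 7L, hotspot_gap = 7L,
                            neighborhood_bp = 1e6, top_k = 5L,
                            top_n = 3L, site_threshold = 0.80,
                            delta_min = 0.05,
                            callability_threshold = 0.85,
                            concordance_threshold = 0.75,
                            pseudocount = 0.25,
                            background = rep(0.25, 4),
                            alpha_strict = 0.001, alpha_ns = 0.05,
                            seed = 1L) {
  config <- list(f_min = f_min, f_max = f_max,
                 class_priority = class_priority, flank = flank,
                 hotspot_gap = hotspot_gap,
                 neighborhood_bp = neighborhood_bp, top_k = top_k,
                 top_n = top_n, site_threshold = site_threshold,
                 delta_min = delta_min,
                 callability_threshold = callability_threshold,
                 concordance_threshold = concordance_threshold,
                 pseudocount = pseudocount, background = background,
                 alpha_strict = alpha_strict, alpha_ns = alpha_ns,
                 seed = seed)
  validate_config(config)
  config
}

validate_config <- function(config) {
  fr <- c("f_min", "f_max", "site_threshold", "delta_min",
          "callability_threshold", "concordance_threshold",
          "alpha_strict", "alpha_ns")
  for (f in fr) {
    v <- config[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop("config error: ", f, " must be a fraction in [0, 1]")
    }
  }
  if (config$f_max >= config$f_min) {
    stop("config error: f_max must be < f_min")
  }
  if (config$flank < 1) stop("config error: flank must be >= 1")
  stopifnot(config$top_k >= 1, config$top_n >= 1,
            config$hotspot_gap >= 0, config$pseudocount > 0)
  invisible(config)
}

#' Run the full pipeline on an input bundle
#'
#' Executes specificity calling, element classification and enrichment,
#' known-SNP filtering, SNV-enhancer mapping with hotspot clustering and
#' candidate prioritization, TF affinity scanning of the candidates'
#' SNVs, and the validation-cohort summaries, in that order. The report
#' is a deterministic function of (config, inputs): it carries no
#' timestamps, so identical runs serialize identically.
#'
#' @param inputs Input bundle as produced by [simulate_study()] or
#'   [read_study_inputs()]: `genome`, `cohort_a`, `cohort_b`, `tracks`,
#'   `genes`, `curated`, `interactions`, `snvs`, `known_snps`, `pfms`,
#'   `genotype`.
#' @param config A [pipeline_config()].
#' @param out Optional directory; when given, per-stage TSVs and the
#'   combined `report.json` are written there.
#' @return The report: a nested list with elements `parameters`,
#'   `specificity`, `enrichment`, `snv_filter`, `overlap`, `candidates`,
#'   `tf_scans`, `cohort`.
#' @export
run_all <- function(inputs, config = pipeline_config(), out = NULL) {
  validate_config(config)
  report <- list(parameters = config[setdiff(names(config), "background")])
  report$parameters$background <- as.numeric(config$background)

  ## stage 1: group-specific accessible regions
  calls <- call_specific_regions(inputs$cohort_a, inputs$cohort_b,
                                 f_min = config$f_min,
                                 f_max = config$f_max)
  report$specificity <- list(
    n_A_specific = sum(calls$status == "A_specific"),
    n_B_specific = sum(calls$status == "B_specific"),
    n_shared = sum(calls$status == "shared")
  )

  ## stage 2: element classification + enrichment
  cls_a <- classify_elements(calls[calls$status == "A_specific", ],
                             inputs$tracks, config$class_priority)
  cls_b <- classify_elements(calls[calls$status == "B_specific", ],
                             inputs$tracks, config$class_priority)
  enr <- enrichment_report(cls_a, cls_b,
                           alpha_strict = config$alpha_strict,
                           alpha_ns = config$alpha_ns)
  report$enrichment <- enr

  ## stage 3: somatic filter + SNV-enhancer overlap + prioritization
  flt <- filter_known_snps(inputs$snvs, inputs$known_snps)
  report$snv_filter <- list(n_input = nrow(inputs$snvs),
                            n_somatic = nrow(flt$somatic),
                            n_flagged = nrow(flt$flagged))
  ee_a <- cls_a[cls_a$class == "enhancer", , drop = FALSE]
  ee_a$id <- element_id(ee_a)
  mapping <- map_snvs_to_elements(flt$somatic, ee_a,
                                  genome = inputs$genome,
                                  hotspot_gap = config$hotspot_gap)
  candidates <- prioritize_candidates(
    mapping$profiles, inputs$genes, inputs$curated, inputs$interactions,
    top_n = config$top_n, neighborhood_bp = config$neighborhood_bp)
  report$overlap <- list(
    n_group_specific_enhancers = nrow(ee_a),
    n_mutated_enhancers = length(mapping$profiles),
    n_spillover_snvs = nrow(mapping$spillover)
  )
  report$candidates <- candidates

  ## stage 4: TF affinity scans of the candidates' SNVs
  pwms <- lapply(inputs$pfms, build_pwm,
                 pseudocount = config$pseudocount,
                 background = config$background)
  scans <- list()
  for (cid in candidates$element_id) {
    prof <- mapping$profiles[[cid]]
    alleles <- unique(prof$snvs[, c("chrom", "pos", "ref", "alt")])
    for (i in seq_len(nrow(alleles))) {
      snv <- alleles[i, , drop = FALSE]
      snv$patient <- "candidate"
      snv$origin <- "somatic"
      sc <- scan_variant(inputs$genome, pwms, snv, flank = config$flank,
                         top_k = config$top_k,
                         site_threshold = config$site_threshold,
                         delta_min = config$delta_min)
      key <- snv_key(snv$chrom, snv$pos, snv$ref, snv$alt)
      scans[[key]] <- list(element_id = cid, top = sc$top,
                           wt_window = sc$wt_window,
                           mut_window = sc$mut_window)
    }
  }
  report$tf_scans <- scans

  ## stage 5: validation-cohort summaries
  geno <- inputs$genotype$table
  callab <- region_callability(geno, config$callability_threshold)
  freqs <- mutation_frequencies(geno)
  cooc <- co_occurrence(geno)
  conc <- multifocal_concordance(geno, config$concordance_threshold)
  peri <- peritumoral_exclusivity(geno)
  report$cohort <- list(
    callability = callab$per_region,
    n_regions_callable = callab$n_above_threshold,
    frequency = freqs$per_region,
    burden = freqs$burden,
    n_cooccurring = nrow(cooc$patients),
    cooccurring_patients = cooc$patients,
    concordance = conc$per_region,
    n_regions_concordant = conc$n_above_threshold,
    tumor_exclusive = peri$tumor_exclusive
  )

  if (!is.null(out)) write_report(report, out)
  report
}

#' Write a pipeline report bundle
#'
#' @param report Output of [run_all()].
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
write_report <- function(report, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$enrichment,
                     file.path(out, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$candidates,
                     file.path(out, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(out)
}
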