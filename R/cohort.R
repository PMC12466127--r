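GENO_META_COLS <- c("specimen", "patient", "section", "compartment")

#' Validate a targeted-sequencing genotype table
#'
#' A genotype table has one row per tissue specimen with metadata columns
#' `specimen`, `patient`, `section`, `compartment`
#' (`tumor`/`peritumoral`) followed by one column per target region. Cell
#' values are `"WT"`, `"NS"` (non-sequenced) or a mutation call
#' `"chrom:posREF>ALT"`.
#'
#' @param table Genotype data.frame.
#' @param regions Optional interval table with `id` matching the region
#'   columns; when given, every MUT cell's position is checked to lie
#'   inside its column's region.
#' @return `table`, invisibly.
#' @export
validate_genotype_table <- function(table, regions = NULL) {
  if (!all(GENO_META_COLS %in% names(table))) {
    stop("genotype table needs columns ",
         paste(GENO_META_COLS, collapse = ", "))
  }
  if (nrow(table) == 0) stop("genotype table is empty")
  if (anyDuplicated(table$specimen)) stop("duplicated specimen IDs")
  if (!all(table$compartment %in% c("tumor", "peritumoral"))) {
    stop("compartment must be 'tumor' or 'peritumoral'")
  }
  for (rc in genotype_region_cols(table)) {
    cells <- table[[rc]]
    mut <- !(cells %in% c("WT", "NS"))
    if (any(mut)) {
      parsed <- parse_mut_cells(cells[mut])
      if (!is.null(regions)) {
        reg <- regions[regions$id == rc, , drop = FALSE]
        if (nrow(reg) == 1) {
          ok <- parsed$chrom == reg$chrom &
            vcf_pos_in_interval(parsed$pos, reg)
          if (!all(ok)) {
            stop("MUT call outside its region in column ", rc)
          }
        }
      }
    }
  }
  invisible(table)
}

genotype_region_cols <- function(table) {
  setdiff(names(table), GENO_META_COLS)
}

## parse "chrom:posREF>ALT" cells into an SNV-like data.frame
parse_mut_cells <- function(cells) {
  m <- regmatches(cells,
                  regexec("^([^:]+):([0-9]+)([ACGT])>([ACGT])$", cells))
  bad <- which(lengths(m) != 5)
  if (length(bad)) stop("unparseable genotype cell: ", cells[bad[1]])
  data.frame(
    chrom = vapply(m, `[`, "", 2),
    pos = as.integer(vapply(m, `[`, "", 3)),
    ref = vapply(m, `[`, "", 4),
    alt = vapply(m, `[`, "", 5),
    stringsAsFactors = FALSE
  )
}

#' Read / write a genotype table as TSV
#'
#' @param path TSV path.
#' @return The genotype data.frame.
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  validate_genotype_table(tab)
  tab
}

#' @rdname read_genotype_table
#' @param table Genotype data.frame.
#' @export
write_genotype_table <- function(table, path) {
  validate_genotype_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-region callability of a genotype table
#'
#' Callability is the fraction of tumor specimens with a sequencing call
#' (anything but `NS`) in a region. Peritumoral specimens are excluded.
#'
#' @param table Genotype table.
#' @param threshold Callability above which a region is flagged
#'   high-quality (strict `>`; default 0.85).
#' @return List with `per_region` (data.frame: `region`, `n_callable`,
#'   `n_total`, `fraction`, `above_threshold`) and `n_above_threshold`.
#' @export
region_callability <- function(table, threshold = 0.85) {
  validate_genotype_table(table)
  tumor <- table[table$compartment == "tumor", , drop = FALSE]
  if (nrow(tumor) == 0) stop("no tumor specimens in table")
  regions <- genotype_region_cols(table)
  per <- do.call(rbind, lapply(regions, function(rc) {
    callable <- sum(tumor[[rc]] != "NS")
    data.frame(region = rc, n_callable = callable, n_total = nrow(tumor),
               fraction = callable / nrow(tumor),
               stringsAsFactors = FALSE)
  }))
  per$above_threshold <- per$fraction > threshold
  list(per_region = per, n_above_threshold = sum(per$above_threshold))
}

#' Per-region mutation frequency and sample-level mutation burden
#'
#' Per-region frequency is `MUT / (MUT + WT)` over tumor specimens; `NS`
#' cells are excluded from the denominator (counting them as wild-type
#' would bias frequencies down). Burden is patient-level: the fraction of
#' tumor patients with at least one mutation in any region and section,
#' among patients with at least one callable region.
#'
#' @param table Genotype table.
#' @return List with `per_region` (data.frame: `region`, `n_mut`,
#'   `n_callable`, `frequency` — `NA` when no cell is callable) and
#'   `burden` (list: `n_mutated`, `n_eligible`, `fraction`).
#' @export
mutation_frequencies <- function(table) {
  validate_genotype_table(table)
  tumor <- table[table$compartment == "tumor", , drop = FALSE]
  if (nrow(tumor) == 0) stop("no tumor specimens in table")
  regions <- genotype_region_cols(table)
  per <- do.call(rbind, lapply(regions, function(rc) {
    cells <- tumor[[rc]]
    n_call <- sum(cells != "NS")
    n_mut <- sum(!(cells %in% c("WT", "NS")))
    data.frame(region = rc, n_mut = n_mut, n_callable = n_call,
               frequency = if (n_call > 0) n_mut / n_call else NA_real_,
               stringsAsFactors = FALSE)
  }))
  by_patient <- split(tumor, tumor$patient)
  eligible <- vapply(by_patient, function(p) {
    any(unlist(p[regions]) != "NS")
  }, logical(1))
  mutated <- vapply(by_patient, function(p) {
    any(!(unlist(p[regions]) %in% c("WT", "NS")))
  }, logical(1))
  n_elig <- sum(eligible)
  list(per_region = per,
       burden = list(n_mutated = sum(mutated & eligible),
                     n_eligible = n_elig,
                     fraction = if (n_elig > 0)
                       sum(mutated & eligible) / n_elig else NA_real_))
}

#' Patients mutated in two or more target regions
#'
#' Patient-level co-occurrence: a patient counts as mutated in a region
#' if any tumor section carries a MUT call there.
#'
#' @param table Genotype table.
#' @return List with `patients` (data.frame of patients with >= 2 mutated
#'   regions: `patient`, `n_mutated_regions`, `regions` comma-joined) and
#'   `comutation_matrix` (symmetric region x region counts of patients
#'   mutated in both, zero diagonal).
#' @export
co_occurrence <- function(table) {
  validate_genotype_table(table)
  tumor <- table[table$compartment == "tumor", , drop = FALSE]
  regions <- genotype_region_cols(table)
  by_patient <- split(tumor, tumor$patient)
  mut_regions <- lapply(by_patient, function(p) {
    regions[vapply(regions, function(rc) {
      any(!(p[[rc]] %in% c("WT", "NS")))
    }, logical(1))]
  })
  multi <- names(mut_regions)[lengths(mut_regions) >= 2]
  patients <- data.frame(
    patient = multi,
    n_mutated_regions = lengths(mut_regions)[multi],
    regions = vapply(mut_regions[multi], paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(patients) <- NULL
  mat <- matrix(0L, length(regions), length(regions),
                dimnames = list(regions, regions))
  for (mr in mut_regions) {
    if (length(mr) >= 2) {
      for (pair in utils::combn(mr, 2, simplify = FALSE)) {
        mat[pair[1], pair[2]] <- mat[pair[1], pair[2]] + 1L
        mat[pair[2], pair[1]] <- mat[pair[2], pair[1]] + 1L
      }
    }
  }
  list(patients = patients, comutation_matrix = mat)
}

#' Partition mutations into somatic and known-SNP-flagged sets
#'
#' A mutation is flagged iff its exact `(chrom, pos, ref, alt)` tuple is
#' in the known-SNP set — allele-aware, so a different alternate allele
#' at a catalogued position stays somatic.
#'
#' @param mutations SNV table.
#' @param snps Known-SNP set: data.frame with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return List with `somatic` and `flagged` SNV tables; row counts sum
#'   to the input count.
#' @export
filter_known_snps <- function(mutations, snps) {
  validate_snvs(mutations)
  if (nrow(mutations) == 0) {
    return(list(somatic = mutations, flagged = mutations))
  }
  keys <- snv_key(mutations$chrom, mutations$pos, mutations$ref,
                  mutations$alt)
  snp_keys <- if (nrow(snps)) {
    snv_key(snps$chrom, snps$pos, snps$ref, snps$alt)
  } else character(0)
  flagged <- keys %in% snp_keys
  list(somatic = mutations[!flagged, , drop = FALSE],
       flagged = mutations[flagged, , drop = FALSE])
}

#' Multifocal concordance between tumor sections
#'
#' For each region, among patients with at least two callable tumor
#' sections in that region, concordance is the fraction of patients
#' whose sections all carry an identical call (the same mutant allele,
#' or all wild-type). Regions above the threshold (strict `>`) are
#' flagged.
#'
#' @param table Genotype table.
#' @param threshold Concordance flag threshold (default 0.75).
#' @return List with `per_region` (data.frame: `region`,
#'   `n_multifocal`, `n_concordant`, `concordance`, `above_threshold`)
#'   and `n_above_threshold`. When no patient has two callable sections
#'   anywhere, an empty result is returned with a warning.
#' @export
multifocal_concordance <- function(table, threshold = 0.75) {
  validate_genotype_table(table)
  tumor <- table[table$compartment == "tumor", , drop = FALSE]
  regions <- genotype_region_cols(table)
  by_patient <- split(tumor, tumor$patient)
  per <- do.call(rbind, lapply(regions, function(rc) {
    calls <- lapply(by_patient, function(p) p[[rc]][p[[rc]] != "NS"])
    calls <- calls[lengths(calls) >= 2]
    n_conc <- sum(vapply(calls, function(x) length(unique(x)) == 1,
                         logical(1)))
    data.frame(region = rc, n_multifocal = length(calls),
               n_concordant = n_conc,
               concordance = if (length(calls) > 0)
                 n_conc / length(calls) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (all(per$n_multifocal == 0)) {
    warning("no patient has two or more callable sections in any region")
    per <- per[0, , drop = FALSE]
    return(list(per_region = per, n_above_threshold = 0L))
  }
  per$above_threshold <- !is.na(per$concordance) &
    per$concordance > threshold
  list(per_region = per, n_above_threshold = sum(per$above_threshold))
}

#' Tumor exclusivity of mutations vs peritumoral tissue
#'
#' For each patient with at least one tumor MUT call and at least one
#' peritumoral specimen, reports whether any peritumoral cell carries a
#' mutation. The summary flag `tumor_exclusive` is `TRUE` iff none does.
#'
#' @param table Genotype table; must contain peritumoral specimens.
#' @return List with `per_patient` (data.frame: `patient`,
#'   `n_peritumoral`, `peritumoral_mut`, `offending_specimens`) and
#'   `tumor_exclusive`.
#' @export
peritumoral_exclusivity <- function(table) {
  validate_genotype_table(table)
  peri <- table[table$compartment == "peritumoral", , drop = FALSE]
  if (nrow(peri) == 0) {
    stop("table contains no peritumoral specimens")
  }
  tumor <- table[table$compartment == "tumor", , drop = FALSE]
  regions <- genotype_region_cols(table)
  is_mut <- function(p) any(!(unlist(p[regions]) %in% c("WT", "NS")))
  mut_patients <- names(Filter(is_mut, split(tumor, tumor$patient)))
  eligible <- intersect(mut_patients, unique(peri$patient))
  per <- do.call(rbind, lapply(eligible, function(pt) {
    pp <- peri[peri$patient == pt, , drop = FALSE]
    mut_rows <- vapply(seq_len(nrow(pp)), function(i) {
      any(!(unlist(pp[i, regions]) %in% c("WT", "NS")))
    }, logical(1))
    data.frame(patient = pt, n_peritumoral = nrow(pp),
               peritumoral_mut = any(mut_rows),
               offending_specimens = paste(pp$specimen[mut_rows],
                                           collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per)) {
    per <- data.frame(patient = character(), n_peritumoral = integer(),
                      peritumoral_mut = logical(),
                      offending_specimens = character(),
                      stringsAsFactors = FALSE)
  }
  list(per_patient = per,
       tumor_exclusive = !any(per$peritumoral_mut))
}
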