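#' Construct a table of somatic SNV records
#'
#' @param chrom,pos,ref,alt,patient,origin Parallel vectors: chromosome,
#'   1-based position, reference and alternate single bases, patient ID,
#'   and origin flag (`somatic`, `germline` or `unknown`).
#' @return data.frame of validated SNV records.
#' @export
snv_records <- function(chrom, pos, ref, alt, patient,
                        origin = "somatic") {
  snvs <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    patient = as.character(patient),
    origin = rep_len(as.character(origin), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_snvs(snvs)
  snvs
}

validate_snvs <- function(snvs) {
  need <- c("chrom", "pos", "ref", "alt", "patient")
  if (!all(need %in% names(snvs))) {
    stop("SNV table needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(snvs) == 0) return(invisible(snvs))
  stopifnot(all(snvs$pos >= 1))
  if (any(nchar(snvs$ref) != 1 | nchar(snvs$alt) != 1)) {
    stop("SNV records must have single-base ref and alt")
  }
  if (any(!snvs$ref %in% c("A", "C", "G", "T")) ||
      any(!snvs$alt %in% c("A", "C", "G", "T"))) {
    stop("SNV alleles must be in {A,C,G,T}")
  }
  bad <- which(snvs$ref == snvs$alt)
  if (length(bad)) {
    stop("SNV with ref == alt at row ", bad[1])
  }
  if ("origin" %in% names(snvs) &&
      !all(snvs$origin %in% c("somatic", "germline", "unknown"))) {
    stop("origin must be somatic, germline or unknown")
  }
  invisible(snvs)
}

#' Read SNVs from a per-patient VCF
#'
#' Parses a VCF through `vcfR` and keeps single-nucleotide records only;
#' indels, multi-allelic and symbolic records are skipped and their count
#' reported as the `n_skipped` attribute.
#'
#' @param path Path to a VCF file.
#' @param patient Patient ID to attach to every record.
#' @param origin Origin flag for the records (default `"somatic"`).
#' @return SNV table (see [snv_records()]), with attribute `n_skipped`.
#' @export
read_snv_vcf <- function(path, patient, origin = "somatic") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0) {
    out <- snv_records(character(0), integer(0), character(0),
                       character(0), character(0))
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  out <- snv_records(fx[is_snv, "CHROM"], as.integer(fx[is_snv, "POS"]),
                     ref[is_snv], alt[is_snv], patient, origin)
  attr(out, "n_skipped") <- sum(!is_snv)
  out
}

#' Write SNVs as a minimal VCF 4.2 file
#'
#' @param snvs SNV table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(snvs, path) {
  validate_snvs(snvs)
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(snvs)) {
    o <- order(snvs$chrom, snvs$pos)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            snvs$chrom[o], snvs$pos[o], snvs$ref[o], snvs$alt[o])
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Map SNVs onto regulatory elements
#'
#' Intersects 1-based SNV positions with half-open element intervals and
#' builds one mutation profile per element carrying at least one SNV.
#' SNVs falling in no element are returned in a spill-over table rather
#' than dropped. When a genome is supplied, every SNV's ref allele is
#' checked against it.
#'
#' @param snvs SNV table.
#' @param elements Interval table with an `id` column (typically the
#'   enhancer-class subset of one group's specific regions).
#' @param genome Optional genome (named character vector) for ref-allele
#'   consistency checking.
#' @param hotspot_gap Gap (bp) used to cluster each profile's SNVs into
#'   hotspots (default 7; see [cluster_hotspots()]).
#' @return List with `profiles` (a list, one per mutated element:
#'   `element`, `snvs`, `n_patients`, `hotspots`) and `spillover` (SNV
#'   table of unassigned records).
#' @export
map_snvs_to_elements <- function(snvs, elements, genome = NULL,
                                 hotspot_gap = 7L) {
  validate_snvs(snvs)
  validate_intervals(elements)
  if (is.null(elements$id)) {
    elements$id <- sprintf("element_%04d", seq_len(nrow(elements)))
  }
  if (!is.null(genome) && nrow(snvs)) {
    obs <- vapply(seq_len(nrow(snvs)), function(i) {
      substr(genome[[snvs$chrom[i]]], snvs$pos[i], snvs$pos[i])
    }, character(1))
    bad <- which(obs != snvs$ref)
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "ref allele mismatch for %s (patient %s): genome has %s",
        snv_key(snvs$chrom[i], snvs$pos[i], snvs$ref[i], snvs$alt[i]),
        snvs$patient[i], obs[i]
      ))
    }
  }
  assigned <- rep(FALSE, nrow(snvs))
  profiles <- list()
  for (j in seq_len(nrow(elements))) {
    el <- elements[j, , drop = FALSE]
    inside <- snvs$chrom == el$chrom & vcf_pos_in_interval(snvs$pos, el)
    if (!any(inside)) next
    sub <- snvs[inside, , drop = FALSE]
    assigned <- assigned | inside
    profiles[[el$id]] <- list(
      element = el,
      snvs = sub,
      n_patients = length(unique(sub$patient)),
      hotspots = cluster_hotspots(sub, gap = hotspot_gap)
    )
  }
  list(profiles = profiles,
       spillover = snvs[!assigned, , drop = FALSE])
}

#' Cluster SNV positions into mutational hotspots
#'
#' Single-linkage clustering per chromosome: two SNVs belong to one
#' hotspot iff their positions are within `gap` bp of each other,
#' directly or transitively. On a line this reduces to splitting the
#' sorted positions wherever consecutive positions differ by more than
#' `gap`.
#'
#' @param snvs SNV table.
#' @param gap Maximum linking distance in bp (default 7).
#' @return data.frame, one row per cluster: `chrom`, `pos_min`,
#'   `pos_max`, `n_snvs`, `n_patients`.
#' @export
cluster_hotspots <- function(snvs, gap = 7L) {
  validate_snvs(snvs)
  stopifnot(gap >= 0)
  empty <- data.frame(chrom = character(), pos_min = integer(),
                      pos_max = integer(), n_snvs = integer(),
                      n_patients = integer(), stringsAsFactors = FALSE)
  if (nrow(snvs) == 0) return(empty)
  out <- list()
  for (ch in unique(snvs$chrom)) {
    sub <- snvs[snvs$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    brk <- c(0L, which(diff(sub$pos) > gap), nrow(sub))
    for (k in seq_len(length(brk) - 1L)) {
      members <- sub[(brk[k] + 1L):brk[k + 1L], , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos_min = min(members$pos), pos_max = max(members$pos),
        n_snvs = nrow(members),
        n_patients = length(unique(members$patient)),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$pos_min), , drop = FALSE]
}

## distance from an element's midpoint to a gene interval's nearest edge,
## in bp; 0 when the midpoint falls inside the gene
midpoint_gene_distance <- function(element, genes) {
  mid <- (element$start + element$end) %/% 2L  # 0-based midpoint base
  d <- rep(Inf, nrow(genes))
  same <- genes$chrom == element$chrom
  gs <- genes$start[same]; ge <- genes$end[same]
  dd <- ifelse(mid < gs, gs - mid, ifelse(mid >= ge, mid - (ge - 1L), 0L))
  d[same] <- dd
  d
}

#' Prioritize candidate mutated enhancers
#'
#' Ranks enhancer mutation profiles for follow-up. Recurrence across
#' patients outranks raw SNV count; curated disease genes in the
#' neighborhood and high-confidence enhancer-gene interactions act as
#' successive tiebreaks, and the element ID as the final deterministic
#' tiebreak. The full lexicographic key, all descending except the last:
#' (distinct patients, SNV count, curated genes within the neighborhood,
#' has high-confidence interaction, element ID ascending).
#'
#' @param profiles `profiles` list from [map_snvs_to_elements()].
#' @param genes Interval table of gene bodies with a `name` column.
#' @param curated Character vector of curated disease-gene symbols
#'   (subset of `genes$name`); `NULL` treats every gene as curated.
#' @param interactions Optional data.frame of enhancer-gene links with
#'   columns `element_id`, `gene`, `confidence` (`high`/`low`).
#' @param top_n Number of candidates to return (default 3).
#' @param neighborhood_bp Gene-neighborhood half-width around the element
#'   midpoint, in bp (default 1e6, i.e., a 2 Mb window).
#' @return data.frame of the top `top_n` candidates: element coordinates
#'   and ID, `n_patients`, `n_snvs`, `n_hotspots`, `n_nearby_curated`,
#'   `nearby_curated` (comma-joined symbols), `high_conf_interaction`,
#'   `rank`.
#' @export
prioritize_candidates <- function(profiles, genes, curated = NULL,
                                  interactions = NULL, top_n = 3L,
                                  neighborhood_bp = 1e6) {
  stopifnot(top_n >= 1)
  if (length(profiles) == 0) {
    return(data.frame(element_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_patients = integer(), n_snvs = integer(),
                      n_hotspots = integer(), n_nearby_curated = integer(),
                      nearby_curated = character(),
                      high_conf_interaction = logical(), rank = integer(),
                      stringsAsFactors = FALSE))
  }
  validate_intervals(genes)
  if (is.null(curated)) curated <- genes$name
  rows <- lapply(profiles, function(p) {
    el <- p$element
    d <- midpoint_gene_distance(el, genes)
    nearby <- genes$name[d <= neighborhood_bp & genes$name %in% curated]
    has_high <- !is.null(interactions) && nrow(interactions) > 0 &&
      any(interactions$element_id == el$id &
            interactions$confidence == "high")
    data.frame(
      element_id = el$id, chrom = el$chrom, start = el$start, end = el$end,
      n_patients = p$n_patients, n_snvs = nrow(p$snvs),
      n_hotspots = nrow(p$hotspots),
      n_nearby_curated = length(nearby),
      nearby_curated = paste(sort(nearby), collapse = ","),
      high_conf_interaction = has_high,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  o <- order(-tab$n_patients, -tab$n_snvs, -tab$n_nearby_curated,
             -as.integer(tab$high_conf_interaction), tab$element_id)
  tab <- tab[o, , drop = FALSE]
  tab <- utils::head(tab, top_n)
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
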