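#' Construct a peak cohort
#'
#' A cohort is one tumor group's per-sample sets of already-called
#' chromatin-accessibility peaks (e.g., ATAC-seq peak BED files).
#'
#' @param group Group label, e.g. `"GBM"`.
#' @param samples Named list: one interval table (see
#'   [genomic_intervals()]) per sample, names are sample IDs.
#' @return A `peak_cohort` object (list with `group`, `samples`).
#' @export
peak_cohort <- function(group, samples) {
  stopifnot(is.character(group), length(group) == 1, nzchar(group))
  if (length(samples) == 0) stop("cohort must contain at least one sample")
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    stop("samples must be a named list (names are sample IDs)")
  }
  lapply(samples, validate_intervals)
  structure(list(group = group, samples = samples), class = "peak_cohort")
}

#' Read a peak cohort from per-sample BED files
#'
#' @param group Group label.
#' @param paths Named character vector of BED paths (names = sample IDs).
#' @return A [peak_cohort()].
#' @export
read_peak_cohort <- function(group, paths) {
  peak_cohort(group, lapply(paths, read_bed))
}

## recurrence of each region of `regions` in a cohort: fraction of samples
## with >= 1 bp of peak overlapping the region
region_recurrence <- function(regions, cohort) {
  gr <- intervals_to_granges(regions)
  hits <- integer(nrow(regions))
  for (s in cohort$samples) {
    hits <- hits + as.integer(
      GenomicRanges::countOverlaps(gr, intervals_to_granges(s)) > 0
    )
  }
  hits / length(cohort$samples)
}

#' Recurrently accessible regions of one cohort
#'
#' Merges the union of all samples' peaks and computes, for each merged
#' region, the fraction of samples carrying at least one peak with >= 1 bp
#' of overlap. Regions at or above `f_min` recurrence are returned.
#'
#' @param cohort A [peak_cohort()].
#' @param f_min Minimum recurrence fraction in `(0, 1]` (default 0.5).
#' @return Interval table with a `recurrence` column, restricted to
#'   regions with `recurrence >= f_min`.
#' @export
recurrent_regions <- function(cohort, f_min = 0.5) {
  stopifnot(inherits(cohort, "peak_cohort"), f_min > 0, f_min <= 1)
  merged <- merge_intervals(do.call(rbind, lapply(cohort$samples, function(s) {
    s[, c("chrom", "start", "end", "strand")]
  })))
  if (nrow(merged) == 0) {
    merged$recurrence <- numeric(0)
    return(merged)
  }
  merged$recurrence <- region_recurrence(merged, cohort)
  merged[merged$recurrence >= f_min, , drop = FALSE]
}

#' Call group-specific and shared accessible regions
#'
#' Partitions the recurrently accessible chromatin of two cohorts into
#' A-specific, B-specific and shared regions. The region universe is the
#' merged union of every sample's peaks across both cohorts; for each
#' merged region the per-cohort recurrence (fraction of samples with
#' >= 1 bp peak overlap) decides its status:
#' \itemize{
#'   \item \strong{A_specific}: recurrence_A >= `f_min` and
#'     recurrence_B <= `f_max` (symmetric for B_specific);
#'   \item \strong{shared}: recurrent (>= `f_min`) in at least one cohort
#'     and specific to neither.
#' }
#' Regions recurrent in neither cohort are dropped (they are not "active"
#' anywhere). Statuses are mutually exclusive and every recurrent region
#' receives exactly one.
#'
#' @param cohort_a,cohort_b Two [peak_cohort()]s.
#' @param f_min Recurrence threshold to call a region active in a group
#'   (default 0.5).
#' @param f_max Maximum recurrence tolerated in the other group for a
#'   specific call (default 0.1). Must satisfy `f_max < f_min`.
#' @return A data.frame of specificity calls: `chrom`, `start`, `end`,
#'   `status` (`A_specific` / `B_specific` / `shared`), `recurrence_A`,
#'   `recurrence_B`, and the two group labels as attributes.
#' @export
call_specific_regions <- function(cohort_a, cohort_b,
                                  f_min = 0.5, f_max = 0.1) {
  stopifnot(inherits(cohort_a, "peak_cohort"),
            inherits(cohort_b, "peak_cohort"))
  if (!(f_min > 0 && f_min <= 1 && f_max >= 0)) {
    stop("need 0 < f_min <= 1 and f_max >= 0")
  }
  if (f_max >= f_min) stop("config error: f_max must be < f_min")
  all_peaks <- do.call(rbind, c(
    lapply(cohort_a$samples, function(s) s[, c("chrom", "start", "end", "strand")]),
    lapply(cohort_b$samples, function(s) s[, c("chrom", "start", "end", "strand")])
  ))
  merged <- merge_intervals(all_peaks)
  if (nrow(merged) == 0) {
    out <- merged
    out$status <- character(0)
    out$recurrence_A <- out$recurrence_B <- numeric(0)
    return(out)
  }
  rec_a <- region_recurrence(merged, cohort_a)
  rec_b <- region_recurrence(merged, cohort_b)
  keep <- rec_a >= f_min | rec_b >= f_min
  out <- merged[keep, , drop = FALSE]
  ra <- rec_a[keep]
  rb <- rec_b[keep]
  status <- ifelse(ra >= f_min & rb <= f_max, "A_specific",
            ifelse(rb >= f_min & ra <= f_max, "B_specific", "shared"))
  out$status <- status
  out$recurrence_A <- ra
  out$recurrence_B <- rb
  rownames(out) <- NULL
  attr(out, "group_A") <- cohort_a$group
  attr(out, "group_B") <- cohort_b$group
  out
}

#' Write specificity calls as per-status BED files plus a TSV summary
#'
#' @param calls Output of [call_specific_regions()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_specificity_calls <- function(calls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (st in unique(calls$status)) {
    sub <- calls[calls$status == st, , drop = FALSE]
    sub$name <- sprintf("%s_%04d", st, seq_len(nrow(sub)))
    sub$score <- ifelse(st == "B_specific", sub$recurrence_B, sub$recurrence_A)
    p <- file.path(dir, paste0(st, ".bed"))
    write_bed(sub, p)
    paths <- c(paths, p)
  }
  summ <- as.data.frame(table(status = calls$status))
  sp <- file.path(dir, "specificity_summary.tsv")
  utils::write.table(summ, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sp))
}
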