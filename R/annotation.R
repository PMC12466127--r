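#' Bundle promoter / insulator / enhancer annotation tracks
#'
#' Each track is merged internally so that no two intervals of one track
#' overlap; classification then reduces to a single overlap query per
#' track.
#'
#' @param promoter,insulator,enhancer Interval tables.
#' @return An `annotation_tracks` object.
#' @export
annotation_tracks <- function(promoter, insulator, enhancer) {
  tracks <- list(
    promoter = merge_intervals(promoter),
    insulator = merge_intervals(insulator),
    enhancer = merge_intervals(enhancer)
  )
  structure(tracks, class = "annotation_tracks")
}

#' Read annotation tracks from BED files
#'
#' @param promoter,insulator,enhancer Paths to BED files.
#' @return An [annotation_tracks()] object.
#' @export
read_annotation_tracks <- function(promoter, insulator, enhancer) {
  annotation_tracks(read_bed(promoter), read_bed(insulator),
                    read_bed(enhancer))
}

#' Classify regions into regulatory-element classes
#'
#' Assigns each region exactly one class by priority: the first track in
#' `priority` with at least 1 bp of overlap wins; a region overlapping no
#' track is classed `"other"`. The default priority
#' promoter > insulator (IE) > enhancer (EE) reflects that promoters are
#' the most confidently mapped element class.
#'
#' @param regions Interval table (typically specificity calls).
#' @param tracks An [annotation_tracks()] object.
#' @param priority Character vector ordering the track names.
#' @return `regions` with an added `class` column over
#'   `{promoter, insulator, enhancer, other}`.
#' @export
classify_elements <- function(regions, tracks,
                              priority = c("promoter", "insulator",
                                           "enhancer")) {
  stopifnot(inherits(tracks, "annotation_tracks"),
            setequal(priority, names(tracks)))
  validate_intervals(regions)
  cls <- rep("other", nrow(regions))
  if (nrow(regions)) {
    gr <- intervals_to_granges(regions)
    for (track_name in rev(priority)) {
      trk <- tracks[[track_name]]
      if (nrow(trk) == 0) next
      hit <- GenomicRanges::countOverlaps(gr, intervals_to_granges(trk)) > 0
      cls[hit] <- track_name
    }
  }
  regions$class <- cls
  regions
}

#' Chi-square test for class enrichment between two groups
#'
#' Pearson chi-square on the 2x2 table
#' `[[count_A, total_A - count_A], [count_B, total_B - count_B]]` with one
#' degree of freedom and no continuity correction, via the closed form
#' `chi2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. With group totals in
#' the tens of thousands the Yates correction is immaterial; omitting it
#' keeps the statistic bit-reproducible against the closed form.
#'
#' @param count_a,total_a Count of the class and total regions in group A.
#' @param count_b,total_b Same for group B.
#' @return List with `chi2`, `p_value` (two-sided, 1 df) and the table.
#' @export
class_enrichment_test <- function(count_a, total_a, count_b, total_b) {
  stopifnot(count_a >= 0, count_b >= 0,
            count_a <= total_a, count_b <= total_b,
            total_a > 0, total_b > 0)
  a <- count_a; b <- total_a - count_a
  c_ <- count_b; d <- total_b - count_b
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    stop("undefined chi-square statistic: a marginal total is zero")
  }
  chi2 <- n * (a * d - b * c_)^2 / prod(margins)
  list(
    chi2 = chi2,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    table = matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("in_class", "not_in_class")))
  )
}

#' Per-class enrichment report between two classified region sets
#'
#' For each element class (promoter, insulator, enhancer) compares the
#' class proportion between groups A and B with
#' [class_enrichment_test()]. Two significance tiers are annotated,
#' mirroring the conventional figure legend: `significant` at
#' `alpha_strict` (default 0.001) and `ns` above `alpha_ns` (default
#' 0.05).
#'
#' @param classified_a,classified_b Outputs of [classify_elements()] for
#'   the two groups (must be non-empty).
#' @param alpha_strict Strict significance level (default 0.001).
#' @param alpha_ns Non-significance level (default 0.05).
#' @return data.frame with one row per class: counts, totals,
#'   proportions, `chi2`, `p_value`, `significant`, `ns`.
#' @export
enrichment_report <- function(classified_a, classified_b,
                              alpha_strict = 0.001, alpha_ns = 0.05) {
  if (nrow(classified_a) == 0 || nrow(classified_b) == 0) {
    stop("both classification tables must be non-empty")
  }
  classes <- c("promoter", "insulator", "enhancer")
  total_a <- nrow(classified_a)
  total_b <- nrow(classified_b)
  rows <- lapply(classes, function(cl) {
    ca <- sum(classified_a$class == cl)
    cb <- sum(classified_b$class == cl)
    tst <- class_enrichment_test(ca, total_a, cb, total_b)
    data.frame(
      class = cl,
      count_A = ca, total_A = total_a, prop_A = ca / total_a,
      count_B = cb, total_B = total_b, prop_B = cb / total_b,
      chi2 = tst$chi2, p_value = tst$p_value,
      significant = tst$p_value < alpha_strict,
      ns = tst$p_value > alpha_ns,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
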