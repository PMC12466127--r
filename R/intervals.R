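#' @importFrom GenomicRanges GRanges reduce findOverlaps countOverlaps seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols
NULL

#' Construct a table of genomic intervals
#'
#' All region coordinates in the package are BED-style: 0-based,
#' half-open `[start, end)`. Variant positions, by contrast, are VCF-style
#' 1-based; [vcf_pos_in_interval()] is the single conversion point between
#' the two conventions.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, 0-based exclusive end coordinates.
#' @param strand Strand, one of `"+"`, `"-"`, `"."` (default `"."`).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  iv <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(iv)
  iv
}

#' Validate an interval table
#'
#' Checks the invariants `0 <= start < end`, non-empty chromosome names and
#' legal strand codes. Called by every operation that consumes intervals.
#'
#' @param iv A data.frame with at least `chrom`, `start`, `end` columns.
#' @return `iv`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(iv))) {
    stop("interval table must have columns chrom, start, end")
  }
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(is.na(iv$chrom)) || any(!nzchar(iv$chrom))) {
    stop("interval with empty chromosome name")
  }
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad)) {
    stop(sprintf(
      "malformed interval (need 0 <= start < end) at row %d: %s:%d-%d",
      bad[1], iv$chrom[bad[1]], iv$start[bad[1]], iv$end[bad[1]]
    ))
  }
  if ("strand" %in% names(iv) && !all(iv$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  invisible(iv)
}

## BED half-open [start, end) <-> GRanges 1-based closed [start+1, end]
intervals_to_granges <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end))
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = ".",
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping and abutting intervals
#'
#' Returns the union of the input intervals as a sorted, non-redundant set.
#' Abutting intervals (`end == start` under the half-open convention) are
#' merged: regulatory regions are treated as closed genomic segments.
#'
#' @param iv Interval table (see [genomic_intervals()]).
#' @return Interval table sorted by `(chrom, start)` in which no two
#'   intervals on the same chromosome overlap or abut. The set of covered
#'   bases is exactly preserved.
#' @examples
#' merge_intervals(genomic_intervals(rep("chr1", 2), c(0, 5), c(10, 15)))
#' @export
merge_intervals <- function(iv) {
  validate_intervals(iv)
  if (nrow(iv) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  out <- granges_to_intervals(GenomicRanges::reduce(intervals_to_granges(iv)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Do two intervals overlap?
#'
#' @param a,b Single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return `TRUE` iff the intervals share a chromosome and at least one
#'   base. Half-open semantics: `[0,10)` and `[10,20)` do not overlap.
#' @export
intervals_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

#' Does a 1-based variant position fall inside a half-open interval?
#'
#' The single VCF-to-BED conversion point: a variant at 1-based position
#' `pos` occupies 0-based position `pos - 1`.
#'
#' @param pos Integer vector of 1-based positions (`pos >= 1`).
#' @param iv A single interval (list or one-row data.frame).
#' @return Logical vector, `TRUE` where `iv$start <= pos - 1 < iv$end`.
#' @export
vcf_pos_in_interval <- function(pos, iv) {
  stopifnot(all(pos >= 1))
  p0 <- pos - 1L
  iv$start <= p0 & p0 < iv$end
}

#' Read a BED file into an interval table
#'
#' Reads BED3/BED6 (tab-separated, no header, 0-based half-open) through
#' `rtracklayer`. Columns beyond the first three are preserved as `name`,
#' `score`, `strand` when present.
#'
#' @param path Path to a BED file.
#' @return Interval table; `name`/`score` columns added when present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  iv <- granges_to_intervals(gr)
  m <- S4Vectors::mcols(gr)
  if (!is.null(m$name)) iv$name <- as.character(m$name)
  if (!is.null(m$score)) iv$score <- as.numeric(m$score)
  st <- as.character(GenomicRanges::strand(gr))
  iv$strand <- ifelse(st == "*", ".", st)
  validate_intervals(iv)
  iv
}

#' Write an interval table to a BED file
#'
#' Writes BED6 when `name`/`score` columns are present, BED3 otherwise.
#'
#' @param iv Interval table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  gr <- intervals_to_granges(iv)
  if (!is.null(iv$name)) S4Vectors::mcols(gr)$name <- iv$name
  if (!is.null(iv$score)) S4Vectors::mcols(gr)$score <- iv$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
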