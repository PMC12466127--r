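DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position frequency matrix (PFM)
#'
#' @param name TF name.
#' @param id Matrix identifier.
#' @param counts Numeric 4 x L matrix of non-negative base counts, rows
#'   A, C, G, T; L >= 4 and every column sum > 0.
#' @return A `pfm` object.
#' @export
pfm <- function(name, id, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("PFM needs 4 rows (A, C, G, T)")
  rownames(counts) <- DNA_BASES
  if (ncol(counts) < 4) stop("PFM must have at least 4 columns")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("PFM column with zero total count")
  structure(list(name = name, id = id, counts = counts), class = "pfm")
}

#' Read a JASPAR-style PFM text file
#'
#' Expected format per motif: a `>ID NAME` header followed by four rows
#' `A [ n1 n2 ... ]` ... `T [ ... ]` (brackets optional).
#'
#' @param path Path to the PFM text file.
#' @return Named list of [pfm()] objects (names are TF names).
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no PFM headers found in ", path)
  out <- list()
  for (k in seq_along(hdr)) {
    top <- hdr[k]
    bottom <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    fields <- strsplit(sub("^>\\s*", "", lines[top]), "\\s+")[[1]]
    id <- fields[1]
    name <- if (length(fields) >= 2) fields[2] else fields[1]
    block <- lines[(top + 1):bottom]
    rows <- lapply(DNA_BASES, function(b) {
      ln <- grep(paste0("^", b, "\\b"), block, value = TRUE)
      if (length(ln) != 1) stop("PFM ", id, ": missing or duplicated ", b, " row")
      nums <- gsub("[][]", " ", sub(paste0("^", b), "", ln))
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop("PFM ", id, ": ragged count rows")
    out[[name]] <- pfm(name, id, do.call(rbind, rows))
  }
  out
}

#' Write PFMs in JASPAR-style text
#'
#' @param pfms Named list of [pfm()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(sprintf(">%s %s", p$id, p$name),
      vapply(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(p$counts[b, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Build a log-odds position weight matrix from a PFM
#'
#' Per cell, `w[b, j] = log2(((counts[b, j] + pseudocount) /
#' (colsum_j + 4 * pseudocount)) / background[b])`. The achievable score
#' extremes `S_min = sum_j min_b w[b, j]` and `S_max = sum_j max_b
#' w[b, j]` are stored for min-max normalization of alignment scores.
#'
#' @param x A [pfm()] object.
#' @param pseudocount Pseudocount added to every cell (default 0.25).
#' @param background Background base frequencies (A, C, G, T), summing to
#'   1, all positive; default uniform.
#' @return A `pwm` object: `name`, `id`, `w` (4 x L weights), `s_min`,
#'   `s_max`, `length`. An uninformative motif (`s_min == s_max`) is
#'   rejected.
#' @export
build_pwm <- function(x, pseudocount = 0.25,
                      background = rep(0.25, 4)) {
  stopifnot(inherits(x, "pfm"), pseudocount > 0, length(background) == 4,
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  counts <- x$counts
  colsum <- colSums(counts)
  if (any(colsum <= 0)) stop("PFM column with zero total count")
  prob <- sweep(counts + pseudocount, 2, colsum + 4 * pseudocount, "/")
  w <- log2(prob / background)
  s_min <- sum(apply(w, 2, min))
  s_max <- sum(apply(w, 2, max))
  if (s_max - s_min <= 1e-12) {
    stop("degenerate motif ", x$name, ": S_min equals S_max")
  }
  structure(list(name = x$name, id = x$id, w = w,
                 s_min = s_min, s_max = s_max, length = ncol(w)),
            class = "pwm")
}

## raw PWM alignment score of `chars` (length L character vector) --
## N bases contribute the background-expected weight 0
pwm_raw_score <- function(w, chars) {
  s <- 0
  for (j in seq_along(chars)) {
    b <- chars[j]
    if (b != "N") s <- s + w[b, j]
  }
  unname(s)
}

#' Best relative PWM score over alignments covering a position
#'
#' Scans every alignment offset, on both strands, at which the motif
#' covers the `must_cover` position of the window (for the minus strand,
#' coverage is assessed after reverse-complementing the window), and
#' returns the min-max normalized best score
#' `rel = (S_best - S_min) / (S_max - S_min)`, in `[0, 1]`. Constraining
#' the scan to variant-covering alignments guarantees that a wild-type vs
#' mutant score difference can only arise where the variant base is
#' actually scored. `N` bases are scored with weight 0 (their background
#' expectation).
#'
#' @param pwm A [build_pwm()] object.
#' @param window DNA string, length >= motif length.
#' @param must_cover 1-based index in `window` that every scored
#'   alignment must cover; defaults to the center.
#' @return List with `rel` in `[0, 1]`, `offset` (1-based alignment start
#'   in the scanned-strand window) and `strand` of the best alignment.
#' @export
relative_score <- function(pwm, window,
                           must_cover = (nchar(window) + 1L) %/% 2L) {
  stopifnot(inherits(pwm, "pwm"))
  wlen <- nchar(window)
  L <- pwm$length
  if (L > wlen) {
    stop("motif ", pwm$name, " (length ", L,
         ") longer than window (length ", wlen, ")")
  }
  stopifnot(must_cover >= 1, must_cover <= wlen)
  best <- -Inf
  best_offset <- NA_integer_
  best_strand <- NA_character_
  for (strand in c("+", "-")) {
    seq_chars <- strsplit(if (strand == "+") window else revcomp(window),
                          "")[[1]]
    cover <- if (strand == "+") must_cover else wlen + 1L - must_cover
    off_lo <- max(1L, cover - L + 1L)
    off_hi <- min(wlen - L + 1L, cover)
    if (off_lo > off_hi) next
    for (o in off_lo:off_hi) {
      s <- pwm_raw_score(pwm$w, seq_chars[o:(o + L - 1L)])
      if (s > best) {
        best <- s
        best_offset <- o
        best_strand <- strand
      }
    }
  }
  list(rel = (best - pwm$s_min) / (pwm$s_max - pwm$s_min),
       offset = best_offset, strand = best_strand)
}

#' Wild-type vs mutant binding-affinity shifts across a PWM library
#'
#' Scores both alleles' windows with [relative_score()] (alignments
#' constrained to cover the center, i.e., the variant base) and
#' categorizes each TF's shift:
#' \itemize{
#'   \item \strong{novel}: `wt_rel < site_threshold <= mut_rel` — the
#'     variant creates a motif match where none existed;
#'   \item \strong{lost_site}: `mut_rel < site_threshold <= wt_rel`;
#'   \item \strong{gain} / \strong{loss}: `|delta| >= delta_min` without
#'     crossing the site threshold;
#'   \item \strong{neutral}: otherwise.
#' }
#'
#' @param pwms Named list of [build_pwm()] objects.
#' @param wt_window,mut_window Equal-length DNA windows identical except
#'   at the center base.
#' @param site_threshold Relative score at or above which a sequence is
#'   called a binding site (default 0.80).
#' @param delta_min Minimum `|mut_rel - wt_rel|` for a gain/loss call
#'   (default 0.05).
#' @return data.frame, one row per TF: `tf`, `wt_rel`, `mut_rel`,
#'   `delta`, `category`, `wt_offset`, `wt_strand`, `mut_offset`,
#'   `mut_strand`.
#' @export
affinity_shift <- function(pwms, wt_window, mut_window,
                           site_threshold = 0.80, delta_min = 0.05) {
  wlen <- nchar(wt_window)
  if (nchar(mut_window) != wlen) stop("windows must have equal length")
  center <- (wlen + 1L) %/% 2L
  wt_chars <- strsplit(wt_window, "")[[1]]
  mut_chars <- strsplit(mut_window, "")[[1]]
  diff_at <- which(wt_chars != mut_chars)
  if (!identical(diff_at, center)) {
    stop("windows must differ at the center base and nowhere else")
  }
  empty <- data.frame(tf = character(), wt_rel = numeric(),
                      mut_rel = numeric(), delta = numeric(),
                      category = character(), wt_offset = integer(),
                      wt_strand = character(), mut_offset = integer(),
                      mut_strand = character(), stringsAsFactors = FALSE)
  if (length(pwms) == 0) return(empty)
  rows <- lapply(pwms, function(p) {
    wt <- relative_score(p, wt_window, must_cover = center)
    mut <- relative_score(p, mut_window, must_cover = center)
    delta <- mut$rel - wt$rel
    category <-
      if (wt$rel < site_threshold && mut$rel >= site_threshold) "novel"
      else if (mut$rel < site_threshold && wt$rel >= site_threshold) "lost_site"
      else if (delta >= delta_min) "gain"
      else if (delta <= -delta_min) "loss"
      else "neutral"
    data.frame(tf = p$name, wt_rel = wt$rel, mut_rel = mut$rel,
               delta = delta, category = category,
               wt_offset = wt$offset, wt_strand = wt$strand,
               mut_offset = mut$offset, mut_strand = mut$strand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Top-K affinity shifts
#'
#' Orders shifts by `|delta|` descending, ties by
#' `max(wt_rel, mut_rel)` descending, then TF name ascending, and returns
#' the first `k`.
#'
#' @param shifts Output of [affinity_shift()].
#' @param k Number of shifts to keep (default 5).
#' @return The top `k` rows, re-ranked.
#' @export
rank_top_k <- function(shifts, k = 5L) {
  stopifnot(k >= 1)
  if (nrow(shifts) == 0) return(shifts)
  o <- order(-abs(shifts$delta), -pmax(shifts$wt_rel, shifts$mut_rel),
             shifts$tf)
  out <- utils::head(shifts[o, , drop = FALSE], k)
  rownames(out) <- NULL
  out
}

#' Scan one SNV against a PWM library
#'
#' Composition of [extract_window()], center-base substitution,
#' [affinity_shift()] and [rank_top_k()]: the end-to-end
#' variant-to-binding-shift operation for a single somatic SNV.
#'
#' @param genome Named character vector (see [read_genome()]).
#' @param pwms Named list of [build_pwm()] objects.
#' @param snv One-row SNV table (see [snv_records()]).
#' @param flank Window half-width in bp (default 7, a 15 bp window).
#' @param top_k Size of the ranked shortlist (default 5).
#' @param site_threshold,delta_min Passed to [affinity_shift()].
#' @return List with `shifts` (full table), `top` (ranked top-K),
#'   `wt_window`, `mut_window`.
#' @export
scan_variant <- function(genome, pwms, snv, flank = 7L, top_k = 5L,
                         site_threshold = 0.80, delta_min = 0.05) {
  validate_snvs(snv)
  stopifnot(nrow(snv) == 1)
  wt_window <- extract_window(genome, snv$chrom, snv$pos, flank)
  obs <- substr(wt_window, flank + 1L, flank + 1L)
  if (obs != snv$ref) {
    stop(sprintf("ref allele mismatch at %s:%d: expected %s, genome has %s",
                 snv$chrom, snv$pos, snv$ref, obs))
  }
  mut_window <- wt_window
  substr(mut_window, flank + 1L, flank + 1L) <- snv$alt
  shifts <- affinity_shift(pwms, wt_window, mut_window,
                           site_threshold = site_threshold,
                           delta_min = delta_min)
  list(shifts = shifts, top = rank_top_k(shifts, top_k),
       wt_window = wt_window, mut_window = mut_window)
}
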