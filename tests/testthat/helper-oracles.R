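# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (no merge_intervals, no relative_score) so that tests
# compare two independent routes to the same answer.

## set of 0-based covered positions, encoded "chrom:pos"
covered_bases <- function(iv) {
  unlist(lapply(seq_len(nrow(iv)), function(i) {
    paste0(iv$chrom[i], ":", seq(iv$start[i], iv$end[i] - 1L))
  }), use.names = FALSE)
}

## per-base chromosome occupancy count across a list of interval tables
base_occupancy <- function(sample_list, chrom, len) {
  occ <- matrix(0L, nrow = length(sample_list), ncol = len)
  for (s in seq_along(sample_list)) {
    iv <- sample_list[[s]]
    iv <- iv[iv$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      occ[s, (iv$start[i] + 1L):iv$end[i]] <- 1L
    }
  }
  occ
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
        collapse = "")
}

## exhaustive (offset x strand) PWM scan, independent of relative_score()
oracle_relative_score <- function(w, s_min, s_max, window, must_cover) {
  L <- ncol(w)
  wlen <- nchar(window)
  best <- -Inf
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") window else oracle_revcomp(window)
    cover <- if (strand == "+") must_cover else wlen + 1L - must_cover
    for (o in seq_len(wlen - L + 1L)) {
      if (!(o <= cover && cover <= o + L - 1L)) next
      chars <- strsplit(substr(seq, o, o + L - 1L), "")[[1]]
      s <- 0
      for (j in seq_len(L)) {
        if (chars[j] != "N") s <- s + w[chars[j], j]
      }
      best <- max(best, s)
    }
  }
  (best - s_min) / (s_max - s_min)
}

## connected components of the |pos_i - pos_j| <= gap graph
oracle_hotspot_count <- function(positions, gap) {
  n <- length(positions)
  adj <- outer(positions, positions,
               function(a, b) abs(a - b) <= gap)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    comps <- comps + 1L
    frontier <- i
    while (length(frontier)) {
      seen[frontier] <- TRUE
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) &
                          !seen)
    }
  }
  comps
}

random_window <- function(len = 15L, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)),
        collapse = "")
}

## PFM with a fixed worst base (A and T both worst in every column) so
## that an all-A window scores exactly S_min on both strands
cg_pfm <- function(L = 4L, name = "CGM") {
  counts <- matrix(0, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["C", ] <- c(8, 2, 8, 2)[seq_len(L) %% 4 + 1]
  counts["G", ] <- c(2, 8, 2, 8)[seq_len(L) %% 4 + 1]
  pfm(name, "CGM0001.1", counts)
}

random_pfm <- function(L, name = "RND") {
  counts <- matrix(sample(0:9, 4 * L, replace = TRUE), 4, L)
  counts[1, colSums(counts) == 0] <- 1
  for (j in seq_len(L)) counts[sample.int(4, 1), j] <- sample(10:20, 1)
  pfm(name, "RND0001.1", counts)
}
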