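#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAStringSet
NULL

#' Read a reference genome from FASTA
#'
#' Multi-record, line-wrapped FASTA via `Biostrings`. Sequences are
#' uppercased; only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one uppercase DNA string per
#'   chromosome. Names are the first whitespace-delimited token of each
#'   FASTA header.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_genome(seqs)
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of chromosome sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome chromosomes must be named")
  }
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad)) {
    stop("genome contains characters outside {A,C,G,T,N} on ",
         names(genome)[bad][1])
  }
  invisible(genome)
}

#' Extract a sequence window centered on a variant position
#'
#' Returns the `2 * flank + 1` bp window around a 1-based position, the
#' variant base at the center. The default `flank = 7` yields the 15 bp
#' window used for wild-type/mutant binding-affinity comparison.
#'
#' @param genome Named character vector (see [read_genome()]).
#' @param chrom Chromosome name.
#' @param pos 1-based position of the variant base.
#' @param flank Bases of context on each side (default 7).
#' @return A DNA string of length `2 * flank + 1` with the base at `pos`
#'   in the middle. Windows running off a chromosome end are an error;
#'   no padding is performed.
#' @export
extract_window <- function(genome, chrom, pos, flank = 7L) {
  stopifnot(flank >= 0, pos >= 1)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  lo <- pos - flank
  hi <- pos + flank
  if (lo < 1 || hi > len) {
    stop(sprintf(
      "window [%d,%d] around %s:%d runs off the chromosome (length %d)",
      lo, hi, chrom, pos, len
    ))
  }
  substr(genome[[chrom]], lo, hi)
}

#' Reverse-complement a DNA string
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return Its reverse complement (`N` maps to `N`).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
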