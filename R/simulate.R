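# Synthetic-data generators. Every generator is a pure function of
# (parameters, seed): randomness is routed through with_seed() and no
# global RNG state leaks. Planted quantities that must hit a target
# fraction exactly use integer arithmetic, not Bernoulli draws; the
# realized counts are recorded in the ground-truth object so recovery
# tests can assert exact equality.

element_id <- function(iv) sprintf("%s:%d-%d", iv$chrom, iv$start, iv$end)

#' Generate a random genome
#'
#' @param n_chroms Number of chromosomes (default 2).
#' @param length_bp Length of each chromosome in bp (default 1e5,
#'   minimum 1e4).
#' @param gc GC fraction (default 0.41, roughly genomic).
#' @param seed RNG seed (required).
#' @return Named character vector `chr1..chrN`.
#' @export
generate_genome <- function(n_chroms = 2L, length_bp = 1e5, gc = 0.41,
                            seed) {
  stopifnot(n_chroms >= 1, length_bp >= 1e4, gc >= 0, gc <= 1)
  with_seed(seed, {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(c("A", "T", "C", "G"), length_bp, replace = TRUE,
                   prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    seqs
  })
}

## place n non-overlapping intervals on the genome, spread across
## chromosomes proportionally to length; random widths and gaps
plant_intervals <- function(genome, n, width_range = c(300L, 800L),
                            min_gap = 50L) {
  lens <- nchar(genome)
  k <- floor(n * lens / sum(lens))
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(lens, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  out <- list()
  for (ci in seq_along(genome)) {
    kk <- k[ci]
    if (kk == 0) next
    len <- lens[ci]
    widths <- sample(width_range[1]:width_range[2], kk, replace = TRUE)
    free <- len - sum(widths) - (kk + 1L) * min_gap
    if (free < 0) {
      stop("infeasible packing: ", kk, " regions do not fit on ",
           names(genome)[ci])
    }
    props <- diff(c(0, sort(stats::runif(kk)), 1))
    gaps <- min_gap + floor(props * free)
    starts <- cumsum(gaps[seq_len(kk)]) + cumsum(c(0L, widths))[seq_len(kk)]
    out[[ci]] <- data.frame(chrom = names(genome)[ci],
                            start = as.integer(starts),
                            end = as.integer(starts + widths),
                            strand = ".", stringsAsFactors = FALSE)
  }
  iv <- do.call(rbind, out)
  validate_intervals(iv)
  iv[order(iv$chrom, iv$start), , drop = FALSE]
}

#' Generate two peak cohorts with planted specific and shared regions
#'
#' Plants non-overlapping accessible regions and labels each A-specific,
#' B-specific or shared. Every sample of a group carries each of its
#' group's specific regions, except that an exact number
#' `round(dropout * n_group)` of samples (chosen at random per region)
#' drop it; other-group specific regions never appear; shared regions
#' appear in all samples of both groups. The exact-count dropout keeps
#' planted recurrence at `1 - dropout` precisely, so specificity calling
#' recovers the planted statuses whenever `dropout <= 1 - f_min`.
#'
#' @param genome Named character vector (defines chromosome lengths).
#' @param n_a,n_b Samples per group (defaults 9 and 12, the two
#'   tumor-cohort sizes the pipeline is built around).
#' @param n_specific_a,n_specific_b,n_shared Planted region counts
#'   (defaults 20 / 30 / 50).
#' @param dropout Per-region fraction of own-group samples lacking the
#'   peak (default 0).
#' @param group_a,group_b Group labels.
#' @param width_range,min_gap Region geometry in bp.
#' @param seed RNG seed (required).
#' @return List with `cohort_a`, `cohort_b` ([peak_cohort()]s) and
#'   `truth` (list with `regions`: chrom/start/end/status/id, and the
#'   generation parameters).
#' @export
generate_cohorts <- function(genome, n_a = 9L, n_b = 12L,
                             n_specific_a = 20L, n_specific_b = 30L,
                             n_shared = 50L, dropout = 0,
                             group_a = "GBM", group_b = "LGG",
                             width_range = c(300L, 800L), min_gap = 50L,
                             seed) {
  stopifnot(n_a >= 1, n_b >= 1, dropout >= 0, dropout < 1)
  with_seed(seed, {
    n_tot <- n_specific_a + n_specific_b + n_shared
    regions <- plant_intervals(genome, n_tot, width_range, min_gap)
    status <- sample(c(rep("A_specific", n_specific_a),
                       rep("B_specific", n_specific_b),
                       rep("shared", n_shared)))
    regions$status <- status
    regions$id <- element_id(regions)

    build_group <- function(n_samples, own_status, prefix) {
      own <- regions[regions$status == own_status, , drop = FALSE]
      shared <- regions[regions$status == "shared", , drop = FALSE]
      drop_k <- round_half_up(dropout * n_samples)
      dropped <- lapply(seq_len(nrow(own)), function(i) {
        if (drop_k > 0) sample.int(n_samples, drop_k) else integer(0)
      })
      samples <- lapply(seq_len(n_samples), function(s) {
        keep <- vapply(dropped, function(d) !(s %in% d), logical(1))
        iv <- rbind(own[keep, c("chrom", "start", "end", "strand")],
                    shared[, c("chrom", "start", "end", "strand")])
        iv[order(iv$chrom, iv$start), , drop = FALSE]
      })
      names(samples) <- sprintf("%s%02d", prefix, seq_len(n_samples))
      samples
    }
    cohort_a <- peak_cohort(group_a, build_group(n_a, "A_specific", "A"))
    cohort_b <- peak_cohort(group_b, build_group(n_b, "B_specific", "B"))
    list(cohort_a = cohort_a, cohort_b = cohort_b,
         truth = list(regions = regions,
                      params = list(n_a = n_a, n_b = n_b,
                                    n_specific_a = n_specific_a,
                                    n_specific_b = n_specific_b,
                                    n_shared = n_shared,
                                    dropout = dropout, seed = seed)))
  })
}

DEFAULT_CLASS_MIX <- list(
  A = c(promoter = 0.377, insulator = 0.124, enhancer = 0.098),
  B = c(promoter = 0.379, insulator = 0.102, enhancer = 0.035),
  shared = c(promoter = 0.40, insulator = 0.10, enhancer = 0.05)
)

#' Generate annotation tracks, genes, a curated list and interactions
#'
#' Assigns each planted region a regulatory-element class by the
#' per-status class mix (exact integer counts via largest-share
#' rounding; the remainder is `other`, i.e., covered by no track), and
#' builds the three annotation tracks as exactly the intervals of their
#' assigned regions. Around the first `n_candidates` A-specific enhancer
#' regions it places curated genes inside the +/- 1 Mb neighborhood, a
#' curated gene outside it (beyond 1 Mb on the same chromosome when it
#' fits, else on another chromosome), non-curated neighbor genes, and an
#' enhancer-gene interaction table with high/low confidence tiers.
#'
#' @param truth Truth list from [generate_cohorts()].
#' @param genome Named character vector.
#' @param class_mix List of named proportion vectors for statuses `A`,
#'   `B`, `shared`; proportions per status must sum to <= 1.
#' @param n_candidates Number of candidate enhancers to dress with genes
#'   and interactions (default 3).
#' @param seed RNG seed (required).
#' @return List with `tracks` ([annotation_tracks()]), `genes` (interval
#'   table with `name`), `curated` (character), `interactions`
#'   (data.frame `element_id`, `gene`, `confidence`) and the updated
#'   `truth` (adds `classes`, `candidates`, `gene_plan`).
#' @export
generate_annotations <- function(truth, genome,
                                 class_mix = DEFAULT_CLASS_MIX,
                                 n_candidates = 3L, seed) {
  for (mx in class_mix) {
    if (sum(mx) > 1 + 1e-9) stop("class mix proportions must sum to <= 1")
  }
  with_seed(seed, {
    regions <- truth$regions
    regions$class <- "other"
    for (st in c("A_specific", "B_specific", "shared")) {
      key <- c(A_specific = "A", B_specific = "B", shared = "shared")[[st]]
      idx <- which(regions$status == st)
      mx <- class_mix[[key]]
      counts <- stats::setNames(round_half_up(mx * length(idx)),
                                names(mx))
      while (sum(counts) > length(idx)) counts[which.max(counts)] <-
          counts[which.max(counts)] - 1L
      pool <- sample(idx)
      off <- 0L
      for (cl in names(counts)) {
        if (counts[[cl]] > 0) {
          regions$class[pool[(off + 1L):(off + counts[[cl]])]] <- cl
          off <- off + counts[[cl]]
        }
      }
    }
    tracks <- annotation_tracks(
      promoter = regions[regions$class == "promoter",
                         c("chrom", "start", "end", "strand")],
      insulator = regions[regions$class == "insulator",
                          c("chrom", "start", "end", "strand")],
      enhancer = regions[regions$class == "enhancer",
                         c("chrom", "start", "end", "strand")]
    )

    ee_a <- regions[regions$status == "A_specific" &
                      regions$class == "enhancer", , drop = FALSE]
    ee_a <- ee_a[order(ee_a$chrom, ee_a$start), , drop = FALSE]
    cands <- utils::head(ee_a, n_candidates)

    genes <- list(); curated <- character(0); inter <- list()
    add_gene <- function(chrom, start, width, name) {
      len <- nchar(genome[[chrom]])
      start <- max(0L, min(start, len - width - 1L))
      genes[[length(genes) + 1L]] <<- data.frame(
        chrom = chrom, start = as.integer(start),
        end = as.integer(start + width), strand = ".", name = name,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(cands))) {
      cd <- cands[i, ]
      mid <- (cd$start + cd$end) %/% 2L
      len <- nchar(genome[[cd$chrom]])
      for (j in 1:2) {
        nm <- sprintf("CURGENE_%d_%d", i, j)
        d <- 3000L * i + 1500L * j
        start <- if (mid + d + 2000L < len) mid + d else mid - d - 2000L
        add_gene(cd$chrom, start, 2000L, nm)
        curated <- c(curated, nm)
        inter[[length(inter) + 1L]] <- data.frame(
          element_id = cd$id, gene = nm,
          confidence = if (i == 1 && j == 1) "high" else "low",
          stringsAsFactors = FALSE)
      }
      ## curated gene outside the neighborhood
      far_nm <- sprintf("FARGENE_%d", i)
      if (mid + 1e6 + 2002 < len) {
        add_gene(cd$chrom, as.integer(mid + 1e6 + 1), 2000L, far_nm)
      } else {
        other <- setdiff(names(genome), cd$chrom)[1]
        if (!is.na(other)) add_gene(other, 1000L + 5000L * i, 2000L, far_nm)
      }
      curated <- c(curated, far_nm)
      ## non-curated neighbor
      add_gene(cd$chrom, max(0L, mid - 20000L), 2000L,
               sprintf("NONCUR_%d", i))
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), name = character(),
                 stringsAsFactors = FALSE)
    interactions <- if (length(inter)) do.call(rbind, inter) else
      data.frame(element_id = character(), gene = character(),
                 confidence = character(), stringsAsFactors = FALSE)

    truth$classes <- regions[, c("id", "chrom", "start", "end",
                                 "status", "class")]
    truth$candidates <- cands$id
    truth$class_counts <- lapply(
      split(regions$class, regions$status),
      function(x) as.list(table(x)))
    list(tracks = tracks, genes = genes, curated = unique(curated),
         interactions = interactions, truth = truth)
  })
}

## next base in A->C->G->T->A order; deterministic alt-allele choice
next_base <- function(b) {
  c(A = "C", C = "G", G = "T", T = "A")[[b]]
}

#' Generate per-patient somatic SNVs with planted recurrence and decoys
#'
#' Plants SNVs at specified positions inside candidate enhancer
#' elements, distributes them over patients (recurrent positions are
#' carried by several patients, hotspot neighbors sit within 7 bp of a
#' recurrent position), scatters spill-over somatic SNVs outside every
#' planted region, and adds germline decoys whose exact alleles are
#' recorded in the known-SNP set.
#'
#' The default plan, built from `truth$candidates` (requires
#' [generate_annotations()] to have run), mimics the discovery pattern
#' the pipeline targets: candidate 1 and 2 each carry two distinct
#' mutated sites ~60 bp apart, candidate 3 carries one recurrent SNV
#' shared by three patients plus a fourth patient mutated 5 bp away.
#'
#' @param genome Named character vector.
#' @param truth Truth list (after [generate_annotations()]).
#' @param n_patients Number of whole-genome patients (default 39).
#' @param plan Optional data.frame overriding the default:
#'   columns `element_id`, `pos` (1-based, inside the element),
#'   `n_patients`. A position outside its element is an error.
#' @param n_spillover Somatic SNVs planted outside all regions
#'   (default 5).
#' @param n_germline_decoys Known-SNP decoys planted inside
#'   non-candidate enhancers (default 2).
#' @param seed RNG seed (required).
#' @return List with `snvs` (SNV table over all patients), `known_snps`
#'   (data.frame chrom/pos/ref/alt) and updated `truth` (adds
#'   `snv_plan`, `spillover_n`, `decoys`).
#' @export
generate_snvs <- function(genome, truth, n_patients = 39L, plan = NULL,
                          n_spillover = 5L, n_germline_decoys = 2L,
                          seed) {
  if (is.null(truth$classes)) {
    stop("truth lacks element classes; run generate_annotations() first")
  }
  empty_snvs <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           patient = character(), origin = character(),
                           element_id = character(),
                           stringsAsFactors = FALSE)
  empty_snps <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           stringsAsFactors = FALSE)
  if (n_patients == 0) {
    truth$snv_plan <- data.frame(element_id = character(),
                                 pos = integer(), n_patients = integer(),
                                 ref = character(), alt = character(),
                                 chrom = character(),
                                 stringsAsFactors = FALSE)
    truth$spillover_n <- 0L
    truth$decoys <- empty_snps
    truth$mutated_elements <- character(0)
    return(list(snvs = empty_snvs, known_snps = empty_snps,
                truth = truth))
  }
  with_seed(seed, {
    classes <- truth$classes
    if (is.null(plan)) {
      cands <- truth$candidates
      if (length(cands) < 1) stop("no candidate enhancers in truth")
      mk <- function(id, offset, n) {
        el <- classes[classes$id == id, ]
        mid <- (el$start + el$end) %/% 2L
        data.frame(element_id = id, pos = mid + offset, n_patients = n,
                   stringsAsFactors = FALSE)
      }
      plan <- do.call(rbind, c(
        if (length(cands) >= 1) list(mk(cands[1], -30L, 1L),
                                     mk(cands[1], 30L, 1L)),
        if (length(cands) >= 2) list(mk(cands[2], -30L, 1L),
                                     mk(cands[2], 30L, 1L)),
        if (length(cands) >= 3) list(mk(cands[3], 0L, 3L),
                                     mk(cands[3], 5L, 1L))
      ))
    }
    patients <- sprintf("P%02d", seq_len(n_patients))
    snv_rows <- list()
    for (i in seq_len(nrow(plan))) {
      el <- classes[classes$id == plan$element_id[i], , drop = FALSE]
      if (nrow(el) != 1) stop("unknown element in plan: ",
                              plan$element_id[i])
      if (!vcf_pos_in_interval(plan$pos[i], el)) {
        stop(sprintf("planted position %s:%d outside its element %s",
                     el$chrom, plan$pos[i], el$id))
      }
      ref <- substr(genome[[el$chrom]], plan$pos[i], plan$pos[i])
      alt <- next_base(ref)
      if (n_patients < plan$n_patients[i]) stop("not enough patients")
      who <- sample(patients, plan$n_patients[i])
      for (p in who) {
        snv_rows[[length(snv_rows) + 1L]] <- data.frame(
          chrom = el$chrom, pos = plan$pos[i], ref = ref, alt = alt,
          patient = p, origin = "somatic", element_id = el$id,
          stringsAsFactors = FALSE)
      }
    }
    ## spill-over somatic SNVs outside every planted region
    all_regions <- truth$regions
    outside <- function(chrom, pos) {
      sub <- all_regions[all_regions$chrom == chrom, , drop = FALSE]
      !any(vcf_pos_in_interval(pos, sub))
    }
    n_placed <- 0L
    while (n_placed < n_spillover) {
      ch <- sample(names(genome), 1)
      pos <- sample.int(nchar(genome[[ch]]) - 20L, 1) + 10L
      if (!outside(ch, pos)) next
      ref <- substr(genome[[ch]], pos, pos)
      if (ref == "N") next
      snv_rows[[length(snv_rows) + 1L]] <- data.frame(
        chrom = ch, pos = pos, ref = ref, alt = next_base(ref),
        patient = sample(patients, 1), origin = "somatic",
        element_id = NA_character_, stringsAsFactors = FALSE)
      n_placed <- n_placed + 1L
    }
    ## germline decoys inside non-candidate enhancers
    decoy_pool <- classes[classes$class == "enhancer" &
                            !(classes$id %in% truth$candidates), ,
                          drop = FALSE]
    decoys <- list()
    for (k in seq_len(n_germline_decoys)) {
      if (nrow(decoy_pool) == 0) break
      el <- decoy_pool[sample.int(nrow(decoy_pool), 1), ]
      pos <- el$start + sample.int(el$end - el$start, 1)  # 1-based in el
      ref <- substr(genome[[el$chrom]], pos, pos)
      if (ref == "N") next
      alt <- next_base(ref)
      snv_rows[[length(snv_rows) + 1L]] <- data.frame(
        chrom = el$chrom, pos = pos, ref = ref, alt = alt,
        patient = sample(patients, 1), origin = "germline",
        element_id = el$id, stringsAsFactors = FALSE)
      decoys[[length(decoys) + 1L]] <- data.frame(
        chrom = el$chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
    snvs <- do.call(rbind, snv_rows)
    known_snps <- if (length(decoys)) do.call(rbind, decoys) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE)
    plan$ref <- vapply(seq_len(nrow(plan)), function(i) {
      el <- classes[classes$id == plan$element_id[i], ]
      substr(genome[[el$chrom]], plan$pos[i], plan$pos[i])
    }, character(1))
    plan$alt <- vapply(plan$ref, next_base, character(1))
    plan$chrom <- classes$chrom[match(plan$element_id, classes$id)]
    truth$snv_plan <- plan
    truth$spillover_n <- n_spillover
    truth$decoys <- known_snps
    truth$mutated_elements <- unique(plan$element_id)
    list(snvs = snvs, known_snps = known_snps, truth = truth)
  })
}

## PFM whose consensus matches `target_window` across a motif placed over
## the center, with the center column strongly favoring the target allele
## and assigning the other allele its minimum weight
planted_pfm_once <- function(target_window, other_base, motif_length,
                             name, id,
                             col_var = (motif_length + 1L) %/% 2L) {
  center <- (nchar(target_window) + 1L) %/% 2L
  o <- center - col_var + 1L
  consensus <- strsplit(substr(target_window, o, o + motif_length - 1L),
                        "")[[1]]
  counts <- matrix(1, 4, motif_length, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(motif_length)) counts[consensus[j], j] <- 7
  counts[, col_var] <- 1
  counts[consensus[col_var], col_var] <- 997
  counts[other_base, col_var] <- 0
  pfm(name, id, counts)
}

## The construction above guarantees that the favored allele's window
## scores 1.0, but the sequence context around the variant can by chance
## hold a near-copy of the short consensus, lifting the disfavored
## allele's best covering alignment toward the site threshold and
## destroying the planted novel/lost-site contrast. Lengthening the
## motif makes such chance re-matches exponentially unlikely while the
## dominant variant column still pins the disfavored allele's score at
## the planted alignment. The motif length and its placement over the
## variant are therefore searched (within the window) until the
## disfavored allele scores below `margin` at every covering alignment;
## the placement with the lowest disfavored-allele score wins.
planted_pfm <- function(target_window, other_window, other_base,
                        motif_length, name, id, margin = 0.7) {
  best <- NULL
  best_rel <- Inf
  wlen <- nchar(target_window)
  center <- (wlen + 1L) %/% 2L
  for (L in seq(motif_length, wlen - 2L, by = 2L)) {
    for (col_var in seq_len(L)) {
      o <- center - col_var + 1L
      if (o < 1L || o + L - 1L > wlen) next
      cand <- planted_pfm_once(target_window, other_base, L, name, id,
                               col_var = col_var)
      pw <- build_pwm(cand)
      other_rel <- relative_score(pw, other_window)$rel
      if (relative_score(pw, target_window)$rel == 1 &&
          other_rel < best_rel) {
        best <- cand
        best_rel <- other_rel
      }
      if (best_rel < margin) break
    }
    if (best_rel < margin) break
  }
  best
}

#' Generate a PWM library with planted gain/loss motifs
#'
#' For each planted effect, constructs a motif whose consensus equals
#' the favored allele's window subsequence spanning the variant, with a
#' strongly unfavorable weight for the other allele at the variant
#' column: a `gain` motif matches the mutant sequence (the variant
#' creates a novel site), a `loss` motif matches the wild type (the
#' variant destroys an existing site). Background motifs are random and
#' unrelated to the planted windows.
#'
#' @param truth Truth list (after [generate_snvs()]) — used for the
#'   default planting on the first two planted SNVs.
#' @param genome Named character vector.
#' @param n_background Number of random background motifs (default 8).
#' @param planted Optional list of `list(chrom, pos, ref, alt, effect)`
#'   entries (`effect` is `"gain"` or `"loss"`); defaults to a gain on
#'   the first planted SNV and a loss on the second.
#' @param motif_length Planted motif length (default 6).
#' @param flank Window half-width (default 7).
#' @param seed RNG seed (required).
#' @return List with `pfms` (named list of [pfm()]), `truth` updated
#'   with `pwm_plan` (data.frame: `tf`, `effect`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @export
generate_pwms <- function(truth, genome, n_background = 8L,
                          planted = NULL, motif_length = 6L, flank = 7L,
                          seed) {
  with_seed(seed, {
    if (is.null(planted)) {
      sp <- truth$snv_plan
      if (is.null(sp) || nrow(sp) < 1) {
        planted <- list()
      } else {
        take <- utils::head(seq_len(nrow(sp)), 2)
        planted <- lapply(seq_along(take), function(k) {
          i <- take[k]
          list(chrom = sp$chrom[i], pos = sp$pos[i], ref = sp$ref[i],
               alt = sp$alt[i], effect = if (k == 1) "gain" else "loss")
        })
      }
    }
    pfms <- list()
    plan_rows <- list()
    for (k in seq_along(planted)) {
      pl <- planted[[k]]
      wt <- extract_window(genome, pl$chrom, pl$pos, flank)
      stopifnot(substr(wt, flank + 1L, flank + 1L) == pl$ref)
      mut <- wt
      substr(mut, flank + 1L, flank + 1L) <- pl$alt
      nm <- sprintf("PLANTED_%s_%d", toupper(pl$effect), k)
      pfms[[nm]] <- if (pl$effect == "gain") {
        planted_pfm(mut, wt, pl$ref, motif_length, nm,
                    sprintf("SYNP%03d.1", k))
      } else {
        planted_pfm(wt, mut, pl$alt, motif_length, nm,
                    sprintf("SYNP%03d.1", k))
      }
      plan_rows[[k]] <- data.frame(tf = nm, effect = pl$effect,
                                   chrom = pl$chrom, pos = pl$pos,
                                   ref = pl$ref, alt = pl$alt,
                                   stringsAsFactors = FALSE)
    }
    for (k in seq_len(n_background)) {
      nm <- sprintf("BG_%02d", k)
      counts <- matrix(sample(0:3, 4 * motif_length, replace = TRUE),
                       4, motif_length, dimnames = list(DNA_BASES, NULL))
      for (j in seq_len(motif_length)) {
        counts[sample.int(4, 1), j] <- sample(8:16, 1)
      }
      pfms[[nm]] <- pfm(nm, sprintf("SYNB%03d.1", k), counts)
    }
    truth$pwm_plan <- if (length(plan_rows)) do.call(rbind, plan_rows) else
      data.frame(tf = character(), effect = character(),
                 chrom = character(), pos = integer(), ref = character(),
                 alt = character(), stringsAsFactors = FALSE)
    list(pfms = pfms, truth = truth)
  })
}

## Gale-Ryser-style greedy assignment: give each region's demand to the
## distinct patients with the largest remaining capacity
assign_pairs <- function(demand, capacities) {
  assigned <- vector("list", length(demand))
  names(assigned) <- names(demand)
  for (r in order(demand, decreasing = TRUE)) {
    need <- demand[r]
    if (need == 0) { assigned[[r]] <- character(0); next }
    avail <- names(capacities)[capacities > 0]
    if (length(avail) < need) stop("infeasible plan: not enough patients")
    pick <- avail[order(-capacities[avail])][seq_len(need)]
    capacities[pick] <- capacities[pick] - 1L
    assigned[[r]] <- pick
  }
  if (any(capacities != 0)) stop("infeasible plan: stranded capacity")
  assigned
}

#' Generate a targeted-sequencing genotype table with planted statistics
#'
#' Builds a specimen x region genotype table whose realized per-region
#' mutation frequency, callability and multifocal concordance, patient
#' burden, co-occurrence count and peritumoral exclusivity match the
#' plan exactly; targets are converted to counts by round-half-up and
#' the realized counts are recorded in the returned truth. Multifocal
#' patients contribute two tumor sections and are always callable, so
#' every region's concordance denominator is `n_multifocal`; `NS` cells
#' are distributed over non-mutated single-section specimens.
#'
#' The defaults mirror a 54-patient validation cohort with five target
#' regions: one region with high mutation frequency (30%) but low
#' callability (50%), one region with no detectable alterations, 11
#' multifocal patients, nine peritumoral specimens from mutated
#' patients, seven patients mutated in two regions and 25 mutated
#' patients overall.
#'
#' @param regions Optional data.frame `id`, `chrom`, `start`, `end` of
#'   target regions; synthesized when `NULL`.
#' @param genome Optional genome for drawing reference alleles.
#' @param n_patients,n_multifocal,n_peritumoral Cohort design counts.
#' @param frequencies,callability,concordance Planted per-region
#'   fractions (all in `[0, 1]`, one per region).
#' @param n_cooccurring Patients mutated in exactly two regions.
#' @param n_mutated_patients Patients with at least one mutation
#'   (includes the co-occurring ones).
#' @param peritumoral_violation Plant one peritumoral MUT cell
#'   (for negative-control testing; default `FALSE`).
#' @param seed RNG seed (required).
#' @return List with `table` (genotype data.frame), `mutations` (SNV
#'   table of all planted MUT alleles) and `truth` (realized counts and
#'   fractions).
#' @export
generate_genotype_table <- function(regions = NULL, genome = NULL,
                                    n_patients = 54L, n_multifocal = 11L,
                                    n_peritumoral = 9L,
                                    frequencies = c(0.30, 0.15, 0.0,
                                                    0.12, 0.18),
                                    callability = c(0.50, 0.95, 0.90,
                                                    0.90, 0.88),
                                    concordance = c(0.60, 0.90, 1.00,
                                                    0.82, 0.78),
                                    n_cooccurring = 7L,
                                    n_mutated_patients = 25L,
                                    peritumoral_violation = FALSE,
                                    seed) {
  nr <- length(frequencies)
  stopifnot(length(callability) == nr, length(concordance) == nr,
            all(frequencies >= 0 & frequencies <= 1),
            all(callability >= 0 & callability <= 1),
            all(concordance >= 0 & concordance <= 1),
            n_multifocal >= 0, n_multifocal <= n_patients,
            n_cooccurring <= n_mutated_patients,
            n_mutated_patients <= n_patients)
  if (is.null(regions)) {
    ids <- sprintf("EE-%02d", seq_len(nr))
    regions <- data.frame(id = ids, chrom = "chr1",
                          start = 1000L + 500L * (seq_len(nr) - 1L),
                          end = 1000L + 500L * (seq_len(nr) - 1L) + 200L,
                          stringsAsFactors = FALSE)
  }
  stopifnot(nrow(regions) == nr)

  with_seed(seed, {
    M <- as.integer(n_multifocal)
    P <- as.integer(n_patients)
    n_spec <- P + M  # tumor specimens: multifocal contribute 2 sections
    n_call <- round_half_up(callability * n_spec)
    if (any(n_call < 2L * M)) {
      stop("infeasible plan: callability too low to keep multifocal ",
           "sections callable")
    }
    m <- round_half_up(frequencies * n_call)
    n_conc <- round_half_up(concordance * M)
    d <- M - n_conc
    if (any(d > m)) {
      stop("infeasible plan: discordance requires more mutations than ",
           "the region frequency provides")
    }
    pairs_target <- n_mutated_patients + n_cooccurring
    c2_total <- sum(m) - pairs_target
    if (c2_total < 0) {
      stop("infeasible plan: fewer mutations than mutated patients")
    }
    remaining <- m - d
    c2 <- integer(nr)
    cap <- pmin(remaining %/% 2L, M - d)
    left <- c2_total
    for (r in rep(order(remaining, decreasing = TRUE), times = 2L * nr)) {
      if (left == 0) break
      if (c2[r] < cap[r]) { c2[r] <- c2[r] + 1L; left <- left - 1L }
    }
    if (left > 0) stop("infeasible plan: cannot absorb excess mutations ",
                       "into concordant multifocal pairs")
    s <- remaining - 2L * c2
    t_m <- sum(d + c2)
    u <- min(M, t_m)           # mutated multifocal patients
    x <- t_m - u               # of which co-occurring
    if (x > n_cooccurring || x > u || u > n_mutated_patients) {
      stop("infeasible plan: multifocal mutation load")
    }
    y <- n_cooccurring - x     # co-occurring singleton patients
    v <- n_mutated_patients - u  # mutated singleton patients
    if (v < y || sum(s) != v + y) {
      stop("infeasible plan: singleton mutation load")
    }

    patients <- sprintf("VC%03d", seq_len(P))
    multifocal <- sort(sample(patients, M))
    singletons <- setdiff(patients, multifocal)

    mf_caps <- integer(M); names(mf_caps) <- sample(multifocal)
    if (u > 0) mf_caps[seq_len(u)] <- 1L
    if (x > 0) mf_caps[seq_len(x)] <- 2L
    sg_caps <- integer(length(singletons))
    names(sg_caps) <- sample(singletons)
    if (v > 0) sg_caps[seq_len(v)] <- 1L
    if (y > 0) sg_caps[seq_len(y)] <- 2L

    dem_m <- d + c2; names(dem_m) <- regions$id
    dem_s <- s; names(dem_s) <- regions$id
    mf_assign <- assign_pairs(dem_m, mf_caps)
    sg_assign <- assign_pairs(dem_s, sg_caps)

    ## canonical allele per region (center), plus a hotspot neighbor
    region_alleles <- lapply(seq_len(nr), function(r) {
      reg <- regions[r, ]
      pos <- as.integer((reg$start + reg$end) %/% 2L)
      ref <- if (!is.null(genome)) {
        substr(genome[[reg$chrom]], pos, pos)
      } else "C"
      alt <- next_base(ref)
      npos <- pos + 5L
      nref <- if (!is.null(genome)) {
        substr(genome[[reg$chrom]], npos, npos)
      } else "T"
      list(canonical = snv_key(reg$chrom, pos, ref, alt),
           neighbor = snv_key(reg$chrom, npos, nref, next_base(nref)),
           canon = data.frame(chrom = reg$chrom, pos = pos, ref = ref,
                              alt = alt, stringsAsFactors = FALSE),
           neigh = data.frame(chrom = reg$chrom, pos = npos, ref = nref,
                              alt = next_base(nref),
                              stringsAsFactors = FALSE))
    })

    ## assemble specimens
    spec <- rbind(
      data.frame(specimen = paste0(multifocal, "_S1"),
                 patient = multifocal, section = "S1",
                 compartment = "tumor", stringsAsFactors = FALSE),
      data.frame(specimen = paste0(multifocal, "_S2"),
                 patient = multifocal, section = "S2",
                 compartment = "tumor", stringsAsFactors = FALSE),
      data.frame(specimen = paste0(singletons, "_S1"),
                 patient = singletons, section = "S1",
                 compartment = "tumor", stringsAsFactors = FALSE)
    )
    tab <- spec
    mut_rows <- list()
    for (r in seq_len(nr)) {
      id <- regions$id[r]
      cells <- rep("WT", nrow(tab))
      names(cells) <- tab$specimen
      al <- region_alleles[[r]]
      mf_pat <- mf_assign[[id]]
      disc <- if (d[r] > 0) sample(mf_pat, d[r]) else character(0)
      conc_mut <- setdiff(mf_pat, disc)
      k <- 0L
      give <- function(pat, sections, key, rec) {
        for (sc in sections) {
          cells[paste0(pat, "_", sc)] <<- key
        }
        mut_rows[[length(mut_rows) + 1L]] <<-
          cbind(rec, data.frame(patient = pat, region = id,
                                stringsAsFactors = FALSE))
      }
      for (pat in disc) {
        k <- k + 1L
        key <- if (k %% 3L == 0L) al$neighbor else al$canonical
        rec <- if (k %% 3L == 0L) al$neigh else al$canon
        give(pat, sample(c("S1", "S2"), 1), key, rec)
      }
      for (pat in conc_mut) {
        k <- k + 1L
        give(pat, c("S1", "S2"), al$canonical, al$canon)
      }
      for (pat in sg_assign[[id]]) {
        k <- k + 1L
        key <- if (k %% 4L == 0L) al$neighbor else al$canonical
        rec <- if (k %% 4L == 0L) al$neigh else al$canon
        give(pat, "S1", key, rec)
      }
      ## NS cells among non-mutated singleton specimens
      ns_n <- n_spec - n_call[r]
      pool <- paste0(setdiff(singletons, sg_assign[[id]]), "_S1")
      if (length(pool) < ns_n) {
        stop("infeasible plan: not enough singleton specimens to absorb ",
             "NS cells in region ", id)
      }
      if (ns_n > 0) cells[sample(pool, ns_n)] <- "NS"
      tab[[id]] <- unname(cells)
    }
    ## no patient may end up non-sequenced everywhere (it would drop out
    ## of the burden denominator): swap an NS cell with a callable WT
    reg_ids <- regions$id
    repeat {
      all_ns <- vapply(split(tab, tab$patient), function(p) {
        all(unlist(p[reg_ids]) == "NS")
      }, logical(1))
      offenders <- names(all_ns)[all_ns]
      if (length(offenders) == 0) break
      pt <- offenders[1]
      row_i <- which(tab$patient == pt)[1]
      fixed <- FALSE
      for (id in reg_ids) {
        donors <- which(tab[[id]] == "WT" & tab$patient != pt &
                          tab$patient %in% singletons)
        donors <- donors[vapply(donors, function(dr) {
          sum(unlist(tab[dr, reg_ids]) != "NS") >= 2
        }, logical(1))]
        if (length(donors)) {
          tab[[id]][row_i] <- "WT"
          tab[[id]][donors[1]] <- "NS"
          fixed <- TRUE
          break
        }
      }
      if (!fixed) stop("infeasible plan: cannot keep every patient callable")
    }

    mutated_patients <- unique(vapply(mut_rows, function(r) r$patient, ""))
    stopifnot(length(mutated_patients) == n_mutated_patients)
    if (n_peritumoral > length(mutated_patients)) {
      stop("infeasible plan: fewer mutated patients than requested ",
           "peritumoral specimens")
    }
    peri_pat <- sort(sample(mutated_patients, n_peritumoral))
    if (n_peritumoral > 0) {
      peri <- data.frame(specimen = paste0(peri_pat, "_PT"),
                         patient = peri_pat, section = "PT",
                         compartment = "peritumoral",
                         stringsAsFactors = FALSE)
      for (id in reg_ids) peri[[id]] <- "WT"
      if (peritumoral_violation) {
        mr <- mut_rows[[which(vapply(mut_rows, function(r)
          r$patient %in% peri_pat, logical(1)))[1]]]
        peri[[mr$region]][peri$patient == mr$patient] <-
          snv_key(mr$chrom, mr$pos, mr$ref, mr$alt)
      }
      tab <- rbind(tab, peri)
    }
    rownames(tab) <- NULL
    mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
      data.frame(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), patient = character(),
                 region = character(), stringsAsFactors = FALSE)
    mutations$origin <- rep_len("somatic", nrow(mutations))
    rownames(mutations) <- NULL
    validate_snvs(mutations)

    truth <- list(
      regions = regions,
      n_patients = P, n_multifocal = M, n_specimens = n_spec,
      n_peritumoral = n_peritumoral,
      callability = as.numeric(n_call / n_spec),
      frequency = as.numeric(ifelse(n_call > 0, m / n_call, NA)),
      concordance = as.numeric(if (M > 0) n_conc / M else rep(NA, nr)),
      n_callable = as.integer(n_call), n_mut = as.integer(m),
      n_concordant = as.integer(n_conc),
      burden = n_mutated_patients / P,
      n_mutated_patients = as.integer(n_mutated_patients),
      n_cooccurring = as.integer(n_cooccurring),
      cooccurring_patients = sort(c(names(mf_caps)[mf_caps == 2L],
                                    names(sg_caps)[sg_caps == 2L])),
      peritumoral_patients = peri_pat,
      tumor_exclusive = !peritumoral_violation
    )
    list(table = tab, mutations = mutations, truth = truth)
  })
}
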