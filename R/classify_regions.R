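#' Genome region classification
#'
#' The accessible genome is partitioned by two tracks: per-locus
#' individual-assembly coverage (how many samples' assemblies align
#' there) and consensus-scaffold multiplicity (how many meta-assembly
#' scaffolds cover the locus). Loci covered by two or more consensus
#' scaffolds, or by none despite high individual coverage, are complex
#' candidates (too structurally diverse for one consensus
#' representation); loci under the coverage threshold are low-coverage;
#' the rest are low-complexity. The default threshold is 60% of the
#' cohort (92 of 154 samples; half on chrY).
#' @name region-classification
NULL

#' Coverage threshold used for region classification
#' @param n_samples Cohort size (default 154).
#' @param fraction Required fraction with aligned assembly (default 0.6).
#' @return Numeric threshold.
#' @export
coverage_threshold <- function(n_samples = 154, fraction = 0.6) {
  round(n_samples * fraction)
}

# tracks are data frames (start, end, value), 0-based half-open,
# covering [0, L) without overlap

check_track <- function(track, len, what) {
  if (nrow(track) == 0 || track$start[1] != 0 ||
      track$end[nrow(track)] != len ||
      (nrow(track) > 1 && any(track$start[-1] != track$end[-nrow(track)])))
    stop(what, " track does not tile the chromosome")
  invisible(track)
}

#' Classify the genome by coverage and consensus multiplicity
#'
#' @param indiv_cov Named (by chromosome) list of data frames `(start,
#'   end, value)`: number of samples with an aligned assembly.
#' @param consensus_count Same layout: number of consensus scaffolds.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param threshold Coverage threshold (default [coverage_threshold()]);
#'   chromosomes named `chrY`/`Y` use half of it.
#' @return Data frame `(chrom, start, end, class)` with class in
#'   `complex_candidate`, `low_coverage`, `low_complexity`; the rows
#'   partition each chromosome.
#' @export
classify_coverage_state <- function(indiv_cov, consensus_count,
                                    chrom_lengths,
                                    threshold = coverage_threshold()) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    cov <- check_track(indiv_cov[[ch]], len, "coverage")
    cns <- check_track(consensus_count[[ch]], len, "consensus")
    thr <- if (ch %in% c("chrY", "Y")) threshold / 2 else threshold
    brk <- sort(unique(c(cov$start, cov$end, cns$start, cns$end)))
    starts <- brk[-length(brk)]
    ends <- brk[-1]
    val_at <- function(track, pos)
      track$value[findInterval(pos, track$start)]
    c_v <- val_at(cov, starts)
    n_v <- val_at(cns, starts)
    cls <- ifelse(n_v >= 2 | (n_v == 0 & c_v >= thr), "complex_candidate",
                  ifelse(c_v < thr, "low_coverage", "low_complexity"))
    df <- data.frame(chrom = ch, start = starts, end = ends, class = cls)
    # merge adjacent rows of the same class
    keep <- c(TRUE, df$class[-1] != df$class[-nrow(df)])
    grp <- cumsum(keep)
    df <- data.frame(chrom = ch,
                     start = tapply(df$start, grp, min),
                     end = tapply(df$end, grp, max),
                     class = df$class[keep])
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Does a region's SV inventory qualify it as structurally complex?
#'
#' A region is complex when it contains at least three distinct SVs that
#' recur in the cohort (cohort occurrence at least 2), after discarding
#' indels of 10 kb or less; when only indels remain, at least one must
#' exceed 100 kb.
#'
#' @param sv_inventory Data frame with columns `sv_type`, `size_bp`
#'   (absolute size) and `cohort_count` (distinct samples carrying it).
#' @param min_svs Minimum distinct qualifying SVs (default 3).
#' @param min_recurrence Minimum cohort occurrence (default 2).
#' @param indel_min_bp Indel size floor (default 10 kb).
#' @param indel_only_max_bp Required maximum size when only indels
#'   remain (default 100 kb).
#' @return Logical.
#' @export
flag_complex_candidate <- function(sv_inventory, min_svs = 3,
                                   min_recurrence = 2,
                                   indel_min_bp = 10000,
                                   indel_only_max_bp = 100000) {
  inv <- as.data.frame(sv_inventory)
  if (nrow(inv) == 0) return(FALSE)
  indel <- inv$sv_type %in% c("insertion", "deletion", "multi_indel")
  inv <- inv[inv$cohort_count >= min_recurrence &
               (!indel | inv$size_bp > indel_min_bp), , drop = FALSE]
  if (nrow(inv) < min_svs) return(FALSE)
  still_indel <- inv$sv_type %in% c("insertion", "deletion", "multi_indel")
  if (all(still_indel) && !any(inv$size_bp > indel_only_max_bp))
    return(FALSE)
  TRUE
}

# interval helpers (0-based half-open data frames chrom/start/end)

overlaps_any <- function(chrom, start, end, bed) {
  sub <- bed[bed$chrom == chrom, , drop = FALSE]
  any(sub$start < end & sub$end > start)
}

count_overlap_events <- function(regions, feature) {
  n <- 0L
  for (i in seq_len(nrow(regions))) {
    sub <- feature[feature$chrom == regions$chrom[i], , drop = FALSE]
    n <- n + sum(sub$start < regions$end[i] & sub$end > regions$start[i])
  }
  n
}

subtract_intervals <- function(len, excl) {
  # maximal sub-intervals of [0, len) not covered by excl (start,end)
  if (nrow(excl) == 0) return(data.frame(start = 0, end = len))
  excl <- excl[order(excl$start), , drop = FALSE]
  free <- list()
  cur <- 0
  for (i in seq_len(nrow(excl))) {
    if (excl$start[i] > cur)
      free[[length(free) + 1L]] <- c(cur, min(excl$start[i], len))
    cur <- max(cur, excl$end[i])
    if (cur >= len) break
  }
  if (cur < len) free[[length(free) + 1L]] <- c(cur, len)
  if (length(free) == 0) return(data.frame(start = numeric(),
                                           end = numeric()))
  m <- do.call(rbind, free)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Permutation test of region-feature overlap enrichment
#'
#' The observed number of region-feature overlap events is compared with
#' its distribution under `n_perm` random placements of the regions
#' (lengths preserved, placement uniform over the genome minus the
#' excluded space, regions allowed to overlap each other). The p-value
#' uses the add-one correction `(1 + #\{perm >= obs\}) / (n_perm + 1)`.
#'
#' @param regions,feature,excluded Data frames `(chrom, start, end)`.
#' @param chrom_lengths Named numeric vector.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List: `p_value`, `observed`, `perm_mean`.
#' @export
permutation_overlap_test <- function(regions, feature, excluded,
                                     chrom_lengths, n_perm = 10000,
                                     seed = 1L) {
  set.seed(seed)
  observed <- count_overlap_events(regions, feature)
  # allowed placement space per chromosome
  free <- lapply(names(chrom_lengths), function(ch)
    subtract_intervals(chrom_lengths[[ch]],
                       excluded[excluded$chrom == ch, , drop = FALSE]))
  names(free) <- names(chrom_lengths)
  # features per chromosome, sorted for interval counting:
  # #{fs < e & fe > s} = #{fs < e} - #{fe <= s}
  feat <- lapply(names(chrom_lengths), function(ch) {
    f <- feature[feature$chrom == ch, , drop = FALSE]
    list(fs = sort(f$start), fe = sort(f$end))
  })
  names(feat) <- names(chrom_lengths)
  count_on <- function(ch, s, e) {
    f <- feat[[ch]]
    findInterval(e, f$fs, left.open = FALSE) -
      findInterval(s, f$fe)
  }
  reg_len <- regions$end - regions$start
  perm_counts <- numeric(n_perm)
  for (i in seq_along(reg_len)) {
    L <- reg_len[i]
    # slot table: every free interval (on any chromosome) that can hold
    # the region, weighted by its room
    chs <- character(); starts <- numeric(); room <- numeric()
    for (ch in names(free)) {
      f <- free[[ch]]
      ok <- f$end - f$start >= L
      if (any(ok)) {
        chs <- c(chs, rep(ch, sum(ok)))
        starts <- c(starts, f$start[ok])
        room <- c(room, f$end[ok] - f$start[ok] - L)
      }
    }
    if (length(starts) == 0)
      stop("region of length ", L, " does not fit in the allowed space")
    w <- room + 1e-9
    slot <- findInterval(stats::runif(n_perm, 0, sum(w)),
                         cumsum(w), left.open = TRUE) + 1L
    s <- starts[slot] + stats::runif(n_perm) * room[slot]
    for (ch in unique(chs[slot])) {
      sel <- chs[slot] == ch
      perm_counts[sel] <- perm_counts[sel] +
        count_on(ch, s[sel], s[sel] + L)
    }
  }
  list(p_value = (1 + sum(perm_counts >= observed)) / (n_perm + 1),
       observed = observed, perm_mean = mean(perm_counts))
}

#' Annotate regions with filtered genomic features
#'
#' Segmental duplications are filtered to length >= 10 kb and percent
#' identity >= 0.95; tandem repeats to score > 2000; subtelomeric means
#' within 7 Mb of a chromosome end, pericentromeric within 9 Mb of the
#' centromere.
#'
#' @param regions Data frame `(chrom, start, end)`.
#' @param segdups Optional data frame `(chrom, start, end,
#'   percent_identity)`.
#' @param tandem_repeats Optional data frame `(chrom, start, end, score)`.
#' @param chrom_lengths Named numeric vector (needed for subtelomeric).
#' @param centromeres Optional data frame `(chrom, pos)`.
#' @param sd_min_len,sd_min_identity,tr_min_score,subtelo_bp,pericen_bp
#'   Filter settings with the stated defaults.
#' @return `regions` with appended columns `sd_overlap_bp`,
#'   `tr_overlap_bp`, `subtelomeric`, `pericentromeric`.
#' @export
annotate_region_features <- function(regions, segdups = NULL,
                                     tandem_repeats = NULL,
                                     chrom_lengths = NULL,
                                     centromeres = NULL,
                                     sd_min_len = 10000,
                                     sd_min_identity = 0.95,
                                     tr_min_score = 2000,
                                     subtelo_bp = 7e6, pericen_bp = 9e6) {
  out <- as.data.frame(regions)
  overlap_bp <- function(bed, i) {
    sub <- bed[bed$chrom == out$chrom[i], , drop = FALSE]
    sum(pmax(0, pmin(sub$end, out$end[i]) - pmax(sub$start, out$start[i])))
  }
  if (!is.null(segdups)) {
    if (!"percent_identity" %in% names(segdups))
      stop("segdups must carry a percent_identity column")
    sd_f <- segdups[segdups$end - segdups$start >= sd_min_len &
                      segdups$percent_identity >= sd_min_identity, ,
                    drop = FALSE]
    out$sd_overlap_bp <- vapply(seq_len(nrow(out)), function(i)
      overlap_bp(sd_f, i), 0)
  }
  if (!is.null(tandem_repeats)) {
    if (!"score" %in% names(tandem_repeats))
      stop("tandem_repeats must carry a score column")
    tr_f <- tandem_repeats[tandem_repeats$score > tr_min_score, ,
                           drop = FALSE]
    out$tr_overlap_bp <- vapply(seq_len(nrow(out)), function(i)
      overlap_bp(tr_f, i), 0)
  }
  if (!is.null(chrom_lengths)) {
    out$subtelomeric <- vapply(seq_len(nrow(out)), function(i) {
      len <- chrom_lengths[[out$chrom[i]]]
      out$start[i] < subtelo_bp || out$end[i] > len - subtelo_bp
    }, TRUE)
  }
  if (!is.null(centromeres)) {
    out$pericentromeric <- vapply(seq_len(nrow(out)), function(i) {
      sub <- centromeres[centromeres$chrom == out$chrom[i], , drop = FALSE]
      nrow(sub) > 0 && any(out$start[i] < sub$pos + pericen_bp &
                             out$end[i] > sub$pos - pericen_bp)
    }, TRUE)
  }
  out
}

#' Estimate a reference N-gap's size from a spanning alignment
#'
#' The map-based gap size is the query distance between the paired
#' labels flanking the gap minus the reference distance outside the gap
#' between those labels. Negative estimates are legitimate (a deletion
#' removing the gap's flanking sequence).
#'
#' @param gap List or one-row data frame with `chrom`, `start`, `end`.
#' @param alignment An [om_alignment()] spanning the gap.
#' @param query The query [label_map()].
#' @param ref A `reference_digest`.
#' @return List: `sized` (logical), `size_bp` (NA when unsized).
#' @export
estimate_gap_size <- function(gap, alignment, query, ref) {
  a <- alignment
  if (a$ref_id != gap$chrom)
    return(list(sized = FALSE, size_bp = NA_real_))
  rpos <- ref$maps[[a$ref_id]]$positions
  qpos <- query$positions
  ord <- order(a$r_idx)
  ri <- a$r_idx[ord]; qi <- a$q_idx[ord]
  left <- which(rpos[ri] <= gap$start)
  right <- which(rpos[ri] >= gap$end)
  if (length(left) == 0 || length(right) == 0)
    return(list(sized = FALSE, size_bp = NA_real_))
  li <- left[length(left)]; riid <- right[1]
  dq <- abs(qpos[qi[riid]] - qpos[qi[li]])
  d_outside <- (gap$start - rpos[ri[li]]) + (rpos[ri[riid]] - gap$end)
  list(sized = TRUE, size_bp = dq - d_outside)
}
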