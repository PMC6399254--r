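#' Complex SV detection from split alignments
#'
#' Contigs are split-aligned to the reference; the junctions between
#' consecutive segments are candidate breakpoints, typed by their
#' split-alignment signature. Molecules around each breakpoint are then
#' sorted into supporting (split-aligned consistently with the
#' candidate) and rejecting (contiguously aligned across the
#' breakpoint); each molecule is scored by the minimum over its adjacent
#' split maps of `n/(n+l) * log(n)` (`n` matched sites, `l` extra or
#' missing sites; natural log), and the candidate is accepted when the
#' accumulated supporting score exceeds the rejecting score.
#' @name complex-sv
NULL

#' Classify the signature of a split alignment
#'
#' Consecutive segment pairs are typed: different chromosomes give an
#' inter-chromosomal translocation; the same chromosome more than 5 Mb
#' apart an intra-chromosomal translocation; within 5 Mb with opposite
#' orientations an inversion; overlapping reference intervals a
#' duplication; anything else no candidate.
#'
#' @param sa An [om_split_alignment()] with at least two segments.
#' @param max_inv_span_bp Inversion/translocation distance boundary
#'   (default 5 Mb).
#' @return List of candidate records (one per qualifying junction):
#'   `candidate_type`, `chrom1`, `bp1`, `chrom2`, `bp2`, `source_contig`,
#'   `segments` (the two segment alignments).
#' @export
classify_split_signature <- function(sa, max_inv_span_bp = 5e6) {
  stopifnot(is_split(sa), length(sa$segments) >= 2)
  out <- list()
  for (k in seq_len(length(sa$segments) - 1)) {
    a <- sa$segments[[k]]
    b <- sa$segments[[k + 1]]
    bp_a <- if (a$orientation == "+") a$ref_end_bp else a$ref_start_bp
    bp_b <- if (b$orientation == "+") b$ref_start_bp else b$ref_end_bp
    type <- NULL
    if (a$ref_id != b$ref_id) {
      type <- "inter_translocation"
    } else {
      gap <- max(a$ref_start_bp, b$ref_start_bp) -
        min(a$ref_end_bp, b$ref_end_bp)
      overlap <- min(a$ref_end_bp, b$ref_end_bp) -
        max(a$ref_start_bp, b$ref_start_bp)
      if (abs(bp_b - bp_a) > max_inv_span_bp) {
        type <- "intra_translocation"
      } else if (a$orientation != b$orientation) {
        type <- "inversion"
      } else if (overlap > 0) {
        type <- "duplication"
      }
    }
    if (!is.null(type))
      out[[length(out) + 1L]] <- list(
        candidate_type = type, chrom1 = a$ref_id, bp1 = bp_a,
        chrom2 = b$ref_id, bp2 = bp_b, source_contig = sa$query_id,
        segments = list(a, b))
  }
  out
}

#' Per-molecule support/rejection score over adjacent split maps
#'
#' For each adjacent pair of split maps the pair score is the minimum
#' over the two maps of `n/(n+l) * log(n)`; the molecule score `S_M` is
#' the minimum over adjacent pairs (a single pair gives that pair's
#' value). Natural logarithm.
#'
#' @param split_maps Matrix or data frame with columns `n` (matched
#'   sites, >= 1) and `l` (extra or missing sites, >= 0), one row per
#'   split map in query order (at least two rows).
#' @return Numeric `S_M`.
#' @export
score_molecule_eq1 <- function(split_maps) {
  sm <- as.matrix(as.data.frame(split_maps))
  n <- sm[, "n"]; l <- sm[, "l"]
  if (any(n < 1)) stop("each split map needs n >= 1 mapping sites")
  if (any(l < 0)) stop("l must be non-negative")
  if (nrow(sm) < 2) stop("a molecule score needs at least two split maps")
  per_map <- n / (n + l) * log(n)
  min(vapply(seq_len(nrow(sm) - 1),
             function(i) min(per_map[i], per_map[i + 1]), 0))
}

# (n, l) rows for the split maps of a split alignment
split_map_counts <- function(sa) {
  t(vapply(sa$segments, segment_site_counts, c(n = 0, l = 0)))
}

# notional split of a contiguous alignment at reference coordinate bp
notional_split_counts <- function(a, ref, bp) {
  rpos <- ref$maps[[a$ref_id]]$positions
  ord <- order(a$r_idx)
  ri <- a$r_idx[ord]; qi <- a$q_idx[ord]
  left <- rpos[ri] <= bp
  counts <- function(sel) {
    if (sum(sel) == 0) return(c(n = 0, l = 0))
    n <- sum(sel)
    l <- (max(ri[sel]) - min(ri[sel]) + 1 - n) +
      (max(qi[sel]) - min(qi[sel]) + 1 - n)
    c(n = n, l = l)
  }
  rbind(counts(left), counts(!left))
}

#' Adjudicate a complex-SV candidate against the molecule evidence
#'
#' Molecules within `window_bp` of a breakpoint are classified:
#' split-aligned consistently with the candidate (same type, junction
#' breakpoints within the window) they support; contiguously aligned
#' across a breakpoint they reject, scored as if notionally split at the
#' breakpoint. One record per molecule is kept (the largest score; a
#' molecule scored on both sides goes to the higher-scoring side). The
#' candidate is called when the total supporting score strictly exceeds
#' the total rejecting score.
#'
#' @param cand A candidate from [classify_split_signature()] or
#'   [find_small_inversions()].
#' @param molecule_alignments Alignments of single molecules (mixed
#'   single and split).
#' @param ref A `reference_digest`.
#' @param window_bp Breakpoint window (default 200 kb).
#' @return List with `accepted`, `S_s`, `S_r`, `n_support`, `n_reject`,
#'   and `call` (an [sv_calls()] row when accepted, else NULL).
#' @export
adjudicate_candidate <- function(cand, molecule_alignments, ref,
                                 window_bp = 2e5) {
  sup <- list(); rej <- list()
  bps <- list(list(chrom = cand$chrom1, bp = cand$bp1),
              list(chrom = cand$chrom2, bp = cand$bp2))
  for (a in molecule_alignments) {
    if (is_split(a)) {
      sigs <- classify_split_signature(a)
      for (sg in sigs) {
        if (sg$candidate_type != cand$candidate_type) next
        if (sg$chrom1 != cand$chrom1 || sg$chrom2 != cand$chrom2) next
        if (abs(sg$bp1 - cand$bp1) > window_bp ||
            abs(sg$bp2 - cand$bp2) > window_bp) next
        s <- score_molecule_eq1(split_map_counts(a))
        sup[[length(sup) + 1L]] <- list(id = a$query_id, s = s)
      }
    } else {
      for (b in bps) {
        if (a$ref_id != b$chrom) next
        if (a$ref_start_bp >= b$bp || a$ref_end_bp <= b$bp) next
        s <- tryCatch(
          score_molecule_eq1(notional_split_counts(a, ref, b$bp)),
          error = function(e) NA_real_)
        if (is.na(s)) next
        rej[[length(rej) + 1L]] <- list(id = a$query_id, s = s)
      }
    }
  }
  dedup <- function(lst) {
    if (length(lst) == 0)
      return(data.frame(id = character(), s = numeric()))
    df <- data.frame(id = vapply(lst, `[[`, "", "id"),
                     s = vapply(lst, `[[`, 0, "s"))
    df <- df[order(df$id, -df$s), ]
    df[!duplicated(df$id), , drop = FALSE]
  }
  sup_d <- dedup(sup); rej_d <- dedup(rej)
  both <- intersect(sup_d$id, rej_d$id)
  for (id in both) {
    if (sup_d$s[sup_d$id == id] >= rej_d$s[rej_d$id == id])
      rej_d <- rej_d[rej_d$id != id, , drop = FALSE]
    else sup_d <- sup_d[sup_d$id != id, , drop = FALSE]
  }
  if (nrow(sup_d) + nrow(rej_d) == 0)
    return(list(accepted = FALSE, S_s = 0, S_r = 0, n_support = 0L,
                n_reject = 0L, call = NULL, dropped = TRUE))
  S_s <- sum(sup_d$s); S_r <- sum(rej_d$s)
  accepted <- S_s > S_r
  call <- NULL
  if (accepted) {
    lo <- min(cand$bp1, cand$bp2); hi <- max(cand$bp1, cand$bp2)
    if (cand$chrom1 != cand$chrom2) { lo <- cand$bp1; hi <- cand$bp1 }
    call <- sv_calls(chrom = cand$chrom1, start_bp = lo, end_bp = hi,
                     sv_type = cand$candidate_type, size_delta_bp = 0,
                     zygosity = "unknown", support = nrow(sup_d),
                     score = S_s - S_r, module = "complex")
  }
  list(accepted = accepted, S_s = S_s, S_r = S_r,
       n_support = nrow(sup_d), n_reject = nrow(rej_d), call = call,
       dropped = FALSE)
}

#' Search contig alignments for small inversions
#'
#' Within each contig's aligned span, runs of at least `min_labels`
#' unaligned contig labels are re-aligned in reversed orientation
#' against the corresponding reference window; the window is reported as
#' an inversion candidate when the reversed score beats the forward
#' score by `margin`. Spans over 5 Mb are re-typed as intra-chromosomal
#' translocations.
#'
#' @param contig_alignments Contig alignments (single segments are
#'   examined; split alignments contribute each segment).
#' @param contigs Contig [label_map()]s.
#' @param ref A `reference_digest`.
#' @param min_labels Minimum inverted labels (default 4).
#' @param params [align_params()] for the window re-alignment.
#' @param margin Required score advantage of the reversed orientation
#'   (default 2).
#' @return List of candidate records in the format of
#'   [classify_split_signature()].
#' @export
find_small_inversions <- function(contig_alignments, contigs, ref,
                                  min_labels = 4L,
                                  params = align_params(), margin = 2,
                                  poor_cut = 15) {
  qmap <- query_index(contigs)
  out <- list()
  for (a in flatten_alignments(contig_alignments)) {
    ctg <- qmap[[a$query_id]]
    if (is.null(ctg) || !a$ref_id %in% names(ref$maps)) next
    rpos <- ref$maps[[a$ref_id]]$positions
    qi <- sort(a$q_idx)
    # windows of entirely unaligned contig labels between aligned flanks
    windows <- list()
    ord <- order(a$q_idx)
    q2r <- stats::setNames(a$r_idx[ord], as.character(a$q_idx[ord]))
    for (r in unaligned_runs(qi, n_labels(ctg))) {
      if (length(r) < min_labels) next
      left_q <- suppressWarnings(max(qi[qi < r[1]]))
      right_q <- suppressWarnings(min(qi[qi > r[length(r)]]))
      if (!is.finite(left_q) || !is.finite(right_q)) next
      windows[[length(windows) + 1L]] <-
        list(qrun = r, rl = q2r[[as.character(left_q)]],
             rr = q2r[[as.character(right_q)]])
    }
    # poorly aligned stretches: each substantially negative chain step
    # seeds a window, expanded across weak neighbouring steps and widened
    # by one anchor pair on each side; the window's query labels (paired
    # or not) are then tested in reversed orientation
    qo <- a$q_idx[ord]; ro <- a$r_idx[ord]
    steps <- chain_step_nets(ctg$positions, rpos, qo, ro, params)
    np <- length(qo)
    seen <- character()
    for (k in which(steps < -2)) {
      s <- k; e <- k
      while (s > 1 && steps[s - 1] < 1) s <- s - 1
      while (e < length(steps) && steps[e + 1] < 1) e <- e + 1
      al <- max(1L, s - 1L)          # anchor pairs around the region
      ar <- min(np, e + 2L)
      key <- paste(al, ar)
      if (key %in% seen) next
      seen <- c(seen, key)
      inner_q <- seq(min(qo[al], qo[ar]) + 1L, max(qo[al], qo[ar]) - 1L)
      inner_q <- inner_q[inner_q >= 1 & inner_q <= n_labels(ctg)]
      if (length(inner_q) < min_labels) next
      windows[[length(windows) + 1L]] <-
        list(qrun = inner_q, rl = ro[al], rr = ro[ar])
    }
    for (w in windows) {
      rwin <- sort(c(w$rl, w$rr))
      if (rwin[2] - rwin[1] < 2) next
      rsub <- rpos[seq(rwin[1], rwin[2])]
      qsub <- ctg$positions[w$qrun]
      fwd <- dp_align(qsub, rsub, params)$score
      rev_ <- dp_align(max(qsub) - rev(qsub), rsub, params)$score
      if (rev_ > fwd + margin) {
        lo <- rpos[rwin[1]]; hi <- rpos[rwin[2]]
        type <- if (hi - lo > 5e6) "intra_translocation" else "inversion"
        out[[length(out) + 1L]] <- list(
          candidate_type = type, chrom1 = a$ref_id, bp1 = lo,
          chrom2 = a$ref_id, bp2 = hi, source_contig = a$query_id,
          segments = NULL, reversed_score = rev_, forward_score = fwd)
      }
    }
  }
  out
}

unaligned_runs <- function(aligned_idx, n) {
  un <- setdiff(seq_len(n), aligned_idx)
  if (length(un) == 0) return(list())
  brk <- c(0, which(diff(un) > 1), length(un))
  lapply(seq_len(length(brk) - 1),
         function(i) un[seq(brk[i] + 1, brk[i + 1])])
}

#' Full complex-SV pipeline
#'
#' Candidates from contig split-alignment signatures and from the
#' small-inversion search are merged (reciprocal overlap 0.5) and each
#' is adjudicated against the molecule alignments.
#'
#' @param contig_alignments,molecule_alignments Alignment lists.
#' @param contigs Contig [label_map()]s.
#' @param ref A `reference_digest`.
#' @param window_bp Breakpoint window (default 200 kb).
#' @param min_inv_labels Small-inversion label floor (default 4).
#' @param params [align_params()] for window re-alignment.
#' @return An [sv_calls()] data frame (module `complex`).
#' @export
call_complex_svs <- function(contig_alignments, molecule_alignments,
                             contigs, ref, window_bp = 2e5,
                             min_inv_labels = 4L,
                             params = align_params()) {
  cands <- list()
  for (a in contig_alignments)
    if (is_split(a)) cands <- c(cands, classify_split_signature(a))
  cands <- c(cands, find_small_inversions(contig_alignments, contigs,
                                          ref, min_inv_labels, params))
  cands <- dedup_candidates(cands, window_bp)
  calls <- list()
  for (cand in cands) {
    adj <- adjudicate_candidate(cand, molecule_alignments, ref, window_bp)
    if (!is.null(adj$call)) calls[[length(calls) + 1L]] <- adj$call
  }
  out <- bind_sv_calls(calls)
  if (nrow(out) > 0) {
    # complex calls are breakpoint pairs: merge only records whose two
    # breakpoints both agree within the window (reciprocal interval
    # overlap would collapse distinct distant translocations)
    cl <- integer(nrow(out))
    for (i in seq_len(nrow(out))) {
      hit <- which(cl > 0 & out$sv_type == out$sv_type[i] &
                     out$chrom == out$chrom[i] &
                     abs(out$start_bp - out$start_bp[i]) <= window_bp &
                     abs(out$end_bp - out$end_bp[i]) <= window_bp)
      cl[i] <- if (length(hit) > 0) cl[hit[1]] else max(cl) + 1L
    }
    keep <- !duplicated(cl)
    agg <- out[keep, , drop = FALSE]
    agg$support <- vapply(split(out$support, cl), max, 0L)
    out <- as_sv_calls(agg[order(agg$chrom, agg$start_bp), , drop = FALSE])
  }
  log_stage("call_complex", candidates = length(cands), calls = nrow(out))
  out
}

dedup_candidates <- function(cands, window_bp) {
  if (length(cands) <= 1) return(cands)
  keep <- list()
  for (cand in cands) {
    dup <- FALSE
    for (k in keep) {
      if (k$candidate_type == cand$candidate_type &&
          k$chrom1 == cand$chrom1 && k$chrom2 == cand$chrom2 &&
          abs(k$bp1 - cand$bp1) <= window_bp &&
          abs(k$bp2 - cand$bp2) <= window_bp) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1L]] <- cand
  }
  keep
}

#' Count tandem repeat units between two flank patterns on a contig
#'
#' Label-distance patterns are matched within a per-interval sizing
#' tolerance. Both flank patterns must occur exactly once, left before
#' right; the count is the number of non-overlapping unit occurrences
#' between them.
#'
#' @param contig A contig [label_map()].
#' @param left_flank_pattern,right_flank_pattern,unit_pattern Numeric
#'   vectors of consecutive inter-label distances (bp).
#' @param tol Relative tolerance per interval (default 0.15).
#' @return List with `countable` (logical), `copy_number` (integer or
#'   NA) and `reason` when uncountable.
#' @export
count_tandem_units <- function(contig, left_flank_pattern,
                               right_flank_pattern, unit_pattern,
                               tol = 0.15) {
  gaps <- diff(contig$positions)
  left_hits <- match_distance_pattern(gaps, left_flank_pattern, tol)
  right_hits <- match_distance_pattern(gaps, right_flank_pattern, tol)
  if (length(left_hits) != 1)
    return(list(countable = FALSE, copy_number = NA_integer_,
                reason = if (length(left_hits) == 0) "left flank absent"
                         else "left flank duplicated"))
  if (length(right_hits) != 1)
    return(list(countable = FALSE, copy_number = NA_integer_,
                reason = if (length(right_hits) == 0) "right flank absent"
                         else "right flank duplicated"))
  lo <- left_hits + length(left_flank_pattern)  # first gap index inside
  hi <- right_hits - 1                           # last gap index inside
  if (hi < lo - 1 || right_hits <= left_hits)
    return(list(countable = FALSE, copy_number = NA_integer_,
                reason = "flanks out of order"))
  inner <- if (hi >= lo) gaps[lo:hi] else numeric()
  k <- length(unit_pattern)
  count <- 0L
  i <- 1L
  while (i + k - 1L <= length(inner)) {
    seg <- inner[i:(i + k - 1L)]
    if (all(abs(seg - unit_pattern) <= tol * unit_pattern)) {
      count <- count + 1L
      i <- i + k
    } else i <- i + 1L
  }
  list(countable = TRUE, copy_number = count, reason = NA_character_)
}

match_distance_pattern <- function(gaps, pattern, tol) {
  k <- length(pattern)
  n <- length(gaps)
  if (n < k) return(integer())
  hits <- integer()
  for (i in seq_len(n - k + 1)) {
    seg <- gaps[i:(i + k - 1)]
    if (all(abs(seg - pattern) <= tol * pattern))
      hits <- c(hits, i)
  }
  hits
}
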