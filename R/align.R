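#' Alignment parameters
#'
#' Scoring constants for the label-chain dynamic program. Each paired
#' label earns `match_bonus`; skipped query/reference labels cost `cq`/
#' `cr` each; a chain step spanning query distance `dq` and reference
#' distance `dr` pays `min((dq-dr)^2 / (sf_pen^2 + (sr_pen*dr)^2),
#' outlier_cap)`. The cap keeps a single large-indel interval from
#' severing an otherwise well-anchored alignment, so indels are bridged
#' and left to the interval-distance test.
#'
#' @param match_bonus Per-pair bonus (default 3).
#' @param cq,cr Per-skipped-label costs (default 1.5 each).
#' @param sf_pen Additive sizing scale in bp (default 500).
#' @param sr_pen Relative sizing coefficient (default 0.02).
#' @param K Maximum labels skipped per step (default 9, enough to bridge
#'   the label content of indels up to ~50 kb at typical label density).
#' @param outlier_cap Upper bound on one step's sizing penalty
#'   (default 12).
#' @param min_query_labels Minimum query labels to attempt alignment
#'   (default 5).
#' @param min_labels_per_segment Minimum matched labels for a split
#'   segment (default 5).
#' @param floor Reporting floor: alignments scoring at or below it are
#'   discarded (default 0).
#' @param chim_cut Chimeric cut: a run of two or more consecutive
#'   negative-scoring steps whose net score is `-chim_cut` or worse is
#'   excised and the alignment split there (default 25). A single bad
#'   step — the signature of a bridged indel — is never cut.
#' @return List of class `align_params`.
#' @export
align_params <- function(match_bonus = 3, cq = 1.5, cr = 1.5,
                         sf_pen = 500, sr_pen = 0.02, K = 9L,
                         outlier_cap = 12, min_query_labels = 5L,
                         min_labels_per_segment = 5L, floor = 0,
                         chim_cut = 25) {
  structure(list(match_bonus = match_bonus, cq = cq, cr = cr,
                 sf_pen = sf_pen, sr_pen = sr_pen, K = as.integer(K),
                 outlier_cap = outlier_cap,
                 min_query_labels = as.integer(min_query_labels),
                 min_labels_per_segment = as.integer(min_labels_per_segment),
                 floor = floor, chim_cut = chim_cut),
            class = "align_params")
}

# per-step net contributions of a chain (in chain order): between pair k
# and pair k+1. Step net = match_bonus - sizing_pen - skip costs; the
# first pair contributes match_bonus separately.
chain_step_nets <- function(qpos, rpos, qi, ri, p) {
  if (length(qi) < 2) return(numeric())
  dq <- abs(diff(qpos[qi]))
  dr <- diff(rpos[ri])
  pen <- pmin((dq - dr)^2 / (p$sf_pen^2 + (p$sr_pen * dr)^2),
              p$outlier_cap)
  p$match_bonus - pen - p$cq * (abs(diff(qi)) - 1) -
    p$cr * (abs(diff(ri)) - 1)
}

# Split a chain where it crosses a region it does not genuinely fit.
# The worst (minimum-sum) contiguous stretch of steps is excised when its
# net score is -chim_cut or worse AND it contains at least two
# substantially bad steps (<= -5): a bridged indel is a single bad step
# flanked by good ones and is deliberately never cut. Applied
# recursively to both remaining sides. Returns pair-index ranges.
chimeric_fragments <- function(steps, chim_cut) {
  n_pairs <- length(steps) + 1L
  if (length(steps) == 0) return(list(seq_len(n_pairs)))
  min_subarray <- function(lo, hi) {
    best <- c(sum = Inf, s = lo, e = lo)
    run <- 0; run_s <- lo
    for (k in lo:hi) {
      if (run > 0) { run <- 0; run_s <- k }
      run <- run + steps[k]
      if (run < best["sum"]) best <- c(sum = run, s = run_s, e = k)
    }
    best
  }
  frag <- function(plo, phi) {
    if (phi - plo < 1) return(list(seq(plo, phi)))
    b <- min_subarray(plo, phi - 1L)
    s <- b[["s"]]; e <- b[["e"]]
    if (b[["sum"]] > -chim_cut || sum(steps[s:e] <= -5) < 2)
      return(list(seq(plo, phi)))
    out <- list()
    if (s >= plo) out <- c(out, frag(plo, s))
    if (e + 1L <= phi) out <- c(out, frag(e + 1L, phi))
    out
  }
  frag(1L, n_pairs)
}

dp_align <- function(qpos, rpos, p) {
  dp_align_cpp(qpos, rpos, p$match_bonus, p$cq, p$cr, p$sf_pen, p$sr_pen,
               p$K, p$outlier_cap)
}

# Coarse-to-fine alignment against a long reference: a cheap K=2 scan
# locates the placement, then the full dynamic program runs on a window
# of the reference around it (pad labels each side). Exact full DP is
# used whenever the reference is not much longer than the query.
dp_align_fast <- function(qpos, rpos, p, pad = 30L) {
  nr <- length(rpos)
  if (nr <= length(qpos) + 2L * pad + 20L) return(dp_align(qpos, rpos, p))
  coarse <- dp_align_cpp(qpos, rpos, p$match_bonus, p$cq, p$cr,
                         p$sf_pen, p$sr_pen, 2L, p$outlier_cap)
  if (coarse$score <= p$floor || length(coarse$r_idx) == 0)
    return(coarse)
  w0 <- max(1L, min(coarse$r_idx) - pad)
  w1 <- min(nr, max(coarse$r_idx) + pad)
  full <- dp_align(qpos, rpos[w0:w1], p)
  full$r_idx <- full$r_idx + w0 - 1L
  full
}

build_alignment <- function(query, ref, orientation, q_orig, r_idx,
                            score) {
  rpos <- ref$positions
  qspan <- range(q_orig)
  n_extra <- (qspan[2] - qspan[1] + 1L) - length(q_orig)
  n_miss <- (max(r_idx) - min(r_idx) + 1L) - length(r_idx)
  om_alignment(query$map_id, ref$map_id, orientation,
               q_idx = q_orig, r_idx = r_idx, score = score,
               ref_start_bp = rpos[min(r_idx)],
               ref_end_bp = rpos[max(r_idx)],
               n_extra_query = n_extra, n_missed_ref = n_miss)
}

# Align a subset of query labels (original indices idx) against all refs
# and both orientations; the best chain is chimera-cut into fragments.
# Returns a list of om_alignment (possibly empty).
best_placement <- function(query, idx, refs, p) {
  qpos <- query$positions[idx]
  nq <- length(qpos)
  best <- NULL
  for (ref in refs) {
    rpos <- ref$positions
    if (length(rpos) == 0) next
    fwd <- dp_align_fast(qpos, rpos, p)
    if (is.null(best) || fwd$score > best$score)
      best <- list(score = fwd$score, q = fwd$q_idx, r = fwd$r_idx,
                   ref = ref, orientation = "+")
    rev_pos <- query$length_bp - rev(qpos)
    bwd <- dp_align_fast(rev_pos, rpos, p)
    if (bwd$score > best$score)
      best <- list(score = bwd$score, q = bwd$q_idx, r = bwd$r_idx,
                   ref = ref, orientation = "-")
  }
  if (is.null(best) || best$score <= p$floor ||
      length(best$q) < p$min_labels_per_segment) return(list())
  q_orig <- if (best$orientation == "+") idx[best$q] else
    idx[nq + 1L - best$q]  # reversed coordinates back to original
  rpos <- best$ref$positions
  steps <- chain_step_nets(query$positions, rpos, q_orig, best$r, p)
  frags <- chimeric_fragments(steps, p$chim_cut)
  out <- list()
  for (fr in frags) {
    if (length(fr) < p$min_labels_per_segment) next
    qi <- q_orig[fr]; ri <- best$r[fr]
    sc <- p$match_bonus +
      sum(chain_step_nets(query$positions, rpos, qi, ri, p))
    if (sc <= p$floor) next
    out[[length(out) + 1L]] <-
      build_alignment(query, best$ref, best$orientation, qi, ri, sc)
  }
  out
}

#' Align a query label map to reference maps
#'
#' Orientation-aware local alignment by dynamic programming over label
#' chains. When `split = TRUE`, unaligned query flanks of at least
#' `min_labels_per_segment` labels are re-aligned recursively, producing a
#' split alignment whose junctions are candidate SV breakpoints.
#'
#' @param query A [label_map()] (molecule or contig).
#' @param refs A [label_map()], list of them, or a `reference_digest`.
#' @param params An [align_params()] object.
#' @param split Attempt split alignment of unaligned flanks
#'   (default `TRUE`).
#' @return An [om_alignment()], an [om_split_alignment()], or `NULL` when
#'   no placement scores above the reporting floor.
#' @export
align_map <- function(query, refs, params = align_params(), split = TRUE) {
  refs <- as_ref_list(refs)
  if (n_labels(query) < params$min_query_labels) return(NULL)
  segments <- list()
  recurse <- function(idx, depth) {
    if (length(idx) < params$min_labels_per_segment || depth > 8) return()
    frags <- best_placement(query, idx, refs, params)
    if (length(frags) == 0) return()
    for (a in frags) segments[[length(segments) + 1L]] <<- a
    if (split) {
      taken <- sort(unlist(lapply(frags, `[[`, "q_idx")))
      left <- setdiff(idx, seq(min(taken), max(taken)))
      inner <- setdiff(seq(min(taken), max(taken)), taken)
      for (run in contiguous_runs(sort(c(left, inner))))
        if (length(run) >= params$min_labels_per_segment)
          recurse(run, depth + 1)
    }
  }
  recurse(seq_len(n_labels(query)), 1)
  if (length(segments) == 0) return(NULL)
  if (length(segments) == 1) return(segments[[1]])
  ord <- order(vapply(segments, function(s) min(s$q_idx), 0L))
  om_split_alignment(query$map_id, segments[ord])
}

contiguous_runs <- function(x) {
  if (length(x) == 0) return(list())
  brk <- c(0, which(diff(x) > 1), length(x))
  lapply(seq_len(length(brk) - 1),
         function(i) x[seq(brk[i] + 1, brk[i + 1])])
}

as_ref_list <- function(refs) {
  if (inherits(refs, "reference_digest")) return(refs$maps)
  if (inherits(refs, "label_map")) return(list(refs))
  refs
}

#' Align a set of molecules to reference maps
#'
#' @param molecules List of [label_map()]s.
#' @param refs Reference maps (see [align_map()]).
#' @param params An [align_params()].
#' @param split Allow split alignments.
#' @return List of alignments (NULL results dropped).
#' @export
align_all <- function(molecules, refs, params = align_params(),
                      split = TRUE) {
  refs <- as_ref_list(refs)
  out <- lapply(molecules, align_map, refs = refs, params = params,
                split = split)
  out <- out[!vapply(out, is.null, TRUE)]
  log_stage("align", queries = length(molecules), placed = length(out))
  out
}

#' Calibrate the alignment-confidence null model
#'
#' The confidence of an alignment is defined as `-log10` of the
#' probability that a random query of comparable label content achieves
#' at least the observed score anywhere on the reference. The null is
#' estimated by aligning `n_perm` label-shuffled queries (intervals
#' resampled from the reference's inter-label distances) against a window
#' of the reference, then fitting a Gumbel law to the best-score
#' distribution; the tail is extrapolated beyond the empirical range and
#' a Bonferroni-style factor accounts for the full reference search
#' space. The model is deterministic under `seed` and is cached by
#' [confidence_score()] callers.
#'
#' @param refs Reference maps.
#' @param params An [align_params()].
#' @param n_labels Label count of the shuffled queries (default 20).
#' @param n_perm Number of permuted queries (default 10000).
#' @param window_labels Reference window size in labels used for the
#'   permutation alignments (default 200).
#' @param seed Integer seed.
#' @return List of class `confidence_null`.
#' @export
calibrate_confidence <- function(refs, params = align_params(),
                                 n_labels = 20L, n_perm = 10000L,
                                 window_labels = 200L, seed = 1L) {
  refs <- as_ref_list(refs)
  all_iv <- unlist(lapply(refs, function(m) diff(m$positions)))
  if (length(all_iv) < 2) stop("reference has too few labels to calibrate")
  total_labels <- sum(vapply(refs, n_labels, 0L))
  w <- min(window_labels, max(vapply(refs, n_labels, 0L)))
  ref_big <- refs[[which.max(vapply(refs, n_labels, 0L))]]
  rpos <- ref_big$positions[seq_len(w)]
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  queries <- lapply(seq_len(n_perm), function(i) {
    iv <- sample(all_iv, n_labels - 1L, replace = TRUE)
    cumsum(c(0, iv))
  })
  s_f <- dp_best_scores_cpp(queries, rpos, params$match_bonus, params$cq,
                            params$cr, params$sf_pen, params$sr_pen,
                            params$K, params$outlier_cap)
  queries_r <- lapply(queries, function(q) max(q) - rev(q))
  s_r <- dp_best_scores_cpp(queries_r, rpos, params$match_bonus, params$cq,
                            params$cr, params$sf_pen, params$sr_pen,
                            params$K, params$outlier_cap)
  scores <- pmax(s_f, s_r)
  scale <- stats::sd(scores) * sqrt(6) / pi
  loc <- mean(scores) - 0.5772156649 * scale
  structure(list(scores = scores, loc = loc, scale = scale,
                 window_labels = w, total_labels = total_labels,
                 n_labels = n_labels, n_perm = n_perm, seed = seed),
            class = "confidence_null")
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Confidence score of an alignment
#'
#' `-log10` of the Gumbel-tail probability that a shuffled query reaches
#' the alignment's score anywhere on the reference (see
#' [calibrate_confidence()]). Monotone non-decreasing in the score.
#'
#' @param alignment An [om_alignment()] (or split alignment: the minimum
#'   segment confidence is returned).
#' @param null_model A `confidence_null` from [calibrate_confidence()].
#' @return Numeric confidence (capped at 60).
#' @export
confidence_score <- function(alignment, null_model) {
  if (is.null(null_model) || !inherits(null_model, "confidence_null"))
    stop("null model absent: run calibrate_confidence() first")
  if (is_split(alignment))
    return(min(vapply(alignment$segments, confidence_score, 0,
                      null_model = null_model)))
  z <- (alignment$score - null_model$loc) / null_model$scale
  # Gumbel upper tail; log-scale for numerical stability deep in the tail
  log_p <- log1mexp(exp(-z))
  trials <- max(1, null_model$total_labels / null_model$window_labels)
  log_p <- log_p + log(trials)
  conf <- -log_p / log(10)
  max(0, min(conf, 60))
}

# log(1 - exp(-x)) for x > 0, stable for both small and large x
log1mexp <- function(x) {
  ifelse(x <= log(2), log(-expm1(-x)), log1p(-exp(-x)))
}

#' Attach confidences and filter alignments
#'
#' @param alignments List of alignments.
#' @param null_model A `confidence_null`.
#' @param min_confidence Threshold; alignments below it are dropped
#'   (default 9, the pipeline's standard filter).
#' @return Filtered list with `confidence` fields set.
#' @export
filter_by_confidence <- function(alignments, null_model,
                                 min_confidence = 9) {
  out <- list()
  for (a in alignments) {
    cf <- confidence_score(a, null_model)
    if (cf <= min_confidence) next
    if (is_split(a)) {
      a$segments <- lapply(a$segments, function(s) {
        s$confidence <- confidence_score(s, null_model); s })
    } else a$confidence <- cf
    out[[length(out) + 1L]] <- a
  }
  log_stage("confidence_filter", input = length(alignments),
            kept = length(out), threshold = min_confidence)
  out
}

#' Compose molecule-to-contig and contig-to-reference alignments
#'
#' The molecule-contig-reference (MCR) route: if molecule label `i` is
#' aligned to contig label `j` and `j` to reference label `k`, then `i`
#' and `k` are aligned indirectly. Each molecule is assigned to exactly
#' one contig, the one it aligns to with the highest score (ties broken
#' by contig id); composed pairs are split into maximal runs of
#' consistent orientation.
#'
#' @param mol_to_contig List of alignments of molecules to contigs.
#' @param contig_to_ref List of alignments of contigs to the reference.
#' @param min_pairs Minimum composed pairs per emitted run (default 2).
#' @return List with `alignments` (composed [om_alignment()]s) and
#'   `n_unassigned` (molecules with no contig alignment).
#' @export
align_indirect <- function(mol_to_contig, contig_to_ref, min_pairs = 2L) {
  ctr_segs <- flatten_alignments(contig_to_ref)
  ctr_by_contig <- split(ctr_segs,
                         vapply(ctr_segs, `[[`, "", "query_id"))
  mtc <- flatten_alignments(mol_to_contig)
  by_mol <- split(mtc, vapply(mtc, `[[`, "", "query_id"))
  out <- list()
  n_unassigned <- 0L
  for (mol_id in names(by_mol)) {
    segs <- by_mol[[mol_id]]
    contigs <- vapply(segs, `[[`, "", "ref_id")
    sc <- vapply(split(vapply(segs, `[[`, 0, "score"), contigs),
                 sum, 0)
    best_contig <- names(sc)[order(-sc, names(sc))][1]
    if (!best_contig %in% names(ctr_by_contig)) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    mol_segs <- segs[contigs == best_contig]
    for (ms in mol_segs) {
      for (cs in ctr_by_contig[[best_contig]]) {
        comp <- compose_pair(ms, cs)
        if (!is.null(comp) && comp$n_matched >= min_pairs)
          out[[length(out) + 1L]] <- comp
      }
    }
  }
  list(alignments = out, n_unassigned = n_unassigned)
}

compose_pair <- function(ms, cs) {
  # ms: molecule -> contig; cs: contig -> reference
  m <- match(ms$r_idx, cs$q_idx)
  keep <- !is.na(m)
  if (sum(keep) == 0) return(NULL)
  qi <- ms$q_idx[keep]
  rk <- cs$r_idx[m[keep]]
  orient <- if (ms$orientation == cs$orientation) "+" else "-"
  ord <- order(rk)
  qi <- qi[ord]; rk <- rk[ord]
  # keep the longest run monotone in the molecule coordinate
  dir <- if (orient == "+") 1 else -1
  runs <- split_monotone_runs(qi * dir)
  best <- runs[[which.max(lengths(runs))]]
  if (length(best) < 1) return(NULL)
  qi <- qi[best]; rk <- rk[best]
  om_alignment(ms$query_id, cs$ref_id, orient, q_idx = qi, r_idx = rk,
               score = min(ms$score, cs$score),
               ref_start_bp = NA_real_, ref_end_bp = NA_real_,
               confidence = min(ms$confidence, cs$confidence))
}

split_monotone_runs <- function(x) {
  if (length(x) <= 1) return(list(seq_along(x)))
  brk <- c(0, which(diff(x) <= 0), length(x))
  lapply(seq_len(length(brk) - 1),
         function(i) seq(brk[i] + 1, brk[i + 1]))
}

# number of matched sites (n) and extra+missing sites (l) used by the
# complex-SV molecule score
segment_site_counts <- function(a) {
  c(n = a$n_matched, l = a$n_extra_query + a$n_missed_ref)
}
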