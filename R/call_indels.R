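#' Indel calling from inter-label distances
#'
#' For every pair of adjacent labels on the reference, the reference
#' distance `d0` is compared with the distances `d1..dn` measured on the
#' aligned molecules (directly, MR, or via contigs, MCR). Under the
#' sizing-error model a measured distance over true spanned length `t` is
#' `Normal(t, sigma(t))` with `sigma(t)^2 = (1000*sizing_sf)^2 +
#' (sizing_sr*t)^2`. Five hypotheses are compared by maximum likelihood:
#'
#' * `H0`: no indel, `t = d0`;
#' * `Hhom`: homozygous indel, `t = d0 + delta`;
#' * `Hhet_ins`/`Hhet_del`: equal-weight mixture of `t = d0` and
#'   `t = d0 + delta` with `delta` at least / at most +-`min_delta_bp`;
#' * `Htri`: equal-weight mixture of two distinct indel alleles.
#'
#' A call is emitted when the winning alternative's log10 likelihood
#' ratio against `H0` reaches the cutoff, the size estimate exceeds the
#' 2 kb floor, and enough molecules support the variant component.
#' @name indel-calling
NULL

sigma_bp <- function(t, noise) {
  sqrt((1000 * noise$sizing_sf)^2 + (noise$sizing_sr * t)^2)
}

#' Collect interval evidence from alignments
#'
#' @param alignments List of (confidence-filtered) alignments; split
#'   alignments contribute each segment.
#' @param ref A `reference_digest`.
#' @param queries List of the query [label_map()]s (molecules or
#'   contigs), named or not; needed to read off query distances.
#' @param source Evidence source tag, `"MR"` or `"MCR"`.
#' @return List of `interval_evidence` records: `chrom`, `left_idx`,
#'   `right_idx`, `left_pos`, `right_pos`, `d0`, `distances`, `mol_ids`,
#'   `source`.
#' @export
collect_interval_evidence <- function(alignments, ref, queries,
                                      source = "MR") {
  qmap <- query_index(queries)
  segs <- flatten_alignments(alignments)
  segs <- segs[vapply(segs, function(a)
    a$ref_id %in% names(ref$maps) && !is.null(qmap[[a$query_id]]), TRUE)]
  # pass 1: candidate site pairs = pairs consecutive in any alignment
  # chain (adjacent on the reference, or adjacent on the molecule when
  # interior reference sites are absent from it)
  keys <- new.env(parent = emptyenv())
  for (a in segs) {
    ord <- order(a$r_idx)
    ri <- a$r_idx[ord]
    if (length(ri) < 2) next
    for (k in seq_len(length(ri) - 1)) {
      key <- paste0(a$ref_id, ":", ri[k], ":", ri[k + 1])
      keys[[key]] <- c(a$ref_id, ri[k], ri[k + 1])
    }
  }
  # pass 2: for each candidate pair, the query distance on every
  # alignment pairing both sites
  acc <- new.env(parent = emptyenv())
  for (a in segs) {
    qpos <- qmap[[a$query_id]]$positions
    rpos <- ref$maps[[a$ref_id]]$positions
    ord <- order(a$r_idx)
    ri <- a$r_idx[ord]; qi <- a$q_idx[ord]
    if (length(ri) < 2) next
    for (k1 in seq_len(length(ri) - 1)) {
      for (k2 in (k1 + 1):length(ri)) {
        key <- paste0(a$ref_id, ":", ri[k1], ":", ri[k2])
        if (is.null(keys[[key]])) next
        rec <- acc[[key]]
        if (is.null(rec)) {
          j1 <- ri[k1]; j2 <- ri[k2]
          rec <- list(chrom = a$ref_id, left_idx = j1, right_idx = j2,
                      left_pos = rpos[j1], right_pos = rpos[j2],
                      d0 = rpos[j2] - rpos[j1], distances = numeric(),
                      mol_ids = character(), source = source)
        }
        rec$distances <- c(rec$distances,
                           abs(qpos[qi[k2]] - qpos[qi[k1]]))
        rec$mol_ids <- c(rec$mol_ids, a$query_id)
        acc[[key]] <- rec
      }
    }
  }
  out <- lapply(ls(acc), function(k) acc[[k]])
  ord <- order(vapply(out, `[[`, "", "chrom"),
               vapply(out, `[[`, 0, "left_pos"),
               vapply(out, `[[`, 0, "right_pos"))
  log_stage("collect_evidence", intervals = length(out), source = source)
  out[ord]
}

query_index <- function(queries) {
  ids <- vapply(queries, `[[`, "", "map_id")
  stats::setNames(queries, ids)
}

# every hypothesis carries a small uniform outlier component so that a
# few misaligned molecules cannot flip the verdict
OUTLIER_DENS <- 1e-6

mix_loglik <- function(d, t1, t2, noise, outlier_frac = 0.03) {
  l1 <- stats::dnorm(d, t1, sigma_bp(t1, noise)) / 2
  l2 <- stats::dnorm(d, t2, sigma_bp(t2, noise)) / 2
  sum(log((1 - outlier_frac) * (l1 + l2) +
            outlier_frac * OUTLIER_DENS))
}

hom_loglik <- function(d, t, noise, outlier_frac = 0.03) {
  sum(log((1 - outlier_frac) *
            stats::dnorm(d, t, sigma_bp(t, noise)) +
            outlier_frac * OUTLIER_DENS))
}

# maximize a 1-d loglik over delta by coarse grid + golden refinement
opt_delta <- function(f, lower, upper, d, d0) {
  if (lower >= upper) return(list(delta = NA_real_, loglik = -Inf))
  cand <- unique(pmin(pmax(c(d - d0, seq(lower, upper, length.out = 41)),
                           lower), upper))
  vals <- vapply(cand, f, 0)
  best <- cand[which.max(vals)]
  span <- max((upper - lower) / 40, 1)
  o <- stats::optimize(f, lower = max(lower, best - span),
                       upper = min(upper, best + span), maximum = TRUE)
  if (o$objective >= max(vals))
    list(delta = o$maximum, loglik = o$objective)
  else list(delta = best, loglik = max(vals))
}

tri_fit <- function(d, d0, noise, min_delta, max_delta = 5e5) {
  n <- length(d)
  qs <- list(c(0.25, 0.75), c(0.1, 0.9), c(0.35, 0.65), c(0.05, 0.5),
             c(0.5, 0.95))
  clamp <- function(delta) {
    s <- ifelse(delta >= 0, 1, -1)
    s * pmin(pmax(abs(delta), min_delta), max_delta)
  }
  best <- list(loglik = -Inf, deltas = c(NA_real_, NA_real_),
               post = NULL)
  for (q in qs) {
    t1 <- stats::quantile(d, q[1], names = FALSE)
    t2 <- stats::quantile(d, q[2], names = FALSE)
    t1 <- d0 + clamp(t1 - d0); t2 <- d0 + clamp(t2 - d0)
    for (it in 1:50) {
      p1 <- stats::dnorm(d, t1, sigma_bp(t1, noise))
      p2 <- stats::dnorm(d, t2, sigma_bp(t2, noise))
      r1 <- p1 / pmax(p1 + p2, 1e-300)
      t1n <- d0 + clamp(sum(r1 * d) / max(sum(r1), 1e-12) - d0)
      t2n <- d0 + clamp(sum((1 - r1) * d) / max(sum(1 - r1), 1e-12) - d0)
      if (abs(t1n - t1) < 0.5 && abs(t2n - t2) < 0.5) {
        t1 <- t1n; t2 <- t2n; break
      }
      t1 <- t1n; t2 <- t2n
    }
    # two alleles closer than the size floor are indistinguishable at
    # this resolution; such fits merely split the sizing noise in half
    if (abs(t1 - t2) < min_delta) next
    ll <- mix_loglik(d, t1, t2, noise)
    if (ll > best$loglik)
      best <- list(loglik = ll, deltas = c(t1 - d0, t2 - d0),
                   post = NULL)
  }
  best
}

#' Likelihood-ratio test of one interval's evidence
#'
#' @param ev An `interval_evidence` record (see
#'   [collect_interval_evidence()]).
#' @param noise A [noise_model()] supplying the sizing-error law.
#' @param min_delta_bp Indel size floor (default 2000).
#' @param min_support Minimum molecules supporting the variant component
#'   (default 10; the loose threshold is 6).
#' @param lr_cutoff_log10 log10 likelihood-ratio cutoff vs `H0`
#'   (default 3).
#' @param max_delta_bp Upper bound of the size search (default 500 kb).
#' @param outlier_frac Weight of the uniform outlier component shared by
#'   all hypotheses (default 0.03); robustifies the verdict against the
#'   occasional misaligned molecule.
#' @return List of class `hypothesis_result` with per-hypothesis
#'   logliks, MLE deltas, the winning hypothesis, `log10_LR_vs_H0`,
#'   `support`, and `call` (an [sv_calls()] row or NULL).
#' @export
test_interval <- function(ev, noise = noise_model(), min_delta_bp = 2000,
                          min_support = 10, lr_cutoff_log10 = 3,
                          max_delta_bp = 5e5, outlier_frac = 0.03) {
  d <- ev$distances
  d0 <- ev$d0
  n <- length(d)
  ll0 <- hom_loglik(d, d0, noise, outlier_frac)
  res_hom <- opt_delta(function(x) hom_loglik(d, d0 + x, noise,
                                              outlier_frac),
                       -d0 + 1, max_delta_bp, d, d0)
  res_ins <- opt_delta(function(x) mix_loglik(d, d0, d0 + x, noise,
                                              outlier_frac),
                       min_delta_bp, max_delta_bp, d, d0)
  res_del <- opt_delta(function(x) mix_loglik(d, d0, d0 + x, noise,
                                              outlier_frac),
                       -min(d0 - 1, max_delta_bp), -min_delta_bp, d, d0)
  res_tri <- tri_fit(d, d0, noise, min_delta_bp, max_delta_bp)
  logliks <- c(H0 = ll0, Hhom = res_hom$loglik, Hhet_ins = res_ins$loglik,
               Hhet_del = res_del$loglik, Htri = res_tri$loglik)
  alts <- logliks[-1]
  # Htri carries one more free allele size than the other alternatives;
  # it wins only when it beats the best one-allele hypothesis by a full
  # log10 unit, otherwise the simpler model is preferred
  one_allele <- alts[c("Hhom", "Hhet_ins", "Hhet_del")]
  winning <- if (alts[["Htri"]] - max(one_allele) > log(10))
    "Htri" else names(one_allele)[which.max(one_allele)]
  lr <- (logliks[[winning]] - ll0) / log(10)
  deltas <- switch(winning,
                   Hhom = res_hom$delta,
                   Hhet_ins = res_ins$delta,
                   Hhet_del = res_del$delta,
                   Htri = res_tri$deltas)
  support <- variant_support(d, d0, winning, deltas, noise)
  delta_hat <- deltas[which.max(abs(deltas))]
  call <- NULL
  flagged <- n < min_support
  if (!flagged && winning != "H0" && lr >= lr_cutoff_log10 &&
      abs(delta_hat) > min_delta_bp && support >= min_support) {
    zyg <- switch(winning, Hhom = "hom", Hhet_ins = "het",
                  Hhet_del = "het", Htri = "tri")
    type <- if (winning == "Htri") "multi_indel" else
      if (delta_hat > 0) "insertion" else "deletion"
    call <- sv_calls(chrom = ev$chrom, start_bp = ev$left_pos,
                     end_bp = ev$right_pos, sv_type = type,
                     size_delta_bp = delta_hat, zygosity = zyg,
                     support = support, score = lr,
                     module = ev$source)
  }
  # H0 is nested in Hhom, so the best alternative is reported as winning
  # only when it beats the null by a meaningful margin (one log10 unit)
  # with an estimate above the size floor
  if (lr < 1 || abs(delta_hat) < min_delta_bp) winning <- "H0"
  structure(list(logliks = logliks, mle_deltas = deltas,
                 winning = winning,
                 log10_LR_vs_H0 = max(lr, 0), support = support, n = n,
                 under_supported = flagged, call = call),
            class = "hypothesis_result")
}

variant_support <- function(d, d0, winning, deltas, noise) {
  if (winning == "Hhom") return(length(d))
  if (winning == "Htri") return(length(d))
  t1 <- d0; t2 <- d0 + deltas[1]
  p_ref <- stats::dnorm(d, t1, sigma_bp(t1, noise))
  p_var <- stats::dnorm(d, t2, sigma_bp(t2, noise))
  sum(p_var / pmax(p_ref + p_var, 1e-300) > 0.5)
}

#' Molecule/contig-vs-reference indel calling over all intervals
#'
#' @param alignments Confidence-filtered alignments.
#' @param ref A `reference_digest`.
#' @param queries Query [label_map()]s backing the alignments.
#' @param noise A [noise_model()].
#' @param source Module tag for the emitted calls (`"MR"` or `"MCR"`).
#' @param min_delta_bp,min_support,lr_cutoff_log10 See [test_interval()].
#' @param bagging Optional list `list(total_aligned, target_total,
#'   seed)`: resample each interval's molecule distances so coverage
#'   corresponds to `target_total` aligned molecules (see
#'   [bagging_normalize()]).
#' @return An [sv_calls()] data frame.
#' @export
call_mr_indels <- function(alignments, ref, queries,
                           noise = noise_model(), source = "MR",
                           min_delta_bp = 2000, min_support = 10,
                           lr_cutoff_log10 = 3, bagging = NULL) {
  evidence <- collect_interval_evidence(alignments, ref, queries, source)
  calls <- list()
  for (ev in evidence) {
    if (!is.null(bagging)) {
      idx <- bagging_normalize(seq_along(ev$distances),
                               bagging$total_aligned,
                               bagging$target_total %||% 1e6,
                               seed = bagging$seed %||% 1L)
      ev$distances <- ev$distances[idx]
      ev$mol_ids <- ev$mol_ids[idx]
    }
    hr <- test_interval(ev, noise, min_delta_bp, min_support,
                        lr_cutoff_log10)
    if (!is.null(hr$call)) calls[[length(calls) + 1L]] <- hr$call
  }
  out <- dedup_indel_calls(bind_sv_calls(calls))
  log_stage("call_indels", source = source, intervals = length(evidence),
            calls = nrow(out))
  out
}

# Overlapping site-pair keys bracket the same indel several times over;
# keep one call per locus: the narrowest bracketing interval (best
# localized, least contaminated by flanking intervals), ties broken by
# likelihood ratio.
dedup_indel_calls <- function(calls) {
  n <- nrow(calls)
  if (n <= 1) return(calls)
  df <- as.data.frame(calls)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (df$chrom[i] != df$chrom[j]) next
      if (df$start_bp[j] >= df$end_bp[i] || df$start_bp[i] >= df$end_bp[j])
        next
      if (!sizes_agree(df$size_delta_bp[i], df$size_delta_bp[j])) next
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  keep <- vapply(split(seq_len(n), roots), function(idx) {
    w <- df$end_bp[idx] - df$start_bp[idx]
    idx[order(w, -df$score[idx])][1]
  }, 0L)
  out <- df[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contig-vs-reference indel calling
#'
#' A call is emitted for every adjacent aligned reference label pair
#' where the contig distance differs from the reference distance by more
#' than `min_delta_bp` and by more than `k_sigma` sizing standard
#' deviations. Contigs are consensus objects, so no zygosity is assigned.
#'
#' @param contig_alignments Confidence-filtered contig alignments.
#' @param ref A `reference_digest`.
#' @param contigs Contig [label_map()]s.
#' @param noise A [noise_model()].
#' @param min_delta_bp Size floor (default 2000).
#' @param k_sigma Discrepancy threshold in sizing SDs (default 3).
#' @return An [sv_calls()] data frame (module `CR`, zygosity `unknown`).
#' @export
call_cr_indels <- function(contig_alignments, ref, contigs,
                           noise = noise_model(), min_delta_bp = 2000,
                           k_sigma = 3) {
  evidence <- collect_interval_evidence(contig_alignments, ref, contigs,
                                        source = "MR")
  calls <- list()
  for (ev in evidence) {
    for (i in seq_along(ev$distances)) {
      delta <- ev$distances[i] - ev$d0
      if (abs(delta) > min_delta_bp &&
          abs(delta) > k_sigma * sigma_bp(ev$d0, noise)) {
        calls[[length(calls) + 1L]] <- sv_calls(
          chrom = ev$chrom, start_bp = ev$left_pos, end_bp = ev$right_pos,
          sv_type = if (delta > 0) "insertion" else "deletion",
          size_delta_bp = delta, zygosity = "unknown", support = 1L,
          score = abs(delta) / sigma_bp(ev$d0, noise), module = "CR")
      }
    }
  }
  out <- bind_sv_calls(calls)
  if (nrow(out) > 0) out <- harmonize_calls(cr = out)
  log_stage("call_cr_indels", calls = nrow(out))
  out
}

#' Coverage normalisation by with-replacement resampling (bagging)
#'
#' Rescales the molecule set at a locus so every sample behaves as if it
#' had `target_total` aligned molecules in total: the locus set is
#' resampled with replacement to `round(n_locus * target_total /
#' total_aligned)` entries. Samples already at or above the target are
#' left untouched.
#'
#' @param molecules_at_locus Vector (or list) of molecules at the locus.
#' @param total_aligned_in_sample Total aligned molecules in the sample.
#' @param target_total Normalisation target (default 1e6).
#' @param seed Integer seed.
#' @return Resampled vector of the same type as the input.
#' @export
bagging_normalize <- function(molecules_at_locus, total_aligned_in_sample,
                              target_total = 1e6, seed = 1L) {
  stopifnot(total_aligned_in_sample >= 1)
  n <- length(molecules_at_locus)
  if (total_aligned_in_sample >= target_total || n == 0)
    return(molecules_at_locus)
  n_new <- round(n * target_total / total_aligned_in_sample)
  set.seed(seed)
  molecules_at_locus[sample.int(n, n_new, replace = TRUE)]
}

# --- cross-call merging ---------------------------------------------------

reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- pmin(e1, e2) - pmax(s1, s2)
  if (inter <= 0) return(0)
  min(inter / max(e1 - s1, 1), inter / max(e2 - s2, 1))
}

sizes_agree <- function(a, b, abs_tol = 2000, rel_tol = 0.2) {
  tol <- max(abs_tol, rel_tol * max(abs(a), abs(b)))
  (sign(a) == sign(b) || a == 0 || b == 0) && abs(a - b) <= tol
}

indel_types <- c("insertion", "deletion", "multi_indel")

# multi-allele loci are reported as multi_indel; they match a plain
# insertion/deletion of agreeing signed size at the same locus
types_compatible <- function(ti, tj) {
  ti == tj || (ti %in% indel_types && tj %in% indel_types &&
                 (ti == "multi_indel" || tj == "multi_indel"))
}

calls_match <- function(df, i, j, merge_tol, abs_tol = 2000,
                        rel_tol = 0.2, ins_window = 10000) {
  if (df$chrom[i] != df$chrom[j] ||
      !types_compatible(df$sv_type[i], df$sv_type[j]))
    return(FALSE)
  if (!sizes_agree(df$size_delta_bp[i], df$size_delta_bp[j],
                   abs_tol, rel_tol)) return(FALSE)
  # bracketing intervals vary with which flanking labels each sample's
  # molecules anchored; midpoint proximity is accepted alongside
  # reciprocal overlap (insertions are point events and rely on it)
  mid_ok <- abs((df$start_bp[i] + df$end_bp[i]) / 2 -
                  (df$start_bp[j] + df$end_bp[j]) / 2) <= ins_window
  mid_ok || reciprocal_overlap(df$start_bp[i], df$end_bp[i],
                               df$start_bp[j], df$end_bp[j]) >= merge_tol
}

# single-linkage clustering of calls under the match rule; returns an
# integer cluster id per row
cluster_calls <- function(df, merge_tol = 0.5, ...) {
  n <- nrow(df)
  if (n == 0) return(integer())
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  match_class <- ifelse(df$sv_type %in% indel_types, "indel", df$sv_type)
  ord <- order(match_class, df$chrom, df$start_bp)
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (match_class[ord[b]] != match_class[ord[a]] ||
          df$chrom[j] != df$chrom[i])
        break
      if (df$start_bp[j] - df$end_bp[i] > 1e6) break
      if (calls_match(df, i, j, merge_tol, ...)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' Harmonize MR, CR and MCR calls into one list
#'
#' Same-type calls whose intervals reciprocally overlap at least
#' `merge_tol` (insertions: breakpoints within 10 kb) and whose sizes
#' agree within `max(2 kb, 20%)` are merged. Zygosity is taken from
#' MR/MCR when available; provenance modules are recorded
#' (comma-separated) and the best score kept.
#'
#' @param mr,cr,mcr [sv_calls()] data frames (any may be empty/missing).
#' @param merge_tol Reciprocal-overlap threshold (default 0.5).
#' @return A merged, sorted [sv_calls()] data frame.
#' @export
harmonize_calls <- function(mr = sv_calls(), cr = sv_calls(),
                            mcr = sv_calls(), merge_tol = 0.5) {
  all <- bind_sv_calls(list(mr, cr, mcr))
  if (nrow(all) == 0) return(all)
  cl <- cluster_calls(all, merge_tol)
  rows <- lapply(split(seq_len(nrow(all)), cl), function(idx) {
    sub <- all[idx, , drop = FALSE]
    zy <- sub$zygosity[sub$module %in% c("MR", "MCR")]
    zy <- if (length(zy) > 0) zy[1] else sub$zygosity[1]
    best <- which.max(sub$score)
    data.frame(chrom = sub$chrom[1],
               start_bp = min(sub$start_bp), end_bp = max(sub$end_bp),
               sv_type = sub$sv_type[1],
               size_delta_bp = sub$size_delta_bp[best],
               zygosity = zy, support = max(sub$support),
               score = sub$score[best],
               module = paste(sort(unique(unlist(
                 strsplit(sub$module, ",", fixed = TRUE)))),
                 collapse = ","),
               sample_id = sub$sample_id[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sv_calls", "data.frame")
  out
}
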