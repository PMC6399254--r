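#' Evaluate indel calls against a simulated truth set
#'
#' A truth indel is recovered when a call of compatible type
#' (`multi_indel` matches either sign) has a signed size within
#' `max(size_abs, size_rel * |truth size|)` and a bracketing interval
#' overlapping the truth locus padded by `pad` bp. Among multiple
#' matching calls the highest-scoring one is taken.
#'
#' @param truth Truth data frame from an `om_sample` (columns `chrom`,
#'   `ref_start`, `ref_end`, `size_delta_bp`, `zygosity`).
#' @param calls An [sv_calls()] data frame.
#' @param pad Locus padding in bp (default 15000, roughly one label
#'   interval each side).
#' @param size_rel,size_abs Size agreement tolerances (defaults 0.3 and
#'   2000 bp).
#' @return List: `recovered` (logical per truth row), `zygosity_ok`,
#'   `delta_hat` (matched size estimates), `hit_idx`, and `n_unmatched`
#'   (calls matching no truth row).
#' @export
evaluate_indel_calls <- function(truth, calls, pad = 15000,
                                 size_rel = 0.3, size_abs = 2000) {
  n <- nrow(truth)
  hits <- integer(n)
  zyg_ok <- logical(n)
  dhat <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- truth[i, ]
    tol <- max(size_abs, size_rel * abs(tr$size_delta_bp))
    cand <- which(calls$chrom == tr$chrom &
                    calls$start_bp < tr$ref_end + pad &
                    calls$end_bp > tr$ref_start - pad &
                    abs(calls$size_delta_bp - tr$size_delta_bp) <= tol)
    if (length(cand) > 0) {
      j <- cand[which.max(calls$score[cand])]
      hits[i] <- j
      zyg_ok[i] <- calls$zygosity[j] == tr$zygosity
      dhat[i] <- calls$size_delta_bp[j]
    }
  }
  list(recovered = hits > 0, zygosity_ok = zyg_ok, delta_hat = dhat,
       hit_idx = hits,
       n_unmatched = sum(!seq_len(nrow(calls)) %in% hits))
}

#' Evaluate complex-SV calls against a simulated truth set
#'
#' A truth rearrangement is recovered when a call of the same type has
#' breakpoints near the implanted segment. Inversions and duplications
#' must bracket the segment (both breakpoints within `window` of the
#' segment boundaries); translocations are matched when either call
#' breakpoint lies within `window` of the segment's boundaries or of
#' its destination.
#'
#' @param truth Truth data frame (with `dest_chrom`/`dest_pos` for
#'   translocations).
#' @param calls An [sv_calls()] data frame (module `complex`).
#' @param window Breakpoint tolerance in bp (default 300 kb).
#' @return Logical vector, one element per truth row.
#' @export
evaluate_complex_calls <- function(truth, calls, window = 3e5) {
  vapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    ok <- calls$sv_type == tr$sv_type
    if (tr$sv_type %in% c("intra_translocation", "inter_translocation")) {
      pts <- c(tr$ref_start, tr$ref_end,
               if (!is.na(tr$dest_pos)) tr$dest_pos)
      any(ok & (vapply(seq_len(nrow(calls)), function(j)
        any(abs(calls$start_bp[j] - pts) < window |
              abs(calls$end_bp[j] - pts) < window), TRUE)))
    } else {
      any(ok & calls$chrom == tr$chrom &
            abs(calls$start_bp - tr$ref_start) < window &
            abs(calls$end_bp - tr$ref_end) < window)
    }
  }, TRUE)
}
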