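# Independent oracles and shared fixtures for the test suite.

# --- motif scan oracle: brute-force substring comparison ------------------
oracle_scan <- function(sequence, motif) {
  sequence <- toupper(sequence)
  k <- nchar(motif)
  rc <- paste(rev(chartr("ACGTN", "TGCAN",
                         strsplit(motif, "")[[1]])), collapse = "")
  n <- nchar(sequence)
  if (n < k) return(numeric())
  starts <- seq_len(n - k + 1)
  words <- substring(sequence, starts, starts + k - 1)
  sort(unique(c(starts[words == motif], starts[words == rc])) - 1)
}

# --- label-merge oracle: iterative pairwise union-find --------------------
oracle_merge <- function(positions, resolution = 450) {
  if (length(positions) <= 1) return(as.numeric(positions))
  grp <- seq_along(positions)
  repeat {
    changed <- FALSE
    for (i in seq_len(length(positions) - 1)) {
      if (positions[i + 1] - positions[i] <= resolution &&
          grp[i + 1] != grp[i]) {
        grp[grp == grp[i + 1]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- vapply(unique(grp), function(g) {
    x <- positions[grp == g]
    (min(x) + max(x)) / 2
  }, 0)
  sort(out)
}

# --- alignment score oracle ----------------------------------------------
# Top-down memoised recursion over chain ends; identical scoring rules to
# the package's dynamic program (match bonus, skip costs, capped sizing
# penalty, K-skip window), independently implemented in R.
oracle_align_score <- function(qpos, rpos, p) {
  nq <- length(qpos); nr <- length(rpos)
  if (nq == 0 || nr == 0) return(0)
  memo <- matrix(NA_real_, nq, nr)
  best_end <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- p$match_bonus
    for (ii in seq_len(i - 1)) {
      if (i - ii > p$K + 1) next
      for (jj in seq_len(j - 1)) {
        if (j - jj > p$K + 1) next
        dq <- qpos[i] - qpos[ii]
        dr <- rpos[j] - rpos[jj]
        pen <- min((dq - dr)^2 / (p$sf_pen^2 + (p$sr_pen * dr)^2),
                   p$outlier_cap)
        cand <- best_end(ii, jj) + p$match_bonus - pen -
          p$cq * (i - ii - 1) - p$cr * (j - jj - 1)
        if (cand > val) val <- cand
      }
    }
    memo[i, j] <<- val
    val
  }
  best <- 0
  for (i in seq_len(nq)) for (j in seq_len(nr))
    best <- max(best, best_end(i, j))
  best
}

# --- Eq.1 molecule score oracle ------------------------------------------
oracle_eq1 <- function(nl) {
  per <- numeric(nrow(nl))
  for (i in seq_len(nrow(nl)))
    per[i] <- nl[i, 1] / (nl[i, 1] + nl[i, 2]) * log(nl[i, 1])
  worst <- Inf
  for (i in seq_len(nrow(nl) - 1))
    worst <- min(worst, min(per[i], per[i + 1]))
  worst
}

# --- random small alignment instances ------------------------------------
random_instance <- function(seed, nq_max = 15, nr_max = 30) {
  set.seed(seed)
  nq <- sample(5:nq_max, 1)
  nr <- sample(nq:nr_max, 1)
  list(q = cumsum(runif(nq, 2000, 20000)),
       r = cumsum(runif(nr, 2000, 20000)))
}

# --- random sequence ------------------------------------------------------
random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- truth joining for indel evaluations ----------------------------------
# A truth indel is recovered when a call of compatible type (multi_indel
# matches either sign) has a size within max(2 kb, 30%) and an interval
# overlapping the truth locus padded by 15 kb.
match_truth_calls <- function(truth, calls, pad = 15000,
                              size_rel = 0.3, size_abs = 2000) {
  hits <- integer(nrow(truth))
  zyg_ok <- logical(nrow(truth))
  dhat <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
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
  list(recovered = hits > 0, zyg_ok = zyg_ok, delta_hat = dhat,
       hit_idx = hits)
}

# shared cache for expensive end-to-end fixtures (built once per session)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}
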