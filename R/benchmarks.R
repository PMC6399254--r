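#' Simulation benchmarks
#'
#' Self-contained benchmark scenarios exercising the whole pipeline on
#' synthetic data at the package's default coverage and noise model (79x,
#' label false-negative rate 0.06, 0.6 false labels per 100 kb, sizing
#' noise sf 0.20 / sr 0.01). They are used by the package's acceptance
#' checks and are exported so results can be reproduced from a shell
#' with a single call. All randomness derives from the `seed` argument.
#'
#' Problem sizes are desk-scale by design: batches of a few tens of SVs
#' on 10-15 Mb genomes rather than genome-wide cohorts; the methods
#' vignette discusses what these sizes do and do not demonstrate.
#' @name benchmarks
NULL

#' Indel recovery benchmark
#'
#' Implants `svs_per_batch` hom/het insertions and deletions of 3-50 kb
#' per batch on a fresh 12 Mb reference, simulates molecules at default
#' noise and coverage, runs the molecule-reference caller with the
#' high-confidence loose support threshold, and joins calls to truth.
#'
#' @param seed Integer seed.
#' @param n_batches Number of independent batches (default 4, i.e. 200
#'   SVs).
#' @param svs_per_batch SVs per batch (default 50).
#' @param min_support Support threshold (default 6, the loose
#'   high-confidence setting).
#' @return List with `truth`, `calls`, and summary `metrics`
#'   (`del_recall`, `ins_recall`, `zygosity_accuracy`, `bias_mean`,
#'   `bias_se`, `n_extra_calls`).
#' @export
benchmark_indel_recovery <- function(seed = 1L, n_batches = 4L,
                                     svs_per_batch = 50L,
                                     min_support = 6L) {
  nm <- noise_model()
  p <- align_params()
  truth_all <- list(); eval_all <- list(); calls_all <- list()
  extra <- 0L
  for (b in seq_len(n_batches)) {
    ref <- simulate_reference(1, 12e6, 10000, seed = seed * 100 + b)
    set.seed(seed * 200 + b)
    spec <- data.frame(
      sv_type = rep(c("deletion", "insertion"),
                    length.out = svs_per_batch),
      size_bp = round(stats::runif(svs_per_batch, 3000, 50000)),
      zygosity = rep(c("hom", "het"), length.out = svs_per_batch))
    smp <- implant_svs(ref, spec, seed = seed * 300 + b,
                       min_separation = 80000,
                       sample_id = paste0("batch", b))
    mols <- generate_molecules(smp, nm, seed = seed * 400 + b)
    alns <- align_all(mols, ref, p)
    calls <- call_mr_indels(alns, ref, mols, nm,
                            min_support = min_support)
    ev <- evaluate_indel_calls(smp$truth, calls)
    truth_all[[b]] <- smp$truth
    eval_all[[b]] <- ev
    calls_all[[b]] <- calls
    extra <- extra + ev$n_unmatched
  }
  truth <- do.call(rbind, truth_all)
  recovered <- unlist(lapply(eval_all, `[[`, "recovered"))
  zyg_ok <- unlist(lapply(eval_all, `[[`, "zygosity_ok"))
  dhat <- unlist(lapply(eval_all, `[[`, "delta_hat"))
  del <- truth$sv_type == "deletion"
  bias <- (dhat - truth$size_delta_bp)[recovered]
  metrics <- list(
    del_recall = mean(recovered[del]),
    ins_recall = mean(recovered[!del]),
    zygosity_accuracy = mean(zyg_ok[recovered]),
    bias_mean = mean(bias),
    bias_se = stats::sd(bias) / sqrt(length(bias)),
    n_extra_calls = extra,
    n_truth = nrow(truth))
  list(truth = truth, calls = calls_all, metrics = metrics)
}

#' SV-free false-call benchmark
#'
#' Runs the indel and complex callers on SV-free 5 Mb replicates at
#' default noise and coverage; any call is a false call.
#'
#' @param seed Integer seed.
#' @param n_replicates Number of replicates (default 20).
#' @param min_support Support threshold for the indel caller
#'   (default 6).
#' @return Data frame with per-replicate `indel_calls` and
#'   `complex_calls`.
#' @export
benchmark_svfree <- function(seed = 1L, n_replicates = 20L,
                             min_support = 6L) {
  nm <- noise_model()
  p <- align_params()
  res <- lapply(seq_len(n_replicates), function(s) {
    ref <- simulate_reference(1, 5e6, 10000, seed = seed * 1000 + s)
    smp <- implant_svs(ref, data.frame(sv_type = character(),
                                       size_bp = numeric(),
                                       zygosity = character()),
                       seed = seed * 2000 + s)
    mols <- generate_molecules(smp, nm, seed = seed * 3000 + s)
    alns <- align_all(mols, ref, p)
    indel <- call_mr_indels(alns, ref, mols, nm,
                            min_support = min_support)
    ctgs <- make_contigs(smp, nm, seed = seed * 4000 + s)
    ca <- align_all(ctgs, ref, p)
    cx <- call_complex_svs(ca, alns, ctgs, ref)
    data.frame(indel_calls = nrow(indel), complex_calls = nrow(cx))
  })
  do.call(rbind, res)
}

#' Complex-SV recovery benchmark
#'
#' Four single-type scenarios (inversions, tandem duplications,
#' intra- and inter-chromosomal translocations) implanted homozygously
#' at explicit, geometry-safe loci; duplication units are placed on
#' windows carrying at least six labels, since every tandem copy must
#' hold enough labels to anchor its own split segment.
#'
#' @param seed Integer seed.
#' @return List with per-type `recall`, plus `truth` and `calls`.
#' @export
benchmark_complex_recovery <- function(seed = 1L) {
  nm <- noise_model()
  p <- align_params()
  run_one <- function(spec, n_chrom, len, tag) {
    ref <- simulate_reference(n_chrom, len, 10000,
                              seed = seed * 100 + tag)
    smp <- implant_svs(ref, spec, seed = seed * 200 + tag)
    mols <- generate_molecules(smp, nm, seed = seed * 300 + tag)
    ma <- align_all(mols, ref, p)
    ctgs <- make_contigs(smp, nm, seed = seed * 400 + tag)
    ca <- align_all(ctgs, ref, p)
    calls <- call_complex_svs(ca, ma, ctgs, ref)
    list(truth = smp$truth, calls = calls,
         rec = evaluate_complex_calls(smp$truth, calls))
  }
  scen <- list()
  scen$inversion <- run_one(data.frame(
    sv_type = "inversion",
    size_bp = c(25e4, 3e5, 35e4, 28e4, 32e4), zygosity = "hom",
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(1e6, 2.2e6, 3.4e6, 1.2e6, 2.6e6)), 2, 4.5e6, 1)
  # duplication units need label-dense windows
  ref_d <- simulate_reference(1, 6e6, 10000, seed = seed * 100 + 2)
  rp <- ref_d$maps$chr1$positions
  cand <- seq(6e5, 5.2e6, by = 1e5)
  labs <- vapply(cand, function(x) sum(rp >= x & rp < x + 5e4), 0L)
  dense <- cand[labs >= 6]
  pos_d <- dense[round(seq(1, length(dense), length.out = 3))]
  scen$duplication <- run_one(data.frame(
    sv_type = "duplication", size_bp = 5e4, zygosity = "hom",
    chrom = "chr1", pos = pos_d, n_copies = 4), 1, 6e6, 2)
  scen$intra_translocation <- run_one(data.frame(
    sv_type = "intra_translocation", size_bp = c(3e5, 25e4, 28e4),
    zygosity = "hom", chrom = "chr1",
    pos = c(1e6, 2.3e6, 3.6e6)), 1, 14e6, 3)
  scen$inter_translocation <- run_one(data.frame(
    sv_type = "inter_translocation", size_bp = c(3e5, 26e4),
    zygosity = "hom", chrom = c("chr1", "chr2"),
    pos = c(1e6, 3.5e6)), 2, 5e6, 4)
  list(recall = vapply(scen, function(s) mean(s$rec), 0),
       truth = lapply(scen, `[[`, "truth"),
       calls = lapply(scen, `[[`, "calls"))
}

#' Trio Mendelian-concordance benchmark
#'
#' Simulates trios (each parent carrying hom/het indels of 5-30 kb on a
#' 1.5 Mb reference), runs the molecule-reference caller independently
#' on father, mother and child, and pools the children's Mendelian
#' concordance.
#'
#' @param seed Integer seed.
#' @param n_trios Number of trios (default 20).
#' @param svs_per_parent SVs per parent (default 4).
#' @return List: `concordance` (pooled), `n_child_calls`, per-trio
#'   data frame `per_trio`.
#' @export
benchmark_trios <- function(seed = 1L, n_trios = 20L,
                            svs_per_parent = 4L) {
  nm <- noise_model()
  p <- align_params()
  rows <- list()
  for (t in seq_len(n_trios)) {
    ref <- simulate_reference(1, 1.5e6, 10000, seed = seed * 100 + t)
    set.seed(seed * 150 + t)
    mk_parent <- function(who, s) {
      spec <- data.frame(
        sv_type = sample(c("deletion", "insertion"), svs_per_parent,
                         replace = TRUE),
        size_bp = round(stats::runif(svs_per_parent, 5000, 30000)),
        zygosity = sample(c("hom", "het"), svs_per_parent,
                          replace = TRUE))
      implant_svs(ref, spec, seed = s, sample_id = who,
                  min_separation = 100000, edge_margin = 250000)
    }
    f <- mk_parent("father", seed * 200 + t)
    m <- mk_parent("mother", seed * 250 + t)
    ch <- simulate_trio(f, m, seed = seed * 300 + t)
    pipeline <- function(smp, s) {
      mols <- generate_molecules(smp, nm, seed = s)
      alns <- align_all(mols, ref, p)
      call_mr_indels(alns, ref, mols, nm, min_support = 6)
    }
    cc <- trio_concordance(pipeline(ch, seed * 350 + t),
                           pipeline(f, seed * 400 + t),
                           pipeline(m, seed * 450 + t))
    rows[[t]] <- data.frame(trio = t, n_child = cc$n_child,
                            n_concordant = cc$n_concordant)
  }
  per_trio <- do.call(rbind, rows)
  list(concordance = sum(per_trio$n_concordant) / sum(per_trio$n_child),
       n_child_calls = sum(per_trio$n_child), per_trio = per_trio)
}
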