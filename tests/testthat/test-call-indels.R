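nm <- noise_model()

make_ev <- function(d0, distances, chrom = "chr1", left_pos = 1e6) {
  list(chrom = chrom, left_idx = 10L, right_idx = 11L,
       left_pos = left_pos, right_pos = left_pos + d0, d0 = d0,
       distances = distances,
       mol_ids = paste0("m", seq_along(distances)), source = "MR")
}

sim_distances <- function(t, n, seed) {
  set.seed(seed)
  rnorm(n, t, nicksv:::sigma_bp(t, nm))
}

test_that("homozygous deletions win the hypothesis test with unbiased size", {
  d <- sim_distances(25000, 20, 1)
  hr <- test_interval(make_ev(30000, d), nm)
  expect_equal(hr$winning, "Hhom")
  expect_s3_class(hr$call, "sv_calls")
  expect_equal(hr$call$sv_type, "deletion")
  expect_equal(hr$call$zygosity, "hom")
  se <- nicksv:::sigma_bp(25000, nm) / sqrt(20)
  expect_lt(abs(hr$mle_deltas[1] + 5000), 3 * se)
  expect_equal(hr$support, 20)
})

test_that("clean reference intervals stay under the null", {
  d <- sim_distances(30000, 20, 2)
  hr <- test_interval(make_ev(30000, d), nm)
  expect_equal(hr$winning, "H0")
  expect_null(hr$call)
})

test_that("bimodal distances give a heterozygous insertion with recovered size", {
  d <- c(sim_distances(30000, 10, 3), sim_distances(36000, 10, 4))
  hr <- test_interval(make_ev(30000, d), nm)
  expect_equal(hr$winning, "Hhet_ins")
  expect_equal(hr$call$zygosity, "het")
  expect_lt(abs(hr$mle_deltas[1] - 6000), 500)
  expect_equal(hr$support, 10)
})

test_that("sub-threshold sizes are never called regardless of evidence", {
  d <- sim_distances(30900, 20, 5)
  hr <- test_interval(make_ev(30000, d), nm)
  expect_null(hr$call)
  # even a massive LR cannot rescue a size below the floor
  d2 <- sim_distances(31500, 200, 6)
  hr2 <- test_interval(make_ev(30000, d2), nm)
  expect_null(hr2$call)
})

test_that("under-supported evidence is flagged and produces no call", {
  d <- sim_distances(24000, 5, 7)
  hr <- test_interval(make_ev(30000, d), nm, min_support = 10)
  expect_true(hr$under_supported)
  expect_null(hr$call)
  # the same evidence passes at the loose threshold
  d6 <- sim_distances(24000, 6, 8)
  hr6 <- test_interval(make_ev(30000, d6), nm, min_support = 6)
  expect_false(hr6$under_supported)
  expect_false(is.null(hr6$call))
})

test_that("two-allele (tri) intervals are recognised", {
  d <- c(sim_distances(25000, 12, 9), sim_distances(37000, 12, 10))
  hr <- test_interval(make_ev(30000, d), nm)
  expect_equal(hr$winning, "Htri")
  expect_equal(sort(round(hr$mle_deltas, -3)), c(-5000, 7000))
  expect_equal(hr$call$sv_type, "multi_indel")
  expect_equal(hr$call$zygosity, "tri")
})

test_that("a lone outlier molecule does not flip zygosity", {
  d <- c(sim_distances(25000, 24, 11), 32000)
  hr <- test_interval(make_ev(30000, d), nm)
  expect_equal(hr$winning, "Hhom")
  expect_equal(hr$call$zygosity, "hom")
})

test_that("loosening the support threshold can only enlarge the call set", {
  set.seed(12)
  evs <- lapply(1:30, function(i) {
    n <- sample(4:20, 1)
    delta <- sample(c(0, -6000, 8000), 1)
    make_ev(30000, sim_distances(30000 + delta, n, 100 + i))
  })
  calls_at <- function(ms) {
    sum(vapply(evs, function(ev)
      !is.null(test_interval(ev, nm, min_support = ms)$call), TRUE))
  }
  expect_gte(calls_at(6), calls_at(10))
})

test_that("contig-reference calling flags large discrepancies without zygosity", {
  ref <- simulate_reference(1, 2e6, 10000, seed = 30)
  smp <- implant_svs(ref, data.frame(sv_type = "deletion", size_bp = 8000,
                                     zygosity = "hom",
                                     chrom = "chr1", pos = 1e6), seed = 31)
  ctg <- make_contigs(smp, noise_model(), seed = 32)[[1]]
  a <- align_map(ctg, ref, align_params())
  calls <- call_cr_indels(list(a), ref, list(ctg), nm)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$sv_type, "deletion")
  expect_equal(calls$zygosity, "unknown")
  expect_equal(calls$module, "CR")
  expect_lt(abs(calls$size_delta_bp + 8000), 3 * nicksv:::sigma_bp(8000, nm))

  # an identical contig yields no calls
  ctg0 <- make_contigs(smp$haplotypes["h1"], noise_model(), seed = 33,
                       consensus_factor = 0)
  names(ctg0[[1]])
  ref0 <- reference_digest_from_maps(
    list(chr1 = label_map("chr1", smp$haplotypes$h1$chr1$positions,
                          smp$haplotypes$h1$chr1$length_bp,
                          kind = "reference")))
  a0 <- align_map(ctg0[[1]], ref0, align_params())
  expect_equal(nrow(call_cr_indels(list(a0), ref0, ctg0, nm)), 0)
})

test_that("sub-threshold contig discrepancies are not called", {
  # 1.5 kb shift on a 30 kb interval: below the 2 kb floor
  rmap <- label_map("chr1", c(0, 3e4, 6e4, 9e4, 1.2e5, 1.5e5), 2e5,
                    kind = "reference")
  ref <- reference_digest_from_maps(list(chr1 = rmap))
  qpos <- c(0, 3e4, 6e4 - 1500, 9e4 - 1500, 1.2e5 - 1500, 1.5e5 - 1500)
  ctg <- label_map("ctg", qpos, 2e5, kind = "contig")
  a <- om_alignment("ctg", "chr1", "+", 1:6, 1:6, 18, 0, 1.5e5)
  expect_equal(nrow(call_cr_indels(list(a), ref, list(ctg), nm)), 0)
})

test_that("bagging resampling scales locus molecule counts exactly", {
  expect_length(bagging_normalize(1:20, 5e5, seed = 1), 40)
  expect_identical(bagging_normalize(1:20, 1e6, seed = 1), 1:20)
  expect_identical(bagging_normalize(1:20, 2e6, seed = 1), 1:20)
  rs <- bagging_normalize(letters[1:10], 25e4, seed = 2)
  expect_length(rs, 40)
  expect_true(all(rs %in% letters[1:10]))
  # expected multiplicity equals the scale factor
  reps <- table(factor(unlist(lapply(1:300, function(s)
    bagging_normalize(1:5, 5e5, seed = s))), levels = 1:5))
  expect_lt(max(abs(reps / 300 - 2)), 0.35)
})

test_that("harmonization merges concordant calls and keeps CR-only calls", {
  mr <- sv_calls("chr1", 1e6, 1.01e6, "deletion", -8000, "het", 15L, 40,
                 "MR")
  mcr <- sv_calls("chr1", 1.001e6, 1.011e6, "deletion", -7800, "het",
                  18L, 55, "MCR")
  cr <- sv_calls("chr2", 2e6, 2.02e6, "insertion", 12000, "unknown", 1L,
                 8, "CR")
  out <- harmonize_calls(mr, cr, mcr)
  expect_equal(nrow(out), 2)
  del <- out[out$sv_type == "deletion", ]
  expect_equal(del$module, "MCR,MR")
  expect_equal(del$zygosity, "het")
  expect_equal(del$score, 55)
  expect_equal(out[out$sv_type == "insertion", ]$zygosity, "unknown")

  # calls far apart stay separate
  far <- sv_calls(c("chr1", "chr1"), c(1e6, 11e6), c(1.01e6, 11.01e6),
                  "deletion", -8000, "het", 10L, 30, "MR")
  expect_equal(nrow(harmonize_calls(mr = far)), 2)
})

test_that("recall rises with coverage and with indel size", {
  recall_at <- function(n_mols, delta, reps = 60) {
    hits <- 0
    for (r in seq_len(reps)) {
      set.seed(1000 * n_mols + abs(delta) + r)
      d <- c(rnorm(ceiling(n_mols / 2), 30000,
                   nicksv:::sigma_bp(30000, nm)),
             rnorm(floor(n_mols / 2), 30000 + delta,
                   nicksv:::sigma_bp(30000 + delta, nm)))
      hr <- test_interval(make_ev(30000, d), nm, min_support = 6)
      if (!is.null(hr$call)) hits <- hits + 1
    }
    hits / reps
  }
  # coverage grid at fixed size
  r_cov <- vapply(c(12, 20, 40), recall_at, 0, delta = -2500)
  expect_true(all(diff(r_cov) >= -0.05))   # non-decreasing up to MC noise
  # size grid at fixed coverage
  r_size <- vapply(c(2200, 3000, 6000), function(dd)
    recall_at(16, -dd), 0)
  expect_true(all(diff(r_size) >= -0.05))
  expect_gt(max(r_size), max(r_size[1], 0.5))
})

test_that("MCR equals MR on clean data with perfect contigs", {
  ref <- simulate_reference(1, 4e6, 10000, seed = 40)
  spec <- data.frame(
    sv_type = c("deletion", "insertion", "deletion"),
    size_bp = c(10000, 12000, 20000), zygosity = "hom")
  smp <- implant_svs(ref, spec, seed = 41)
  nm0 <- noiseless_model(target_coverage = 15)
  mols <- generate_molecules(smp, nm0, seed = 42)
  p <- align_params()
  mr_aln <- align_all(mols, ref, p)
  mr <- call_mr_indels(mr_aln, ref, mols, noise_model(), min_support = 6)

  ctgs <- make_contigs(smp, nm0, seed = 43, consensus_factor = 0)
  m2c <- align_all(mols, ctgs, p, split = FALSE)
  c2r <- align_all(ctgs, ref, p)
  mcr_aln <- align_indirect(m2c, c2r)$alignments
  mcr <- call_mr_indels(mcr_aln, ref, mols, noise_model(),
                        source = "MCR", min_support = 6)
  res_mr <- match_truth_calls(smp$truth, mr)
  res_mcr <- match_truth_calls(smp$truth, mcr)
  expect_true(all(res_mr$recovered))
  expect_gte(mean(res_mcr$recovered == res_mr$recovered), 0.95)
})
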