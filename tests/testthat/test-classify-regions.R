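track <- function(...) {
  v <- list(...)
  data.frame(start = vapply(v, `[[`, 0, 1), end = vapply(v, `[[`, 0, 2),
             value = vapply(v, `[[`, 0, 3))
}

test_that("coverage and consensus tracks partition into the three classes", {
  lens <- c(chr1 = 1e6)
  cov <- list(chr1 = track(c(0, 4e5, 100), c(4e5, 7e5, 50),
                           c(7e5, 1e6, 100)))
  cns <- list(chr1 = track(c(0, 2e5, 1), c(2e5, 4e5, 0),
                           c(4e5, 8e5, 1), c(8e5, 1e6, 2)))
  out <- classify_coverage_state(cov, cns, lens)
  get_class <- function(pos)
    out$class[out$start <= pos & out$end > pos]
  expect_equal(get_class(1e5), "low_complexity")   # cov 100, cns 1
  expect_equal(get_class(3e5), "complex_candidate") # cov 100, cns 0
  expect_equal(get_class(5e5), "low_coverage")      # cov 50 < 92
  expect_equal(get_class(9e5), "complex_candidate") # cns 2
  # the classification partitions the chromosome
  expect_equal(sum(out$end - out$start), 1e6)
  expect_equal(out$start[-1], out$end[-nrow(out)])
})

test_that("chrY uses the halved coverage threshold", {
  lens <- c(chrY = 1e5)
  cov <- list(chrY = track(c(0, 1e5, 50)))
  cns <- list(chrY = track(c(0, 1e5, 1)))
  out <- classify_coverage_state(cov, cns, lens)
  expect_equal(out$class, "low_complexity")   # 50 >= 46
})

test_that("complex-candidate flag applies the recurrence and size rules", {
  inv <- function(types, sizes, counts)
    data.frame(sv_type = types, size_bp = sizes, cohort_count = counts)
  # mixed types, all recurrent, one indel above 10 kb -> complex
  expect_true(flag_complex_candidate(inv(
    c("inversion", "duplication", "insertion"),
    c(50000, 30000, 15000), c(3, 2, 5))))
  # three recurrent 20-50 kb indels only: none > 100 kb -> not complex
  expect_false(flag_complex_candidate(inv(
    rep("deletion", 3), c(20000, 30000, 50000), c(3, 3, 3))))
  # same but one indel > 100 kb -> complex
  expect_true(flag_complex_candidate(inv(
    rep("deletion", 3), c(20000, 30000, 120000), c(3, 3, 3))))
  # two recurrent SVs of any type -> below the minimum of three
  expect_false(flag_complex_candidate(inv(
    c("inversion", "duplication"), c(50000, 30000), c(3, 3))))
  # singletons are not counted
  expect_false(flag_complex_candidate(inv(
    c("inversion", "duplication", "insertion"),
    c(50000, 30000, 15000), c(1, 1, 1))))
  # indels at or below 10 kb are dropped before counting
  expect_false(flag_complex_candidate(inv(
    c("inversion", "duplication", "insertion"),
    c(50000, 30000, 9000), c(3, 3, 3))))
})

test_that("permutation test attains its extreme p-values", {
  lens <- c(chr1 = 1e6)
  regions <- data.frame(chrom = "chr1", start = c(1e5, 5e5),
                        end = c(1.5e5, 5.5e5))
  excluded <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
  # feature = the regions themselves: observed overlap is maximal
  res <- permutation_overlap_test(regions, regions, excluded, lens,
                                  n_perm = 200, seed = 1)
  expect_gte(res$observed, 2)
  expect_lt(res$p_value, 0.1)
  # empty feature: p = 1
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric())
  res2 <- permutation_overlap_test(regions, empty, excluded, lens,
                                   n_perm = 100, seed = 2)
  expect_equal(res2$p_value, 1)
  # a region longer than any allowed gap cannot be placed
  big <- data.frame(chrom = "chr1", start = 0, end = 9e5)
  excl <- data.frame(chrom = "chr1", start = 4e5, end = 6e5)
  expect_error(permutation_overlap_test(big, empty, excl, lens,
                                        n_perm = 5, seed = 3),
               "does not fit")
})

test_that("permutations avoid the excluded space", {
  lens <- c(chr1 = 1e6)
  excl <- data.frame(chrom = "chr1", start = 0, end = 9e5)
  regions <- data.frame(chrom = "chr1", start = 9.2e5, end = 9.3e5)
  feature <- data.frame(chrom = "chr1", start = 0, end = 9e5)
  # all placements must fall in [9e5, 1e6]: overlap with the excluded
  # region used as a feature must always be zero
  res <- permutation_overlap_test(regions, feature, excl, lens,
                                  n_perm = 100, seed = 4)
  expect_equal(res$perm_mean, 0)
})

test_that("feature annotation applies the stated filters", {
  regions <- data.frame(chrom = "chr1", start = 0, end = 1e6)
  lens <- c(chr1 = 2e7)
  segdups <- data.frame(chrom = "chr1", start = c(1e5, 3e5),
                        end = c(1.08e5, 3.2e5),
                        percent_identity = c(0.99, 0.90))
  tr <- data.frame(chrom = "chr1", start = c(5e5, 6e5), end = c(5.1e5, 6.1e5),
                   score = c(1500, 2500))
  cen <- data.frame(chrom = "chr1", pos = 1e7)
  out <- annotate_region_features(regions, segdups, tr, lens, cen)
  expect_equal(out$sd_overlap_bp, 0)     # 8 kb and 90% identity both fail
  expect_equal(out$tr_overlap_bp, 10000) # only the score-2500 repeat
  expect_true(out$subtelomeric)          # region touches the 7 Mb end zone
  expect_false(out$pericentromeric)      # ends 9 Mb before the centromere
  region2 <- data.frame(chrom = "chr1", start = 8e6, end = 8.1e6)
  out2 <- annotate_region_features(region2, segdups, tr, lens, cen)
  expect_true(out2$pericentromeric)
  expect_false(out2$subtelomeric)
  expect_error(annotate_region_features(regions,
                                        segdups[, 1:3], tr, lens, cen),
               "percent_identity")
})

test_that("map-based gap sizes recover implanted gap content", {
  # reference with a declared 10 kb gap whose true content is filled
  rpos <- seq(1e4, 5e5, by = 2e4)
  ref <- reference_digest_from_maps(list(
    chr1 = label_map("chr1", rpos, 5e5 + 1, kind = "reference")))
  gap <- list(chrom = "chr1", start = 2.05e5, end = 2.15e5)
  # query identical to reference: estimate ~ declared size (10 kb)
  q <- label_map("q", rpos, 5e5 + 1)
  a <- om_alignment("q", "chr1", "+", 1:25, 1:25, 75, 1e4, 4.9e5)
  est <- estimate_gap_size(gap, a, q, ref)
  expect_true(est$sized)
  expect_equal(est$size_bp, 1e4)
  # query with 10 kb more content between the flanking labels
  qpos2 <- c(rpos[rpos <= 2e5], rpos[rpos > 2e5] + 1e4)
  q2 <- label_map("q2", qpos2, 5.1e5 + 1)
  est2 <- estimate_gap_size(gap, a, q2, ref)
  expect_equal(est2$size_bp, 2e4)
  # deletion spanning the gap and flanks gives a negative estimate
  qpos3 <- c(rpos[rpos <= 1.8e5], rpos[rpos > 2.4e5] - 3e4)
  q3 <- label_map("q3", qpos3, 4.7e5 + 1)
  keep <- c(seq_along(rpos[rpos <= 1.8e5]),
            which(rpos > 2.4e5))
  a3 <- om_alignment("q3", "chr1", "+", seq_along(qpos3), keep, 60,
                     1e4, 4.6e5)
  est3 <- estimate_gap_size(gap, a3, q3, ref)
  expect_lt(est3$size_bp, 0)
  expect_equal(est3$size_bp, -2e4)
  # no spanning alignment -> unsized
  a_half <- om_alignment("q", "chr1", "+", 1:10, 1:10, 30, 1e4, 1.9e5)
  expect_false(estimate_gap_size(gap, a_half, q, ref)$sized)
})
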