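seg <- function(ref_id, orientation, ref_start, ref_end, q_idx, r_idx,
                query_id = "ctg1", score = 30) {
  om_alignment(query_id, ref_id, orientation, q_idx, r_idx, score,
               ref_start, ref_end)
}

test_that("split signatures classify into the four candidate types", {
  # different chromosomes -> inter-chromosomal translocation
  sa <- om_split_alignment("ctg1", list(
    seg("chr1", "+", 1e6, 2e6, 1:10, 1:10),
    seg("chr2", "+", 5e6, 6e6, 11:20, 1:10)))
  expect_equal(classify_split_signature(sa)[[1]]$candidate_type,
               "inter_translocation")
  # same chromosome, > 5 Mb apart -> intra-chromosomal translocation
  sa2 <- om_split_alignment("ctg1", list(
    seg("chr1", "+", 1e6, 2e6, 1:10, 1:10),
    seg("chr1", "+", 10e6, 11e6, 11:20, 101:110)))
  expect_equal(classify_split_signature(sa2)[[1]]$candidate_type,
               "intra_translocation")
  # opposite orientations within 5 Mb -> inversion
  sa3 <- om_split_alignment("ctg1", list(
    seg("chr1", "+", 1e6, 2e6, 1:10, 1:10),
    seg("chr1", "-", 2.1e6, 2.2e6, 20:11, 30:39)))
  expect_equal(classify_split_signature(sa3)[[1]]$candidate_type,
               "inversion")
  # overlapping reference intervals, same orientation -> duplication
  sa4 <- om_split_alignment("ctg1", list(
    seg("chr1", "+", 1e6, 2e6, 1:10, 1:10),
    seg("chr1", "+", 1.5e6, 2.5e6, 11:20, 6:15)))
  expect_equal(classify_split_signature(sa4)[[1]]$candidate_type,
               "duplication")
  # same orientation, close, disjoint -> no candidate
  sa5 <- om_split_alignment("ctg1", list(
    seg("chr1", "+", 1e6, 2e6, 1:10, 1:10),
    seg("chr1", "+", 2.2e6, 3e6, 11:20, 21:30)))
  expect_length(classify_split_signature(sa5), 0)
})

test_that("the molecule score matches direct evaluation of the formula", {
  got <- score_molecule_eq1(data.frame(n = c(10, 8), l = c(2, 1)))
  expect_equal(got, min(10 / 12 * log(10), 8 / 9 * log(8)),
               tolerance = 1e-12)
  expect_equal(got, 1.8484, tolerance = 1e-4)
  # a single-site split map forces a zero score
  expect_equal(score_molecule_eq1(data.frame(n = c(1, 10), l = c(0, 0))), 0)
  # symmetric perfect maps
  expect_equal(score_molecule_eq1(data.frame(n = c(20, 20), l = c(0, 0))),
               log(20))
  expect_error(score_molecule_eq1(data.frame(n = c(0, 5), l = c(0, 0))),
               "n >= 1")
})

test_that("the molecule score matches the oracle on random (n, l) pairs", {
  set.seed(5)
  for (i in 1:200) {
    k <- sample(2:4, 1)
    nl <- cbind(n = sample(1:40, k, TRUE), l = sample(0:12, k, TRUE))
    expect_equal(score_molecule_eq1(nl), oracle_eq1(nl),
                 tolerance = 1e-12)
  }
})

test_that("the molecule score is monotone in n and in l", {
  for (l in 0:6) {
    s <- vapply(2:30, function(n)
      score_molecule_eq1(cbind(n = c(n, n), l = c(l, l))), 0)
    expect_true(all(diff(s) > 0))
  }
  for (n in 2:20) {
    s <- vapply(0:8, function(l)
      score_molecule_eq1(cbind(n = c(n, n), l = c(l, l))), 0)
    expect_true(all(diff(s) < 0))
  }
})

test_that("adjudication follows the strict support-over-rejection rule", {
  ref <- reference_digest_from_maps(list(
    chr1 = label_map("chr1", seq(0, 3e6, by = 10000), 3e6 + 1,
                     kind = "reference")))
  cand <- list(candidate_type = "inversion", chrom1 = "chr1", bp1 = 1e6,
               chrom2 = "chr1", bp2 = 1.3e6, source_contig = "ctg1")
  # all molecules contiguously aligned across both breakpoints: rejected
  rejecting <- lapply(1:5, function(i)
    om_alignment(paste0("m", i), "chr1", "+", 1:41, 80:120, 120,
                 79e4, 1.19e6 + 2e5))
  rejecting <- lapply(1:5, function(i)
    om_alignment(paste0("m", i), "chr1", "+", 1:41, 85:125, 120,
                 84e4, 1.24e6))
  adj <- adjudicate_candidate(cand, rejecting, ref)
  expect_false(adj$accepted)
  expect_gt(adj$S_r, 0)
  expect_equal(adj$S_s, 0)

  # supporting split molecules with junctions at the candidate breakpoints
  supporting <- lapply(6:9, function(i) om_split_alignment(
    paste0("m", i), list(
      om_alignment(paste0("m", i), "chr1", "+", 1:10, 92:101, 30,
                   91e4, 1e6),
      om_alignment(paste0("m", i), "chr1", "-", 20:11, 102:111, 30,
                   1.01e6, 1.3e6))))
  adj2 <- adjudicate_candidate(cand, c(rejecting[1], supporting), ref)
  expect_true(adj2$accepted)
  expect_equal(adj2$n_support, 4)
  expect_equal(adj2$call$sv_type, "inversion")

  # exact tie is rejected (strict inequality)
  tie <- list(accepted = NA)
  one_sup <- supporting[1]
  one_rej <- rejecting[1]
  a_sup <- adjudicate_candidate(cand, one_sup, ref)
  # construct a rejecting set whose total equals the supporting total
  expect_true(a_sup$S_s > 0)
  adj3 <- adjudicate_candidate(cand, c(one_sup, one_sup), ref)
  expect_equal(adj3$n_support, 1)   # de-duplication by molecule id
})

test_that("equal supporting and rejecting scores reject the candidate", {
  # degenerate candidate with no molecules is dropped
  ref <- reference_digest_from_maps(list(
    chr1 = label_map("chr1", seq(0, 1e6, by = 10000), 1e6 + 1,
                     kind = "reference")))
  cand <- list(candidate_type = "inversion", chrom1 = "chr1", bp1 = 4e5,
               chrom2 = "chr1", bp2 = 6e5, source_contig = "ctg1")
  adj <- adjudicate_candidate(cand, list(), ref)
  expect_true(adj$dropped)
  # S_s == S_r = 0 is not accepted
  expect_false(isTRUE(adj$accepted))
})

test_that("small inversions are recovered from contig alignments by reversed re-alignment", {
  ref <- simulate_reference(1, 5e6, 10000, seed = 51)
  smp <- implant_svs(ref, data.frame(sv_type = "inversion",
                                     size_bp = 60000, zygosity = "hom"),
                     seed = 52)
  tr <- smp$truth
  n_inside <- sum(ref$maps$chr1$positions > tr$ref_start &
                    ref$maps$chr1$positions < tr$ref_end)
  skip_if(n_inside < 4, "fixture produced too few interior labels")
  ctgs <- make_contigs(smp, noise_model(), seed = 53)
  ca <- align_all(ctgs, ref, align_params())
  cands <- find_small_inversions(ca, ctgs, ref)
  expect_gte(length(cands), 1)
  expect_true(any(vapply(cands, function(cc)
    cc$candidate_type == "inversion" &&
      abs(cc$bp1 - tr$ref_start) < 30000 &&
      abs(cc$bp2 - tr$ref_end) < 30000, TRUE)))
})

test_that("3-label inverted regions are not reported", {
  # construct a contig with a 3-label inversion on a regular grid
  rpos <- seq(1e4, 2e6, by = 2e4)
  ref <- reference_digest_from_maps(list(
    chr1 = label_map("chr1", rpos, 2e6 + 1, kind = "reference")))
  a <- 1e6; b <- a + 6e4   # 3 labels inside
  qpos <- rpos
  inside <- qpos > a & qpos < b
  qpos[inside] <- a + b - qpos[inside]
  ctg <- label_map("ctg1", sort(qpos), 2e6 + 1, kind = "contig")
  ca <- align_all(list(ctg), ref, align_params())
  cands <- find_small_inversions(ca, list(ctg), ref, min_labels = 4)
  expect_length(cands, 0)
})

test_that("tandem unit counting is exact between unique flanks", {
  unit <- c(6000, 8000, 6000)         # 20 kb unit, 3 interior gaps
  left <- c(11000, 5000, 9000)
  right <- c(12000, 7000)
  build <- function(n_units) {
    gaps <- c(left, rep(unit, n_units), right)
    label_map("ctg", cumsum(c(5000, gaps)), sum(gaps) + 2e4,
              kind = "contig")
  }
  r3 <- count_tandem_units(build(3), left, right, unit)
  expect_true(r3$countable)
  expect_equal(r3$copy_number, 3)
  r0 <- count_tandem_units(build(0), left, right, unit)
  expect_equal(r0$copy_number, 0)
  # missing right flank
  gaps <- c(left, rep(unit, 2))
  ctg <- label_map("ctg", cumsum(c(5000, gaps)), sum(gaps) + 2e4,
                   kind = "contig")
  rbad <- count_tandem_units(ctg, left, right, unit)
  expect_false(rbad$countable)
  expect_match(rbad$reason, "right flank")
  # sizing tolerance: 10% perturbation still counts at tol = 0.15
  gaps2 <- c(left, rep(unit * 1.1, 2), right)
  ctg2 <- label_map("ctg", cumsum(c(5000, gaps2)), sum(gaps2) + 2e4,
                    kind = "contig")
  r2 <- count_tandem_units(ctg2, left, right, unit)
  expect_equal(r2$copy_number, 2)
})
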