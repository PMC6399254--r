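test_that("simulated references have Poisson label counts and are reproducible", {
  ref <- simulate_reference(1, 1e6, 10000, seed = 1)
  n <- n_labels(ref$maps$chr1)
  expect_lt(abs(n - 100), 4 * sqrt(100))   # Poisson count within 4 SD
  ref2 <- simulate_reference(1, 1e6, 10000, seed = 1)
  expect_identical(ref$maps$chr1$positions, ref2$maps$chr1$positions)
  ref3 <- simulate_reference(1, 1e6, 10000, seed = 2)
  expect_false(identical(ref$maps$chr1$positions,
                         ref3$maps$chr1$positions))
  expect_error(simulate_reference(1, 1e6, 400, seed = 1),
               "exceed the merge resolution")
})

test_that("hom deletions remove labels and length from both haplotypes", {
  ref <- simulate_reference(1, 2e6, 10000, seed = 5)
  smp <- implant_svs(ref, data.frame(sv_type = "deletion", size_bp = 50000,
                                     zygosity = "hom"), seed = 6)
  tr <- smp$truth
  n_inside <- sum(ref$maps$chr1$positions >= tr$ref_start &
                    ref$maps$chr1$positions < tr$ref_end)
  expect_gt(n_inside, 0)
  for (h in 1:2) {
    hap <- smp$haplotypes[[h]]$chr1
    expect_equal(hap$length_bp, 2e6 - 50000)
    expect_equal(n_labels(hap), n_labels(ref$maps$chr1) - n_inside)
  }
})

test_that("het inversions reverse exactly one haplotype's sub-pattern", {
  ref <- simulate_reference(1, 2e6, 10000, seed = 7)
  smp <- implant_svs(ref, data.frame(sv_type = "inversion",
                                     size_bp = 200000, zygosity = "het"),
                     seed = 8)
  tr <- smp$truth
  carrier <- if (tr$hap1) 1 else 2
  other <- 3 - carrier
  expect_identical(smp$haplotypes[[other]]$chr1$positions,
                   ref$maps$chr1$positions)
  hap <- smp$haplotypes[[carrier]]$chr1
  inside_ref <- ref$maps$chr1$positions[
    ref$maps$chr1$positions >= tr$ref_start &
      ref$maps$chr1$positions < tr$ref_end]
  inside_hap <- hap$positions[hap$positions >= tr$ref_start &
                                hap$positions < tr$ref_end]
  expect_equal(sort(tr$ref_start + tr$ref_end - inside_ref), inside_hap)
})

test_that("tandem duplication repeats the unit pattern arithmetically", {
  ref <- simulate_reference(1, 2e6, 10000, seed = 9)
  smp <- implant_svs(ref, data.frame(sv_type = "duplication",
                                     size_bp = 20000, zygosity = "hom",
                                     n_copies = 3), seed = 10)
  tr <- smp$truth
  expect_equal(tr$size_delta_bp, 40000)   # two extra copies
  hap <- smp$haplotypes$h1$chr1
  expect_equal(hap$length_bp, 2e6 + 40000)
  unit <- ref$maps$chr1$positions[
    ref$maps$chr1$positions >= tr$ref_start &
      ref$maps$chr1$positions < tr$ref_end] - tr$ref_start
  expected <- sort(c(outer(unit, tr$ref_start + (0:2) * 20000, `+`)))
  got <- hap$positions[hap$positions >= tr$ref_start &
                         hap$positions < tr$ref_end + 40000]
  expect_equal(got, expected)
})

test_that("noiseless molecules are exact sub-maps of their haplotype", {
  ref <- simulate_reference(1, 1e6, 10000, seed = 11)
  smp <- implant_svs(ref, data.frame(sv_type = character(),
                                     size_bp = numeric(),
                                     zygosity = character()), seed = 1)
  mols <- generate_molecules(smp, noiseless_model(target_coverage = 3),
                             seed = 12)
  for (m in mols[1:min(10, length(mols))]) {
    src <- smp$haplotypes$h1$chr1  # both haplotypes equal the reference
    start <- attr(m, "source_start")
    expected <- src$positions[src$positions >= start &
                                src$positions < start + m$length_bp] - start
    expect_equal(m$positions, expected)
  }
})

test_that("false-negative label dropout follows the configured rate", {
  ref <- simulate_reference(1, 5e6, 5000, seed = 13)
  smp <- implant_svs(ref, data.frame(sv_type = character(),
                                     size_bp = numeric(),
                                     zygosity = character()), seed = 1)
  nm <- noise_model(fn_rate = 0.06, fp_per_100kb = 0, sizing_sf = 0,
                    sizing_sr = 0, target_coverage = 12)
  mols <- generate_molecules(smp, nm, seed = 14)
  n_true <- 0; n_kept <- 0
  for (m in mols) {
    src <- smp$haplotypes$h1$chr1
    start <- attr(m, "source_start")
    n_true <- n_true + sum(src$positions >= start &
                             src$positions < start + m$length_bp)
    n_kept <- n_kept + n_labels(m)
  }
  phat <- n_kept / n_true
  se <- sqrt(0.94 * 0.06 / n_true)
  expect_lt(abs(phat - 0.94), 4 * se)
})

test_that("molecule totals reach the target coverage", {
  ref <- simulate_reference(1, 1e6, 10000, seed = 15)
  smp <- implant_svs(ref, data.frame(sv_type = character(),
                                     size_bp = numeric(),
                                     zygosity = character()), seed = 1)
  nm <- noise_model(target_coverage = 79)
  mols <- generate_molecules(smp, nm, seed = 16)
  total <- sum(vapply(mols, `[[`, 0, "length_bp"))
  expect_gte(total / 1e6, 75)
  expect_lte(total / 1e6, 83)
  expect_true(all(vapply(mols, `[[`, 0, "length_bp") >= 150000))
})

test_that("simulated molecule lengths respect the N50 law", {
  law <- nicksv:::fit_molecule_length_law(262000, 150000)
  set.seed(3)
  x <- rlnorm(2e5, law$meanlog, law$sdlog)
  x <- x[x >= 150000]
  x <- sort(x)
  n50 <- x[which.max(cumsum(x) >= sum(x) / 2)]
  expect_lt(abs(n50 - 262000) / 262000, 0.02)
})

test_that("contigs are faithful at zero consensus noise and fragment at the break density", {
  ref <- simulate_reference(1, 1e6, 10000, seed = 17)
  smp <- implant_svs(ref, data.frame(sv_type = character(),
                                     size_bp = numeric(),
                                     zygosity = character()), seed = 1)
  ctgs <- make_contigs(smp, noise_model(), seed = 18,
                       consensus_factor = 0)
  expect_length(ctgs, 2)   # one per haplotype chromosome
  expect_equal(ctgs[[1]]$positions, smp$haplotypes$h1$chr1$positions)
  # Poisson fragmentation: 1 break per 500 kb on 1 Mb -> ~3 contigs/hap
  counts <- vapply(1:20, function(s)
    length(make_contigs(smp, noise_model(), seed = s,
                        break_density_per_bp = 1 / 5e5)), 0L)
  expect_gt(mean(counts) / 2, 1.8)   # per haplotype
  expect_lt(mean(counts) / 2, 4.5)
})

test_that("trio transmission is Mendelian", {
  ref <- simulate_reference(1, 2e6, 10000, seed = 19)
  # both parents hom -> child hom
  f <- implant_svs(ref, data.frame(sv_type = "deletion", size_bp = 10000,
                                   zygosity = "hom",
                                   chrom = "chr1", pos = 1e6), seed = 1,
                   sample_id = "dad")
  m <- implant_svs(ref, data.frame(sv_type = "deletion", size_bp = 10000,
                                   zygosity = "hom",
                                   chrom = "chr1", pos = 1e6), seed = 2,
                   sample_id = "mum")
  ch <- simulate_trio(f, m, seed = 3)
  expect_equal(ch$truth$zygosity, "hom")

  # het x ref/ref transmits at 1/2 over many seeded trios
  f2 <- implant_svs(ref, data.frame(sv_type = "deletion", size_bp = 10000,
                                    zygosity = "het",
                                    chrom = "chr1", pos = 1e6), seed = 4)
  m2 <- implant_svs(ref, data.frame(sv_type = character(),
                                    size_bp = numeric(),
                                    zygosity = character()), seed = 5)
  n_trials <- 400
  carried <- vapply(seq_len(n_trials), function(s)
    nrow(simulate_trio(f2, m2, seed = s)$truth) > 0, TRUE)
  phat <- mean(carried)
  expect_lt(abs(phat - 0.5), 4 * sqrt(0.25 / n_trials))

  # child SVs are a subset of the parental union
  f3 <- implant_svs(ref, data.frame(
    sv_type = c("deletion", "insertion"), size_bp = c(8000, 9000),
    zygosity = c("het", "het"), chrom = "chr1", pos = c(6e5, 1.4e6)),
    seed = 6)
  ch3 <- simulate_trio(f3, m2, seed = 7)
  expect_true(all(ch3$truth$ref_start %in% f3$truth$ref_start))
})

test_that("cohort genotypes follow Hardy-Weinberg and divergence scales structure", {
  ref <- simulate_reference(1, 6e6, 10000, seed = 20)
  co <- simulate_cohort(ref, n_pops = 2, samples_per_pop = 250,
                        n_svs = 12, divergence = 0, seed = 21)
  # chi-square check of genotype counts per SV within each population
  freq <- co$sv_panel$p_global
  for (k in sample(12, 4)) {
    g <- co$genotypes[co$metadata$population == "pop1", k]
    p <- mean(g) / 2
    exp_counts <- 250 * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1, 3)
    keep <- exp_counts > 1
    chi <- sum((obs[keep] - exp_counts[keep])^2 / exp_counts[keep])
    expect_lt(chi, qchisq(1 - 1e-4, df = sum(keep) - 1))
  }
  # divergence increases between-population frequency differences
  co_div <- simulate_cohort(ref, n_pops = 2, samples_per_pop = 250,
                            n_svs = 12, divergence = 0.25, seed = 21)
  fdiff <- function(co) {
    f1 <- colMeans(co$genotypes[co$metadata$population == "pop1", ]) / 2
    f2 <- colMeans(co$genotypes[co$metadata$population == "pop2", ]) / 2
    mean(abs(f1 - f2))
  }
  expect_gt(fdiff(co_div), fdiff(co) * 2)
})
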