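#' Optical-map noise model
#'
#' Label-level error model of the nick-mapping instrument, with the
#' defaults used throughout the package: a true label is missed with
#' probability `fn_rate`; false labels arise as a Poisson process with
#' `fp_per_100kb` expected events per 100 kb; an inter-label distance `d`
#' is measured as `d + e` with `e ~ Normal(0, sqrt((sizing_sf*1000)^2 +
#' (sizing_sr*d)^2))` (`sizing_sf` in kb, vendor convention); labels
#' closer than `resolution_bp` merge. Molecules pass a `min_molecule_bp`
#' length filter and are collected to `target_coverage`-fold depth with
#' length N50 `length_n50_bp`.
#'
#' @param fn_rate Missed-label probability (default 0.06).
#' @param fp_per_100kb False labels per 100 kb (default 0.6).
#' @param sizing_sf Additive sizing noise scale, kb (default 0.20).
#' @param sizing_sr Relative sizing noise coefficient (default 0.01).
#' @param resolution_bp Label merge radius (default 450).
#' @param min_molecule_bp Molecule length floor (default 150000).
#' @param target_coverage Fold coverage to simulate (default 79).
#' @param length_n50_bp Molecule length N50 after truncation
#'   (default 262000).
#' @return List of class `noise_model`.
#' @export
noise_model <- function(fn_rate = 0.06, fp_per_100kb = 0.6,
                        sizing_sf = 0.20, sizing_sr = 0.01,
                        resolution_bp = 450, min_molecule_bp = 150000,
                        target_coverage = 79, length_n50_bp = 262000) {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_per_100kb >= 0,
            sizing_sf >= 0, sizing_sr >= 0,
            min_molecule_bp <= length_n50_bp)
  structure(list(fn_rate = fn_rate, fp_per_100kb = fp_per_100kb,
                 sizing_sf = sizing_sf, sizing_sr = sizing_sr,
                 resolution_bp = resolution_bp,
                 min_molecule_bp = min_molecule_bp,
                 target_coverage = target_coverage,
                 length_n50_bp = length_n50_bp),
            class = "noise_model")
}

#' Zero-noise model (exact sub-maps), for tests and calibration
#' @param ... Overrides passed to [noise_model()].
#' @return A `noise_model` with all error rates zero.
#' @export
noiseless_model <- function(...) {
  args <- list(fn_rate = 0, fp_per_100kb = 0, sizing_sf = 0, sizing_sr = 0)
  do.call(noise_model, utils::modifyList(args, list(...)))
}

#' Simulate a reference digest
#'
#' Label positions are drawn as a homogeneous Poisson point process with
#' the requested mean spacing, then resolution-merged, emulating the in
#' silico digest of a random genome.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len_bp Length of each chromosome in bp.
#' @param mean_label_spacing_bp Mean inter-label spacing (must exceed the
#'   merge resolution; ~10 kb is typical of Nt.BspQI on human sequence).
#' @param seed Integer seed.
#' @param resolution Merge radius in bp (default 450).
#' @return A `reference_digest`.
#' @export
simulate_reference <- function(n_chrom = 1L, chrom_len_bp = 5e6,
                               mean_label_spacing_bp = 10000, seed = 1L,
                               resolution = 450) {
  if (mean_label_spacing_bp <= resolution)
    stop("mean_label_spacing_bp must exceed the merge resolution")
  set.seed(seed)
  maps <- list()
  for (i in seq_len(n_chrom)) {
    chrom <- paste0("chr", i)
    n_exp <- ceiling(chrom_len_bp / mean_label_spacing_bp * 1.5) + 10
    gaps <- stats::rexp(n_exp, rate = 1 / mean_label_spacing_bp)
    pos <- cumsum(gaps)
    pos <- pos[pos < chrom_len_bp]
    pos <- merge_labels(pos, resolution)
    maps[[chrom]] <- label_map(chrom, pos, chrom_len_bp, kind = "reference")
  }
  reference_digest_from_maps(maps, motif = "GCTCTTC",
                             resolution = resolution)
}

#' Implant structural variants into two haplotypes
#'
#' Applies a list of SVs to the reference label maps, producing two
#' haplotype label maps per chromosome plus a ground-truth table.
#' Deletions remove a segment and its labels; insertions add a segment
#' carrying labels at the reference density (or none, for label-free
#' insertions); inversions reverse a segment's label offsets;
#' duplications tandem-repeat a segment; translocations move a segment
#' (between chromosomes for `inter_translocation`). Heterozygous SVs land
#' on exactly one (randomly chosen) haplotype.
#'
#' @param ref A `reference_digest`.
#' @param sv_spec Data frame with columns `sv_type`, `size_bp`,
#'   `zygosity`, and optionally `chrom`, `pos` (explicit loci),
#'   `n_copies` (duplications, default 3), `insert_labels` (default
#'   TRUE). Loci left `NA` are placed uniformly at random, separated by
#'   `min_separation` and away from chromosome ends by `edge_margin`.
#' @param seed Integer seed.
#' @param sample_id Sample name recorded in the truth table.
#' @param min_separation Minimum distance between SV loci (default 150 kb).
#' @param edge_margin Keep SVs this far from chromosome ends
#'   (default 300 kb).
#' @return List of class `om_sample`: `sample_id`, `haplotypes` (list
#'   `h1`/`h2` of named lists of [label_map()]s) and `truth` (data frame
#'   with `sv_type`, `chrom`, `ref_start`, `ref_end`, `size_delta_bp`,
#'   `zygosity`, `hap1`, `hap2`).
#' @export
implant_svs <- function(ref, sv_spec, seed = 1L, sample_id = "s1",
                        min_separation = 150000, edge_margin = 300000) {
  set.seed(seed)
  spec <- as.data.frame(sv_spec)
  n <- nrow(spec)
  spec <- within_spec_defaults(spec)
  spec <- place_loci(ref, spec, min_separation, edge_margin)
  # decide haplotype assignment
  spec$hap1 <- spec$zygosity %in% c("hom")
  spec$hap2 <- spec$hap1
  het <- spec$zygosity == "het"
  pick <- stats::runif(n) < 0.5
  spec$hap1[het] <- pick[het]
  spec$hap2[het] <- !pick[het]
  mean_spacing <- mean(unlist(lapply(ref$maps, function(m)
    diff(m$positions))))
  haps <- list(h1 = NULL, h2 = NULL)
  for (h in 1:2) {
    carried <- spec[spec[[paste0("hap", h)]], , drop = FALSE]
    haps[[h]] <- apply_svs_to_maps(ref$maps, carried, mean_spacing,
                                   paste0(sample_id, "_h", h))
  }
  truth <- data.frame(sv_type = spec$sv_type, chrom = spec$chrom,
                      ref_start = spec$ref_start, ref_end = spec$ref_end,
                      size_delta_bp = spec$size_delta,
                      zygosity = spec$zygosity,
                      hap1 = spec$hap1, hap2 = spec$hap2,
                      dest_chrom = spec$dest_chrom,
                      dest_pos = spec$dest_pos,
                      sample_id = rep_len(sample_id, n),
                      stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, haplotypes = haps, truth = truth),
            class = "om_sample")
}

place_loci <- function(ref, spec, min_separation, edge_margin) {
  n <- nrow(spec)
  spec$ref_start <- rep(NA_real_, n)
  spec$ref_end <- rep(NA_real_, n)
  spec$size_delta <- rep(NA_real_, n)
  spec$dest_chrom <- rep(NA_character_, n)
  spec$dest_pos <- rep(NA_real_, n)
  placed <- lapply(names(ref$maps), function(ch) numeric())
  names(placed) <- names(ref$maps)
  chrom_len <- vapply(ref$maps, `[[`, 0, "length_bp")
  for (i in seq_len(n)) {
    type <- spec$sv_type[i]
    size <- spec$size_bp[i]
    span <- if (type == "insertion") 0 else size
    if (is.na(spec$chrom[i]) || is.na(spec$pos[i])) {
      ok <- FALSE
      for (try in 1:500) {
        ch <- sample(names(ref$maps), 1,
                     prob = pmax(chrom_len - 2 * edge_margin - span, 1))
        pos <- stats::runif(1, edge_margin,
                            chrom_len[[ch]] - edge_margin - span)
        if (all(abs(placed[[ch]] - pos) > min_separation + span)) {
          ok <- TRUE; break
        }
      }
      if (!ok) {
        # deterministic fallback: scan a fine grid for a feasible slot
        for (ch in names(ref$maps)[order(-chrom_len)]) {
          grid <- seq(edge_margin, chrom_len[[ch]] - edge_margin - span,
                      by = min_separation / 4)
          feas <- grid[vapply(grid, function(g)
            all(abs(placed[[ch]] - g) > min_separation + span), TRUE)]
          if (length(feas) > 0) {
            pos <- feas[sample.int(length(feas), 1)]
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place SV ", i,
                      ": loci too dense for min_separation")
      }
      spec$chrom[i] <- ch
      spec$pos[i] <- pos
    } else {
      ch <- spec$chrom[i]; pos <- spec$pos[i]
      if (any(abs(placed[[ch]] - pos) <= min_separation + span))
        stop("explicit SV loci overlap (sv ", i, ")")
    }
    placed[[spec$chrom[i]]] <- c(placed[[spec$chrom[i]]], spec$pos[i])
    spec$ref_start[i] <- spec$pos[i]
    spec$ref_end[i] <- spec$pos[i] + span
    if (type == "intra_translocation") {
      len <- chrom_len[[spec$chrom[i]]]
      pos <- spec$pos[i]
      if (pos + 6e6 + 2 * span < len - edge_margin) {
        spec$dest_pos[i] <- pos + 6e6 + span
      } else if (pos - 6e6 > edge_margin) {
        spec$dest_pos[i] <- pos - 6e6
      } else stop("chromosome too short to move a segment > 5 Mb away")
      spec$dest_chrom[i] <- spec$chrom[i]
    } else if (type == "inter_translocation") {
      others <- setdiff(names(ref$maps), spec$chrom[i])
      if (length(others) == 0)
        stop("inter_translocation needs at least two chromosomes")
      spec$dest_chrom[i] <- others[1]
      spec$dest_pos[i] <- chrom_len[[others[1]]] / 2
    }
    spec$size_delta[i] <- switch(type,
      insertion = size, deletion = -size,
      duplication = size * (spec$n_copies[i] - 1L),
      0)
  }
  spec
}

# Apply SVs (sorted by position, descending, per chromosome) to reference
# maps; returns named list of haplotype label maps.
apply_svs_to_maps <- function(maps, svs, mean_spacing, hap_tag) {
  state <- lapply(maps, function(m)
    list(pos = m$positions, len = m$length_bp))
  if (nrow(svs) > 0) {
    svs <- svs[order(svs$chrom, -svs$ref_start), , drop = FALSE]
    for (i in seq_len(nrow(svs))) {
      s <- svs[i, ]
      st <- state[[s$chrom]]
      state[[s$chrom]] <- apply_one_sv(st, s, mean_spacing, state)
      if (s$sv_type == "inter_translocation") {
        # segment re-inserted on the partner chromosome recorded in attr
        dest <- attr(state[[s$chrom]], "dest")
        if (!is.null(dest)) {
          state[[dest$chrom]] <- dest$state
          attr(state[[s$chrom]], "dest") <- NULL
        }
      }
    }
  }
  out <- list()
  for (ch in names(maps)) {
    st <- state[[ch]]
    pos <- sort(st$pos[st$pos >= 0 & st$pos < st$len])
    out[[ch]] <- label_map(paste0(hap_tag, "_", ch), pos, st$len,
                           kind = "reference")
  }
  out
}

apply_one_sv <- function(st, s, mean_spacing, all_state) {
  pos <- st$pos; len <- st$len
  a <- s$ref_start; b <- s$ref_end
  if (s$sv_type == "deletion") {
    keep <- pos < a | pos >= b
    pos <- pos[keep]
    pos[pos >= b - (b - a)] <- pos[pos >= b - (b - a)]  # no-op clarity
    pos[pos >= a] <- pos[pos >= a] - (b - a)
    len <- len - (b - a)
  } else if (s$sv_type == "insertion") {
    size <- s$size_bp
    new_labels <- numeric()
    if (isTRUE(s$insert_labels)) {
      k <- stats::rpois(1, size / mean_spacing)
      if (k > 0) new_labels <- a + sort(stats::runif(k, 0, size))
    }
    pos[pos >= a] <- pos[pos >= a] + size
    pos <- sort(c(pos, new_labels))
    len <- len + size
  } else if (s$sv_type == "inversion") {
    inside <- pos >= a & pos < b
    pos[inside] <- a + b - pos[inside]
    pos <- sort(pos)
  } else if (s$sv_type == "duplication") {
    unit <- b - a
    extra <- s$n_copies - 1L
    inside <- pos[pos >= a & pos < b]
    added <- unlist(lapply(seq_len(extra), function(k) inside + k * unit))
    pos[pos >= b] <- pos[pos >= b] + extra * unit
    pos <- sort(c(pos, added))
    len <- len + extra * unit
  } else if (s$sv_type == "intra_translocation") {
    seg <- pos[pos >= a & pos < b] - a
    keep <- pos < a | pos >= b
    pos <- pos[keep]
    pos[pos >= a] <- pos[pos >= a] - (b - a)
    dest <- s$dest_pos
    if (dest > a) dest <- dest - (b - a)  # excision shifted the target
    pos[pos >= dest] <- pos[pos >= dest] + (b - a)
    pos <- sort(c(pos, dest + seg))
  } else if (s$sv_type == "inter_translocation") {
    seg <- pos[pos >= a & pos < b] - a
    keep <- pos < a | pos >= b
    pos <- pos[keep]
    pos[pos >= a] <- pos[pos >= a] - (b - a)
    len <- len - (b - a)
    dch <- s$dest_chrom
    dst <- all_state[[dch]]
    ins_at <- min(s$dest_pos, dst$len - (b - a) - 1)
    dpos <- dst$pos
    dpos[dpos >= ins_at] <- dpos[dpos >= ins_at] + (b - a)
    dst$pos <- sort(c(dpos, ins_at + seg))
    dst$len <- dst$len + (b - a)
    res <- list(pos = pos, len = len)
    attr(res, "dest") <- list(chrom = dch, state = dst)
    return(res)
  } else stop("unknown sv_type: ", s$sv_type)
  list(pos = pos, len = len)
}

# Fit the log-normal meanlog so the truncated law has the requested
# length-weighted median (N50); sdlog fixed at 0.55.
fit_molecule_length_law <- function(n50, floor_bp, sdlog = 0.55) {
  target <- function(mu) {
    za <- (log(floor_bp) - mu - sdlog^2) / sdlog
    zm <- (log(n50) - mu - sdlog^2) / sdlog
    (stats::pnorm(zm) - stats::pnorm(za)) - 0.5 * (1 - stats::pnorm(za))
  }
  mu <- stats::uniroot(target, c(log(floor_bp) - 3, log(n50) + 3))$root
  list(meanlog = mu, sdlog = sdlog)
}

#' Generate noisy single molecules from haplotype maps
#'
#' Molecules are sampled uniformly from both haplotypes (weighted by
#' length) until the summed molecule length reaches `target_coverage`
#' times the haploid genome length. Lengths follow a log-normal law
#' calibrated to the model's N50, truncated at the molecule length floor.
#' Each true label is kept with probability `1 - fn_rate`; false labels
#' are added as a Poisson process; inter-label distances receive Gaussian
#' sizing error; labels within the optical resolution merge.
#'
#' @param sample An `om_sample` (from [implant_svs()]), or a list of two
#'   haplotype map lists.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param sample_id Sample identifier stamped on molecules.
#' @return List of molecule [label_map()]s; each carries attributes
#'   `source_map`, `source_start`, `source_rc` for evaluation only.
#' @export
generate_molecules <- function(sample, noise = noise_model(), seed = 1L,
                               sample_id = NULL) {
  haps <- sample_haplotype_maps(sample)
  if (is.null(sample_id))
    sample_id <- if (inherits(sample, "om_sample")) sample$sample_id else "s1"
  set.seed(seed)
  maps <- unlist(haps, recursive = FALSE)
  lens <- vapply(maps, `[[`, 0, "length_bp")
  genome_len <- sum(lens) / 2
  if (max(lens) < noise$min_molecule_bp)
    stop("all haplotype maps are shorter than the molecule length floor")
  law <- fit_molecule_length_law(noise$length_n50_bp, noise$min_molecule_bp)
  target <- noise$target_coverage * genome_len
  mols <- list()
  total <- 0
  i <- 0L
  while (total < target) {
    i <- i + 1L
    len <- Inf
    while (len < noise$min_molecule_bp || len > max(lens))
      len <- stats::rlnorm(1, law$meanlog, law$sdlog)
    src <- sample(seq_along(maps), 1, prob = pmax(lens - len, 0) + 1)
    m <- maps[[src]]
    if (m$length_bp < len) next
    start <- stats::runif(1, 0, m$length_bp - len)
    lab <- m$positions[m$positions >= start & m$positions < start + len] -
      start
    lab <- noisy_labels(lab, len, noise)
    mol <- label_map(sprintf("%s_mol_%06d", sample_id, i), lab, len,
                     kind = "molecule", sample_id = sample_id)
    attr(mol, "source_map") <- m$map_id
    attr(mol, "source_start") <- start
    mols[[length(mols) + 1L]] <- mol
    total <- total + len
  }
  log_stage("simulate_molecules", n = length(mols),
            coverage = round(total / genome_len, 1), seed = seed)
  mols
}

sample_haplotype_maps <- function(sample) {
  if (inherits(sample, "om_sample")) sample$haplotypes else sample
}

noisy_labels <- function(lab, len, noise) {
  if (length(lab) > 0 && noise$fn_rate > 0)
    lab <- lab[stats::runif(length(lab)) >= noise$fn_rate]
  if (length(lab) > 1 && (noise$sizing_sf > 0 || noise$sizing_sr > 0)) {
    gaps <- diff(c(0, lab))
    sd_g <- sqrt((noise$sizing_sf * 1000)^2 + (noise$sizing_sr * gaps)^2)
    gaps <- pmax(gaps + stats::rnorm(length(gaps), 0, sd_g), 1)
    lab <- cumsum(gaps)
  }
  n_fp <- if (noise$fp_per_100kb > 0)
    stats::rpois(1, len / 1e5 * noise$fp_per_100kb) else 0L
  if (n_fp > 0) lab <- sort(c(lab, stats::runif(n_fp, 0, len)))
  lab <- lab[lab >= 0 & lab < len]
  merge_labels(sort(lab), noise$resolution_bp)
}

#' Build stand-in consensus contigs from haplotype maps
#'
#' Consensus assembly is emulated rather than performed: each haplotype
#' chromosome yields contigs (optionally fragmented at a Poisson break
#' density) whose label noise is the molecule noise attenuated by a
#' consensus factor, by default `1/sqrt(target_coverage)` — the error
#' reduction expected from averaging independent molecules.
#'
#' @param sample An `om_sample` or haplotype map list.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param break_density_per_bp Expected contig breaks per bp (default 0:
#'   one contig per haplotype chromosome).
#' @param consensus_factor Noise attenuation factor (default
#'   `1/sqrt(target_coverage)`; 0 gives exact copies).
#' @return List of contig [label_map()]s with attribute `source_map`.
#' @export
make_contigs <- function(sample, noise = noise_model(), seed = 1L,
                         break_density_per_bp = 0,
                         consensus_factor = NULL) {
  haps <- sample_haplotype_maps(sample)
  if (is.null(consensus_factor))
    consensus_factor <- 1 / sqrt(noise$target_coverage)
  set.seed(seed)
  cnoise <- noise_model(
    fn_rate = noise$fn_rate * consensus_factor,
    fp_per_100kb = noise$fp_per_100kb * consensus_factor,
    sizing_sf = noise$sizing_sf * consensus_factor,
    sizing_sr = noise$sizing_sr * consensus_factor,
    resolution_bp = noise$resolution_bp,
    min_molecule_bp = noise$min_molecule_bp,
    target_coverage = noise$target_coverage,
    length_n50_bp = noise$length_n50_bp)
  contigs <- list()
  k <- 0L
  for (h in seq_along(haps)) {
    for (ch in names(haps[[h]])) {
      m <- haps[[h]][[ch]]
      n_brk <- if (break_density_per_bp > 0)
        stats::rpois(1, m$length_bp * break_density_per_bp) else 0L
      brk <- sort(stats::runif(n_brk, 0, m$length_bp))
      bounds <- c(0, brk, m$length_bp)
      for (j in seq_len(length(bounds) - 1)) {
        a <- bounds[j]; b <- bounds[j + 1]
        if (b - a < 2 * cnoise$resolution_bp) next
        lab <- m$positions[m$positions >= a & m$positions < b] - a
        lab <- noisy_labels(lab, b - a, cnoise)
        k <- k + 1L
        ctg <- label_map(sprintf("ctg_%03d_h%d_%s", k, h, ch), lab, b - a,
                         kind = "contig")
        attr(ctg, "source_map") <- m$map_id
        attr(ctg, "source_start") <- a
        contigs[[length(contigs) + 1L]] <- ctg
      }
    }
  }
  contigs
}

#' Simulate a child from two parents
#'
#' The child receives one randomly chosen haplotype from each parent per
#' chromosome (whole-haplotype transmission; optional recombination
#' breakpoints are not applied by default).
#'
#' @param father,mother `om_sample` objects built on the same reference.
#' @param seed Integer seed.
#' @param sample_id Child sample name.
#' @return An `om_sample` for the child; its truth table lists the SVs on
#'   the transmitted haplotypes.
#' @export
simulate_trio <- function(father, mother, seed = 1L, sample_id = "child") {
  chroms_f <- names(father$haplotypes$h1)
  chroms_m <- names(mother$haplotypes$h1)
  strip <- function(x) sub("^.*_h[12]_", "", x)
  if (!identical(strip(chroms_f), strip(chroms_m)))
    stop("parents are not on the same reference")
  set.seed(seed)
  pick_f <- sample(1:2, length(chroms_f), replace = TRUE)
  pick_m <- sample(1:2, length(chroms_f), replace = TRUE)
  take <- function(parent, pick, hap_out) {
    out <- list()
    for (i in seq_along(chroms_f)) {
      src <- parent$haplotypes[[pick[i]]][[i]]
      ch <- strip(src$map_id)
      out[[ch]] <- label_map(paste0(sample_id, "_", hap_out, "_", ch),
                             src$positions, src$length_bp,
                             kind = "reference")
    }
    out
  }
  h1 <- take(father, pick_f, "h1")
  h2 <- take(mother, pick_m, "h2")
  truth_from <- function(parent, pick, hap_col) {
    tr <- parent$truth
    if (nrow(tr) == 0) return(tr[0, ])
    chrom_pick <- pick[match(tr$chrom, strip(chroms_f))]
    carried <- ifelse(chrom_pick == 1, tr$hap1, tr$hap2)
    tr[carried, , drop = FALSE]
  }
  tf <- truth_from(father, pick_f, "hap1")
  tm <- truth_from(mother, pick_m, "hap2")
  mk <- function(tr, hap1) {
    if (nrow(tr) == 0) return(NULL)
    data.frame(sv_type = tr$sv_type, chrom = tr$chrom,
               ref_start = tr$ref_start, ref_end = tr$ref_end,
               size_delta_bp = tr$size_delta_bp, zygosity = "het",
               hap1 = hap1, hap2 = !hap1, sample_id = sample_id,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(mk(tf, TRUE), mk(tm, FALSE))
  if (is.null(truth))
    truth <- father$truth[0, ]
  # collapse duplicate loci transmitted from both parents into hom
  if (nrow(truth) > 1) {
    key <- paste(truth$chrom, round(truth$ref_start), truth$sv_type)
    dup <- duplicated(key)
    if (any(dup)) {
      for (k in unique(key[dup])) {
        rows <- which(key == k)
        truth$zygosity[rows[1]] <- "hom"
        truth$hap1[rows[1]] <- TRUE
        truth$hap2[rows[1]] <- TRUE
      }
      truth <- truth[!dup, , drop = FALSE]
    }
  }
  structure(list(sample_id = sample_id,
                 haplotypes = list(h1 = h1, h2 = h2), truth = truth),
            class = "om_sample")
}

#' Simulate a multi-population cohort with ground truth
#'
#' A fixed panel of SV loci is generated on the reference; each SV gets a
#' global allele frequency and per-population frequencies drawn from the
#' Balding-Nichols Beta model `Beta(p(1-F)/F, (1-p)(1-F)/F)` with
#' divergence `F`; per-sample genotypes follow Hardy-Weinberg within each
#' population. Populations are assigned to the five super-populations in
#' rotation.
#'
#' @param ref A `reference_digest`.
#' @param n_pops Number of populations.
#' @param samples_per_pop Samples per population (default 6, three males
#'   and three females).
#' @param n_svs Number of SV loci in the panel.
#' @param divergence Allele-frequency dispersion `F` in `[0, 1)`;
#'   0 means no population structure. A length-2 vector
#'   `c(between, within)` (even `n_pops` only) generates nested
#'   structure: consecutive population pairs form clades whose shared
#'   frequency diverges from the global one with `between`, and the two
#'   populations diverge from their clade with `within`.
#' @param seed Integer seed.
#' @param size_range Indel size range in bp (default 3-50 kb).
#' @param freq_range Global allele-frequency range (default 0.05-0.95).
#' @param sv_types Types to draw loci from (default insertion/deletion).
#' @param min_separation,edge_margin Locus placement constraints
#'   passed to the implanting step (defaults 150 kb / 300 kb).
#' @return List of class `om_cohort`: `samples` (list of `om_sample`),
#'   `metadata` ([cohort_metadata()]), `sv_panel` (per-locus truth with
#'   per-population frequencies) and `genotypes` (samples x loci allele
#'   count matrix).
#' @export
simulate_cohort <- function(ref, n_pops = 4L, samples_per_pop = 6L,
                            n_svs = 50L, divergence = 0.1, seed = 1L,
                            size_range = c(3000, 50000),
                            freq_range = c(0.05, 0.95),
                            sv_types = c("insertion", "deletion"),
                            min_separation = 150000,
                            edge_margin = 300000) {
  stopifnot(n_svs >= 1)
  set.seed(seed)
  panel <- data.frame(
    sv_type = sample(sv_types, n_svs, replace = TRUE),
    size_bp = round(stats::runif(n_svs, size_range[1], size_range[2])),
    zygosity = "het")
  panel <- place_loci(ref, within_spec_defaults(panel), min_separation,
                      edge_margin)
  p_global <- stats::runif(n_svs, freq_range[1], freq_range[2])
  supers <- c("AFR", "AMR", "EAS", "EUR", "SAS")
  pops <- paste0("pop", seq_len(n_pops))
  pop_super <- supers[((seq_len(n_pops) - 1) %% 5) + 1]
  draw_bn <- function(p, f) {
    if (f <= 0) return(p)
    stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }
  freq <- matrix(NA_real_, n_svs, n_pops, dimnames = list(NULL, pops))
  if (length(divergence) == 2) {
    if (n_pops %% 2 != 0)
      stop("nested divergence needs an even number of populations")
    for (clade in seq_len(n_pops / 2)) {
      p_clade <- draw_bn(p_global, divergence[1])
      for (j in (2 * clade - 1):(2 * clade))
        freq[, j] <- draw_bn(p_clade, divergence[2])
    }
  } else {
    for (j in seq_len(n_pops)) freq[, j] <- draw_bn(p_global, divergence)
  }
  samples <- list()
  meta_rows <- list()
  geno <- matrix(0L, n_pops * samples_per_pop, n_svs)
  sid <- 0L
  sample_ids <- character()
  for (j in seq_len(n_pops)) {
    for (k in seq_len(samples_per_pop)) {
      sid <- sid + 1L
      sample_id <- sprintf("%s_s%02d", pops[j], k)
      sample_ids <- c(sample_ids, sample_id)
      alleles1 <- stats::runif(n_svs) < freq[, j]
      alleles2 <- stats::runif(n_svs) < freq[, j]
      geno[sid, ] <- as.integer(alleles1) + as.integer(alleles2)
      carried <- which(geno[sid, ] > 0)
      sv_spec <- panel[carried, , drop = FALSE]
      if (nrow(sv_spec) > 0)
        sv_spec$zygosity <- ifelse(geno[sid, carried] == 2, "hom", "het")
      sample <- make_cohort_sample(ref, sv_spec, sample_id)
      samples[[sample_id]] <- sample
      meta_rows[[sid]] <- data.frame(
        sample_id = sample_id, population = pops[j],
        super_population = pop_super[j],
        sex = if (k %% 2 == 0) "F" else "M")
    }
  }
  rownames(geno) <- sample_ids
  meta <- do.call(rbind, meta_rows)
  meta <- cohort_metadata(meta$sample_id, meta$population,
                          meta$super_population, meta$sex)
  panel$p_global <- p_global
  panel <- cbind(panel, as.data.frame(freq))
  structure(list(samples = samples, metadata = meta, sv_panel = panel,
                 genotypes = geno, divergence = divergence),
            class = "om_cohort")
}

within_spec_defaults <- function(spec) {
  n <- nrow(spec)
  if (!"n_copies" %in% names(spec)) spec$n_copies <- rep(3L, n)
  if (!"insert_labels" %in% names(spec)) spec$insert_labels <- rep(TRUE, n)
  if (!"chrom" %in% names(spec)) spec$chrom <- rep(NA_character_, n)
  if (!"pos" %in% names(spec)) spec$pos <- rep(NA_real_, n)
  spec
}

# build an om_sample with explicit hap assignment from genotypes (no
# re-randomisation of zygosity; loci already placed)
make_cohort_sample <- function(ref, sv_spec, sample_id) {
  n <- nrow(sv_spec)
  if (n == 0) {
    haps <- list(
      h1 = copy_ref_maps(ref, paste0(sample_id, "_h1")),
      h2 = copy_ref_maps(ref, paste0(sample_id, "_h2")))
    truth <- data.frame(sv_type = character(), chrom = character(),
                        ref_start = numeric(), ref_end = numeric(),
                        size_delta_bp = numeric(), zygosity = character(),
                        hap1 = logical(), hap2 = logical(),
                        sample_id = character())
    return(structure(list(sample_id = sample_id, haplotypes = haps,
                          truth = truth), class = "om_sample"))
  }
  spec <- sv_spec
  spec$hap1 <- spec$zygosity == "hom"
  spec$hap2 <- spec$hap1
  het <- spec$zygosity == "het"
  pick <- stats::runif(n) < 0.5
  spec$hap1[het] <- pick[het]
  spec$hap2[het] <- !pick[het]
  mean_spacing <- mean(unlist(lapply(ref$maps, function(m)
    diff(m$positions))))
  haps <- list(h1 = NULL, h2 = NULL)
  for (h in 1:2) {
    carried <- spec[spec[[paste0("hap", h)]], , drop = FALSE]
    haps[[h]] <- apply_svs_to_maps(ref$maps, carried, mean_spacing,
                                   paste0(sample_id, "_h", h))
  }
  truth <- data.frame(sv_type = spec$sv_type, chrom = spec$chrom,
                      ref_start = spec$ref_start, ref_end = spec$ref_end,
                      size_delta_bp = spec$size_delta,
                      zygosity = spec$zygosity, hap1 = spec$hap1,
                      hap2 = spec$hap2, sample_id = sample_id,
                      stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, haplotypes = haps, truth = truth),
            class = "om_sample")
}

copy_ref_maps <- function(ref, tag) {
  out <- list()
  for (ch in names(ref$maps)) {
    m <- ref$maps[[ch]]
    out[[ch]] <- label_map(paste0(tag, "_", ch), m$positions, m$length_bp,
                           kind = "reference")
  }
  out
}

#' Convert a sample's ground truth to an SV call table
#'
#' Used to feed cohort-level analyses with noise-free calls, or to join
#' pipeline calls against truth in evaluations.
#'
#' @param sample An `om_sample`.
#' @return An [sv_calls()] data frame (module `MR`, score `Inf`).
#' @export
truth_to_calls <- function(sample) {
  tr <- sample$truth
  if (nrow(tr) == 0) return(sv_calls())
  sv_calls(chrom = tr$chrom, start_bp = tr$ref_start, end_bp = tr$ref_end,
           sv_type = tr$sv_type, size_delta_bp = tr$size_delta_bp,
           zygosity = tr$zygosity, support = 0L, score = Inf,
           module = "MR", sample_id = tr$sample_id)
}
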