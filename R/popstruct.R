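#' Cohort-level population structure of SVs
#'
#' Per-sample call sets are merged into cross-sample loci (single
#' linkage under the reciprocal-overlap + size-agreement rule) and
#' summarised as an occurrence matrix of allele counts, which feeds the
#' sharing, tree, PCA, and size-ANOVA analyses.
#' @name popstruct
NULL

#' Build the SV occurrence matrix of a cohort
#'
#' @param per_sample_calls Named list of [sv_calls()] data frames, one
#'   per sample (names are sample ids; unnamed lists use the tables'
#'   `sample_id`).
#' @param merge_tol Reciprocal-overlap threshold for cross-sample
#'   merging (default 0.5); sizes must agree within `max(2 kb, 20%)`.
#' @return List of class `occurrence_matrix`: `matrix` (samples x loci
#'   allele counts: hom 2, het 1, unknown 1, tri 2), `loci` (data frame
#'   with `chrom`, `start_bp`, `end_bp`, `sv_type`, `n_carriers`) and
#'   `sizes` (samples x loci signed size estimates, NA where absent).
#' @export
build_occurrence_matrix <- function(per_sample_calls, merge_tol = 0.5) {
  if (is.null(names(per_sample_calls)))
    names(per_sample_calls) <- vapply(per_sample_calls, function(x)
      x$sample_id[1], "")
  for (s in names(per_sample_calls))
    if (nrow(per_sample_calls[[s]]) > 0)
      per_sample_calls[[s]]$sample_id <- s
  all <- bind_sv_calls(per_sample_calls)
  samples <- names(per_sample_calls)
  if (nrow(all) == 0) {
    m <- matrix(0L, length(samples), 0,
                dimnames = list(samples, NULL))
    return(structure(list(matrix = m, loci = data.frame(),
                          sizes = m), class = "occurrence_matrix"))
  }
  cl <- cluster_calls(as.data.frame(all), merge_tol)
  n_loci <- max(cl)
  m <- matrix(0L, length(samples), n_loci,
              dimnames = list(samples, paste0("locus", seq_len(n_loci))))
  sz <- matrix(NA_real_, length(samples), n_loci,
               dimnames = dimnames(m))
  loci <- data.frame(chrom = character(n_loci),
                     start_bp = numeric(n_loci), end_bp = numeric(n_loci),
                     sv_type = character(n_loci),
                     n_carriers = integer(n_loci))
  alleles <- c(hom = 2L, het = 1L, tri = 2L, unknown = 1L)
  for (k in seq_len(n_loci)) {
    sub <- all[cl == k, , drop = FALSE]
    loci$chrom[k] <- sub$chrom[1]
    loci$start_bp[k] <- stats::median(sub$start_bp)
    loci$end_bp[k] <- stats::median(sub$end_bp)
    loci$sv_type[k] <- sub$sv_type[1]
    for (r in seq_len(nrow(sub))) {
      s <- sub$sample_id[r]
      m[s, k] <- max(m[s, k], alleles[[sub$zygosity[r]]])
      sz[s, k] <- sub$size_delta_bp[r]
    }
    loci$n_carriers[k] <- sum(m[, k] > 0)
  }
  structure(list(matrix = m, loci = loci, sizes = sz),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix: %d samples x %d loci>\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

occ_matrix <- function(x) {
  if (inherits(x, "occurrence_matrix")) x$matrix else as.matrix(x)
}

#' Super-population sharing fractions with balanced sub-sampling
#'
#' For each random sub-sample (equal numbers of samples drawn per
#' super-population), every SV present in a focal super-population is
#' classified as unique to it, shared with some but not all others, or
#' shared with all; fractions are averaged over sub-samples.
#'
#' @param occurrence An `occurrence_matrix` (or plain matrix).
#' @param meta A [cohort_metadata()].
#' @param n_subsamples Number of random sub-samples (default 100).
#' @param draw_size Samples drawn per super-population (default: the
#'   smallest super-population's size).
#' @param seed Integer seed.
#' @return Data frame with rows per super-population and columns
#'   `unique`, `partial`, `universal` (fractions summing to 1).
#' @export
sharing_fractions <- function(occurrence, meta, n_subsamples = 100,
                              draw_size = NULL, seed = 1L) {
  m <- occ_matrix(occurrence)
  sp <- meta$super_population[match(rownames(m), meta$sample_id)]
  if (anyNA(sp)) stop("samples missing from cohort metadata")
  supers <- sort(unique(sp))
  if (length(supers) < 2)
    stop("sharing fractions need at least two super-populations")
  sizes <- table(sp)
  if (is.null(draw_size)) draw_size <- min(sizes)
  if (any(sizes < draw_size))
    stop("a super-population is smaller than the draw size")
  set.seed(seed)
  acc <- matrix(0, length(supers), 3,
                dimnames = list(supers, c("unique", "partial", "universal")))
  for (b in seq_len(n_subsamples)) {
    idx <- unlist(lapply(supers, function(s)
      sample(which(sp == s), draw_size)))
    pres <- rowsum((m[idx, , drop = FALSE] > 0) + 0, sp[idx]) > 0
    n_with <- colSums(pres)
    for (s in supers) {
      here <- pres[s, ]
      n_sv <- sum(here)
      if (n_sv == 0) next
      uni <- sum(here & n_with == 1) / n_sv
      all_ <- sum(here & n_with == length(supers)) / n_sv
      acc[s, ] <- acc[s, ] + c(uni, 1 - uni - all_, all_)
    }
  }
  as.data.frame(acc / n_subsamples)
}

#' Neighbour-joining tree over populations from SV allele frequencies
#'
#' Per-population allele frequencies are computed from the occurrence
#' matrix; populations are compared by Euclidean distance on the
#' frequency vectors and joined with the neighbour-joining algorithm.
#'
#' @param occurrence An `occurrence_matrix` (or matrix).
#' @param meta A [cohort_metadata()].
#' @param level Grouping column (default `"population"`).
#' @return An `ape::phylo` tree (unrooted).
#' @export
population_tree <- function(occurrence, meta, level = "population") {
  m <- occ_matrix(occurrence)
  grp <- meta[[level]][match(rownames(m), meta$sample_id)]
  if (anyNA(grp)) stop("samples missing from cohort metadata")
  if (length(unique(grp)) < 3)
    stop("tree building needs at least three populations")
  freq <- rowsum(m, grp) / (2 * as.vector(table(grp)[sort(unique(grp))]))
  d <- stats::dist(freq)
  ape::nj(d)
}

#' PCA of the SV occurrence matrix
#'
#' Column-centred principal components of the allele counts (no
#' frequency scaling). A constant matrix yields zero scores.
#'
#' @param occurrence An `occurrence_matrix` (or matrix).
#' @param n_components Components to return (default 2).
#' @param presence_absence Use 0/1 presence instead of allele counts
#'   (default FALSE).
#' @return List: `scores` (samples x components), `var_explained`.
#' @export
pca_samples <- function(occurrence, n_components = 2,
                        presence_absence = FALSE) {
  m <- occ_matrix(occurrence)
  if (presence_absence) m <- (m > 0) + 0
  k <- min(n_components, nrow(m) - 1, ncol(m))
  ctr <- scale(m, center = TRUE, scale = FALSE)
  if (all(abs(ctr) < 1e-12) || k < 1) {
    scores <- matrix(0, nrow(m), max(n_components, 1),
                     dimnames = list(rownames(m),
                                     paste0("PC", seq_len(max(n_components, 1)))))
    return(list(scores = scores, var_explained = rep(0, ncol(scores))))
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(p$x))
  list(scores = p$x[, seq_len(k), drop = FALSE],
       var_explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}

#' Per-locus ANOVA of SV sizes across super-populations
#'
#' Loci carried by at least `min_samples` samples are tested by one-way
#' ANOVA of the per-sample size estimates across super-populations,
#' with Bonferroni correction over the tested loci.
#'
#' @param occurrence An `occurrence_matrix` with a `sizes` component.
#' @param meta A [cohort_metadata()].
#' @param min_samples Minimum carriers per tested locus (default 10).
#' @param alpha Family significance level (default 0.05).
#' @return Data frame of tested loci with `p_value`, `p_bonferroni`,
#'   `significant`.
#' @export
size_anova <- function(occurrence, meta, min_samples = 10, alpha = 0.05) {
  stopifnot(inherits(occurrence, "occurrence_matrix"))
  sz <- occurrence$sizes
  sp <- meta$super_population[match(rownames(sz), meta$sample_id)]
  testable <- which(colSums(!is.na(sz)) >= min_samples)
  rows <- list()
  for (k in testable) {
    y <- sz[, k]
    ok <- !is.na(y)
    g <- factor(sp[ok])
    if (nlevels(droplevels(g)) < 2) next
    if (all(stats::sd(y[ok]) < 1e-12)) {
      p <- 1
    } else {
      p <- stats::anova(stats::lm(y[ok] ~ droplevels(g)))[["Pr(>F)"]][1]
      if (is.na(p)) p <- 1
    }
    rows[[length(rows) + 1L]] <- data.frame(locus = k, p_value = p)
  }
  if (length(rows) == 0)
    return(data.frame(locus = integer(), p_value = numeric(),
                      p_bonferroni = numeric(), significant = logical()))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_value * nrow(out), 1)
  out$significant <- out$p_bonferroni < alpha
  out
}

#' Mendelian concordance of a trio's SV calls
#'
#' A child call is concordant when a same-type call matching under the
#' cross-sample merge rule exists in at least one parent.
#'
#' @param child,father,mother [sv_calls()] data frames.
#' @param merge_tol Reciprocal-overlap threshold (default 0.5).
#' @return List: `concordant_fraction` (NA when the child has no
#'   calls), `n_child`, `n_concordant`.
#' @export
trio_concordance <- function(child, father, mother, merge_tol = 0.5) {
  nc <- nrow(child)
  if (nc == 0)
    return(list(concordant_fraction = NA_real_, n_child = 0L,
                n_concordant = 0L))
  parents <- bind_sv_calls(list(father, mother))
  conc <- 0L
  if (nrow(parents) > 0) {
    for (i in seq_len(nc)) {
      joint <- rbind(as.data.frame(child[i, , drop = FALSE]),
                     as.data.frame(parents))
      hit <- FALSE
      for (j in 2:nrow(joint)) {
        if (calls_match(joint, 1L, j, merge_tol)) { hit <- TRUE; break }
      }
      conc <- conc + hit
    }
  }
  list(concordant_fraction = conc / nc, n_child = nc,
       n_concordant = as.integer(conc))
}
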