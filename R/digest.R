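#' In silico digestion of a reference sequence
#'
#' Optical maps are produced by fluorescently labelling DNA at the
#' recognition sites of a nicking endonuclease (Nt.BspQI, motif
#' 5'-GCTCTTC-3', by default). To align maps to a reference assembly the
#' same labelling is emulated in silico: every occurrence of the motif on
#' either strand becomes a label, and labels closer than the instrument's
#' optical resolution (450 bp) are merged into one label at the midpoint
#' of the run.
#'
#' @name insilico-digest
NULL

REV_BASE <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  out <- REV_BASE[chars]
  if (anyNA(out)) stop("sequence contains characters outside {A,C,G,T,N}")
  paste(out, collapse = "")
}

#' Scan a sequence for motif occurrences on both strands
#'
#' Returns the sorted union of start offsets (0-based) of exact matches of
#' `motif` and of its reverse complement. Matches never overlap an `N`
#' because matching is exact over `{A,C,G,T}`.
#'
#' @param sequence A nucleotide string over `{A,C,G,T,N}` (case
#'   insensitive).
#' @param motif Non-degenerate recognition motif (default `GCTCTTC`,
#'   Nt.BspQI).
#' @return Sorted numeric vector of 0-based match start offsets.
#' @export
scan_motif <- function(sequence, motif = "GCTCTTC") {
  sequence <- toupper(sequence)
  motif <- toupper(motif)
  if (!grepl("^[ACGT]+$", motif))
    stop("unsupported motif: only non-degenerate {A,C,G,T} motifs are handled")
  rc <- revcomp(motif)
  hit0 <- function(pat) {
    m <- gregexpr(pat, sequence, fixed = TRUE)[[1]]
    if (m[1] == -1) return(numeric())
    as.numeric(m) - 1
  }
  fwd <- hit0(motif)
  # fixed-string matching misses overlapping occurrences only for
  # self-overlapping motifs; rescan shifted starts to be safe
  rev_ <- hit0(rc)
  pos <- sort(unique(c(fwd, rev_, overlap_rescan(sequence, motif),
                       overlap_rescan(sequence, rc))))
  pos
}

# gregexpr(fixed = TRUE) skips matches that start inside a previous match;
# enumerate those explicitly for self-overlapping motifs.
overlap_rescan <- function(sequence, pat) {
  k <- nchar(pat)
  # self-overlap periods: shifts s where suffix == prefix
  shifts <- integer()
  for (s in seq_len(k - 1)) {
    if (substr(pat, s + 1, k) == substr(pat, 1, k - s)) shifts <- c(shifts, s)
  }
  if (length(shifts) == 0) return(numeric())
  base <- gregexpr(pat, sequence, fixed = TRUE)[[1]]
  if (base[1] == -1) return(numeric())
  found <- as.numeric(base) - 1
  extra <- numeric()
  repeat {
    cand <- sort(unique(unlist(lapply(shifts, function(s) found + s))))
    cand <- setdiff(cand, found)
    cand <- cand[cand + k <= nchar(sequence)]
    ok <- cand[vapply(cand, function(p)
      substr(sequence, p + 1, p + k) == pat, logical(1))]
    if (length(ok) == 0) break
    found <- sort(c(found, ok))
    extra <- c(extra, ok)
  }
  extra
}

#' Merge labels closer than the optical resolution
#'
#' Maximal runs of labels in which every consecutive gap is at most
#' `resolution` bp are collapsed to a single label at the midpoint of the
#' run's first and last member. All gaps in the output exceed
#' `resolution`.
#'
#' @param positions Sorted numeric vector of label positions (bp).
#' @param resolution Merge radius in bp (default 450).
#' @return Sorted numeric vector of merged positions.
#' @export
merge_labels <- function(positions, resolution = 450) {
  n <- length(positions)
  if (n <= 1) return(as.numeric(positions))
  if (is.unsorted(positions)) stop("positions must be sorted")
  gaps <- diff(positions)
  chain <- cumsum(c(0L, as.integer(gaps > resolution)))
  first <- tapply(positions, chain, function(x) x[1])
  last <- tapply(positions, chain, function(x) x[length(x)])
  as.numeric((first + last) / 2)
}

#' Digest reference sequences into label maps
#'
#' @param sequences Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param motif Nicking motif (default `GCTCTTC`).
#' @param resolution Label-merge radius in bp (default 450).
#' @return A `reference_digest`: list with `maps` (named list of reference
#'   [label_map()]s), `n_gaps` (named list of data frames with 0-based
#'   half-open `start`/`end` of N runs), `motif` and `resolution`.
#' @export
digest_reference <- function(sequences, motif = "GCTCTTC", resolution = 450) {
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by chromosome")
  maps <- list()
  n_gaps <- list()
  for (chrom in names(sequences)) {
    s <- toupper(sequences[[chrom]])
    pos <- merge_labels(scan_motif(s, motif), resolution)
    maps[[chrom]] <- label_map(chrom, pos, nchar(s), kind = "reference")
    n_gaps[[chrom]] <- find_n_runs(s)
  }
  structure(list(maps = maps, n_gaps = n_gaps, motif = motif,
                 resolution = resolution),
            class = "reference_digest")
}

#' Build a reference digest directly from label positions
#'
#' Used when the reference is available as a pre-digested label map
#' (e.g. read from a CMAP file) rather than as sequence.
#'
#' @param maps Named list of reference [label_map()]s.
#' @param n_gaps Optional named list of data frames (`start`, `end`).
#' @param motif,resolution Digest metadata.
#' @return A `reference_digest`.
#' @export
reference_digest_from_maps <- function(maps, n_gaps = NULL,
                                       motif = "GCTCTTC", resolution = 450) {
  if (is.null(names(maps))) names(maps) <- vapply(maps, `[[`, "", "map_id")
  if (is.null(n_gaps))
    n_gaps <- lapply(maps, function(m)
      data.frame(start = numeric(), end = numeric()))
  structure(list(maps = maps, n_gaps = n_gaps, motif = motif,
                 resolution = resolution),
            class = "reference_digest")
}

#' @export
print.reference_digest <- function(x, ...) {
  cat(sprintf("<reference_digest: %d chromosome(s), motif %s, res %g bp>\n",
              length(x$maps), x$motif, x$resolution))
  invisible(x)
}

find_n_runs <- function(s) {
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1) return(data.frame(start = numeric(), end = numeric()))
  start <- as.numeric(m) - 1
  data.frame(start = start,
             end = start + as.numeric(attr(m, "match.length")))
}

#' Find mapping-inaccessible reference regions
#'
#' Two classes of region cannot be interrogated by nick-label mapping:
#' long assembly N-gaps (no in silico label information at all) and long
#' stretches devoid of the nicking motif (featureless molecules that
#' cannot be anchored). Overlapping reasons are reported separately.
#'
#' @param digest A `reference_digest`.
#' @param gap_min Minimum N-gap length to report (default 50 kb).
#' @param desert_min Minimum label-free stretch to report (default 100 kb).
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `reason` (`sequence_gap_ge_50kb` or `label_desert_ge_100kb`).
#' @export
find_inaccessible <- function(digest, gap_min = 50000, desert_min = 100000) {
  out <- list()
  for (chrom in names(digest$maps)) {
    map <- digest$maps[[chrom]]
    g <- digest$n_gaps[[chrom]]
    if (!is.null(g) && nrow(g) > 0) {
      big <- g[g$end - g$start >= gap_min, , drop = FALSE]
      if (nrow(big) > 0)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = big$start, end = big$end,
          reason = "sequence_gap_ge_50kb")
    }
    bounds <- c(0, map$positions, map$length_bp)
    ds <- bounds[-length(bounds)]
    de <- bounds[-1]
    keep <- (de - ds) >= desert_min
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = ds[keep], end = de[keep],
        reason = "label_desert_ge_100kb")
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), reason = character()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
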