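#' Construct a label map
#'
#' A label map is the fundamental object of optical genome mapping: an
#' ordered set of fluorescent-label positions (in bp, 0-based offsets from
#' the start of the DNA piece) on a named molecule, contig, or reference
#' chromosome, together with the total length of that piece.
#'
#' @param map_id Character scalar naming the map (chromosome, molecule or
#'   contig identifier).
#' @param positions Numeric vector of strictly increasing label positions in
#'   bp, each in `[0, length_bp)`. May be empty.
#' @param length_bp Total map length in bp (positive).
#' @param kind One of `"reference"`, `"molecule"`, `"contig"`.
#' @param sample_id Optional sample identifier.
#' @return An object of class `label_map`.
#' @export
label_map <- function(map_id, positions, length_bp,
                      kind = c("molecule", "reference", "contig"),
                      sample_id = NULL) {
  kind <- match.arg(kind)
  positions <- as.numeric(positions)
  length_bp <- as.numeric(length_bp)
  if (length(length_bp) != 1L || !is.finite(length_bp) || length_bp <= 0)
    stop("length_bp must be a single positive number")
  if (length(positions) > 0) {
    if (anyNA(positions)) stop("positions contain NA")
    if (is.unsorted(positions, strictly = TRUE))
      stop("positions must be strictly increasing (map '", map_id, "')")
    if (positions[1] < 0 || positions[length(positions)] >= length_bp)
      stop("positions must lie in [0, length_bp) (map '", map_id, "')")
  }
  structure(
    list(map_id = as.character(map_id), kind = kind,
         length_bp = length_bp, positions = positions,
         sample_id = if (is.null(sample_id)) NA_character_ else as.character(sample_id)),
    class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map %s [%s] %d labels / %.0f bp>\n",
              x$map_id, x$kind, length(x$positions), x$length_bp))
  invisible(x)
}

#' Number of labels on a map
#' @param x A `label_map`.
#' @return Integer label count.
#' @export
n_labels <- function(x) length(x$positions)

sv_types <- c("insertion", "deletion", "inversion", "duplication",
              "intra_translocation", "inter_translocation", "multi_indel")
zygosities <- c("hom", "het", "tri", "unknown")
sv_modules <- c("MR", "CR", "MCR", "complex")

#' Construct a table of structural-variant calls
#'
#' SV calls are kept in an ordinary data frame (class `sv_calls`) with one
#' row per call. Coordinates are 0-based half-open on the reference;
#' `size_delta_bp` is signed (insertions positive, deletions negative).
#'
#' @param chrom Character vector of reference map names.
#' @param start_bp,end_bp Numeric, 0-based half-open reference interval.
#' @param sv_type Character, one of insertion, deletion, inversion,
#'   duplication, intra_translocation, inter_translocation, multi_indel.
#' @param size_delta_bp Signed size change in bp.
#' @param zygosity One of hom, het, tri, unknown.
#' @param support Integer count of supporting molecules/maps.
#' @param score Numeric calling score (log10 likelihood ratio for indel
#'   modules, `S_s - S_r` for the complex module).
#' @param module Calling module: MR, CR, MCR or complex.
#' @param sample_id Optional sample identifier (recycled).
#' @return A data frame of class `sv_calls`.
#' @export
sv_calls <- function(chrom = character(), start_bp = numeric(),
                     end_bp = numeric(), sv_type = character(),
                     size_delta_bp = numeric(), zygosity = character(),
                     support = integer(), score = numeric(),
                     module = character(), sample_id = NA_character_) {
  df <- data.frame(chrom = as.character(chrom),
                   start_bp = as.numeric(start_bp),
                   end_bp = as.numeric(end_bp),
                   sv_type = as.character(sv_type),
                   size_delta_bp = as.numeric(size_delta_bp),
                   zygosity = as.character(zygosity),
                   support = as.integer(support),
                   score = as.numeric(score),
                   module = as.character(module),
                   sample_id = rep_len(as.character(sample_id),
                                       length(chrom)),
                   stringsAsFactors = FALSE)
  validate_sv_calls(df)
  class(df) <- c("sv_calls", "data.frame")
  df
}

validate_sv_calls <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (!all(df$sv_type %in% sv_types))
    stop("unknown sv_type: ", paste(setdiff(df$sv_type, sv_types), collapse = ", "))
  if (!all(df$zygosity %in% zygosities))
    stop("unknown zygosity: ", paste(setdiff(df$zygosity, zygosities), collapse = ", "))
  mods <- unlist(strsplit(df$module, ",", fixed = TRUE))
  if (!all(mods %in% sv_modules))
    stop("unknown module: ", paste(setdiff(mods, sv_modules), collapse = ", "))
  if (any(df$start_bp > df$end_bp)) stop("start_bp > end_bp in sv_calls")
  invisible(df)
}

as_sv_calls <- function(df) {
  cols <- c("chrom", "start_bp", "end_bp", "sv_type", "size_delta_bp",
            "zygosity", "support", "score", "module", "sample_id")
  if (nrow(df) == 0) return(sv_calls())
  if (!"sample_id" %in% names(df)) df$sample_id <- NA_character_
  df <- df[, cols]
  rownames(df) <- NULL
  validate_sv_calls(df)
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' Bind several sv_calls tables into one
#' @param ... `sv_calls` data frames (or a single list of them).
#' @return One `sv_calls` data frame.
#' @export
bind_sv_calls <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) && !is.data.frame(lst[[1]]))
    lst <- lst[[1]]
  lst <- lst[vapply(lst, nrow, 0L) > 0]
  if (length(lst) == 0) return(sv_calls())
  as_sv_calls(do.call(rbind, lapply(lst, as.data.frame)))
}

#' Construct an alignment object
#'
#' An orientation-aware correspondence between the label indices of a query
#' map and a reference map. `q_idx` and `r_idx` are parallel integer
#' vectors; `r_idx` is strictly increasing, `q_idx` strictly increasing for
#' `+` orientation and strictly decreasing for `-`.
#'
#' @param query_id,ref_id Map identifiers.
#' @param orientation `"+"` or `"-"`.
#' @param q_idx,r_idx Paired label indices (1-based into the maps'
#'   `positions`).
#' @param score Alignment score.
#' @param ref_start_bp,ref_end_bp Reference interval covered by the paired
#'   labels.
#' @param n_extra_query,n_missed_ref Unpaired interior label counts.
#' @param confidence Permutation-calibrated confidence (set by
#'   [confidence_score()]; `NA` until calibrated).
#' @return An object of class `om_alignment`.
#' @export
om_alignment <- function(query_id, ref_id, orientation, q_idx, r_idx,
                         score, ref_start_bp, ref_end_bp,
                         n_extra_query = 0L, n_missed_ref = 0L,
                         confidence = NA_real_) {
  stopifnot(length(q_idx) == length(r_idx), length(q_idx) >= 1,
            orientation %in% c("+", "-"))
  structure(
    list(query_id = query_id, ref_id = ref_id, orientation = orientation,
         q_idx = as.integer(q_idx), r_idx = as.integer(r_idx),
         score = score, confidence = confidence,
         ref_start_bp = ref_start_bp, ref_end_bp = ref_end_bp,
         n_matched = length(q_idx),
         n_extra_query = as.integer(n_extra_query),
         n_missed_ref = as.integer(n_missed_ref)),
    class = "om_alignment")
}

#' @export
print.om_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment %s -> %s (%s) %d pairs, score %.2f, conf %.2f, ref %.0f-%.0f>\n",
    x$query_id, x$ref_id, x$orientation, x$n_matched, x$score,
    x$confidence, x$ref_start_bp, x$ref_end_bp))
  invisible(x)
}

#' Construct a split alignment
#'
#' Different parts of one query map aligned to different reference
#' locations/orientations. Segments are ordered by query coordinate; the
#' junctions between consecutive segments are candidate SV breakpoints.
#'
#' @param query_id Query map identifier.
#' @param segments List of [om_alignment()] objects ordered by query
#'   coordinate.
#' @return An object of class `om_split_alignment`.
#' @export
om_split_alignment <- function(query_id, segments) {
  stopifnot(length(segments) >= 1)
  structure(list(query_id = query_id, segments = segments),
            class = "om_split_alignment")
}

#' @export
print.om_split_alignment <- function(x, ...) {
  cat(sprintf("<split alignment %s: %d segments>\n", x$query_id,
              length(x$segments)))
  for (s in x$segments) print(s)
  invisible(x)
}

is_split <- function(a) inherits(a, "om_split_alignment")
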