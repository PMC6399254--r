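#' File formats
#'
#' The toolkit reads and writes minimal documented subsets of the optical
#' mapping ecosystem's text formats. Internal coordinates are always
#' 0-based half-open bp; the CMAP/SMAP-style writers alone convert to the
#' ecosystem's 1-based positions.
#'
#' * BNX subset (single molecules): `#`-prefixed header lines, then per
#'   molecule a `0` line (`0 <id> <length> [<sample_id>]`) and a `1` line
#'   listing label positions in bp.
#' * CMAP subset (reference/contig maps): tab-separated columns CMapId,
#'   ContigLength, NumSites, SiteID, LabelChannel, Position; one channel-1
#'   row per label (1-based positions) plus the conventional terminal
#'   channel-0 row at the map length.
#' * XMAP subset (alignments): one row per alignment with a
#'   `(ref,qry)` site-index pair string.
#' * SMAP-like TSV (SV calls): one row per call, 1-based start.
#' * BED (regions, features, SV calls): 0-based half-open.
#'
#' Unknown header lines are ignored on read and not preserved.
#' @name nicksv-formats
NULL

#' Read label maps from a BNX- or CMAP-subset file
#'
#' @param path File path.
#' @param dialect `"bnx"` (molecules) or `"cmap"` (reference/contig maps).
#' @param kind Map kind to assign (`cmap` only; default `"reference"`).
#' @return List of [label_map()] objects.
#' @export
read_maps <- function(path, dialect = c("bnx", "cmap"),
                      kind = c("reference", "contig", "molecule")) {
  dialect <- match.arg(dialect)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "bnx") read_bnx_lines(lines, path) else
    read_cmap_lines(lines, path, kind)
}

read_bnx_lines <- function(lines, path) {
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  maps <- list()
  i <- 1
  while (i <= length(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (f[1] != "0")
      stop(sprintf("BNX parse error at line %d of %s: expected a '0' record",
                   ln, path))
    id <- f[2]
    len <- as.numeric(f[3])
    sample_id <- if (length(f) >= 4) f[4] else NULL
    if (i + 1 > length(body))
      stop(sprintf("BNX parse error at line %d of %s: missing '1' record",
                   ln, path))
    ln2 <- body[i + 1]
    g <- strsplit(lines[ln2], "\t", fixed = TRUE)[[1]]
    if (g[1] != "1")
      stop(sprintf("BNX parse error at line %d of %s: expected a '1' record",
                   ln2, path))
    pos <- as.numeric(g[-1])
    if (anyNA(pos))
      stop(sprintf("BNX parse error at line %d of %s: non-numeric position",
                   ln2, path))
    maps[[length(maps) + 1L]] <-
      label_map(id, pos, len, kind = "molecule", sample_id = sample_id)
    i <- i + 2
  }
  maps
}

read_cmap_lines <- function(lines, path, kind) {
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) return(list())
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6))
    stop(sprintf("CMAP parse error in %s: line with %d < 6 fields",
                 path, min(nf)))
  rec <- data.frame(id = vapply(f, `[[`, "", 1),
                    len = as.numeric(vapply(f, `[[`, "", 2)),
                    channel = as.integer(vapply(f, `[[`, "", 5)),
                    pos = as.numeric(vapply(f, `[[`, "", 6)))
  if (anyNA(rec$pos) || anyNA(rec$len))
    stop("CMAP parse error in ", path, ": non-numeric field")
  maps <- list()
  for (id in unique(rec$id)) {
    sub <- rec[rec$id == id, , drop = FALSE]
    pos <- sub$pos[sub$channel == 1] - 1  # 1-based on disk
    maps[[length(maps) + 1L]] <-
      label_map(id, sort(pos), sub$len[1], kind = kind)
  }
  maps
}

#' Write label maps to a BNX- or CMAP-subset file
#'
#' @param maps List of [label_map()]s.
#' @param path Output path.
#' @param dialect `"bnx"` or `"cmap"`.
#' @return `path`, invisibly.
#' @export
write_maps <- function(maps, path, dialect = c("bnx", "cmap")) {
  dialect <- match.arg(dialect)
  if (inherits(maps, "label_map")) maps <- list(maps)
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "bnx") {
    writeLines("# BNX subset written by nicksv", con)
    for (m in maps) {
      head <- c("0", m$map_id, format_bp(m$length_bp))
      if (!is.na(m$sample_id)) head <- c(head, m$sample_id)
      writeLines(paste(head, collapse = "\t"), con)
      writeLines(paste(c("1", format_bp(m$positions)), collapse = "\t"), con)
    }
  } else {
    writeLines(c("# CMAP subset written by nicksv",
                 "#h CMapId\tContigLength\tNumSites\tSiteID\tLabelChannel\tPosition"),
               con)
    for (m in maps) {
      n <- n_labels(m)
      if (n > 0)
        writeLines(sprintf("%s\t%s\t%d\t%d\t1\t%s", m$map_id,
                           format_bp(m$length_bp), n, seq_len(n),
                           format_bp(m$positions + 1)), con)
      writeLines(sprintf("%s\t%s\t%d\t%d\t0\t%s", m$map_id,
                         format_bp(m$length_bp), n, n + 1L,
                         format_bp(m$length_bp)), con)
    }
  }
  invisible(path)
}

format_bp <- function(x) formatC(x, format = "f", digits = 1)

#' Write SV calls to an SMAP-like TSV or BED file
#'
#' The SMAP-like dialect uses 1-based starts (ecosystem convention); BED
#' is 0-based half-open. Both carry every `sv_calls` column so that
#' [read_sv_calls()] round-trips all fields.
#'
#' @param calls An [sv_calls()] data frame.
#' @param path Output path.
#' @param dialect `"smap_like"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path, dialect = c("smap_like", "bed")) {
  dialect <- match.arg(dialect)
  validate_sv_calls(calls)
  df <- as.data.frame(calls)
  if (dialect == "smap_like") {
    out <- data.frame(chrom = df$chrom, start = df$start_bp + 1,
                      end = df$end_bp, type = df$sv_type,
                      size_delta = df$size_delta_bp, zygosity = df$zygosity,
                      support = df$support, score = df$score,
                      module = df$module, sample_id = df$sample_id)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    out <- data.frame(chrom = df$chrom, start = df$start_bp,
                      end = df$end_bp, name = df$sv_type,
                      score = df$score, strand = rep(".", nrow(df)),
                      size_delta = df$size_delta_bp, zygosity = df$zygosity,
                      support = df$support, module = df$module,
                      sample_id = df$sample_id)
    fields <- lapply(out, function(x)
      if (is.numeric(x) && !is.integer(x))
        formatC(x, format = "g", digits = 15) else as.character(x))
    body <- if (nrow(out) == 0) character() else
      do.call(paste, c(fields, sep = "\t"))
    writeLines(c(paste0("#chrom\tstart\tend\tname\tscore\tstrand\t",
                        "size_delta\tzygosity\tsupport\tmodule\tsample_id"),
                 body), path)
  }
  invisible(path)
}

#' Read SV calls written by [write_sv_calls()]
#'
#' @param path File path.
#' @param dialect `"smap_like"` or `"bed"`.
#' @return An [sv_calls()] data frame.
#' @export
read_sv_calls <- function(path, dialect = c("smap_like", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "smap_like") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c(chrom = "character",
                                           sample_id = "character"))
    if (nrow(df) == 0) return(sv_calls())
    sv_calls(chrom = df$chrom, start_bp = df$start - 1, end_bp = df$end,
             sv_type = df$type, size_delta_bp = df$size_delta,
             zygosity = df$zygosity, support = df$support,
             score = df$score, module = df$module,
             sample_id = df$sample_id)
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(lines) == 0) return(sv_calls())
    f <- strsplit(lines, "\t", fixed = TRUE)
    get <- function(i) vapply(f, `[[`, "", i)
    sv_calls(chrom = get(1), start_bp = as.numeric(get(2)),
             end_bp = as.numeric(get(3)), sv_type = get(4),
             score = as.numeric(get(5)),
             size_delta_bp = as.numeric(get(7)), zygosity = get(8),
             support = as.integer(get(9)), module = get(10),
             sample_id = get(11))
  }
}

#' Write alignments to an XMAP-subset file
#'
#' @param alignments List of [om_alignment()]s (split alignments are
#'   flattened to their segments).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xmap <- function(alignments, path) {
  alignments <- flatten_alignments(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# XMAP subset written by nicksv",
               paste0("#h XmapEntryID\tQryContigID\tRefContigID\t",
                      "RefStartPos\tRefEndPos\tOrientation\tScore\t",
                      "Confidence\tAlignment")), con)
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    pairs <- paste0(sprintf("(%d,%d)", a$r_idx, a$q_idx), collapse = "")
    writeLines(sprintf("%d\t%s\t%s\t%s\t%s\t%s\t%.4f\t%.4f\t%s",
                       i, a$query_id, a$ref_id,
                       format_bp(a$ref_start_bp + 1), format_bp(a$ref_end_bp),
                       a$orientation, a$score,
                       if (is.na(a$confidence)) 0 else a$confidence, pairs),
               con)
  }
  invisible(path)
}

flatten_alignments <- function(alignments) {
  out <- list()
  for (a in alignments) {
    if (is_split(a)) out <- c(out, a$segments) else
      out <- c(out, list(a))
  }
  out
}

#' Read cohort metadata from a TSV file
#'
#' Expected columns: `sample_id`, `population`, `super_population`
#' (AFR/AMR/EAS/EUR/SAS), `sex` (M/F).
#'
#' @param path File path.
#' @return Data frame of class `cohort_metadata`.
#' @export
read_cohort_metadata <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  cohort_metadata(df$sample_id, df$population, df$super_population, df$sex)
}

#' Construct cohort metadata
#' @param sample_id,population,super_population,sex Character vectors of
#'   equal length.
#' @return Data frame of class `cohort_metadata`.
#' @export
cohort_metadata <- function(sample_id, population, super_population,
                            sex = NA_character_) {
  if (anyDuplicated(sample_id)) stop("duplicated sample_id in metadata")
  df <- data.frame(sample_id = sample_id, population = population,
                   super_population = super_population,
                   sex = rep_len(sex, length(sample_id)),
                   stringsAsFactors = FALSE)
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Read a flat INI-style configuration file
#'
#' `key = value` lines grouped under `[section]` headers; values parsed as
#' numeric where possible. Returned as a nested named list.
#'
#' @param path File path.
#' @return Nested named list of settings.
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, ";")]
  cfg <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      if (!is.na(num)) val <- num
      if (is.null(section)) cfg[[key]] <- val else cfg[[section]][[key]] <- val
    }
  }
  cfg
}

#' Emit one structured log line for a pipeline stage
#'
#' Enabled by `options(nicksv.verbose = TRUE)`.
#'
#' @param stage Stage name.
#' @param ... Named values (counts, seeds) appended as `key=value`.
#' @return Invisibly, the formatted line.
#' @export
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("[nicksv] stage=", stage,
                if (length(kv))
                  paste0(" ", paste(names(kv), unlist(kv), sep = "=",
                                    collapse = " ")) else "")
  if (isTRUE(getOption("nicksv.verbose", FALSE))) message(msg)
  invisible(msg)
}
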