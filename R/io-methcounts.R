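#' Read a methcounts-style per-site count track
#'
#' Parses a tab-delimited track with six columns: chromosome, 0-based
#' position of the cytosine, strand (`+`/`-`), sequence context token
#' (e.g. `CpG`), methylation level (fraction of unconverted reads, in
#' `[0, 1]`) and read coverage.  Lines starting with `#` are comments.
#' Malformed lines raise an error naming the offending line number.
#'
#' @param path path to the track file.
#' @return A `data.frame` with columns `chrom`, `position`, `strand`,
#'   `context`, `level`, `coverage`, in file order.  An empty file gives
#'   a zero-row frame.
#' @seealso [joinTracks()], [MethCountSet()]
#' @export
readMethCounts <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  empty <- data.frame(chrom = character(), position = integer(),
                      strand = character(), context = character(),
                      level = numeric(), coverage = integer(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)

  flds <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(flds) != 6L)
  if (length(bad))
    stop(sprintf("%s, line %d: expected 6 tab-delimited columns, found %d",
                 path, keep[bad[1L]], lengths(flds)[bad[1L]]), call. = FALSE)
  f <- matrix(unlist(flds, use.names = FALSE), ncol = 6L, byrow = TRUE)

  fail <- function(test, msg) {
    i <- which(test)
    if (length(i))
      stop(sprintf("%s, line %d: %s", path, keep[i[1L]], msg),
           call. = FALSE)
  }
  position <- suppressWarnings(as.numeric(f[, 2L]))
  level <- suppressWarnings(as.numeric(f[, 5L]))
  coverage <- suppressWarnings(as.numeric(f[, 6L]))
  fail(is.na(position) | position < 0 | position != round(position),
       "position must be a non-negative integer")
  fail(!f[, 3L] %in% c("+", "-"), "strand must be '+' or '-'")
  fail(is.na(level), "level must be numeric")
  fail(level < 0 | level > 1, "level must be in [0, 1]")
  fail(is.na(coverage) | coverage < 0 | coverage != round(coverage),
       "coverage must be a non-negative integer")

  data.frame(chrom = f[, 1L], position = as.integer(position),
             strand = f[, 3L], context = f[, 4L],
             level = level, coverage = as.integer(coverage),
             stringsAsFactors = FALSE)
}

#' Convert a level/coverage pair to read counts
#'
#' The methcounts convention stores a fractional level and a coverage;
#' the unconverted-read count is recovered as `level * coverage` rounded
#' half away from zero, and the converted-read count as the remainder.
#' The rounding rule is part of the format contract.
#'
#' @param level numeric vector of levels in `[0, 1]`.
#' @param coverage integer vector of coverages.
#' @return A two-column integer matrix with columns `cReads`, `tReads`.
#' @examples
#' countsFromLevel(0.25, 2)   # 0.5 rounds away from zero: 1 C read, 1 T read
#' @export
countsFromLevel <- function(level, coverage) {
  c_reads <- as.integer(floor(level * coverage + 0.5))
  cbind(cReads = c_reads, tReads = as.integer(coverage) - c_reads)
}

.SITE_COLS <- c("chrom", "position", "strand", "context")

.siteKey <- function(d) paste(d$chrom, d$position, d$strand, sep = "\r")

.checkSorted <- function(d, name) {
  if (nrow(d) < 2L) return(invisible())
  o <- order(d$chrom, d$position, d$strand, method = "radix")
  if (any(o != seq_len(nrow(d)))) {
    i <- which(o != seq_len(nrow(d)))[1L]
    stop("track '", name, "' is not sorted by (chrom, position, strand) ",
         "near record ", i, "; sorted input is required for merge joining",
         call. = FALSE)
  }
}

#' Join per-experiment tracks site-by-site
#'
#' Combines two or three single-experiment tracks (as returned by
#' [readMethCounts()]) into one table with per-experiment level and
#' coverage columns.  In strict mode every track must list exactly the
#' same sites in the same order, and the first mismatch is an error
#' naming the record and both site identities.  In non-strict mode the
#' tracks are merge-joined on (chrom, position, strand); each must be
#' sorted on that key, and a site absent from a track gets coverage 0
#' there.
#'
#' @param tracks named list of track `data.frame`s; names must be
#'   experiment types (`"BS"`, `"OXBS"`, `"TAB"`), no duplicates.
#' @param strict logical; see Details.
#' @return A `data.frame` with the site-identity columns followed by
#'   `level.<TYPE>` and `coverage.<TYPE>` for each supplied experiment.
#' @export
joinTracks <- function(tracks, strict = TRUE) {
  if (is.null(names(tracks)) || !all(names(tracks) %in% EXPERIMENT_TYPES))
    stop("'tracks' must be a list named with experiment types (",
         paste(EXPERIMENT_TYPES, collapse = ", "), ")", call. = FALSE)
  if (anyDuplicated(names(tracks)))
    stop("duplicate experiment types in 'tracks'", call. = FALSE)
  if (length(tracks) < 2L)
    stop("at least two tracks are required", call. = FALSE)

  types <- names(tracks)
  if (strict) {
    ref <- tracks[[1L]]
    for (ty in types[-1L]) {
      d <- tracks[[ty]]
      if (nrow(d) != nrow(ref))
        stop(sprintf("track '%s' has %d records but track '%s' has %d",
                     ty, nrow(d), types[1L], nrow(ref)), call. = FALSE)
      diff <- which(d$chrom != ref$chrom | d$position != ref$position |
                      d$strand != ref$strand)
      if (length(diff)) {
        i <- diff[1L]
        stop(sprintf(
          "site mismatch between tracks '%s' and '%s' at record %d: %s:%d:%s vs %s:%d:%s",
          types[1L], ty, i,
          ref$chrom[i], ref$position[i], ref$strand[i],
          d$chrom[i], d$position[i], d$strand[i]), call. = FALSE)
      }
    }
    out <- ref[.SITE_COLS]
    keys <- .siteKey(ref)
  } else {
    for (ty in types) .checkSorted(tracks[[ty]], ty)
    all <- do.call(rbind, lapply(tracks, function(d) d[.SITE_COLS]))
    all <- all[!duplicated(.siteKey(all)), , drop = FALSE]
    o <- order(all$chrom, all$position, all$strand, method = "radix")
    out <- all[o, , drop = FALSE]
    rownames(out) <- NULL
    keys <- .siteKey(out)
  }
  for (ty in types) {
    d <- tracks[[ty]]
    idx <- match(keys, .siteKey(d))
    lv <- ifelse(is.na(idx), 0, d$level[idx])
    cv <- ifelse(is.na(idx), 0L, d$coverage[idx])
    out[[paste0("level.", ty)]] <- lv
    out[[paste0("coverage.", ty)]] <- cv
  }
  out
}

#' Write per-site estimates as a tab-delimited track
#'
#' Writes one line per site with columns chrom, position (0-based),
#' strand, context, p_m, p_h, p_u (fixed-point, 6 decimals) and the
#' confidence-interval conflict count.  Sites whose levels are not
#' identified (fewer than two covered experiments) carry `NA` in the
#' unidentified fields.  A `#`-prefixed header documents the column
#' order and package version.
#'
#' @param x a [MethCountSet-class] on which [estimateLevels()] has been
#'   run.
#' @param path output file path.
#' @return Invisibly, the number of data lines written.
#' @export
writeLevels <- function(x, path) {
  res <- levelResults(x)
  rr <- SummarizedExperiment::rowRanges(x)
  fmt <- function(p) ifelse(is.na(p), "NA", sprintf("%.6f", p))
  header <- paste0(
    "# jointMeth ", as.character(utils::packageVersion("jointMeth")),
    ": chrom position strand context p_m p_h p_u n_conflicts")
  ctx <- if (!is.null(res$context)) res$context
         else rep("CpG", length(rr))
  lines <- paste(as.character(GenomicRanges::seqnames(rr)),
                 GenomicRanges::start(rr) - 1L,
                 as.character(GenomicRanges::strand(rr)),
                 ctx,
                 fmt(res$pM), fmt(res$pH), fmt(res$pU),
                 ifelse(is.na(res$nConflicts), "NA", res$nConflicts),
                 sep = "\t")
  writeLines(c(header, lines), path)
  invisible(length(lines))
}
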