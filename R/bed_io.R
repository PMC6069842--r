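# BED / chrom.sizes I/O.
#
# Dialect: tab-separated, no header; "track", "browser" and "#" lines are
# skipped. BED3 = chrom/start/end; BED5 adds name (label, "." when absent)
# and score; BED6 adds strand. Coordinates are written verbatim (0-based
# half-open) and scores with full double precision so that a write/read
# round trip is lossless.

#' Read a BED file
#'
#' @param path path to a BED3/BED5/BED6 file.
#' @param has_score logical; parse column 5 as a numeric score.
#' @return A sorted [interval_set()]. An empty file yields an empty set.
#'   Malformed lines (fewer than 3 columns, non-numeric coordinates,
#'   `end <= start`) raise an error naming the offending line number.
#' @export
read_bed <- function(path, has_score = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(interval_set(sorted = TRUE))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop(sprintf("line %d: fewer than 3 tab-separated columns",
                 idx[which(ncol < 3L)[1]]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop(sprintf("line %d: non-integer coordinates", idx[bad[1]]),
         call. = FALSE)
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("line %d: invalid interval (end <= start or start < 0)",
                 idx[bad[1]]), call. = FALSE)
  }
  n <- length(idx)
  label <- rep(NA_character_, n)
  score <- rep(NA_real_, n)
  strand <- rep(".", n)
  has4 <- ncol >= 4L
  label[has4] <- vapply(fields[has4], `[[`, character(1), 4L)
  label[label == "."] <- NA_character_
  if (has_score) {
    has5 <- ncol >= 5L
    sc <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, character(1), 5L)))
    bad <- which(is.na(sc))
    if (length(bad)) {
      stop(sprintf("line %d: non-numeric score", idx[has5][bad[1]]),
           call. = FALSE)
    }
    score[has5] <- sc
  }
  has6 <- ncol >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, character(1), 6L)
  sort_intervals(interval_set(chrom, start, end, score = score,
                              strand = strand, label = label))
}

#' Write an interval set as BED
#'
#' Column count adapts to content: BED3 when no score/label/strand is
#' present, BED5 when any score or label is set (name column is the label or
#' `"."`), BED6 when any strand is set. Scores are written with 17
#' significant digits so [read_bed()] recovers them exactly.
#'
#' @param x an [interval_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  if (nrow(x) == 0L) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to ", path, call. = FALSE)
    return(invisible(path))
  }
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  want_strand <- any(x$strand != ".")
  want_score <- want_strand || !all(is.na(x$score)) || !all(is.na(x$label))
  if (want_score) {
    lab <- ifelse(is.na(x$label), ".", x$label)
    sc <- ifelse(is.na(x$score), ".", sprintf("%.17g", x$score))
    cols <- c(cols, list(lab, sc))
  }
  if (want_strand) cols <- c(cols, list(x$strand))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a UCSC-style chrom.sizes table
#'
#' @param path two-column tab-separated file: chromosome name, length (bp).
#' @return Named numeric vector of chromosome lengths, suitable for
#'   [genome_binning()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric"))
  if (any(tb[[2]] <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  stats::setNames(tb[[2]], tb[[1]])
}
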