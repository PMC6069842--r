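# BinnedTrack: one numeric value per genome bin (read counts, mean peak
# height), in bin order of a genome_binning. I/O as bedGraph and as a plain
# two-column TSV (bin index, value).

#' Construct a binned track
#'
#' @param binning a [genome_binning()].
#' @param values numeric vector, one value per bin in bin order.
#' @return A `binned_track`.
#' @export
binned_track <- function(binning, values) {
  stopifnot(inherits(binning, "genome_binning"))
  if (length(values) != total_bins(binning)) {
    stop(sprintf("values has length %d but the binning has %d bins",
                 length(values), total_bins(binning)), call. = FALSE)
  }
  structure(list(binning = binning, values = as.numeric(values)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> %d bins of %g bp; total %g\n",
              total_bins(x$binning), x$binning$bin_size, sum(x$values)))
  invisible(x)
}

same_binning <- function(a, b) {
  identical(a$bin_size, b$bin_size) &&
    identical(a$chrom_sizes, b$chrom_sizes)
}

#' Count fragments per genome bin
#'
#' Each fragment lands in exactly one bin, chosen by its start coordinate
#' (or its midpoint with `assign = "midpoint"`); bin boundaries are
#' half-open, so a fragment starting exactly at a boundary belongs to the
#' bin on the right. Column sums equal the fragment count.
#'
#' @param fragments data.frame with columns chrom, start, end (0-based
#'   half-open), e.g. from [simulate_fragments_with_duplicates()].
#' @param binning a [genome_binning()]; every fragment chromosome must be in
#'   it.
#' @param assign `"start"` (default) or `"midpoint"`.
#' @return A [binned_track()] of counts.
#' @export
bin_fragments <- function(fragments, binning, assign = c("start", "midpoint")) {
  assign <- match.arg(assign)
  stopifnot(is.data.frame(fragments), inherits(binning, "genome_binning"))
  nb <- total_bins(binning)
  if (nrow(fragments) == 0L) return(binned_track(binning, numeric(nb)))
  pos <- if (assign == "start") fragments$start
         else floor((fragments$start + fragments$end) / 2)
  idx <- bin_index(binning, fragments$chrom, pos)
  binned_track(binning, tabulate(idx, nbins = nb))
}

#' Write a binned track as bedGraph
#'
#' @param track a [binned_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  bins <- make_bins(track$binning)
  df <- data.frame(bins$chrom,
                   format(bins$start, scientific = FALSE, trim = TRUE),
                   format(bins$end, scientific = FALSE, trim = TRUE),
                   sprintf("%.17g", track$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph written over a known binning
#'
#' @param path bedGraph path (fixed-step bins matching `binning`).
#' @param binning the [genome_binning()] the file was written over.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path, binning) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  idx <- bin_index(binning, tb[[1]], tb[[2]])
  vals <- numeric(total_bins(binning))
  vals[idx] <- tb[[4]]
  binned_track(binning, vals)
}

#' Write / read a binned track as two-column TSV (bin index, value)
#'
#' @param track a [binned_track()].
#' @param path file path.
#' @return `path` (writer) or a numeric vector of values (reader; combine
#'   with a binning via [binned_track()]).
#' @export
write_track_tsv <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  utils::write.table(
    data.frame(bin = seq_along(track$values),
               value = sprintf("%.17g", track$values)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "numeric"))
  vals <- numeric(max(tb$bin))
  vals[tb$bin] <- tb$value
  vals
}
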