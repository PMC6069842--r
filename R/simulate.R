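# Seeded simulator of ground-truth footprinting worlds.
#
# A world is a small genome with open chromatin regions (OCRs), motif sites
# packed inside them, a known bound/unbound flag per site, ChIP peaks built
# by padding bound sites, two replicates of scored footprints (detection is
# Bernoulli with a sensitivity for bound sites and a false positive rate for
# unbound sites; scores for true footprints are shifted upward by
# score_separation), two replicates of per-bin read counts, and two
# replicates of PCR-duplicated fragment lists. One global seed drives
# everything; each sub-step uses a fixed-offset sub-stream so adding a step
# never perturbs the others.

#' Simulation parameters for a footprinting world
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length (bp); all chromosomes share it.
#' @param n_ocrs total number of open chromatin regions.
#' @param ocr_len_mean mean OCR length (bp); individual lengths vary
#'   uniformly within +/- 20%.
#' @param sites_per_ocr motif sites packed (non-overlapping) into each OCR.
#' @param n_tfs number of transcription factors; each site is assigned one
#'   uniformly at random.
#' @param bound_fraction probability that a site is truly bound. The default
#'   1/11 reproduces the roughly 10:1 negative:positive imbalance typical of
#'   genome-wide motif scans evaluated against ChIP.
#' @param footprint_sensitivity probability a bound site is covered by a
#'   footprint, independently per replicate.
#' @param footprint_fpr probability an unbound site is covered by a
#'   footprint, independently per replicate.
#' @param score_separation mean score gap between true and false
#'   footprints: true scores ~ Normal(mu + separation, 1), false scores
#'   ~ Normal(mu, 1), clipped at 0 (mu = 5).
#' @param depth fragments per replicate (before deduplication effects).
#' @param replicate_share weight in `[0, 1]` of the shared intensity
#'   component of the two replicates' bin counts; 1 gives identical
#'   expected tracks, 0 independent ones.
#' @param dup_geom_p PCR-duplication parameter: each unique parent fragment
#'   receives Geometric(`dup_geom_p`) copies (support 1, 2, ...); 1 means no
#'   duplication.
#' @param seed integer master seed.
#' @param chip_pad padding (bp) applied to each bound site before merging
#'   into ChIP peaks.
#' @param bin_size genome bin size (bp) for count tracks.
#' @param site_len motif site length (bp).
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_chroms = 2, chrom_len = 1e6, n_ocrs = 150,
                       ocr_len_mean = 1000, sites_per_ocr = 10, n_tfs = 15,
                       bound_fraction = 1 / 11,
                       footprint_sensitivity = 0.9, footprint_fpr = 0.05,
                       score_separation = 2, depth = 2e5,
                       replicate_share = 0.8, dup_geom_p = 0.8, seed = 1,
                       chip_pad = 100, bin_size = 10000, site_len = 15) {
  p <- list(n_chroms = n_chroms, chrom_len = chrom_len, n_ocrs = n_ocrs,
            ocr_len_mean = ocr_len_mean, sites_per_ocr = sites_per_ocr,
            n_tfs = n_tfs, bound_fraction = bound_fraction,
            footprint_sensitivity = footprint_sensitivity,
            footprint_fpr = footprint_fpr,
            score_separation = score_separation, depth = depth,
            replicate_share = replicate_share, dup_geom_p = dup_geom_p,
            seed = seed, chip_pad = chip_pad, bin_size = bin_size,
            site_len = site_len, score_null_mean = 5)
  counts <- c("n_chroms", "chrom_len", "n_ocrs", "ocr_len_mean",
              "sites_per_ocr", "n_tfs", "depth", "bin_size", "site_len")
  for (nm in counts) {
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  probs <- c("bound_fraction", "footprint_sensitivity", "footprint_fpr",
             "replicate_share")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", nm), call. = FALSE)
    }
  }
  if (p$bound_fraction <= 0 || p$bound_fraction >= 1) {
    stop("`bound_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (p$dup_geom_p <= 0 || p$dup_geom_p > 1) {
    stop("`dup_geom_p` must lie in (0, 1]", call. = FALSE)
  }
  if (p$score_separation < 0) {
    stop("`score_separation` must be >= 0", call. = FALSE)
  }
  if (p$n_chroms * p$chrom_len < 2 * p$n_ocrs * p$ocr_len_mean) {
    stop("genome too small: need n_chroms * chrom_len >= ",
         "2 * n_ocrs * ocr_len_mean", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

# sub-stream offsets, fixed per operation
.SIM_OFFSETS <- c(layout = 1, heights = 2, sites = 3, bound = 4,
                  footprints1 = 5, footprints2 = 6, counts = 7,
                  fragments1 = 8, fragments2 = 9)

#' Simulate a ground-truth footprinting world
#'
#' Deterministic given `params$seed`. Sites are non-overlapping within each
#' OCR; each is bound with probability `bound_fraction`; ChIP peaks are the
#' bound sites padded by `chip_pad` bp and merged per TF, so every bound
#' site lies inside a ChIP peak of its own TF; footprints coincide with
#' sites, lie inside OCRs by construction, and are detected independently
#' per replicate with the stated sensitivity / false positive rate.
#'
#' @param params a [sim_params()] object.
#' @return A `synthetic_truth` list with elements `params`, `binning`,
#'   `ocrs` (scored with peak heights), `sites` (an [interval_set()] with
#'   the TF in `label` and a logical `bound` column), `chip_peaks` (named
#'   list per TF), `footprints_rep1` / `footprints_rep2` (scored
#'   [interval_set()]s), `counts_rep1` / `counts_rep2`
#'   ([binned_track()]s) and `fragments_rep1` / `fragments_rep2`
#'   (data.frames of chrom, start, end, strand, parent).
#' @examples
#' w <- simulate_world(sim_params(n_ocrs = 20, depth = 1000, seed = 1))
#' w$ocrs
#' @export
simulate_world <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  chroms <- sprintf("chr%d", seq_len(p$n_chroms))
  sizes <- stats::setNames(rep(p$chrom_len, p$n_chroms), chroms)
  binning <- genome_binning(sizes, bin_size = p$bin_size)

  # --- OCR layout: one OCR per evenly spaced slot, random offset in slot
  n_per <- diff(floor(seq(0, p$n_ocrs, length.out = p$n_chroms + 1)))
  ocrs <- with_seed(sub_seed(p$seed, .SIM_OFFSETS[["layout"]]), {
    parts <- lapply(seq_len(p$n_chroms), function(ci) {
      k <- n_per[ci]
      if (k == 0L) return(NULL)
      len <- round(p$ocr_len_mean * stats::runif(k, 0.8, 1.2))
      slot <- p$chrom_len / k
      if (slot < max(len) + 1) {
        stop("infeasible packing: OCRs do not fit their chromosome",
             call. = FALSE)
      }
      off <- floor(stats::runif(k) * (slot - len))
      start <- (seq_len(k) - 1) * slot + off
      data.frame(chrom = chroms[ci], start = floor(start),
                 end = floor(start) + len, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  })
  heights <- with_seed(sub_seed(p$seed, .SIM_OFFSETS[["heights"]]),
                       stats::rgamma(nrow(ocrs), shape = 4, scale = 5))
  ocrs <- as_interval_set(
    data.frame(ocrs, score = heights, stringsAsFactors = FALSE))
  ocrs <- sort_intervals(ocrs)

  # --- motif sites: packed into per-OCR slots so they never overlap
  ocr_len <- ocrs$end - ocrs$start
  sub_len <- floor(ocr_len / p$sites_per_ocr)
  if (any(sub_len < p$site_len + 1)) {
    stop("infeasible packing: sites_per_ocr * site_len exceeds OCR length",
         call. = FALSE)
  }
  n_sites <- nrow(ocrs) * p$sites_per_ocr
  ocr_of_site <- rep(seq_len(nrow(ocrs)), each = p$sites_per_ocr)
  slot_of_site <- rep(seq_len(p$sites_per_ocr), times = nrow(ocrs))
  sites_df <- with_seed(sub_seed(p$seed, .SIM_OFFSETS[["sites"]]), {
    play <- sub_len[ocr_of_site] - p$site_len
    off <- floor(stats::runif(n_sites) * (play + 1))
    start <- ocrs$start[ocr_of_site] +
      (slot_of_site - 1) * sub_len[ocr_of_site] + off
    tf <- sprintf("TF%02d", sample.int(p$n_tfs, n_sites, replace = TRUE))
    data.frame(chrom = ocrs$chrom[ocr_of_site], start = start,
               end = start + p$site_len, label = tf,
               stringsAsFactors = FALSE)
  })
  bound <- with_seed(sub_seed(p$seed, .SIM_OFFSETS[["bound"]]),
                     stats::rbinom(n_sites, 1, p$bound_fraction) == 1)
  sites <- as_interval_set(
    data.frame(sites_df, bound = bound, stringsAsFactors = FALSE))
  sites <- sort_intervals(sites)

  # --- ChIP peaks: bound sites padded and merged, per TF. The padding is
  # trimmed wherever it would reach an unbound site of the same TF, so the
  # per-TF ChIP truth coincides exactly with the simulated bound flag.
  tfs <- sprintf("TF%02d", seq_len(p$n_tfs))
  chip_peaks <- stats::setNames(lapply(tfs, function(tf) {
    idx <- which(sites$label == tf & sites$bound)
    if (length(idx) == 0L) return(interval_set(sorted = TRUE))
    neg <- which(sites$label == tf & !sites$bound)
    parts <- lapply(unique(sites$chrom[idx]), function(ch) {
      ii <- idx[sites$chrom[idx] == ch]
      padded <- IRanges::reduce(IRanges::IRanges(
        start = pmax(0, sites$start[ii] - p$chip_pad) + 1,
        end = pmin(p$chrom_len, sites$end[ii] + p$chip_pad)))
      nn <- neg[sites$chrom[neg] == ch]
      if (length(nn)) {
        padded <- IRanges::setdiff(
          padded, IRanges::IRanges(start = sites$start[nn] + 1,
                                   end = sites$end[nn]))
      }
      data.frame(chrom = ch, start = IRanges::start(padded) - 1,
                 end = IRanges::end(padded), stringsAsFactors = FALSE)
    })
    sort_intervals(as_interval_set(do.call(rbind, parts)))
  }), tfs)

  sim_fp <- function(offset) {
    with_seed(sub_seed(p$seed, offset), {
      prob <- ifelse(sites$bound, p$footprint_sensitivity, p$footprint_fpr)
      det <- stats::rbinom(n_sites, 1, prob) == 1
      mu <- p$score_null_mean +
        ifelse(sites$bound[det], p$score_separation, 0)
      sc <- pmax(0, stats::rnorm(sum(det), mean = mu, sd = 1))
      fp <- interval_set(sites$chrom[det], sites$start[det], sites$end[det],
                         score = sc, label = sites$label[det])
      sort_intervals(fp)
    })
  }
  fp1 <- sim_fp(.SIM_OFFSETS[["footprints1"]])
  fp2 <- sim_fp(.SIM_OFFSETS[["footprints2"]])

  truth <- structure(
    list(params = p, binning = binning, ocrs = ocrs, sites = sites,
         chip_peaks = chip_peaks, footprints_rep1 = fp1,
         footprints_rep2 = fp2),
    class = "synthetic_truth")

  counts <- simulate_bin_counts(truth, depth = p$depth,
                                replicate_share = p$replicate_share,
                                seed = sub_seed(p$seed,
                                                .SIM_OFFSETS[["counts"]]))
  truth$counts_rep1 <- counts[[1]]
  truth$counts_rep2 <- counts[[2]]
  truth$fragments_rep1 <- simulate_fragments_with_duplicates(
    truth, depth = p$depth, dup_geom_p = p$dup_geom_p,
    seed = sub_seed(p$seed, .SIM_OFFSETS[["fragments1"]]))
  truth$fragments_rep2 <- simulate_fragments_with_duplicates(
    truth, depth = p$depth, dup_geom_p = p$dup_geom_p,
    seed = sub_seed(p$seed, .SIM_OFFSETS[["fragments2"]]))
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d OCRs, %d sites (%d bound), %d TFs, depth %g\n",
    nrow(x$ocrs), nrow(x$sites), sum(x$sites$bound), x$params$n_tfs,
    x$params$depth))
  invisible(x)
}

#' Simulate replicate-correlated per-bin read counts
#'
#' Per-bin intensities mix a shared component (a gamma draw whose mean is
#' 20-fold enriched in OCR-containing bins, giving both replicates the same
#' accessibility landscape) with a replicate-private component (a spatially
#' flat gamma draw): `lambda = share * shared + (1 - share) * private`, each
#' component normalised to sum 1 so the expected total equals `depth`.
#' Counts are Poisson. The empirical Pearson correlation of the two tracks
#' increases with `replicate_share`: 1 gives near-perfect correlation at
#' high depth, 0 gives independent tracks. (Keeping the private component
#' free of the OCR mask is what makes the zero-share limit genuinely
#' uncorrelated.)
#'
#' @param truth a `synthetic_truth` (only `binning` and `ocrs` are used).
#' @param depth expected total read count per replicate.
#' @param replicate_share shared-signal weight in `[0, 1]`.
#' @param seed integer seed.
#' @return List of two [binned_track()]s.
#' @export
simulate_bin_counts <- function(truth, depth, replicate_share, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  if (replicate_share < 0 || replicate_share > 1) {
    stop("`replicate_share` must lie in [0, 1]", call. = FALSE)
  }
  nb <- total_bins(truth$binning)
  bins <- make_bins(truth$binning)
  in_ocr <- logical(nb)
  hits <- intersect_intervals(bins, truth$ocrs)
  in_ocr[unique(hits$query)] <- TRUE
  with_seed(seed, {
    shared <- stats::rgamma(nb, shape = 2,
                            scale = ifelse(in_ocr, 10, 0.5))
    shared <- shared / sum(shared)
    tracks <- lapply(1:2, function(r) {
      private <- stats::rgamma(nb, shape = 2, scale = 0.5)
      private <- private / sum(private)
      lambda <- replicate_share * shared + (1 - replicate_share) * private
      binned_track(truth$binning, stats::rpois(nb, depth * lambda))
    })
    tracks
  })
}

#' Simulate PCR-duplicated fragments
#'
#' Unique parent fragments are drawn from an OCR-weighted position
#' distribution (`ocr_weight` of the mass inside OCRs, the rest uniform on
#' the genome); each parent is amplified to a Geometric(`dup_geom_p`) copy
#' number (support 1, 2, ...) — the single-parameter heavy-ish-tailed model
#' of stochastic PCR jackpotting — and the copy sequence is truncated so the
#' returned list holds exactly `depth` fragments. Duplicates share their
#' parent's (chrom, start, end, strand) verbatim; the `parent` column
#' annotates provenance so deduplication can be checked against truth.
#'
#' @param truth a `synthetic_truth` (uses `ocrs`, `binning`).
#' @param depth total fragments to emit.
#' @param dup_geom_p geometric parameter in (0, 1]; 1 means every fragment
#'   is unique.
#' @param seed integer seed.
#' @param ocr_weight probability a parent falls inside an OCR.
#' @param frag_len fragment length (bp).
#' @return data.frame with columns chrom, start, end, strand, parent.
#' @export
simulate_fragments_with_duplicates <- function(truth, depth, dup_geom_p,
                                               seed, ocr_weight = 0.9,
                                               frag_len = 50) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  if (dup_geom_p <= 0 || dup_geom_p > 1) {
    stop("`dup_geom_p` must lie in (0, 1]", call. = FALSE)
  }
  ocrs <- truth$ocrs
  sizes <- truth$binning$chrom_sizes
  with_seed(seed, {
    parents <- list()
    copies <- list()
    total <- 0
    while (total < depth) {
      k <- max(64L, ceiling((depth - total) * dup_geom_p * 1.1))
      in_ocr <- stats::runif(k) < ocr_weight
      # OCR parents: uniform position within a uniformly chosen OCR
      oi <- sample.int(nrow(ocrs), k, replace = TRUE)
      pos_ocr <- ocrs$start[oi] +
        floor(stats::runif(k) * pmax(1, ocrs$end[oi] - ocrs$start[oi] -
                                       frag_len))
      chrom_ocr <- ocrs$chrom[oi]
      # background parents: chromosome by length, uniform position
      ci <- sample.int(length(sizes), k, replace = TRUE,
                       prob = sizes / sum(sizes))
      pos_bg <- floor(stats::runif(k) * (sizes[ci] - frag_len))
      chrom <- ifelse(in_ocr, chrom_ocr, names(sizes)[ci])
      start <- ifelse(in_ocr, pos_ocr, pos_bg)
      strand <- ifelse(stats::runif(k) < 0.5, "+", "-")
      cp <- stats::rgeom(k, dup_geom_p) + 1
      parents[[length(parents) + 1L]] <-
        data.frame(chrom = chrom, start = start, end = start + frag_len,
                   strand = strand, stringsAsFactors = FALSE)
      copies[[length(copies) + 1L]] <- cp
      total <- total + sum(cp)
    }
    par <- do.call(rbind, parents)
    cp <- unlist(copies)
    cum <- cumsum(cp)
    n_par <- which(cum >= depth)[1]
    cp <- cp[seq_len(n_par)]
    cp[n_par] <- cp[n_par] - (cum[n_par] - depth)  # truncate the last parent
    par <- par[seq_len(n_par), , drop = FALSE]
    out <- par[rep(seq_len(n_par), cp), , drop = FALSE]
    out$parent <- rep(seq_len(n_par), cp)
    rownames(out) <- NULL
    out
  })
}

#' Remove PCR duplicates from a fragment list
#'
#' Keeps one representative (the first occurrence, so the operation is
#' order-stable and idempotent) per distinct (chrom, start, end, strand).
#'
#' @param fragments data.frame with columns chrom, start, end, strand.
#' @return The deduplicated data.frame.
#' @export
deduplicate_fragments <- function(fragments) {
  stopifnot(is.data.frame(fragments))
  if (nrow(fragments) == 0L) return(fragments)
  key <- paste(fragments$chrom, fragments$start, fragments$end,
               fragments$strand, sep = "\r")
  out <- fragments[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated world as standard files
#'
#' Emits OCRs, per-replicate footprints and motif sites as BED5 (name =
#' label, score column = height / footprint score / bound flag), ChIP peaks
#' as one BED5 with the TF in the name column, bin counts as bedGraph,
#' fragments as BED6, and a JSON manifest of the simulation parameters.
#'
#' @param truth a `synthetic_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(truth, dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  write_bed(truth$ocrs, path("ocrs.bed"))
  sites <- truth$sites
  sites$score <- as.numeric(sites$bound)
  write_bed(as_interval_set(as.data.frame(sites)), path("motif_sites.bed"))
  write_bed(truth$footprints_rep1, path("footprints_rep1.bed"))
  write_bed(truth$footprints_rep2, path("footprints_rep2.bed"))
  chip <- do.call(rbind, lapply(names(truth$chip_peaks), function(tf) {
    pk <- truth$chip_peaks[[tf]]
    if (nrow(pk) == 0L) return(NULL)
    data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
               score = NA_real_, strand = ".", label = tf,
               stringsAsFactors = FALSE)
  }))
  if (is.null(chip)) {
    chip <- interval_set()
  } else {
    chip <- sort_intervals(as_interval_set(chip))
  }
  write_bed(chip, path("chip_peaks.bed"))
  write_bedgraph(truth$counts_rep1, path("counts_rep1.bedgraph"))
  write_bedgraph(truth$counts_rep2, path("counts_rep2.bedgraph"))
  for (r in 1:2) {
    fr <- truth[[sprintf("fragments_rep%d", r)]]
    write_bed(interval_set(fr$chrom, fr$start, fr$end, strand = fr$strand),
              path(sprintf("fragments_rep%d.bed", r)))
  }
  jsonlite::write_json(unclass(truth$params),
                       path("sim_params.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
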