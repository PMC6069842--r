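# The simulator is the ground-truth source for every metric test, so its
# own contracts are checked first: determinism, the stated probability
# model, and the structural invariants (sites inside OCRs, bound sites
# inside ChIP peaks, footprints at sites).

small_params <- function(seed = 1, ...) {
  sim_params(n_chroms = 2, chrom_len = 2e5, n_ocrs = 40, ocr_len_mean = 500,
             sites_per_ocr = 5, depth = 5000, seed = seed, ...)
}

test_that("simulate_world is a pure function of its seed", {
  w1 <- simulate_world(small_params(seed = 3))
  w2 <- simulate_world(small_params(seed = 3))
  expect_identical(w1, w2)
  w3 <- simulate_world(small_params(seed = 4))
  expect_false(identical(w1$sites$start, w3$sites$start))
})

test_that("world structure honours its invariants", {
  w <- simulate_world(small_params(seed = 5))
  # sites lie inside OCRs and do not overlap each other
  hits <- intersect_intervals(w$sites, w$ocrs)
  full <- hits$overlap == (w$sites$end - w$sites$start)[hits$query]
  expect_equal(sort(unique(hits$query[full])), seq_len(nrow(w$sites)))
  self <- intersect_intervals(w$sites, w$sites)
  expect_equal(nrow(self), nrow(w$sites))  # only self-overlaps
  # every bound site lies inside a ChIP peak of its own TF
  for (tf in unique(w$sites$label)) {
    idx <- which(w$sites$label == tf & w$sites$bound)
    if (length(idx) == 0L) next
    sub <- as_interval_set(as.data.frame(w$sites)[idx, , drop = FALSE])
    h <- intersect_intervals(sub, w$chip_peaks[[tf]])
    cov <- h$overlap == (sub$end - sub$start)[h$query]
    expect_equal(sort(unique(h$query[cov])), seq_len(nrow(sub)))
  }
  # footprints coincide with motif sites, hence lie inside OCRs
  for (fp in list(w$footprints_rep1, w$footprints_rep2)) {
    h <- intersect_intervals(fp, w$ocrs)
    expect_equal(sort(unique(h$query)), seq_len(nrow(fp)))
  }
  # fragments per replicate equal the requested depth
  expect_equal(nrow(w$fragments_rep1), w$params$depth)
  expect_equal(nrow(w$fragments_rep2), w$params$depth)
})

test_that("bound-site count follows the binomial model", {
  w <- simulate_world(sim_params(n_ocrs = 110, sites_per_ocr = 10,
                                 bound_fraction = 1 / 11, depth = 1000,
                                 seed = 8))
  n <- nrow(w$sites)
  expect_equal(n, 1100L)
  bounds <- binom99(n, 1 / 11)
  expect_gte(sum(w$sites$bound), bounds[1])
  expect_lte(sum(w$sites$bound), bounds[2])
})

test_that("degenerate detection probabilities behave exactly", {
  w <- simulate_world(small_params(seed = 2, footprint_sensitivity = 1,
                                   footprint_fpr = 0))
  for (fp in list(w$footprints_rep1, w$footprints_rep2)) {
    key_fp <- paste(fp$chrom, fp$start)
    key_bound <- paste(w$sites$chrom, w$sites$start)[w$sites$bound]
    expect_setequal(key_fp, key_bound)
  }
})

test_that("bin counts are deterministic and track replicate_share limits", {
  w <- simulate_world(small_params(seed = 1))
  c1 <- simulate_bin_counts(w, depth = 1e5, replicate_share = 0.5, seed = 9)
  c2 <- simulate_bin_counts(w, depth = 1e5, replicate_share = 0.5, seed = 9)
  expect_identical(c1, c2)
  expect_error(simulate_bin_counts(w, 1e5, replicate_share = 1.5, seed = 1),
               "\\[0, 1\\]")

  # shared-intensity limit: near-perfect correlation at high depth
  cc <- simulate_bin_counts(w, depth = 1e6, replicate_share = 1, seed = 4)
  expect_gt(alignment_reproducibility(cc[[1]], cc[[2]]), 0.95)

  # independence limit: mean correlation over 50 seeds near zero
  rs <- vapply(1:50, function(s) {
    cc <- simulate_bin_counts(w, depth = 1e5, replicate_share = 0, seed = s)
    alignment_reproducibility(cc[[1]], cc[[2]])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("bin-count correlation increases with replicate_share", {
  w <- simulate_world(small_params(seed = 1))
  mean_r <- vapply(c(0, 0.5, 1), function(share) {
    mean(vapply(1:10, function(s) {
      cc <- simulate_bin_counts(w, depth = 1e5, replicate_share = share,
                                seed = s)
      alignment_reproducibility(cc[[1]], cc[[2]])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("PCR duplication follows the truncated-geometric model", {
  w <- simulate_world(small_params(seed = 1))
  # p = 1: geometric degenerates to one copy per parent
  fr <- simulate_fragments_with_duplicates(w, depth = 2000, dup_geom_p = 1,
                                           seed = 3)
  expect_equal(nrow(fr), 2000L)
  expect_equal(length(unique(fr$parent)), 2000L)

  # p = 0.5: unique-parent count within 99% bounds of the enumeration
  depth <- 10000
  fr <- simulate_fragments_with_duplicates(w, depth = depth,
                                           dup_geom_p = 0.5, seed = 6)
  expect_equal(nrow(fr), depth)
  oracle <- truncated_geometric_parents(depth, 0.5)
  n_par <- length(unique(fr$parent))
  expect_gt(n_par, oracle$mean - 2.576 * oracle$sd)
  expect_lt(n_par, oracle$mean + 2.576 * oracle$sd)

  # determinism
  fr2 <- simulate_fragments_with_duplicates(w, depth = depth,
                                            dup_geom_p = 0.5, seed = 6)
  expect_identical(fr, fr2)
})

test_that("deduplication keeps first occurrences and is idempotent", {
  fr <- data.frame(chrom = "chr1", start = c(100, 100, 100),
                   end = c(150, 150, 150), strand = c("+", "+", "-"),
                   stringsAsFactors = FALSE)
  dd <- deduplicate_fragments(fr)
  expect_equal(nrow(dd), 2L)  # strand distinguishes
  expect_equal(dd$strand, c("+", "-"))
  expect_identical(deduplicate_fragments(dd), dd)

  # simulator output deduplicates to exactly the unique-parent coordinates
  w <- simulate_world(small_params(seed = 1))
  fr <- simulate_fragments_with_duplicates(w, depth = 5000,
                                           dup_geom_p = 0.4, seed = 2)
  dd <- deduplicate_fragments(fr)
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  parents <- fr[!duplicated(fr$parent), , drop = FALSE]
  expect_setequal(key(dd), key(parents))
})

test_that("write_world emits a readable standard-file bundle", {
  w <- simulate_world(small_params(seed = 1))
  dir <- withr::local_tempdir()
  write_world(w, dir)
  ocrs <- read_bed(file.path(dir, "ocrs.bed"), has_score = TRUE)
  expect_equal(nrow(ocrs), nrow(w$ocrs))
  expect_equal(ocrs$score, w$ocrs$score)
  fp <- read_bed(file.path(dir, "footprints_rep1.bed"), has_score = TRUE)
  expect_equal(fp$score, w$footprints_rep1$score)
  counts <- read_bedgraph(file.path(dir, "counts_rep1.bedgraph"),
                          w$binning)
  expect_equal(counts$values, w$counts_rep1$values)
  manifest <- jsonlite::read_json(file.path(dir, "sim_params.json"))
  expect_equal(manifest$seed, w$params$seed)
})

test_that("infeasible parameters fail loudly", {
  expect_error(sim_params(n_ocrs = 1e5, chrom_len = 1e5), "genome too small")
  expect_error(sim_params(bound_fraction = 0), "\\(0, 1\\)")
  expect_error(sim_params(dup_geom_p = 0), "\\(0, 1\\]")
  expect_error(
    simulate_world(sim_params(n_chroms = 1, chrom_len = 1e6, n_ocrs = 100,
                              ocr_len_mean = 100, sites_per_ocr = 50)),
    "infeasible packing")
})
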