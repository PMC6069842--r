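test_that("label_sites applies per-TF truth with >= 1 bp overlap", {
  sites <- interval_set(c("chr1", "chr1"), c(100, 100), c(110, 110),
                        label = c("CTCF", "EBF1"))
  peaks <- list(CTCF = interval_set("chr1", 105, 400),
                EBF1 = interval_set())
  tab <- label_sites(sites, peaks)
  expect_equal(tab$chip_positive, c(TRUE, FALSE))  # cross-TF peak ignored
  # abutting peak does not label
  tab <- label_sites(interval_set("chr1", 100, 110, label = "CTCF"),
                     list(CTCF = interval_set("chr1", 110, 400)))
  expect_false(tab$chip_positive)
  # missing TF entry is an error distinct from an empty peak set
  expect_error(label_sites(sites, peaks["CTCF"]), "EBF1")
  expect_error(label_sites(interval_set("chr1", 1, 5), peaks),
               "TF identifier")
})

test_that("footprint scores attach by max over overlapping footprints", {
  tab <- label_sites(interval_set("chr1", 100, 110, label = "TF1"),
                     list(TF1 = interval_set("chr1", 100, 110)))
  fps <- interval_set(c("chr1", "chr1"), c(95, 105), c(105, 120),
                      score = c(4, 7))
  out <- assign_footprint_scores(tab, fps)
  expect_equal(out$footprint_score, 7)
  out <- assign_footprint_scores(tab, fps, combine = "mean")
  expect_equal(out$footprint_score, 5.5)
  # no overlapping footprint, or an abutting one -> score absent
  out <- assign_footprint_scores(tab, interval_set("chr1", 110, 130,
                                                   score = 9))
  expect_true(is.na(out$footprint_score))
  expect_error(assign_footprint_scores(tab, interval_set("chr1", 1, 5)),
               "score")
})

test_that("confusion_counts fills the four cells and sums to n", {
  tab <- site_table(chip_positive = c(TRUE, FALSE, TRUE, FALSE),
                    scores = c(5, 3, NA, NA))
  expect_equal(confusion_counts(tab), c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  tab <- site_table(rep(TRUE, 4), c(1, 2, 3, 4))
  expect_equal(unname(confusion_counts(tab)), c(4L, 0L, 0L, 0L))
})

test_that("confusion counts on simulated worlds match the (s, f) model", {
  w <- simulate_world(sim_params(n_ocrs = 100, sites_per_ocr = 10,
                                 footprint_sensitivity = 0.8,
                                 footprint_fpr = 0.1, depth = 1000,
                                 seed = 12))
  tab <- label_sites(w$sites, w$chip_peaks)
  tab <- assign_footprint_scores(tab, w$footprints_rep1)
  # padded ChIP peaks cover exactly the bound sites in this construction
  expect_equal(sum(tab$chip_positive), sum(w$sites$bound))
  cc <- confusion_counts(tab)
  P <- sum(tab$chip_positive); N <- nrow(tab) - P
  expect_true(cc["TP"] >= binom99(P, 0.8)[1] && cc["TP"] <= binom99(P, 0.8)[2])
  expect_true(cc["FP"] >= binom99(N, 0.1)[1] && cc["FP"] <= binom99(N, 0.1)[2])
  expect_equal(unname(cc["TP"] + cc["FN"]), P)
  expect_equal(unname(cc["FP"] + cc["TN"]), N)
})

test_that("rank_sites orders footprinted-first and is seed-reproducible", {
  tab <- site_table(chip_positive = c(TRUE, FALSE, TRUE, FALSE),
                    scores = c(5, 3, NA, NA))
  r <- rank_sites(tab, mode = "expected")
  expect_equal(r$footprint_score[1:2], c(5, 3))
  expect_true(all(is.na(r$footprint_score[3:4])))
  p1 <- rank_sites(tab, mode = "permutation", seed = 7)
  p2 <- rank_sites(tab, mode = "permutation", seed = 7)
  expect_identical(p1, p2)
  expect_error(rank_sites(tab, mode = "permutation"), "seed")
})

test_that("roc_auc reproduces the worked four-site example and edge cases", {
  tab <- site_table(chip_positive = c(TRUE, FALSE, TRUE, FALSE),
                    scores = c(5, 3, NA, NA))
  res <- roc_auc(tab, "TF1", mode = "expected")
  expect_equal(res$auc, 0.625)  # pairs: 1, 1, 0, 1/2 over 4
  expect_equal(res$n_pos, 2L)
  expect_equal(res$n_neg, 2L)
  expect_equal(res$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(res$curve[nrow(res$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(res$curve$fpr) >= 0) && all(diff(res$curve$tpr) >= 0))

  # perfect separation: footprinted positives above unfootprinted negatives
  tab <- site_table(c(TRUE, TRUE, FALSE, FALSE), c(2, 9, NA, NA))
  expect_equal(roc_auc(tab, "TF1")$auc, 1.0)
  # no footprints at all: one tied block
  tab <- site_table(c(TRUE, FALSE, TRUE), c(NA, NA, NA))
  expect_equal(roc_auc(tab, "TF1")$auc, 0.5)
  # undefined without both classes
  tab <- site_table(c(TRUE, TRUE), c(1, 2))
  expect_error(roc_auc(tab, "TF1"), "TF1")
})

test_that("roc_auc equals the all-pairs oracle and its invariances hold", {
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    pos <- runif(n) < 0.3
    if (!any(pos) || all(pos)) next
    scores <- ifelse(runif(n) < 0.6, round(rnorm(n, 5), 1), NA)
    tab <- site_table(pos, scores)
    auc <- roc_auc(tab, "TF1")$auc
    expect_equal(auc, brute_pair_auc(scores, pos), tolerance = 1e-12)
    # strictly monotone transform of scores leaves the AUC unchanged
    tab2 <- site_table(pos, exp(scores / 2))
    expect_equal(roc_auc(tab2, "TF1")$auc, auc, tolerance = 1e-12)
    # label swap maps AUC to 1 - AUC
    tab3 <- site_table(!pos, scores)
    expect_equal(roc_auc(tab3, "TF1")$auc, 1 - auc, tolerance = 1e-12)
  }
})

test_that("expected mode equals the exhaustive mean over unfootprinted orders", {
  pos <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  scores <- c(5, 5, NA, NA, 2, NA)
  tab <- site_table(pos, scores)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  all_aucs <- vapply(perms(1:3), function(ord)
    auc_given_missing_order(scores, pos, ord), numeric(1))
  expect_equal(roc_auc(tab, "TF1", mode = "expected")$auc, mean(all_aucs),
               tolerance = 1e-12)
})

test_that("score model yields the closed-form AUC among footprinted sites", {
  # with sensitivity and fpr both 1, every site is footprinted and the AUC
  # is the probability a Normal(mu + sep, 1) draw beats a Normal(mu, 1)
  # draw: Phi(sep / sqrt(2))
  sep <- 1
  w <- simulate_world(sim_params(n_ocrs = 1000, sites_per_ocr = 10,
                                 n_chroms = 4, chrom_len = 1e6,
                                 footprint_sensitivity = 1,
                                 footprint_fpr = 1, score_separation = sep,
                                 depth = 1000, seed = 17))
  tab <- label_sites(w$sites, w$chip_peaks)
  tab <- assign_footprint_scores(tab, w$footprints_rep1)
  aucs <- vapply(sort(unique(tab$tf)), function(tf)
    roc_auc(tab, tf)$auc, numeric(1))
  expect_equal(mean(aucs), pnorm(sep / sqrt(2)), tolerance = 0.02)
})

test_that("mean_auc and improvement_over_random follow their definitions", {
  expect_equal(mean_auc(c(0.6, 0.8)), 0.7)
  r <- structure(list(tf = "A", auc = 0.66), class = "roc_result")
  expect_equal(mean_auc(list(r)), 0.66)
  expect_error(mean_auc(list()), "no AUC")
  expect_equal(improvement_over_random(0.7, 0.6), 100)
  expect_equal(improvement_over_random(0.6, 0.6), 0)
  expect_error(improvement_over_random(0.7, 0.5), "exceed 0.5")
})

test_that("AUC tables and summaries round-trip to disk", {
  tab <- site_table(chip_positive = c(TRUE, FALSE, TRUE, FALSE),
                    scores = c(5, 3, NA, NA))
  res <- list(roc_auc(tab, "TF1"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_auc_table(res, f)
  got <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(got$auc, 0.625)
  j <- withr::local_tempfile(fileext = ".json")
  write_auc_summary(res, j, provenance = list(motif_scan_p = 1e-4))
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$mean_auc, 0.625)
  expect_equal(parsed$provenance$motif_scan_p, 1e-4)
})
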