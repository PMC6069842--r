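test_that("pipeline_config enforces footprinter-conditional arguments", {
  cfg <- pipeline_config(footprinter = "hint", hint_bias_mode = "none")
  expect_s3_class(cfg, "pipeline_config")
  expect_null(cfg$wellington_p_cutoff)
  cfg <- pipeline_config(footprinter = "wellington",
                         wellington_p_cutoff = 0.01, wellington_fdr = 0.05)
  expect_null(cfg$hint_bias_mode)
  expect_error(pipeline_config(footprinter = "hint"), "hint_bias_mode")
  expect_error(pipeline_config(footprinter = "hint",
                               hint_bias_mode = "none",
                               wellington_fdr = 0.05), "Wellington")
  expect_error(pipeline_config(footprinter = "wellington",
                               wellington_p_cutoff = 0.01), "wellington_fdr")
  expect_error(pipeline_config(peak_size = 0, footprinter = "hint",
                               hint_bias_mode = "none"), "peak_size")
})

test_that("expand_grid_configs crosses conditional arguments within their footprinter", {
  # plain product when only one footprinter is involved
  cfgs <- expand_grid_configs(list(
    align_scope = c("global", "local"), bam_processor = c("plain", "dedup"),
    peak_size = c(60, 200, 500), footprinter = "hint",
    hint_bias_mode = "none"))
  expect_length(cfgs, 12L)
  # a single value per argument gives a single configuration
  expect_length(expand_grid_configs(list(footprinter = "hint",
                                         hint_bias_mode = "none")), 1L)
  # (3 HINT bias modes + 2 Wellington p-cutoffs) x 2 shared peak sizes
  cfgs <- expand_grid_configs(list(
    peak_size = c(200, 500), footprinter = c("hint", "wellington"),
    hint_bias_mode = c("none", "known-enzyme", "estimated"),
    wellington_p_cutoff = c(0.01, 0.001), wellington_fdr = 0.05))
  expect_length(cfgs, 10L)
  # no duplicates, deterministic order
  keys <- vapply(cfgs, function(c)
    paste(names(unclass(c)), unlist(unclass(c)), collapse = "|"),
    character(1))
  expect_equal(anyDuplicated(keys), 0L)
  cfgs2 <- expand_grid_configs(list(
    peak_size = c(200, 500), footprinter = c("hint", "wellington"),
    hint_bias_mode = c("none", "known-enzyme", "estimated"),
    wellington_p_cutoff = c(0.01, 0.001), wellington_fdr = 0.05))
  expect_identical(cfgs, cfgs2)
  expect_error(expand_grid_configs(list(peek_size = 1)), "peek_size")
  expect_error(expand_grid_configs(list(hint_bias_mode = "none")),
               "footprinter")
})

test_that("the shipped example grid expands through the YAML reader", {
  spec <- read_grid_spec(system.file("extdata", "grid_default.yaml",
                                     package = "footprintbench"))
  cfgs <- expand_grid_configs(spec)
  # closed form: shared 2*2*2*6*3, footprinter hint x3 + wellington x(2*2)
  expect_length(cfgs, 2 * 2 * 2 * 6 * 3 * (3 + 2 * 2))
})

test_that("evaluate_config is deterministic and in-range", {
  w <- simulate_world(sim_params(n_ocrs = 60, sites_per_ocr = 8,
                                 depth = 5000, dup_geom_p = 0.5, seed = 3))
  cfg <- pipeline_config(bam_processor = "dedup", peak_size = 500,
                         footprinter = "hint", hint_bias_mode = "none")
  g1 <- evaluate_config(cfg, w, seed = 11)
  g2 <- evaluate_config(cfg, w, seed = 11)
  expect_identical(g1, g2)
  for (g in list(g1)) {
    expect_true(g$alignment_r >= -1 && g$alignment_r <= 1)
    expect_true(g$ocr_r >= -1 && g$ocr_r <= 1)
    expect_true(g$mean_auc >= 0 && g$mean_auc <= 1)
    expect_true(is.na(g$footprint_overlap_at_1pct) ||
                  (g$footprint_overlap_at_1pct >= 0 &&
                     g$footprint_overlap_at_1pct <= 1))
  }
  # a config axis with no effects entry fails loudly
  expect_error(evaluate_config(cfg, w, effects = list(), seed = 1),
               "align_scope")
})

test_that("deduplication raises alignment reproducibility on duplicate-heavy worlds", {
  cfg_plain <- pipeline_config(bam_processor = "plain", peak_size = 2000,
                               footprinter = "hint", hint_bias_mode = "none")
  cfg_dedup <- pipeline_config(bam_processor = "dedup", peak_size = 2000,
                               footprinter = "hint", hint_bias_mode = "none")
  wins <- vapply(1:10, function(s) {
    w <- simulate_world(sim_params(n_ocrs = 60, sites_per_ocr = 5,
                                   depth = 10000, dup_geom_p = 0.3,
                                   seed = s))
    evaluate_config(cfg_dedup, w, seed = s)$alignment_r >
      evaluate_config(cfg_plain, w, seed = s)$alignment_r
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("select_optimal maximises its objective with a first-wins tie rule", {
  mk <- function(auc, ar, or) {
    structure(list(config = NULL, alignment_r = ar, ocr_r = or,
                   mean_auc = auc), class = "grid_result")
  }
  res <- list(mk(0.6, 0.9, 0.9), mk(0.7, 0.5, 0.5))
  expect_equal(select_optimal(res, "mean_auc")$mean_auc, 0.7)
  expect_equal(select_optimal(res, "reproducibility")$alignment_r, 0.9)
  tie <- list(mk(0.7, 0.5, 0.5), mk(0.7, 0.9, 0.9))
  expect_identical(select_optimal(tie, "mean_auc"), tie[[1]])
  expect_error(select_optimal(list(), "mean_auc"), "no results")
})

test_that("AUC- and reproducibility-optimal configs diverge under the core tradeoff", {
  # duplicate-heavy world; small scanning windows keep only the OCR core
  # (reproducible heights, but footprints outside the core are lost, which
  # costs AUC), while duplicate removal helps alignment reproducibility
  # without touching the AUC path
  w <- simulate_world(sim_params(n_ocrs = 80, sites_per_ocr = 8,
                                 depth = 10000, dup_geom_p = 0.3, seed = 5))
  space <- list(bam_processor = c("plain", "dedup"),
                peak_size = c(60, 2000),
                footprinter = "hint", hint_bias_mode = "none")
  results <- lapply(expand_grid_configs(space), evaluate_config, world = w,
                    seed = 5)
  best_auc <- select_optimal(results, "mean_auc")
  best_rep <- select_optimal(results, "reproducibility")
  expect_false(identical(best_auc$config, best_rep$config))
  expect_equal(best_auc$config$peak_size, 2000)
  expect_equal(best_rep$config$peak_size, 60)
})

test_that("summarize_grid emits long rows and per-argument 95% CIs", {
  w <- simulate_world(sim_params(n_ocrs = 40, sites_per_ocr = 8,
                                 depth = 3000, seed = 2))
  cfgs <- expand_grid_configs(list(bam_processor = c("plain", "dedup"),
                                   peak_size = c(500, 2000),
                                   footprinter = "hint",
                                   hint_bias_mode = "none"))
  results <- lapply(cfgs, evaluate_config, world = w, seed = 2)
  smry <- summarize_grid(results)
  expect_equal(nrow(smry$long), length(results) * 5L)  # 5 metrics
  # per-level means match a hand aggregation
  by_hand <- mean(vapply(results[vapply(results, function(r)
    r$config$bam_processor == "dedup", logical(1))],
    function(r) r$alignment_r, numeric(1)))
  row <- smry$by_argument[smry$by_argument$argument == "bam_processor" &
                            smry$by_argument$level == "dedup" &
                            smry$by_argument$metric == "alignment_r", ]
  expect_equal(row$mean, by_hand)
  expect_equal(row$n, 2L)
  expect_true(row$ci_lo <= row$mean && row$ci_hi >= row$mean)
  # a single-member group has no confidence interval
  single <- summarize_grid(results[1])
  expect_true(all(is.na(single$by_argument$ci_lo)))

  f <- withr::local_tempfile(fileext = ".tsv")
  j <- withr::local_tempfile(fileext = ".json")
  write_grid_results(results, tsv_path = f, json_path = j)
  expect_equal(nrow(read.table(f, sep = "\t", header = TRUE)),
               nrow(smry$long))
  expect_length(jsonlite::read_json(j), length(results))
})
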