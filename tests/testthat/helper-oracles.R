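# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately naive (O(n^2) scans, explicit pair
# counting, dynamic programming) so it cannot share a bug with the
# implementation it checks.

# All-pairs interval overlap scan: the brute-force counterpart of
# intersect_intervals().
brute_intersect <- function(a, b) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= 1) {
        rows[[length(rows) + 1L]] <- data.frame(query = i, subject = j,
                                                overlap = ov)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = numeric()))
  }
  out <- do.call(rbind, rows)
  out[order(out$query, out$subject), , drop = FALSE]
}

# Random interval set; caller controls the RNG with set.seed().
random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 10000, max_len = 500,
                             scored = FALSE, labelled = FALSE) {
  start <- floor(runif(n, 0, max_pos))
  len <- 1 + floor(runif(n, 0, max_len))
  interval_set(sample(chroms, n, replace = TRUE), start, start + len,
               score = if (scored) round(rnorm(n, 10, 3), 6) else NULL,
               label = if (labelled) sample(sprintf("TF%d", 1:3), n,
                                            replace = TRUE) else NULL)
}

# Mann-Whitney AUC by explicit pair counting. Missing scores form one tied
# block below every real score (the expected-mode semantics).
brute_pair_auc <- function(scores, positive) {
  v <- ifelse(is.na(scores), -Inf, scores)
  pos <- v[positive]
  neg <- v[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# AUC for one explicit strict ordering of the unfootprinted sites: the
# sites in `order_of_missing` (indices into the missing block) are placed
# below all scored sites in that order, with no ties.
auc_given_missing_order <- function(scores, positive, order_of_missing) {
  v <- scores
  miss <- which(is.na(v))
  floor_val <- if (length(miss) == length(v)) 0 else min(v, na.rm = TRUE) - 1
  v[miss[order_of_missing]] <- floor_val - seq_along(miss)
  brute_pair_auc(v, positive)
}

# Build a motif_site_table through the real labelling/scoring path:
# site i sits at chr1:[100 i, 100 i + 10); ChIP peaks cover the positive
# sites of each TF; footprints carry the requested scores (NA = no
# footprint at that site).
site_table <- function(chip_positive, scores, tf = NULL) {
  n <- length(chip_positive)
  stopifnot(length(scores) == n)
  if (is.null(tf)) tf <- rep("TF1", n)
  start <- 100 * seq_len(n)
  sites <- interval_set("chr1", start, start + 10, label = tf)
  peaks <- lapply(unique(tf), function(t) {
    idx <- which(tf == t & chip_positive)
    if (length(idx) == 0L) return(interval_set())
    interval_set("chr1", start[idx] - 5, start[idx] + 15)
  })
  names(peaks) <- unique(tf)
  tab <- label_sites(sites, peaks)
  has <- !is.na(scores)
  fp <- if (any(has)) {
    interval_set("chr1", start[has], start[has] + 10, score = scores[has])
  } else {
    interval_set()
  }
  # label_sites() sorts nothing (sites already in coordinate order), so row
  # i of the table is site i
  assign_footprint_scores(tab, fp)
}

# Expected number of unique parents when geometric copy numbers are
# truncated at a total of `depth` fragments: renewal-function dynamic
# programming over totals, plus the CLT standard deviation of the renewal
# count.
truncated_geometric_parents <- function(depth, p) {
  gmax <- ceiling(log(1e-14) / log(1 - p))
  q <- p * (1 - p)^(seq_len(gmax) - 1)
  u <- numeric(depth)        # u[t+1] = P(some partial sum equals t)
  u[1] <- 1
  for (t in seq_len(depth - 1)) {
    g <- seq_len(min(gmax, t))
    u[t + 1] <- sum(q[g] * u[t + 1 - g])
  }
  mu <- 1 / p
  s2 <- (1 - p) / p^2
  list(mean = sum(u), sd = sqrt(depth * s2 / mu^3))
}

# 99% binomial bounds for an observed count
binom99 <- function(n, prob) qbinom(c(0.005, 0.995), n, prob)
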