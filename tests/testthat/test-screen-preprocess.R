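test_that("background filter applies the strict 2-fold rule per channel", {
  tab <- random_raw_table(3)
  # 100 < 2*60: discarded
  tab[1, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(100, 60, 500, 100)
  # 120 is not < 120: kept (strict inequality at the boundary)
  tab[2, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(120, 60, 500, 100)
  tab[3, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(500, 100, 90, 60)
  out <- filter_background(tab, fold = 2)
  expect_setequal(out$hairpin_id, tab$hairpin_id[2])
  removed <- attr(out, "removed")
  expect_equal(sort(removed$hairpin_id), sort(tab$hairpin_id[c(1, 3)]))
  expect_equal(removed$reason[removed$hairpin_id == tab$hairpin_id[1]], "cy5")
  expect_equal(removed$reason[removed$hairpin_id == tab$hairpin_id[3]], "cy3")

  neg <- tab; neg$cy3_fg[1] <- -5
  expect_error(filter_background(neg), "negative")
})

test_that("background filter agrees with a per-row loop oracle and is monotone in fold", {
  tab <- random_raw_table(1000, seed = 21)
  for (fold in c(1.5, 2, 3)) {
    kept <- filter_background(tab, fold = fold)$hairpin_id
    oracle <- character()
    for (i in seq_len(nrow(tab))) {
      ok <- !(tab$cy3_fg[i] < fold * tab$cy3_bg[i]) &&
            !(tab$cy5_fg[i] < fold * tab$cy5_bg[i])
      if (ok) oracle <- c(oracle, tab$hairpin_id[i])
    }
    expect_identical(kept, oracle)
  }
  k1 <- filter_background(tab, fold = 1.5)$hairpin_id
  k2 <- filter_background(tab, fold = 2)$hairpin_id
  k3 <- filter_background(tab, fold = 3)$hairpin_id
  expect_true(all(k2 %in% k1) && all(k3 %in% k2))
})

test_that("log ratios follow the net-intensity formula, with missing where undefined", {
  tab <- random_raw_table(4)
  tab$replicate <- 1:4 %% 2 + 1
  tab$hairpin_id <- c("h1", "h1", "h2", "h2")
  tab$gene_id <- "g1"
  # identity and the 1000/500 hand case
  tab[1, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(600, 100, 600, 100)
  tab[2, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(1100, 100, 600, 100)
  # non-positive net: entry missing and counted, not an error
  tab[3, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(90, 100, 600, 100)
  tab[4, c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")] <- c(700, 100, 600, 100)
  rg <- compute_log_ratios(tab)
  expect_equal(rg$values["h1", "rep2"], 0)
  expect_equal(rg$values["h1", "rep1"], 1)   # log2(1000/500)
  expect_true(is.na(rg$values["h2", "rep2"]))
  expect_equal(rg$n_nonpositive, 1L)

  # random table equals the elementwise hand formula
  big <- random_raw_table(500, seed = 31)
  big$cy3_fg <- big$cy3_bg + runif(500, 1, 900)   # positive nets
  big$cy5_fg <- big$cy5_bg + runif(500, 1, 900)
  rg_big <- compute_log_ratios(big)
  manual <- log2((big$cy5_fg - big$cy5_bg) / (big$cy3_fg - big$cy3_bg))
  expect_equal(unname(rg_big$values[big$hairpin_id, "rep1"]), manual)

  # antisymmetry: swapping channels negates every finite entry
  swapped <- big
  swapped[c("cy3_fg", "cy3_bg", "cy5_fg", "cy5_bg")] <-
    big[c("cy5_fg", "cy5_bg", "cy3_fg", "cy3_bg")]
  expect_equal(compute_log_ratios(swapped)$values, -rg_big$values)
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  # hand-computed oracle: [1,3] and [2,6] -> both [1.5, 4.5] in rank order
  rg <- make_rg(cbind(rep1 = c(1, 3), rep2 = c(2, 6)))
  out <- quantile_normalize(rg)
  expect_equal(unname(out$values), cbind(c(1.5, 4.5), c(1.5, 4.5)))

  # identical columns are a fixed point
  same <- make_rg(cbind(rep1 = c(0.3, -1, 2), rep2 = c(0.3, -1, 2)))
  expect_equal(quantile_normalize(same)$values, same$values)

  # invariant + idempotence on random complete data, per pool group
  set.seed(41)
  vals <- matrix(rnorm(300), 100, 3,
                 dimnames = list(sprintf("hp%03d", 1:100), paste0("rep", 1:3)))
  rg2 <- make_rg(vals, pool = rep(1:2, each = 50))
  n1 <- quantile_normalize(rg2)
  for (p in 1:2) {
    sub <- n1$values[rg2$pool == p, ]
    expect_equal(sort(unname(sub[, 1])), sort(unname(sub[, 2])))
    expect_equal(sort(unname(sub[, 2])), sort(unname(sub[, 3])))
  }
  expect_equal(quantile_normalize(n1)$values, n1$values)
  # within-column ranks preserved inside each normalization group
  for (p in 1:2) {
    idx <- rg2$pool == p
    expect_equal(apply(n1$values[idx, ], 2, rank), apply(vals[idx, ], 2, rank))
  }
})

test_that("quantile normalization matches limma on complete data", {
  set.seed(42)
  vals <- matrix(rnorm(240), 80, 3,
                 dimnames = list(sprintf("hp%03d", 1:80), paste0("rep", 1:3)))
  ours <- quantile_normalize(make_rg(vals))$values
  ref <- limma::normalizeQuantiles(vals)
  expect_equal(unname(ours), unname(ref))
})

test_that("quantile normalization ranks among non-missing values only", {
  vals <- cbind(rep1 = c(1, 2, 3, 4), rep2 = c(10, NA, 30, 40))
  out <- quantile_normalize(make_rg(vals))
  expect_true(is.na(out$values[2, 2]))
  expect_equal(sum(is.na(out$values)), 1L)
  # non-missing entries of each column keep their within-column order
  expect_equal(order(out$values[, 1]), order(vals[, 1]))
  expect_equal(order(out$values[!is.na(vals[, 2]), 2]),
               order(vals[!is.na(vals[, 2]), 2]))

  # a column with < 2 non-missing values passes through with a warning
  sparse <- cbind(rep1 = c(1, 2, 3), rep2 = c(NA, NA, 5))
  expect_warning(out2 <- quantile_normalize(make_rg(sparse)), "passed through")
  expect_equal(out2$values[3, 2], 5)

  expect_error(quantile_normalize(make_rg(cbind(rep1 = 1:3))), ">= 2 replicate")
})

test_that("median centering shifts each pool group onto zero", {
  vals <- cbind(rep1 = c(1, 2, 3, 11, 12, 13), rep2 = c(2, 3, 4, 12, 13, 14))
  rg <- make_rg(vals, pool = rep(1:2, each = 3))
  out <- median_center(rg)
  expect_equal(median(out$values[1:3, ]), 0)
  expect_equal(median(out$values[4:6, ]), 0)
  # the shift is common to all columns: equal-multiset property survives
  qn <- quantile_normalize(rg)
  cen <- median_center(qn)
  expect_equal(sort(unname(cen$values[1:3, 1])), sort(unname(cen$values[1:3, 2])))
})

test_that("replicate QC reports correlations, range and discard fraction", {
  v <- cbind(rep1 = c(0.1, -0.5, 1.2, 0.8), rep2 = c(0.1, -0.5, 1.2, 0.8))
  qc <- replicate_qc(make_rg(v))
  expect_equal(qc$correlations$pearson, 1)
  neg <- cbind(rep1 = c(0.1, -0.5, 1.2), rep2 = -c(0.1, -0.5, 1.2))
  expect_equal(replicate_qc(make_rg(neg))$correlations$pearson, -1)

  # fewer than 3 jointly observed entries -> undefined correlation
  holey <- cbind(rep1 = c(1, 2, NA, NA), rep2 = c(1, NA, 3, 4))
  qc_h <- replicate_qc(make_rg(holey))
  expect_true(is.na(qc_h$correlations$pearson))
  expect_equal(qc_h$fraction_missing, 3 / 8)
  expect_equal(qc_h$rg_range, c(1, 4))
  expect_true(sum(qc_h$histogram$counts) == 5)
})

test_that("replicate correlation matches the analytic intraclass value on simulated data", {
  # hairpin-level effect spread sd 0.5, replicate noise sd 0.25:
  # expected Pearson r = 0.5^2 / (0.5^2 + 0.25^2) = 0.8
  lib <- make_library(800, c(1, 1), n_pools = 1, efficacy_range = c(1, 1), seed = 51)
  set.seed(52)
  genes <- unique(lib$gene_id)
  effects <- stats::setNames(rnorm(length(genes), 0, 0.5), genes)
  truth <- screen_truth(gene_effects = effects, baseline_stress_survival = 1,
                        noise_sd = 0.25)
  raw <- simulate_screen(lib, truth, 3, bg_meanlog = -Inf, amp_sdlog = 0, seed = 53)
  rg <- compute_log_ratios(raw)
  qc <- replicate_qc(rg)
  r <- qc$correlations$pearson
  # 3 SE of a correlation at n = 800 via Fisher z
  se_z <- 1 / sqrt(800 - 3)
  expect_true(all(abs(atanh(r) - atanh(0.8)) < 3 * se_z))
})

test_that("rg matrices round-trip through TSV", {
  lib <- make_library(6, c(2, 3), n_pools = 2, seed = 61)
  raw <- simulate_screen(lib, screen_truth(), 3, seed = 62)
  rg <- compute_log_ratios(filter_background(raw))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_rg_matrix(rg, p)
  back <- read_rg_matrix(p)
  expect_equal(back$values, rg$values, tolerance = 1e-12)
  expect_equal(back$gene_id, rg$gene_id)
  expect_equal(as.integer(back$pool), as.integer(rg$pool),
               ignore_attr = TRUE)
})
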