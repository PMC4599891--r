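test_that("make_library honors bounds, seed determinism and pool balance", {
  # forced bounds: one gene, exactly 3 hairpins, single pool
  lib <- make_library(1, c(3, 3), n_pools = 1, seed = 0)
  expect_equal(nrow(lib), 3L)
  expect_true(all(lib$pool_id == 1L))
  expect_equal(length(unique(lib$hairpin_id)), 3L)

  # identical seed -> identical library
  a <- make_library(100, c(2, 6), n_pools = 6, seed = 1)
  b <- make_library(100, c(2, 6), n_pools = 6, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_library(100, c(2, 6), n_pools = 6, seed = 2)))

  # structural invariants
  expect_true(all(lib$efficacy >= 0 & lib$efficacy <= 1))
  expect_true(all(table(a$gene_id) >= 2 & table(a$gene_id) <= 6))

  # random pool assignment stays near balanced: 500*4/6 per pool +/- 20%
  big <- make_library(500, c(4, 4), n_pools = 6, seed = 3)
  sizes <- as.integer(table(factor(big$pool_id, levels = 1:6)))
  expected <- 500 * 4 / 6
  expect_true(all(abs(sizes - expected) <= 0.2 * expected))

  expect_error(make_library(0, c(2, 2)), "n_genes")
  expect_error(make_library(5, c(3, 2)), "hairpins_per_gene")
})

test_that("simulate_screen reproduces clean signal exactly in noiseless limits", {
  lib <- make_library(5, c(2, 2), n_pools = 1, efficacy_range = c(1, 1), seed = 1)

  # identity case: no noise, no effects, full survival, zero background
  truth <- screen_truth(baseline_stress_survival = 1, noise_sd = 0)
  raw <- simulate_screen(lib, truth, 3, bg_meanlog = -Inf, amp_sdlog = 0, seed = 2)
  expect_equal(raw$cy5_fg, raw$cy3_fg)
  expect_true(all(raw$cy3_bg == 0 & raw$cy5_bg == 0))

  # planted effect +2 with efficacy 1: net ratio = 2^2 = 4 exactly
  truth2 <- screen_truth(gene_effects = c(gene_0001 = 2),
                         baseline_stress_survival = 1, noise_sd = 0)
  raw2 <- simulate_screen(lib, truth2, 1, bg_meanlog = -Inf, amp_sdlog = 0, seed = 3)
  hit_rows <- raw2$gene_id == "gene_0001" & raw2$cy3_fg > 0
  expect_equal(raw2$cy5_fg[hit_rows] / raw2$cy3_fg[hit_rows],
               rep(4, sum(hit_rows)))

  # conservation: one probe row per hairpin x replicate
  expect_equal(nrow(raw), nrow(lib) * 3L)
  expect_false(any(duplicated(raw[c("hairpin_id", "replicate")])))

  expect_error(simulate_screen(lib[0, ], truth, 3), "non-empty")
})

test_that("neutral-gene log ratios center on log2(survival) within Monte-Carlo error", {
  lib <- make_library(500, c(2, 2), n_pools = 1, seed = 10)
  truth <- screen_truth(baseline_stress_survival = 0.5, noise_sd = 0.25)
  raw <- simulate_screen(lib, truth, 3, bg_meanlog = -Inf, amp_sdlog = 0, seed = 11)
  lr <- log2((raw$cy5_fg - raw$cy5_bg) / (raw$cy3_fg - raw$cy3_bg))
  lr <- lr[is.finite(lr)]
  se <- sd(lr) / sqrt(length(lr))
  expect_lt(abs(mean(lr) - log2(0.5)), 3 * se)
})

test_that("expected hairpin ratio increases strictly with delta * efficacy", {
  effects <- c(gene_0001 = -2, gene_0002 = -0.5, gene_0003 = 0,
               gene_0004 = 0.8, gene_0005 = 2)
  lib <- make_library(5, c(3, 3), n_pools = 1, efficacy_range = c(1, 1), seed = 4)
  truth <- screen_truth(gene_effects = effects, baseline_stress_survival = 0.5,
                        noise_sd = 0)
  raw <- simulate_screen(lib, truth, 1, bg_meanlog = -Inf, amp_sdlog = 0, seed = 5)
  lr <- log2(raw$cy5_fg / raw$cy3_fg)
  mean_by_gene <- tapply(lr[is.finite(lr)], raw$gene_id[is.finite(lr)], mean)
  expect_true(all(diff(mean_by_gene[names(effects)]) > 0))
})

test_that("simulate_expression plants class differences as configured", {
  truth <- make_expression_truth(200, n_de = 20, overlap = 0.5, seed = 6)

  # noiseless: class-mean difference exactly +/- effect_size on DE genes, 0 elsewhere
  x <- simulate_expression(truth, 3, program = "a", effect_size = 1,
                           noise_sd = 0, seed = 7)
  labels <- attr(x, "class_labels")
  d <- rowMeans(x[, labels == 1L]) - rowMeans(x[, labels == 0L])
  de <- names(truth$program_a)
  expect_equal(unname(d[de]), unname(truth$program_a * 1))
  expect_equal(unname(d[setdiff(names(d), de)]),
               rep(0, length(d) - length(de)))

  # DE genes carry larger |t| than non-DE genes under noise
  xn <- simulate_expression(truth, 6, program = "a", effect_size = 1,
                            noise_sd = 0.5, seed = 8)
  lab <- attr(xn, "class_labels")
  tstat <- apply(xn, 1, function(v) t.test(v[lab == 1L], v[lab == 0L])$statistic)
  expect_gt(mean(abs(tstat[de])), mean(abs(tstat[setdiff(names(d), de)])))

  expect_error(simulate_expression(truth, 3, effect_size = -1), "effect_size")
  expect_error(simulate_expression(truth, 1), "samples_per_class")
})

test_that("expression truth programs share the configured gene overlap", {
  truth <- make_expression_truth(1000, n_de = 50, overlap = 0.6, seed = 9)
  shared <- intersect(names(truth$program_a), names(truth$program_b))
  expect_equal(length(shared), 30L)
  expect_equal(length(truth$program_a), 50L)
  expect_equal(length(truth$program_b), 50L)
  # shared genes keep the same direction in both programs
  expect_equal(truth$program_a[shared], truth$program_b[shared])
})

test_that("simulate_metabolites plants recoverable condition effects", {
  spec <- metabolite_panel_spec(
    metabolites = c("alpha-ketoglutarate" = 10, succinate = 5, lactate = 20),
    cell_lines = c("shScramble", "shACC1"),
    effects = data.frame(cell_line = "shACC1", metabolite = "alpha-ketoglutarate",
                         condition = "hypoxia", fold = 1.5),
    noise_sd = 0, protein_sd = 5
  )
  panel <- simulate_metabolites(spec, seed = 12)
  fc <- hypoxia_change(panel, mode = "fold")
  akg_kd <- fc[fc$cell_line == "shACC1" & fc$metabolite == "alpha-ketoglutarate", ]
  expect_equal(akg_kd$estimate, 1.5)
  # untouched combinations: all percent changes exactly 0
  pc <- hypoxia_change(panel, mode = "percent")
  untouched <- !(pc$cell_line == "shACC1" & pc$metabolite == "alpha-ketoglutarate")
  expect_equal(pc$estimate[untouched], rep(0, sum(untouched)))

  # with noise, recovered fold within 3 SE of planted
  spec_n <- metabolite_panel_spec(
    metabolites = c("alpha-ketoglutarate" = 10, succinate = 5),
    cell_lines = "shACC1", n_replicates = 30,
    effects = data.frame(cell_line = "shACC1", metabolite = "alpha-ketoglutarate",
                         condition = "hypoxia", fold = 1.5),
    noise_sd = 0.1
  )
  fc_n <- hypoxia_change(simulate_metabolites(spec_n, seed = 13), mode = "fold")
  akg <- fc_n[fc_n$metabolite == "alpha-ketoglutarate", ]
  expect_lt(abs(akg$estimate - 1.5), 3 * akg$sem)

  expect_error(metabolite_panel_spec(metabolites = c(succinate = 5)),
               "alpha-ketoglutarate")
})

test_that("generators are deterministic and leave the caller's RNG alone", {
  truth <- make_expression_truth(50, n_de = 5, seed = 1)
  expect_identical(simulate_expression(truth, 3, seed = 2),
                   simulate_expression(truth, 3, seed = 2))
  set.seed(42); before <- runif(1)
  set.seed(42); invisible(make_library(10, c(2, 3), seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("array tables and metabolite panels round-trip through text files", {
  lib <- make_library(4, c(2, 2), n_pools = 2, seed = 1)
  raw <- simulate_screen(lib, screen_truth(), 2, seed = 2)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_array_table(raw, p)
  back <- read_array_table(p, condition = "hypoxia")
  expect_equal(as.data.frame(back), as.data.frame(raw), tolerance = 1e-12,
               ignore_attr = TRUE)

  spec <- metabolite_panel_spec(metabolites = c("alpha-ketoglutarate" = 1,
                                                succinate = 2))
  panel <- simulate_metabolites(spec, seed = 3)
  pm <- withr::local_tempfile(fileext = ".csv")
  write_metabolite_csv(panel, pm)
  back_m <- read_metabolite_csv(pm)
  key <- function(d) with(d, order(cell_line, condition, replicate, metabolite))
  expect_equal(back_m[key(back_m), ]$raw_value, panel[key(panel), ]$raw_value,
               tolerance = 1e-12)
})
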