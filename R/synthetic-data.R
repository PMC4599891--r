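# Synthetic-data generators: shRNA library, pooled-screen arrays, two-class
# expression matrices, metabolite panels. Every generator is deterministic for
# a fixed seed and returns the ground truth it planted.

#' Construct an shRNA library with gene/hairpin/pool structure
#'
#' Builds the hairpin-to-gene map a pooled fitness screen is deconvolved
#' against. The genome-wide library is split into sub-pools, each hybridized
#' on its own array; per-hairpin knockdown efficacy (a fraction of the full
#' gene-level effect) is drawn so that multi-hairpin concordance is a
#' meaningful property downstream.
#'
#' @param n_genes number of genes.
#' @param hairpins_per_gene integer range `c(lo, hi)`; each gene's hairpin
#'   count is drawn uniformly from `lo:hi`.
#' @param n_pools number of sub-pools (default 6, one array each).
#' @param efficacy_range per-hairpin knockdown efficacy is drawn
#'   Uniform(`efficacy_range[1]`, `efficacy_range[2]`).
#' @param pool_assignment `"random"` assigns hairpins to pools uniformly at
#'   random; `"round_robin"` cycles pools deterministically.
#' @param seed RNG seed; identical inputs and seed give an identical library.
#' @return A data frame of class `shrna_library` with columns `hairpin_id`,
#'   `gene_id`, `pool_id`, `efficacy` and attribute `n_pools`.
#' @examples
#' lib <- make_library(n_genes = 10, hairpins_per_gene = c(3, 5), seed = 1)
#' table(lib$pool_id)
#' @export
make_library <- function(n_genes, hairpins_per_gene = c(2L, 6L), n_pools = 6L,
                         efficacy_range = c(0.5, 1.0),
                         pool_assignment = c("random", "round_robin"),
                         seed = NULL) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_pools, "n_pools")
  if (length(hairpins_per_gene) != 2L || any(hairpins_per_gene < 1) ||
      hairpins_per_gene[2] < hairpins_per_gene[1]) {
    stop("`hairpins_per_gene` must be c(lo, hi) with 1 <= lo <= hi", call. = FALSE)
  }
  if (any(efficacy_range < 0) || any(efficacy_range > 1)) {
    stop("`efficacy_range` must lie in [0, 1]", call. = FALSE)
  }
  pool_assignment <- match.arg(pool_assignment)

  with_seed(seed, {
    lo <- as.integer(hairpins_per_gene[1]); hi <- as.integer(hairpins_per_gene[2])
    counts <- if (lo == hi) rep(lo, n_genes) else sample(lo:hi, n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    gene_of <- rep(gene_id, counts)
    hairpin_id <- unlist(lapply(seq_len(n_genes), function(i) {
      sprintf("%s_sh%d", gene_id[i], seq_len(counts[i]))
    }), use.names = FALSE)
    n_hp <- length(hairpin_id)
    pool_id <- switch(pool_assignment,
      random      = sample.int(n_pools, n_hp, replace = TRUE),
      round_robin = rep_len(seq_len(n_pools), n_hp)
    )
    lib <- data.frame(
      hairpin_id = hairpin_id, gene_id = gene_of, pool_id = pool_id,
      efficacy = stats::runif(n_hp, efficacy_range[1], efficacy_range[2]),
      stringsAsFactors = FALSE
    )
    attr(lib, "n_pools") <- as.integer(n_pools)
    class(lib) <- c("shrna_library", "data.frame")
    lib
  })
}

#' Ground-truth fitness model for a simulated screen
#'
#' @param gene_effects named numeric vector of signed log2 fitness effects
#'   under stress (positive = knockdown protects, negative = knockdown is
#'   lethal). Genes not named are neutral (effect exactly 0).
#' @param baseline_stress_survival fraction of cells surviving the stress
#'   treatment for a neutral gene; the default 0.5 mirrors a treatment that
#'   roughly halves cell number.
#' @param representation expected cells per hairpin at library seeding
#'   (default 1000).
#' @param noise_sd replicate-level noise on the stress abundance, sd in log2
#'   units.
#' @return A list of class `screen_truth`.
#' @export
screen_truth <- function(gene_effects = numeric(), baseline_stress_survival = 0.5,
                         representation = 1000L, noise_sd = 0.25) {
  if (length(gene_effects) && is.null(names(gene_effects))) {
    stop("`gene_effects` must be a named vector (gene_id -> log2 effect)", call. = FALSE)
  }
  if (baseline_stress_survival <= 0 || baseline_stress_survival > 1) {
    stop("`baseline_stress_survival` must be in (0, 1]", call. = FALSE)
  }
  stopifnot_scalar_count(representation, "representation")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    gene_effects = gene_effects,
    baseline_stress_survival = baseline_stress_survival,
    representation = as.integer(representation),
    noise_sd = noise_sd
  ), class = "screen_truth")
}

#' Simulate a two-color pooled-screen array table
#'
#' Emulates the competitive-hybridization readout of a pooled shRNA fitness
#' screen. Per hairpin and replicate, an initial cell count is seeded
#' Poisson(`representation`); the stress-arm endpoint abundance is
#' `initial * survival * 2^(delta_g * efficacy_h + eps)` with replicate noise
#' `eps ~ N(0, noise_sd)` on the log2 scale. Control abundance labels Cy3,
#' stress abundance Cy5. A shared lognormal per-probe amplification factor
#' multiplies both channels (it cancels in the ratio, as when both samples go
#' through the same PCR); additive lognormal background is added per channel
#' and also reported as the background estimate.
#'
#' @param library an [make_library()] object.
#' @param truth a [screen_truth()] object.
#' @param n_replicates biological replicates (default 3).
#' @param condition label for the stress arm.
#' @param bg_meanlog,bg_sdlog lognormal background parameters (natural-log
#'   scale); `bg_meanlog = -Inf` gives zero background.
#' @param amp_sdlog sd (natural log) of the shared per-probe amplification
#'   factor.
#' @param gain intensity units per cell (default 1).
#' @param seed RNG seed.
#' @return A data frame of class `raw_array_table` with columns `probe_id`,
#'   `hairpin_id`, `gene_id`, `pool`, `replicate`, `cy3_fg`, `cy3_bg`,
#'   `cy5_fg`, `cy5_bg`, and attributes `condition` and `truth`.
#' @export
simulate_screen <- function(library, truth, n_replicates = 3L,
                            condition = "hypoxia",
                            bg_meanlog = log(50), bg_sdlog = 0.3,
                            amp_sdlog = 0.3, gain = 1, seed = NULL) {
  if (!inherits(library, "shrna_library") || nrow(library) == 0L) {
    stop("`library` must be a non-empty shrna_library", call. = FALSE)
  }
  if (!inherits(truth, "screen_truth")) stop("`truth` must be a screen_truth", call. = FALSE)
  stopifnot_scalar_count(n_replicates, "n_replicates")

  delta <- truth$gene_effects[library$gene_id]
  delta[is.na(delta)] <- 0
  per_hp_effect <- delta * library$efficacy   # log2 units, per hairpin

  with_seed(seed, {
    n_hp <- nrow(library)
    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      n0 <- stats::rpois(n_hp, truth$representation)
      eps <- if (truth$noise_sd > 0) stats::rnorm(n_hp, 0, truth$noise_sd) else 0
      ctrl_ab <- as.numeric(n0)
      strs_ab <- n0 * truth$baseline_stress_survival * 2^(per_hp_effect + eps)
      amp <- if (amp_sdlog > 0) stats::rlnorm(n_hp, 0, amp_sdlog) else 1
      bg3 <- if (is.finite(bg_meanlog)) stats::rlnorm(n_hp, bg_meanlog, bg_sdlog) else 0
      bg5 <- if (is.finite(bg_meanlog)) stats::rlnorm(n_hp, bg_meanlog, bg_sdlog) else 0
      rows[[r]] <- data.frame(
        probe_id = paste0("p_", library$hairpin_id),
        hairpin_id = library$hairpin_id,
        gene_id = library$gene_id,
        pool = library$pool_id,
        replicate = r,
        cy3_fg = gain * amp * ctrl_ab + bg3,
        cy3_bg = bg3,
        cy5_fg = gain * amp * strs_ab + bg5,
        cy5_bg = bg5,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    attr(tab, "condition") <- condition
    attr(tab, "truth") <- truth
    class(tab) <- c("raw_array_table", "data.frame")
    tab
  })
}

#' Write / read a raw array table as tab-delimited text
#'
#' One file per condition, header `probe_id hairpin_id gene_id pool replicate
#' cy3_fg cy3_bg cy5_fg cy5_bg`.
#' @param raw a `raw_array_table`.
#' @param path file path.
#' @export
write_array_table <- function(raw, path) {
  utils::write.table(as.data.frame(raw), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_array_table
#' @param condition condition label attached on read.
#' @export
read_array_table <- function(path, condition = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "hairpin_id", "gene_id", "pool", "replicate",
            "cy3_fg", "cy3_bg", "cy5_fg", "cy5_bg")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("array table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  attr(tab, "condition") <- condition
  class(tab) <- c("raw_array_table", "data.frame")
  tab
}

#' Ground truth for a two-class expression experiment
#'
#' Defines two knockdown gene programs (sets of differentially expressed
#' genes with signed directions) that share a configurable fraction of their
#' genes, plus the per-gene baseline log2 expression used by both the
#' training and cohort simulators so that profiles are projectable across
#' datasets.
#'
#' @param n_genes measured genes.
#' @param n_de differentially expressed genes per program.
#' @param overlap fraction of each program's DE genes shared with the other
#'   program (shared genes keep the same direction in both).
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression is
#'   drawn Normal(`baseline_mean`, `baseline_sd`).
#' @param seed RNG seed.
#' @return list of class `expression_truth` with `baseline` (named numeric),
#'   `program_a`, `program_b` (named sign vectors over DE genes), `overlap`.
#' @export
make_expression_truth <- function(n_genes, n_de = 50L, overlap = 0.6,
                                  baseline_mean = 7, baseline_sd = 1,
                                  seed = NULL) {
  stopifnot_scalar_count(n_genes, "n_genes")
  stopifnot_scalar_count(n_de, "n_de")
  if (overlap < 0 || overlap > 1) stop("`overlap` must be in [0, 1]", call. = FALSE)
  n_shared <- round(overlap * n_de)
  if (2L * n_de - n_shared > n_genes) {
    stop("not enough genes for two programs at this overlap", call. = FALSE)
  }
  with_seed(seed, {
    genes <- sprintf("g_%05d", seq_len(n_genes))
    baseline <- stats::setNames(stats::rnorm(n_genes, baseline_mean, baseline_sd), genes)
    pick <- sample(genes, 2L * n_de - n_shared)
    shared <- pick[seq_len(n_shared)]
    only_a <- pick[seq_len(n_de - n_shared) + n_shared]
    only_b <- pick[seq_len(n_de - n_shared) + (n_de - n_shared) + n_shared]
    sgn <- function(ids) stats::setNames(sample(c(-1, 1), length(ids), replace = TRUE), ids)
    s_shared <- sgn(shared)
    program_a <- c(s_shared, sgn(only_a))
    program_b <- c(s_shared, sgn(only_b))
    structure(list(baseline = baseline, program_a = program_a,
                   program_b = program_b, overlap = overlap),
              class = "expression_truth")
  })
}

#' Simulate a labeled two-class expression matrix
#'
#' Emulates a scramble-control vs knockdown experiment: train0 (scramble)
#' samples are baseline plus Gaussian noise; train1 (knockdown) samples
#' additionally shift each of the chosen program's DE genes by
#' `sign * effect_size` log2 units.
#'
#' @param truth an [make_expression_truth()] object.
#' @param samples_per_class samples per class (>= 2).
#' @param program `"a"` or `"b"` — which planted knockdown program train1
#'   expresses.
#' @param effect_size log2 shift magnitude (>= 0; direction is per gene in
#'   `truth`).
#' @param noise_sd Gaussian noise sd (log2 units).
#' @param seed RNG seed.
#' @param label_prefix prefix for sample names.
#' @return genes x samples numeric matrix with attribute `class_labels`
#'   (0 = train0/scramble, 1 = train1/knockdown, named by sample).
#' @export
simulate_expression <- function(truth, samples_per_class, program = c("a", "b"),
                                effect_size = 1, noise_sd = 0.5, seed = NULL,
                                label_prefix = NULL) {
  if (!inherits(truth, "expression_truth")) {
    stop("`truth` must come from make_expression_truth()", call. = FALSE)
  }
  stopifnot_scalar_count(samples_per_class, "samples_per_class", min = 2L)
  if (effect_size < 0) {
    stop("`effect_size` must be >= 0 (directions are encoded per gene in `truth`)",
         call. = FALSE)
  }
  program <- match.arg(program)
  prog <- if (program == "a") truth$program_a else truth$program_b
  label_prefix <- label_prefix %||% paste0("sh", toupper(program))

  with_seed(seed, {
    genes <- names(truth$baseline)
    n_g <- length(genes)
    n_s <- 2L * samples_per_class
    x <- matrix(truth$baseline, n_g, n_s) +
      matrix(stats::rnorm(n_g * n_s, 0, noise_sd), n_g, n_s)
    shift <- stats::setNames(rep(0, n_g), genes)
    shift[names(prog)] <- prog * effect_size
    idx1 <- samples_per_class + seq_len(samples_per_class)
    x[, idx1] <- x[, idx1] + shift
    rownames(x) <- genes
    colnames(x) <- c(sprintf("scramble_%d", seq_len(samples_per_class)),
                     sprintf("%s_%d", label_prefix, seq_len(samples_per_class)))
    attr(x, "class_labels") <- stats::setNames(
      rep(c(0L, 1L), each = samples_per_class), colnames(x))
    x
  })
}

#' Simulate a cohort of expression profiles with latent program activity
#'
#' Each cohort sample carries independent Uniform(0, 1) activities of the two
#' planted knockdown programs; its expression is baseline plus
#' `activity * sign * effect_size` per program gene plus Gaussian noise. Any
#' correlation between the two projected signatures on this cohort therefore
#' arises only through the programs' shared genes.
#'
#' @inheritParams simulate_expression
#' @param n_samples cohort size.
#' @return genes x samples matrix with attribute `activities` (data frame of
#'   the latent per-sample activities of programs a and b).
#' @export
simulate_cohort <- function(truth, n_samples = 130L, effect_size = 1,
                            noise_sd = 0.5, seed = NULL) {
  if (!inherits(truth, "expression_truth")) {
    stop("`truth` must come from make_expression_truth()", call. = FALSE)
  }
  stopifnot_scalar_count(n_samples, "n_samples")
  with_seed(seed, {
    genes <- names(truth$baseline)
    n_g <- length(genes)
    a <- stats::runif(n_samples); b <- stats::runif(n_samples)
    shift_a <- stats::setNames(rep(0, n_g), genes)
    shift_a[names(truth$program_a)] <- truth$program_a * effect_size
    shift_b <- stats::setNames(rep(0, n_g), genes)
    shift_b[names(truth$program_b)] <- truth$program_b * effect_size
    x <- matrix(truth$baseline, n_g, n_samples) +
      outer(shift_a, a) + outer(shift_b, b) +
      matrix(stats::rnorm(n_g * n_samples, 0, noise_sd), n_g, n_samples)
    rownames(x) <- genes
    colnames(x) <- sprintf("tumor_%03d", seq_len(n_samples))
    attr(x, "activities") <- data.frame(sample = colnames(x), a = a, b = b,
                                        stringsAsFactors = FALSE)
    x
  })
}

#' Specification for a synthetic metabolite panel
#'
#' @param metabolites named numeric of baseline normalized abundances; must
#'   include `alpha-ketoglutarate` and `succinate` (the substrate/product
#'   pair of 2-oxoglutarate-dependent dioxygenases).
#' @param cell_lines character vector of line labels.
#' @param n_replicates replicates per (line, condition) (default 3).
#' @param effects data frame with columns `cell_line`, `metabolite`,
#'   `condition`, `fold`: multiplicative planted effects relative to
#'   baseline. Unlisted combinations have fold 1.
#' @param noise_sd lognormal measurement noise sd (natural-log scale).
#' @param protein_mean,protein_sd per-sample total protein content (ug);
#'   raw metabolite signal scales with protein, so normalization by protein
#'   removes it.
#' @return list of class `metabolite_panel_spec`.
#' @export
metabolite_panel_spec <- function(metabolites, cell_lines = c("shScramble", "shACC1"),
                                  n_replicates = 3L, effects = NULL,
                                  noise_sd = 0.1, protein_mean = 100,
                                  protein_sd = 10) {
  required <- c("alpha-ketoglutarate", "succinate")
  miss <- setdiff(required, names(metabolites))
  if (length(miss)) {
    stop("`metabolites` must include: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(metabolites <= 0)) stop("baseline metabolite levels must be positive", call. = FALSE)
  stopifnot_scalar_count(n_replicates, "n_replicates")
  if (is.null(effects)) {
    effects <- data.frame(cell_line = character(), metabolite = character(),
                          condition = character(), fold = numeric(),
                          stringsAsFactors = FALSE)
  }
  structure(list(metabolites = metabolites, cell_lines = cell_lines,
                 n_replicates = as.integer(n_replicates), effects = effects,
                 noise_sd = noise_sd, protein_mean = protein_mean,
                 protein_sd = protein_sd),
            class = "metabolite_panel_spec")
}

#' Simulate a metabolite panel with per-sample protein content
#'
#' Raw signal for each sample is proportional to that sample's total protein,
#' so the planted condition effects are recoverable only after protein
#' normalization — the structure the downstream statistics assume.
#'
#' @param spec a [metabolite_panel_spec()].
#' @param seed RNG seed.
#' @return long data frame (`cell_line`, `condition`, `replicate`,
#'   `metabolite`, `raw_value`, `protein_ug`) of class `metabolite_panel`.
#' @export
simulate_metabolites <- function(spec, seed = NULL) {
  if (!inherits(spec, "metabolite_panel_spec")) {
    stop("`spec` must come from metabolite_panel_spec()", call. = FALSE)
  }
  with_seed(seed, {
    conditions <- c("normoxia", "hypoxia")
    samples <- expand.grid(cell_line = spec$cell_lines, condition = conditions,
                           replicate = seq_len(spec$n_replicates),
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    samples$protein_ug <- abs(stats::rnorm(nrow(samples), spec$protein_mean,
                                           spec$protein_sd))
    mets <- names(spec$metabolites)
    panel <- samples[rep(seq_len(nrow(samples)), each = length(mets)), ]
    panel$metabolite <- rep(mets, nrow(samples))
    key <- function(l, m, c) paste(l, m, c, sep = "\r")
    fold_map <- stats::setNames(spec$effects$fold,
                                key(spec$effects$cell_line, spec$effects$metabolite,
                                    spec$effects$condition))
    fold <- fold_map[key(panel$cell_line, panel$metabolite, panel$condition)]
    fold[is.na(fold)] <- 1
    base <- spec$metabolites[panel$metabolite]
    noise <- if (spec$noise_sd > 0) exp(stats::rnorm(nrow(panel), 0, spec$noise_sd)) else 1
    panel$raw_value <- base * fold * (panel$protein_ug / spec$protein_mean) * noise
    panel <- panel[, c("cell_line", "condition", "replicate", "metabolite",
                       "raw_value", "protein_ug")]
    rownames(panel) <- NULL
    class(panel) <- c("metabolite_panel", "data.frame")
    panel
  })
}

#' Write a metabolite panel as CSV (wide, one row per sample)
#' @param panel a `metabolite_panel` long data frame.
#' @param path file path.
#' @export
write_metabolite_csv <- function(panel, path) {
  wide <- stats::reshape(as.data.frame(panel), direction = "wide",
                         idvar = c("cell_line", "condition", "replicate", "protein_ug"),
                         timevar = "metabolite", v.names = "raw_value")
  names(wide) <- sub("^raw_value\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metabolite_csv
#' @export
read_metabolite_csv <- function(path) {
  wide <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  id_cols <- c("cell_line", "condition", "replicate", "protein_ug")
  miss <- setdiff(id_cols, names(wide))
  if (length(miss)) stop("metabolite CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  mets <- setdiff(names(wide), id_cols)
  long <- do.call(rbind, lapply(mets, function(m) {
    data.frame(cell_line = wide$cell_line, condition = wide$condition,
               replicate = wide$replicate, metabolite = m,
               raw_value = wide[[m]], protein_ug = wide$protein_ug,
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  class(long) <- c("metabolite_panel", "data.frame")
  long
}
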