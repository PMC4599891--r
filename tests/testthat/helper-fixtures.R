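# In-code fixtures shared across test files.

# Build an rg_matrix directly from a numeric matrix (hairpins x replicates).
make_rg <- function(values, gene_id = NULL, pool = NULL, condition = "test") {
  if (is.null(rownames(values))) rownames(values) <- sprintf("hp%03d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("rep", seq_len(ncol(values)))
  hp <- rownames(values)
  if (is.null(gene_id)) gene_id <- hp
  if (is.null(pool)) pool <- rep(1L, nrow(values))
  structure(list(values = values,
                 gene_id = stats::setNames(gene_id, hp),
                 pool = stats::setNames(pool, hp),
                 condition = condition, n_nonpositive = 0L),
            class = "rg_matrix")
}

# Minimal shrna_library from a gene-per-hairpin assignment.
make_test_library <- function(gene_of_hairpin, efficacy = 1, pool = 1L) {
  lib <- data.frame(hairpin_id = names(gene_of_hairpin),
                    gene_id = unname(gene_of_hairpin),
                    pool_id = rep_len(pool, length(gene_of_hairpin)),
                    efficacy = rep_len(efficacy, length(gene_of_hairpin)),
                    stringsAsFactors = FALSE)
  attr(lib, "n_pools") <- max(lib$pool_id)
  class(lib) <- c("shrna_library", "data.frame")
  lib
}

# Random raw array table with controllable intensity ranges.
random_raw_table <- function(n, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    probe_id = sprintf("p%04d", seq_len(n)),
    hairpin_id = sprintf("hp%04d", seq_len(n)),
    gene_id = sprintf("g%04d", ceiling(seq_len(n) / 4)),
    pool = sample.int(3L, n, replace = TRUE),
    replicate = 1L,
    cy3_fg = stats::runif(n, 0, 1000),
    cy3_bg = stats::runif(n, 0, 300),
    cy5_fg = stats::runif(n, 0, 1000),
    cy5_bg = stats::runif(n, 0, 300),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("raw_array_table", "data.frame")
  tab
}

# Long metabolite panel from explicit per-sample values.
make_panel <- function(values_by_met, cell_line = "lineA",
                       conditions = c("normoxia", "hypoxia"), protein = 1) {
  rows <- list()
  for (m in names(values_by_met)) {
    for (cond in conditions) {
      v <- values_by_met[[m]][[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = cell_line, condition = cond, replicate = seq_along(v),
        metabolite = m, raw_value = v,
        protein_ug = rep_len(protein, length(v)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("metabolite_panel", "data.frame")
  out
}
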