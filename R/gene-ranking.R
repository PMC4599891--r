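# Second-best-hairpin gene ranking with a permutation normalized enrichment
# score (NES), stratified by hairpin count.

#' Per-hairpin log-fold-change scores
#'
#' Arithmetic mean of the non-missing replicate log2 R/G values per hairpin.
#' Hairpins with no observed replicate are excluded.
#'
#' @param rg an `rg_matrix`.
#' @return named numeric vector, hairpin id -> mean log2 R/G.
#' @export
hairpin_scores <- function(rg) {
  stopifnot(inherits(rg, "rg_matrix"))
  m <- rowMeans(rg$values, na.rm = TRUE)
  m[!is.nan(m)]
}

#' Second-best hairpin gene scores
#'
#' The gene score is the second most extreme hairpin score in the tested
#' direction: the second-largest for enrichment, the second-smallest for
#' depletion. Taking the second order statistic makes the score robust to a
#' single off-target hairpin. Genes with fewer than two scored hairpins are
#' omitted.
#'
#' @param scores named hairpin score vector from [hairpin_scores()].
#' @param library the `shrna_library`.
#' @param direction `"enrichment"` or `"depletion"`.
#' @return data frame of class `gene_scores`: `gene_id`, `n_hairpins`
#'   (scored), `gene_score`, `best_score`; attribute `direction`.
#' @export
second_best_gene_score <- function(scores, library,
                                   direction = c("enrichment", "depletion")) {
  direction <- match.arg(direction)
  stopifnot(inherits(library, "shrna_library"))
  unknown <- setdiff(names(scores), library$hairpin_id)
  if (length(unknown)) {
    stop("scores contain hairpins absent from the library: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  gene_of <- stats::setNames(library$gene_id, library$hairpin_id)
  by_gene <- split(unname(scores), gene_of[names(scores)])
  by_gene <- by_gene[lengths(by_gene) >= 2L]
  second <- vapply(by_gene, function(s) {
    s <- sort(s, decreasing = (direction == "enrichment"))
    s[2L]
  }, numeric(1))
  best <- vapply(by_gene, function(s) {
    if (direction == "enrichment") max(s) else min(s)
  }, numeric(1))
  out <- data.frame(gene_id = names(by_gene),
                    n_hairpins = lengths(by_gene),
                    gene_score = unname(second),
                    best_score = unname(best),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  class(out) <- c("gene_scores", "data.frame")
  out
}

#' Permutation normalized enrichment score and gene ranking
#'
#' For each hairpin-count stratum m, B pseudo-genes are formed by drawing m
#' hairpin scores without replacement from the global score pool and taking
#' their second-best statistic in the tested direction. The NES is the
#' z-score of the observed gene score against its stratum's null mean and
#' standard deviation (stratification because the second order statistic's
#' null distribution depends on the hairpin count). `1/NES` is reported
#' where the NES is nonzero. Genes are ranked by NES — descending for
#' enrichment, ascending for depletion — with lexicographic gene-id
#' tie-break; a degenerate stratum (null sd 0) yields an undefined NES,
#' ranked last.
#'
#' @param gene_scores a `gene_scores` table from [second_best_gene_score()].
#' @param scores the global named hairpin score vector the table was built
#'   from (the permutation pool).
#' @param B permutations per stratum (default 1000, minimum 100).
#' @param seed RNG seed for the permutation stream.
#' @return data frame of class `gene_ranking`: `gene_id`, `n_hairpins`,
#'   `gene_score`, `nes`, `inv_nes`, `rank`; attributes `direction`, `B`,
#'   `seed`.
#' @export
permutation_nes <- function(gene_scores, scores, B = 1000L, seed = NULL) {
  stopifnot(inherits(gene_scores, "gene_scores"))
  if (B < 100L) stop("`B` must be >= 100", call. = FALSE)
  if (nrow(gene_scores) < 2L) stop("need >= 2 genes to rank", call. = FALSE)
  direction <- attr(gene_scores, "direction")
  pool <- unname(scores)
  dec <- direction == "enrichment"
  second_best <- function(s) sort(s, decreasing = dec)[2L]

  strata <- sort(unique(gene_scores$n_hairpins))
  null_stats <- with_seed(seed, {
    out <- list()
    for (m in strata) {
      draws <- vapply(seq_len(B), function(i) {
        second_best(pool[sample.int(length(pool), m)])
      }, numeric(1))
      out[[as.character(m)]] <- c(mean = mean(draws), sd = stats::sd(draws))
    }
    out
  })
  mu <- vapply(as.character(gene_scores$n_hairpins),
               function(k) null_stats[[k]]["mean"], numeric(1))
  sig <- vapply(as.character(gene_scores$n_hairpins),
                function(k) null_stats[[k]]["sd"], numeric(1))
  nes <- ifelse(sig > 0, (gene_scores$gene_score - mu) / sig, NA_real_)
  inv_nes <- ifelse(!is.na(nes) & nes != 0, 1 / nes, NA_real_)

  key <- if (dec) -nes else nes
  ord <- order(key, gene_scores$gene_id, na.last = TRUE)
  rank <- integer(length(ord)); rank[ord] <- seq_along(ord)
  out <- data.frame(gene_id = gene_scores$gene_id,
                    n_hairpins = gene_scores$n_hairpins,
                    gene_score = gene_scores$gene_score,
                    nes = nes, inv_nes = inv_nes, rank = rank,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "direction") <- direction
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- seed
  class(out) <- c("gene_ranking", "data.frame")
  out
}

#' Write a gene ranking as TSV
#' @param ranking a `gene_ranking`.
#' @param path file path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
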