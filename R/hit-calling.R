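# Multiple-hairpin analysis: per-hairpin event detection on replicate R/G
# values, gene-level hit classification, cross-stress overlap.

#' Call per-hairpin enrichment/depletion events
#'
#' A hairpin scores an event when (1) its absolute normalized log2 R/G
#' exceeds `tau` in at least `min_reps` replicates (strict `>`; a value
#' exactly at `tau` does not count) and (2) the coefficient of variation of
#' its replicate values — sample (n-1) standard deviation over the absolute
#' mean — is below `cv_max` (strict `<`). The event direction is the sign of
#' the replicate mean. A zero mean leaves the CV undefined and calls no
#' event.
#'
#' @param rg an `rg_matrix` (normalized log2 R/G values).
#' @param tau absolute R/G threshold (default 0.7).
#' @param min_reps replicates that must individually exceed `tau` (default 2).
#' @param cv_max upper bound on stdev/|mean| (default 0.5).
#' @return data frame of class `hairpin_calls`: `hairpin_id`, `gene_id`,
#'   `direction` (`enriched` / `depleted` / `none`), `n_passing_reps`, `cv`,
#'   `mean_rg`, `n_obs`, `flag` (`insufficient_data` when fewer than
#'   `min_reps` non-missing replicates).
#' @export
call_hairpin_events <- function(rg, tau = 0.7, min_reps = 2L, cv_max = 0.5) {
  stopifnot(inherits(rg, "rg_matrix"))
  if (tau <= 0 || cv_max <= 0) stop("thresholds must be positive", call. = FALSE)
  stopifnot_scalar_count(min_reps, "min_reps")
  if (ncol(rg$values) < min_reps) {
    stop("fewer replicate columns than `min_reps`", call. = FALSE)
  }
  v <- rg$values
  n_obs <- rowSums(!is.na(v))
  n_pass <- rowSums(abs(v) > tau, na.rm = TRUE)
  mean_rg <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  cv <- ifelse(n_obs >= 2L & mean_rg != 0, sdv / abs(mean_rg), NA_real_)
  insufficient <- n_obs < min_reps
  event <- !insufficient & n_pass >= min_reps & !is.na(cv) & cv < cv_max
  direction <- rep("none", nrow(v))
  direction[event & mean_rg > 0] <- "enriched"
  direction[event & mean_rg < 0] <- "depleted"
  out <- data.frame(
    hairpin_id = rownames(v),
    gene_id = unname(rg$gene_id[rownames(v)]),
    direction = direction,
    n_passing_reps = n_pass,
    cv = cv,
    mean_rg = ifelse(n_obs > 0, mean_rg, NA_real_),
    n_obs = n_obs,
    flag = ifelse(insufficient, "insufficient_data", ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("hairpin_calls", "data.frame")
  out
}

#' Classify genes from hairpin events (multiple-hairpin rule)
#'
#' A gene is `protective` (synthetic survival) when at least `min_hairpins`
#' of its hairpins are enriched under stress, `lethal` (synthetic sick) when
#' at least `min_hairpins` are depleted. A gene satisfying both via distinct
#' hairpin subsets is flagged `ambiguous` and classed `none`: mixed-direction
#' support is biologically incoherent for a knockdown phenotype (set
#' `allow_mixed_direction = TRUE` to count events regardless of direction
#' and class by the majority direction, ties giving `none`).
#'
#' @param calls a `hairpin_calls` data frame.
#' @param library the `shrna_library` the screen was run against.
#' @param min_hairpins distinct same-direction hairpins required (default 2).
#' @param allow_mixed_direction disable the same-direction requirement.
#' @return data frame of class `gene_hits`, one row per library gene:
#'   `gene_id`, `class` (`protective` / `lethal` / `none`),
#'   `n_enriched`, `n_depleted`, `n_hairpins_total`, `supporting_hairpins`
#'   (comma-joined), `flag`.
#' @export
call_gene_hits <- function(calls, library, min_hairpins = 2L,
                           allow_mixed_direction = FALSE) {
  stopifnot(inherits(library, "shrna_library"))
  stopifnot_scalar_count(min_hairpins, "min_hairpins")
  unknown <- setdiff(calls$gene_id, library$gene_id)
  if (length(unknown)) {
    stop("calls reference genes absent from the library: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  genes <- unique(library$gene_id)
  n_total <- table(library$gene_id)[genes]
  enr <- calls$hairpin_id[calls$direction == "enriched"]
  dep <- calls$hairpin_id[calls$direction == "depleted"]
  enr_by <- split(enr, calls$gene_id[calls$direction == "enriched"])
  dep_by <- split(dep, calls$gene_id[calls$direction == "depleted"])
  n_enr <- vapply(genes, function(g) length(enr_by[[g]]), integer(1))
  n_dep <- vapply(genes, function(g) length(dep_by[[g]]), integer(1))

  cls <- rep("none", length(genes))
  flag <- rep("", length(genes))
  supp <- rep("", length(genes))
  if (allow_mixed_direction) {
    hit <- (n_enr + n_dep) >= min_hairpins
    maj <- ifelse(n_enr > n_dep, "protective",
                  ifelse(n_dep > n_enr, "lethal", "none"))
    cls[hit] <- maj[hit]
    flag[hit & maj == "none"] <- "tied_direction"
    for (i in which(hit & maj != "none")) {
      g <- genes[i]
      supp[i] <- paste(if (maj[i] == "protective") enr_by[[g]] else dep_by[[g]],
                       collapse = ",")
    }
  } else {
    prot <- n_enr >= min_hairpins
    leth <- n_dep >= min_hairpins
    both <- prot & leth
    cls[prot & !both] <- "protective"
    cls[leth & !both] <- "lethal"
    flag[both] <- "ambiguous"
    for (i in which(prot & !both)) supp[i] <- paste(enr_by[[genes[i]]], collapse = ",")
    for (i in which(leth & !both)) supp[i] <- paste(dep_by[[genes[i]]], collapse = ",")
  }
  out <- data.frame(gene_id = genes, class = cls,
                    n_enriched = n_enr, n_depleted = n_dep,
                    n_hairpins_total = as.integer(n_total),
                    supporting_hairpins = supp, flag = flag,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("gene_hits", "data.frame")
  out
}

#' Overlap of gene hits between two stress conditions
#'
#' Set intersections and differences computed separately for the protective
#' (enriched) and lethal (depleted) classes — one Venn per class.
#'
#' @param hits_a,hits_b `gene_hits` tables from [call_gene_hits()] over the
#'   same library.
#' @param label_a,label_b condition labels used in the output.
#' @return list of class `overlap_summary` with one element per class, each
#'   holding the unique/shared gene id vectors and their counts.
#' @export
cross_condition_overlap <- function(hits_a, hits_b,
                                    label_a = "condition_a",
                                    label_b = "condition_b") {
  if (!setequal(hits_a$gene_id, hits_b$gene_id)) {
    stop("hit tables cover different gene sets", call. = FALSE)
  }
  per_class <- function(cl) {
    a <- hits_a$gene_id[hits_a$class == cl]
    b <- hits_b$gene_id[hits_b$class == cl]
    shared <- intersect(a, b)
    list(n_a = length(a), n_b = length(b),
         n_unique_a = length(setdiff(a, b)),
         n_unique_b = length(setdiff(b, a)),
         n_shared = length(shared),
         unique_a = setdiff(a, b), unique_b = setdiff(b, a), shared = shared)
  }
  structure(list(labels = c(label_a, label_b),
                 protective = per_class("protective"),
                 lethal = per_class("lethal")),
            class = "overlap_summary")
}

#' Write hairpin calls / gene hits as TSV, overlap summary as JSON
#' @param x the object to write.
#' @param path file path.
#' @export
write_hits_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
write_overlap_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
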