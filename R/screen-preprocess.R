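# Two-color array preprocessing: background filter, log2 R/G ratios,
# pool-wise quantile normalization, replicate QC.

#' Discard probes too close to background
#'
#' A probe row is removed when a channel's foreground intensity is less than
#' `fold` times that channel's background estimate (strict inequality: a
#' foreground exactly at `fold * bg` is kept). Filtering is applied per
#' replicate independently, so a hairpin can fail on one array and survive on
#' another.
#'
#' @param raw a `raw_array_table` (see [simulate_screen()] /
#'   [read_array_table()]).
#' @param fold threshold multiple of background (default 2).
#' @param rule `"either"` removes the row when either channel fails (default);
#'   `"cy5"` / `"cy3"` test a single channel.
#' @return The surviving rows, same class, with attributes `removed` (the
#'   discarded rows plus a `reason` column) and `n_input`.
#' @export
filter_background <- function(raw, fold = 2.0, rule = c("either", "cy5", "cy3")) {
  rule <- match.arg(rule)
  if (fold <= 0) stop("`fold` must be positive", call. = FALSE)
  ints <- c("cy3_fg", "cy3_bg", "cy5_fg", "cy5_bg")
  if (any(vapply(raw[ints], function(v) any(v < 0, na.rm = TRUE), logical(1)))) {
    stop("negative intensities in array table", call. = FALSE)
  }
  fail3 <- raw$cy3_fg < fold * raw$cy3_bg
  fail5 <- raw$cy5_fg < fold * raw$cy5_bg
  drop <- switch(rule,
    either = fail3 | fail5,
    cy5 = fail5,
    cy3 = fail3
  )
  removed <- as.data.frame(raw)[drop, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- ifelse(fail3[drop] & fail5[drop], "both_channels",
                             ifelse(fail3[drop], "cy3", "cy5"))
  } else removed$reason <- character(0)
  kept <- raw[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "condition") <- attr(raw, "condition")
  attr(kept, "removed") <- removed
  attr(kept, "n_input") <- nrow(raw)
  class(kept) <- c("raw_array_table", "data.frame")
  kept
}

#' Compute the log2 R/G ratio matrix
#'
#' Builds the hairpins x replicates matrix of `log2(Cy5net / Cy3net)` the
#' screen analysis consumes, where net intensity is foreground minus
#' background (set `use_net = FALSE` to ratio raw foregrounds). Entries are
#' missing where the probe was discarded by the background filter in that
#' replicate or where a net intensity is non-positive (counted, not an
#' error).
#'
#' @param filtered a background-filtered `raw_array_table`.
#' @param use_net subtract background before the ratio (default TRUE).
#' @return An `rg_matrix`: list with `values` (matrix, rownames hairpin ids,
#'   columns `rep1..repR`), `gene_id` and `pool` (named by hairpin),
#'   `condition`, and `n_nonpositive` (entries dropped for non-positive net
#'   intensity).
#' @export
compute_log_ratios <- function(filtered, use_net = TRUE) {
  tab <- as.data.frame(filtered)
  if (!nrow(tab)) stop("no probes left after filtering", call. = FALSE)
  hp <- sort(unique(tab$hairpin_id))
  reps <- sort(unique(tab$replicate))
  net5 <- if (use_net) tab$cy5_fg - tab$cy5_bg else tab$cy5_fg
  net3 <- if (use_net) tab$cy3_fg - tab$cy3_bg else tab$cy3_fg
  ok <- net5 > 0 & net3 > 0
  vals <- matrix(NA_real_, length(hp), length(reps),
                 dimnames = list(hp, paste0("rep", reps)))
  ri <- match(tab$hairpin_id, hp)
  ci <- match(tab$replicate, reps)
  vals[cbind(ri[ok], ci[ok])] <- log2(net5[ok] / net3[ok])
  first <- !duplicated(tab$hairpin_id)
  gene_id <- stats::setNames(tab$gene_id[first], tab$hairpin_id[first])[hp]
  pool <- stats::setNames(tab$pool[first], tab$hairpin_id[first])[hp]
  structure(list(values = vals, gene_id = gene_id, pool = pool,
                 condition = attr(filtered, "condition"),
                 n_nonpositive = sum(!ok)),
            class = "rg_matrix")
}

# Quantile-normalize the columns of a numeric matrix, missing-value aware:
# ranks are taken among non-missing values only, and each column's sorted
# values are mapped onto the mean quantile function of all columns. With
# complete, tie-free data this is exactly "replace the k-th order statistic
# by the mean of all columns' k-th order statistics".
qn_columns <- function(x) {
  n <- nrow(x)
  m <- colSums(!is.na(x))
  good <- m >= 2L
  if (!any(good)) {
    warning("no column with >= 2 non-missing values; group left unnormalized")
    return(x)
  }
  if (any(!good)) {
    warning(sum(!good), " column(s) with < 2 non-missing values passed through unnormalized")
  }
  grid <- if (n > 1) seq(0, 1, length.out = n) else 0.5
  qfun <- vapply(which(good), function(j) {
    s <- sort(x[, j])
    if (length(s) == n) s
    else stats::approx(seq(0, 1, length.out = length(s)), s, xout = grid,
                       rule = 2)$y
  }, numeric(n))
  ref <- rowMeans(qfun)
  out <- x
  for (j in which(good)) {
    idx <- !is.na(x[, j])
    r <- rank(x[idx, j], ties.method = "average")
    # fractional position of each rank on the reference grid; integer
    # positions index the reference exactly so equal-count columns end up
    # with bit-identical value multisets
    pos <- 1 + (r - 1) * (n - 1) / (m[j] - 1)
    lo <- pmax(1L, pmin(n, floor(pos)))
    hi <- pmax(1L, pmin(n, ceiling(pos)))
    frac <- pos - lo
    out[idx, j] <- ifelse(frac == 0, ref[lo], ref[lo] * (1 - frac) + ref[hi] * frac)
  }
  out
}

#' Quantile-normalize an R/G matrix within pool groups
#'
#' Each sub-pool is a separate physical array, so by default the replicate
#' columns are normalized jointly within each pool's probe set; with
#' `group_by_pool = FALSE` all hairpins form one group. After the call, every
#' column of a group carries the same multiset of non-missing values (exact
#' on complete data); within-column ranks are preserved. Missing entries stay
#' missing and never enter rank computation. A column with fewer than 2
#' non-missing values in a group is passed through with a warning.
#'
#' @param rg an `rg_matrix` from [compute_log_ratios()].
#' @param group_by_pool normalize within pools (default) or globally.
#' @return the normalized `rg_matrix`.
#' @export
quantile_normalize <- function(rg, group_by_pool = TRUE) {
  stopifnot(inherits(rg, "rg_matrix"))
  if (ncol(rg$values) < 2L) {
    stop("quantile normalization needs >= 2 replicate columns", call. = FALSE)
  }
  if (group_by_pool) {
    for (p in unique(rg$pool)) {
      idx <- which(rg$pool == p)
      rg$values[idx, ] <- qn_columns(rg$values[idx, , drop = FALSE])
    }
  } else {
    rg$values <- qn_columns(rg$values)
  }
  rg
}

#' Median-center an R/G matrix
#'
#' Subtracts the median of the non-missing values from each normalization
#' group (per pool by default). Competitive hybridization compares equal
#' amounts of labeled product, so the global survival factor shared by all
#' hairpins carries no information; centering puts the unchanged bulk of the
#' library at R/G = 0, the scale on which the enrichment/depletion
#' thresholds operate. Applied after [quantile_normalize()] the shift is
#' common to all columns of a group, so the equal-multiset invariant is
#' preserved.
#'
#' @param rg an `rg_matrix`.
#' @param by_pool center within pools (default) or globally.
#' @param per_column center each replicate column on its own median instead
#'   of a single group shift.
#' @return the centered `rg_matrix`.
#' @export
median_center <- function(rg, by_pool = TRUE, per_column = FALSE) {
  stopifnot(inherits(rg, "rg_matrix"))
  center <- function(x) {
    if (per_column) sweep(x, 2, apply(x, 2, stats::median, na.rm = TRUE))
    else x - stats::median(x, na.rm = TRUE)
  }
  if (by_pool) {
    for (p in unique(rg$pool)) {
      idx <- which(rg$pool == p)
      rg$values[idx, ] <- center(rg$values[idx, , drop = FALSE])
    }
  } else rg$values <- center(rg$values)
  rg
}

#' Replicate-reproducibility QC for an R/G matrix
#'
#' @param rg an `rg_matrix`.
#' @param nbins histogram bin count over the observed R/G range.
#' @return A `qc_report` list: `correlations` (data frame of per-replicate-
#'   pair Pearson correlations over jointly non-missing entries; `NA` when a
#'   pair shares fewer than 3 entries), `fraction_missing` (entries dropped
#'   by the background filter or non-positive nets), `rg_range`, `histogram`
#'   (breaks and counts), `condition`.
#' @export
replicate_qc <- function(rg, nbins = 40L) {
  stopifnot(inherits(rg, "rg_matrix"))
  v <- rg$values
  if (ncol(v) < 2L) stop("replicate QC needs >= 2 replicate columns", call. = FALSE)
  prs <- utils::combn(colnames(v), 2)
  cors <- apply(prs, 2, function(pr) {
    a <- v[, pr[1]]; b <- v[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3L) NA_real_ else stats::cor(a[ok], b[ok])
  })
  fin <- v[is.finite(v)]
  h <- graphics::hist(fin, breaks = nbins, plot = FALSE)
  structure(list(
    correlations = data.frame(rep_a = prs[1, ], rep_b = prs[2, ],
                              pearson = cors, stringsAsFactors = FALSE),
    fraction_missing = mean(is.na(v)),
    rg_range = range(fin),
    histogram = list(breaks = h$breaks, counts = h$counts),
    condition = rg$condition
  ), class = "qc_report")
}

#' Write / read an R/G matrix as TSV
#'
#' Columns: `hairpin_id`, `gene_id`, `pool`, `rep1..repR`.
#' @param rg an `rg_matrix`.
#' @param path file path.
#' @export
write_rg_matrix <- function(rg, path) {
  df <- data.frame(hairpin_id = rownames(rg$values),
                   gene_id = unname(rg$gene_id),
                   pool = unname(rg$pool),
                   rg$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rg_matrix
#' @param condition condition label attached on read.
#' @export
read_rg_matrix <- function(path, condition = NA_character_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rep_cols <- grep("^rep", names(df), value = TRUE)
  vals <- as.matrix(df[rep_cols])
  rownames(vals) <- df$hairpin_id
  structure(list(values = vals,
                 gene_id = stats::setNames(df$gene_id, df$hairpin_id),
                 pool = stats::setNames(df$pool, df$hairpin_id),
                 condition = condition, n_nonpositive = NA_integer_),
            class = "rg_matrix")
}

#' Write a QC report as JSON
#' @param qc a `qc_report`.
#' @param path file path.
#' @export
write_qc_json <- function(qc, path) {
  jsonlite::write_json(unclass(qc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
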