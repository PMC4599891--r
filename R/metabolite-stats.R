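# Protein-normalized metabolite summaries: fold / percent change under
# hypoxia and substrate/product ratios, with small-n SEMs.

#' Normalize metabolite measurements by total protein content
#'
#' @param panel long `metabolite_panel` data frame (`cell_line`, `condition`,
#'   `replicate`, `metabolite`, `raw_value`, `protein_ug`).
#' @return the panel with a `normalized_value = raw_value / protein_ug`
#'   column.
#' @export
protein_normalize <- function(panel) {
  need <- c("cell_line", "condition", "replicate", "metabolite",
            "raw_value", "protein_ug")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(panel$protein_ug)) || any(panel$protein_ug <= 0)) {
    stop("`protein_ug` must be positive for every sample", call. = FALSE)
  }
  panel$normalized_value <- panel$raw_value / panel$protein_ug
  class(panel) <- unique(c("metabolite_panel", class(panel)))
  panel
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Fold or percent change of metabolite levels under hypoxia
#'
#' Per (cell line, metabolite): `fold = mean_hypoxia / mean_normoxia` over
#' protein-normalized replicate values; `percent = (fold - 1) * 100`. The
#' SEM is propagated by the delta method for a ratio of independent means:
#' `sem_fold = fold * sqrt((sem_H/mean_H)^2 + (sem_N/mean_N)^2)`. A zero
#' normoxic mean leaves the statistic undefined (`NA`, flagged).
#'
#' @param panel a `metabolite_panel`; normalized on the fly if needed.
#' @param mode `"fold"` or `"percent"`.
#' @return data frame: `cell_line`, `metabolite`, `mean_normoxia`,
#'   `mean_hypoxia`, `n_normoxia`, `n_hypoxia`, `estimate`, `sem`, `mode`,
#'   `flag`.
#' @export
hypoxia_change <- function(panel, mode = c("fold", "percent")) {
  mode <- match.arg(mode)
  if (is.null(panel$normalized_value)) panel <- protein_normalize(panel)
  combos <- unique(panel[, c("cell_line", "metabolite")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- panel[panel$cell_line == combos$cell_line[i] &
                 panel$metabolite == combos$metabolite[i], ]
    vN <- sub$normalized_value[sub$condition == "normoxia"]
    vH <- sub$normalized_value[sub$condition == "hypoxia"]
    if (!length(vN) || !length(vH)) {
      stop(sprintf("both conditions required for %s / %s",
                   combos$cell_line[i], combos$metabolite[i]), call. = FALSE)
    }
    mN <- mean(vN); mH <- mean(vH)
    if (mN == 0) {
      fold <- NA_real_; se_f <- NA_real_; flag <- "zero_normoxia_mean"
    } else {
      fold <- mH / mN
      se_f <- if (length(vN) > 1L && length(vH) > 1L && mH != 0) {
        abs(fold) * sqrt((sem(vH) / mH)^2 + (sem(vN) / mN)^2)
      } else NA_real_
      flag <- ""
    }
    est <- if (mode == "fold") fold else (fold - 1) * 100
    se <- if (mode == "fold") se_f else 100 * se_f
    data.frame(cell_line = combos$cell_line[i],
               metabolite = combos$metabolite[i],
               mean_normoxia = mN, mean_hypoxia = mH,
               n_normoxia = length(vN), n_hypoxia = length(vH),
               estimate = est, sem = se, mode = mode, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Substrate/product metabolite ratio per cell line and condition
#'
#' Ratio of two protein-normalized metabolites, computed per sample then
#' summarized by mean and SEM over replicates (matching per-replicate error
#' bars; `method = "ratio_of_means"` divides the replicate means instead).
#' The default pair, alpha-ketoglutarate over succinate, proxies the
#' activity of 2-oxoglutarate-dependent dioxygenases. Samples with a zero
#' denominator are excluded and counted.
#'
#' @param panel a `metabolite_panel`.
#' @param numerator,denominator metabolite names.
#' @param method `"per_sample"` (default) or `"ratio_of_means"`.
#' @return data frame: `cell_line`, `condition`, `ratio`, `sem`, `n_used`,
#'   `n_excluded`.
#' @export
substrate_product_ratio <- function(panel, numerator = "alpha-ketoglutarate",
                                    denominator = "succinate",
                                    method = c("per_sample", "ratio_of_means")) {
  method <- match.arg(method)
  if (is.null(panel$normalized_value)) panel <- protein_normalize(panel)
  for (m in c(numerator, denominator)) {
    if (!m %in% panel$metabolite) stop("metabolite absent from panel: ", m,
                                       call. = FALSE)
  }
  num <- panel[panel$metabolite == numerator, ]
  den <- panel[panel$metabolite == denominator, ]
  key <- function(d) paste(d$cell_line, d$condition, d$replicate, sep = "\r")
  den_val <- stats::setNames(den$normalized_value, key(den))
  num$den <- den_val[key(num)]
  if (any(is.na(num$den))) {
    stop("numerator and denominator samples do not match one-to-one", call. = FALSE)
  }
  combos <- unique(num[, c("cell_line", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- num[num$cell_line == combos$cell_line[i] &
               num$condition == combos$condition[i], ]
    if (method == "per_sample") {
      ok <- sub$den != 0
      r <- sub$normalized_value[ok] / sub$den[ok]
      data.frame(cell_line = combos$cell_line[i],
                 condition = combos$condition[i],
                 ratio = if (length(r)) mean(r) else NA_real_,
                 sem = if (length(r) > 1L) sem(r) else NA_real_,
                 n_used = sum(ok), n_excluded = sum(!ok),
                 stringsAsFactors = FALSE)
    } else {
      md <- mean(sub$den)
      data.frame(cell_line = combos$cell_line[i],
                 condition = combos$condition[i],
                 ratio = if (md != 0) mean(sub$normalized_value) / md else NA_real_,
                 sem = NA_real_, n_used = nrow(sub), n_excluded = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
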