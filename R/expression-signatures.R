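# Expression-side analysis: zero transformation to scramble controls,
# occurrence/fold filtering, two-class signature creation/projection,
# cross-signature regression. GCT 1.2 / CLS readers and writers included.

#' Read / write GCT 1.2 expression matrices
#'
#' GCT 1.2: line 1 `#1.2`, line 2 `<n_genes>\t<n_samples>`, then a header
#' row `Name Description <samples...>` and one row per gene.
#'
#' @param path file path.
#' @return `read_gct()` returns a genes x samples numeric matrix (gene ids as
#'   rownames; the Description column is kept as attribute `description`).
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 2L)
  if (!grepl("^#1\\.2", header[1])) stop("not a GCT 1.2 file: ", path, call. = FALSE)
  dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
  df <- utils::read.delim(path, skip = 2L, stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df[[1]]
  if (nrow(m) != dims[1] || ncol(m) != dims[2]) {
    stop("GCT dimension header disagrees with table", call. = FALSE)
  }
  attr(m, "description") <- df[[2]]
  m
}

#' @rdname read_gct
#' @param x genes x samples numeric matrix with rownames.
#' @export
write_gct <- function(x, path) {
  desc <- attr(x, "description") %||% rownames(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  df <- data.frame(Name = rownames(x), Description = desc, x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write CLS class-label files
#'
#' Categorical CLS: line 1 `<n> <k> 1`, line 2 `# <names...>`, line 3
#' space-separated numeric labels.
#' @param path file path.
#' @return `read_cls()` returns an integer label vector with attribute
#'   `class_names`.
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  names_ <- strsplit(sub("^#\\s*", "", lines[2]), "\\s+")[[1]]
  labels <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
  attr(labels, "class_names") <- names_
  labels
}

#' @rdname read_cls
#' @param labels integer vector of class labels (0-based).
#' @param class_names names of the classes in label order.
#' @export
write_cls <- function(labels, class_names, path) {
  writeLines(c(paste(length(labels), length(class_names), 1),
               paste("#", paste(class_names, collapse = " ")),
               paste(labels, collapse = " ")), path)
  invisible(path)
}

#' Zero-transform expression to scramble controls
#'
#' Subtracts, per gene, the mean log2 expression of the designated control
#' (scramble) samples, so every value reads as a log2 change relative to
#' controls. Idempotent for a fixed control set.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param control_ids column names of the control samples.
#' @return the transformed matrix with attribute `control_ids`.
#' @export
zero_transform <- function(expr, control_ids) {
  if (!length(control_ids)) stop("need >= 1 control sample", call. = FALSE)
  miss <- setdiff(control_ids, colnames(expr))
  if (length(miss)) {
    stop("control ids absent from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ctrl_mean <- rowMeans(expr[, control_ids, drop = FALSE])
  out <- expr - ctrl_mean
  attr(out, "control_ids") <- control_ids
  attr(out, "class_labels") <- attr(expr, "class_labels")
  out
}

#' Occurrence/fold filter on a zero-transformed matrix
#'
#' Keeps genes whose absolute change reaches the threshold in at least
#' `min_arrays` samples. The threshold is a linear fold change by default
#' (`fold = 1.7` keeps values with `|log2 value| >= log2(1.7)`); with
#' `scale = "log2"` the threshold is applied directly in log2 units. The
#' boundary is inclusive (`>=`) unless `strict = TRUE`.
#'
#' @param zt zero-transformed genes x samples matrix.
#' @param fold threshold (default 1.7).
#' @param min_arrays minimum qualifying samples (default 6).
#' @param scale `"fold"` (linear, default) or `"log2"`.
#' @param strict use strict `>` at the boundary.
#' @return the row-filtered matrix.
#' @export
fold_filter <- function(zt, fold = 1.7, min_arrays = 6L,
                        scale = c("fold", "log2"), strict = FALSE) {
  scale <- match.arg(scale)
  stopifnot_scalar_count(min_arrays, "min_arrays")
  if (min_arrays > ncol(zt)) {
    stop("`min_arrays` exceeds the number of samples", call. = FALSE)
  }
  thr <- if (scale == "fold") {
    if (fold <= 1) stop("`fold` must be > 1 on the fold scale", call. = FALSE)
    log2(fold)
  } else {
    if (fold <= 0) stop("`fold` must be > 0 on the log2 scale", call. = FALSE)
    fold
  }
  hits <- if (strict) rowSums(abs(zt) > thr) else rowSums(abs(zt) >= thr)
  out <- zt[hits >= min_arrays, , drop = FALSE]
  attr(out, "control_ids") <- attr(zt, "control_ids")
  out
}

# Ridge-penalized probit fit by Newton/Fisher scoring; the intercept is
# unpenalized. Small ridge keeps coefficients finite under the perfect
# separation that tiny training sets produce.
probit_ridge <- function(Z, y, ridge = 0.01, max_iter = 100L, tol = 1e-8) {
  p <- ncol(Z)
  pen <- diag(c(0, rep(ridge, p - 1L)), p)
  b <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% b)
    mu <- stats::pnorm(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    d <- stats::dnorm(eta)
    g <- drop(crossprod(Z, d * (y - mu) / (mu * (1 - mu)))) - pen %*% b
    W <- d^2 / (mu * (1 - mu))
    H <- crossprod(Z, Z * W) + pen
    step <- solve(H, g)
    b_new <- b + step
    if (max(abs(b_new - b)) < tol) { b <- b_new; break }
    b <- drop(b_new)
  }
  drop(b)
}

#' Train a two-class expression signature
#'
#' Genes are ranked by the absolute signal-to-noise ratio between the two
#' training classes — difference of class means over the sum of class
#' standard deviations — and the top `n_sig` retained. The selected training
#' submatrix (rows centered on the training mean) is decomposed by SVD; a
#' ridge-penalized probit regression of class on the top `k_factors` factor
#' scores maps any profile to a probability of resembling the train1
#' (knockdown) class. Deterministic given its inputs.
#'
#' @param zt zero-transformed (or otherwise comparable) genes x samples
#'   matrix containing the training columns.
#' @param train0_ids,train1_ids column names of the two training classes
#'   (train0 = control/scramble, train1 = knockdown); >= 2 samples each.
#' @param n_sig signature size (default 100).
#' @param k_factors number of SVD factors (default 2; capped at
#'   n_train - 1).
#' @param ridge probit ridge penalty (default 0.01).
#' @return list of class `signature_model`: `genes`, `center` (per-gene
#'   training means), `basis` (genes x k left singular vectors,
#'   sign-normalized), `coef` (probit coefficients, intercept first), `snr`,
#'   `train0_ids`, `train1_ids`, `train_prob` (fitted training
#'   probabilities), `n_sd_floored`.
#' @export
create_signature <- function(zt, train0_ids, train1_ids, n_sig = 100L,
                             k_factors = 2L, ridge = 0.01) {
  if (length(train0_ids) < 2L || length(train1_ids) < 2L) {
    stop("need >= 2 samples per training class", call. = FALSE)
  }
  miss <- setdiff(c(train0_ids, train1_ids), colnames(zt))
  if (length(miss)) stop("training ids absent from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  X0 <- zt[, train0_ids, drop = FALSE]
  X1 <- zt[, train1_ids, drop = FALSE]
  eps <- 1e-6
  s0 <- apply(X0, 1, stats::sd); s1 <- apply(X1, 1, stats::sd)
  n_floored <- sum(s0 < eps) + sum(s1 < eps)
  snr <- (rowMeans(X1) - rowMeans(X0)) / (pmax(s0, eps) + pmax(s1, eps))
  n_sig <- min(n_sig, nrow(zt))
  ord <- order(-abs(snr), rownames(zt))   # tie-break by gene id: deterministic
  sel <- sort(rownames(zt)[ord[seq_len(n_sig)]])

  Xtr <- cbind(X0, X1)[sel, , drop = FALSE]
  center <- rowMeans(Xtr)
  Xc <- Xtr - center
  k <- min(k_factors, ncol(Xtr) - 1L, n_sig)
  sv <- svd(Xc, nu = k, nv = 0)
  U <- sv$u[, seq_len(k), drop = FALSE]
  # SVD signs are arbitrary; anchor each factor's largest loading positive
  for (j in seq_len(k)) {
    if (U[which.max(abs(U[, j])), j] < 0) U[, j] <- -U[, j]
  }
  rownames(U) <- sel
  scores <- crossprod(Xc, U)                     # samples x k
  y <- c(rep(0L, length(train0_ids)), rep(1L, length(train1_ids)))
  b <- probit_ridge(cbind(1, scores), y, ridge = ridge)
  train_prob <- stats::pnorm(drop(cbind(1, scores) %*% b))
  names(train_prob) <- colnames(Xtr)
  structure(list(genes = sel, center = center, basis = U, coef = b,
                 snr = snr[sel], k = k, ridge = ridge,
                 train0_ids = train0_ids, train1_ids = train1_ids,
                 train_prob = train_prob, n_sd_floored = n_floored),
            class = "signature_model")
}

#' Project expression profiles through a trained signature
#'
#' Test profiles are centered with the training statistics, mapped onto the
#' factor basis and through the probit link. Genes outside the signature
#' never influence the result.
#'
#' @param model a `signature_model`.
#' @param test genes x samples matrix containing all signature genes.
#' @return named numeric vector of per-sample probabilities in `[0, 1]`.
#' @export
project_signature <- function(model, test) {
  stopifnot(inherits(model, "signature_model"))
  miss <- setdiff(model$genes, rownames(test))
  if (length(miss)) {
    stop("test matrix is missing signature genes: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10),
         call. = FALSE)
  }
  Y <- test[model$genes, , drop = FALSE] - model$center
  scores <- crossprod(Y, model$basis)
  p <- stats::pnorm(drop(cbind(1, scores) %*% model$coef))
  stats::setNames(p, colnames(test))
}

#' Ordinary least-squares regression between two signature probability sets
#'
#' Simple linear regression of `prob_b` on `prob_a` over a shared sample
#' set, with the slope's t-test p-value — used to ask whether samples
#' resembling one knockdown signature also resemble another.
#'
#' @param prob_a,prob_b named per-sample probability vectors over the same
#'   samples.
#' @return list of class `signature_regression`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`. Zero variance in `prob_a` yields an
#'   undefined slope (all fields `NA` except `n`).
#' @export
signature_regression <- function(prob_a, prob_b) {
  if (!is.null(names(prob_a)) && !is.null(names(prob_b))) {
    if (!setequal(names(prob_a), names(prob_b))) {
      stop("probability vectors cover different samples", call. = FALSE)
    }
    prob_b <- prob_b[names(prob_a)]
  }
  n <- length(prob_a)
  if (n < 3L || n != length(prob_b)) {
    stop("need the same >= 3 samples in both vectors", call. = FALSE)
  }
  if (stats::var(prob_a) == 0) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, p_value = NA_real_, n = n,
                          note = "zero variance in predictor"),
                     class = "signature_regression"))
  }
  fit <- stats::lm(prob_b ~ prob_a)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = n),
            class = "signature_regression")
}

#' Serialize a signature model / regression result as JSON
#' @param x the object.
#' @param path file path.
#' @export
write_signature_json <- function(x, path) {
  if (inherits(x, "signature_model")) {
    out <- list(genes = x$genes, center = as.list(x$center),
                basis = apply(x$basis, 2, identity, simplify = FALSE),
                coef = x$coef, k = x$k, ridge = x$ridge,
                train0_ids = x$train0_ids, train1_ids = x$train1_ids)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
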