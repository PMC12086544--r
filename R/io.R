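#' Move beta-values off the boundaries of [0, 1]
#'
#' The beta likelihood is undefined at exactly 0 or 1, but methylation data
#' routinely contain both (e.g. a locus with zero methylated reads). Two
#' squeezing rules are offered: `"clip"` truncates to `[eps, 1 - eps]` and is
#' idempotent, leaving interior values untouched; `"smithson"` applies the
#' Smithson-Verkuilen compression `(y * (n - 1) + 0.5) / n`, where `n` is the
#' number of samples, which moves every value slightly toward 0.5.
#'
#' @param y Numeric vector or matrix of proportions in `[0, 1]`; `NA` allowed.
#' @param method `"clip"` (default) or `"smithson"`.
#' @param eps Clipping margin for `method = "clip"`.
#' @param n Sample count used by the Smithson-Verkuilen formula; defaults to
#'   the number of columns if `y` is a matrix, otherwise `length(y)`.
#' @return Object of the same shape with all non-missing values strictly
#'   inside (0, 1). For `"clip"`, the attribute `"squeezed"` holds a logical
#'   index of the cells that were moved.
#' @export
squeeze_beta <- function(y, method = c("clip", "smithson"), eps = 1e-6, n = NULL) {
  method <- match.arg(method)
  bad <- !is.na(y) & (y < 0 | y > 1)
  if (any(bad)) {
    stop("values outside [0, 1] at position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (method == "clip") {
    out <- pmin(pmax(y, eps), 1 - eps)
    attr(out, "squeezed") <- !is.na(y) & (y != out)
  } else {
    if (is.null(n)) n <- if (is.matrix(y)) ncol(y) else length(y)
    out <- (y * (n - 1) + 0.5) / n
    attr(out, "squeezed") <- !is.na(y)
  }
  if (is.matrix(y)) dimnames(out) <- dimnames(y)
  out
}

#' Logit transform between beta-values and M-values
#'
#' M-values are `log(beta / (1 - beta))`; they live on the whole real line
#' and are approximately Gaussian away from the boundaries, which is why
#' Gaussian linear-model machinery is applied to them.
#'
#' @param beta Proportions strictly in (0, 1) (`NA` allowed).
#' @return Matrix/vector of M-values.
#' @export
beta_to_m <- function(beta) {
  v <- beta[!is.na(beta)]
  if (any(v <= 0 | v >= 1)) {
    stop("beta_to_m() requires values strictly in (0, 1); squeeze first")
  }
  log(beta / (1 - beta))
}

#' @rdname beta_to_m
#' @param m M-values on the real line.
#' @export
m_to_beta <- function(m) stats::plogis(m)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a features-by-samples beta-value matrix
#'
#' Expects a TSV (comma auto-detected) with a header row of sample IDs and a
#' first column of feature IDs. Values must lie in `[0, 1]`; boundary values
#' are squeezed into the open interval on load (see [squeeze_beta()]).
#'
#' @param path Path to the delimited file.
#' @param squeeze_mode `"clip"` or `"smithson"`.
#' @param eps Clipping margin when `squeeze_mode = "clip"`.
#' @return Numeric matrix (features x samples) with dimnames; strictly inside
#'   (0, 1) apart from `NA` cells.
#' @export
read_beta_matrix <- function(path, squeeze_mode = c("clip", "smithson"), eps = 1e-6) {
  squeeze_mode <- match.arg(squeeze_mode)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          row.names = NULL, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a feature-ID column plus at least one sample column")
  fid <- as.character(df[[1L]])
  if (anyDuplicated(fid)) stop("duplicate feature IDs: ", fid[duplicated(fid)][1L])
  sid <- colnames(df)[-1L]
  if (anyDuplicated(sid)) stop("duplicate sample IDs: ", sid[duplicated(sid)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in beta-value matrix")
  out_of_range <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    stop(sprintf("beta-value outside [0, 1] at feature '%s', sample '%s'",
                 fid[out_of_range[1L, 1L]], sid[out_of_range[1L, 2L]]))
  }
  rownames(m) <- fid
  squeeze_beta(m, method = squeeze_mode, eps = eps)
}

#' Write a beta-value matrix to TSV
#'
#' Values are written with 15 significant digits so that a write/read
#' round-trip is the identity to better than 1e-12.
#'
#' @param matrix Numeric features x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_beta_matrix <- function(matrix, path) {
  if (!is.matrix(matrix) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("need a non-empty matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must carry feature (row) and sample (column) names")
  }
  df <- data.frame(feature = rownames(matrix),
                   format(matrix, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Construct a sample design
#'
#' Bundles per-sample batch and condition labels (plus optional numeric
#' covariates) and validates the layout: every batch must hold at least two
#' samples (a single sample cannot inform a batch precision estimate), and
#' batch must not be perfectly confounded with condition/covariates, i.e. the
#' full design matrix must have full column rank.
#'
#' @param sample_ids Character vector of unique sample IDs.
#' @param batch Batch label per sample (coerced to factor).
#' @param condition Biological condition per sample (coerced to factor).
#' @param covariates Optional numeric matrix/data.frame (samples x covariates).
#' @return An object of class `sample_design` with elements `sample_ids`,
#'   `batch`, `condition`, `covariates`, `batch_sizes`, `n_batches`.
#' @export
sample_design <- function(sample_ids, batch, condition, covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  S <- length(sample_ids)
  if (length(batch) != S || length(condition) != S) {
    stop("batch and condition must have one entry per sample")
  }
  if (anyNA(batch) || anyNA(condition)) stop("missing batch or condition labels")
  batch <- factor(batch)
  condition <- factor(condition)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != S) stop("covariates must have one row per sample")
    if (!is.numeric(covariates)) stop("covariates must be numeric")
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
  }
  batch_sizes <- table(batch)
  if (any(batch_sizes < 2L)) {
    stop("batch(es) with a single sample: ",
         paste(names(batch_sizes)[batch_sizes < 2L], collapse = ", "),
         " (every batch needs >= 2 samples for precision estimation)")
  }
  X <- mean_model_matrix(batch = batch, condition = condition, covariates = covariates)
  if (qr(X)$rank < ncol(X)) {
    stop("batch is confounded with condition/covariates (design matrix is rank deficient)")
  }
  structure(list(sample_ids = sample_ids, batch = batch, condition = condition,
                 covariates = covariates,
                 batch_sizes = as.integer(batch_sizes),
                 n_batches = nlevels(batch)),
            names_batch_sizes = names(batch_sizes),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("sample_design: %d samples, %d batches (%s), %d condition levels\n",
              length(x$sample_ids), x$n_batches,
              paste(sprintf("%s=%d", levels(x$batch), x$batch_sizes), collapse = ", "),
              nlevels(x$condition)))
  invisible(x)
}

# intercept + condition + covariates + batch dummies; used for both the rank
# check and the regression mean model
mean_model_matrix <- function(batch, condition, covariates = NULL, ref_batch = NULL) {
  if (!is.null(ref_batch)) batch <- stats::relevel(batch, ref = ref_batch)
  X <- if (nlevels(factor(condition)) > 1L) {
    stats::model.matrix(~.cond, data.frame(.cond = condition))
  } else {
    matrix(1, length(condition), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.null(covariates)) X <- cbind(X, covariates)
  if (nlevels(batch) > 1L) {
    Xb <- stats::model.matrix(~.b, data.frame(.b = batch))[, -1L, drop = FALSE]
    colnames(Xb) <- paste0("batch", levels(batch)[-1L])
    X <- cbind(X, Xb)
  }
  X
}

#' Read a sample-design table
#'
#' TSV/CSV with columns `sample`, `batch`, `condition`; any further numeric
#' columns are treated as covariates.
#'
#' @param path Path to the table.
#' @return A [sample_design()] object.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "batch", "condition")
  if (!all(need %in% colnames(df))) {
    stop("design table needs columns: ", paste(need, collapse = ", "))
  }
  extra <- setdiff(colnames(df), need)
  cov <- if (length(extra)) as.matrix(df[, extra, drop = FALSE]) else NULL
  sample_design(df$sample, df$batch, df$condition, covariates = cov)
}

#' Convert methylated/coverage count matrices to beta-values
#'
#' @param methylated,coverage Non-negative integer matrices of identical shape;
#'   `methylated <= coverage` cellwise.
#' @param squeeze_mode,eps Passed to [squeeze_beta()].
#' @return Beta-value matrix; cells with zero coverage are `NA`.
#' @export
counts_to_beta <- function(methylated, coverage,
                           squeeze_mode = c("clip", "smithson"), eps = 1e-6) {
  if (!identical(dim(methylated), dim(coverage))) stop("shape mismatch")
  if (any(methylated < 0, na.rm = TRUE) || any(coverage < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (any(methylated > coverage, na.rm = TRUE)) {
    stop("methylated counts exceed coverage")
  }
  b <- methylated / coverage
  b[!is.na(coverage) & coverage == 0] <- NA_real_
  dimnames(b) <- dimnames(methylated)
  squeeze_beta(b, method = match.arg(squeeze_mode), eps = eps)
}

check_matrix_design <- function(matrix, design) {
  if (!is.matrix(matrix)) stop("expected a features x samples matrix")
  if (ncol(matrix) != length(design$sample_ids)) {
    stop("matrix has ", ncol(matrix), " columns but design has ",
         length(design$sample_ids), " samples")
  }
  if (!is.null(colnames(matrix)) &&
      !identical(colnames(matrix), design$sample_ids)) {
    stop("matrix column names do not match design sample IDs (same order required)")
  }
  invisible(TRUE)
}
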