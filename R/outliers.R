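#' Outlier-calling configuration
#'
#' Quantile cutoffs and the informativeness filter used to turn a scaled
#' expression matrix into binary high/low outlier matrices. Defaults follow
#' the analysis the package implements: 10%/90% quantiles, genes with fewer
#' than 10 outliers across samples discarded.
#'
#' @param q_low Lower quantile in (0, 0.5); values strictly below this
#'   per-gene cutoff are low outliers.
#' @param q_high Upper quantile in (0.5, 1); values strictly above this
#'   per-gene cutoff are high outliers.
#' @param min_outliers Genes with fewer outliers than this across all
#'   samples are dropped as uninformative.
#' @param quantile_scope `"per_batch"` (cutoffs per gene within each batch,
#'   matching the per-batch scaling) or `"pooled"` (per gene across the
#'   concatenated cohort).
#' @return A list of class `outlier_config`.
#' @export
outlier_config <- function(q_low = 0.10, q_high = 0.90, min_outliers = 10L,
                           quantile_scope = c("per_batch", "pooled")) {
  quantile_scope <- match.arg(quantile_scope)
  if (!(q_low > 0 && q_low < 0.5)) abort("`q_low` must be in (0, 0.5).")
  if (!(q_high > 0.5 && q_high < 1)) abort("`q_high` must be in (0.5, 1).")
  if (q_low >= q_high) abort("`q_low` must be smaller than `q_high`.")
  if (min_outliers < 0) abort("`min_outliers` must be >= 0.")
  structure(list(q_low = q_low, q_high = q_high,
                 min_outliers = as.integer(min_outliers),
                 quantile_scope = quantile_scope),
            class = "outlier_config")
}

#' COPA-style robust scaling per gene within batch
#'
#' Each gene is median-centred and divided by its raw median absolute
#' deviation (no 1.4826 consistency factor), separately within every batch
#' so that platform/sub-cohort distribution differences do not leak into
#' the outlier calls. Genes missing in more than `max_missing` of the
#' samples of any batch are dropped with a warning; a gene whose MAD is 0
#' in a batch is flagged degenerate there and its scaled values set `NA`
#' (excluded from outlier calling in that batch).
#'
#' @param x An [expr_mat] of log2 expression.
#' @param mad_constant Multiplier applied to the raw MAD; 1 keeps the raw
#'   MAD of the transformation this scaling follows, 1.4826 would make it
#'   consistent for a Gaussian scale.
#' @param max_missing Maximum tolerated fraction of missing values per
#'   gene within a batch.
#' @return A list of class `robust_scaled`: `scaled` (an [expr_mat] of
#'   scaled values), `params` (tibble gene_id, batch, median, mad,
#'   degenerate) and `dropped` (gene ids removed for missingness).
#' @export
robust_scale <- function(x, mad_constant = 1, max_missing = 0.2) {
  stopifnot(inherits(x, "expr_mat"))
  batches <- unique(x$batch)
  miss_frac <- sapply(batches, function(b) {
    rowMeans(is.na(x$values[, x$batch == b, drop = FALSE]))
  })
  dropped <- rownames(x$values)[apply(as.matrix(miss_frac), 1, max) > max_missing]
  if (length(dropped)) {
    warn(sprintf("Dropping %d gene(s) missing in > %d%% of samples in some batch: %s",
                 length(dropped), round(100 * max_missing),
                 paste(head(dropped, 5), collapse = ", ")))
  }
  vals <- x$values[setdiff(rownames(x$values), dropped), , drop = FALSE]
  scaled <- vals
  params <- vector("list", length(batches))
  for (i in seq_along(batches)) {
    b <- batches[[i]]
    idx <- x$batch == b
    sub <- vals[, idx, drop = FALSE]
    n_ok <- rowSums(!is.na(sub))
    if (any(n_ok < 3)) {
      abort(sprintf("Gene(s) with fewer than 3 values in batch '%s': %s", b,
                    paste(head(rownames(sub)[n_ok < 3], 5), collapse = ", ")))
    }
    med <- apply(sub, 1, median, na.rm = TRUE)
    mad_raw <- apply(abs(sub - med), 1, median, na.rm = TRUE) * mad_constant
    degenerate <- mad_raw == 0
    sc <- (sub - med) / mad_raw
    sc[degenerate, ] <- NA_real_
    scaled[, idx] <- sc
    params[[i]] <- tibble(gene_id = rownames(sub), batch = b,
                          median = med, mad = mad_raw, degenerate = degenerate)
  }
  params <- bind_rows(params)
  if (any(params$degenerate)) {
    warn(sprintf("%d (gene, batch) pair(s) with MAD = 0 flagged degenerate.",
                 sum(params$degenerate)))
  }
  structure(list(scaled = expr_mat(scaled, batch = batch_of(x)),
                 params = params, dropped = dropped),
            class = "robust_scaled")
}

#' @export
print.robust_scaled <- function(x, ...) {
  cat(sprintf("<robust_scaled> %d genes x %d samples; %d degenerate (gene, batch) pairs\n",
              nrow(x$scaled$values), ncol(x$scaled$values), sum(x$params$degenerate)))
  invisible(x)
}

row_quantiles <- function(m, q) {
  apply(m, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else quantile(v, q, type = 7, names = FALSE)
  })
}

#' Call quantile outliers on a robust-scaled matrix
#'
#' Per gene (within the configured scope) the high cutoff is the `q_high`
#' quantile and the low cutoff the `q_low` quantile of the scaled values
#' (type-7 linear interpolation between order statistics). A value is a
#' high outlier iff strictly above the high cutoff, a low outlier iff
#' strictly below the low cutoff, so constant genes yield no outliers.
#' Missing/degenerate values are never outliers.
#'
#' @param scaled A `robust_scaled` object from [robust_scale()], or an
#'   [expr_mat] of already-scaled values.
#' @param config An [outlier_config()].
#' @return A list of class `outlier_pair`: binary matrices `B_high` and
#'   `B_low` (genes x samples) plus `config` provenance.
#' @export
call_outliers <- function(scaled, config = outlier_config()) {
  stopifnot(inherits(config, "outlier_config"))
  x <- if (inherits(scaled, "robust_scaled")) scaled$scaled else scaled
  stopifnot(inherits(x, "expr_mat"))
  vals <- x$values
  hi <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  lo <- hi
  scopes <- if (config$quantile_scope == "per_batch") unique(x$batch) else "pooled"
  for (b in scopes) {
    idx <- if (identical(b, "pooled")) rep(TRUE, ncol(vals)) else x$batch == b
    sub <- vals[, idx, drop = FALSE]
    cut_hi <- row_quantiles(sub, config$q_high)
    cut_lo <- row_quantiles(sub, config$q_low)
    hi[, idx] <- (!is.na(sub) & !is.na(cut_hi) & sub > cut_hi) * 1L
    lo[, idx] <- (!is.na(sub) & !is.na(cut_lo) & sub < cut_lo) * 1L
  }
  structure(list(B_high = hi, B_low = lo, config = config),
            class = "outlier_pair")
}

#' @export
print.outlier_pair <- function(x, ...) {
  cat(sprintf("<outlier_pair> high: %d genes, low: %d genes, %d samples; q = %.2f/%.2f\n",
              nrow(x$B_high), nrow(x$B_low), ncol(x$B_high),
              x$config$q_low, x$config$q_high))
  invisible(x)
}

#' Drop genes with too few outliers to support inference
#'
#' Applied independently to the high and low matrices: rows whose total
#' outlier count across samples is below `min_outliers` are removed.
#' Removed gene ids are retained as attributes `removed_high` /
#' `removed_low` for reporting.
#'
#' @param pair An `outlier_pair` from [call_outliers()].
#' @param min_outliers Minimum row sum; defaults to the pair's config.
#' @return A filtered `outlier_pair`.
#' @export
filter_informative <- function(pair, min_outliers = NULL) {
  stopifnot(inherits(pair, "outlier_pair"))
  min_outliers <- min_outliers %||% pair$config$min_outliers
  keep_hi <- rowSums(pair$B_high) >= min_outliers
  keep_lo <- rowSums(pair$B_low) >= min_outliers
  out <- structure(list(B_high = pair$B_high[keep_hi, , drop = FALSE],
                        B_low = pair$B_low[keep_lo, , drop = FALSE],
                        config = pair$config),
                   class = "outlier_pair")
  attr(out, "removed_high") <- rownames(pair$B_high)[!keep_hi]
  attr(out, "removed_low") <- rownames(pair$B_low)[!keep_lo]
  out
}

#' Tidy an outlier pair into sparse triplet form
#'
#' @param x An `outlier_pair`.
#' @param ... Unused.
#' @return Tibble (gene_id, sample_id, direction) with one row per flag.
#' @exportS3Method generics::tidy
tidy.outlier_pair <- function(x, ...) {
  trip <- function(m, dir) {
    w <- which(m == 1L, arr.ind = TRUE)
    tibble(gene_id = rownames(m)[w[, 1]], sample_id = colnames(m)[w[, 2]],
           direction = dir)
  }
  bind_rows(trip(x$B_high, "high"), trip(x$B_low, "low")) |>
    arrange(.data$direction, .data$gene_id, .data$sample_id)
}
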