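#' Expression matrix with per-sample batch labels
#'
#' `expr_mat` is the package's container for a genes-by-samples matrix of
#' log2 expression values together with the batch (sub-cohort) each sample
#' came from. Batches are kept because robust scaling and outlier cutoffs
#' are computed within batch to avoid distribution biases between
#' platforms or institutions.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   complete, unique dimnames. Values are expected on the log2 scale;
#'   missing measurements are `NA`.
#' @param batch Character vector of batch labels, one per sample. Either
#'   named by sample id or in column order.
#' @return An object of class `expr_mat`: a list with elements `values`
#'   (the matrix) and `batch` (named character vector, one entry per sample).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' x <- expr_mat(m, batch = c(s1 = "K", s2 = "K"))
#' x
#' @export
expr_mat <- function(values, batch) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene row names and sample column names.")
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("Duplicate gene ids: ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (is.null(names(batch))) {
    if (length(batch) == 1L) batch <- rep(batch, length(sample_ids))
    if (length(batch) != length(sample_ids)) {
      abort("`batch` must have one label per sample.")
    }
    names(batch) <- sample_ids
  }
  if (!setequal(names(batch), sample_ids) || anyNA(batch)) {
    abort("Every sample must have exactly one batch label.")
  }
  structure(list(values = values, batch = as.character(batch[sample_ids])),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples, %d batch(es): %s\n",
              nrow(x$values), ncol(x$values), length(unique(x$batch)),
              paste(unique(x$batch), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample ids of an expression matrix
#' @param x An [expr_mat].
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Batch label per sample
#' @param x An [expr_mat].
#' @return Named character vector, one label per sample, in column order.
#' @export
batch_of <- function(x) setNames(x$batch, colnames(x$values))

#' @exportS3Method tibble::as_tibble
as_tibble.expr_mat <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    batch = rep(x$batch, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

path_connection <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a tab-delimited expression table
#'
#' Expects a header row of sample ids, a first column of probe/gene ids,
#' and numeric cells (empty cells and `NA` are recorded as missing).
#' Gzipped files are accepted. All samples in one file receive the same
#' batch label; read each batch from its own file and combine with
#' [merge_batches()].
#'
#' @param path Path to a tab-delimited file (optionally `.gz`).
#' @param batch_label Single batch label applied to every sample.
#' @return An [expr_mat].
#' @export
read_expression_table <- function(path, batch_label) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  con <- path_connection(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  if (length(lines) < 1L) abort("Empty expression table.")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) == 0L) abort("Expression table has no sample columns.")
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample ids in header: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  cells <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(cells, `[[`, character(1), 1L)
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(sample_ids),
                dimnames = list(ids, sample_ids))
  for (i in seq_along(cells)) {
    row <- cells[[i]][-1L]
    length(row) <- length(sample_ids)      # ragged short rows -> missing
    missing <- is.na(row) | row == "" | row == "NA"
    vals <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(vals) & !missing)
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' at row %d (gene '%s'), column %d ('%s').",
                    row[bad[1]], i, ids[i], bad[1], sample_ids[bad[1]]))
    }
    mat[i, ] <- vals
  }
  expr_mat(mat, batch = batch_label)
}

#' Write an expression matrix as a tab-delimited table
#'
#' Inverse of [read_expression_table()]: full-precision values so a
#' write/read round trip reproduces the matrix exactly.
#'
#' @param x An [expr_mat].
#' @param path Output path (`.gz` for compressed output).
#' @param id_column Name used for the first (id) column header.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, id_column = "gene_id") {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  vals <- format(x$values, digits = 17, trim = TRUE, scientific = FALSE)
  vals[is.na(x$values)] <- "NA"
  writeLines(paste(c(id_column, colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(rownames(x$values),
                   apply(vals, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probes map to the same gene, the probe with the highest
#' median expression across samples (computed on available values) is
#' retained and renamed to the gene id. Ties go to the lexicographically
#' smallest probe id, so the result is deterministic.
#'
#' @param x An [expr_mat] whose rows are probe ids.
#' @param probe_map Data frame with columns `probe_id` and `gene_id`
#'   (many probes to one gene).
#' @return An [expr_mat] with one row per gene, rows sorted by gene id.
#' @export
collapse_probes <- function(x, probe_map) {
  probe_map <- as_tibble(probe_map)
  if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
    abort("`probe_map` needs columns `probe_id` and `gene_id`.")
  }
  if (anyDuplicated(probe_map$probe_id)) {
    abort("`probe_map` maps some probe to more than one gene.")
  }
  probes <- rownames(x$values)
  missing <- setdiff(probes, probe_map$probe_id)
  if (length(missing)) {
    abort(paste0("Probes absent from map: ", paste(missing, collapse = ", ")))
  }
  med <- apply(x$values, 1, median, na.rm = TRUE)
  pick <- tibble(probe_id = probes, med = med) |>
    left_join(probe_map, by = "probe_id") |>
    arrange(.data$gene_id, dplyr::desc(.data$med), .data$probe_id) |>
    group_by(.data$gene_id) |>
    slice(1L) |>
    ungroup() |>
    arrange(.data$gene_id)
  out <- x$values[pick$probe_id, , drop = FALSE]
  rownames(out) <- pick$gene_id
  expr_mat(out, batch = batch_of(x))
}

#' Concatenate per-batch expression matrices over samples
#'
#' The merged gene set is the intersection of the inputs' gene sets
#' (only genes measured on every platform are comparable); samples are
#' concatenated in input order, keeping their batch labels.
#'
#' @param matrices List of [expr_mat] objects (at least one).
#' @return A single [expr_mat].
#' @export
merge_batches <- function(matrices) {
  if (!length(matrices)) abort("Need at least one matrix.")
  stopifnot(all(vapply(matrices, inherits, logical(1), "expr_mat")))
  if (length(matrices) == 1L) return(matrices[[1L]])
  genes <- Reduce(intersect, lapply(matrices, gene_ids))
  if (!length(genes)) abort("No genes shared by all batches.")
  all_samples <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(all_samples)) {
    abort(paste0("Sample ids collide across batches: ",
                 paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")))
  }
  vals <- do.call(cbind, lapply(matrices, function(m) m$values[genes, , drop = FALSE]))
  expr_mat(vals, batch = unlist(lapply(matrices, batch_of)))
}

#' Read gene annotation (symbol, chromosome, span, cytoband)
#'
#' Tab-delimited with header columns `gene_id`, `chrom`, `start`, `end`,
#' `cytoband`. Coordinates are 1-based inclusive base pairs; printed
#' thousands separators (commas) are accepted. Records are validated
#' (`start <= end`, unique gene ids) and returned sorted by
#' (chrom, start).
#'
#' @param path Path to the annotation file (optionally `.gz`).
#' @return Tibble with columns gene_id, chrom, start, end, cytoband.
#' @export
read_gene_annotation <- function(path) {
  con <- path_connection(path)
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), cytoband = character())
  if (length(lines) <= 1L) return(empty)
  df <- readr::read_tsv(I(lines), col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(df))) {
    abort(paste0("Annotation needs columns: ", paste(need, collapse = ", ")))
  }
  if (!"cytoband" %in% names(df)) df$cytoband <- NA_character_
  df <- df |>
    mutate(start = as.numeric(gsub(",", "", .data$start, fixed = TRUE)),
           end = as.numeric(gsub(",", "", .data$end, fixed = TRUE)))
  if (anyNA(df$start) || anyNA(df$end)) abort("Non-numeric start/end coordinate.")
  bad <- df$gene_id[df$start > df$end]
  if (length(bad)) {
    abort(paste0("start > end for: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("Duplicate annotation records: ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  df |>
    select("gene_id", "chrom", "start", "end", "cytoband") |>
    arrange(.data$chrom, .data$start)
}

#' Sort an annotation tibble by genomic position
#' @param annotation Tibble as returned by [read_gene_annotation()].
#' @return The same tibble ordered by (chrom, start, gene_id).
#' @export
sort_annotation <- function(annotation) {
  as_tibble(annotation) |> arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Read a clinical table
#'
#' Comma-separated with header. Required: `sample_id`, `time` (follow-up,
#' years), `event` (0/1). Recognised covariates: `age`, `tumor_size`,
#' `grade` (low/intermediate/high), `node_negative`, `her2`, `er`.
#' Missing covariate values stay `NA` — they are flagged by downstream
#' models, never imputed.
#'
#' @param path Path to the CSV file (optionally `.gz`).
#' @return Tibble, one row per sample.
#' @export
read_clinical_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE)
  validate_clinical(df)
}

validate_clinical <- function(df) {
  df <- as_tibble(df)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    abort(paste0("Clinical table needs columns: ", paste(need, collapse = ", ")))
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("Duplicate sample ids in clinical table.")
  if (any(df$time < 0, na.rm = TRUE)) abort("Negative follow-up time.")
  if (!all(df$event %in% c(0, 1, NA))) abort("`event` must be 0/1.")
  if ("grade" %in% names(df)) {
    ok <- c("low", "intermediate", "high")
    bad <- setdiff(unique(df$grade[!is.na(df$grade)]), ok)
    if (length(bad)) {
      abort(paste0("Unknown grade label(s): ", paste(bad, collapse = ", "),
                   " (expected low/intermediate/high)"))
    }
    df$grade <- factor(df$grade, levels = ok)
  }
  df
}
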