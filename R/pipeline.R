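#' End-to-end amplicon discovery pipeline
#'
#' Runs the full analysis on an assembled cohort: per-batch robust
#' scaling, quantile outlier calling, the informativeness filter, the
#' per-gene outlier-vs-normal survival screen, phi pruning and clustering
#' of the screened high-outlier genes, sliding-window enrichment of the
#' poor-prognosis cluster to define amplicon regions, per-sample presence
#' calls, and carrier-vs-amplicon-free survival stratification. Stages
#' degrade gracefully: a run with no screened or no clustered genes
#' returns an empty amplicon list rather than failing.
#'
#' @param expression An [expr_mat] (merged over batches).
#' @param annotation Annotation tibble covering the expression genes.
#' @param clinical Clinical tibble covering the expression samples.
#' @param outlier_cfg An [outlier_config()].
#' @param prune_cfg A [prune_config()].
#' @param window_cfg A [window_config()].
#' @param alpha Log-rank screen significance level.
#' @param odx_weights Optional `odx_weights` table; when supplied (and all
#'   panel genes are present) relative recurrence scores are computed.
#' @return Object of class `amplicon_pipeline` with elements `screen`,
#'   `clusters` (may be `NULL`), `amplicons`, `calls`, `outcomes` (may be
#'   `NULL` when no amplicon was found), `scores` (optional), `params`.
#'   `tidy()` returns the amplicon table, `glance()` a one-row summary.
#' @export
run_amplicon_pipeline <- function(expression, annotation, clinical,
                                  outlier_cfg = outlier_config(),
                                  prune_cfg = prune_config(),
                                  window_cfg = window_config(),
                                  alpha = 0.05,
                                  odx_weights = NULL) {
  stopifnot(inherits(expression, "expr_mat"))
  annotation <- sort_annotation(annotation)
  clinical <- validate_clinical(clinical)
  missing_ann <- setdiff(gene_ids(expression), annotation$gene_id)
  if (length(missing_ann)) {
    abort(paste0("Genes without annotation: ",
                 paste(head(missing_ann, 5), collapse = ", ")))
  }
  scaled <- robust_scale(expression)
  pair <- call_outliers(scaled, outlier_cfg)
  pair_f <- filter_informative(pair)
  screen <- outlier_survival_screen(pair_f, clinical, alpha = alpha)

  hi_genes <- screen |> filter(.data$direction == "high") |> pull("gene_id")
  clusters <- NULL
  amplicons <- empty_amplicons()
  if (length(hi_genes) >= 2) {
    B <- pair_f$B_high[hi_genes, , drop = FALSE]
    retained <- prune_correlation_graph(phi_matrix(B), prune_cfg)
    if (length(retained) >= 2) {
      clusters <- pca_clusters(B[retained, , drop = FALSE], screen, prune_cfg)
      poor <- cluster_genes(clusters, "poor")
      if (length(poor)) {
        amplicons <- define_amplicons(poor, annotation, window_cfg,
                                      universe = gene_ids(expression))
      }
    }
  }
  calls <- call_amplicons_per_sample(pair$B_high, amplicons)
  outcomes <- if (nrow(amplicons)) stratified_outcome(calls, clinical) else NULL
  scores <- NULL
  if (!is.null(odx_weights)) {
    scores <- dichotomize_score(relative_odx_score(expression, odx_weights))
  }
  structure(list(screen = screen, clusters = clusters, amplicons = amplicons,
                 calls = calls, outcomes = outcomes, scores = scores,
                 params = list(outlier = outlier_cfg, prune = prune_cfg,
                               window = window_cfg, alpha = alpha)),
            class = "amplicon_pipeline")
}

empty_amplicons <- function() {
  tibble(name = character(), chrom = character(), start_idx = integer(),
         end_idx = integer(), span_start = numeric(), span_end = numeric(),
         n_markers = integer(), markers = list(), q_min = numeric())
}

#' @export
print.amplicon_pipeline <- function(x, ...) {
  cat(sprintf("<amplicon_pipeline> %d screened gene(s), %d amplicon(s)\n",
              nrow(x$screen), nrow(x$amplicons)))
  if (nrow(x$amplicons)) print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.amplicon_pipeline <- function(x, ...) {
  x$amplicons |> select(-"markers")
}

#' @exportS3Method generics::glance
glance.amplicon_pipeline <- function(x, ...) {
  any_row <- if (!is.null(x$outcomes)) {
    x$outcomes |> filter(.data$amplicon == "any_amplicon")
  } else NULL
  tibble(n_samples = nrow(x$calls),
         n_screened = nrow(x$screen),
         n_clustered = if (is.null(x$clusters)) 0L else nrow(x$clusters$genes),
         n_amplicons = nrow(x$amplicons),
         n_any_carrier = sum(x$calls$any_amplicon),
         any_amplicon_hr = if (!is.null(any_row) && nrow(any_row))
           any_row$hazard_ratio else NA_real_,
         any_amplicon_p = if (!is.null(any_row) && nrow(any_row))
           any_row$p_value else NA_real_)
}

#' Write the pipeline's stage outputs to a directory
#'
#' Emits tab-separated tables for each stage (screen, clusters, amplicon
#' definitions in BED-like form with 0-based half-open coordinates, calls,
#' outcomes, scores) plus a JSON summary with the parameters used.
#'
#' @param x An `amplicon_pipeline`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(x, dir) {
  stopifnot(inherits(x, "amplicon_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")))
  }
  w(x$screen, "screen")
  if (!is.null(x$clusters)) w(x$clusters$genes, "clusters")
  bed <- x$amplicons |>
    mutate(bed_start = .data$span_start - 1,  # 1-based inclusive -> 0-based half-open
           markers = vapply(.data$markers, paste, character(1), collapse = ",")) |>
    select("chrom", "bed_start", span_end_bed = "span_end", "name", "markers")
  w(bed, "amplicons")
  w(x$calls, "calls")
  if (!is.null(x$outcomes)) w(x$outcomes, "outcomes")
  if (!is.null(x$scores)) w(x$scores, "scores")
  summary <- list(
    n_amplicons = nrow(x$amplicons),
    amplicons = x$amplicons$name,
    outcomes = if (!is.null(x$outcomes)) x$outcomes else list(),
    params = list(q_low = x$params$outlier$q_low,
                  q_high = x$params$outlier$q_high,
                  min_outliers = x$params$outlier$min_outliers,
                  alpha = x$params$alpha,
                  tau = x$params$prune$tau,
                  window_width = x$params$window$width,
                  window_pace = x$params$window$pace,
                  fdr = x$params$window$fdr))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
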