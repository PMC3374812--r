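#' Sliding-window configuration for chromosomal enrichment
#' @param width Window width in genes.
#' @param pace Step between window starts, in genes (`1 <= pace <= width`).
#' @param fdr Benjamini-Hochberg FDR level for calling significant windows.
#' @return A list of class `window_config`.
#' @export
window_config <- function(width = 25L, pace = 5L, fdr = 0.05) {
  width <- as.integer(width); pace <- as.integer(pace)
  if (pace < 1L || pace > width) abort("Need 1 <= pace <= width.")
  if (!(fdr > 0 && fdr < 1)) abort("`fdr` must be in (0, 1).")
  structure(list(width = width, pace = pace, fdr = fdr), class = "window_config")
}

#' Build sliding windows over position-sorted genes
#'
#' Per chromosome, windows of `width` genes start every `pace` genes; a
#' final window anchored to the chromosome end is added when needed so
#' every gene is covered. Chromosomes with fewer genes than `width` yield
#' a single window spanning all their genes. Gene indices below are
#' 1-based positions within the chromosome's (start-sorted) gene order.
#'
#' @param annotation Annotation tibble (gene_id, chrom, start, end,
#'   cytoband); sorted internally.
#' @param config A [window_config()].
#' @return Tibble (window_id, chrom, start_idx, end_idx, n_genes, genes
#'   list-column, span_start, span_end).
#' @export
make_windows <- function(annotation, config = window_config()) {
  stopifnot(inherits(config, "window_config"))
  ann <- sort_annotation(annotation)
  out <- ann |>
    group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      n <- nrow(df)
      w <- min(config$width, n)
      starts <- as.integer(seq(1L, by = config$pace,
                               length.out = max(1L, (n - w) %/% config$pace + 1L)))
      if (tail(starts, 1L) + w - 1L < n) starts <- c(starts, n - w + 1L)
      tibble(chrom = key$chrom, start_idx = starts, end_idx = starts + w - 1L,
             n_genes = w,
             genes = lapply(starts, function(s) df$gene_id[s:(s + w - 1L)]),
             span_start = df$start[starts], span_end = df$end[starts + w - 1L])
    }) |>
    bind_rows()
  out |> mutate(window_id = paste0(.data$chrom, ":", .data$start_idx, "-",
                                   .data$end_idx), .before = 1)
}

#' One-sided Fisher exact (hypergeometric) enrichment of a gene set
#'
#' The enrichment p-value is the upper hypergeometric tail at the observed
#' overlap: the probability of drawing at least `k` set genes when `n`
#' target genes are sampled from a universe of `N` containing `K` set
#' genes — identical to the one-sided Fisher exact test on the 2x2 table.
#'
#' @param target_genes Genes being tested (e.g. a window's genes).
#' @param set_genes The gene set of interest (e.g. an outlier cluster).
#' @param universe All analysable genes; both arguments must be subsets.
#' @return One-row tibble (k, K, n, N, p_value).
#' @export
hypergeometric_enrichment <- function(target_genes, set_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("Empty universe.")
  target_genes <- unique(target_genes); set_genes <- unique(set_genes)
  if (length(setdiff(target_genes, universe)) || length(setdiff(set_genes, universe))) {
    abort("`target_genes` and `set_genes` must be subsets of `universe`.")
  }
  N <- length(universe); K <- length(set_genes); n <- length(target_genes)
  k <- length(intersect(target_genes, set_genes))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(k = k, K = K, n = n, N = N, p_value = min(p, 1))
}

#' Benjamini-Hochberg step-up adjusted q-values
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of monotone q-values capped at 1 (`stats::p.adjust`,
#'   method `"BH"`).
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must be in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Define amplicon regions from a gene cluster by window enrichment
#'
#' Every window is tested for enrichment of the cluster's genes against
#' the universe; p-values are BH-adjusted genome-wide across all windows;
#' windows with `q < fdr` that overlap on the same chromosome are merged
#' by interval union. The merged region's marker genes are the cluster
#' genes falling inside the merged index span, and regions are named by
#' their spanned cytobands.
#'
#' @param genes Cluster gene ids (typically the poor-prognosis cluster).
#' @param annotation Annotation tibble for the full universe.
#' @param config A [window_config()].
#' @param universe Universe gene ids; defaults to all annotated genes.
#' @return Tibble of class in spirit "amplicon definitions": (name, chrom,
#'   start_idx, end_idx, span_start, span_end, n_markers, markers
#'   list-column, q_min). Zero rows when nothing is significant. The full
#'   per-window enrichment table is attached as attribute `"enrichment"`.
#' @export
define_amplicons <- function(genes, annotation, config = window_config(),
                             universe = NULL) {
  ann <- sort_annotation(annotation)
  universe <- universe %||% ann$gene_id
  genes <- intersect(unique(genes), universe)
  if (!length(genes)) abort("Empty cluster gene set.")
  windows <- make_windows(ann |> filter(.data$gene_id %in% universe), config)
  cluster_set <- genes
  enr <- bind_cols(
    windows,
    purrr::map_dfr(windows$genes, function(gs) {
      hypergeometric_enrichment(gs, cluster_set, universe)
    })) |>
    mutate(q_value = bh_adjust(.data$p_value))
  sig <- enr |> filter(.data$q_value < config$fdr)
  empty <- tibble(name = character(), chrom = character(),
                  start_idx = integer(), end_idx = integer(),
                  span_start = numeric(), span_end = numeric(),
                  n_markers = integer(), markers = list(), q_min = numeric())
  attr(empty, "enrichment") <- enr |> select(-"genes")
  if (!nrow(sig)) return(empty)
  merged <- sig |>
    group_by(.data$chrom) |>
    arrange(.data$start_idx, .by_group = TRUE) |>
    mutate(new_run = cumsum(.data$start_idx > cummax(dplyr::lag(.data$end_idx,
                                                                default = 0L)))) |>
    group_by(.data$chrom, .data$new_run) |>
    summarise(start_idx = min(.data$start_idx), end_idx = max(.data$end_idx),
              q_min = min(.data$q_value), .groups = "drop")
  per_chrom <- split(ann[ann$gene_id %in% universe, ], ~chrom)
  rows <- purrr::pmap(merged, function(chrom, new_run, start_idx, end_idx, q_min) {
    df <- per_chrom[[chrom]]
    span <- df[start_idx:end_idx, ]
    markers <- intersect(span$gene_id, genes)
    mk <- span |> filter(.data$gene_id %in% markers)
    tibble(name = cytoband_span_name(chrom, mk$cytoband),
           chrom = chrom, start_idx = start_idx, end_idx = end_idx,
           span_start = min(mk$start), span_end = max(mk$end),
           n_markers = length(markers), markers = list(markers), q_min = q_min)
  })
  out <- bind_rows(rows) |> arrange(.data$chrom, .data$start_idx)
  attr(out, "enrichment") <- enr |> select(-"genes")
  out
}

# "8q24.3" for a single band, "17q21.33-q25.1" for a span; accepts
# cytoband strings with or without the chromosome prefix and falls back
# to the chromosome name when cytobands are unannotated.
cytoband_span_name <- function(chrom, cytobands) {
  chrom_clean <- sub("^chr", "", chrom)
  cb <- unique(cytobands[!is.na(cytobands)])
  cb <- sub("^chr", "", cb)
  cb <- cb[nzchar(cb)]
  if (!length(cb)) return(chrom_clean)
  full <- ifelse(grepl(paste0("^", chrom_clean, "[pq]"), cb),
                 cb, paste0(chrom_clean, cb))
  if (length(full) == 1L) return(full)
  paste0(full[1L], "-", sub(paste0("^", chrom_clean), "", full[length(full)]))
}

#' Call amplicon presence per sample from high-outlier flags
#'
#' A sample carries an amplicon iff at least half of the amplicon's marker
#' genes are flagged as high outliers in that sample. An `any_amplicon`
#' column (logical OR over amplicons) is added, and per-amplicon carrier
#' frequencies are attached, ordered by descending frequency.
#'
#' @param B_high Binary high-outlier matrix (genes x samples) containing
#'   all marker genes.
#' @param amplicons Amplicon definition tibble from [define_amplicons()].
#' @param min_fraction Fraction of markers required (default 0.5).
#' @return Tibble (sample_id, one 0/1 column per amplicon name,
#'   any_amplicon), with attribute `"frequencies"`.
#' @export
call_amplicons_per_sample <- function(B_high, amplicons, min_fraction = 0.5) {
  if (!nrow(amplicons)) {
    out <- tibble(sample_id = colnames(B_high), any_amplicon = 0L)
    attr(out, "frequencies") <- tibble(amplicon = character(), n_carriers = integer(),
                                       frequency = numeric())
    return(out)
  }
  calls <- purrr::map(seq_len(nrow(amplicons)), function(i) {
    markers <- amplicons$markers[[i]]
    if (!length(markers)) abort(paste0("Amplicon without markers: ", amplicons$name[i]))
    absent <- setdiff(markers, rownames(B_high))
    if (length(absent)) {
      abort(paste0("Marker genes absent from B_high: ", paste(absent, collapse = ", ")))
    }
    sub <- B_high[markers, , drop = FALSE]
    as.integer(colSums(sub) / length(markers) >= min_fraction)
  })
  names(calls) <- amplicons$name
  out <- tibble(sample_id = colnames(B_high)) |> bind_cols(as_tibble(calls))
  out$any_amplicon <- as.integer(rowSums(out[amplicons$name]) > 0)
  freq <- tibble(amplicon = amplicons$name,
                 n_carriers = vapply(calls, sum, integer(1)),
                 frequency = vapply(calls, mean, numeric(1))) |>
    arrange(dplyr::desc(.data$frequency))
  attr(out, "frequencies") <- freq
  out
}

#' Survival stratified by amplicon presence
#'
#' For each amplicon (and for `any_amplicon`), carriers are compared
#' against the samples carrying **zero** amplicons — not merely
#' non-carriers of that amplicon — by log-rank test and univariate Cox
#' hazard ratio. Optionally restricted to a histologic grade stratum.
#'
#' @param calls Call tibble from [call_amplicons_per_sample()].
#' @param clinical Clinical tibble covering the called samples.
#' @param grade_stratum Optional grade label (`"low"`, `"intermediate"`,
#'   `"high"`) to restrict the comparison to.
#' @return Tibble (amplicon, n_carrier, n_none, hazard_ratio, hr_low,
#'   hr_high, logrank_stat, p_value); Kaplan-Meier curves for both arms
#'   are attached as attribute `"km"` (a named list).
#' @export
stratified_outcome <- function(calls, clinical, grade_stratum = NULL) {
  clinical <- as_tibble(clinical)
  dat <- calls |> left_join(clinical, by = "sample_id")
  if (anyNA(dat$time)) abort("Calls and clinical table do not align.")
  if (!is.null(grade_stratum)) {
    dat <- dat |> filter(!is.na(.data$grade), .data$grade == grade_stratum)
    if (!nrow(dat)) abort("Empty grade stratum.")
  }
  amp_names <- setdiff(names(calls), c("sample_id", "any_amplicon"))
  targets <- c(amp_names, "any_amplicon")
  km_list <- list()
  rows <- purrr::map(targets, function(a) {
    carrier <- dat[[a]] == 1
    none <- dat$any_amplicon == 0
    if (!any(carrier)) abort(paste0("Amplicon with zero carriers: ", a))
    if (!any(none)) abort("No amplicon-free samples to compare against.")
    sub <- dat[carrier | none, ]
    grp <- ifelse(sub[[a]] == 1, "carrier", "none")
    if (sum(sub$event) == 0) abort(paste0("No events in comparison for ", a))
    lr <- log_rank_test(sub$time, sub$event, grp)
    fit <- survival::coxph(survival::Surv(sub$time, sub$event) ~ I(grp == "carrier"),
                           ties = "efron")
    ci <- exp(stats::confint(fit))
    km_list[[a]] <<- list(carrier = km_estimate(sub$time[grp == "carrier"],
                                                sub$event[grp == "carrier"]),
                          none = km_estimate(sub$time[grp == "none"],
                                             sub$event[grp == "none"]))
    tibble(amplicon = a, n_carrier = sum(carrier), n_none = sum(none),
           hazard_ratio = unname(exp(stats::coef(fit))),
           hr_low = ci[1], hr_high = ci[2],
           logrank_stat = lr$statistic, p_value = lr$p_value)
  })
  out <- bind_rows(rows)
  attr(out, "km") <- km_list
  out
}
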