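#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-batch log2 expression cohort with heavy right tails,
#' planted contiguous amplicon blocks over-expressed in a carrier subset,
#' a diffuse "cell-cycle" gene set co-elevated in carriers, and survival
#' times whose hazard is multiplied per carried amplicon, with
#' independent censoring.
#'
#' @param n_genes Total genes, spread evenly over `n_chromosomes`.
#' @param n_chromosomes Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param batches Named integer vector of batch sizes.
#' @param amplicons Tibble/data frame with columns `chrom`, `start_idx`,
#'   `end_idx` (1-based gene indices within the chromosome), `prevalence`,
#'   `delta` (shift in MAD units of the background) and `hr` (true hazard
#'   ratio per carried amplicon). Spans must be disjoint.
#' @param cellcycle_size Number of diffuse proliferation genes scattered
#'   outside the amplicon spans.
#' @param cellcycle_prob Probability that a given cell-cycle gene is
#'   co-elevated in a given amplicon-carrier sample.
#' @param baseline_hazard Baseline event hazard per year.
#' @param censoring_rate Target fraction of censored samples; the uniform
#'   censoring horizon is solved from it.
#' @param df Degrees of freedom of the t-distributed background noise
#'   (heavy tails so outliers exist even without planted signal).
#' @param batch_shift,batch_scale Per-batch location/scale multipliers
#'   (recycled over batches) emulating platform differences.
#' @param dosage_range Per-carrier copy-number dosage multiplier range;
#'   the amplicon shift of one carrier is `delta * dosage` on every span
#'   gene, so marker over-expression co-occurs within a sample.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_chromosomes = 10L,
                       batches = c(KIT = 100L, OXFT = 100L, GUYT = 100L),
                       amplicons = tibble(
                         chrom = c("chr1", "chr2"),
                         start_idx = c(51L, 101L), end_idx = c(75L, 125L),
                         prevalence = 0.25, delta = 4, hr = 4),
                       cellcycle_size = 50L, cellcycle_prob = 0.6,
                       baseline_hazard = 0.03, censoring_rate = 0.30,
                       df = 5, batch_shift = c(0, 0.3, -0.3),
                       batch_scale = c(1, 1.15, 0.9),
                       dosage_range = c(0.7, 1.3)) {
  amplicons <- as_tibble(amplicons)
  stopifnot(all(c("chrom", "start_idx", "end_idx", "prevalence", "delta", "hr")
                %in% names(amplicons)))
  if (any(amplicons$prevalence <= 0 | amplicons$prevalence >= 1)) {
    abort("Prevalence must be in (0, 1).")
  }
  if (any(amplicons$delta <= 0) || any(amplicons$hr <= 0)) {
    abort("delta and hr must be positive.")
  }
  if (nrow(amplicons) > 1) {
    spans <- amplicons |> arrange(.data$chrom, .data$start_idx)
    same <- spans$chrom[-1] == spans$chrom[-nrow(spans)]
    if (any(same & spans$start_idx[-1] <= spans$end_idx[-nrow(spans)])) {
      abort("Amplicon spans overlap.")
    }
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 batches = batches, amplicons = amplicons,
                 cellcycle_size = as.integer(cellcycle_size),
                 cellcycle_prob = cellcycle_prob,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate, df = df,
                 batch_shift = batch_shift, batch_scale = batch_scale,
                 dosage_range = dosage_range),
            class = "sim_config")
}

# Uniform censoring horizon h with P(censored) = P(C < T) = target under
# the configured hazard mixture; for T ~ Exp(l), C ~ U(0, h) this is
# (1 - exp(-l h)) / (l h), decreasing in h.
censoring_horizon <- function(hazards, weights, target) {
  f <- function(h) {
    sum(weights * (1 - exp(-hazards * h)) / (hazards * h)) - target
  }
  if (f(500) > 0) return(500)
  uniroot(f, c(1e-3, 500))$root
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Background expression is t-distributed (heavy right tail) with
#' batch-specific location and scale. Carriers of each amplicon receive a
#' shift of `delta` background-MAD units (times a per-sample dosage) on
#' all span genes; cell-cycle genes are elevated gene-wise with the
#' configured probability in any carrier sample. Event times are
#' exponential with hazard `baseline * prod(hr over carried amplicons)`;
#' censoring is independent uniform. Fully reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed driving all randomness.
#' @return A list of class `sim_cohort`: `expression` ([expr_mat]),
#'   `annotation` (tibble), `clinical` (tibble) and `truth` (list with
#'   `amplicons` incl. carrier sets, `carriers` matrix, `cellcycle_genes`,
#'   `config`).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_genes <- config$n_genes
  n_samples <- sum(config$batches)
  per_chrom <- ceiling(n_genes / config$n_chromosomes)
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)),
               each = per_chrom, length.out = n_genes)
  idx_in_chrom <- stats::ave(seq_len(n_genes), chrom, FUN = seq_along)
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  start <- idx_in_chrom * 100000
  annotation <- tibble(gene_id = gene_id, chrom = chrom, start = start,
                       end = start + 50000,
                       cytoband = paste0(sub("^chr", "", chrom), "q",
                                         (idx_in_chrom - 1) %/% 25 + 1)) |>
    sort_annotation()

  batch <- rep(names(config$batches), times = config$batches)
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  shift <- rep(config$batch_shift, length.out = length(config$batches))
  scale <- rep(config$batch_scale, length.out = length(config$batches))
  vals <- matrix(rt(n_genes * n_samples, df = config$df), n_genes, n_samples,
                 dimnames = list(gene_id, sample_id))
  for (i in seq_along(config$batches)) {
    idx <- batch == names(config$batches)[i]
    vals[, idx] <- 7 + shift[i] + scale[i] * vals[, idx]
  }
  # theoretical MAD of the scaled-t background, per batch
  mad_bg <- setNames(qt(0.75, config$df) * scale, names(config$batches))

  amps <- config$amplicons
  amp_gene_sets <- purrr::pmap(amps, function(chrom, start_idx, end_idx, ...) {
    on_chrom <- annotation$gene_id[annotation$chrom == chrom]
    if (end_idx > length(on_chrom)) {
      abort(sprintf("Amplicon span %s:%d-%d exceeds the %d genes on %s.",
                    chrom, start_idx, end_idx, length(on_chrom), chrom))
    }
    on_chrom[start_idx:end_idx]
  })
  amp_names <- purrr::pmap_chr(amps, function(chrom, start_idx, end_idx, ...) {
    paste0(chrom, ":", start_idx, "-", end_idx)
  })
  carriers <- matrix(0L, n_samples, nrow(amps),
                     dimnames = list(sample_id, amp_names))
  for (a in seq_len(nrow(amps))) {
    carr <- runif(n_samples) < amps$prevalence[a]
    carriers[, a] <- as.integer(carr)
    if (any(carr)) {
      dosage <- runif(sum(carr), config$dosage_range[1], config$dosage_range[2])
      gset <- amp_gene_sets[[a]]
      shift_per_sample <- amps$delta[a] * dosage * mad_bg[batch[carr]]
      vals[gset, carr] <- vals[gset, carr] +
        rep(shift_per_sample, each = length(gset))
    }
  }

  non_amp <- setdiff(gene_id, unlist(amp_gene_sets))
  cellcycle <- sort(sample(non_amp, config$cellcycle_size))
  any_carrier <- rowSums(carriers) > 0
  if (any(any_carrier) && length(cellcycle)) {
    idx <- which(any_carrier)
    elev <- matrix(rbinom(length(cellcycle) * length(idx), 1,
                          config$cellcycle_prob),
                   length(cellcycle), length(idx))
    bump <- elev * rep(amps$delta[1] * mad_bg[batch[idx]],
                       each = length(cellcycle))
    vals[cellcycle, idx] <- vals[cellcycle, idx] + bump
  }

  hazard <- config$baseline_hazard *
    apply(carriers, 1, function(cr) prod(amps$hr^cr))
  event_time <- rexp(n_samples, rate = hazard)
  tab <- table(hazard)
  h <- censoring_horizon(as.numeric(names(tab)), as.vector(prop.table(tab)),
                         config$censoring_rate)
  cens_time <- runif(n_samples, 0, h)
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)
  clinical <- tibble(sample_id = sample_id, time = time, event = event,
                     age = round(runif(n_samples, 40, 80)),
                     tumor_size = sample(1:4, n_samples, replace = TRUE),
                     grade = sample(c("low", "intermediate", "high"),
                                    n_samples, replace = TRUE,
                                    prob = c(0.3, 0.45, 0.25)),
                     node_negative = rbinom(n_samples, 1, 0.6),
                     her2 = rbinom(n_samples, 1, 0.1),
                     er = 1L) |>
    validate_clinical()

  truth <- list(
    amplicons = amps |>
      mutate(name = amp_names, genes = amp_gene_sets,
             carriers = lapply(seq_len(nrow(amps)),
                               function(a) sample_id[carriers[, a] == 1])),
    carriers = carriers,
    cellcycle_genes = cellcycle,
    config = config, seed = seed)
  structure(list(expression = expr_mat(vals, batch = setNames(batch, sample_id)),
                 annotation = annotation, clinical = clinical, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d genes x %d samples, %d planted amplicon(s), seed %d\n",
              nrow(x$expression$values), ncol(x$expression$values),
              nrow(x$truth$amplicons), x$truth$seed))
  invisible(x)
}

#' Simulate FISH spot counts for a synthetic cohort
#'
#' Carriers of an amplicon draw mean spot counts one unit above the
#' region's presence cutoff plus Gaussian noise; non-carriers draw counts
#' around the diploid value 2.0. A small fraction of measurements drops
#' out as "no signal" (`NA`).
#'
#' @param truth The `truth` element of a [simulate_cohort()] result.
#' @param cutoffs Named per-amplicon presence cutoffs (defaults to 3.5
#'   for every planted amplicon).
#' @param noise_sd Gaussian noise on the mean counts; 0 gives perfect
#'   separation.
#' @param dropout Probability that a (sample, region) score is missing.
#' @param seed Integer seed.
#' @return Long tibble (sample_id, region, mean_count).
#' @export
simulate_fish_counts <- function(truth, cutoffs = NULL, noise_sd = 0.3,
                                 dropout = 0.02, seed = 1L) {
  set.seed(seed)
  amp_names <- truth$amplicons$name
  cutoffs <- cutoffs %||% 3.5
  if (is.null(names(cutoffs))) {
    cutoffs <- setNames(rep(cutoffs, length.out = length(amp_names)), amp_names)
  }
  samples <- rownames(truth$carriers)
  out <- purrr::map(amp_names, function(a) {
    carr <- truth$carriers[, a] == 1
    mu <- ifelse(carr, cutoffs[[a]] + 1, 2.0)
    counts <- pmax(mu + rnorm(length(mu), 0, noise_sd), 0)
    counts[runif(length(counts)) < dropout] <- NA_real_
    tibble(sample_id = samples, region = a, mean_count = counts)
  })
  bind_rows(out)
}
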