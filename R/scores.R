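#' Recurrence-score weight table
#'
#' Gene groups and weights for the relative, array-based analogue of the
#' 21-gene recurrence score. The default table shipped with the package
#' (`inst/extdata/odx_weights.yaml`) carries the published group weights
#' of Paik et al. (2004, N Engl J Med 351:2817-26) — reference-derived
#' values, editable by the user. Higher scores are oriented towards worse
#' prognosis: the proliferation group weight is positive, the hormonal
#' (ER) group weight negative.
#'
#' @param path Path to a YAML weight file with top-level keys `groups`
#'   (each with `genes` and `weight`) and `genes` (individual gene:
#'   weight pairs).
#' @return A list of class `odx_weights` with elements `groups` and
#'   `genes`.
#' @export
read_odx_weights <- function(path) {
  w <- yaml::read_yaml(path)
  if (is.null(w$groups)) abort("Weight file needs a `groups` key.")
  w$genes <- w$genes %||% list()
  all_genes <- c(unlist(lapply(w$groups, `[[`, "genes")), names(w$genes))
  if (anyDuplicated(all_genes)) {
    abort(paste0("Gene(s) in more than one group: ",
                 paste(unique(all_genes[duplicated(all_genes)]), collapse = ", ")))
  }
  stopifnot(all(is.finite(vapply(w$groups, `[[`, numeric(1), "weight"))))
  structure(list(groups = w$groups, genes = lapply(w$genes, as.numeric)),
            class = "odx_weights")
}

#' @rdname read_odx_weights
#' @export
default_odx_weights <- function() {
  read_odx_weights(system.file("extdata", "odx_weights.yaml",
                               package = "amplimark", mustWork = TRUE))
}

#' Genes referenced by a weight table
#' @param weights An `odx_weights` object.
#' @return Character vector of gene ids.
#' @export
odx_genes <- function(weights) {
  c(unlist(lapply(weights$groups, `[[`, "genes"), use.names = FALSE),
    names(weights$genes))
}

#' Relative recurrence score from expression
#'
#' Each panel gene is z-normalised across the samples of its batch; each
#' group's score is the mean of its member genes; the final score is the
#' weighted sum of group scores plus individually weighted genes. Because
#' of the per-batch z-normalisation the score is relative — centred near
#' zero within each batch — and invariant to affine rescaling of the raw
#' expression.
#'
#' @param x An [expr_mat] containing all panel genes (an error lists any
#'   that are missing).
#' @param weights An `odx_weights` table; defaults to the shipped one.
#' @return Tibble (sample_id, batch, one `score_<group>` column per
#'   group, score).
#' @export
relative_odx_score <- function(x, weights = default_odx_weights()) {
  stopifnot(inherits(x, "expr_mat"))
  panel <- odx_genes(weights)
  missing <- setdiff(panel, gene_ids(x))
  if (length(missing)) {
    abort(paste0("Panel gene(s) absent from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  z <- x$values[panel, , drop = FALSE]
  for (b in unique(x$batch)) {
    idx <- x$batch == b
    sub <- z[, idx, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1, sd, na.rm = TRUE)
    flat <- sdv == 0 | is.na(sdv)
    if (any(flat)) {
      warn(sprintf("Zero-variance panel gene(s) in batch '%s' excluded: %s",
                   b, paste(panel[flat], collapse = ", ")))
      sdv[flat] <- NA_real_
    }
    z[, idx] <- (sub - mu) / sdv
  }
  out <- tibble(sample_id = sample_ids(x), batch = x$batch)
  total <- rep(0, ncol(z))
  for (gname in names(weights$groups)) {
    grp <- weights$groups[[gname]]
    gs <- colMeans(z[grp$genes, , drop = FALSE], na.rm = TRUE)
    gs[is.nan(gs)] <- 0
    out[[paste0("score_", gname)]] <- gs
    total <- total + grp$weight * gs
  }
  for (g in names(weights$genes)) {
    v <- z[g, ]
    v[is.na(v)] <- 0
    total <- total + weights$genes[[g]] * v
  }
  out$score <- unname(total)
  out
}

#' Dichotomize recurrence scores
#' @param scores Numeric scores or the tibble from [relative_odx_score()].
#' @param cutoff Scores strictly above are labelled `"high"`; at or below,
#'   `"low"`.
#' @return Character vector of labels (or the tibble with a `risk`
#'   column added).
#' @export
dichotomize_score <- function(scores, cutoff = 0) {
  if (is.data.frame(scores)) {
    scores$risk <- dichotomize_score(scores$score, cutoff)
    return(scores)
  }
  if (any(!is.finite(scores))) abort("Scores must be finite.")
  ifelse(scores > cutoff, "high", "low")
}

#' FISH classification thresholds
#'
#' Presence cutoffs are mean spots/cell per region; the defaults are the
#' survival-optimised multiplex values 3.5 (8p11.2), 4.0 (17q22 probe)
#' and 2.8 (8q24.3). The tri-class bounds label a count amplified when
#' strictly above `amplified_above`, not amplified when strictly below
#' `not_below`, and borderline on the closed interval between them.
#'
#' @param presence Named numeric vector of per-region presence cutoffs.
#' @param amplified_above,not_below Tri-class bounds.
#' @return A list of class `fish_thresholds`.
#' @export
fish_thresholds <- function(presence = c("8p11.2" = 3.5, "17q22" = 4.0,
                                         "8q24.3" = 2.8),
                            amplified_above = 4, not_below = 2) {
  if (any(presence <= 0)) abort("Presence cutoffs must be positive.")
  if (not_below > amplified_above) abort("Tri-class bounds out of order.")
  structure(list(presence = presence, amplified_above = amplified_above,
                 not_below = not_below),
            class = "fish_thresholds")
}

#' Classify FISH spot counts
#'
#' Counts are mean probe spots per nucleus averaged over 20 scored tumour
#' cells. In `triclass` mode each scored region is labelled amplified
#' (`> 4`), borderline (`[2, 4]`, bounds inclusive) or not amplified
#' (`< 2`). In `presence` mode a region is positive iff its count reaches
#' the region's cutoff (`>=`); borderline does not count as positive.
#' "No signal" entries (missing counts, `NA`) are unscored: they are
#' excluded from the `any_amplicon` OR, which is still 1 when another
#' region is positive and `NA` only when no region was scored.
#'
#' @param fish Tibble (sample_id, region, mean_count) with `NA` for
#'   no-signal entries, or a wide tibble with one column per region.
#' @param thresholds A [fish_thresholds()].
#' @param mode `"triclass"` or `"presence"`.
#' @return Wide tibble, one row per sample: per-region labels (triclass)
#'   or 0/1 flags plus `any_amplicon` (presence).
#' @export
classify_fish <- function(fish, thresholds = fish_thresholds(),
                          mode = c("triclass", "presence")) {
  mode <- match.arg(mode)
  fish <- as_tibble(fish)
  if (!"region" %in% names(fish)) {
    fish <- fish |>
      tidyr::pivot_longer(-"sample_id", names_to = "region",
                          values_to = "mean_count")
  }
  if (any(fish$mean_count < 0, na.rm = TRUE)) abort("Negative spot count.")
  if (all(is.na(fish$mean_count))) abort("At least one region must be scored.")
  th <- thresholds
  if (mode == "triclass") {
    fish |>
      mutate(label = dplyr::case_when(
        is.na(.data$mean_count) ~ "no signal",
        .data$mean_count > th$amplified_above ~ "amplified",
        .data$mean_count < th$not_below ~ "not amplified",
        TRUE ~ "borderline")) |>
      select("sample_id", "region", "label") |>
      tidyr::pivot_wider(names_from = "region", values_from = "label")
  } else {
    miss <- setdiff(unique(fish$region), names(th$presence))
    if (length(miss)) {
      abort(paste0("No presence cutoff configured for region(s): ",
                   paste(miss, collapse = ", ")))
    }
    flags <- fish |>
      mutate(flag = as.integer(.data$mean_count >= th$presence[.data$region])) |>
      select("sample_id", "region", "flag") |>
      tidyr::pivot_wider(names_from = "region", values_from = "flag")
    regions <- setdiff(names(flags), "sample_id")
    any_amp <- apply(flags[regions], 1, function(r) {
      if (all(is.na(r))) NA_integer_ else as.integer(any(r == 1, na.rm = TRUE))
    })
    flags$any_amplicon <- any_amp
    flags
  }
}

#' Survival-optimised FISH presence thresholds
#'
#' Exhaustive grid search over per-region presence cutoffs: for every
#' combination, samples are classified (presence mode), the any-amplicon
#' carriers are compared against amplicon-free samples by log-rank test,
#' and the combination maximising the statistic is chosen. Ties are
#' broken toward larger cutoffs. This is in-sample optimisation — the
#' chosen thresholds are reported together with the full grid trace and
#' must be validated independently.
#'
#' @param fish Long or wide FISH tibble as for [classify_fish()].
#' @param clinical Clinical tibble with `sample_id`, `time`, `event`.
#' @param grid Named list of candidate cutoffs per region; defaults to
#'   `seq(2, 5, by = 0.25)` for every scored region.
#' @return A list of class `fish_opt`: `thresholds` (a
#'   [fish_thresholds()]), `statistic`, and `trace` (tibble of all grid
#'   points with their log-rank statistics).
#' @export
optimize_fish_thresholds <- function(fish, clinical, grid = NULL) {
  fish <- as_tibble(fish)
  if (!"region" %in% names(fish)) {
    fish <- fish |>
      tidyr::pivot_longer(-"sample_id", names_to = "region",
                          values_to = "mean_count")
  }
  clinical <- as_tibble(clinical)
  regions <- sort(unique(fish$region))
  grid <- grid %||% setNames(rep(list(seq(2, 5, by = 0.25)), length(regions)),
                             regions)
  if (!setequal(names(grid), regions)) abort("Grid regions do not match data.")
  wide <- fish |>
    tidyr::pivot_wider(names_from = "region", values_from = "mean_count") |>
    left_join(clinical |> select("sample_id", "time", "event"), by = "sample_id")
  if (anyNA(wide$time)) abort("FISH samples missing from clinical table.")
  counts <- as.matrix(wide[regions])
  combos <- expand.grid(grid[regions], KEEP.OUT.ATTRS = FALSE)
  # combos x samples matrix of any-amplicon calls, then one vectorised
  # log-rank sweep over all grid points at once
  calls <- matrix(0L, nrow(combos), nrow(wide))
  for (i in seq_len(nrow(combos))) {
    pos <- sweep(counts, 2, as.numeric(combos[i, ]), `>=`)
    calls[i, ] <- as.integer(apply(pos, 1, function(r) any(r, na.rm = TRUE)))
  }
  arm_ok <- rowSums(calls) > 0 & rowSums(calls) < ncol(calls)
  if (!any(arm_ok)) abort("No grid point yields two non-empty arms.")
  lr <- logrank_vec(calls, wide$time, wide$event)
  trace <- as_tibble(combos) |>
    mutate(n_carrier = rowSums(calls), statistic = lr$statistic,
           valid = arm_ok)
  best_stat <- max(trace$statistic[arm_ok])
  cand <- trace |>
    mutate(.row = row_number()) |>
    filter(.data$valid, .data$statistic == best_stat) |>
    arrange(dplyr::across(dplyr::all_of(regions), dplyr::desc)) |>
    slice(1L)
  chosen <- setNames(as.numeric(cand[1, regions]), regions)
  structure(list(thresholds = fish_thresholds(presence = chosen),
                 statistic = best_stat, trace = trace |> select(-"valid")),
            class = "fish_opt")
}

#' @export
print.fish_opt <- function(x, ...) {
  cat("<fish_opt> survival-optimised FISH cutoffs (in-sample):\n")
  print(x$thresholds$presence)
  cat(sprintf("log-rank statistic at optimum: %.3f (grid of %d points)\n",
              x$statistic, nrow(x$trace)))
  invisible(x)
}
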