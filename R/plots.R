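#' Plot a Kaplan-Meier curve
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot: survival step function with Greenwood 95% band.
#' @exportS3Method ggplot2::autoplot
autoplot.km_curve <- function(object, ...) {
  df <- bind_rows(tibble(time = 0, surv = 1, lower = 1, upper = 1),
                  object$steps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = "dashed",
                       alpha = 0.5) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = "dashed",
                       alpha = 0.5) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (years)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot gene clusters in the PCA plane
#' @param object A `gene_cluster_set` from [pca_clusters()].
#' @param ... Unused.
#' @return A ggplot of each gene's outlier profile projected on the first
#'   two principal components, coloured by cluster, shaped by prognosis.
#' @exportS3Method ggplot2::autoplot
autoplot.gene_cluster_set <- function(object, ...) {
  ggplot2::ggplot(object$genes,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = factor(.data$cluster),
                               shape = .data$prognosis)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(colour = "Cluster", shape = "Prognosis") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier comparison for one amplicon's stratified outcome
#'
#' @param outcomes Result of [stratified_outcome()].
#' @param amplicon Amplicon name (a row of `outcomes`), e.g.
#'   `"any_amplicon"`.
#' @return A ggplot with carrier and amplicon-free curves.
#' @export
plot_stratified_km <- function(outcomes, amplicon = "any_amplicon") {
  km <- attr(outcomes, "km")[[amplicon]]
  if (is.null(km)) abort(paste0("No curves stored for ", amplicon))
  df <- bind_rows(
    tidy(km$carrier) |> mutate(arm = "carrier"),
    tidy(km$none) |> mutate(arm = "no amplicon")) |>
    group_by(.data$arm) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$arm)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = amplicon, x = "Time (years)",
                  y = "Survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}
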