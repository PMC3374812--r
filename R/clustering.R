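#' Phi-coefficient correlation matrix of binary outlier profiles
#'
#' For every pair of rows the phi coefficient is computed from the 2x2
#' contingency table of the two binary profiles,
#' `phi = (n11 n00 - n10 n01) / sqrt(r1 r0 c1 c0)`,
#' which equals the Pearson correlation of the two rows. Rows must be
#' non-constant (a constant profile has no defined phi).
#'
#' @param B Binary matrix (genes x samples), e.g. a screened subset of an
#'   outlier matrix.
#' @return Symmetric numeric matrix with unit diagonal, dimnames taken
#'   from `B`'s rows.
#' @export
phi_matrix <- function(B) {
  if (!is.matrix(B) || !all(B %in% c(0, 1))) abort("`B` must be a 0/1 matrix.")
  n <- ncol(B)
  r1 <- rowSums(B)
  constant <- r1 == 0 | r1 == n
  if (any(constant)) {
    abort(paste0("Constant row(s), phi undefined: ",
                 paste(rownames(B)[constant], collapse = ", ")))
  }
  n11 <- B %*% t(B)
  n10 <- r1 - n11                 # recycled by column: n10[i,j] = r1[i] - n11
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  denom <- sqrt(outer(r1 * (n - r1), r1 * (n - r1)))
  phi <- (n11 * n00 - n10 * n01) / denom
  diag(phi) <- 1
  dimnames(phi) <- list(rownames(B), rownames(B))
  phi
}

#' Pruning configuration for the phi correlation graph
#' @param tau Correlation threshold in (0, 1); genes i, j are connected
#'   iff `phi[i, j] >= tau`.
#' @param min_degree Minimum number of neighbours a gene must keep.
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(tau = 0.30, min_degree = 1L) {
  if (!(tau > 0 && tau < 1)) abort("`tau` must be in (0, 1).")
  if (min_degree < 0) abort("`min_degree` must be >= 0.")
  structure(list(tau = tau, min_degree = as.integer(min_degree)),
            class = "prune_config")
}

#' Iteratively prune weakly correlated genes from a phi matrix
#'
#' The phi matrix is thresholded at `tau` into an adjacency matrix
#' (edge iff `phi >= tau`, `i != j`); while any gene has degree below
#' `min_degree`, the single gene of smallest degree (ties broken by gene
#' id) is removed and degrees recomputed. The process stops when the
#' retained set is stable, i.e. its size stops changing.
#'
#' @param R Phi matrix from [phi_matrix()].
#' @param config A [prune_config()].
#' @return Character vector of retained gene ids (possibly empty).
#' @export
prune_correlation_graph <- function(R, config = prune_config()) {
  stopifnot(inherits(config, "prune_config"))
  if (!length(R)) return(character())
  A <- (R >= config$tau) * 1L
  diag(A) <- 0L
  keep <- rownames(A)
  repeat {
    if (!length(keep)) break
    deg <- rowSums(A[keep, keep, drop = FALSE])
    below <- deg < config$min_degree
    if (!any(below)) break
    victim <- keep[below][order(deg[below], keep[below])][1L]
    keep <- setdiff(keep, victim)
  }
  keep
}

#' PCA projection and connected-component clustering of outlier profiles
#'
#' Genes are the observations and samples the (mean-centred) variables;
#' each gene's outlier profile is projected onto the first two principal
#' axes for visualisation. Cluster membership is the connected components
#' of the tau-thresholded phi graph — the programmatic counterpart of
#' circling tight groups in the PCA plane. Each cluster receives a
#' prognosis label from the majority hazard-ratio direction of its member
#' genes in the survival screen (`HR > 1` poor, otherwise good).
#'
#' @param B Binary outlier matrix restricted to the retained genes
#'   (at least 2 rows).
#' @param screen Screen tibble from [outlier_survival_screen()] providing
#'   `gene_id` and `hazard_ratio` for the retained genes.
#' @param config A [prune_config()] (only `tau` is used here).
#' @return Object of class `gene_cluster_set`; its `genes` element is a
#'   tibble (gene_id, cluster, prognosis, PC1, PC2), `clusters` a
#'   per-cluster summary. Plot with [autoplot()].
#' @export
pca_clusters <- function(B, screen, config = prune_config()) {
  if (nrow(B) < 2L) abort("Need at least 2 genes for PCA clustering.")
  R <- phi_matrix(B)
  A <- (R >= config$tau) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)$membership
  pcs <- prcomp(B, center = TRUE, scale. = FALSE)$x
  pc2 <- if (ncol(pcs) >= 2) pcs[, 2] else rep(0, nrow(B))
  genes <- tibble(gene_id = rownames(B),
                  cluster = as.integer(comp[rownames(B)]),
                  PC1 = pcs[, 1], PC2 = pc2) |>
    left_join(screen |> select("gene_id", "hazard_ratio") |>
                distinct(.data$gene_id, .keep_all = TRUE),
              by = "gene_id") |>
    group_by(.data$cluster) |>
    mutate(prognosis = ifelse(mean(.data$hazard_ratio > 1, na.rm = TRUE) >= 0.5,
                              "poor", "good")) |>
    ungroup()
  clusters <- genes |>
    group_by(.data$cluster, .data$prognosis) |>
    summarise(n_genes = n(), .groups = "drop") |>
    arrange(.data$cluster)
  structure(list(genes = genes, clusters = clusters, tau = config$tau),
            class = "gene_cluster_set")
}

#' @export
print.gene_cluster_set <- function(x, ...) {
  cat(sprintf("<gene_cluster_set> %d genes in %d cluster(s) at tau = %.2f\n",
              nrow(x$genes), nrow(x$clusters), x$tau))
  print(x$clusters)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gene_cluster_set <- function(x, ...) x$genes

#' Genes belonging to clusters with a given prognosis label
#' @param x A `gene_cluster_set`.
#' @param prognosis `"poor"` or `"good"`.
#' @return Character vector of gene ids.
#' @export
cluster_genes <- function(x, prognosis = c("poor", "good")) {
  prognosis <- match.arg(prognosis)
  x$genes |> filter(.data$prognosis == !!prognosis) |> pull("gene_id")
}
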