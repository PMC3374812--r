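# Small in-code fixtures shared across test files.

make_expr <- function(values, batch = "A") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expr_mat(values, batch = batch)
}

random_expr <- function(n_genes = 20, n_samples = 10, seed = 1, batch = "A") {
  set.seed(seed)
  make_expr(matrix(rnorm(n_genes * n_samples), n_genes, n_samples),
            batch = batch)
}

# binary matrix with non-constant rows
random_binary <- function(n_genes, n_samples, seed = 1, p = 0.3) {
  set.seed(seed)
  repeat {
    B <- matrix(rbinom(n_genes * n_samples, 1, p), n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    rs <- rowSums(B)
    if (all(rs > 0 & rs < n_samples)) return(B)
  }
}

# minimal clinical tibble for n samples
make_clinical <- function(time, event, sample_id = sprintf("s%02d", seq_along(time))) {
  tibble::tibble(sample_id = sample_id, time = time, event = event)
}

# exponential survival cohort with a binary covariate of true hazard ratio hr
sim_surv <- function(n, hr, censor_frac = 0, seed = 1, p_carrier = 0.5) {
  set.seed(seed)
  x <- rbinom(n, 1, p_carrier)
  t_event <- rexp(n, rate = 0.1 * hr^x)
  if (censor_frac > 0) {
    t_cens <- rexp(n, rate = 0.1 * censor_frac / (1 - censor_frac))
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                   time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens), x = x)
  } else {
    tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)),
                   time = t_event, event = 1L, x = x)
  }
}

# the default planted-amplicon study cohort used by end-to-end tests
default_fixture <- function(seed = 1) simulate_cohort(sim_config(), seed = seed)

null_sim_config <- function() {
  sim_config(amplicons = tibble::tibble(
    chrom = character(), start_idx = integer(), end_idx = integer(),
    prevalence = numeric(), delta = numeric(), hr = numeric()))
}

# match each defined amplicon to the planted region it overlaps (by markers)
match_regions <- function(amplicons, truth) {
  vapply(seq_len(nrow(amplicons)), function(j) {
    hits <- which(vapply(truth$amplicons$genes, function(g) {
      length(intersect(amplicons$markers[[j]], g)) > 0
    }, logical(1)))
    if (length(hits) == 1L) hits else NA_integer_
  }, integer(1))
}

expect_tibble <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
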