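make_ann <- function(n, chrom = "chr1") {
  tibble::tibble(gene_id = sprintf("%s_g%04d", chrom, seq_len(n)),
                 chrom = chrom, start = seq_len(n) * 1000,
                 end = seq_len(n) * 1000 + 500,
                 cytoband = paste0(sub("chr", "", chrom), "q",
                                   (seq_len(n) - 1) %/% 25 + 1))
}

test_that("sliding windows tile each chromosome and anchor the final window", {
  w <- make_windows(make_ann(60), window_config(width = 25, pace = 5))
  expect_identical(nrow(w), 8L)
  expect_identical(w$start_idx, as.integer(seq(1, 36, by = 5)))
  expect_identical(w$end_idx[8], 60L)
  expect_identical(length(w$genes[[8]]), 25L)

  one <- make_windows(make_ann(25), window_config())
  expect_identical(nrow(one), 1L)

  short <- make_windows(make_ann(10), window_config())
  expect_identical(nrow(short), 1L)
  expect_identical(short$n_genes, 10L)

  # every gene of a multi-chromosome annotation is covered
  ann <- dplyr::bind_rows(make_ann(37, "chr1"), make_ann(12, "chr2"))
  w2 <- make_windows(ann, window_config())
  expect_setequal(unlist(w2$genes), ann$gene_id)
})

test_that("hypergeometric enrichment equals the tail-sum oracle", {
  universe <- sprintf("u%04d", 1:1000)
  set_genes <- universe[1:50]
  window <- c(universe[1:10], universe[900:914])   # overlap 10, size 25
  res <- hypergeometric_enrichment(window, set_genes, universe)
  oracle <- sum(choose(50, 10:25) * choose(950, 25 - (10:25))) / choose(1000, 25)
  expect_equal(res$p_value, oracle, tolerance = 1e-12)
  expect_identical(res$k, 10L)

  none <- hypergeometric_enrichment(universe[900:910], set_genes, universe)
  expect_equal(none$p_value, 1)

  full <- hypergeometric_enrichment(universe, universe, universe)
  expect_equal(full$p_value, 1)

  expect_error(hypergeometric_enrichment("x", "x", character()), "Empty universe")
  expect_error(hypergeometric_enrichment("nope", set_genes, universe), "subsets")
})

test_that("enrichment matches exhaustive fixed-margin enumeration for N <= 60", {
  set.seed(14)
  for (rep in 1:25) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- sprintf("g%03d", 1:N)
    set_genes <- sample(universe, K)
    target <- sample(universe, n)
    k <- length(intersect(target, set_genes))
    # enumerate all tables with the same margins
    ks <- max(0, n + K - N):min(K, n)
    probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
    oracle <- sum(probs[ks >= k])
    mine <- hypergeometric_enrichment(target, set_genes, universe)$p_value
    expect_equal(mine, oracle, tolerance = 1e-10)
    # and agrees with the one-sided Fisher exact test
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(mine, fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-8)
  }
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.04, 0.05)),
               c(0.004, 0.04, 0.05, 0.05))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  naive_bh <- function(p) {       # O(m^2) step-up with monotone correction
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
    }
    q
  }
  set.seed(6)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), naive_bh(p), tolerance = 1e-12)
  }
})

test_that("amplicon definitions merge overlapping significant windows", {
  ann <- make_ann(500)
  cluster <- ann$gene_id[101:130]      # one contiguous planted run
  amp <- define_amplicons(cluster, ann, window_config())
  expect_identical(nrow(amp), 1L)
  expect_lte(amp$start_idx, 101L)
  expect_gte(amp$end_idx, 130L)
  expect_setequal(amp$markers[[1]], cluster)
  enr <- attr(amp, "enrichment")
  expect_true(all(enr$q_value >= enr$p_value))

  # a diffuse cluster reaches no window significance
  set.seed(9)
  diffuse <- sample(ann$gene_id, 25)
  maybe <- define_amplicons(diffuse, ann, window_config())
  expect_identical(nrow(maybe), 0L)
})

test_that("amplicon names span the member cytobands", {
  ann <- make_ann(100, "chr8")
  amp <- define_amplicons(ann$gene_id[10:40], ann, window_config())
  expect_identical(nrow(amp), 1L)
  expect_match(amp$name, "^8q1-q2$|^8q")
})

test_that("per-sample calls follow the >= 50% marker rule and are monotone", {
  B <- matrix(0L, 4, 3, dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
  B[1:2, 1] <- 1L          # 2/4 markers
  B[1, 2] <- 1L            # 1/4 markers
  B[, 3] <- 1L             # 4/4 markers
  amp <- tibble::tibble(name = "ampA", chrom = "chr1", start_idx = 1L,
                        end_idx = 4L, span_start = 1, span_end = 4,
                        n_markers = 4L, markers = list(paste0("m", 1:4)),
                        q_min = 0.01)
  calls <- call_amplicons_per_sample(B, amp)
  expect_identical(calls$ampA, c(1L, 0L, 1L))
  expect_identical(calls$any_amplicon, c(1L, 0L, 1L))
  freq <- attr(calls, "frequencies")
  expect_equal(unname(freq$frequency), 2 / 3)

  # adding one more flag can only add calls
  B2 <- B; B2[2, 2] <- 1L
  calls2 <- call_amplicons_per_sample(B2, amp)
  expect_true(all(calls2$ampA >= calls$ampA))

  empty_mk <- amp; empty_mk$markers <- list(character())
  expect_error(call_amplicons_per_sample(B, empty_mk), "without markers")
})

test_that("zero amplicons yield an all-zero any_amplicon column", {
  B <- matrix(0L, 2, 3, dimnames = list(paste0("m", 1:2), paste0("s", 1:3)))
  calls <- call_amplicons_per_sample(B, amplimark:::empty_amplicons())
  expect_identical(calls$any_amplicon, c(0L, 0L, 0L))
})

test_that("stratified outcomes compare carriers against amplicon-free samples", {
  set.seed(12)
  n <- 200
  carrier <- rbinom(n, 1, 0.3)
  clin <- make_clinical(rexp(n, 0.05 * 4^carrier), rep(1L, n),
                        sprintf("s%03d", 1:n))
  calls <- tibble::tibble(sample_id = clin$sample_id, ampA = carrier,
                          any_amplicon = carrier)
  out <- stratified_outcome(calls, clin)
  row <- out[out$amplicon == "ampA", ]
  expect_gt(row$hazard_ratio, 2.5)
  expect_lt(row$p_value, 1e-4)
  km <- attr(out, "km")$ampA
  expect_s3_class(km$carrier, "km_curve")

  none <- calls; none$ampA <- 0L; none$any_amplicon <- 0L
  expect_error(stratified_outcome(none, clin), "zero carriers")

  clin$grade <- "high"
  expect_error(stratified_outcome(calls, clin, grade_stratum = "low"),
               "Empty grade stratum")
})
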