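test_that("the shipped weight table partitions the panel genes", {
  w <- default_odx_weights()
  expect_s3_class(w, "odx_weights")
  genes <- odx_genes(w)
  expect_identical(anyDuplicated(genes), 0L)
  expect_true(all(c("HER2", "GRB7", "Ki67", "ER", "CD68") %in% genes))
  expect_gt(w$groups$proliferation$weight, 0)   # worse-prognosis orientation
  expect_lt(w$groups$er$weight, 0)
})

test_that("the relative score is the weighted sum of per-batch z-group means", {
  set.seed(17)
  w <- default_odx_weights()
  panel <- odx_genes(w)
  n <- 40
  vals <- matrix(rnorm(length(panel) * n, mean = 8, sd = 1.5),
                 length(panel), n,
                 dimnames = list(panel, sprintf("s%02d", 1:n)))
  x <- expr_mat(vals, batch = rep(c("K", "O"), each = n / 2))
  sc <- relative_odx_score(x, w)

  # oracle: z-normalise by hand per batch, average groups, combine
  oracle <- numeric(n)
  for (b in c("K", "O")) {
    idx <- batch_of(x) == b
    z <- t(scale(t(vals[, idx])))
    tot <- rep(0, sum(idx))
    for (g in names(w$groups)) {
      tot <- tot + w$groups[[g]]$weight * colMeans(z[w$groups[[g]]$genes, ])
    }
    for (g in names(w$genes)) tot <- tot + w$genes[[g]] * z[g, ]
    oracle[idx] <- tot
  }
  expect_equal(sc$score, oracle, tolerance = 1e-12)

  # population mean ~ 0 within each batch by construction
  means <- tapply(sc$score, sc$batch, mean)
  expect_lt(max(abs(means)), 0.3)

  # invariant to per-batch affine rescaling of the raw expression
  y <- expr_mat(2.5 * vals + 4, batch = batch_of(x))
  expect_equal(relative_odx_score(y, w)$score, sc$score, tolerance = 1e-10)

  expect_error(relative_odx_score(expr_mat(vals[-1, , drop = FALSE],
                                           batch = batch_of(x)), w),
               "absent")
})

test_that("raising one group by a constant moves the score by its weight", {
  set.seed(18)
  w <- default_odx_weights()
  panel <- odx_genes(w)
  n <- 30
  vals <- matrix(rnorm(length(panel) * n), length(panel), n,
                 dimnames = list(panel, sprintf("s%02d", 1:n)))
  x <- expr_mat(vals, batch = "K")
  base <- relative_odx_score(x, w)
  # add exactly one per-batch SD to every proliferation gene for sample 1,
  # keeping normalisation fixed by comparing z-space shifts directly
  prolif <- w$groups$proliferation$genes
  z <- t(scale(t(vals)))
  z[prolif, 1] <- z[prolif, 1] + 1
  shifted <- rep(0, n)
  for (g in names(w$groups)) {
    shifted <- shifted + w$groups[[g]]$weight * colMeans(z[w$groups[[g]]$genes, ])
  }
  for (g in names(w$genes)) shifted <- shifted + w$genes[[g]] * z[g, ]
  expect_equal(unname(shifted[1] - base$score[1]), w$groups$proliferation$weight,
               tolerance = 1e-10)
})

test_that("score dichotomisation is strict at the cutoff and shift-invariant", {
  expect_identical(dichotomize_score(c(0.01, -0.01, 0)),
                   c("high", "low", "low"))
  s <- c(-1.2, 0.3, 2.2)
  expect_identical(dichotomize_score(s, 0), dichotomize_score(s + 5, 5))
  expect_error(dichotomize_score(c(1, Inf)), "finite")
  df <- dichotomize_score(tibble::tibble(score = c(0.4, -0.4)))
  expect_identical(df$risk, c("high", "low"))
})

test_that("tri-class FISH labels follow the >4 / [2,4] / <2 bounds", {
  fish <- tibble::tibble(sample_id = rep("t1", 3),
                         region = c("17q22", "8q24.3", "8p11.2"),
                         mean_count = c(4.5, 3.0, 1.5))
  lab <- classify_fish(fish, mode = "triclass")
  expect_identical(lab$`17q22`, "amplified")
  expect_identical(lab$`8q24.3`, "borderline")
  expect_identical(lab$`8p11.2`, "not amplified")

  edge <- classify_fish(tibble::tibble(sample_id = "t", region = "17q22",
                                       mean_count = 4.0), mode = "triclass")
  expect_identical(edge$`17q22`, "borderline")
  edge2 <- classify_fish(tibble::tibble(sample_id = "t", region = "17q22",
                                        mean_count = 2.0), mode = "triclass")
  expect_identical(edge2$`17q22`, "borderline")

  expect_error(classify_fish(tibble::tibble(sample_id = "t", region = "17q22",
                                            mean_count = -1)), "Negative")
})

test_that("tri-class labels partition every scored count", {
  set.seed(23)
  counts <- c(runif(50, 0, 7), NA)
  fish <- tibble::tibble(sample_id = sprintf("t%02d", seq_along(counts)),
                         region = "17q22", mean_count = counts)
  lab <- classify_fish(fish, mode = "triclass")
  expect_identical(sum(is.na(counts)), sum(lab$`17q22` == "no signal"))
  expect_true(all(lab$`17q22` %in%
                    c("amplified", "borderline", "not amplified", "no signal")))
})

test_that("presence mode applies per-region cutoffs and handles no-signal", {
  th <- fish_thresholds()
  fish <- tibble::tibble(
    sample_id = c("a", "a", "a", "b", "b", "b"),
    region = rep(c("8p11.2", "17q22", "8q24.3"), 2),
    mean_count = c(3.6, 2.0, 2.0, NA, NA, 3.0))
  out <- classify_fish(fish, th, mode = "presence")
  expect_identical(out$`8p11.2`[out$sample_id == "a"], 1L)  # 3.6 >= 3.5
  expect_identical(out$any_amplicon[out$sample_id == "a"], 1L)
  # b: two regions unscored, 8q24.3 = 3.0 >= 2.8 -> still positive overall
  expect_identical(out$any_amplicon[out$sample_id == "b"], 1L)

  allna <- tibble::tibble(sample_id = c("c", "c"), region = c("8p11.2", "17q22"),
                          mean_count = c(NA, 1.0))
  out2 <- classify_fish(allna, th, mode = "presence")
  expect_identical(out2$any_amplicon, 0L)

  # presence is monotone in the count
  grid <- tibble::tibble(sample_id = sprintf("g%02d", 1:20), region = "8q24.3",
                         mean_count = seq(0.5, 6, length.out = 20))
  flags <- classify_fish(grid, th, mode = "presence")$`8q24.3`
  expect_true(all(diff(flags) >= 0))
})

test_that("threshold optimisation recovers a generating cutoff from survival", {
  set.seed(33)
  n <- 80
  counts <- runif(n, 1.5, 5.5)
  carrier <- counts > 3                       # generating cutoff 3
  clin <- make_clinical(rexp(n, 0.08 * ifelse(carrier, 3, 1)), rep(1L, n),
                        sprintf("f%02d", 1:n))
  fish <- tibble::tibble(sample_id = clin$sample_id, region = "regA",
                         mean_count = counts)
  opt <- optimize_fish_thresholds(fish, clin,
                                  grid = list(regA = seq(2, 5, by = 0.25)))
  expect_lte(abs(opt$thresholds$presence[["regA"]] - 3), 0.25)
  expect_tibble(opt$trace, c("regA", "statistic", "n_carrier"))

  # survival independent of counts: flat trace, tie-break to larger cutoffs
  clin_flat <- make_clinical(rep(c(1, 2, 3, 4), 20), rep(1L, n),
                             sprintf("f%02d", 1:n))
  fish_flat <- tibble::tibble(sample_id = clin_flat$sample_id, region = "regA",
                              mean_count = rep(c(2.4, 4.6), each = 40))
  opt_flat <- optimize_fish_thresholds(fish_flat, clin_flat,
                                       grid = list(regA = c(2, 2.5, 3, 3.5, 4)))
  valid_stats <- opt_flat$trace$statistic[opt_flat$trace$n_carrier %in% 1:(n - 1)]
  # all grid points between the two count values give identical arms
  expect_lt(diff(range(valid_stats)), 1e-9)
  expect_equal(opt_flat$thresholds$presence[["regA"]], 4)

  expect_error(
    optimize_fish_thresholds(
      tibble::tibble(sample_id = "only", region = "regA", mean_count = 3),
      make_clinical(5, 1, "only"), grid = list(regA = c(2, 4))),
    "non-empty arms")
})
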