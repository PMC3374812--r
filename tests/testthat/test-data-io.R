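test_that("expression tables round-trip through write/read exactly", {
  x <- random_expr(15, 6, seed = 42, batch = "KIT")
  x$values[3, 2] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(x, path)
  y <- read_expression_table(path, batch_label = "KIT")
  expect_identical(dim(y), dim(x))
  expect_identical(rownames(y$values), rownames(x$values))
  expect_identical(colnames(y$values), colnames(x$values))
  expect_identical(y$values, x$values)       # bit-for-bit
  expect_identical(unname(batch_of(y)), rep("KIT", 6))

  # gzipped dialect reads the same
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_expression_table(x, gz)
  expect_identical(read_expression_table(gz, "KIT")$values, x$values)
})

test_that("malformed expression tables are rejected with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tS1\tS1", "g1\t1\t2"), path)
  expect_error(read_expression_table(path, "A"), "Duplicate sample ids")

  writeLines(c("id\tS1\tS2", "g1\t1\ttwo"), path)
  expect_error(read_expression_table(path, "A"), "row 1.*column 2|column 2.*row 1")

  writeLines(c("id\tS1\tS2", "g1\t1\t", "g2\tNA\t3"), path)
  y <- read_expression_table(path, "A")   # empty and NA cells are missing
  expect_identical(is.na(y$values), matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                                           dimnames = dimnames(y$values),
                                           byrow = TRUE))
})

test_that("collapse_probes keeps the highest-median probe per gene", {
  m <- make_expr(matrix(c(1, 5, 9,
                          3, 7, 11,
                          2, 2, 2), nrow = 3, byrow = TRUE,
                        dimnames = list(c("pA", "pB", "pC"), NULL)))
  pm <- tibble::tibble(probe_id = c("pA", "pB", "pC"),
                       gene_id = c("G1", "G1", "G2"))
  out <- collapse_probes(m, pm)
  expect_identical(sort(gene_ids(out)), c("G1", "G2"))
  expect_identical(unname(out$values["G1", ]), c(3, 7, 11))  # median 7 beats 5

  # single probe per gene: values unchanged, rows renamed
  single <- collapse_probes(make_expr(m$values["pC", , drop = FALSE]),
                            pm[pm$probe_id == "pC", ])
  expect_identical(unname(single$values["G2", ]), c(2, 2, 2))

  # equal medians: lexicographically smaller probe id wins
  tie <- make_expr(matrix(c(1, 2, 3, 3, 2, 1), nrow = 2, byrow = TRUE,
                          dimnames = list(c("pB", "pA"), NULL)))
  tie_pm <- tibble::tibble(probe_id = c("pA", "pB"), gene_id = "G")
  out_tie <- collapse_probes(tie, tie_pm)
  expect_identical(unname(out_tie$values["G", ]), c(3, 2, 1))  # pA's row

  expect_error(collapse_probes(m, pm[1:2, ]), "absent from map")
})

test_that("collapse_probes is idempotent once one probe per gene remains", {
  x <- random_expr(10, 5, seed = 7)
  pm <- tibble::tibble(probe_id = gene_ids(x), gene_id = gene_ids(x))
  once <- collapse_probes(x, pm)
  twice <- collapse_probes(once, pm)
  expect_identical(once$values, twice$values)
})

test_that("merge_batches intersects genes and concatenates samples", {
  a <- make_expr(matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
                 batch = "K")
  b <- make_expr(matrix(7:12, 3, 2, dimnames = list(c("B", "C", "D"), c("s3", "s4"))),
                 batch = "O")
  m <- merge_batches(list(a, b))
  expect_identical(gene_ids(m), c("B", "C"))
  expect_identical(sample_ids(m), c("s1", "s2", "s3", "s4"))
  expect_identical(unname(batch_of(m)), c("K", "K", "O", "O"))
  # sample count and batch partition preserved
  expect_identical(ncol(m$values), ncol(a$values) + ncol(b$values))

  expect_identical(merge_batches(list(a))$values, a$values)

  clash <- make_expr(matrix(1:2, 1, 2, dimnames = list("B", c("s1", "x"))), "P")
  expect_error(merge_batches(list(a, clash)), "collide")
})

test_that("gene annotation parses printed 1-based coordinates and validates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstart\tend\tcytoband",
               "STARD3\tchr17\t35,046,940\t35,073,248\t17q12",
               "SPFH2\tchr8\t37,713,267\t37,734,476\t8p11.2"), path)
  ann <- read_gene_annotation(path)
  expect_identical(ann$start[ann$gene_id == "STARD3"], 35046940)
  expect_identical(ann$end[ann$gene_id == "STARD3"], 35073248)
  expect_identical(ann$chrom, sort(ann$chrom))   # sorted by (chrom, start)

  writeLines("gene_id\tchrom\tstart\tend\tcytoband", path)
  expect_identical(nrow(read_gene_annotation(path)), 0L)

  writeLines(c("gene_id\tchrom\tstart\tend\tcytoband",
               "BAD\tchr1\t100\t50\tq1"), path)
  expect_error(read_gene_annotation(path), "start > end")
})

test_that("the shipped chr8/17 gene table loads as annotation", {
  path <- system.file("extdata", "amplicon_genes_chr8_17.tsv",
                      package = "amplimark")
  ann <- read_gene_annotation(path)
  expect_identical(nrow(ann), 62L)
  expect_true(all(ann$start <= ann$end))
  expect_setequal(unique(ann$chrom), c("chr8", "chr17"))
})

test_that("clinical tables validate grades, events and ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,time,event,grade",
               "s1,5.2,1,high", "s2,9.1,0,intermediate", "s3,3.3,0,NA"), path)
  clin <- read_clinical_table(path)
  expect_identical(nrow(clin), 3L)
  expect_true(is.na(clin$grade[3]))

  writeLines(c("sample_id,time,event,grade", "s1,5,1,medium"), path)
  expect_error(read_clinical_table(path), "Unknown grade")

  writeLines(c("sample_id,time,event", "s1,5,1", "s1,2,0"), path)
  expect_error(read_clinical_table(path), "Duplicate")

  writeLines(c("sample_id,time,event", "s1,-1,1"), path)
  expect_error(read_clinical_table(path), "Negative")
})
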