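test_that("orientation x region truth table matches the inactivating rule", {
  gm <- tiny_genes()
  # all 4 combinations on the + strand gene (intron of gplus = [1200,1800))
  cases <- data.frame(
    position = c(1100L, 1100L, 1500L, 1500L),
    strand   = c("+", "-", "+", "-"),
    region   = c("exon", "exon", "intron", "intron"),
    orientation = c("sense", "antisense", "sense", "antisense"),
    inactivating = c(TRUE, TRUE, TRUE, FALSE)
  )
  for (i in seq_len(nrow(cases))) {
    site <- insertion_sites("chrT", cases$position[i], cases$strand[i])
    cls <- classify_insertion(site, gm, "gplus")
    expect_identical(cls$orientation, cases$orientation[i])
    expect_identical(cls$region, cases$region[i])
    expect_identical(cls$inactivating, cases$inactivating[i])
  }
  # and the mirror on the - strand gene (intron of gminus = [3200,3800))
  cls <- classify_insertion(insertion_sites("chrT", 3500L, "-"), gm, "gminus")
  expect_identical(cls$orientation, "sense")
  expect_true(cls$inactivating)
  cls <- classify_insertion(insertion_sites("chrT", 3500L, "+"), gm, "gminus")
  expect_identical(cls$orientation, "antisense")
  expect_false(cls$inactivating)
})

test_that("a site outside the gene span is a classification error", {
  expect_error(
    classify_insertion(insertion_sites("chrT", 50L, "+"), tiny_genes(),
                       "gplus"),
    "outside the span"
  )
})

test_that("per-gene counts follow the classification table and the mode", {
  gm <- tiny_genes()
  # gplus: 2 sense-intronic, 1 antisense-intronic
  sites <- insertion_sites("chrT", c(1300L, 1600L, 1500L),
                           c("+", "+", "-"))
  inact <- count_gene_insertions(sites, gm, "inactivating_only")
  row <- inact[inact$gene_id == "gplus", ]
  expect_identical(row$count, 2L)
  expect_identical(row$sense_intronic, 2L)
  expect_identical(row$antisense_intronic, 1L)
  expect_identical(inact[inact$gene_id == "gminus", "count"], 0L)

  any <- count_gene_insertions(sites, gm, "any_orientation")
  expect_identical(any[any$gene_id == "gplus", "count"], 3L)
  expect_identical(attr(any, "total"), 3L)
  expect_identical(attr(any, "n_intragenic"), 3L)
})

test_that("zero sites give all-zero counts and totals", {
  cnt <- count_gene_insertions(insertion_sites(), tiny_genes(),
                               "any_orientation")
  expect_true(all(cnt$count == 0L))
  expect_identical(attr(cnt, "total"), 0L)
})

test_that("any-orientation counts over non-overlapping genes conserve intragenic sites", {
  gm <- sim_genome(n_genes = 30)
  cfg <- sim_config(gm, seed = 4)
  sites <- simulate_integration(cfg, 3000)
  cnt <- count_gene_insertions(sites, gm, "any_orientation")
  expect_identical(attr(cnt, "total"), attr(cnt, "n_intragenic"))
  expect_true(all(
    count_gene_insertions(sites, gm, "inactivating_only")$count <= cnt$count
  ))
})

test_that("flipping every site strand swaps sense and antisense tallies", {
  gm <- tiny_genes()
  set.seed(8)
  sites <- insertion_sites("chrT", sample(3000:3999, 40),
                           sample(c("+", "-"), 40, replace = TRUE))
  flipped <- sites
  flipped$strand <- ifelse(sites$strand == "+", "-", "+")
  a <- count_gene_insertions(sites, gm, "any_orientation")
  b <- count_gene_insertions(flipped, gm, "any_orientation")
  expect_identical(a$sense_intronic, b$antisense_intronic)
  expect_identical(a$antisense_intronic, b$sense_intronic)
  expect_identical(a$sense_exonic, b$antisense_exonic)
  expect_identical(a$count, b$count)
})

test_that("histogram bins tile the gene 5' to 3' and conserve counts", {
  gm <- tiny_genes()
  expect_true(all(gene_insertion_histogram(insertion_sites(), gm,
                                           "gplus")$sense == 0L))
  set.seed(9)
  pos <- sample(1000:1999, 10)
  sites <- insertion_sites("chrT", pos, sample(c("+", "-"), 10, TRUE))
  h <- gene_insertion_histogram(sites, gm, "gplus", bin = 500L)
  expect_identical(nrow(h), 2L)
  expect_identical(sum(h$sense + h$antisense), 10L)
  # for the minus-strand gene the first bin is the 3'-most coordinate range
  s2 <- insertion_sites("chrT", 3950L, "-")  # 5'-proximal on gminus
  h2 <- gene_insertion_histogram(s2, gm, "gminus", bin = 500L)
  expect_identical(h2$sense, c(1L, 0L))
})

test_that("a 3'-restricted sense pattern concentrates in the last bins", {
  gm <- tiny_genes()
  # sense insertions in the 3'-terminal part of gplus
  sites <- insertion_sites("chrT", c(1700L, 1750L, 1790L), rep("+", 3))
  h <- gene_insertion_histogram(sites, gm, "gplus", bin = 100L)
  expect_identical(sum(h$sense[h$bin_start >= 700]), 3L)
  expect_identical(sum(h$sense[h$bin_start < 700]), 0L)
})

test_that("refFlat round-trips through write and read", {
  gm <- tiny_genes()
  f <- withr::local_tempfile(fileext = ".refflat")
  write_refflat(gm, f)
  back <- read_refflat(f)
  expect_equal(back$genes[order(back$genes$gene_id), ],
               gm$genes[order(gm$genes$gene_id), ], ignore_attr = TRUE)
  expect_equal(back$exons[order(back$exons$gene_id, back$exons$start), ],
               gm$exons[order(gm$exons$gene_id, gm$exons$start), ],
               ignore_attr = TRUE)
})

test_that("refFlat transcript variants merge into one gene model", {
  lines <- c(
    paste("GENE", "tx1", "chr1", "+", 100, 1000, 100, 1000, 2,
          "100,600,", "300,1000,", sep = "\t"),
    paste("GENE", "tx2", "chr1", "+", 200, 1200, 200, 1200, 2,
          "200,900,", "400,1200,", sep = "\t")
  )
  f <- withr::local_tempfile(fileext = ".refflat")
  writeLines(lines, f)
  gm <- read_refflat(f)
  expect_identical(nrow(gm$genes), 1L)
  expect_identical(gm$genes$start, 100L)
  expect_identical(gm$genes$end, 1200L)
  # exon unions: [100,400) (merged 100-300 and 200-400), [600,1000), [900,1200) merge to [600,1200)
  expect_identical(gm$exons$start, c(100L, 600L))
  expect_identical(gm$exons$end, c(400L, 1200L))
  # a position exonic in any transcript is exonic
  cls <- classify_insertion(insertion_sites("chr1", 350L, "+"), gm, "GENE")
  expect_identical(cls$region, "exon")
})

test_that("GTF exon features build the same gene model as refFlat", {
  gtf <- c(
    paste("chrT", "test", "exon", 1001, 1200, ".", "+", ".",
          'gene_id "gplus"; transcript_id "gplus_tx";', sep = "\t"),
    paste("chrT", "test", "exon", 1801, 2000, ".", "+", ".",
          'gene_id "gplus"; transcript_id "gplus_tx";', sep = "\t")
  )
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gtf, f)
  gm <- read_gtf(f)
  expect_identical(gm$genes$gene_id, "gplus")
  expect_identical(gm$genes$start, 1000L)
  expect_identical(gm$genes$end, 2000L)
  expect_identical(gm$exons$start, c(1000L, 1800L))
  cls <- classify_insertion(insertion_sites("chrT", 1500L, "+"), gm, "gplus")
  expect_identical(cls$region, "intron")
})
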