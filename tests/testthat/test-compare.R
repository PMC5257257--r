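test_that("IGTIOB matches its closed form on the printed examples", {
  expect_identical(igtiob(0, 0), 0)
  expect_identical(igtiob(7, 7), 0)
  expect_equal(igtiob(3, 0), log2(4) * log(4), tolerance = 1e-12)
  expect_equal(igtiob(3, 0), 2.772589, tolerance = 1e-6)
  expect_equal(igtiob(0, 3), -log2(4) * log(4), tolerance = 1e-12)
  expect_error(igtiob(-1, 0), ">= 0")
})

test_that("IGTIOB is antisymmetric and sign-consistent over the count grid", {
  grid <- expand.grid(a = 0:50, b = 0:50)
  sc <- igtiob(grid$a, grid$b)
  expect_equal(sc, -igtiob(grid$b, grid$a), tolerance = 1e-12)
  expect_true(all(sign(sc) == sign(grid$a - grid$b)))
  # sense-only evidence grows the score strictly
  expect_true(all(diff(igtiob(0:50, 0)) > 0))
})

# two deterministic screen_result stand-ins for matrix-assembly tests
fake_screen <- function(gene_id, q, S_raw, A_raw) {
  structure(
    data.frame(gene_id = gene_id, k = S_raw, N = 100L, m = 1L, M = 1000L,
               S_raw = S_raw, A_raw = A_raw, p_value = q, fdr_q = q,
               hit = q < 0.01, stringsAsFactors = FALSE),
    class = c("screen_result", "data.frame"), hit_q = 0.01
  )
}

test_that("comparison matrix admits genes by the stringent threshold in any screen", {
  s1 <- fake_screen(c("A", "B", "C"), c(1e-6, 1e-3, 0.5),
                    S_raw = c(9, 4, 1), A_raw = c(0, 4, 1))
  s2 <- fake_screen(c("A", "B", "D"), c(0.2, 1e-3, 1e-5),
                    S_raw = c(2, 0, 7), A_raw = c(1, 3, 0))
  cm <- build_comparison_matrix(list(scr1 = s1, scr2 = s2))
  # B's best q = 1e-3 > 1e-4 -> excluded; A and D admitted
  expect_setequal(rownames(cm$scores), c("A", "D"))
  # admitted genes carry scores in every screen, incl. where insignificant
  expect_equal(cm$scores["A", "scr1"], igtiob(9, 0))
  expect_equal(cm$scores["A", "scr2"], igtiob(2, 1))
  # D untested in screen 1: score 0 (the formula's own value at 0/0 counts)
  expect_identical(cm$scores["D", "scr1"], 0)
  expect_identical(unname(cm$included_by["A"]), "scr1")
  expect_error(build_comparison_matrix(list(scr1 = s1)), "at least 2")
})

test_that("inclusion is monotone in the threshold and empty matrices are allowed", {
  s1 <- fake_screen(c("A", "B"), c(1e-6, 1e-3), c(5, 1), c(0, 0))
  s2 <- fake_screen(c("A", "B"), c(0.9, 0.8), c(1, 1), c(1, 1))
  loose <- build_comparison_matrix(list(a = s1, b = s2), threshold = 1e-2)
  strict <- build_comparison_matrix(list(a = s1, b = s2), threshold = 1e-4)
  expect_true(all(rownames(strict$scores) %in% rownames(loose$scores)))
  none <- build_comparison_matrix(list(a = s1, b = s2), threshold = 1e-9)
  expect_identical(nrow(none$scores), 0L)
})

test_that("complete-linkage clustering reproduces a hand-traced merge order", {
  rows <- matrix(c(0, 0,
                   0, 3,
                   10, 10), ncol = 2, byrow = TRUE,
                 dimnames = list(c("r1", "r2", "r3"), c("s1", "s2")))
  # L1 distances: d(r1,r2)=3 < d(r2,r3)=17 < d(r1,r3)=20, so r1+r2 merge
  # first and r3 joins last
  ord <- gtscreen:::complete_linkage_order(rows)
  expect_identical(ord, c(1L, 2L, 3L))
  # identical rows merge first at distance 0
  rows2 <- matrix(c(5, 5, 1, 1, 5, 5), ncol = 2, byrow = TRUE)
  expect_identical(gtscreen:::complete_linkage_order(rows2)[1:2], c(1L, 3L))
})

test_that("clustering agrees with a naive complete-linkage oracle on small matrices", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(2:8, 1)
    x <- matrix(sample(0:6, n * 3, replace = TRUE), nrow = n)  # with ties
    expect_identical(gtscreen:::complete_linkage_order(x),
                     oracle_linkage_order(x), info = paste("case", rep))
  }
})

test_that("leaf order is consistent with the stats::hclust tree on tie-free data", {
  # on continuous data the complete-linkage tree is unique, so every cluster
  # of the hclust dendrogram must occupy a contiguous block of our leaf order
  set.seed(78)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    x <- matrix(rnorm(n * 4), nrow = n)
    ord <- gtscreen:::complete_linkage_order(x)
    expect_identical(sort(ord), seq_len(n))
    hc <- stats::hclust(stats::dist(x, method = "manhattan"),
                        method = "complete")
    pos <- match(seq_len(n), ord)
    for (k in 2:(n - 1)) {
      grp <- stats::cutree(hc, k)
      for (g in unique(grp)) {
        p <- sort(pos[grp == g])
        expect_identical(p, seq(min(p), max(p)), info = paste(rep, k, g))
      }
    }
  }
})

test_that("display clipping zeroes negatives after clustering, preserving order", {
  scores <- matrix(c(-2.77, 1, 4, -1, 0.5, -3), ncol = 2,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  cm <- structure(list(scores = scores, included_by = NULL, threshold = 1e-4,
                       gene_order = NULL), class = "comparison_matrix")
  cm <- cluster_genes(cm)
  disp <- clip_for_display(cm)
  expect_true(all(disp >= 0))
  expect_identical(rownames(disp), rownames(scores)[cm$gene_order])
  # an all-negative row becomes all zeros but keeps its position
  i <- which(rownames(disp) == "gC")
  expect_identical(unname(disp["gA", ]), c(0, pmax(scores["gA", 2], 0)))
  expect_true(length(i) == 1)
})

test_that("clustering operates on signed scores by default, absolute on request", {
  scores <- matrix(c(-5, 5, 0,
                     -5, 5, 0), ncol = 2,
                   dimnames = list(c("gA", "gB", "gC"), c("s1", "s2")))
  cm <- structure(list(scores = scores, included_by = NULL, threshold = 1e-4,
                       gene_order = NULL), class = "comparison_matrix")
  signed <- cluster_genes(cm)$gene_order
  absolute <- cluster_genes(cm, on = "absolute")$gene_order
  # signed: gA (-5,-5) is 10 from gC and 20 from gB -> gC sits between
  expect_identical(signed, c(1L, 3L, 2L))
  # absolute: gA and gB coincide at (5,5) and merge first
  expect_identical(absolute[1:2], c(1L, 2L))
})

test_that("median_sem implements the 1.253 sd/sqrt(n) convention", {
  expect_equal(unname(median_sem(c(5, 5, 5, 5))), c(5, 0))
  x <- c(1, 2, 3, 4, 5)
  ms <- median_sem(x)
  expect_equal(unname(ms["median"]), 3)
  expect_equal(unname(ms["sem"]), 1.253 * sd(x) / sqrt(5))
  expect_equal(unname(ms["sem"]), 0.8860, tolerance = 1e-4)
  expect_identical(median_sem(sample(x)), ms)
  expect_error(median_sem(3), "at least 2")
})
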