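#' One-sided Fisher exact test for per-gene insertion enrichment
#'
#' Tests whether a gene carries inactivating insertions in the sorted
#' dataset at a higher relative frequency than it carries any insertion in
#' the control dataset. The 2x2 table is
#' \preformatted{  [ k      N - k ]
#'   [ m      M - m ]}
#' with `k` inactivating insertions in the gene (sorted), `N` total
#' inactivating insertions over all genes (sorted), `m` any-orientation
#' insertions in the gene (control) and `M` the control total. The one-sided
#' p-value (alternative: gene frequency greater in sorted) is the exact
#' hypergeometric upper tail P(X >= k) with X ~ Hypergeom(k+m, N+M-k-m, N);
#' no continuity correction and no pseudocounts.
#'
#' All arguments are vectorised over genes.
#'
#' @param k,N,m,M integer counts as above; requires `k <= N`, `m <= M`,
#'   `N >= 1`, `M >= 1`.
#' @return numeric vector of one-sided p-values.
#' @export
#' @examples
#' fisher_enrichment(k = 8, N = 100, m = 2, M = 400)
fisher_enrichment <- function(k, N, m, M) {
  if (any(k < 0 | m < 0)) stop("counts must be non-negative")
  if (any(k > N | m > M)) stop("gene counts cannot exceed dataset totals")
  if (any(N < 1 | M < 1)) stop("dataset totals must be >= 1")
  stats::phyper(k - 1, k + m, (N - k) + (M - m), N, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values: on ascending p-values, q_(i) = min over j >= i of
#' min(1, p_(j) * m / j), mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
fdr_correct <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Analyze one screen: per-gene enrichment of inactivating insertions
#'
#' Builds per-gene counts (inactivating mode on the sorted dataset,
#' any-orientation mode on the control dataset), applies the one-sided
#' Fisher exact test to every gene with at least one insertion in either
#' dataset, and corrects across exactly that tested family with
#' Benjamini-Hochberg. Genes hit at `fdr_q < hit_q` are flagged.
#'
#' @param sorted_sites unique insertion sites from the FACS-sorted
#'   population.
#' @param control_sites unique insertion sites from the unsorted control
#'   population.
#' @param genes a [gene_models] object.
#' @param hit_q FDR threshold for calling hits (default 0.01).
#' @return a `screen_result`: data.frame sorted by (fdr_q, p_value, gene_id)
#'   with columns `gene_id`, `k` (sorted inactivating), `N`, `m` (control
#'   any), `M`, `S_raw`/`A_raw` (sorted sense/antisense intronic),
#'   `p_value`, `fdr_q`, `hit`. Attribute `hit_q` records the threshold.
#' @export
analyze_screen <- function(sorted_sites, control_sites, genes, hit_q = 0.01) {
  if (!nrow(sorted_sites)) {
    stop("sorted dataset is empty: nothing to test")
  }
  cs <- count_gene_insertions(sorted_sites, genes, "inactivating_only")
  cc <- count_gene_insertions(control_sites, genes, "any_orientation")
  N <- attr(cs, "total")
  M <- attr(cc, "total")
  if (N < 1) stop("sorted dataset has no inactivating intragenic insertions")
  if (M < 1) stop("control dataset has no intragenic insertions")
  tested <- cs$count > 0 | cc$count > 0
  res <- data.frame(
    gene_id = cs$gene_id[tested],
    k = cs$count[tested],
    N = N,
    m = cc$count[tested],
    M = M,
    S_raw = cs$sense_intronic[tested],
    A_raw = cs$antisense_intronic[tested],
    stringsAsFactors = FALSE
  )
  res$p_value <- fisher_enrichment(res$k, res$N, res$m, res$M)
  res$fdr_q <- fdr_correct(res$p_value)
  res$hit <- res$fdr_q < hit_q
  res <- res[order(res$fdr_q, res$p_value, res$gene_id), ]
  rownames(res) <- NULL
  attr(res, "hit_q") <- hit_q
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d genes tested, %d hits at q < %g\n",
              nrow(x), sum(x$hit), attr(x, "hit_q")))
  print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write a screen result as TSV
#' @param result a `screen_result` from [analyze_screen()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}

#' Per-gene circle-plot coordinates
#'
#' The conventional display of a screen plots each gene at
#' -log10(FDR-corrected p) on the y axis with the circle diameter
#' proportional to the number of unique inactivating insertions.
#'
#' @param result a `screen_result`.
#' @return data.frame `gene_id`, `neg_log10_q`, `inactivating_count`, `hit`.
#' @export
circle_plot_data <- function(result) {
  data.frame(
    gene_id = result$gene_id,
    neg_log10_q = -log10(result$fdr_q),
    inactivating_count = result$k,
    hit = result$hit,
    stringsAsFactors = FALSE
  )
}
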