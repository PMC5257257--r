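#' Intronic GT insertion orientation-bias (IGTIOB) score
#'
#' A sorted-dataset-only metric for comparing hits between screens. With
#' S = 1 + (unique sense intronic insertions) and A = 1 + (unique antisense
#' intronic insertions) in a gene, the score is
#' \deqn{\mathrm{IGTIOB} = \log_2(S/A) \cdot \ln(S \cdot A).}
#' The log-ratio term captures the orientation bias expected of a gene whose
#' disruption drives the sorted phenotype (the gene trap disrupts intronic
#' targets chiefly in the sense orientation), and the ln(S*A) term weights it
#' by the overall intronic insertion load. The score is 0 when the raw
#' counts are equal and antisymmetric under swapping them.
#'
#' @param S_raw,A_raw non-negative counts of unique sense / antisense
#'   intronic insertions (vectorised).
#' @return numeric score(s).
#' @export
#' @examples
#' igtiob(3, 0)   # log2(4) * ln(4)
#' igtiob(5, 5)   # 0
igtiob <- function(S_raw, A_raw) {
  if (any(S_raw < 0 | A_raw < 0)) stop("insertion counts must be >= 0")
  S <- 1 + S_raw
  A <- 1 + A_raw
  log2(S / A) * log(S * A)
}

#' Build the gene x screen IGTIOB comparison matrix
#'
#' Genes are admitted when their enrichment q-value falls below a stringent
#' threshold (default 1e-4) in at least one of the screens; admitted genes
#' get an IGTIOB score in every screen, computed from that screen's sorted
#' intronic counts. A gene absent from a screen's tested set has
#' S_raw = A_raw = 0 and hence score 0 by the formula itself.
#'
#' @param screens named list of `screen_result` objects (>= 2).
#' @param threshold inclusion threshold on the FDR-corrected p-value
#'   (default 1e-4).
#' @return a `comparison_matrix`: list with `scores` (gene x screen numeric
#'   matrix, signed), `included_by` (per gene, one screen where q <
#'   threshold), `threshold`, and `gene_order` (`NULL` until
#'   [cluster_genes()] is applied).
#' @export
build_comparison_matrix <- function(screens, threshold = 1e-4) {
  if (length(screens) < 2) stop("need at least 2 screens to compare")
  if (is.null(names(screens)) || anyDuplicated(names(screens)) ||
      any(names(screens) == "")) {
    stop("screens must be a uniquely named list")
  }
  q_of <- lapply(screens, function(s) {
    stats::setNames(s$fdr_q, s$gene_id)
  })
  all_genes <- sort(unique(unlist(lapply(screens, `[[`, "gene_id"))))
  min_q <- rep(Inf, length(all_genes))
  included_by <- rep(NA_character_, length(all_genes))
  for (sc in names(screens)) {
    q <- q_of[[sc]][all_genes]
    q[is.na(q)] <- Inf
    pass <- q < threshold & is.na(included_by)
    included_by[pass] <- sc
    min_q <- pmin(min_q, q)
  }
  keep <- min_q < threshold
  genes <- all_genes[keep]
  scores <- matrix(0, nrow = length(genes), ncol = length(screens),
                   dimnames = list(genes, names(screens)))
  for (sc in names(screens)) {
    s <- screens[[sc]]
    i <- match(genes, s$gene_id)
    hit <- !is.na(i)
    scores[hit, sc] <- igtiob(s$S_raw[i[hit]], s$A_raw[i[hit]])
  }
  structure(
    list(scores = scores,
         included_by = stats::setNames(included_by[keep], genes),
         threshold = threshold,
         gene_order = NULL),
    class = "comparison_matrix"
  )
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf(
    "comparison_matrix: %d genes x %d screens (inclusion q < %g)%s\n",
    nrow(x$scores), ncol(x$scores), x$threshold,
    if (is.null(x$gene_order)) "" else ", clustered"))
  invisible(x)
}

#' Cluster comparison-matrix genes (city-block, complete linkage)
#'
#' Agglomerative hierarchical clustering of the gene rows using the
#' city-block (L1) distance and complete linkage, without row normalization,
#' on the signed scores (the display clipping of negative values happens
#' after clustering). Merge-distance ties are broken toward the pair whose
#' first member has the lowest original row index, so the leaf order is
#' fully deterministic.
#'
#' @param cm a `comparison_matrix`.
#' @param on cluster on `"signed"` scores (default) or on `"absolute"`
#'   values.
#' @return the input with `gene_order` set to the dendrogram leaf order
#'   (integer permutation of row indices).
#' @export
cluster_genes <- function(cm, on = c("signed", "absolute")) {
  on <- match.arg(on)
  x <- cm$scores
  if (on == "absolute") x <- abs(x)
  n <- nrow(x)
  if (n == 0) {
    cm$gene_order <- integer()
    return(cm)
  }
  cm$gene_order <- complete_linkage_order(x)
  cm
}

# Complete-linkage agglomeration on L1 distances with deterministic
# tie-breaks; returns the dendrogram leaf order. Lance-Williams update:
# complete-linkage distance to a merged cluster is the max of the two
# distances.
complete_linkage_order <- function(x) {
  n <- nrow(x)
  if (n == 1L) return(1L)
  d <- as.matrix(stats::dist(x, method = "manhattan"))
  diag(d) <- Inf
  members <- as.list(seq_len(n))   # leaf order within each cluster
  lead <- seq_len(n)               # lowest original index per cluster
  alive <- rep(TRUE, n)
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    sub <- d[idx, idx, drop = FALSE]
    best <- min(sub)
    # candidate pairs at the minimum; break ties by lowest original index of
    # the first member, then of the second
    cand <- which(sub == best, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(lead[idx[cand[, 1]]], lead[idx[cand[, 2]]])
    a <- idx[cand[ord[1], 1]]
    b <- idx[cand[ord[1], 2]]
    if (lead[a] > lead[b]) { tmp <- a; a <- b; b <- tmp }
    members[[a]] <- c(members[[a]], members[[b]])
    lead[a] <- min(lead[a], lead[b])
    alive[b] <- FALSE
    upd <- which(alive)
    upd <- upd[upd != a]
    d[a, upd] <- d[upd, a] <- pmax(d[a, upd], d[b, upd])
  }
  members[[which(alive)]]
}

#' Clip a comparison matrix for display
#'
#' The heat-map display encompasses only non-negative scores: negative
#' values are shown as 0. Clipping is applied after clustering, which
#' operates on the unclipped scores; the gene order is unchanged.
#'
#' @param cm a `comparison_matrix` (ideally already clustered).
#' @return numeric matrix `pmax(scores, 0)`, rows in `gene_order` when set.
#' @export
clip_for_display <- function(cm) {
  m <- pmax(cm$scores, 0)
  if (!is.null(cm$gene_order) && length(cm$gene_order)) {
    m <- m[cm$gene_order, , drop = FALSE]
  }
  m
}

#' Write comparison-matrix TSVs (signed and display-clipped)
#' @param cm a `comparison_matrix`.
#' @param path_signed,path_display output paths; either may be `NULL` to
#'   skip.
#' @return invisibly, the written paths.
#' @export
write_comparison_tsv <- function(cm, path_signed = NULL, path_display = NULL) {
  ord <- if (is.null(cm$gene_order) || !length(cm$gene_order)) {
    seq_len(nrow(cm$scores))
  } else {
    cm$gene_order
  }
  out <- character()
  if (!is.null(path_signed)) {
    df <- data.frame(gene_id = rownames(cm$scores)[ord],
                     cm$scores[ord, , drop = FALSE], check.names = FALSE)
    data.table::fwrite(df, path_signed, sep = "\t")
    out <- c(out, path_signed)
  }
  if (!is.null(path_display)) {
    m <- pmax(cm$scores, 0)
    df <- data.frame(gene_id = rownames(cm$scores)[ord],
                     m[ord, , drop = FALSE], check.names = FALSE)
    data.table::fwrite(df, path_display, sep = "\t")
    out <- c(out, path_display)
  }
  invisible(out)
}

#' Plot the comparison heat map
#'
#' Presentation-only convenience wrapper around pheatmap: rows in the
#' clustered order, negative scores clipped to 0, no further clustering or
#' scaling applied by the plotting layer.
#'
#' @param cm a clustered `comparison_matrix`.
#' @param ... passed to [pheatmap::pheatmap()].
#' @export
plot_comparison <- function(cm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_comparison requires the pheatmap package")
  }
  pheatmap::pheatmap(clip_for_display(cm), cluster_rows = FALSE,
                     cluster_cols = FALSE, ...)
}

#' Median with standard error of the median
#'
#' For FACS fluorescence summaries the median is reported with its standard
#' error, SEM = 1.253 * sd / sqrt(n) (the large-sample normal approximation
#' for the median's sampling error).
#'
#' @param values numeric vector, length >= 2.
#' @return named numeric vector `c(median = ..., sem = ...)`.
#' @export
#' @examples
#' median_sem(c(1, 2, 3, 4, 5))
median_sem <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  c(median = stats::median(values),
    sem = 1.253 * stats::sd(values) / sqrt(length(values)))
}
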