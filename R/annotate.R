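#' Classify intragenic insertions by orientation and region
#'
#' Each insertion overlapping a gene span is classified as sense or antisense
#' (insertion strand vs. gene strand) and as exonic or intronic (exonic when
#' the position falls in the gene's merged exon union, i.e. exonic in any
#' transcript). The gene trap's splice acceptor is directional, so an
#' insertion is *inactivating* when it is exonic (either orientation) or
#' intronic in the sense orientation; antisense intronic insertions leave the
#' gene intact.
#'
#' A site overlapping several genes yields one classification per gene;
#' sites outside every gene span are absent from the result.
#'
#' @param sites insertion-site data.frame ([insertion_sites()]).
#' @param genes a [gene_models] object.
#' @return data.frame with one row per (site, overlapping gene):
#'   `site_idx` (row in `sites`), `chrom`, `position`, `strand`, `gene_id`,
#'   `orientation` (`"sense"`/`"antisense"`), `region` (`"exon"`/`"intron"`),
#'   `inactivating` (logical).
#' @export
classify_insertions <- function(sites, genes) {
  validate_sites(sites)
  stopifnot(inherits(genes, "gene_models"))
  empty <- data.frame(
    site_idx = integer(), chrom = character(), position = integer(),
    strand = character(), gene_id = character(), orientation = character(),
    region = character(), inactivating = logical(),
    stringsAsFactors = FALSE
  )
  if (!nrow(sites) || !nrow(genes$genes)) return(empty)

  s_gr <- sites_as_granges(sites)
  g_gr <- genes_as_granges(genes)
  ov <- GenomicRanges::findOverlaps(s_gr, g_gr, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  si <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  gene_id <- genes$genes$gene_id[gi]
  gene_strand <- genes$genes$strand[gi]

  # exonic status per (site, gene) pair: overlap with that gene's exon union
  e_gr <- exons_as_granges(genes)
  in_exon <- rep(FALSE, length(ov))
  if (length(e_gr)) {
    ove <- GenomicRanges::findOverlaps(s_gr, e_gr, ignore.strand = TRUE)
    exon_pairs <- paste(S4Vectors::queryHits(ove),
                        S4Vectors::mcols(e_gr)$gene_id[S4Vectors::subjectHits(ove)])
    in_exon <- paste(si, gene_id) %in% exon_pairs
  }
  orientation <- ifelse(sites$strand[si] == gene_strand, "sense", "antisense")
  region <- ifelse(in_exon, "exon", "intron")
  data.frame(
    site_idx = si,
    chrom = sites$chrom[si],
    position = sites$position[si],
    strand = sites$strand[si],
    gene_id = gene_id,
    orientation = orientation,
    region = region,
    inactivating = region == "exon" | orientation == "sense",
    stringsAsFactors = FALSE
  )
}

#' Classify a single insertion against a single gene
#'
#' @param site one-row insertion-site data.frame.
#' @param genes a [gene_models] object.
#' @param gene_id the gene to classify against; the site must lie within its
#'   span.
#' @return one-row classification data.frame (see [classify_insertions()]).
#' @export
classify_insertion <- function(site, genes, gene_id) {
  stopifnot(nrow(site) == 1L)
  gm_sub <- gene_models(genes$genes[genes$genes$gene_id == gene_id, ],
                        genes$exons[genes$exons$gene_id == gene_id, ])
  cls <- classify_insertions(site, gm_sub)
  if (!nrow(cls)) {
    stop("site at ", site$chrom, ":", site$position,
         " lies outside the span of gene ", gene_id)
  }
  cls
}

#' Count insertions per gene
#'
#' Tallies unique insertion sites per gene. In `inactivating_only` mode
#' (used for the sorted dataset) only exonic insertions and sense intronic
#' insertions are counted; in `any_orientation` mode (used for the control
#' dataset) every intragenic site counts regardless of orientation. In both
#' modes the sense/antisense intronic and exonic sub-tallies are reported,
#' and genes without insertions appear with zero counts.
#'
#' @param sites insertion-site data.frame.
#' @param genes a [gene_models] object.
#' @param mode `"inactivating_only"` or `"any_orientation"`.
#' @return data.frame with one row per gene: `gene_id`, `count`,
#'   `sense_intronic`, `antisense_intronic`, `sense_exonic`,
#'   `antisense_exonic`. Attributes: `total` (sum of `count` over genes) and
#'   `n_intragenic` (number of distinct sites overlapping any gene).
#' @export
count_gene_insertions <- function(sites, genes,
                                  mode = c("inactivating_only",
                                           "any_orientation")) {
  mode <- match.arg(mode)
  cls <- classify_insertions(sites, genes)
  counted <- if (mode == "inactivating_only") cls[cls$inactivating, ] else cls
  tab <- function(sub) {
    n <- table(factor(sub$gene_id, levels = genes$genes$gene_id))
    as.integer(n)
  }
  out <- data.frame(
    gene_id = genes$genes$gene_id,
    count = tab(counted),
    sense_intronic = tab(cls[cls$orientation == "sense" &
                               cls$region == "intron", ]),
    antisense_intronic = tab(cls[cls$orientation == "antisense" &
                                   cls$region == "intron", ]),
    sense_exonic = tab(cls[cls$orientation == "sense" &
                             cls$region == "exon", ]),
    antisense_exonic = tab(cls[cls$orientation == "antisense" &
                                 cls$region == "exon", ]),
    stringsAsFactors = FALSE
  )
  attr(out, "total") <- sum(out$count)
  attr(out, "n_intragenic") <- length(unique(cls$site_idx))
  out
}

#' Per-gene insertion histogram in fixed-width bins
#'
#' Counts sense and antisense insertions within consecutive windows (default
#' 500 bp) along a gene, starting from the gene's 5' end, so histograms of
#' genes on either strand read 5' to 3'. This is the per-gene insertion
#' "footprint" used to recognise position-restricted allele classes, e.g. a
#' gene whose insertions cluster sense-only in the last intron.
#'
#' @param sites insertion-site data.frame.
#' @param genes a [gene_models] object.
#' @param gene_id gene to profile.
#' @param bin bin width in bp (default 500).
#' @return data.frame with `bin_start` (bp from the 5' gene end), `sense`
#'   and `antisense` counts per bin.
#' @export
gene_insertion_histogram <- function(sites, genes, gene_id, bin = 500L) {
  stopifnot(bin > 0)
  g <- genes$genes[genes$genes$gene_id == gene_id, ]
  if (!nrow(g)) stop("unknown gene_id: ", gene_id)
  cls <- classify_insertions(sites, genes)
  cls <- cls[cls$gene_id == gene_id, ]
  len <- g$end - g$start
  n_bins <- ceiling(len / bin)
  # distance from the 5' end of the gene, strand-aware
  offset <- if (g$strand == "+") {
    cls$position - g$start
  } else {
    g$end - 1L - cls$position
  }
  idx <- pmin(offset %/% bin, n_bins - 1L) + 1L
  out <- data.frame(
    bin_start = (seq_len(n_bins) - 1L) * bin,
    sense = as.integer(table(factor(idx[cls$orientation == "sense"],
                                    levels = seq_len(n_bins)))),
    antisense = as.integer(table(factor(idx[cls$orientation == "antisense"],
                                        levels = seq_len(n_bins))))
  )
  out
}
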