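#' Gene models for insertion-site annotation
#'
#' A gene model collapses all transcripts of a gene to a single strand-aware
#' span (the union of transcript extents) and a disjoint exon union (a
#' position is exonic when it is exonic in any transcript). Intronic space is
#' the span minus the exon union. Coordinates are 0-based half-open
#' internally; refFlat/BED inputs are already 0-based, GTF is converted on
#' read.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span).
#' @param exons data.frame with columns `gene_id`, `start`, `end`
#'   (0-based half-open). Overlapping exons of a gene are merged.
#' @return object of class `gene_models`: a list with elements `genes` and
#'   `exons` (exons disjoint and sorted within each gene).
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  genes <- data.frame(
    gene_id = as.character(genes$gene_id),
    chrom = as.character(genes$chrom),
    strand = as.character(genes$strand),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in gene models")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(genes$end <= genes$start)) stop("gene span must have end > start")

  ex <- data.table::data.table(
    gene_id = as.character(exons$gene_id),
    start = as.integer(exons$start),
    end = as.integer(exons$end)
  )
  if (nrow(ex) && any(ex$end <= ex$start)) stop("exon end must be > start")
  if (!all(ex$gene_id %in% genes$gene_id)) {
    stop("exon rows refer to unknown gene_id")
  }
  # merge overlapping/adjacent exon intervals per gene
  if (nrow(ex)) {
    merged <- ex[, {
      ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
      list(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    }, by = gene_id]
    ex <- merged[order(merged$gene_id, merged$start), ]
    span <- genes[match(ex$gene_id, genes$gene_id), ]
    if (any(ex$start < span$start | ex$end > span$end)) {
      stop("exons must lie within the gene span")
    }
  }
  structure(list(genes = genes, exons = as.data.frame(ex)),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d merged exons on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons),
              length(unique(x$genes$chrom))))
  invisible(x)
}

genes_as_granges <- function(gm) {
  GenomicRanges::GRanges(
    seqnames = gm$genes$chrom,
    ranges = IRanges::IRanges(start = gm$genes$start + 1L, end = gm$genes$end),
    strand = gm$genes$strand,
    gene_id = gm$genes$gene_id
  )
}

exons_as_granges <- function(gm) {
  if (!nrow(gm$exons)) {
    return(GenomicRanges::GRanges())
  }
  chrom <- gm$genes$chrom[match(gm$exons$gene_id, gm$genes$gene_id)]
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = gm$exons$start + 1L, end = gm$exons$end),
    strand = "*",
    gene_id = gm$exons$gene_id
  )
}

# intron intervals (0-based half-open) of one gene, 5'->3' in gene orientation
gene_introns <- function(gm, gene_id) {
  g <- gm$genes[gm$genes$gene_id == gene_id, ]
  if (!nrow(g)) stop("unknown gene_id: ", gene_id)
  ex <- gm$exons[gm$exons$gene_id == gene_id, ]
  ex <- ex[order(ex$start), ]
  bounds <- sort(unique(c(g$start, ex$start, ex$end, g$end)))
  introns <- data.frame(start = integer(), end = integer())
  if (nrow(ex)) {
    s <- c(g$start, ex$end)
    e <- c(ex$start, g$end)
    keep <- e > s
    introns <- data.frame(start = s[keep], end = e[keep])
  } else {
    introns <- data.frame(start = g$start, end = g$end)
  }
  if (g$strand == "-") introns <- introns[rev(seq_len(nrow(introns))), ]
  rownames(introns) <- NULL
  introns
}

#' Read gene models from a refFlat file
#'
#' refFlat is the UCSC tabular gene-model format: one transcript per line
#' with columns geneName, name, chrom, strand, txStart, txEnd, cdsStart,
#' cdsEnd, exonCount, exonStarts, exonEnds (coordinates 0-based half-open).
#' Transcripts sharing geneName, chrom and strand are merged into one gene
#' model (span = union of transcript extents, exons = union of exons), so an
#' insertion in a region shared by several transcripts of a gene is counted
#' once.
#'
#' @param path path to a refFlat file (no header).
#' @return a [gene_models] object.
#' @export
read_refflat <- function(path) {
  cols <- c("geneName", "name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  tx <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = cols,
                          colClasses = list(character = c(1:4, 10, 11)))
  if (!nrow(tx)) stop("empty refFlat file: ", path)
  key <- paste(tx$geneName, tx$chrom, tx$strand, sep = "\r")
  genes <- data.frame(
    gene_id = tx$geneName[!duplicated(key)],
    chrom = tx$chrom[!duplicated(key)],
    strand = tx$strand[!duplicated(key)],
    start = as.integer(tapply(tx$txStart, key, min)[unique(key)]),
    end = as.integer(tapply(tx$txEnd, key, max)[unique(key)]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    # same symbol on several chroms/strands: disambiguate
    dup <- duplicated(genes$gene_id) | duplicated(genes$gene_id, fromLast = TRUE)
    genes$gene_id[dup] <- paste(genes$gene_id[dup], genes$chrom[dup],
                                genes$strand[dup], sep = "_")
  }
  id_of_key <- stats::setNames(genes$gene_id, unique(key))
  starts <- strsplit(sub(",$", "", tx$exonStarts), ",")
  ends <- strsplit(sub(",$", "", tx$exonEnds), ",")
  exons <- data.frame(
    gene_id = id_of_key[rep(key, lengths(starts))],
    start = as.integer(unlist(starts)),
    end = as.integer(unlist(ends)),
    stringsAsFactors = FALSE
  )
  gene_models(genes, exons)
}

#' Write gene models as refFlat
#'
#' Each merged gene model is written as a single synthetic transcript whose
#' exons are the gene's merged exon union (cdsStart/cdsEnd are set to the
#' transcript bounds).
#'
#' @param gm a [gene_models] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(gm, path) {
  rows <- vapply(seq_len(nrow(gm$genes)), function(i) {
    g <- gm$genes[i, ]
    ex <- gm$exons[gm$exons$gene_id == g$gene_id, ]
    ex <- ex[order(ex$start), ]
    if (!nrow(ex)) ex <- data.frame(start = g$start, end = g$end)
    paste(g$gene_id, paste0(g$gene_id, "_tx"), g$chrom, g$strand,
          g$start, g$end, g$start, g$end, nrow(ex),
          paste0(paste(ex$start, collapse = ","), ","),
          paste0(paste(ex$end, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped by the `gene_id` attribute; the gene span is the
#' union of its exons' extent. GTF 1-based closed coordinates are converted
#' to the package's 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return a [gene_models] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("GTF contains no exon features: ", path)
  gid <- as.character(gr$gene_id)
  df <- data.frame(
    gene_id = gid,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  dt <- data.table::as.data.table(df)
  genes <- dt[, list(chrom = chrom[1], strand = strand[1],
                     start = min(start), end = max(end)), by = gene_id]
  gene_models(as.data.frame(genes),
              df[, c("gene_id", "start", "end")])
}
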