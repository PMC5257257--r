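#' Construct an insertion-site table
#'
#' An insertion site is the first genomic base flanking the proviral LTR
#' junction, with the alignment strand recording the GT orientation.
#' Sites are stored as a plain data.frame with 0-based positions; within one
#' dataset each (chrom, position, strand) combination is unique.
#'
#' @param chrom character chromosome names.
#' @param position integer 0-based positions (leftmost aligned base of the
#'   junction read).
#' @param strand character, `"+"` or `"-"`.
#' @param read_support integer number of reads supporting each site
#'   (default 1).
#' @return data.frame with columns `chrom`, `position`, `strand`,
#'   `read_support`.
#' @export
#' @examples
#' insertion_sites("chr1", c(100L, 250L), c("+", "-"))
insertion_sites <- function(chrom = character(), position = integer(),
                            strand = character(),
                            read_support = rep(1L, length(position))) {
  df <- data.frame(
    chrom = as.character(chrom),
    position = as.integer(position),
    strand = as.character(strand),
    read_support = as.integer(read_support),
    stringsAsFactors = FALSE
  )
  validate_sites(df)
  df
}

validate_sites <- function(sites) {
  stopifnot(is.data.frame(sites))
  need <- c("chrom", "position", "strand", "read_support")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    stop("insertion-site table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(sites)) {
    if (any(sites$position < 0)) stop("insertion positions must be >= 0")
    if (!all(sites$strand %in% c("+", "-"))) {
      stop("insertion strand must be '+' or '-'")
    }
    if (any(sites$read_support < 1)) stop("read_support must be >= 1")
  }
  invisible(sites)
}

# GRanges view of a site table (1-based, width-1 ranges)
sites_as_granges <- function(sites) {
  if (!nrow(sites)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$position + 1L, width = 1L),
    strand = sites$strand
  )
}

#' Read or write insertion sites as BED6
#'
#' The on-disk convention is BED6 with 0-based half-open single-base
#' intervals: `chrom, start, end = start + 1, name = read support,
#' score = 0, strand`.
#'
#' @param path file path.
#' @param sites insertion-site data.frame (see [insertion_sites()]).
#' @return `read_sites_bed()` returns an insertion-site data.frame;
#'   `write_sites_bed()` returns `path` invisibly.
#' @export
read_sites_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  support <- suppressWarnings(as.integer(gr$name))
  if (anyNA(support)) support[is.na(support)] <- 1L
  insertion_sites(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    read_support = support
  )
}

#' @rdname read_sites_bed
#' @export
write_sites_bed <- function(sites, path) {
  validate_sites(sites)
  bed <- data.frame(
    chrom = sites$chrom,
    start = sites$position,
    end = sites$position + 1L,
    name = sites$read_support,
    score = 0L,
    strand = sites$strand
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
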