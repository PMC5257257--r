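#' Filter junction reads to strictly unique alignments
#'
#' A 36-bp junction read is kept only when it aligns to exactly one genomic
#' placement with zero mismatches and has no additional candidate placement
#' at one or two mismatches. Reads failing either condition (ambiguous at
#' 0 mm, or rescued only with mismatches, or with near-miss secondary
#' placements) are dropped; the retained reads keep only their zero-mismatch
#' placement.
#'
#' @param reports alignment-report data.frame: one row per candidate
#'   placement, columns `read_id`, `chrom`, `position` (0-based), `strand`,
#'   `mismatches` (0, 1 or 2).
#' @return the retained placements (one row per kept read), with attribute
#'   `dropped` giving the number of reads removed.
#' @export
filter_unique_reads <- function(reports) {
  validate_reports(reports)
  dt <- data.table::as.data.table(reports)
  if (!nrow(dt)) {
    out <- as.data.frame(dt)
    attr(out, "dropped") <- 0L
    return(out)
  }
  dt[, n_placements := .N, by = read_id]
  dt[, n_zero := sum(mismatches == 0L), by = read_id]
  # unique at 0 mm AND unique even allowing 1-2 mm <=> the read's only
  # placement is its zero-mismatch one
  keep_read <- dt$n_placements == 1L & dt$n_zero == 1L
  kept <- dt[keep_read & dt$mismatches == 0L]
  n_reads <- length(unique(dt$read_id))
  kept[, c("n_placements", "n_zero") := NULL]
  out <- as.data.frame(kept)
  attr(out, "dropped") <- n_reads - nrow(out)
  out
}

validate_reports <- function(reports) {
  need <- c("read_id", "chrom", "position", "strand", "mismatches")
  miss <- setdiff(need, names(reports))
  if (length(miss)) {
    stop("alignment report lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(reports) && !all(reports$mismatches %in% 0:2)) {
    stop("mismatch counts must be 0, 1 or 2")
  }
  invisible(reports)
}

#' Collapse insertion sites lying 1-2 bp apart
#'
#' Junction reads from the same provirus can map a base or two apart
#' (trimming/sequencing slop), so sites within `max_gap` bp of each other on
#' the same chromosome and strand are merged transitively into one. The
#' retained representative is the member with the greatest read support
#' (ties: smallest position); its support becomes the sum over the merged
#' members.
#'
#' @param sites insertion-site data.frame, unique per
#'   (chrom, position, strand).
#' @param max_gap maximum distance (bp) at which two sites are considered
#'   duplicates (default 2).
#' @param ignore_strand merge across strands as well (default `FALSE`:
#'   opposite-strand reads represent opposite provirus orientations and are
#'   kept apart).
#' @return collapsed sites, sorted by (chrom, position, strand).
#' @export
collapse_nearby_sites <- function(sites, max_gap = 2L, ignore_strand = FALSE) {
  validate_sites(sites)
  if (!nrow(sites)) return(sites)
  dt <- data.table::as.data.table(sites)
  grp_cols <- if (ignore_strand) "chrom" else c("chrom", "strand")
  data.table::setorderv(dt, c(grp_cols, "position"))
  dt[, cluster_id := cumsum(c(1L, diff(position) > max_gap)), by = grp_cols]
  out <- dt[, {
    rep_i <- order(-read_support, position)[1L]
    list(position = position[rep_i],
         strand = strand[rep_i],
         read_support = sum(read_support))
  }, by = c(grp_cols, "cluster_id")]
  out[, cluster_id := NULL]
  res <- as.data.frame(out)[, c("chrom", "position", "strand", "read_support")]
  res <- res[order(res$chrom, res$position, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Derive unique insertion sites from alignment reports
#'
#' Composition of the mapping rules: reads are filtered to strictly unique
#' alignments ([filter_unique_reads()]), reads sharing a placement are
#' deduplicated into one site with `read_support` = number of reads, and
#' sites 1-2 bp apart are collapsed ([collapse_nearby_sites()]).
#'
#' @inheritParams filter_unique_reads
#' @inheritParams collapse_nearby_sites
#' @return insertion-site data.frame; attribute `dropped_reads` records the
#'   number of reads excluded by the uniqueness filter.
#' @export
derive_insertion_sites <- function(reports, max_gap = 2L,
                                   ignore_strand = FALSE) {
  kept <- filter_unique_reads(reports)
  if (!nrow(kept)) {
    out <- insertion_sites()
    attr(out, "dropped_reads") <- attr(kept, "dropped")
    return(out)
  }
  dt <- data.table::as.data.table(kept)
  sites <- dt[, list(read_support = .N), by = c("chrom", "position", "strand")]
  out <- collapse_nearby_sites(as.data.frame(sites), max_gap = max_gap,
                               ignore_strand = ignore_strand)
  attr(out, "dropped_reads") <- attr(kept, "dropped")
  out
}

#' Read alignment reports from TSV or SAM
#'
#' The TSV dialect is five named columns (`read_id`, `chrom`, `position`,
#' `strand`, `mismatches`), one row per candidate placement, positions
#' 0-based. SAM input is read through Rsamtools; every mapped record of a
#' read (primary or secondary, e.g. from an aligner reporting up to k
#' placements) contributes one placement, with the mismatch count taken
#' from the NM tag.
#'
#' @param path input path; format inferred from the extension
#'   (`.sam`/`.bam` vs anything else = TSV) unless `format` is given.
#' @param format `"tsv"`, `"sam"` or `NULL` (infer).
#' @return alignment-report data.frame.
#' @export
read_alignment_reports <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) {
      "sam"
    } else {
      "tsv"
    }
  }
  format <- match.arg(format, c("tsv", "sam"))
  if (format == "tsv") {
    rep <- as.data.frame(data.table::fread(path, header = TRUE))
    validate_reports(rep)
    return(rep)
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM input requires the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "flag"),
    tag = "NM"
  )
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  mapped <- !is.na(rec$pos)
  nm <- rec$tag$NM[mapped]
  nm[is.na(nm)] <- 0L
  rep <- data.frame(
    read_id = rec$qname[mapped],
    chrom = as.character(rec$rname[mapped]),
    position = rec$pos[mapped] - 1L,
    strand = as.character(rec$strand[mapped]),
    mismatches = as.integer(nm),
    stringsAsFactors = FALSE
  )
  validate_reports(rep)
  rep
}

#' Write alignment reports as the 5-column TSV dialect
#' @param reports alignment-report data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_reports <- function(reports, path) {
  validate_reports(reports)
  data.table::fwrite(reports, path, sep = "\t")
  invisible(path)
}
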