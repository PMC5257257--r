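# Small in-code fixtures shared across test files.

# two-gene annotation on opposite strands:
#   gplus  chrT:+ span [1000, 2000), exons [1000,1200) and [1800,2000)
#   gminus chrT:- span [3000, 4000), exons [3000,3200) and [3800,4000)
tiny_genes <- function() {
  gene_models(
    genes = data.frame(
      gene_id = c("gplus", "gminus"),
      chrom = "chrT",
      strand = c("+", "-"),
      start = c(1000L, 3000L),
      end = c(2000L, 4000L)
    ),
    exons = data.frame(
      gene_id = rep(c("gplus", "gminus"), each = 2),
      start = c(1000L, 1800L, 3000L, 3800L),
      end = c(1200L, 2000L, 3200L, 4000L)
    )
  )
}

# random, well-separated site set (no two sites within `min_gap`), for
# round-trip tests where collapse must not fire
spaced_sites <- function(n, seed, min_gap = 10L, chrom = "chrT") {
  set.seed(seed)
  insertion_sites(
    chrom = chrom,
    position = sort(sample.int(100000L, n)) * min_gap,
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_support = sample(1:5, n, replace = TRUE)
  )
}

# random site set allowed to contain near-duplicates, for collapse tests
clustered_sites <- function(n, seed, span = 300L) {
  set.seed(seed)
  insertion_sites(
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    position = sample.int(span, n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    read_support = sample(1:9, n, replace = TRUE)
  )
}

# drop exact coordinate duplicates (inputs to collapse must be unique)
unique_sites <- function(sites) {
  key <- paste(sites$chrom, sites$position, sites$strand)
  out <- sites[!duplicated(key), ]
  rownames(out) <- NULL
  out
}
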