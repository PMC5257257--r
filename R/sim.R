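#' Lay out a synthetic genome of gene models for screen simulation
#'
#' Builds a regular, non-overlapping gene layout on one synthetic chromosome:
#' genes of fixed length with evenly spaced exons, alternating strands,
#' separated by intergenic gaps. Each gene carries an effect class that
#' couples its disruption to the FACS gate in [simulate_sorting()]:
#' \describe{
#'   \item{`null`}{no effect; insertions pass the gate at the base rate.}
#'   \item{`lof_positive_regulator`}{any inactivating insertion (exonic, or
#'     sense intronic) qualifies — the generic loss-of-function hit.}
#'   \item{`three_prime_sense_dominant`}{only sense insertions in the last
#'     intron qualify — the 3'-restricted dominant-truncation allele class
#'     (AXIN2-like).}
#'   \item{`orientation_independent_intronic`}{sense or antisense intronic
#'     insertions qualify — the rare class disrupted by either orientation
#'     (TFAP4-like).}
#' }
#'
#' @param n_genes number of genes (default 200).
#' @param gene_length gene span in bp (default 10000).
#' @param n_exons exons per gene (default 5).
#' @param exon_length exon width in bp (default 200).
#' @param intergenic_gap gap between consecutive genes in bp (default 10000).
#' @param chrom chromosome name.
#' @param effect_class named character vector assigning non-null effect
#'   classes to gene ids (e.g. `c(g007 = "lof_positive_regulator")`).
#' @param effect_strength named numeric vector of gate-probability
#'   multipliers for the genes in `effect_class` (default 50 for each).
#' @return a `sim_genes` object: a [gene_models] object extended with
#'   per-gene `effect_class`/`effect_strength` columns and a
#'   `genome_length`.
#' @export
sim_genome <- function(n_genes = 200L, gene_length = 10000L, n_exons = 5L,
                       exon_length = 200L, intergenic_gap = 10000L,
                       chrom = "chrS", effect_class = character(),
                       effect_strength = NULL) {
  stopifnot(n_genes >= 1, gene_length > 0, n_exons >= 1,
            exon_length * n_exons <= gene_length)
  ids <- sprintf("g%03d", seq_len(n_genes))
  starts <- intergenic_gap + (seq_len(n_genes) - 1L) *
    (gene_length + intergenic_gap)
  genes <- data.frame(
    gene_id = ids,
    chrom = chrom,
    strand = rep(c("+", "-"), length.out = n_genes),
    start = as.integer(starts),
    end = as.integer(starts + gene_length),
    stringsAsFactors = FALSE
  )
  # evenly spaced exons: exon i begins at a fixed fraction of the span
  pitch <- (gene_length - exon_length) %/% max(1L, n_exons - 1L)
  ex_off <- (seq_len(n_exons) - 1L) * pitch
  exons <- data.frame(
    gene_id = rep(ids, each = n_exons),
    start = as.integer(rep(starts, each = n_exons) + ex_off),
    end = as.integer(rep(starts, each = n_exons) + ex_off + exon_length),
    stringsAsFactors = FALSE
  )
  gm <- gene_models(genes, exons)

  cls <- rep("null", n_genes)
  strength <- rep(1, n_genes)
  if (length(effect_class)) {
    bad <- setdiff(names(effect_class), ids)
    if (length(bad)) stop("effect gene(s) absent from gene list: ",
                          paste(bad, collapse = ", "))
    ok <- c("lof_positive_regulator", "three_prime_sense_dominant",
            "orientation_independent_intronic")
    if (!all(effect_class %in% ok)) {
      stop("unknown effect_class; use one of: ", paste(ok, collapse = ", "))
    }
    if (is.null(effect_strength)) {
      effect_strength <- stats::setNames(rep(50, length(effect_class)),
                                         names(effect_class))
    }
    cls[match(names(effect_class), ids)] <- unname(effect_class)
    strength[match(names(effect_class), ids)] <-
      unname(effect_strength[names(effect_class)])
  }
  if (any((cls == "null") != (strength == 1))) {
    stop("effect_strength must be 1 exactly for null genes and only for them")
  }
  gm$genes$effect_class <- cls
  gm$genes$effect_strength <- strength
  gm$genome_length <- as.integer(max(genes$end) + intergenic_gap)
  class(gm) <- c("sim_genes", "gene_models")
  gm
}

#' Simulation configuration for a synthetic screen
#'
#' Collects the study conditions of a simulated screen: a mutagenized pool
#' in which every haploid cell carries exactly one gene-trap insertion, a
#' FACS gate admitting a base fraction of cells, and retroviral integration
#' biased toward transcriptional start sites (TSS). Integration positions
#' are drawn from a mixture: with probability `tss_bias_weight` uniform in a
#' window downstream of a random gene's TSS, otherwise uniform over the
#' genome (optionally redirecting a `intergenic_rate` fraction of those
#' draws into intergenic space). Orientation is uniform on the two strands.
#'
#' @param genes a `sim_genes` layout from [sim_genome()].
#' @param n_cells_control cells sampled from the unsorted population
#'   (default 1e5).
#' @param n_cells_sorted_pool cells offered to the FACS gate (default 1e5).
#' @param gate_fraction base probability that a cell passes the gate
#'   (default 0.10, a "lowest 10%" gate; stringent screens use e.g. 0.02).
#' @param tss_bias_weight fraction of integrations drawn from the
#'   TSS-proximal component (default 0.3; the bias is qualitative in real
#'   data and this is a package default, see the vignette).
#' @param tss_window width in bp of the TSS-proximal window (default 500).
#' @param intergenic_rate extra fraction of non-TSS draws forced into
#'   intergenic space (default 0: the uniform component already covers it).
#' @param seed integer seed driving all randomness of the simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genes, n_cells_control = 1e5L,
                       n_cells_sorted_pool = 1e5L, gate_fraction = 0.10,
                       tss_bias_weight = 0.3, tss_window = 500L,
                       intergenic_rate = 0, seed = 1L) {
  stopifnot(inherits(genes, "sim_genes"))
  if (genes$genome_length <= 0) stop("genome_length must be positive")
  stopifnot(gate_fraction > 0, gate_fraction <= 1,
            tss_bias_weight >= 0, tss_bias_weight < 1,
            intergenic_rate >= 0, intergenic_rate < 1, tss_window > 0)
  if (gate_fraction * n_cells_sorted_pool < 1) {
    stop("gate_fraction * n_cells_sorted_pool must be >= 1")
  }
  structure(
    list(genes = genes,
         n_cells_control = as.integer(n_cells_control),
         n_cells_sorted_pool = as.integer(n_cells_sorted_pool),
         gate_fraction = gate_fraction,
         tss_bias_weight = tss_bias_weight,
         tss_window = as.integer(tss_window),
         intergenic_rate = intergenic_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# draw n integration sites without touching the seed (callers seed the RNG)
sim_draw_sites <- function(config, n) {
  g <- config$genes$genes
  L <- config$genes$genome_length
  if (n == 0) return(insertion_sites())
  from_tss <- stats::runif(n) < config$tss_bias_weight
  pos <- integer(n)
  n_uni <- sum(!from_tss)
  if (n_uni) {
    u <- as.integer(floor(stats::runif(n_uni) * L))
    if (config$intergenic_rate > 0) {
      inter <- intergenic_intervals(config$genes)
      if (nrow(inter)) {
        redirect <- stats::runif(n_uni) < config$intergenic_rate
        u[redirect] <- sample_intervals(inter, sum(redirect))
      }
    }
    pos[!from_tss] <- u
  }
  n_tss <- sum(from_tss)
  if (n_tss) {
    gi <- sample.int(nrow(g), n_tss, replace = TRUE)
    off <- as.integer(floor(stats::runif(n_tss) * config$tss_window))
    tss_pos <- ifelse(g$strand[gi] == "+",
                      g$start[gi] + off,
                      g$end[gi] - 1L - off)
    pos[from_tss] <- as.integer(tss_pos)
  }
  pos <- pmin(pmax(pos, 0L), L - 1L)
  insertion_sites(
    chrom = rep(g$chrom[1], n),
    position = pos,
    strand = c("+", "-")[1L + (stats::runif(n) < 0.5)],
    read_support = rep(1L, n)
  )
}

intergenic_intervals <- function(sim_genes) {
  g <- sim_genes$genes[order(sim_genes$genes$start), ]
  s <- c(0L, g$end)
  e <- c(g$start, sim_genes$genome_length)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

sample_intervals <- function(intervals, n) {
  if (!n) return(integer())
  w <- intervals$end - intervals$start
  i <- sample.int(nrow(intervals), n, replace = TRUE, prob = w)
  as.integer(intervals$start[i] +
               floor(stats::runif(n) * w[i]))
}

#' Simulate gene-trap integrations
#'
#' Draws `n` single-insertion cells from the integration model of a
#' [sim_config()]: TSS-biased mixture positions, uniform orientation.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a `sim_config`.
#' @param n number of cells (= insertions; each haploid cell carries exactly
#'   one).
#' @return insertion-site data.frame with `read_support = 1` per cell.
#' @export
simulate_integration <- function(config, n) {
  stopifnot(inherits(config, "sim_config"), n >= 0)
  set.seed(config$seed)
  sim_draw_sites(config, n)
}

# gate-probability multiplier per insertion, from the carrying gene's
# effect class
effect_multiplier <- function(sites, sim_genes) {
  mult <- rep(1, nrow(sites))
  if (!nrow(sites)) return(mult)
  cls <- classify_insertions(sites, sim_genes)
  if (!nrow(cls)) return(mult)
  g <- sim_genes$genes
  eff <- g$effect_class[match(cls$gene_id, g$gene_id)]
  strength <- g$effect_strength[match(cls$gene_id, g$gene_id)]
  qualifies <- rep(FALSE, nrow(cls))

  is_lof <- eff == "lof_positive_regulator"
  qualifies[is_lof] <- cls$inactivating[is_lof]

  is_3p <- eff == "three_prime_sense_dominant"
  if (any(is_3p)) {
    for (gid in unique(cls$gene_id[is_3p])) {
      introns <- gene_introns(sim_genes, gid)
      if (!nrow(introns)) next
      last <- introns[nrow(introns), ]   # 3'-terminal intron
      sel <- is_3p & cls$gene_id == gid
      qualifies[sel] <- cls$orientation[sel] == "sense" &
        cls$region[sel] == "intron" &
        cls$position[sel] >= last$start & cls$position[sel] < last$end
    }
  }

  is_oii <- eff == "orientation_independent_intronic"
  qualifies[is_oii] <- cls$region[is_oii] == "intron"

  # one multiplier per site: a qualifying hit in any overlapped gene counts
  hit <- cls$site_idx[qualifies]
  mult[unique(hit)] <- pmax(mult[unique(hit)],
                            tapply(strength[qualifies], hit, max)[
                              as.character(unique(hit))])
  mult
}

#' Simulate FACS sorting of a mutagenized pool
#'
#' Draws the unsorted control dataset and the sorted dataset of one screen.
#' Every cell of the sorted pool enters the sorted set with probability
#' `min(1, gate_fraction * multiplier)`, where the multiplier is the
#' carrying gene's `effect_strength` when the insertion qualifies under the
#' gene's effect class (see [sim_genome()]) and 1 otherwise (null genes,
#' non-qualifying insertions, intergenic insertions). Sorting is an
#' independent Bernoulli draw per cell, equivalent in expectation to an
#' exact-quantile gate.
#'
#' @param config a `sim_config`.
#' @return list with elements `control` and `sorted`, each an
#'   insertion-site data.frame.
#' @export
simulate_sorting <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  control <- sim_draw_sites(config, config$n_cells_control)
  pool <- sim_draw_sites(config, config$n_cells_sorted_pool)
  mult <- effect_multiplier(pool, config$genes)
  p_gate <- pmin(1, config$gate_fraction * mult)
  keep <- stats::runif(nrow(pool)) < p_gate
  list(control = control, sorted = pool[keep, , drop = FALSE])
}

#' Emit synthetic alignment reports from insertion sites
#'
#' Produces the per-read alignment reports an aligner would emit for the
#' junction reads of a site set, optionally contaminated with the ambiguity
#' classes the uniqueness filter must remove: with probability
#' `multimap_rate` a read gains an extra placement (half of them a second
#' zero-mismatch placement, half an extra placement at 1-2 mismatches), and
#' with probability `near_dup_rate` a site spawns an additional clean read
#' offset by 1-2 bp (a near-duplicate the collapse rule must merge). Clean
#' reads map back to their source site exactly.
#'
#' @param sites insertion-site data.frame; each site emits `read_support`
#'   reads.
#' @param multimap_rate fraction of reads given an extra placement, in
#'   \[0, 1).
#' @param near_dup_rate fraction of sites spawning a 1-2 bp-offset duplicate
#'   read, in \[0, 1\].
#' @param seed integer seed.
#' @return alignment-report data.frame (`read_id`, `chrom`, `position`,
#'   `strand`, `mismatches`).
#' @export
emit_alignment_reports <- function(sites, multimap_rate = 0,
                                   near_dup_rate = 0, seed = 1L) {
  validate_sites(sites)
  stopifnot(multimap_rate >= 0, multimap_rate < 1,
            near_dup_rate >= 0, near_dup_rate <= 1)
  set.seed(seed)
  n_sites <- nrow(sites)
  if (!n_sites) {
    return(data.frame(read_id = character(), chrom = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  src <- rep(seq_len(n_sites), sites$read_support)
  reads <- data.frame(
    read_id = sprintf("read_%06d", seq_along(src)),
    chrom = sites$chrom[src],
    position = sites$position[src],
    strand = sites$strand[src],
    mismatches = 0L,
    stringsAsFactors = FALSE
  )
  out <- reads

  if (multimap_rate > 0) {
    amb <- stats::runif(nrow(reads)) < multimap_rate
    if (any(amb)) {
      extra <- reads[amb, ]
      second_perfect <- stats::runif(nrow(extra)) < 0.5
      extra$mismatches <- ifelse(second_perfect, 0L,
                                 1L + (stats::runif(nrow(extra)) < 0.5))
      # decoy placement well away from the source locus
      extra$position <- extra$position + 1000000L +
        as.integer(floor(stats::runif(nrow(extra)) * 1000))
      out <- rbind(out, extra)
    }
  }

  if (near_dup_rate > 0) {
    dup_site <- stats::runif(n_sites) < near_dup_rate
    if (any(dup_site)) {
      d <- sites[dup_site, , drop = FALSE]
      shift <- (1L + (stats::runif(nrow(d)) < 0.5)) *
        ifelse(stats::runif(nrow(d)) < 0.5, 1L, -1L)
      dup_reads <- data.frame(
        read_id = sprintf("dupread_%06d", seq_len(nrow(d))),
        chrom = d$chrom,
        position = pmax(0L, d$position + shift),
        strand = d$strand,
        mismatches = 0L,
        stringsAsFactors = FALSE
      )
      out <- rbind(out, dup_reads)
    }
  }
  out <- out[order(out$read_id, out$mismatches, out$position), ]
  rownames(out) <- NULL
  out
}
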