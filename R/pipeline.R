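#' Load a pipeline run configuration
#'
#' A run configuration is a YAML file with the keys:
#' \preformatted{
#' annotation: genes.refflat          # refFlat or GTF gene models
#' screens:
#'   - id: wnt_low10
#'     sorted: wnt_low10_sorted.bed   # BED6 sites, or SAM/TSV alignments
#'     control: wnt_low10_control.bed
#' thresholds:
#'   hit_q: 0.01                      # per-screen hit call
#'   compare_q: 1.0e-4                # cross-screen inclusion
#' collapse_bp: 2
#' histogram_bin: 500
#' ignore_strand_collapse: false
#' outdir: results/
#' seed: 1
#' }
#' Relative input paths are resolved against the configuration file's
#' directory. Missing threshold keys default to the values above.
#'
#' @param path YAML configuration file.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  th <- raw$thresholds
  cfg <- list(
    annotation = resolve(raw$annotation),
    screens = lapply(raw$screens, function(s) {
      list(id = s$id, sorted = resolve(s$sorted),
           control = resolve(s$control))
    }),
    hit_q = if (is.null(th$hit_q)) 0.01 else th$hit_q,
    compare_q = if (is.null(th$compare_q)) 1e-4 else th$compare_q,
    collapse_bp = if (is.null(raw$collapse_bp)) 2L else
      as.integer(raw$collapse_bp),
    histogram_bin = if (is.null(raw$histogram_bin)) 500L else
      as.integer(raw$histogram_bin),
    ignore_strand_collapse = isTRUE(raw$ignore_strand_collapse),
    outdir = if (is.null(raw$outdir)) "." else raw$outdir,
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Validate pipeline inputs without running anything
#'
#' Checks screen-id uniqueness, file existence, input-format sniffing,
#' threshold ranges, and (for BED site inputs) that site chromosomes are
#' covered by the annotation. Never mutates state.
#'
#' @param config a `run_config` (see [read_run_config()]), or a path to one.
#' @return data.frame with columns `level` (`"error"`/`"warning"`), `check`
#'   and `message`; zero error rows means the configuration can run.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  fail <- list()
  note <- function(level, check, msg) {
    fail[[length(fail) + 1L]] <<- data.frame(
      level = level, check = check, message = msg, stringsAsFactors = FALSE)
  }
  ids <- vapply(config$screens, `[[`, "", "id")
  if (!length(ids)) note("error", "screens", "no screens configured")
  if (anyDuplicated(ids)) {
    note("error", "screens", paste("duplicate screen id:",
                                   paste(unique(ids[duplicated(ids)]),
                                         collapse = ", ")))
  }
  for (thname in c("hit_q", "compare_q")) {
    th <- config[[thname]]
    if (!is.numeric(th) || th <= 0 || th > 1) {
      note("error", thname, sprintf("%s = %s outside (0, 1]", thname,
                                    format(th)))
    }
  }
  if (config$collapse_bp < 0) note("error", "collapse_bp", "must be >= 0")
  gm <- NULL
  if (!file.exists(config$annotation)) {
    note("error", "annotation", paste("missing file:", config$annotation))
  } else {
    gm <- tryCatch(read_annotation(config$annotation), error = function(e) {
      note("error", "annotation", conditionMessage(e))
      NULL
    })
  }
  for (s in config$screens) {
    for (slot in c("sorted", "control")) {
      p <- s[[slot]]
      if (!file.exists(p)) {
        note("error", paste0(s$id, ".", slot), paste("missing file:", p))
        next
      }
      fmt <- sniff_format(p)
      if (is.na(fmt)) {
        note("error", paste0(s$id, ".", slot),
             paste("unrecognized input format:", p))
        next
      }
      if (fmt == "bed" && !is.null(gm)) {
        sites <- tryCatch(read_sites_bed(p), error = function(e) NULL)
        if (is.null(sites)) {
          note("error", paste0(s$id, ".", slot), paste("unreadable BED:", p))
        } else {
          orphan <- sum(!sites$chrom %in% gm$genes$chrom)
          if (orphan) {
            note("warning", paste0(s$id, ".", slot),
                 sprintf("%d site(s) on chromosomes absent from annotation",
                         orphan))
          }
        }
      }
    }
  }
  if (!length(fail)) {
    return(data.frame(level = character(), check = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, fail)
}

# annotation reader dispatch by extension
read_annotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_gtf(path)
  } else {
    read_refflat(path)
  }
}

sniff_format <- function(path) {
  if (grepl("\\.(sam|bam)$", path, ignore.case = TRUE)) return("sam")
  first <- readLines(path, n = 1L)
  if (!length(first)) return(NA_character_)
  f <- strsplit(first, "\t")[[1]]
  if (length(f) >= 6 && !is.na(suppressWarnings(as.integer(f[2])))) {
    return("bed")
  }
  if (identical(f[1], "read_id")) return("tsv")
  NA_character_
}

# read a screen input (BED sites, or alignments needing site derivation)
read_screen_input <- function(path, collapse_bp, ignore_strand) {
  fmt <- sniff_format(path)
  if (identical(fmt, "bed")) {
    return(read_sites_bed(path))
  }
  reports <- read_alignment_reports(path,
                                    format = if (identical(fmt, "sam"))
                                      "sam" else "tsv")
  derive_insertion_sites(reports, max_gap = collapse_bp,
                         ignore_strand = ignore_strand)
}

#' Run the full screen-analysis pipeline
#'
#' Stages: read annotation; per screen, read (and if necessary derive) the
#' sorted and control unique-site datasets and compute per-gene enrichment;
#' with two or more screens, build and cluster the cross-screen IGTIOB
#' matrix. All stage outputs are written as plain TSV/BED under `outdir`,
#' and a JSON manifest records the configuration, seed and MD5 checksum of
#' every output, so identical configuration and seed reproduce identical
#' checksums.
#'
#' @param config a `run_config`, or a path to a YAML configuration.
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  report <- validate_run_config(config)
  if (any(report$level == "error")) {
    stop("configuration invalid:\n  ",
         paste(report$message[report$level == "error"], collapse = "\n  "))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- read_annotation(config$annotation)
  outputs <- character()
  results <- list()
  for (s in config$screens) {
    sorted <- read_screen_input(s$sorted, config$collapse_bp,
                                config$ignore_strand_collapse)
    control <- read_screen_input(s$control, config$collapse_bp,
                                 config$ignore_strand_collapse)
    res <- analyze_screen(sorted, control, gm, hit_q = config$hit_q)
    results[[s$id]] <- res
    f <- file.path(config$outdir, paste0(s$id, "_enrichment.tsv"))
    write_screen_tsv(res, f)
    outputs <- c(outputs, f)
    message(sprintf("[enrich] %s: %d genes tested, %d hits at q < %g",
                    s$id, nrow(res), sum(res$hit), config$hit_q))
  }
  if (length(results) >= 2) {
    cm <- build_comparison_matrix(results, threshold = config$compare_q)
    if (nrow(cm$scores) >= 2) cm <- cluster_genes(cm)
    f1 <- file.path(config$outdir, "comparison_igtiob_signed.tsv")
    f2 <- file.path(config$outdir, "comparison_igtiob_display.tsv")
    write_comparison_tsv(cm, f1, f2)
    outputs <- c(outputs, f1, f2)
    message(sprintf("[compare] %d gene(s) at q < %g in >= 1 screen",
                    nrow(cm$scores), config$compare_q))
  }
  manifest <- list(
    package = "gtscreen",
    version = as.character(utils::packageVersion("gtscreen")),
    seed = config$seed,
    config = config[setdiff(names(config), "screens")],
    screens = lapply(config$screens, function(s) s[c("id")]),
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  mf <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write the files of a simulated screen to disk
#'
#' Convenience generator for demonstrations and fixtures: simulates one
#' screen under a configuration and writes the control/sorted unique-site
#' BED files (after near-duplicate collapse of coincident integrations)
#' plus the gene annotation as refFlat.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"screen"`).
#' @return named character vector of written paths (`annotation`,
#'   `control`, `sorted`).
#' @export
simulate_screen_files <- function(config, dir, prefix = "screen") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_sorting(config)
  dedupe <- function(sites) {
    dt <- data.table::as.data.table(sites)
    out <- dt[, list(read_support = sum(read_support)),
              by = c("chrom", "position", "strand")]
    collapse_nearby_sites(as.data.frame(out))
  }
  ann <- file.path(dir, paste0(prefix, "_genes.refflat"))
  ctl <- file.path(dir, paste0(prefix, "_control.bed"))
  srt <- file.path(dir, paste0(prefix, "_sorted.bed"))
  write_refflat(config$genes, ann)
  write_sites_bed(dedupe(ds$control), ctl)
  write_sites_bed(dedupe(ds$sorted), srt)
  c(annotation = ann, control = ctl, sorted = srt)
}
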