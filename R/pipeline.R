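# Configuration-driven end-to-end runner: normalize -> QC -> hits ->
# fingerprint, from files or from the simulator.

#' Pipeline configuration
#'
#' Exactly one input source must be given: either the three TSV paths of
#' an existing screen, or a [simulation_config()] to generate one. All
#' stage options are carried here so that a run is fully described by
#' its resolved configuration.
#'
#' @param simulate A [simulation_config()], or `NULL`.
#' @param measurements,layout,samples TSV paths (see [read_screen()]),
#'   or `NULL`.
#' @param out_dir Output directory.
#' @param denominator_roles Relative-viability denominator roles.
#' @param adjust_variance Per-experiment variance adjustment flag.
#' @param thresholds [hit_thresholds()] for candidate calling.
#' @param k_samples Flat sample clusters for the bicluster (default 2).
#' @param alpha Significance level for the differential panel.
#' @param correct Benjamini-Hochberg correction flag (default off).
#' @param qq_delta QQ tail threshold.
#' @param seed Seed for a simulated run (overrides the simulation
#'   config's seed when that is unset).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, measurements = NULL,
                            layout = NULL, samples = NULL,
                            out_dir = "screenprint_run",
                            denominator_roles = c("untreated", "neg_control"),
                            adjust_variance = TRUE,
                            thresholds = hit_thresholds(),
                            k_samples = 2, alpha = 0.05, correct = FALSE,
                            qq_delta = 0.5, seed = NULL) {
  have_files <- !is.null(measurements) || !is.null(layout) || !is.null(samples)
  if (!is.null(simulate) && have_files) {
    stop("give either a simulation config or input file paths, not both",
         call. = FALSE)
  }
  if (is.null(simulate)) {
    if (is.null(measurements) || is.null(layout) || is.null(samples)) {
      stop("file input needs measurements, layout and samples paths",
           call. = FALSE)
    }
    for (p in c(measurements, layout, samples)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  } else {
    stopifnot(inherits(simulate, "simulation_config"))
    if (is.null(simulate$seed) && !is.null(seed)) {
      simulate$seed <- as.integer(seed)
    }
  }
  structure(list(simulate = simulate, measurements = measurements,
                 layout = layout, samples = samples, out_dir = out_dir,
                 denominator_roles = denominator_roles,
                 adjust_variance = adjust_variance, thresholds = thresholds,
                 k_samples = k_samples, alpha = alpha, correct = correct,
                 qq_delta = qq_delta, seed = seed),
            class = "pipeline_config")
}

#' Run the full screen analysis pipeline
#'
#' Sequences all stages in their fixed order: load or simulate the
#' screen, score genes, quality control, candidate calling, fingerprint
#' assembly, sample correlations, grouped differential testing, and
#' bi-dimensional clustering of the selected panel. Every artifact is
#' written under `config$out_dir` (`scores.tsv`, `qc_report.json`,
#' `hits.tsv`, `correlations.tsv`, `panel.tsv`, `panel_genes.txt`, plus
#' the simulated screen TSVs and `truth.tsv` for simulated runs), and a
#' `report.json` records counts, the resolved configuration and an md5
#' manifest of every written file. Runs are deterministic under a fixed
#' seed.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list, class `run_report`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth <- NULL

  if (!is.null(config$simulate)) {
    sim <- simulate_screen(config$simulate)
    dataset <- sim$dataset
    truth <- sim$truth
    files <- c(files, write_screen(dataset, config$out_dir))
    tp <- file.path(config$out_dir, "truth.tsv")
    write_truth(truth, tp)
    files <- c(files, tp)
  } else {
    dataset <- read_screen(config$measurements, config$layout, config$samples)
  }

  scores <- score_genes(dataset,
                        denominator_roles = config$denominator_roles,
                        adjust_variance = config$adjust_variance)
  sp <- file.path(config$out_dir, "scores.tsv")
  write_scores(scores, sp)

  qc <- qc_report(dataset, scores, delta = config$qq_delta)
  qp <- file.path(config$out_dir, "qc_report.json")
  write_qc_report(qc, qp)

  hits <- call_candidates(scores, thresholds = config$thresholds)
  hp <- file.path(config$out_dir, "hits.tsv")
  write_hits(hits, hp)

  fp <- build_fingerprint(dataset, scores)
  cors <- sample_correlations(fp)
  cp <- file.path(config$out_dir, "correlations.tsv")
  write_tsv(data.frame(sample_id = rownames(cors), as.data.frame(cors),
                       check.names = FALSE), cp)

  grouped <- group_samples(fp, dataset$samples)
  panel <- differential_panel(grouped, alpha = config$alpha,
                              correct = config$correct)
  pp <- file.path(config$out_dir, "panel.tsv")
  write_panel(panel, pp)
  gp <- file.path(config$out_dir, "panel_genes.txt")
  panel_gene_list(panel, gp)

  sel <- panel$gene[panel$selected]
  bc <- if (length(sel) >= 2L) {
    bicluster(fp[sel, , drop = FALSE], k_samples = config$k_samples)
  } else NULL

  files <- c(files, sp, qp, hp, cp, pp, gp)
  report <- structure(list(
    n_samples = nrow(dataset$samples),
    n_genes = length(library_genes(dataset)),
    n_replicates = length(unique(dataset$measurements$replicate_id)),
    median_zprime = stats::median(qc$plates$zprime),
    hit_counts = as.list(table(hits$direction[hits$is_candidate])),
    panel_size = length(sel),
    sample_partition = if (!is.null(bc)) as.list(bc$sample_partition) else NULL,
    config = resolved_config(config),
    manifest = data.frame(file = basename(unname(files)),
                          md5 = unname(tools::md5sum(unname(files))),
                          stringsAsFactors = FALSE)),
    class = "run_report")
  jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", force = TRUE)
  invisible(report)
}

resolved_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) {
    sim <- unclass(cfg$simulate)
    sim$samples <- NULL
    sim$gene_ids <- NULL
    cfg$simulate <- sim
  }
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report:", x$n_genes, "genes,", x$n_samples, "samples,",
      x$n_replicates, "replicates; median Z' =",
      format(x$median_zprime, digits = 3),
      "; candidates:", sum(unlist(x$hit_counts)),
      "; panel size:", x$panel_size, "\n")
  invisible(x)
}
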