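# Generative model for multi-donor, multi-replicate kinome viability
# screens with planted effects and full ground truth.

#' Default simulated screen design
#'
#' Seven samples mirroring a two-donor MSC / four-fibroblast comparison:
#' two MSC preparations of donor 1, one MSC preparation of donor 2, two
#' primary fibroblast isolations and two fibroblast cell lines (each
#' fibroblast sample from its own donor).
#'
#' @return Sample annotation data frame (`sample_id`, `cell_class`,
#'   `donor_id`, `preparation_id`).
#' @export
default_screen_samples <- function() {
  data.frame(
    sample_id = c("MSC1A", "MSC1B", "MSC2", "pHF1", "pHF2", "HFF", "HS68"),
    cell_class = c("MSC", "MSC", "MSC", "fibroblast_primary",
                   "fibroblast_primary", "fibroblast_line", "fibroblast_line"),
    donor_id = c("D1", "D1", "D2", "D3", "D4", "D5", "D6"),
    preparation_id = c("D1A", "D1B", "D2A", "D3A", "D4A", "D5A", "D6A"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for a synthetic kinome viability screen
#'
#' Defines the generative model. Per-gene log2 viability effects come
#' from a three-component mixture: a heavy viability-reducing "kill"
#' component (weight `prop_kill`, Normal(`kill_mean`, `kill_sd`^2)), a
#' small "enhance" component, and a near-null bulk. Technical variation
#' follows a four-level hierarchy of per-gene deviations -- donor,
#' preparation, replicate screen, and well -- whose standard deviations
#' (log2 units) are calibrated so that the expected profile correlations
#' reproduce the reproducibility structure of real kinome screens
#' (technical replicates near 0.84, independent donors near 0.7; see
#' [expected_profile_correlation()]). Control siRNA wells share one
#' reagent-level per-screen deviation; positive-control knockdown
#' reduces viability to about 15% (`theta_pos = -2.74` log2). Plate
#' baselines are log-normal. `n_differential` genes carry class-specific
#' offsets `|delta|` uniform in `delta_range`, split into a
#' stronger-in-MSC and a stronger-in-fibroblast cluster (the stronger
#' effect is the more viability-reducing one).
#'
#' @param n_genes Library size (default 778).
#' @param gene_ids Gene identifiers (default `KIN0001`...).
#' @param samples Sample annotation (default [default_screen_samples()]).
#' @param n_replicates Replicate screens per sample (default 2).
#' @param prop_kill,kill_mean,kill_sd Kill mixture component (0.10,
#'   -0.9, 0.35).
#' @param prop_enhance,enhance_mean,enhance_sd Enhancer component
#'   (0.03, +0.35, 0.12).
#' @param null_sd Spread of the near-null bulk (0.05).
#' @param sigma_well,sigma_screen,sigma_prep,sigma_donor Noise sds in
#'   log2 units (0.08, 0.11, 0.08, 0.17).
#' @param theta_pos Positive-control log2 effect (-2.74).
#' @param baseline_rlu Typical plate-median RLU (2e4).
#' @param baseline_log2_sd Log2 sd of the per-plate baseline (0.25).
#' @param n_differential Planted differential panel size (35).
#' @param delta_range Range of |delta| in log2 units (0.4-0.9).
#' @param edge_amplitude Additive log2 bump on the outermost well ring,
#'   a stressor for robustness checks; off (0) by default.
#' @param untreated_wells Untreated well positions per plate.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 778L,
                              gene_ids = sprintf("KIN%04d", seq_len(n_genes)),
                              samples = default_screen_samples(),
                              n_replicates = 2L,
                              prop_kill = 0.10, kill_mean = -0.9, kill_sd = 0.35,
                              prop_enhance = 0.03, enhance_mean = 0.35,
                              enhance_sd = 0.12,
                              null_sd = 0.05,
                              sigma_well = 0.08, sigma_screen = 0.11,
                              sigma_prep = 0.08, sigma_donor = 0.17,
                              theta_pos = -2.74,
                              baseline_rlu = 2e4, baseline_log2_sd = 0.25,
                              n_differential = 35L,
                              delta_range = c(0.4, 0.9),
                              edge_amplitude = 0,
                              untreated_wells = c("K03", "L03", "M03", "N03"),
                              seed = NULL) {
  cfg <- list(n_genes = as.integer(n_genes), gene_ids = as.character(gene_ids),
              samples = samples, n_replicates = as.integer(n_replicates),
              prop_kill = prop_kill, kill_mean = kill_mean, kill_sd = kill_sd,
              prop_enhance = prop_enhance, enhance_mean = enhance_mean,
              enhance_sd = enhance_sd, null_sd = null_sd,
              sigma_well = sigma_well, sigma_screen = sigma_screen,
              sigma_prep = sigma_prep, sigma_donor = sigma_donor,
              theta_pos = theta_pos, baseline_rlu = baseline_rlu,
              baseline_log2_sd = baseline_log2_sd,
              n_differential = as.integer(n_differential),
              delta_range = as.numeric(delta_range),
              edge_amplitude = edge_amplitude,
              untreated_wells = as.character(untreated_wells),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_genes < 1L || length(cfg$gene_ids) != cfg$n_genes ||
      anyDuplicated(cfg$gene_ids)) {
    stop("gene_ids must be distinct and match n_genes", call. = FALSE)
  }
  validate_samples(cfg$samples)
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  w <- c(cfg$prop_kill, cfg$prop_enhance)
  if (any(w < 0) || any(w > 1) || sum(w) > 1) {
    stop("mixture weights must lie in [0, 1] and sum to at most 1", call. = FALSE)
  }
  sds <- c(cfg$kill_sd, cfg$enhance_sd, cfg$null_sd, cfg$sigma_well,
           cfg$sigma_screen, cfg$sigma_prep, cfg$sigma_donor,
           cfg$baseline_log2_sd)
  if (any(sds < 0)) stop("all sds must be >= 0", call. = FALSE)
  if (cfg$n_differential < 0L || cfg$n_differential > cfg$n_genes) {
    stop("n_differential must lie in [0, n_genes]", call. = FALSE)
  }
  if (length(cfg$delta_range) != 2L || cfg$delta_range[1] > cfg$delta_range[2] ||
      any(cfg$delta_range < 0)) {
    stop("delta_range must be an increasing non-negative pair", call. = FALSE)
  }
  if (cfg$baseline_rlu <= 0) stop("baseline_rlu must be positive", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-donor kinome viability screen
#'
#' Draws a complete screen dataset from the generative model of
#' [simulation_config()]. A library well of gene g on the plate of
#' screen (sample, replicate) reads
#' `RLU = baseline_plate * 2^(theta_g + delta_g[class] + nu_donor +
#' nu_prep + nu_screen + eps_well)`; negative-control wells use
#' `theta = 0` and positive-control wells `theta = theta_pos`, both with
#' one shared reagent-level per-screen deviation instead of per-gene
#' screen noise; untreated (and empty) wells carry cells without any
#' reagent-level noise. The run is deterministic under a fixed
#' `config$seed`, and every generated well value is reconstructible
#' from the returned truth.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `dataset` (a [screen_dataset()]) and
#'   `truth` (class `simulation_truth`): `genes` (per-gene component,
#'   `theta`, differential membership, cluster, `delta_msc`,
#'   `delta_fibroblast`), `wells` (per-well additive log2 decomposition)
#'   and the `config`.
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 30, seed = 7))
#' sim$dataset
#' head(planted_panel(sim$truth))
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, simulate_screen_impl(config))
  } else {
    simulate_screen_impl(config)
  }
}

simulate_screen_impl <- function(config) {
  g <- config$gene_ids
  G <- length(g)
  samples <- config$samples
  layouts <- default_kinome_layout(g, untreated_wells = config$untreated_wells)

  # per-gene base effects from the mixture
  comp <- sample(c("kill", "enhance", "null"), G, replace = TRUE,
                 prob = c(config$prop_kill, config$prop_enhance,
                          1 - config$prop_kill - config$prop_enhance))
  theta <- stats::rnorm(G, 0, config$null_sd)
  nk <- sum(comp == "kill"); ne <- sum(comp == "enhance")
  if (nk) theta[comp == "kill"] <- stats::rnorm(nk, config$kill_mean, config$kill_sd)
  if (ne) theta[comp == "enhance"] <- stats::rnorm(ne, config$enhance_mean,
                                                   config$enhance_sd)

  # planted class-differential offsets, split into two clusters
  delta_msc <- numeric(G); delta_fib <- numeric(G)
  cluster <- rep(NA_character_, G)
  nd <- config$n_differential
  if (nd > 0L) {
    diff_idx <- sample.int(G, nd)
    cl <- rep(c("MSC", "fibroblast"),
              c(ceiling(nd / 2), floor(nd / 2)))
    dabs <- stats::runif(nd, config$delta_range[1], config$delta_range[2])
    cluster[diff_idx] <- cl
    delta_msc[diff_idx[cl == "MSC"]] <- -dabs[cl == "MSC"]
    delta_fib[diff_idx[cl == "fibroblast"]] <- -dabs[cl == "fibroblast"]
  }

  donors <- unique(samples$donor_id)
  preps <- unique(samples$preparation_id)
  screens <- expand.grid(replicate_id = paste0("R", seq_len(config$n_replicates)),
                         sample_id = samples$sample_id,
                         stringsAsFactors = FALSE)[, c("sample_id", "replicate_id")]
  screens <- screens[order(match(screens$sample_id, samples$sample_id),
                           screens$replicate_id), ]
  screen_id <- paste(screens$sample_id, screens$replicate_id, sep = ".")
  ns <- nrow(screens)

  nu_donor <- matrix(stats::rnorm(G * length(donors), 0, config$sigma_donor),
                     G, length(donors), dimnames = list(g, donors))
  nu_prep <- matrix(stats::rnorm(G * length(preps), 0, config$sigma_prep),
                    G, length(preps), dimnames = list(g, preps))
  nu_screen <- matrix(stats::rnorm(G * ns, 0, config$sigma_screen),
                      G, ns, dimnames = list(g, screen_id))
  nu_reagent_neg <- stats::rnorm(ns, 0, config$sigma_screen)
  nu_reagent_pos <- stats::rnorm(ns, 0, config$sigma_screen)
  names(nu_reagent_neg) <- names(nu_reagent_pos) <- screen_id

  plate_ids <- unique(layouts$plate_id)
  n_plates <- length(plate_ids)
  baseline <- matrix(log2(config$baseline_rlu) +
                       stats::rnorm(ns * n_plates, 0, config$baseline_log2_sd),
                     ns, n_plates, dimnames = list(screen_id, plate_ids))

  # assemble the well table screen-by-screen in fixed order
  template <- layouts
  pw <- parse_well(template$well)
  template$edge_term <- ifelse(pw$row %in% c("A", "P") | pw$column %in% c(1L, 24L),
                               config$edge_amplitude, 0)
  n_tpl <- nrow(template)
  wells <- template[rep(seq_len(n_tpl), ns), ]
  wells$sample_id <- rep(screens$sample_id, each = n_tpl)
  wells$replicate_id <- rep(screens$replicate_id, each = n_tpl)
  scr <- rep(screen_id, each = n_tpl)
  si <- match(wells$sample_id, samples$sample_id)
  cls <- collapse_class(samples$cell_class[si])

  gi <- match(wells$target, g)               # NA for non-library wells
  lib <- wells$role == "library"
  neg <- wells$role == "neg_control"
  pos <- wells$role == "pos_control"

  th <- numeric(nrow(wells))
  th[lib] <- theta[gi[lib]]
  th[pos] <- config$theta_pos
  de <- numeric(nrow(wells))
  de[lib] <- ifelse(cls[lib] == "MSC", delta_msc[gi[lib]], delta_fib[gi[lib]])
  nu_d <- numeric(nrow(wells))
  nu_d[lib] <- nu_donor[cbind(gi[lib], match(samples$donor_id[si[lib]], donors))]
  nu_p <- numeric(nrow(wells))
  nu_p[lib] <- nu_prep[cbind(gi[lib], match(samples$preparation_id[si[lib]], preps))]
  nu_s <- numeric(nrow(wells))
  nu_s[lib] <- nu_screen[cbind(gi[lib], match(scr[lib], screen_id))]
  nu_s[neg] <- nu_reagent_neg[scr[neg]]
  nu_s[pos] <- nu_reagent_pos[scr[pos]]
  eps <- stats::rnorm(nrow(wells), 0, config$sigma_well)
  base <- baseline[cbind(match(scr, screen_id), match(wells$plate_id, plate_ids))]

  wells$baseline_log2 <- base
  wells$theta <- th
  wells$delta <- de
  wells$nu_donor <- nu_d
  wells$nu_prep <- nu_p
  wells$nu_screen <- nu_s
  wells$eps <- eps
  wells$rlu <- 2^(base + th + de + nu_d + nu_p + nu_s + eps + wells$edge_term)
  rownames(wells) <- NULL

  measurements <- wells[, c("plate_id", "sample_id", "replicate_id", "well", "rlu")]
  dataset <- screen_dataset(samples, layouts, measurements)
  genes_df <- data.frame(gene = g, component = comp, theta = theta,
                         differential = !is.na(cluster), cluster = cluster,
                         delta_msc = delta_msc, delta_fibroblast = delta_fib,
                         stringsAsFactors = FALSE)
  truth <- structure(list(genes = genes_df, wells = wells, config = config),
                     class = "simulation_truth")
  list(dataset = dataset, truth = truth)
}

#' Planted differential panel of a simulation
#'
#' @param truth A `simulation_truth` from [simulate_screen()].
#' @return Data frame of planted differential genes with their cluster
#'   (`MSC` = stronger effect in MSCs, `fibroblast` = stronger in
#'   fibroblasts) and class offsets; empty when `n_differential = 0`.
#' @export
planted_panel <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  d <- truth$genes[truth$genes$differential,
                   c("gene", "cluster", "delta_msc", "delta_fibroblast")]
  rownames(d) <- NULL
  d
}

mixture_variance <- function(config) {
  w <- c(config$prop_kill, config$prop_enhance,
         1 - config$prop_kill - config$prop_enhance)
  mu <- c(config$kill_mean, config$enhance_mean, 0)
  s2 <- c(config$kill_sd, config$enhance_sd, config$null_sd)^2
  m1 <- sum(w * mu)
  m2 <- sum(w * (s2 + mu^2))
  m2 - m1^2
}

#' Expected profile correlation under the simulation model
#'
#' Closed-form expectation of the Pearson correlation between two
#' per-gene fingerprints at a given level of the repetition hierarchy:
#' `r = S / (S + V)`, where `S` is the across-gene variance shared by
#' both profiles and `V` the per-profile noise variance that differs
#' between them. `S` is the effect-mixture variance, plus (for two
#' profiles of the same class) the planted within-class
#' differential-offset variance, plus every hierarchy level the two
#' profiles have in common: donor and preparation deviations for
#' technical replicates, donor deviations for two preparations of one
#' donor. `V` counts the per-gene screen and well variances (divided by
#' the number of replicates when profiles are replicate-summarized)
#' plus the between-plate part of the negative-control normalization
#' noise, plus the preparation and/or donor variances at the levels
#' where the profiles differ. Screen-constant reagent shifts cancel in
#' across-gene correlations and are not counted. This is the
#' calibration oracle for the simulator defaults: with them it
#' evaluates to about 0.88 at the technical level (unsummarized) and
#' 0.70 at the donor level (summarized).
#'
#' @param config A [simulation_config()].
#' @param level `"technical"` (two replicate screens of one
#'   preparation), `"preparation"` (two preparations of one donor) or
#'   `"donor"` (preparations of two donors).
#' @param summarized Are the compared profiles replicate-summarized
#'   (default `FALSE`)?
#' @param same_class Both profiles from this class (`"MSC"`, the
#'   calibration setting) so that its planted differential offsets are
#'   shared; use `NA` to compare profiles ignoring planted offsets.
#' @return Expected Pearson r.
#' @export
expected_profile_correlation <- function(config,
                                         level = c("technical", "preparation", "donor"),
                                         summarized = FALSE,
                                         same_class = "MSC") {
  stopifnot(inherits(config, "simulation_config"))
  level <- match.arg(level)
  S <- mixture_variance(config)
  if (!is.na(same_class) && config$n_differential > 0L) {
    nd <- config$n_differential
    n_cl <- if (same_class == "MSC") ceiling(nd / 2) else floor(nd / 2)
    lo <- config$delta_range[1]; hi <- config$delta_range[2]
    e2 <- (lo^2 + lo * hi + hi^2) / 3     # E[delta^2] for uniform |delta|
    e1 <- (lo + hi) / 2
    share <- n_cl / config$n_genes
    S <- S + share * e2 - (share * e1)^2
  }
  e <- if (summarized) config$n_replicates else 1
  n_neg <- 4
  n_plates <- ceiling(config$n_genes / 320)
  v_norm <- (config$sigma_well^2 / n_neg) * (1 - 1 / n_plates)
  V <- (config$sigma_screen^2 + config$sigma_well^2 + v_norm) / e
  if (level == "technical") S <- S + config$sigma_prep^2 + config$sigma_donor^2
  if (level == "preparation") {
    S <- S + config$sigma_donor^2
    V <- V + config$sigma_prep^2
  }
  if (level == "donor") V <- V + config$sigma_prep^2 + config$sigma_donor^2
  S / (S + V)
}

#' Write simulation ground truth as TSV
#'
#' Writes the per-gene truth table (`gene`, `component`, `theta`,
#' `differential`, `cluster`, `delta_msc`, `delta_fibroblast`).
#'
#' @param truth A `simulation_truth`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  genes <- truth$genes
  genes$cluster[is.na(genes$cluster)] <- ""
  write_tsv(genes, path)
}
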