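# Screen quality statistics: Z'-factor, profile correlations,
# quantile-quantile tail analysis.

#' Z'-factor (screening-window coefficient)
#'
#' Zhang's screening-window coefficient comparing the positive- and
#' negative-control distributions of a plate:
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`. Values above
#' 0.5 indicate an excellent assay window; the statistic is at most 1
#' and equals 1 only when both control groups have zero spread. Z' is
#' invariant under a common positive affine transform of all control
#' values, so computing it on raw RLU within a plate or on relative
#' viability gives identical results.
#'
#' @param neg_values Numeric vector (>= 2) of negative-control readings.
#' @param pos_values Numeric vector (>= 2) of positive-control readings.
#' @return A single number `<= 1`.
#' @examples
#' zprime(c(950, 1000, 1050), c(80, 100, 120))
#' @export
zprime <- function(neg_values, pos_values) {
  if (length(neg_values) < 2L || length(pos_values) < 2L) {
    stop("need at least 2 values in each control group", call. = FALSE)
  }
  mu_n <- mean(neg_values)
  mu_p <- mean(pos_values)
  if (mu_n == mu_p) {
    stop("undefined screening window: control means are equal", call. = FALSE)
  }
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / abs(mu_p - mu_n)
}

#' Pearson correlation between two gene profiles
#'
#' Product-moment correlation between two per-gene profiles aligned by
#' gene. Constant profiles have no defined correlation and abort.
#'
#' @param x,y Numeric vectors of equal length (>= 3), same gene order.
#' @return Pearson r in `[-1, 1]`.
#' @export
profile_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("profiles differ in length", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 paired finite values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant profile", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Quantile-quantile tail analysis of z-scores
#'
#' Compares the ordered z-scores against the theoretical normal
#' quantiles `qnorm((i - 0.5) / n)` and counts genes deviating from the
#' identity reference line by more than `delta` in either direction:
#' observed minus theoretical below `-delta` is lower-tail excess (more
#' viability-impairing phenotypes than a normal distribution predicts),
#' above `+delta` is upper-tail excess. The identity line is the
#' appropriate reference because the input is already standardized.
#'
#' @param zscores Numeric vector of at least 10 z-scores.
#' @param delta Deviation threshold on the z scale (default 0.5).
#' @return A list of class `qq_summary`: `n_genes`, `lower_excess`,
#'   `upper_excess`, `delta`.
#' @export
qq_tail_analysis <- function(zscores, delta = 0.5) {
  zscores <- zscores[is.finite(zscores)]
  n <- length(zscores)
  if (n < 10L) {
    stop("insufficient data: need at least 10 z-scores", call. = FALSE)
  }
  stopifnot(is.numeric(delta), delta > 0)
  obs <- sort(zscores)
  theo <- stats::qnorm((seq_len(n) - 0.5) / n)
  dev <- obs - theo
  structure(list(n_genes = n,
                 lower_excess = sum(dev < -delta),
                 upper_excess = sum(dev > delta),
                 delta = delta),
            class = "qq_summary")
}

#' @export
print.qq_summary <- function(x, ...) {
  cat(sprintf("qq_summary: n=%d, lower excess=%d, upper excess=%d (delta=%g)\n",
              x$n_genes, x$lower_excess, x$upper_excess, x$delta))
  invisible(x)
}

control_stats <- function(dataset) {
  m <- dataset$measurements
  lay <- dataset$layouts[, c("plate_id", "well", "role")]
  df <- merge(m, lay, by = c("plate_id", "well"), sort = FALSE)
  key <- interaction(df$plate_id, df$sample_id, df$replicate_id, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    p <- df[key == k, ]
    neg <- p$rlu[p$role == "neg_control"]
    pos <- p$rlu[p$role == "pos_control"]
    data.frame(plate_id = p$plate_id[1], sample_id = p$sample_id[1],
               replicate_id = p$replicate_id[1],
               mu_neg = mean(neg), sigma_neg = stats::sd(neg),
               mu_pos = mean(pos), sigma_pos = stats::sd(pos),
               zprime = zprime(neg, pos), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# correlation level of a sample pair in the donor -> preparation ->
# replicate hierarchy
pair_level <- function(samples, a, b) {
  ia <- match(a, samples$sample_id); ib <- match(b, samples$sample_id)
  if (a == b) "technical"
  else if (samples$donor_id[ia] == samples$donor_id[ib]) "preparation"
  else "donor"
}

#' Screen quality-control report
#'
#' Computes per-plate control statistics and Z'-factors (with mean and
#' median summaries per screen), pairwise Pearson correlations between
#' gene profiles at three levels of the repetition hierarchy --
#' technical (single-replicate profiles of the same sample),
#' preparation (summarized profiles of samples sharing a donor) and
#' donor (summarized profiles of samples from different donors) -- and a
#' quantile-quantile tail summary of each sample's z-scores.
#'
#' @param dataset A [screen_dataset()].
#' @param scores Optional precomputed [score_genes()] table; computed
#'   internally when `NULL`.
#' @param delta QQ deviation threshold, see [qq_tail_analysis()].
#' @return A list of class `qc_report`: `plates` (per-plate stats incl.
#'   `zprime`), `zprime_summary` (mean/median per screen), `correlations`
#'   (`sample_a`, `sample_b`, `level`, `r`), `qq` (per-sample tail
#'   summaries).
#' @seealso [write_qc_report()]
#' @export
qc_report <- function(dataset, scores = NULL, delta = 0.5) {
  stopifnot(inherits(dataset, "screen_dataset"))
  plates <- control_stats(dataset)
  screen <- paste(plates$sample_id, plates$replicate_id, sep = ".")
  zsum <- do.call(rbind, lapply(unique(screen), function(s) {
    z <- plates$zprime[screen == s]
    data.frame(screen = s, mean_zprime = mean(z),
               median_zprime = stats::median(z), stringsAsFactors = FALSE)
  }))

  # technical level: unsummarized single-replicate profiles
  prof <- replicate_profiles(dataset)
  screen_sample <- sub("\\.[^.]+$", "", colnames(prof))
  cors <- list()
  for (s in unique(screen_sample)) {
    cols <- which(screen_sample == s)
    if (length(cols) >= 2L) {
      pairs <- utils::combn(cols, 2)
      for (j in seq_len(ncol(pairs))) {
        cors[[length(cors) + 1L]] <- data.frame(
          sample_a = s, sample_b = s, level = "technical",
          r = profile_correlation(prof[, pairs[1, j]], prof[, pairs[2, j]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  # preparation/donor levels: replicate-summarized fingerprints
  if (is.null(scores)) scores <- score_genes(dataset)
  fp <- build_fingerprint(dataset, scores)
  ids <- colnames(fp)
  if (length(ids) >= 2L) {
    pairs <- utils::combn(ids, 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      cors[[length(cors) + 1L]] <- data.frame(
        sample_a = a, sample_b = b,
        level = pair_level(dataset$samples, a, b),
        r = profile_correlation(fp[, a], fp[, b]), stringsAsFactors = FALSE)
    }
  }
  correlations <- do.call(rbind, cors)

  qq <- lapply(split(scores, scores$sample_id), function(d) {
    s <- qq_tail_analysis(d$zscore, delta)
    data.frame(sample_id = d$sample_id[1], n = s$n_genes,
               lower_excess = s$lower_excess, upper_excess = s$upper_excess,
               delta = s$delta, stringsAsFactors = FALSE)
  })
  qq <- do.call(rbind, qq)
  rownames(qq) <- NULL

  structure(list(plates = plates, zprime_summary = zsum,
                 correlations = correlations, qq = qq),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", nrow(x$plates), "plate instances; median Z' =",
      format(stats::median(x$plates$zprime), digits = 3), "\n")
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param report A [qc_report()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}
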