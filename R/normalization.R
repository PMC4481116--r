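# Gene scoring pipeline: relative viability, multiplicative plate
# normalization, per-experiment variance adjustment, replicate
# summarization, plate-mean z-scores.

merge_layout <- function(plate, layout) {
  if (!all(c("role", "target") %in% names(plate))) {
    lay <- layout[layout$plate_id == plate$plate_id[1], c("well", "role", "target")]
    plate <- merge(plate, lay, by = "well", sort = FALSE)
  }
  plate
}

#' Control-based relative viability of one plate
#'
#' Scales every well of one measured plate by the mean RLU of the
#' denominator wells of that same plate, yielding a dimensionless
#' fraction-of-control. The default denominator pools untreated (NT)
#' wells and negative-control siRNA wells; restricting it to
#' `"neg_control"` reproduces a control-only normalization. Denominator
#' wells are transformed like every other well.
#'
#' @param plate Data frame with one plate instance: columns `plate_id`,
#'   `well`, `rlu` (plus `sample_id`/`replicate_id` if present).
#' @param layout Layout data frame covering this plate.
#' @param denominator_roles Non-empty subset of
#'   `c("untreated", "neg_control", "pos_control", "library")`.
#' @return The plate data frame with `role`, `target` and a new
#'   `rel_viability` column.
#' @export
relative_viability <- function(plate, layout,
                               denominator_roles = c("untreated", "neg_control")) {
  if (length(denominator_roles) == 0L) {
    stop("denominator_roles must be non-empty", call. = FALSE)
  }
  plate <- merge_layout(plate, layout)
  for (r in denominator_roles) {
    if (!any(plate$role == r)) {
      stop("plate ", plate$plate_id[1], " has no well with role ", r, call. = FALSE)
    }
  }
  denom <- mean(plate$rlu[plate$role %in% denominator_roles])
  if (!is.finite(denom) || denom <= 0) {
    stop("degenerate control: denominator mean is ", format(denom),
         " on plate ", plate$plate_id[1], call. = FALSE)
  }
  plate$rel_viability <- plate$rlu / denom
  plate
}

#' Multiplicative plate normalization (log2 ratio to plate scale)
#'
#' Scores wells on a multiplicative scale: the plate scale factor is the
#' median RLU of the plate's library wells, and each well gets
#' `log2(RLU / scale)`. By construction the median library-well log2
#' ratio is 0, and the result is invariant to multiplying all RLUs of
#' the plate by a positive constant (plate effects cancel). Zero-RLU
#' wells get `-Inf`; zero-RLU library wells are flagged with a warning
#' and carry `NA` so they stay out of downstream log-scale statistics.
#'
#' @inheritParams relative_viability
#' @return The plate data frame with a `log2_ratio` column.
#' @export
multiplicative_normalize <- function(plate, layout) {
  plate <- merge_layout(plate, layout)
  lib <- plate$role == "library"
  if (!any(lib & plate$rlu > 0)) {
    stop("degenerate plate ", plate$plate_id[1],
         ": no library well with RLU > 0", call. = FALSE)
  }
  scale <- stats::median(plate$rlu[lib])
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate plate ", plate$plate_id[1], ": scale factor ",
         format(scale), call. = FALSE)
  }
  plate$log2_ratio <- log2(plate$rlu / scale)
  zero <- lib & plate$rlu == 0
  if (any(zero)) {
    warning("plate ", plate$plate_id[1], ": ", sum(zero),
            " zero-RLU library wells excluded from log-scale statistics",
            call. = FALSE)
    plate$log2_ratio[zero] <- NA_real_
  }
  plate
}

#' Per-plate control-normalized log2 values
#'
#' Normalizes each well to the average of the plate's negative-control
#' siRNA wells and log2-transforms: `log2(RLU / mean(neg-control RLU))`.
#' This is the value that enters the fingerprint matrix. On the linear
#' scale the negative-control wells average to 1 (log ratio 0) by
#' construction.
#'
#' @inheritParams relative_viability
#' @return The plate data frame with a `log2_ctrl` column.
#' @export
control_log2_normalize <- function(plate, layout) {
  plate <- merge_layout(plate, layout)
  neg <- plate$role == "neg_control"
  if (!any(neg & plate$rlu > 0)) {
    stop("plate ", plate$plate_id[1],
         ": no negative-control well with RLU > 0", call. = FALSE)
  }
  ctrl <- mean(plate$rlu[neg])
  if (!is.finite(ctrl) || ctrl <= 0) {
    stop("degenerate control mean ", format(ctrl), " on plate ",
         plate$plate_id[1], call. = FALSE)
  }
  plate$log2_ctrl <- log2(plate$rlu / ctrl)
  plate$log2_ctrl[plate$rlu == 0] <- NA_real_
  plate
}

#' Per-experiment variance adjustment
#'
#' Rescales log2 ratios so that every replicate screen (one experiment,
#' possibly spanning several plates) has the same robust scale: within
#' each group the `log2_ratio` values are divided by the median absolute
#' deviation (scaled by 1.4826) of the group's library wells. After one
#' pass every group has robust scale 1, and a second pass leaves the
#' values unchanged. Setting `robust = FALSE` divides by the plain
#' sample standard deviation instead.
#'
#' @param plates Data frame of normalized wells (rbind of
#'   [multiplicative_normalize()] outputs) with columns `role`,
#'   `log2_ratio` and the grouping columns.
#' @param grouping Character vector of column names identifying one
#'   replicate screen (default `sample_id` + `replicate_id`).
#' @param robust Use the MAD (default) instead of the standard deviation.
#' @return `plates` with `log2_ratio` rescaled per group.
#' @export
adjust_variance_by_experiment <- function(plates,
                                          grouping = c("sample_id", "replicate_id"),
                                          robust = TRUE) {
  key <- interaction(plates[grouping], drop = TRUE)
  for (k in levels(key)) {
    idx <- key == k
    x <- plates$log2_ratio[idx & plates$role == "library"]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      stop("experiment ", k, " has fewer than 2 usable library wells",
           call. = FALSE)
    }
    s <- if (robust) stats::mad(x) else stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop("degenerate variance in experiment ", k,
           ": robust scale is 0", call. = FALSE)
    }
    plates$log2_ratio[idx] <- plates$log2_ratio[idx] / s
  }
  plates
}

#' Summarize replicate values
#'
#' Replicate summarization uses the median across replicate screens,
#' which for duplicate screens equals the mean and for three or more
#' replicates resists a single outlying screen.
#'
#' @param values Numeric vector of per-replicate values for one
#'   (gene, sample); `NA`s are dropped.
#' @return The median, a single number.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1L) {
    stop("no replicate values to summarize", call. = FALSE)
  }
  stats::median(values)
}

#' Plate-mean z-scores
#'
#' Standardizes summarized per-gene values against the mean and sample
#' standard deviation of the library genes of the same source plate:
#' `z = (x - mean(plate)) / sd(plate)`. Control wells never enter the
#' plate statistics. Per plate the resulting z-scores have mean 0 and
#' sd 1.
#'
#' @param values Numeric vector of summarized per-gene values.
#' @param plate Factor/character vector assigning each value to its
#'   source plate (or plate-by-sample group).
#' @return Numeric vector of z-scores, aligned with `values`.
#' @export
plate_zscore <- function(values, plate) {
  stopifnot(length(values) == length(plate))
  plate <- as.factor(plate)
  z <- rep(NA_real_, length(values))
  for (k in levels(plate)) {
    idx <- which(plate == k)
    x <- values[idx]
    ok <- is.finite(x)
    if (sum(ok) < 2L) {
      stop("plate group ", k, " has fewer than 2 finite values", call. = FALSE)
    }
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) {
      stop("degenerate plate group ", k, ": sd is 0", call. = FALSE)
    }
    z[idx] <- (x - mean(x[ok])) / s
  }
  z
}

normalize_wells <- function(dataset,
                            denominator_roles = c("untreated", "neg_control"),
                            adjust_variance = TRUE, robust = TRUE) {
  m <- dataset$measurements
  key <- interaction(m$plate_id, m$sample_id, m$replicate_id, drop = TRUE)
  parts <- lapply(levels(key), function(k) {
    plate <- m[key == k, , drop = FALSE]
    plate <- relative_viability(plate, dataset$layouts, denominator_roles)
    plate <- multiplicative_normalize(plate, dataset$layouts)
    control_log2_normalize(plate, dataset$layouts)
  })
  df <- do.call(rbind, parts)
  if (adjust_variance) {
    df <- adjust_variance_by_experiment(df, robust = robust)
  }
  df
}

#' Score genes of a screen dataset
#'
#' Runs the full scoring pipeline in its fixed order: per-plate
#' multiplicative normalization (and control-based relative viability
#' and control-normalized log2 values), per-experiment variance
#' adjustment of the multiplicative log2 ratios, replicate
#' summarization by the median, then plate-mean z-scores over the
#' library genes of each plate. Two parallel normalization products are
#' kept on purpose: z-scores (and relative viability) for hit scoring,
#' and control-normalized log2 values for fingerprinting.
#'
#' @param dataset A [screen_dataset()].
#' @param denominator_roles Denominator for relative viability; default
#'   pools untreated and negative-control wells.
#' @param adjust_variance Rescale each replicate screen to robust scale
#'   1 before summarization (default `TRUE`).
#' @param robust Use the MAD (default) rather than the sd for the
#'   variance adjustment.
#' @return A data frame with one row per (gene, sample): `gene`,
#'   `sample_id`, `plate_id`, `rel_viability` (replicate-summarized
#'   fraction of control), `log2_ctrl` (replicate-summarized
#'   control-normalized log2), `log2_score` (summarized, variance-
#'   adjusted multiplicative score), `zscore` (plate-mean z-score) and
#'   `n_replicates`; sorted by gene then sample.
#' @examples
#' sim <- simulate_screen(simulation_config(n_genes = 40, seed = 1))
#' scores <- score_genes(sim$dataset)
#' head(scores)
#' @export
score_genes <- function(dataset,
                        denominator_roles = c("untreated", "neg_control"),
                        adjust_variance = TRUE, robust = TRUE) {
  stopifnot(inherits(dataset, "screen_dataset"))
  df <- normalize_wells(dataset, denominator_roles, adjust_variance, robust)
  lib <- df[df$role == "library", , drop = FALSE]

  key <- interaction(lib$target, lib$sample_id, drop = TRUE)
  split_idx <- split(seq_len(nrow(lib)), key)
  rows <- lapply(split_idx, function(i) {
    data.frame(gene = lib$target[i[1]],
               sample_id = lib$sample_id[i[1]],
               plate_id = lib$plate_id[i[1]],
               rel_viability = summarize_replicates(lib$rel_viability[i]),
               log2_ctrl = summarize_replicates(lib$log2_ctrl[i]),
               log2_score = summarize_replicates(lib$log2_ratio[i]),
               n_replicates = length(unique(lib$replicate_id[i])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$zscore <- plate_zscore(out$log2_score,
                             interaction(out$plate_id, out$sample_id, drop = TRUE))
  out <- out[order(out$gene, out$sample_id), ]
  rownames(out) <- NULL
  out[, c("gene", "sample_id", "plate_id", "rel_viability", "log2_ctrl",
          "log2_score", "zscore", "n_replicates")]
}

#' Per-replicate gene profiles
#'
#' Builds unsummarized per-gene profiles, one column per replicate
#' screen (`sample_id.replicate_id`), from the per-well normalized
#' values. Used for technical-replicate quality control, where replicate
#' summarization would hide the quantity of interest.
#'
#' @param dataset A [screen_dataset()].
#' @param value Which normalized value to profile: control-normalized
#'   log2 (default), multiplicative log2 ratio, or relative viability.
#' @param denominator_roles Passed to [relative_viability()].
#' @return Numeric matrix, genes (rows, layout order) by replicate
#'   screens (columns).
#' @export
replicate_profiles <- function(dataset,
                               value = c("log2_ctrl", "log2_ratio", "rel_viability"),
                               denominator_roles = c("untreated", "neg_control")) {
  value <- match.arg(value)
  df <- normalize_wells(dataset, denominator_roles, adjust_variance = FALSE)
  lib <- df[df$role == "library", , drop = FALSE]
  genes <- library_genes(dataset)
  screen <- paste(lib$sample_id, lib$replicate_id, sep = ".")
  screens <- sort(unique(screen))
  m <- matrix(NA_real_, length(genes), length(screens),
              dimnames = list(genes, screens))
  m[cbind(match(lib$target, genes), match(screen, screens))] <- lib[[value]]
  m
}
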