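# Functional fingerprinting: gene x sample matrices, sample
# correlations, grouped two-sample testing, post-hoc power.

#' Assemble the fingerprint matrix
#'
#' The functional fingerprint of a cell preparation is its vector of
#' per-gene loss-of-function viability phenotypes: replicate-summarized,
#' control-normalized log2 values. This builds the genes-by-samples
#' matrix with deterministic ordering (gene id rows, sample id columns)
#' and attaches the cell-class annotation of each column.
#'
#' @param dataset A [screen_dataset()].
#' @param scores A [score_genes()] table for `dataset`.
#' @return Numeric matrix genes x samples with attribute `cell_class`
#'   (named character vector per column).
#' @export
build_fingerprint <- function(dataset, scores) {
  genes <- sort(unique(scores$gene))
  ids <- sort(unique(scores$sample_id))
  m <- matrix(NA_real_, length(genes), length(ids),
              dimnames = list(genes, ids))
  m[cbind(match(scores$gene, genes), match(scores$sample_id, ids))] <-
    scores$log2_ctrl
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    stop("missing (gene, sample) pairs in scores: ",
         paste(utils::head(paste0(genes[miss[, 1]], "/", ids[miss[, 2]]), 5),
               collapse = ", "), call. = FALSE)
  }
  cls <- dataset$samples$cell_class[match(ids, dataset$samples$sample_id)]
  names(cls) <- ids
  attr(m, "cell_class") <- cls
  m
}

#' Pairwise sample correlations of a fingerprint matrix
#'
#' Symmetric matrix of Pearson correlations between the per-gene
#' profiles of every sample pair, with unit diagonal.
#'
#' @param m Fingerprint matrix (genes x samples), >= 3 genes, no
#'   constant column.
#' @return samples x samples correlation matrix.
#' @export
sample_correlations <- function(m) {
  if (nrow(m) < 3L) stop("need at least 3 genes", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("undefined correlation: constant sample profile ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  diag(r) <- 1
  r
}

#' Group technically dependent preparations before testing
#'
#' Preparations of the same donor are not biologically independent:
#' their fingerprints are averaged (unweighted mean) into one profile
#' per donor before any between-class testing, so group sizes count
#' donors, not preparations. With the default simulated design (two MSC
#' preparations of donor 1, one of donor 2, four fibroblast samples)
#' this yields N = 2 MSC and N = 4 fibroblast profiles.
#'
#' @param m Fingerprint matrix from [build_fingerprint()].
#' @param samples Sample annotation data frame (`sample_id`,
#'   `cell_class`, `donor_id`, `preparation_id`).
#' @return A list of class `grouped_profiles`: `profiles` (genes x
#'   donor-level profiles), `cell_class` (per profile, collapsed to
#'   `MSC`/`fibroblast`), `donor_id`, `n_by_class`.
#' @export
group_samples <- function(m, samples) {
  ids <- colnames(m)
  idx <- match(ids, samples$sample_id)
  if (anyNA(idx)) {
    stop("fingerprint columns missing from sample annotation: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  donor <- samples$donor_id[idx]
  cls <- collapse_class(samples$cell_class[idx])
  donors <- unique(donor)
  prof <- vapply(donors, function(d) {
    rowMeans(m[, donor == d, drop = FALSE])
  }, numeric(nrow(m)))
  dimnames(prof) <- list(rownames(m), donors)
  dcls <- vapply(donors, function(d) unique(cls[donor == d])[1], character(1))
  structure(list(profiles = prof, cell_class = dcls, donor_id = donors,
                 n_by_class = table(dcls)),
            class = "grouped_profiles")
}

collapse_class <- function(cell_class) {
  ifelse(cell_class == "MSC", "MSC", "fibroblast")
}

#' Unpaired two-sample Student t-test
#'
#' Equal-variance (pooled) two-sided t-test with
#' `df = n1 + n2 - 2`, the test used throughout for between-class
#' comparisons of per-gene viability effects.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`, `pooled_sd`.
#' @examples
#' ttest_two_sample(c(1.0, 1.2), c(0.0, 0.1, -0.1, 0.2))
#' @export
ttest_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2L)
  if (pooled_var <= 0) {
    stop("degenerate test: zero pooled variance", call. = FALSE)
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mean_a = mean(a), mean_b = mean(b),
       pooled_sd = sqrt(pooled_var))
}

#' Post-hoc power of the two-sided two-sample t-test
#'
#' Power to detect a standardized effect size (Cohen's d) with group
#' sizes `n1`, `n2` at level `alpha`, via the noncentral t
#' distribution: with `ncp = d * sqrt(n1 n2 / (n1 + n2))` and
#' `df = n1 + n2 - 2`, the power is `P(|T'| > t_{1 - alpha/2, df})`.
#' At `d = 0` the power equals `alpha` exactly; it is strictly
#' increasing in `d` and in each group size.
#'
#' @param d Cohen's d (>= 0); vectorized.
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1).
#' @return Power in `[alpha, 1]`.
#' @examples
#' posthoc_power(2, n1 = 2, n2 = 4)
#' @export
posthoc_power <- function(d, n1 = 2, n2 = 4, alpha = 0.05) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("d must be finite and >= 0", call. = FALSE)
  }
  if (n1 < 2 || n2 < 2 || alpha <= 0 || alpha >= 1) {
    stop("invalid power parameters", call. = FALSE)
  }
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp = ncp) + 1 - stats::pt(tcrit, df, ncp = ncp)
}

#' Differential gene panel between two cell classes
#'
#' Per-gene unpaired Student t-tests between the grouped MSC and
#' fibroblast profiles, reported with Cohen's d
#' (`|mean difference| / pooled sd`) and per-gene post-hoc power at the
#' observed effect size and actual group sizes. A gene is selected when
#' its (optionally Benjamini-Hochberg adjusted) p-value is at most
#' `alpha`; no multiple-testing correction is applied by default. Each
#' selected gene is assigned to the cluster of the class with the
#' stronger (more viability-reducing) effect. Genes with zero pooled
#' variance are excluded with a warning and returned flagged.
#'
#' @param grouped A [group_samples()] object.
#' @param alpha Significance level (default 0.05).
#' @param correct Apply Benjamini-Hochberg correction before selection
#'   (default `FALSE`).
#' @param power_by Compute power from the per-gene effect size
#'   (`"gene"`, default) or from the mean |d| of each cluster
#'   (`"cluster"`).
#' @return Data frame of class `differential_panel`, sorted by p-value:
#'   `gene`, `mean_class1` (MSC), `mean_class2` (fibroblast), `t`, `p`,
#'   `cohens_d`, `power`, `selected`, `cluster`, `degenerate`.
#' @export
differential_panel <- function(grouped, alpha = 0.05, correct = FALSE,
                               power_by = c("gene", "cluster")) {
  stopifnot(inherits(grouped, "grouped_profiles"))
  power_by <- match.arg(power_by)
  cls <- grouped$cell_class
  a_cols <- cls == "MSC"
  b_cols <- cls == "fibroblast"
  if (sum(a_cols) < 2L || sum(b_cols) < 2L) {
    stop("each class needs at least 2 grouped profiles (have ",
         sum(a_cols), " MSC, ", sum(b_cols), " fibroblast)", call. = FALSE)
  }
  n1 <- sum(a_cols); n2 <- sum(b_cols)
  m <- grouped$profiles
  genes <- rownames(m)
  rows <- vector("list", length(genes))
  n_degenerate <- 0L
  for (i in seq_along(genes)) {
    a <- m[i, a_cols]; b <- m[i, b_cols]
    pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
    if (pooled_var <= 0) {
      n_degenerate <- n_degenerate + 1L
      rows[[i]] <- data.frame(gene = genes[i], mean_class1 = mean(a),
                              mean_class2 = mean(b), t = NA_real_,
                              p = NA_real_, cohens_d = NA_real_,
                              power = NA_real_, selected = FALSE,
                              cluster = NA_character_, degenerate = TRUE,
                              stringsAsFactors = FALSE)
      next
    }
    tt <- ttest_two_sample(a, b)
    d <- abs(tt$mean_a - tt$mean_b) / tt$pooled_sd
    rows[[i]] <- data.frame(gene = genes[i], mean_class1 = tt$mean_a,
                            mean_class2 = tt$mean_b, t = tt$t, p = tt$p,
                            cohens_d = d, power = NA_real_, selected = FALSE,
                            cluster = if (tt$mean_a < tt$mean_b) "MSC" else "fibroblast",
                            degenerate = FALSE, stringsAsFactors = FALSE)
  }
  if (n_degenerate > 0L) {
    warning(n_degenerate, " genes with zero pooled variance excluded from testing",
            call. = FALSE)
  }
  out <- do.call(rbind, rows)
  ok <- !out$degenerate
  p_use <- out$p
  if (correct) p_use[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$selected <- ok & p_use <= alpha
  if (power_by == "gene") {
    out$power[ok] <- posthoc_power(out$cohens_d[ok], n1, n2, alpha)
  } else {
    for (cl in unique(out$cluster[ok])) {
      idx <- ok & out$cluster == cl
      out$power[idx] <- posthoc_power(mean(out$cohens_d[idx]), n1, n2, alpha)
    }
  }
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "classes") <- c("MSC", "fibroblast")
  attr(out, "n") <- c(n1 = n1, n2 = n2)
  attr(out, "alpha") <- alpha
  class(out) <- c("differential_panel", "data.frame")
  out
}

#' Write a differential panel as TSV, and export the gene list
#'
#' `write_panel()` writes the full per-gene table;
#' `panel_gene_list()` returns (and optionally writes, one id per line)
#' the selected gene ids, a plain list suitable as input to external
#' network-annotation tools.
#'
#' @param panel A [differential_panel()] table.
#' @param path Output file.
#' @return The path (or the gene id vector for `panel_gene_list()` when
#'   `path` is `NULL`).
#' @export
write_panel <- function(panel, path) {
  write_tsv(as.data.frame(panel), path)
}

#' @rdname write_panel
#' @export
panel_gene_list <- function(panel, path = NULL) {
  genes <- panel$gene[panel$selected]
  if (!is.null(path)) {
    writeLines(genes, path)
    return(invisible(path))
  }
  genes
}
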