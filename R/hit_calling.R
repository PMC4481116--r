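# Candidate selection by fold-change thresholds on replicate-summarized
# relative viability.

#' Hit-calling thresholds
#'
#' Inclusive fold-change bounds on mean relative viability: genes whose
#' knockdown increases viability by at least 20% (mean >= 1.20) or
#' decreases it by at least 25% (mean <= 0.75) are candidates.
#'
#' @param increase_min Lower bound for increase candidates (> 1).
#' @param decrease_max Upper bound for decrease candidates (in (0, 1)).
#' @return A list of class `hit_thresholds`.
#' @export
hit_thresholds <- function(increase_min = 1.20, decrease_max = 0.75) {
  if (!(increase_min > 1 && 1 > decrease_max && decrease_max > 0)) {
    stop("thresholds must satisfy increase_min > 1 > decrease_max > 0",
         call. = FALSE)
  }
  structure(list(increase_min = increase_min, decrease_max = decrease_max),
            class = "hit_thresholds")
}

#' Call candidate genes from summarized viability scores
#'
#' Averages the replicate-summarized relative viability of each gene
#' over the selected samples and applies the inclusive thresholds: mean
#' at or above `increase_min` is an increase candidate, at or below
#' `decrease_max` a decrease candidate, anything between is none. The
#' candidate set is monotone in the thresholds: relaxing either bound
#' never removes a candidate.
#'
#' @param scores A [score_genes()] table.
#' @param samples Character vector of sample ids to average over;
#'   `NULL` uses all samples in `scores`.
#' @param thresholds A [hit_thresholds()] object.
#' @return Data frame of class `hit_table`, one row per gene, sorted by
#'   ascending mean viability (ties broken by gene id): `gene`,
#'   `mean_rel_viability`, `direction` (`increase`/`decrease`/`none`),
#'   `is_candidate`, `zscore` (mean supporting z-score over the same
#'   samples).
#' @export
call_candidates <- function(scores, samples = NULL,
                            thresholds = hit_thresholds()) {
  stopifnot(inherits(thresholds, "hit_thresholds"))
  if (is.null(samples)) samples <- unique(scores$sample_id)
  if (length(samples) == 0L) {
    stop("sample subset is empty", call. = FALSE)
  }
  missing <- setdiff(samples, unique(scores$sample_id))
  if (length(missing)) {
    stop("unknown sample_id in subset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sub <- scores[scores$sample_id %in% samples, , drop = FALSE]
  counts <- table(sub$gene)
  short <- names(counts)[counts < length(samples)]
  if (length(short)) {
    stop("genes without rel_viability in every selected sample: ",
         paste(utils::head(short, 5), collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(sub$gene))
  mv <- tapply(sub$rel_viability, sub$gene, mean)[genes]
  mz <- tapply(sub$zscore, sub$gene, mean)[genes]
  direction <- ifelse(mv >= thresholds$increase_min, "increase",
                      ifelse(mv <= thresholds$decrease_max, "decrease", "none"))
  out <- data.frame(gene = genes,
                    mean_rel_viability = as.numeric(mv),
                    direction = direction,
                    is_candidate = direction != "none",
                    zscore = as.numeric(mz),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rel_viability, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Write a hit table as TSV
#'
#' @param hits A [call_candidates()] table.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_hits <- function(hits, path) {
  write_tsv(as.data.frame(hits), path)
}
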