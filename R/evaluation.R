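# Gold-standard bin labelling from known contig origins, and the evaluation
# metrics used to score predictions.

#' F1 score from recall and precision percentages
#'
#' Harmonic mean `2 * recall * precision / (recall + precision)`, with
#' completeness playing the role of recall and purity of precision.
#' Defined as 0 when both arguments are 0.
#'
#' @param recall,precision Percentages in `[0, 100]`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' f1_score(100, 50)  # 66.667
f1_score <- function(recall, precision) {
  ifelse(recall + precision == 0, 0,
         2 * recall * precision / (recall + precision))
}

#' Bounded purity from a CheckM contamination estimate
#'
#' Marker-gene redundancy can exceed 100% contamination; this converts it to
#' a purity bounded in `(0, 100]`: `100 * 100 / (100 + contamination)`.
#' The conversion is a bijection, so contamination can be recovered exactly.
#'
#' @param contamination Contamination percentage, `>= 0`.
#' @return Purity percentage in `(0, 100]`.
#' @export
#' @examples
#' checkm_purity(c(0, 25, 100))  # 100 80 50
checkm_purity <- function(contamination) {
  stopifnot(all(contamination >= 0))
  100 * 100 / (100 + contamination)
}

#' Explained variance of predictions about the observed mean
#'
#' `R2_yx = 1 - sum((y - x)^2) / sum((x - xbar)^2)` with `x` observed and
#' `y` predicted. Unlike a correlation-based R-squared this compares the
#' predictions to the observations directly and becomes negative when the
#' model is worse than always predicting the observed mean.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2;
#'   `observed` must not be constant.
#' @return A real number, at most 1.
#' @export
r2_yx <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  denom <- sum((observed - mean(observed))^2)
  if (denom == 0) stop("observed values are all equal")
  1 - sum((predicted - observed)^2) / denom
}

#' Root-mean-square error
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  sqrt(mean((predicted - observed)^2))
}

#' Gold-standard quality of a bin from known contig origins
#'
#' The best-matching genome is the one with the most assigned base pairs in
#' the bin (ties broken towards the lexicographically smallest genome id).
#' Completeness is the fraction of that genome present in the bin, purity
#' the fraction of the bin belonging to it, both as percentages;
#' completeness is capped at 100 in case of duplicated content.
#'
#' @param bin A [mag_bin].
#' @param contig_to_genome Named character vector (or two-column data frame
#'   `contig_id`, `genome_id`) mapping contig ids to source genomes; contigs
#'   absent from the mapping or mapped to `NA`/`"unassigned"` count as
#'   unassigned.
#' @param genome_sizes Named numeric vector of genome sizes in bp.
#' @return A list of class `bin_truth`: `bin_id`, `best_genome`,
#'   `matching_bp`, `completeness`, `purity`, `f1`.
#' @export
gold_standard <- function(bin, contig_to_genome, genome_sizes) {
  if (is.data.frame(contig_to_genome)) {
    contig_to_genome <- stats::setNames(
      as.character(contig_to_genome$genome_id), contig_to_genome$contig_id)
  }
  g <- unname(contig_to_genome[bin$contigs$id])
  g[is.na(g) | g == "unassigned"] <- NA_character_
  assigned <- !is.na(g)
  if (!any(assigned)) {
    return(structure(list(bin_id = bin$id, best_genome = "none",
                          matching_bp = 0L, completeness = 0, purity = 0,
                          f1 = 0), class = "bin_truth"))
  }
  bp <- tapply(bin$contigs$length[assigned], g[assigned], sum)
  best <- sort(names(bp)[bp == max(bp)])[1L]
  matching <- as.integer(bp[[best]])
  gsize <- genome_sizes[[best]]
  if (is.null(gsize) || is.na(gsize) || gsize <= 0)
    stop("missing or non-positive genome size for ", best)
  completeness <- min(100 * matching / gsize, 100)
  purity <- 100 * matching / bin$size_bp
  structure(list(bin_id = bin$id, best_genome = best,
                 matching_bp = matching, completeness = completeness,
                 purity = purity, f1 = f1_score(completeness, purity)),
            class = "bin_truth")
}

#' @export
print.bin_truth <- function(x, ...) {
  cat(sprintf("bin_truth %s: best %s, completeness %.1f, purity %.1f, F1 %.1f\n",
              x$bin_id, x$best_genome, x$completeness, x$purity, x$f1))
  invisible(x)
}

#' Score predictions against gold-standard truth
#'
#' Joins on `bin_id` and reports `r2_yx` and `rmse` for completeness,
#' purity and F1.
#'
#' @param predictions Data frame from [predict_quality()] (columns `bin_id`,
#'   `completeness_pred`, `purity_pred`, `f1_pred`).
#' @param truth Data frame with `bin_id`, `completeness`, `purity` and
#'   optionally `f1` (recomputed if absent).
#' @return Data frame with columns `target`, `r2_yx`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (is.null(truth$f1)) truth$f1 <- f1_score(truth$completeness, truth$purity)
  m <- merge(predictions, truth, by = "bin_id")
  if (nrow(m) < 2L) stop("fewer than two bins in common")
  targets <- c("completeness", "purity", "f1")
  out <- lapply(targets, function(t) {
    obs <- m[[t]]
    pred <- m[[paste0(t, "_pred")]]
    data.frame(target = t, r2_yx = r2_yx(obs, pred),
               rmse = rmse(obs, pred), n = nrow(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
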