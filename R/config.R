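#' Analysis configuration
#'
#' Bundles every tunable of the feature-extraction and modelling pipeline:
#' the signature-method to fragment-length mapping, the PaSiT tolerance
#' threshold, the pairwise-comparison cap, and the random-forest /
#' preprocessing hyperparameters. The defaults reproduce the production
#' settings (fragment lengths 50/10/10/5 kb for PaSiT4/MMZ3/MMZ4/Freq4 and
#' 1 kb for GC); [desk_config()] scales them down for small simulated
#' genomes.
#'
#' @param fragment_lengths Named integer vector mapping the five feature
#'   blocks (`pasit4`, `mmz3`, `mmz4`, `freq4`, `gc`) to fragment lengths in
#'   bp. The GC length also sets the bin-eligibility thresholds: a bin is
#'   eligible if it has one contig longer than twice the GC length or at
#'   least two contigs longer than the GC length.
#' @param pasit_threshold Tolerance used by the PaSiT distance: two signature
#'   positions agree when their absolute difference is at most this value.
#' @param max_pairs Cap on the number of fragment pairs evaluated per bin and
#'   method; beyond it a seeded uniform subsample of pairs is used.
#' @param min_acgt_frac Fragments with a smaller fraction of unambiguous
#'   A/C/G/T bases are discarded.
#' @param pca_var Fraction of variance the retained principal components must
#'   explain in the preprocessor.
#' @param ntree,nodesize Random-forest size parameters (trees per forest,
#'   minimum terminal node size). `mtry` is always `floor(p/3)`, at least 1.
#' @param cv_folds Number of folds used to obtain out-of-fold forest
#'   predictions for the linear calibration step.
#' @param seed Integer seed controlling the only stochastic step of feature
#'   extraction (pair subsampling when `max_pairs` is exceeded).
#'
#' @return A list of class `magqc_config`.
#' @export
#' @examples
#' cfg <- magqc_config()
#' cfg$fragment_lengths
magqc_config <- function(fragment_lengths = c(pasit4 = 50000L, mmz3 = 10000L,
                                              mmz4 = 10000L, freq4 = 5000L,
                                              gc = 1000L),
                         pasit_threshold = 0.05,
                         max_pairs = 500000L,
                         min_acgt_frac = 0.9,
                         pca_var = 0.95,
                         ntree = 500L,
                         nodesize = 5L,
                         cv_folds = 10L,
                         seed = 1L) {
  blocks <- c("pasit4", "mmz3", "mmz4", "freq4", "gc")
  if (!all(blocks %in% names(fragment_lengths)))
    stop("fragment_lengths must name all of: ", paste(blocks, collapse = ", "))
  fragment_lengths <- as.integer(fragment_lengths[blocks])
  names(fragment_lengths) <- blocks
  if (any(fragment_lengths < 1L)) stop("fragment lengths must be >= 1")
  if (fragment_lengths["gc"] != min(fragment_lengths))
    stop("the GC block must use the smallest fragment length")
  structure(list(
    fragment_lengths = fragment_lengths,
    pasit_threshold = pasit_threshold,
    max_pairs = as.integer(max_pairs),
    min_acgt_frac = min_acgt_frac,
    pca_var = pca_var,
    ntree = as.integer(ntree),
    nodesize = as.integer(nodesize),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  ), class = "magqc_config")
}

#' Desk-scale configuration for small simulated genomes
#'
#' Same pipeline, with fragment lengths scaled by a factor of ten
#' (5/2/2/1 kb for the distance methods, 0.5 kb for GC) so that synthetic
#' genomes of a few hundred kb yield enough fragments per bin. Eligibility
#' thresholds scale with the GC length.
#'
#' @param ... Overrides passed on to [magqc_config()].
#' @return A `magqc_config`.
#' @export
desk_config <- function(...) {
  magqc_config(fragment_lengths = c(pasit4 = 5000L, mmz3 = 2000L,
                                    mmz4 = 2000L, freq4 = 1000L, gc = 500L),
               ...)
}

#' @export
print.magqc_config <- function(x, ...) {
  cat("magqc configuration\n")
  cat("  fragment lengths:",
      paste(names(x$fragment_lengths), x$fragment_lengths,
            sep = "=", collapse = " "), "\n")
  cat("  PaSiT threshold:", x$pasit_threshold,
      " pair cap:", x$max_pairs, " seed:", x$seed, "\n")
  invisible(x)
}

# Distinct model tiers, largest first. Tiers are the distinct fragment
# lengths of the configuration; a bin's tier is the largest length at which
# it still yields enough fragments.
config_tiers <- function(config) {
  sort(unique(unname(config$fragment_lengths)), decreasing = TRUE)
}

# Minimum fragment count for a block to be available: 3 for the pairwise
# distance blocks, 2 for the GC block (whose statistics need no pairs).
block_min_fragments <- function(block) if (block == "gc") 2L else 3L
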