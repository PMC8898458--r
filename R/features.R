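# Summarising distance sets and GC values into the fixed predictor schema:
# 5 feature blocks (PaSiT4, MMZ3, MMZ4, Freq4, GC) x 11 distribution
# statistics, plus a bin-fraction-used and a comparison count per block,
# plus the bin size: 66 predictors when every block is available.

FEATURE_BLOCKS <- c("pasit4", "mmz3", "mmz4", "freq4", "gc")
STAT_NAMES <- c("mean", "sd", "skewness", "kurtosis", "median",
                "p2_5", "p5", "p10", "p90", "p95", "p97_5")

#' Distribution statistics of a distance (or GC) set
#'
#' Eleven summary statistics: mean, sample standard deviation (n-1),
#' skewness `g1 = m3 / m2^1.5` and excess kurtosis `g2 = m4 / m2^2 - 3`
#' (central moments with n denominator), median, and the 2.5/5/10/90/95/97.5
#' percentiles by linear interpolation between order statistics (the
#' `h = (n-1) q` convention). A zero-variance input has skewness and
#' kurtosis defined as 0.
#'
#' @param values Numeric vector, length >= 2.
#' @return Named numeric vector of length 11.
#' @export
#' @examples
#' distribution_stats(1:5)[c("mean", "sd", "p90")]
distribution_stats <- function(values) {
  n <- length(values)
  if (n < 2L) stop("too few values for distribution statistics")
  m <- mean(values)
  ctr <- values - m
  m2 <- mean(ctr^2)
  if (m2 > 0) {
    skew <- mean(ctr^3) / m2^1.5
    kurt <- mean(ctr^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  qs <- stats::quantile(values, c(0.025, 0.05, 0.10, 0.5, 0.90, 0.95, 0.975),
                        type = 7, names = FALSE)
  out <- c(m, stats::sd(values), skew, kurt, qs[4L],
           qs[1L], qs[2L], qs[3L], qs[5L], qs[6L], qs[7L])
  names(out) <- STAT_NAMES
  out
}

#' The predictor-column schema
#'
#' Fixed column order of the feature table: for each block (PaSiT4, MMZ3,
#' MMZ4, Freq4, GC) the 11 distribution statistics, the bin fraction used
#' and the number of comparisons; then the bin size. 66 columns in total.
#' The columns belonging to a tier are those of the blocks whose fragment
#' length is at most the tier length, plus the bin size.
#'
#' @param config A [magqc_config()].
#' @return List with `columns` (all 66 names, in order), `blocks`,
#'   `block_columns` (names per block) and `tier_columns` (names per tier,
#'   named by tier length).
#' @export
feature_schema <- function(config = magqc_config()) {
  block_cols <- lapply(FEATURE_BLOCKS, function(b)
    c(paste(b, STAT_NAMES, sep = "_"),
      paste0(b, "_fraction_used"), paste0(b, "_n_comparisons")))
  names(block_cols) <- FEATURE_BLOCKS
  columns <- c(unlist(block_cols, use.names = FALSE), "bin_size_bp")
  tiers <- config_tiers(config)
  tier_cols <- lapply(tiers, function(L) {
    blocks <- FEATURE_BLOCKS[config$fragment_lengths <= L]
    c(unlist(block_cols[blocks], use.names = FALSE), "bin_size_bp")
  })
  names(tier_cols) <- as.character(tiers)
  list(columns = columns, blocks = FEATURE_BLOCKS,
       block_columns = block_cols, tier_columns = tier_cols)
}

#' Assemble the predictor vector for one bin
#'
#' Fragments the bin at each block's configured fragment length, computes
#' all-against-all intra-bin distances for the four signature methods and
#' per-fragment GC values for the GC block, and summarises each with
#' [distribution_stats()] plus the fraction of the bin covered by retained
#' fragments and the number of comparisons. Blocks with too few fragments
#' (fewer than 3; 2 for GC) are masked as `NA`, and the bin's tier is the
#' largest fully available fragment length.
#'
#' @param bin A [mag_bin].
#' @param config A [magqc_config()].
#' @return One-row data frame: `bin_id`, `tier` (bp), then the 66 schema
#'   columns (`NA` where masked).
#' @export
assemble_features <- function(bin, config = magqc_config()) {
  elig <- bin_eligibility(bin, config)
  if (!elig$eligible) stop("bin below minimum input: ", bin$id)
  schema <- feature_schema(config)
  vals <- stats::setNames(rep(NA_real_, length(schema$columns)),
                          schema$columns)
  vals["bin_size_bp"] <- bin$size_bp

  lens <- config$fragment_lengths
  frag_by_len <- lapply(unique(unname(lens)), function(L)
    fragment_contigs(bin, L, min_acgt_frac = config$min_acgt_frac))
  names(frag_by_len) <- as.character(unique(unname(lens)))

  avail <- stats::setNames(logical(length(FEATURE_BLOCKS)), FEATURE_BLOCKS)
  for (b in FEATURE_BLOCKS) {
    L <- lens[[b]]
    fr <- frag_by_len[[as.character(L)]]
    if (nrow(fr) < block_min_fragments(b)) next
    if (b == "gc") {
      g <- gc_values(fr$sequence)
      g <- g[!is.na(g)]
      if (length(g) < 2L) next
      st <- distribution_stats(g)
      ncmp <- length(g)
    } else {
      ds <- intra_bin_distances(fr, b, config)
      if (is.null(ds)) next
      st <- distribution_stats(ds$values)
      ncmp <- ds$n_comparisons
    }
    avail[b] <- TRUE
    vals[paste(b, STAT_NAMES, sep = "_")] <- st
    vals[paste0(b, "_fraction_used")] <- sum(fr$length) / bin$size_bp
    vals[paste0(b, "_n_comparisons")] <- ncmp
  }
  # the tier is the largest length at which every block at or below it is
  # available; the GC block (smallest length, smallest fragment minimum)
  # anchors the lowest tier
  tier <- NA_integer_
  for (L in config_tiers(config)) {
    if (all(avail[lens <= L])) { tier <- L; break }
  }
  if (is.na(tier)) stop("bin below minimum input: ", bin$id)
  out <- data.frame(bin_id = bin$id, tier = as.integer(tier),
                    stringsAsFactors = FALSE)
  out[schema$columns] <- as.list(unname(vals))
  out
}

#' Feature table for a collection of bins
#'
#' Applies [assemble_features()] to each eligible bin; ineligible bins are
#' skipped with a warning so a mixed directory can still be processed.
#'
#' @param bins List of [mag_bin] objects (e.g. from [read_bins()]).
#' @param config A [magqc_config()].
#' @return Data frame, one row per eligible bin.
#' @export
magqc_features <- function(bins, config = magqc_config()) {
  rows <- vector("list", length(bins))
  for (k in seq_along(bins)) {
    b <- bins[[k]]
    if (!bin_eligibility(b, config)$eligible) {
      warning("skipping ineligible bin: ", b$id, call. = FALSE)
      next
    }
    rows[[k]] <- assemble_features(b, config)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    schema <- feature_schema(config)
    out <- data.frame(bin_id = character(), tier = integer(),
                      stringsAsFactors = FALSE)
    out[schema$columns] <- lapply(schema$columns, function(x) numeric())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a feature table as TSV
#'
#' Tab-separated with a header row; masked cells are written as `NA`.
#'
#' @param features Feature data frame from [magqc_features()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
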