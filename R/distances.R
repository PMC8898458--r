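# Pairwise distances between fragment signatures and their all-against-all
# collection within a bin. All distances live in [0, 1].

#' PaSiT distance between two signature vectors
#'
#' Fraction of signature positions whose absolute difference exceeds the
#' tolerance threshold: `1 - #\{i : |a_i - b_i| <= t\} / length`.
#'
#' @param a,b Numeric vectors of equal length (Karlin signatures).
#' @param threshold Agreement tolerance (default 0.05).
#' @return Distance in `[0, 1]`.
#' @export
#' @examples
#' pasit_distance(c(0, 0.10), c(0.04, 0.30))  # 0.5
pasit_distance <- function(a, b, threshold = 0.05) {
  if (length(a) != length(b)) stop("signature length mismatch")
  1 - mean(abs(a - b) <= threshold)
}

#' Correlation distance between two signature vectors
#'
#' `(1 - r) / 2` where `r` is the Pearson correlation, so identical vectors
#' are at 0 and anti-correlated vectors at 1. A vector with zero variance
#' carries no compositional information; its correlation is defined as 0
#' (distance 0.5) rather than propagating NaN.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Distance in `[0, 1]`.
#' @export
correlation_distance <- function(a, b) {
  if (length(a) != length(b)) stop("signature length mismatch")
  stopifnot(length(a) >= 2L)
  r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  min(max((1 - r) / 2, 0), 1)
}

# Deterministic pair index set: all n(n-1)/2 unordered pairs in
# (1,2),(1,3),(2,3),... order, or a seeded uniform subsample when the count
# exceeds the cap.
pair_indices <- function(n, max_pairs, seed) {
  npair <- n * (n - 1) / 2
  capped <- npair > max_pairs
  if (capped) {
    set.seed(seed)
    t <- sort(sample.int(npair, max_pairs))
  } else {
    t <- seq_len(npair)
  }
  # linear index t (column-major upper triangle) -> pair (i, j), i < j
  j <- ceiling((1 + sqrt(1 + 8 * t)) / 2)
  i <- t - (j - 1) * (j - 2) / 2
  list(i = as.integer(i), j = as.integer(j), capped = capped)
}

# Pairwise PaSiT distances for a signature matrix, chunked so memory stays
# bounded for large pair sets.
pasit_pairs <- function(S, i, j, threshold) {
  d <- numeric(length(i))
  chunk <- 20000L
  for (off in seq(1L, length(i), by = chunk)) {
    idx <- off:min(off + chunk - 1L, length(i))
    d[idx] <- 1 - rowMeans(abs(S[i[idx], , drop = FALSE] -
                               S[j[idx], , drop = FALSE]) <= threshold)
  }
  d
}

# Pairwise correlation distances; zero-variance rows get r = 0 against
# everything.
correlation_pairs <- function(S, i, j) {
  sds <- apply(S, 1L, stats::sd)
  const <- sds == 0
  if (nrow(S) * nrow(S) <= 4e6 && length(i) > nrow(S)) {
    r <- suppressWarnings(stats::cor(t(S)))
    r[!is.finite(r)] <- 0
    d <- (1 - r[cbind(i, j)]) / 2
  } else {
    Z <- S - rowMeans(S)
    norm <- sqrt(rowSums(Z^2))
    norm[norm == 0] <- 1
    Z <- Z / norm
    r <- rowSums(Z[i, , drop = FALSE] * Z[j, , drop = FALSE])
    r[const[i] | const[j]] <- 0
    d <- (1 - r) / 2
  }
  pmin(pmax(d, 0), 1)
}

#' All-against-all intra-bin fragment distances for one method
#'
#' Computes the signature of every fragment and evaluates the method's
#' distance over all unordered fragment pairs. When the pair count exceeds
#' `config$max_pairs` a seeded uniform subsample of pairs is used and
#' recorded. Fewer than three fragments make the block unavailable
#' (returns `NULL`), which is a normal condition for short bins, not an
#' error.
#'
#' @param fragments Fragment data frame from [fragment_contigs()].
#' @param method One of `"pasit4"`, `"mmz3"`, `"mmz4"`, `"freq4"`.
#' @param config A [magqc_config()].
#' @return A list of class `distance_set` with `bin_id`, `method`, `values`,
#'   `n_fragments`, `n_comparisons`, `capped`, `seed`; or `NULL` when the
#'   block is unavailable.
#' @export
intra_bin_distances <- function(fragments, method, config = magqc_config()) {
  if (nrow(fragments) < 3L) return(NULL)
  S <- signature_matrix(fragments$sequence, method)
  ok <- attr(S, "available")
  S <- S[ok, , drop = FALSE]
  n <- nrow(S)
  if (n < 3L) return(NULL)
  p <- pair_indices(n, config$max_pairs, config$seed)
  d <- if (method == "pasit4") {
    pasit_pairs(S, p$i, p$j, config$pasit_threshold)
  } else {
    correlation_pairs(S, p$i, p$j)
  }
  structure(list(bin_id = fragments$bin_id[1L], method = method,
                 values = d, n_fragments = n, n_comparisons = length(d),
                 capped = p$capped, seed = config$seed),
            class = "distance_set")
}

#' @export
print.distance_set <- function(x, ...) {
  cat("distance_set", x$bin_id, x$method, "-", x$n_fragments, "fragments,",
      x$n_comparisons, "comparisons",
      if (x$capped) "(capped)" else "", "\n")
  invisible(x)
}
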