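# Fragment-length optimisation: score a (signature method, fragment length)
# combination by how well a quadratic discriminant separates the two most
# overlapping genomes of a multi-genome set in 2-PC signature space.

#' QDA separability of the hardest genome pair at one fragment length
#'
#' Every genome is cut into overlapping fragments (default step = half the
#' fragment length), the method's signature is computed per fragment, and
#' PCA on the pooled signatures is reduced to two components. The genome
#' pair whose 2-PC centroids are closest (Euclidean) is taken as the most
#' overlapping pair, a quadratic discriminant classifier is fitted between
#' them in 2-PC space, and its resubstitution accuracy is returned. Chance
#' level (0.5) means the pair is inseparable at this fragment length.
#'
#' @param genomes Named character vector / `DNAStringSet` / list of
#'   `synthetic_genome`s, typically 5 genomes.
#' @param method One of `"pasit4"`, `"mmz3"`, `"mmz4"`, `"freq4"`.
#' @param fragment_length Fragment length in bp.
#' @param step Start-to-start distance; default `fragment_length / 2`.
#' @param min_fragments Minimum fragments required per genome.
#' @return A list of class `fraglen_result`: `method`, `fragment_length`,
#'   `accuracy`, `pair` (the two genome ids compared) and `n_fragments`.
#' @export
qda_fraglen_accuracy <- function(genomes, method, fragment_length,
                                 step = max(1L, fragment_length %/% 2L),
                                 min_fragments = 10L) {
  seqs <- genome_sequences(genomes)
  frag_seq <- character(); frag_lab <- character()
  for (gid in names(seqs)) {
    b <- mag_bin(gid, stats::setNames(seqs[[gid]], gid))
    fr <- fragment_contigs(b, fragment_length, step = step)
    if (nrow(fr) < min_fragments)
      stop("insufficient fragments for genome ", gid,
           " at length ", fragment_length)
    frag_seq <- c(frag_seq, fr$sequence)
    frag_lab <- c(frag_lab, rep(gid, nrow(fr)))
  }
  S <- signature_matrix(frag_seq, method)
  keep <- attr(S, "available")
  S <- S[keep, , drop = FALSE]
  frag_lab <- frag_lab[keep]
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  cent <- do.call(rbind, lapply(split(as.data.frame(pc), frag_lab), colMeans))
  dmat <- as.matrix(stats::dist(cent))
  diag(dmat) <- Inf
  idx <- which(dmat == min(dmat), arr.ind = TRUE)[1L, ]
  pair <- sort(rownames(dmat)[idx])
  sel <- frag_lab %in% pair
  x <- pc[sel, , drop = FALSE]
  grp <- factor(frag_lab[sel])
  acc <- tryCatch({
    q <- MASS::qda(x, grouping = grp)
    mean(stats::predict(q, x)$class == grp)
  }, error = function(e) {
    # identical or degenerate classes: no discriminant exists, report the
    # majority-class rate (chance level for balanced classes)
    max(table(grp)) / length(grp)
  })
  structure(list(method = method, fragment_length = as.integer(fragment_length),
                 accuracy = acc, pair = pair, n_fragments = nrow(pc)),
            class = "fraglen_result")
}

genome_sequences <- function(genomes) {
  if (methods::is(genomes, "DNAStringSet")) {
    s <- as.character(genomes)
  } else if (is.list(genomes) &&
             all(vapply(genomes, inherits, TRUE, "synthetic_genome"))) {
    s <- stats::setNames(vapply(genomes, `[[`, "", "sequence"),
                         vapply(genomes, `[[`, "", "id"))
  } else {
    s <- as.character(genomes)
  }
  if (is.null(names(s)) || any(names(s) == ""))
    names(s) <- paste0("genome_", seq_along(s))
  s
}

#' Scan a grid of methods and fragment lengths
#'
#' @param genomes As in [qda_fraglen_accuracy()].
#' @param methods Signature methods to scan.
#' @param lengths Fragment lengths in bp.
#' @param ... Passed to [qda_fraglen_accuracy()].
#' @return Data frame with `method`, `fragment_length`, `accuracy`.
#' @export
fraglen_grid <- function(genomes,
                         methods = c("pasit4", "mmz3", "mmz4", "freq4"),
                         lengths = c(1, 5, 10, 20, 30, 40, 50, 75, 100) * 1000,
                         ...) {
  rows <- list()
  for (m in methods) for (L in lengths) {
    r <- qda_fraglen_accuracy(genomes, m, L, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      method = m, fragment_length = as.integer(L), accuracy = r$accuracy,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Production fragment lengths chosen for the four methods: long fragments
# for the threshold-based Karlin distance, intermediate for the Markov
# z-scores, short for raw frequency profiles.
CANONICAL_LENGTHS <- c(pasit4 = 50000L, mmz3 = 10000L, mmz4 = 10000L,
                       freq4 = 5000L)

#' Select a fragment length per method from a scanned grid
#'
#' Returns the canonical production mapping (PaSiT4 at 50 kb, MMZ3 and MMZ4
#' at 10 kb, Freq4 at 5 kb) restricted to the methods and lengths present in
#' the grid: when a method's canonical length is absent, the closest
#' available length (ties towards the shorter) is chosen. The scanned grid
#' accompanies the mapping so the trade-off can be inspected and
#' overridden.
#'
#' @param grid Data frame from [fraglen_grid()].
#' @return List with `mapping` (named integer vector, bp per method) and
#'   `grid`.
#' @export
select_fragment_lengths <- function(grid) {
  stopifnot(all(c("method", "fragment_length", "accuracy") %in% names(grid)))
  mapping <- integer()
  for (m in unique(grid$method)) {
    avail <- sort(unique(grid$fragment_length[grid$method == m]))
    target <- if (m %in% names(CANONICAL_LENGTHS)) CANONICAL_LENGTHS[[m]]
              else max(avail)
    mapping[[m]] <- avail[order(abs(avail - target), avail)][1L]
  }
  list(mapping = mapping, grid = grid)
}
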