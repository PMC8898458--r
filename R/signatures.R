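# Compositional signatures per fragment.
#
# All methods work from overlapping k-mer window counts restricted to
# unambiguous A/C/G/T windows (windows containing N are skipped), with
# reverse-complement symmetrization switched on: contig orientation in an
# assembly is arbitrary, and symmetrized counts make every signature exactly
# strand-symmetric.

.sig_cache <- new.env(parent = emptyenv())

# k-mer bookkeeping for one k: lexicographic k-mer strings, the permutation
# sending each k-mer to its reverse complement, and (for k >= 3) the indices
# of the prefix/suffix (k-1)-mers and the middle (k-2)-mer used by the
# Markov expectations.
kmer_map <- function(k) {
  key <- paste0("k", k)
  if (!is.null(.sig_cache[[key]])) return(.sig_cache[[key]])
  kmers <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  map <- list(k = k, kmers = kmers, rc = match(rc, kmers))
  if (k >= 2L) {
    sub <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k - 1L)
    map$prefix <- match(substr(kmers, 1L, k - 1L), sub)
    map$suffix <- match(substr(kmers, 2L, k), sub)
  }
  if (k >= 3L) {
    mid <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k - 2L)
    map$middle <- match(substr(kmers, 2L, k - 1L), mid)
  }
  .sig_cache[[key]] <- map
  map
}

# n x 4^k matrix of k-mer window counts for a set of sequences, columns in
# lexicographic order; windows containing N contribute nothing.
kmer_count_matrix <- function(seqs, k, symmetrize = TRUE) {
  dss <- if (methods::is(seqs, "DNAStringSet")) seqs
         else Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(dss, width = k)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L, dimnames = list(NULL, names(m)))
  map <- kmer_map(k)
  m <- m[, map$kmers, drop = FALSE]
  if (symmetrize) m <- m + m[, map$rc, drop = FALSE]
  m
}

#' Count k-mer windows in a sequence
#'
#' Counts every overlapping window of length `k` consisting solely of
#' A/C/G/T (windows containing N or other ambiguity codes are skipped).
#' With `symmetrize = TRUE` the counts of each k-mer's reverse complement
#' are added, making downstream signatures strand-symmetric.
#'
#' @param sequence A single DNA string.
#' @param k Word length, `k >= 1`.
#' @param symmetrize Add reverse-complement counts?
#' @return A list of class `kmer_counts` with `k`, `counts` (named integer
#'   vector over the 4^k k-mers in lexicographic order) and `total`.
#' @export
#' @examples
#' count_kmers("ACGTACGT", 2)$counts[c("AC", "CG", "GT", "TA")]
count_kmers <- function(sequence, k, symmetrize = FALSE) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  if (nchar(sequence) < k) stop("sequence shorter than k")
  m <- kmer_count_matrix(sequence, as.integer(k), symmetrize = symmetrize)
  counts <- m[1L, ]
  structure(list(k = as.integer(k), counts = counts, total = sum(counts)),
            class = "kmer_counts")
}

# ---- matrix-form signatures (one row per fragment) ----------------------

# Karlin-style tetranucleotide relative abundance: observed tetramer
# frequency over its second-order Markov expectation,
# rho(wxyz) = f(wxyz) f(xy) / (f(wxy) f(xyz)), on symmetrized counts.
# Zero denominators give the neutral value 1.
karlin_matrix <- function(seqs) {
  c4 <- kmer_count_matrix(seqs, 4L)
  c3 <- kmer_count_matrix(seqs, 3L)
  c2 <- kmer_count_matrix(seqs, 2L)
  t4 <- rowSums(c4); t3 <- rowSums(c3); t2 <- rowSums(c2)
  ok <- t4 > 0 & t3 > 0 & t2 > 0
  f4 <- c4 / ifelse(t4 > 0, t4, 1)
  f3 <- c3 / ifelse(t3 > 0, t3, 1)
  f2 <- c2 / ifelse(t2 > 0, t2, 1)
  map <- kmer_map(4L)
  num <- f4 * f2[, map$middle, drop = FALSE]
  den <- f3[, map$prefix, drop = FALSE] * f3[, map$suffix, drop = FALSE]
  rho <- num / den
  rho[den == 0] <- 1
  colnames(rho) <- map$kmers
  attr(rho, "available") <- ok
  rho
}

# TETRA-style z-scores under a maximal-order Markov expectation from
# prefix/suffix/overlap counts:
#   N_exp = N(p) N(q) / N(m)
#   var   = N_exp (N(m) - N(p)) (N(m) - N(q)) / N(m)^2
#   z     = (N_obs - N_exp) / sqrt(var)
# with z = 0 whenever the variance degenerates (var <= 0 or N(m) = 0).
mmz_matrix <- function(seqs, k) {
  stopifnot(k %in% c(3L, 4L))
  ck <- kmer_count_matrix(seqs, k)
  cp <- kmer_count_matrix(seqs, k - 1L)
  cm <- kmer_count_matrix(seqs, k - 2L)
  map <- kmer_map(k)
  Np <- cp[, map$prefix, drop = FALSE]
  Nq <- cp[, map$suffix, drop = FALSE]
  Nm <- cm[, map$middle, drop = FALSE]
  Nm_safe <- ifelse(Nm > 0, Nm, 1)
  Nexp <- Np * Nq / Nm_safe
  v <- Nexp * (Nm - Np) * (Nm - Nq) / Nm_safe^2
  z <- (ck - Nexp) / sqrt(ifelse(v > 0, v, 1))
  z[v <= 0 | Nm == 0] <- 0
  colnames(z) <- map$kmers
  attr(z, "available") <- rowSums(ck) > 0
  z
}

# Tetranucleotide frequency profile on symmetrized counts; rows sum to 1.
freq_matrix <- function(seqs) {
  c4 <- kmer_count_matrix(seqs, 4L)
  t4 <- rowSums(c4)
  f <- c4 / ifelse(t4 > 0, t4, 1)
  attr(f, "available") <- t4 > 0
  f
}

# Dispatch: one row of signature values per sequence for a block name.
signature_matrix <- function(seqs, method) {
  switch(method,
         pasit4 = karlin_matrix(seqs),
         mmz3 = mmz_matrix(seqs, 3L),
         mmz4 = mmz_matrix(seqs, 4L),
         freq4 = freq_matrix(seqs),
         stop("unknown signature method: ", method))
}

# ---- scalar (single-sequence) API ---------------------------------------

single_signature <- function(sequence, method) {
  m <- signature_matrix(sequence, method)
  if (!attr(m, "available")[1L]) stop("signature unavailable: no usable k-mers")
  m[1L, ]
}

#' Karlin tetranucleotide relative-abundance signature
#'
#' For each tetranucleotide wxyz, the ratio of its observed relative
#' frequency to its second-order Markov expectation,
#' `f(wxyz) f(xy) / (f(wxy) f(xyz))`, computed from strand-symmetrized
#' window counts. Values near 1 indicate no deviation from the Markov
#' background; cells with a zero denominator are set to the neutral value 1.
#'
#' @param sequence A single DNA string.
#' @return Named numeric vector of length 256.
#' @export
karlin_signature <- function(sequence) single_signature(sequence, "pasit4")

#' Markov-model z-score signature (tri- or tetranucleotides)
#'
#' Standardized deviation of each k-mer count from its Markov expectation
#' built from the counts of its length k-1 prefix and suffix and its length
#' k-2 overlap (the TETRA construction), on strand-symmetrized counts.
#' Degenerate cells (zero variance or zero overlap count) yield z = 0.
#'
#' @param sequence A single DNA string.
#' @param k 3 or 4.
#' @return Named numeric vector of length 64 (`k = 3`) or 256 (`k = 4`).
#' @export
markov_zscores <- function(sequence, k = 4L) {
  stopifnot(k %in% c(3L, 4L))
  single_signature(sequence, if (k == 3L) "mmz3" else "mmz4")
}

#' Tetranucleotide frequency profile
#'
#' Strand-symmetrized tetranucleotide relative frequencies; sums to 1.
#'
#' @param sequence A single DNA string.
#' @return Named numeric vector of length 256.
#' @export
freq_profile <- function(sequence) single_signature(sequence, "freq4")

#' GC content of a sequence
#'
#' `(G + C) / (A + C + G + T)`; N and other ambiguous bases are excluded
#' from both numerator and denominator.
#'
#' @param sequence A single DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' gc_content("ANGC")  # 2/3
gc_content <- function(sequence) {
  lf <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(toupper(sequence)), letters = c("A", "C", "G", "T"))
  tot <- sum(lf)
  if (tot == 0) stop("GC content unavailable: no unambiguous bases")
  unname((lf[1L, "G"] + lf[1L, "C"]) / tot)
}

# Vectorized GC for fragment sets; NA where a fragment has no ACGT at all
# (cannot happen after the ambiguity filter, kept as a guard).
gc_values <- function(seqs) {
  lf <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), letters = c("A", "C", "G", "T"))
  tot <- rowSums(lf)
  ifelse(tot > 0, (lf[, "G"] + lf[, "C"]) / tot, NA_real_)
}
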