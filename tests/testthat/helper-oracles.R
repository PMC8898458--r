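# Independent brute-force oracles for the compositional signatures, built
# by literal window enumeration with base R only. They share no code with
# the package implementation.

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_all_kmers <- function(k) {
  g <- do.call(expand.grid,
               rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE]
  sort(apply(g, 1, paste, collapse = ""))
}

# Named count vector over all 4^k k-mers; windows containing anything but
# A/C/G/T are skipped; optional reverse-complement symmetrization.
oracle_counts <- function(seq, k, symmetrize = TRUE) {
  kmers <- oracle_all_kmers(k)
  n <- nchar(seq)
  counts <- stats::setNames(rep(0L, length(kmers)), kmers)
  if (n >= k) {
    w <- substring(seq, 1:(n - k + 1), k:n)
    w <- w[grepl("^[ACGT]+$", w)]
    tab <- table(w)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  if (symmetrize) {
    rc <- vapply(kmers, oracle_revcomp, "")
    counts <- counts + counts[rc]
    names(counts) <- kmers
  }
  counts
}

oracle_karlin <- function(seq) {
  c4 <- oracle_counts(seq, 4); c3 <- oracle_counts(seq, 3)
  c2 <- oracle_counts(seq, 2)
  f4 <- c4 / sum(c4); f3 <- c3 / sum(c3); f2 <- c2 / sum(c2)
  kmers <- names(c4)
  vapply(kmers, function(s) {
    num <- f4[[s]] * f2[[substr(s, 2, 3)]]
    den <- f3[[substr(s, 1, 3)]] * f3[[substr(s, 2, 4)]]
    if (den == 0) 1 else num / den
  }, 0)
}

oracle_mmz <- function(seq, k) {
  ck <- oracle_counts(seq, k)
  cp <- oracle_counts(seq, k - 1)
  cm <- oracle_counts(seq, k - 2)
  vapply(names(ck), function(s) {
    Np <- cp[[substr(s, 1, k - 1)]]
    Nq <- cp[[substr(s, 2, k)]]
    Nm <- cm[[substr(s, 2, k - 1)]]
    if (Nm == 0) return(0)
    Ne <- Np * Nq / Nm
    v <- Ne * (Nm - Np) * (Nm - Nq) / Nm^2
    if (v <= 0) return(0)
    (ck[[s]] - Ne) / sqrt(v)
  }, 0)
}

oracle_freq <- function(seq) {
  c4 <- oracle_counts(seq, 4)
  c4 / sum(c4)
}

oracle_gc <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% c("A", "C", "G", "T"))
}

oracle_pearson <- function(a, b) {
  n <- length(a)
  (sum(a * b) - n * mean(a) * mean(b)) /
    sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
}
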