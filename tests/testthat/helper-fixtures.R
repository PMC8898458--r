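# Shared fixtures, built in code at test time.

random_dna <- function(n, seed, with_n = FALSE) {
  set.seed(seed)
  alph <- c("A", "C", "G", "T")
  s <- sample(alph, n, replace = TRUE)
  if (with_n) s[sample(n, max(1, n %/% 50))] <- "N"
  paste(s, collapse = "")
}

# A bin made of plain repeated-letter contigs of given lengths (fast to
# build; composition is irrelevant for structural tests).
lengths_bin <- function(lengths, id = "bin", base = "ACGT") {
  seqs <- vapply(lengths, function(L)
    paste(rep(strrep(base, ceiling(L / nchar(base))), 1), collapse = ""), "")
  seqs <- substr(seqs, 1, lengths)
  names(seqs) <- paste0("c", seq_along(lengths))
  mag_bin(id, seqs)
}

# A bin cut from a simulated genome into equal contigs, so every feature
# block has realistic compositional signal.
genome_bin <- function(genome, contig_len, id = "bin") {
  n <- genome$length %/% contig_len
  seqs <- substring(genome$sequence,
                    (0:(n - 1)) * contig_len + 1,
                    (1:n) * contig_len)
  names(seqs) <- paste0("c", seq_len(n))
  mag_bin(id, seqs)
}

write_fasta_file <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(seqs[i], con)
  }
  path
}
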