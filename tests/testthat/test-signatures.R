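test_that("k-mer window counting enumerates literally and skips N windows", {
  k <- count_kmers("ACGTACGT", 2)
  expect_equal(k$counts[c("AC", "CG", "GT", "TA")], c(AC = 2, CG = 2, GT = 2, TA = 1))
  expect_equal(k$total, 7)
  k2 <- count_kmers("AANAA", 2)
  expect_equal(unname(k2$counts["AA"]), 2)
  expect_equal(k2$total, 2)
  k3 <- count_kmers("ACGT", 4, symmetrize = TRUE)
  expect_equal(unname(k3$counts["ACGT"]), 2)  # own reverse complement
  expect_equal(k3$total, 2)
  expect_error(count_kmers("ACG", 4), "shorter")
})

test_that("Karlin signature is neutral on a homopolymer and near 1 on i.i.d. sequence", {
  s <- karlin_signature(strrep("A", 1000))
  expect_equal(unname(s["AAAA"]), 1)
  expect_equal(unname(s["TTTT"]), 1)
  r <- karlin_signature(random_dna(100000, seed = 7))
  expect_true(all(abs(r - 1) < 0.2))
})

test_that("Markov z-scores vanish where the variance degenerates", {
  z <- markov_zscores(strrep("A", 1000), 4)
  # only the AAAA/TTTT cells have positive variance, and it is tiny
  expect_lt(max(abs(z[c("AAAA", "TTTT")])), 0.05)
  expect_equal(unname(z[setdiff(names(z), c("AAAA", "TTTT"))]),
               rep(0, 254))
  z3 <- markov_zscores(strrep("A", 1000), 3)
  expect_lt(max(abs(z3)), 0.05)
  expect_error(markov_zscores("AC", 4), "shorter|unavailable")
})

test_that("frequency profile is a normalized symmetrized tetramer distribution", {
  f <- freq_profile(strrep("ACGT", 250))
  expect_equal(sum(f), 1)
  # mass only on rotations of ACGT (all self-reverse-complementary classes)
  expect_true(all(f[f > 0] >= 0.2))
  fh <- freq_profile(strrep("A", 1000))
  expect_equal(unname(fh[c("AAAA", "TTTT")]), c(0.5, 0.5))
})

test_that("GC content excludes ambiguous bases from both terms", {
  expect_equal(gc_content("ACGT"), 0.5)
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ANGC"), 2 / 3)
  expect_error(gc_content("NNNN"), "unavailable")
})

test_that("every signature is exactly strand-symmetric", {
  for (seed in 1:5) {
    s <- random_dna(600, seed = seed)
    rc <- oracle_revcomp(s)
    expect_identical(karlin_signature(s), karlin_signature(rc))
    expect_identical(markov_zscores(s, 3), markov_zscores(rc, 3))
    expect_identical(markov_zscores(s, 4), markov_zscores(rc, 4))
    expect_identical(freq_profile(s), freq_profile(rc))
  }
})

test_that("signatures match the brute-force window-counting oracles", {
  set.seed(99)
  lens <- sample(100:2000, 25)
  for (i in seq_along(lens)) {
    s <- random_dna(lens[i], seed = 1000 + i, with_n = i %% 5 == 0)
    expect_equal(unname(karlin_signature(s)), unname(oracle_karlin(s)),
                 tolerance = 1e-12)
    expect_equal(unname(markov_zscores(s, 3)), unname(oracle_mmz(s, 3)),
                 tolerance = 1e-9)
    expect_equal(unname(markov_zscores(s, 4)), unname(oracle_mmz(s, 4)),
                 tolerance = 1e-9)
    expect_equal(unname(freq_profile(s)), unname(oracle_freq(s)),
                 tolerance = 1e-12)
    expect_equal(gc_content(s), oracle_gc(s), tolerance = 1e-12)
  }
})

test_that("symmetrized counts equal raw counts of sequence plus its reverse complement", {
  s <- random_dna(500, seed = 31)
  sym <- count_kmers(s, 3, symmetrize = TRUE)$counts
  raw <- count_kmers(s, 3)$counts + count_kmers(oracle_revcomp(s), 3)$counts
  expect_equal(sym, raw)
})
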