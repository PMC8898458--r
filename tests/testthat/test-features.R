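test_that("distribution statistics match hand-computed values", {
  s <- distribution_stats(1:5)
  expect_equal(unname(s["mean"]), 3)
  expect_equal(unname(s["median"]), 3)
  expect_equal(unname(s["skewness"]), 0)
  expect_equal(unname(s["sd"]), sqrt(2.5))
  expect_equal(unname(s["p90"]), 4.6)  # h = (n-1)q interpolation
  k <- distribution_stats(rep(2, 3))
  expect_equal(unname(k[c("sd", "skewness", "kurtosis")]), c(0, 0, 0))
  expect_true(all(k[c("median", "p2_5", "p97_5")] == 2))
  expect_error(distribution_stats(1), "few")
})

test_that("percentiles are ordered for arbitrary inputs", {
  for (seed in 1:10) {
    set.seed(seed)
    s <- distribution_stats(rexp(sample(3:50, 1)))
    q <- s[c("p2_5", "p5", "p10", "median", "p90", "p95", "p97_5")]
    expect_true(all(diff(q) >= 0))
    expect_gte(s["sd"], 0)
  }
})

test_that("the schema fixes 66 predictors and the tier column counts", {
  sch <- feature_schema(magqc_config())
  expect_length(sch$columns, 66)
  counts <- vapply(sch$tier_columns, length, 1L)
  expect_equal(unname(counts[c("50000", "10000", "5000", "1000")]),
               c(66L, 53L, 27L, 14L))
})

test_that("feature assembly masks blocks by contig length and sets the tier", {
  cfg <- desk_config()  # pasit4@5k mmz@2k freq4@1k gc@500
  g <- simulate_genome(120000, seed = 55, id = "g")

  full <- assemble_features(genome_bin(g, 30000, id = "full"), cfg)
  expect_equal(sum(is.na(full)), 0)
  expect_equal(full$tier, 5000L)
  expect_equal(ncol(full), 68)  # bin_id + tier + 66 predictors

  # longest contig 3.5 kb: the 5 kb block is masked, tier drops
  mid <- assemble_features(genome_bin(g, 3500, id = "mid"), cfg)
  expect_true(all(is.na(mid[grep("^pasit4_", names(mid))])))
  expect_false(anyNA(mid[grep("^mmz4_", names(mid))]))
  expect_equal(mid$tier, 2000L)

  # a single 1.25 kb contig: only the GC block remains
  tiny <- assemble_features(mag_bin("tiny",
                                    c(c1 = substr(g$sequence, 1, 1250))), cfg)
  expect_false(anyNA(tiny[grep("^gc_", names(tiny))]))
  expect_true(all(is.na(tiny[grep("^(pasit4|mmz3|mmz4|freq4)_", names(tiny))])))
  expect_equal(tiny$tier, 500L)

  expect_error(assemble_features(mag_bin("no", c(c1 = strrep("ACGT", 100))),
                                 cfg), "minimum input")
})

test_that("fraction used never increases with fragment length", {
  g <- simulate_genome(80000, seed = 66, id = "g")
  b <- genome_bin(g, 7000)
  f <- assemble_features(b, desk_config())
  fr <- unlist(f[paste0(c("gc", "freq4", "mmz4", "pasit4"),
                        "_fraction_used")])
  fr <- fr[!is.na(fr)]
  expect_true(all(diff(fr) <= 1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("the feature table skips ineligible bins with a warning", {
  cfg <- desk_config()
  g <- simulate_genome(40000, seed = 77, id = "g")
  bins <- list(genome_bin(g, 8000, id = "good"),
               mag_bin("bad", c(c1 = strrep("ACGT", 100))))
  expect_warning(tab <- magqc_features(bins, cfg), "ineligible")
  expect_equal(tab$bin_id, "good")
  # all-ineligible input: empty table, header intact
  expect_warning(emp <- magqc_features(bins[2], cfg), "ineligible")
  expect_equal(nrow(emp), 0)
  expect_true(all(feature_schema(cfg)$columns %in% names(emp)))
})
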