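test_that("genome simulation is seed-deterministic and hits its GC target", {
  g1 <- simulate_genome(50000, seed = 5, id = "g")
  g2 <- simulate_genome(50000, seed = 5, id = "g")
  expect_identical(g1$sequence, g2$sequence)
  expect_equal(nchar(g1$sequence), 50000)
  lo <- simulate_genome(200000, gc_target = 0.30, seed = 6, id = "lo")
  hi <- simulate_genome(200000, gc_target = 0.70, seed = 7, id = "hi")
  expect_lt(abs(gc_content(lo$sequence) - 0.30), 0.05)
  expect_lt(abs(gc_content(hi$sequence) - 0.70), 0.05)
  expect_error(simulate_genome(5000, seed = 1), "10000")
})

test_that("whole-genome bins are complete and pure", {
  g <- simulate_genome(60000, seed = 8, id = "g")
  sb <- simulate_bin(g, target_completeness = 1, target_purity = 1,
                     seed = 9, id = "b")
  expect_equal(sb$truth$completeness, 100)
  expect_equal(sb$truth$purity, 100)
  expect_equal(sb$bin$size_bp, g$length)
})

test_that("realized completeness and purity land near their targets", {
  g <- simulate_genome(500000, seed = 10, id = "src")
  cont <- lapply(1:4, function(i)
    simulate_genome(200000, seed = 20 + i, id = paste0("c", i)))
  sb <- simulate_bin(g, cont, target_completeness = 0.6, target_purity = 0.8,
                     meanlog = log(5000), seed = 11, id = "b")
  expect_lt(abs(sb$truth$completeness - 60), 2)
  expect_lt(abs(sb$truth$purity - 80), 2)
})

test_that("stored truth is exactly the gold standard of the provenance", {
  g <- simulate_genome(100000, seed = 12, id = "src")
  cont <- lapply(1:3, function(i)
    simulate_genome(80000, seed = 30 + i, id = paste0("c", i)))
  sb <- simulate_bin(g, cont, target_completeness = 0.7, target_purity = 0.6,
                     seed = 13, id = "b")
  sizes <- c(src = 100000, c1 = 80000, c2 = 80000, c3 = 80000)
  redo <- gold_standard(sb$bin,
                        stats::setNames(sb$provenance$genome_id,
                                        sb$provenance$contig_id), sizes)
  expect_identical(redo$completeness, sb$truth$completeness)
  expect_identical(redo$purity, sb$truth$purity)
  expect_identical(redo$best_genome, sb$truth$best_genome)
  # provenance intervals re-extract to the stored contig sequences
  i <- which(sb$provenance$genome_id == "src")[1]
  expect_identical(substring(g$sequence, sb$provenance$start[i] + 1,
                             sb$provenance$end[i]),
                   sb$bin$contigs$sequence[
                     sb$bin$contigs$id == sb$provenance$contig_id[i]])
})

test_that("a forced contaminant with purity 1 is infeasible", {
  g <- simulate_genome(50000, seed = 14, id = "src")
  expect_error(simulate_bin(g, list(), target_completeness = 0.5,
                            target_purity = 0.5, seed = 15, id = "b"),
               "infeasible")
})

test_that("dataset simulation is byte-deterministic and within ranges", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  args <- list(n_genomes = 5, n_bins = 30,
               genome_length_range = c(60000, 100000), seed = 77)
  s1 <- do.call(simulate_dataset, c(args, list(out_dir = dir1)))
  s2 <- do.call(simulate_dataset, c(args, list(out_dir = dir2)))
  f1 <- list.files(dir1, recursive = TRUE)
  expect_identical(f1, list.files(dir2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(dir1, f), "raw", 3e6),
                     readBin(file.path(dir2, f), "raw", 3e6))
  expect_equal(nrow(s1$truth), 30)
  expect_true(all(s1$truth$completeness >= 15 & s1$truth$completeness <= 100))
  expect_true(all(s1$truth$purity >= 25 & s1$truth$purity <= 100))
  cfg <- desk_config()
  expect_true(all(vapply(s1$bins, function(b)
    bin_eligibility(b, cfg)$eligible, TRUE)))
  # bins read back from FASTA equal the in-memory bins
  rb <- read_bins(file.path(dir1, "bins"))
  expect_identical(rb[[s1$bins[[3]]$id]]$contigs, s1$bins[[3]]$contigs)
})
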