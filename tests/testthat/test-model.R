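# A small labelled synthetic dataset shared by the model tests.
model_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_dataset(n_genomes = 5, n_bins = 36,
                              genome_length_range = c(80000, 150000),
                              seed = 404)
      cfg <- desk_config()
      cache <<- list(sim = sim, cfg = cfg,
                     feats = magqc_features(sim$bins, cfg))
    }
    cache
  }
})

test_that("the log shift makes every variable strictly positive", {
  set.seed(2)
  X <- cbind(a = runif(12, 1, 2), b = runif(12, -1.5, -0.5), c = rnorm(12))
  X[1, "b"] <- -2  # fix the minimum exactly
  pre <- fit_preprocessor(X)
  expect_equal(unname(pre$shift["a"]), 0)
  expect_equal(unname(pre$shift["b"]), 3)  # 1 - (-2)
  expect_true(all(X + rep(pre$shift, each = 12) > 0))
})

test_that("the preprocessor reprojects its own training data exactly", {
  f <- model_fixture()
  cols <- feature_schema(f$cfg)$tier_columns[["1000"]]
  X <- f$feats[f$feats$tier >= 1000, cols]
  X <- X[stats::complete.cases(X), ]
  pre <- fit_preprocessor(X)
  expect_true(all(abs(crossprod(pre$rotation) -
                        diag(pre$n_comp)) < 1e-9))  # orthonormal loadings
  aug1 <- apply_preprocessor(pre, X)
  aug2 <- apply_preprocessor(pre, X)
  expect_identical(aug1, aug2)
  expect_equal(ncol(aug1), ncol(X) + pre$n_comp)
  # a test value below the training minimum still maps to a finite number
  Xlow <- X[1, , drop = FALSE]
  Xlow[1, ] <- Xlow[1, ] - 10 * abs(Xlow[1, ]) - 10
  expect_true(all(is.finite(apply_preprocessor(pre, Xlow))))
})

test_that("constant labels yield constant calibrated predictions", {
  f <- model_fixture()
  truth <- f$sim$truth
  truth$completeness <- 80
  truth$purity <- 80
  # the constant response triggers randomForest's regression caution; that
  # degenerate input is exactly what this test exercises
  bundle <- suppressWarnings(train_quality_model(f$feats, truth, f$cfg,
                                                 seed = 9))
  p <- predict_quality(bundle, f$feats)
  expect_equal(p$completeness_pred, rep(80, nrow(p)), tolerance = 1e-6)
  expect_equal(p$purity_pred, rep(80, nrow(p)), tolerance = 1e-6)
})

test_that("training is deterministic given the seed", {
  f <- model_fixture()
  b1 <- train_quality_model(f$feats, f$sim$truth, f$cfg, seed = 11)
  b2 <- train_quality_model(f$feats, f$sim$truth, f$cfg, seed = 11)
  expect_identical(predict_quality(b1, f$feats), predict_quality(b2, f$feats))
})

test_that("predictions are percentages and every eligible bin is scored", {
  f <- model_fixture()
  bundle <- train_quality_model(f$feats, f$sim$truth, f$cfg, seed = 12)
  p <- predict_quality(bundle, f$feats)
  expect_setequal(p$bin_id, f$feats$bin_id)
  expect_true(all(p$completeness_pred >= 0 & p$completeness_pred <= 100))
  expect_true(all(p$purity_pred >= 0 & p$purity_pred <= 100))
  expect_equal(p$f1_pred, f1_score(p$completeness_pred, p$purity_pred))
  # resubstitution predictions beat the mean-label baseline
  m <- merge(p, f$sim$truth, by = "bin_id")
  expect_gt(r2_yx(m$completeness, m$completeness_pred), 0)
  expect_gt(r2_yx(m$purity, m$purity_pred), 0)
})

test_that("bins lacking long contigs are served by a lower-tier model", {
  f <- model_fixture()
  bundle <- train_quality_model(f$feats, f$sim$truth, f$cfg, seed = 13)
  g <- f$sim$genomes[[1]]
  short <- mag_bin("shorty", stats::setNames(
    substring(g$sequence, seq(1, 36001, 1200), seq(1200, 37200, 1200)),
    paste0("c", 1:31)))
  sf <- assemble_features(short, f$cfg)
  expect_lt(sf$tier, 5000L)
  p <- predict_quality(bundle, sf)
  expect_equal(p$tier, sf$tier)
  expect_true(is.finite(p$completeness_pred))
})

test_that("bundles round-trip through disk and refuse foreign schemas", {
  f <- model_fixture()
  bundle <- train_quality_model(f$feats, f$sim$truth, f$cfg, seed = 14)
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, path)
  b2 <- load_bundle(path)
  expect_identical(predict_quality(bundle, f$feats),
                   predict_quality(b2, f$feats))
  bad <- bundle
  bad$schema_version <- "someone-elses-bundle"
  path2 <- withr::local_tempfile(fileext = ".rds")
  saveRDS(bad, path2)
  expect_error(load_bundle(path2), "schema mismatch")
})

test_that("quality covariates must accompany a covariate-trained bundle", {
  f <- model_fixture()
  truth <- f$sim$truth
  set.seed(1)
  chk <- data.frame(bin_id = truth$bin_id,
                    checkm_completeness = pmin(pmax(
                      truth$completeness + rnorm(nrow(truth), 0, 5), 0), 100),
                    checkm_contamination = pmax(
                      100 * 100 / pmax(truth$purity, 1) - 100, 0))
  bundle <- train_quality_model(f$feats, truth, f$cfg, seed = 15, checkm = chk)
  expect_error(predict_quality(bundle, f$feats), "covariates")
  p <- predict_quality(bundle, f$feats, checkm = chk)
  expect_true(all(is.finite(p$completeness_pred)))
})
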