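# End-to-end parameter-recovery experiment on synthetic data: simulate a
# labelled bin set, extract features, and estimate held-out performance by
# k-fold cross-validation of the full train/predict pipeline. This is the
# package's self-contained substitute for benchmarking on a wet-lab mock:
# it measures whether the distance-distribution features carry enough
# signal to recover known completeness and purity.

#' Held-out recovery of completeness and purity on synthetic bins
#'
#' Simulates `n_genomes` genomes and `n_bins` bins ([simulate_dataset()]),
#' extracts the predictor table, and runs `folds`-fold cross-validation of
#' [train_quality_model()] / [predict_quality()]. Reports `r2_yx` and
#' `rmse` per target over the pooled held-out predictions, together with
#' the RMSE of the mean-label baseline (predicting every bin at the
#' training-fold mean).
#'
#' @param seed Root seed for simulation, feature extraction and training.
#' @param config Feature/model configuration; defaults to [desk_config()],
#'   which matches the default synthetic genome sizes.
#' @param n_genomes,n_bins Simulation size.
#' @param folds Number of cross-validation folds.
#' @param checkm_noise_sd If not `NULL`, also trains the CheckM-augmented
#'   variant using synthetic quality covariates (truth plus Gaussian noise
#'   of this SD) and reports it as targets prefixed `checkm_`.
#' @param ... Passed to [simulate_dataset()].
#' @return List with `metrics` (data frame: `target`, `r2_yx`, `rmse`,
#'   `baseline_rmse`, `n`), `predictions` (pooled held-out predictions with
#'   truth), and `features`.
#' @export
quality_recovery_experiment <- function(seed = 1L, config = desk_config(),
                                        n_genomes = 20L, n_bins = 200L,
                                        folds = 5L, checkm_noise_sd = NULL,
                                        ...) {
  sim <- simulate_dataset(n_genomes = n_genomes, n_bins = n_bins,
                          seed = seed, ...)
  feats <- magqc_features(sim$bins, config)
  truth <- sim$truth
  checkm <- NULL
  if (!is.null(checkm_noise_sd)) {
    set.seed(derive_seed(seed, 99L))
    checkm <- data.frame(
      bin_id = truth$bin_id,
      checkm_completeness = pmin(pmax(
        truth$completeness + stats::rnorm(nrow(truth), 0, checkm_noise_sd),
        0), 100),
      checkm_contamination = pmax(
        (100 / pmin(pmax(truth$purity +
                           stats::rnorm(nrow(truth), 0, checkm_noise_sd),
                         1), 100)) * 100 - 100, 0),
      stringsAsFactors = FALSE)
  }
  cv <- recovery_cv(feats, truth, config, seed, folds, checkm = NULL)
  metrics <- cv$metrics
  preds <- cv$predictions
  if (!is.null(checkm)) {
    cvk <- recovery_cv(feats, truth, config, derive_seed(seed, 7L), folds,
                       checkm = checkm)
    mk <- cvk$metrics
    mk$target <- paste0("checkm_", mk$target)
    metrics <- rbind(metrics, mk)
  }
  list(metrics = metrics, predictions = preds, features = feats,
       truth = truth)
}

recovery_cv <- function(feats, truth, config, seed, folds, checkm = NULL) {
  d <- merge(feats["bin_id"], truth, by = "bin_id")
  n <- nrow(d)
  set.seed(derive_seed(seed, 501L))
  fold <- sample(rep_len(seq_len(folds), n))
  preds <- vector("list", folds)
  base_sq <- stats::setNames(numeric(3L), c("completeness", "purity", "f1"))
  for (f in seq_len(folds)) {
    tr_ids <- d$bin_id[fold != f]
    te_ids <- d$bin_id[fold == f]
    bundle <- train_quality_model(feats[feats$bin_id %in% tr_ids, ],
                                  truth[truth$bin_id %in% tr_ids, ],
                                  config, seed = derive_seed(seed, 600L + f),
                                  checkm = if (is.null(checkm)) NULL else
                                    checkm[checkm$bin_id %in% tr_ids, ])
    p <- predict_quality(bundle, feats[feats$bin_id %in% te_ids, ],
                         checkm = if (is.null(checkm)) NULL else
                           checkm[checkm$bin_id %in% te_ids, ])
    preds[[f]] <- p
    # mean-label baseline: training-fold mean predicted for every test bin
    tr <- truth[truth$bin_id %in% tr_ids, ]
    te <- truth[truth$bin_id %in% te_ids, ]
    for (tg in names(base_sq))
      base_sq[tg] <- base_sq[tg] + sum((te[[tg]] - mean(tr[[tg]]))^2)
  }
  pred <- do.call(rbind, preds)
  m <- merge(pred, truth, by = "bin_id")
  rows <- lapply(names(base_sq), function(tg) {
    data.frame(target = tg,
               r2_yx = r2_yx(m[[tg]], m[[paste0(tg, "_pred")]]),
               rmse = rmse(m[[tg]], m[[paste0(tg, "_pred")]]),
               baseline_rmse = sqrt(base_sq[[tg]] / nrow(m)),
               n = nrow(m), stringsAsFactors = FALSE)
  })
  list(metrics = do.call(rbind, rows), predictions = m)
}
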