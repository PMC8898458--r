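# Tiered quality model: per tier, a log/PCA preprocessor, one random forest
# per target (completeness, purity) fed with the original predictors plus
# their principal-component scores, and a linear calibration fitted to
# out-of-fold forest predictions.

#' Fit the log/PCA preprocessor on a training feature table
#'
#' Each variable is shifted to be strictly positive (`shift = 1 - min` when
#' the minimum is non-positive, else 0), log10-transformed, centred and unit
#' scaled, then projected by PCA. The smallest number of components
#' explaining at least `pca_var` of the variance is retained. Zero-variance
#' columns are kept with scale 1 and flagged.
#'
#' @param X Numeric matrix or data frame of predictors (rows = bins), no
#'   missing values, at least 10 rows.
#' @param pca_var Fraction of variance to retain.
#' @return A list of class `magqc_preprocessor` with per-variable `shift`,
#'   `center`, `scale`, `arg_floor` (smallest positive log argument seen in
#'   training, used to clamp out-of-range test values), the PCA `rotation`
#'   and `n_comp`, and the training column names.
#' @export
fit_preprocessor <- function(X, pca_var = 0.95) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 10L, all(is.finite(X)))
  mins <- apply(X, 2L, min)
  shift <- ifelse(mins <= 0, 1 - mins, 0)
  A <- sweep(X, 2L, shift, "+")
  L <- log10(A)
  center <- colMeans(L)
  sds <- apply(L, 2L, stats::sd)
  flagged <- sds == 0
  scl <- ifelse(flagged, 1, sds)
  Z <- sweep(sweep(L, 2L, center, "-"), 2L, scl, "/")
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  n_comp <- which(cumsum(ev) / sum(ev) >= pca_var)[1L]
  structure(list(columns = colnames(X), shift = shift, center = center,
                 scale = scl, zero_variance = flagged,
                 arg_floor = apply(A, 2L, min),
                 rotation = pr$rotation[, seq_len(n_comp), drop = FALSE],
                 n_comp = n_comp, pca_var = pca_var),
            class = "magqc_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' Returns the concatenation of the original untransformed predictors and
#' the principal-component scores computed with the training-set shift,
#' centre, scale and loadings. A test value whose shifted log argument is
#' non-positive is clamped to the smallest positive argument seen in
#' training.
#'
#' @param pre A `magqc_preprocessor`.
#' @param X Predictor matrix/data frame with the training columns.
#' @return Numeric matrix with `ncol(X) + n_comp` columns.
#' @export
apply_preprocessor <- function(pre, X) {
  X <- as.matrix(X)
  if (!all(pre$columns %in% colnames(X)))
    stop("feature schema mismatch: missing predictor columns")
  X <- X[, pre$columns, drop = FALSE]
  A <- sweep(X, 2L, pre$shift, "+")
  for (j in seq_len(ncol(A))) {
    bad <- A[, j] <= 0
    if (any(bad)) A[bad, j] <- pre$arg_floor[j]
  }
  L <- log10(A)
  Z <- sweep(sweep(L, 2L, pre$center, "-"), 2L, pre$scale, "/")
  scores <- Z %*% pre$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  cbind(X, scores)
}

# Deterministic sub-seed derivation (kept below 2^31).
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (p in parts) s <- (s * 1103515245 + p + 12345) %% 2147483647
  as.integer(s)
}

fit_forest <- function(Xa, y, config, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = as.data.frame(Xa), y = y,
    ntree = config$ntree,
    mtry = max(1L, floor(ncol(Xa) / 3)),
    nodesize = config$nodesize)
}

# Out-of-fold forest predictions for the calibration regression; the
# preprocessor is refitted inside each fold so no test information leaks.
cv_predictions <- function(X, y, config, seed) {
  n <- nrow(X)
  k <- min(config$cv_folds, n)
  set.seed(derive_seed(seed, 1L))
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    pre <- fit_preprocessor(X[tr, , drop = FALSE], config$pca_var)
    rf <- fit_forest(apply_preprocessor(pre, X[tr, , drop = FALSE]),
                     y[tr], config, derive_seed(seed, 2L, f))
    pred[!tr] <- stats::predict(
      rf, as.data.frame(apply_preprocessor(pre, X[!tr, , drop = FALSE])))
  }
  pred
}

# Ordinary-least-squares calibration of raw forest output against truth;
# degenerates to a constant when the CV predictions carry no signal.
fit_calibration <- function(truth, cvpred) {
  if (stats::sd(cvpred) == 0)
    return(c(intercept = mean(truth), slope = 0))
  co <- stats::coef(stats::lm(truth ~ cvpred))
  c(intercept = unname(co[1L]), slope = unname(co[2L]))
}

#' Train the tiered bin-quality model
#'
#' For each tier (fragment length), bins whose tier is at least that length
#' are selected, the tier's predictor columns are preprocessed
#' ([fit_preprocessor()]), and one random forest per target (completeness,
#' purity) is fitted on the original plus PCA-projected predictors. A
#' linear calibration is then fitted to out-of-fold cross-validated forest
#' predictions. With `checkm = TRUE`, the supplied numeric CheckM columns
#' are appended to the predictor set of every tier before preprocessing.
#'
#' @param features Feature table from [magqc_features()].
#' @param truth Data frame with `bin_id`, `completeness`, `purity` (in
#'   percent, `[0, 100]`).
#' @param config A [magqc_config()].
#' @param seed Integer seed for forest fitting and fold assignment.
#' @param checkm Optional data frame with `bin_id` plus numeric columns
#'   (typically `checkm_completeness`, `checkm_contamination`,
#'   `checkm_strain_heterogeneity` from a CheckM qa table).
#' @return A `magqc_bundle`: schema version, config, per-tier preprocessor,
#'   forests, calibration lines and training metadata.
#' @export
train_quality_model <- function(features, truth, config = magqc_config(),
                                seed = 1L, checkm = NULL) {
  stopifnot(all(c("bin_id", "tier") %in% names(features)),
            all(c("bin_id", "completeness", "purity") %in% names(truth)))
  d <- merge(features, truth[c("bin_id", "completeness", "purity")],
             by = "bin_id")
  if (nrow(d) < 30L) stop("need at least 30 labelled bins to train")
  if (any(d$completeness < 0 | d$completeness > 100) ||
      any(d$purity < 0 | d$purity > 100))
    stop("targets must be percentages in [0, 100]")
  checkm_cols <- character()
  if (!is.null(checkm)) {
    num <- names(checkm)[vapply(checkm, is.numeric, TRUE)]
    checkm_cols <- setdiff(num, "bin_id")
    if (length(checkm_cols) == 0L) stop("checkm table has no numeric columns")
    d <- merge(d, checkm[c("bin_id", checkm_cols)], by = "bin_id")
  }
  schema <- feature_schema(config)
  tiers <- config_tiers(config)
  targets <- c("completeness", "purity")
  tier_models <- list()
  n_per_tier <- integer()
  for (ti in seq_along(tiers)) {
    L <- tiers[ti]
    rows <- d$tier >= L
    cols <- c(schema$tier_columns[[as.character(L)]], checkm_cols)
    X <- d[rows, cols, drop = FALSE]
    ok <- stats::complete.cases(X)
    X <- X[ok, , drop = FALSE]
    y <- d[rows, targets, drop = FALSE][ok, , drop = FALSE]
    if (nrow(X) < 10L) {
      warning("tier ", L, " omitted: only ", nrow(X), " usable bins",
              call. = FALSE)
      next
    }
    pre <- fit_preprocessor(X, config$pca_var)
    Xa <- apply_preprocessor(pre, X)
    models <- list()
    for (tg in targets) {
      rf <- fit_forest(Xa, y[[tg]], config, derive_seed(seed, ti, match(tg, targets)))
      cvp <- cv_predictions(X, y[[tg]], config,
                            derive_seed(seed, ti, 10L + match(tg, targets)))
      models[[tg]] <- list(forest = rf,
                           calibration = fit_calibration(y[[tg]], cvp))
    }
    tier_models[[as.character(L)]] <- list(tier = L, preprocessor = pre,
                                           models = models)
    n_per_tier[as.character(L)] <- nrow(X)
  }
  if (length(tier_models) == 0L) stop("no tier had enough training bins")
  structure(list(schema_version = "magqc-bundle-1",
                 config = config, schema = schema,
                 checkm_cols = checkm_cols,
                 tiers = tier_models,
                 metadata = list(n_bins = nrow(d), n_per_tier = n_per_tier,
                                 seed = as.integer(seed),
                                 trained = format(Sys.time(), "%Y-%m-%d"))),
            class = "magqc_bundle")
}

#' @export
print.magqc_bundle <- function(x, ...) {
  cat("magqc model bundle (", x$schema_version, ")\n", sep = "")
  cat("  tiers:", paste(names(x$tiers), collapse = ", "), "bp\n")
  cat("  trained on", x$metadata$n_bins, "bins; seed", x$metadata$seed, "\n")
  if (length(x$checkm_cols))
    cat("  CheckM covariates:", paste(x$checkm_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Predict bin quality with a trained bundle
#'
#' Each bin is served by the largest bundle tier not exceeding its own tier
#' (so bins lacking long contigs fall back to models trained without the
#' missing feature blocks). Raw forest output is passed through the tier's
#' calibration line, clipped to `[0, 100]`, and the F1 score is the
#' harmonic mean of the predicted completeness and purity.
#'
#' @param bundle A `magqc_bundle` from [train_quality_model()].
#' @param features Feature table from [magqc_features()]; when the bundle
#'   was trained with CheckM covariates, supply them via `checkm`.
#' @param checkm Optional CheckM table as in [train_quality_model()].
#' @return Data frame: `bin_id`, `tier` (model tier used, bp),
#'   `completeness_pred`, `purity_pred`, `f1_pred`.
#' @export
predict_quality <- function(bundle, features, checkm = NULL) {
  if (!inherits(bundle, "magqc_bundle") ||
      !identical(bundle$schema_version, "magqc-bundle-1"))
    stop("model bundle schema mismatch")
  d <- features
  if (length(bundle$checkm_cols)) {
    if (is.null(checkm)) stop("bundle requires CheckM covariates")
    d <- merge(d, checkm[c("bin_id", bundle$checkm_cols)], by = "bin_id")
  }
  bundle_tiers <- sort(as.integer(names(bundle$tiers)), decreasing = TRUE)
  used <- vapply(d$tier, function(bt) {
    fit <- bundle_tiers[bundle_tiers <= bt]
    if (length(fit) == 0L) NA_integer_ else fit[1L]
  }, integer(1))
  if (anyNA(used))
    stop("bin below minimum input: ",
         paste(d$bin_id[is.na(used)], collapse = ", "))
  out <- data.frame(bin_id = d$bin_id, tier = used,
                    completeness_pred = NA_real_, purity_pred = NA_real_,
                    f1_pred = NA_real_, stringsAsFactors = FALSE)
  for (L in unique(used)) {
    tm <- bundle$tiers[[as.character(L)]]
    rows <- used == L
    cols <- c(bundle$schema$tier_columns[[as.character(L)]],
              bundle$checkm_cols)
    X <- d[rows, cols, drop = FALSE]
    if (anyNA(X)) stop("masked predictors within the served tier")
    Xa <- apply_preprocessor(tm$preprocessor, X)
    for (tg in c("completeness", "purity")) {
      m <- tm$models[[tg]]
      raw <- stats::predict(m$forest, as.data.frame(Xa))
      cal <- m$calibration["intercept"] + m$calibration["slope"] * raw
      out[rows, paste0(tg, "_pred")] <- pmin(pmax(unname(cal), 0), 100)
    }
  }
  out$f1_pred <- f1_score(out$completeness_pred, out$purity_pred)
  out
}

#' Save / load a model bundle
#'
#' Single-file serialized archive; the schema version is checked on load
#' and a mismatch is refused.
#'
#' @param bundle A `magqc_bundle`.
#' @param path File path.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "magqc_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "magqc_bundle") ||
      !identical(b$schema_version, "magqc-bundle-1"))
    stop("model bundle schema mismatch: ", path)
  b
}
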