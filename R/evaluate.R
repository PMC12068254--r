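#' Threshold scores into class labels
#'
#' Label 1 (HR) iff `score > threshold`, strictly: a score exactly at the
#' threshold is assigned to class 0 (TW). Order is preserved.
#'
#' @param scores Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Integer vector of 0/1 labels.
#' @export
predict_labels <- function(scores, threshold = 0.5) {
  as.integer(scores > threshold)
}

#' Classification metrics (support-weighted, percent)
#'
#' Accuracy plus precision, recall and F1 computed per class and averaged
#' with class-support weights, reported on the 0-100 scale. A class that is
#' never predicted contributes precision 0. With this averaging, a
#' constant-class predictor on balanced labels scores
#' 50.00 / 25.00 / 50.00 / 33.33 and weighted recall always equals accuracy.
#'
#' @param y_true,y_pred Binary vectors (0/1).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be binary")
  n <- length(y_true)
  acc <- mean(y_true == y_pred)
  prec <- rec <- f1 <- 0
  for (cls in c(0, 1)) {
    sup <- sum(y_true == cls)
    if (sup == 0) next
    tp <- sum(y_true == cls & y_pred == cls)
    fp <- sum(y_true != cls & y_pred == cls)
    fn <- sup - tp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    w <- sup / n
    prec <- prec + w * p; rec <- rec + w * r; f1 <- f1 + w * f
  }
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1) * 100
}

#' Taylor-diagram statistics
#'
#' The triple relating a score series to its reference labels: population
#' standard deviations, Pearson correlation and centered RMSE, which obey
#' the law of cosines
#' `cRMSE^2 = sd_m^2 + sd_r^2 - 2 sd_m sd_r r`.
#'
#' @param scores Predicted scores.
#' @param labels Reference labels (non-constant).
#' @return Object of class `wm_taylor` with `sd_model`, `sd_reference`,
#'   `pearson_r`, `centered_rmse`.
#' @export
taylor_statistics <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  n <- length(scores)
  if (n < 2) stop("need at least 2 points")
  if (stats::sd(labels) == 0) stop("constant labels: correlation undefined")
  psd <- function(v) sqrt(mean((v - mean(v))^2))
  sm <- psd(scores); sr <- psd(labels)
  r <- stats::cor(scores, labels)
  crmse <- sqrt(mean(((scores - mean(scores)) - (labels - mean(labels)))^2))
  structure(list(sd_model = sm, sd_reference = sr, pearson_r = r,
                 centered_rmse = crmse), class = "wm_taylor")
}

#' @export
print.wm_taylor <- function(x, ...) {
  cat(sprintf("<taylor stats: sd_model %.4f, sd_ref %.4f, r %.4f, cRMSE %.4f>\n",
              x$sd_model, x$sd_reference, x$pearson_r, x$centered_rmse))
  invisible(x)
}

#' Leave-one-patient-out cross-validation
#'
#' One fold per patient: the model is trained on all other patients' points
#' (labeled and unlabeled) and scored on every labeled point of the held-out
#' patient; the held-out patient's points, including its unlabeled ones,
#' never enter training, and the per-channel normalization statistics are
#' recomputed per fold from the training patients only. Cohort-level metrics
#' are the unweighted mean of the per-patient metrics. Patients without
#' labeled points are skipped with a warning.
#'
#' @param cohort A `wm_cohort`, or a `wm_features` object.
#' @param variant Method variant (see [wallnet_variant()]).
#' @param config,loss Model and loss configuration.
#' @param epochs,batch_size,lr,validation_split,patience Passed to
#'   [wallnet()].
#' @param factor Interpolation factor for feature extraction (when `cohort`
#'   is a `wm_cohort`).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @param verbose Print per-fold progress.
#' @return Object of class `wm_lopo`: `folds` (per-patient results with
#'   scores, predictions, truth, attention maps, metrics and the training
#'   patient set) and `metrics` (cohort-level unweighted means).
#' @export
lopo_cross_validate <- function(cohort, variant = "proposed",
                                config = wallnet_config(),
                                loss = loss_config(), epochs = 30L,
                                batch_size = 32L, lr = 1e-3,
                                validation_split = 0.1, patience = 10L,
                                factor = 1L, seed = 1L, verbose = FALSE) {
  feats <- if (inherits(cohort, "wm_features")) cohort
    else build_feature_batch(cohort$trajectories, factor = factor)
  pats <- sort(unique(feats$patient))
  if (length(pats) < 2) stop("LOPO needs at least 2 patients")
  folds <- list()
  for (i in seq_along(pats)) {
    held <- pats[i]
    te <- feats$patient == held & !is.na(feats$y)
    if (!any(te)) {
      warning("patient ", held, " has no labeled points; fold skipped")
      next
    }
    tr_lab <- feats$patient != held & !is.na(feats$y)
    tr_unl <- feats$patient != held & is.na(feats$y)
    fit <- wallnet(
      x = feats$x[tr_lab, , , drop = FALSE], y = feats$y[tr_lab],
      patient = feats$patient[tr_lab],
      x_unlabeled = if (any(tr_unl)) feats$x[tr_unl, , , drop = FALSE],
      variant = variant, config = config, loss = loss, epochs = epochs,
      batch_size = batch_size, lr = lr,
      validation_split = validation_split, patience = patience,
      seed = derive_seed(seed, i))
    sc <- predict(fit, feats$x[te, , , drop = FALSE], type = "score")
    pr <- predict_labels(sc)
    am <- predict(fit, feats$x[te, , , drop = FALSE], type = "attention")
    met <- classification_metrics(feats$y[te], pr)
    folds[[held]] <- list(patient = held, point_id = feats$point_id[te],
                          score = sc, pred = pr, truth = feats$y[te],
                          attention = am, metrics = met,
                          train_patients = sort(unique(feats$patient[tr_lab | tr_unl])))
    if (verbose)
      message(sprintf("fold %s: accuracy %.2f%%", held, met["accuracy"]))
  }
  if (length(folds) == 0) stop("no fold had labeled points")
  mm <- do.call(rbind, lapply(folds, function(f) f$metrics))
  structure(list(folds = folds, metrics = colMeans(mm), variant = variant,
                 seed = seed),
            class = "wm_lopo")
}

#' @export
print.wm_lopo <- function(x, ...) {
  cat(sprintf("<wm_lopo: variant '%s', %d folds>\n", x$variant,
              length(x$folds)))
  print(round(x$metrics, 2))
  invisible(x)
}

#' Per-patient accuracies of a LOPO run
#' @param lopo A `wm_lopo`.
#' @return Named numeric vector (percent).
#' @export
patient_accuracies <- function(lopo) {
  vapply(lopo$folds, function(f) unname(f$metrics["accuracy"]), numeric(1))
}

#' Run several method variants on identical folds
#'
#' All variants share the same fold partitions and per-fold seeds, so rows
#' are paired.
#'
#' @param cohort A `wm_cohort` or `wm_features`.
#' @param variants Subset of the five variant names.
#' @param ... Passed to [lopo_cross_validate()].
#' @param seed Master seed (shared across variants).
#' @return Object of class `wm_ablation`: `table` (data.frame, rows =
#'   variants, columns = the four metrics) and `runs` (the `wm_lopo`
#'   objects).
#' @export
run_ablation <- function(cohort, variants = c("proposed", "baseline",
                                              "only-mae", "no-patient",
                                              "no-unlabeled"),
                         seed = 1L, ...) {
  known <- c("proposed", "baseline", "only-mae", "no-patient", "no-unlabeled")
  bad <- setdiff(variants, known)
  if (length(bad)) stop("unknown variant: ", paste(bad, collapse = ", "))
  feats <- if (inherits(cohort, "wm_features")) cohort
    else build_feature_batch(cohort$trajectories)
  runs <- lapply(variants, function(v)
    lopo_cross_validate(feats, variant = v, seed = seed, ...))
  names(runs) <- variants
  tab <- as.data.frame(do.call(rbind, lapply(runs, function(r) r$metrics)))
  tab <- cbind(variant = variants, tab)
  rownames(tab) <- NULL
  structure(list(table = tab, runs = runs), class = "wm_ablation")
}

#' @export
print.wm_ablation <- function(x, ...) {
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Stratify patients into failed and succeeded sets
#'
#' A patient "fails" when its accuracy under the designated reference
#' variant falls below the cutoff (default: below 80% under the `only-mae`
#' method). Metric averages are recomputed for both strata, for every
#' variant supplied.
#'
#' @param results Named list of `wm_lopo` objects (one per variant), or a
#'   `wm_ablation`.
#' @param reference Variant whose accuracies define the stratification.
#' @param cutoff Accuracy cutoff in percent.
#' @return Object of class `wm_strata`: `failed`, `succeeded` (patient id
#'   vectors) and `table` (stratified unweighted metric means per variant).
#' @export
stratify_patients <- function(results, reference = "only-mae", cutoff = 80) {
  if (inherits(results, "wm_ablation")) results <- results$runs
  if (!reference %in% names(results))
    stop("reference variant '", reference, "' not in results")
  ref_acc <- patient_accuracies(results[[reference]])
  failed <- names(ref_acc)[ref_acc < cutoff]
  succeeded <- names(ref_acc)[ref_acc >= cutoff]
  metric_names <- c("accuracy", "precision", "recall", "f1")
  strat_row <- function(run, pats) {
    if (length(pats) == 0)
      return(stats::setNames(rep(NA_real_, 4), metric_names))
    mm <- do.call(rbind, lapply(run$folds[pats], function(f) f$metrics))
    stats::setNames(colMeans(mm), metric_names)
  }
  rows <- list()
  for (v in names(results)) {
    rows[[length(rows) + 1]] <- data.frame(
      variant = v, stratum = "failed",
      t(strat_row(results[[v]], failed)))
    rows[[length(rows) + 1]] <- data.frame(
      variant = v, stratum = "succeeded",
      t(strat_row(results[[v]], succeeded)))
  }
  tab <- do.call(rbind, rows)
  names(tab)[3:6] <- c("accuracy", "precision", "recall", "f1")
  structure(list(failed = failed, succeeded = succeeded, table = tab,
                 reference = reference, cutoff = cutoff),
            class = "wm_strata")
}

#' @export
print.wm_strata <- function(x, ...) {
  cat(sprintf("<wm_strata: %d failed, %d succeeded (reference '%s', cutoff %g%%)>\n",
              length(x$failed), length(x$succeeded), x$reference, x$cutoff))
  tab <- x$table
  tab[, 3:6] <- round(tab[, 3:6], 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
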