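#' Two-sample Kolmogorov-Smirnov test
#'
#' Statistic: supremum over the pooled sample points of the absolute ECDF
#' difference; p-value from the asymptotic two-sample KS distribution
#' (sample sizes here are in the hundreds, where the asymptotic form is
#' adequate).
#'
#' @param a,b Numeric samples with at least 2 values each.
#' @return List with `statistic` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 values")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Levene's variance-equality test
#'
#' Classic (mean-centered) Levene W: a one-way ANOVA F statistic on the
#' absolute deviations from each group's mean, with the p-value from the F
#' distribution.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   values).
#' @return List with `statistic`, `p`, and the degrees of freedom.
#' @export
levene_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  z <- unlist(lapply(groups, function(g) abs(g - mean(g))))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::sd(z) == 0)
    return(list(statistic = 0, p = 1, df1 = length(groups) - 1,
                df2 = length(z) - length(groups)))
  ow <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(ow$statistic), p = unname(ow$p.value),
       df1 = unname(ow$parameter[1]), df2 = unname(ow$parameter[2]))
}

#' Dynamic time warping distance
#'
#' Classic dynamic-programming alignment with unit steps (match, insert,
#' delete), absolute-difference local cost, no window and no normalization;
#' returns the optimal cumulative cost.
#'
#' @param s1,s2 Non-empty numeric series.
#' @return Non-negative scalar.
#' @export
dtw_distance <- function(s1, s2) {
  if (length(s1) == 0 || length(s2) == 0) stop("series must be non-empty")
  cpp_dtw(as.numeric(s1), as.numeric(s2))
}

#' 1-D first-order Wasserstein distance
#'
#' The integral of the absolute ECDF difference, computed exactly from the
#' pooled quantile breakpoints; for equal sample sizes this reduces to the
#' mean absolute difference of the sorted samples.
#'
#' @param a,b Non-empty numeric samples.
#' @return Non-negative scalar.
#' @export
wasserstein_1d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("samples must be non-empty")
  sa <- sort(a); sb <- sort(b)
  if (na == nb) return(mean(abs(sa - sb)))
  qs <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  lo <- c(0, qs[-length(qs)])
  w <- qs - lo
  # type-1 quantile: F^{-1}(q) = sorted[ceiling(q n)] on each interval
  qa <- sa[pmin(na, ceiling(qs * na - 1e-12))]
  qb <- sb[pmin(nb, ceiling(qs * nb - 1e-12))]
  sum(w * abs(qa - qb))
}

#' Per-patient distributional heterogeneity report
#'
#' Reproduces the distribution diagnostics comparing TW and HR motion within
#' each patient and contrasting failed against succeeded patients:
#' \itemize{
#'   \item per patient and feature channel, the two-sample KS statistic
#'     between the pooled TW and HR feature values of that patient's points;
#'   \item per patient, the DTW distance between the patient's mean TW speed
#'     series and mean HR speed series;
#'   \item per patient, the 1-D Wasserstein distance between the pooled TW
#'     and HR speed values;
#'   \item with a stratification, a second KS test comparing the failed
#'     patients' KS statistics against the succeeded patients', and a
#'     Levene test on per-trajectory mean speed (movement-feature
#'     dispersion) between the two groups.
#' }
#' Patients missing a labeled class are excluded with a warning.
#'
#' @param feats A `wm_features` object (see [build_feature_batch()]), or a
#'   `wm_cohort`.
#' @param stratification Optional character vector of failed patient ids
#'   (e.g. `wm_strata$failed`), or a `wm_strata`.
#' @return Object of class `wm_heterogeneity`: `per_patient` (data.frame
#'   with KS statistics and p-values per channel, DTW, Wasserstein, group),
#'   `group_tests` (KS + Levene comparing failed vs succeeded; `NULL`
#'   without stratification) and `boxplot_data` (long-format CSV-ready
#'   data.frame of KS statistics).
#' @export
patient_heterogeneity_report <- function(feats, stratification = NULL) {
  if (inherits(feats, "wm_cohort"))
    feats <- build_feature_batch(feats$trajectories)
  if (inherits(stratification, "wm_strata"))
    stratification <- stratification$failed
  chans <- feature_channels()
  pats <- sort(unique(feats$patient))
  rows <- list(); box <- list()
  for (p in pats) {
    tw <- feats$patient == p & !is.na(feats$y) & feats$y == 0
    hr <- feats$patient == p & !is.na(feats$y) & feats$y == 1
    if (!any(tw) || !any(hr)) {
      warning("patient ", p, " lacks a labeled class; excluded")
      next
    }
    grp <- if (is.null(stratification)) NA_character_
      else if (p %in% stratification) "failed" else "succeeded"
    ksr <- lapply(seq_along(chans), function(ci)
      ks_two_sample(as.numeric(feats$x[tw, ci, ]),
                    as.numeric(feats$x[hr, ci, ])))
    dtw <- dtw_distance(colMeans(feats$x[tw, 1, , drop = FALSE][, 1, ]),
                        colMeans(feats$x[hr, 1, , drop = FALSE][, 1, ]))
    was <- wasserstein_1d(as.numeric(feats$x[tw, 1, ]),
                          as.numeric(feats$x[hr, 1, ]))
    row <- data.frame(patient = p, group = grp, dtw_speed = dtw,
                      wasserstein_speed = was)
    for (ci in seq_along(chans)) {
      row[[paste0("ks_", chans[ci])]] <- ksr[[ci]]$statistic
      row[[paste0("ksp_", chans[ci])]] <- ksr[[ci]]$p
    }
    rows[[p]] <- row
    box[[p]] <- data.frame(patient = p, group = grp, channel = chans,
                           ks_statistic = vapply(ksr, function(k)
                             k$statistic, numeric(1)))
  }
  if (length(rows) == 0) stop("no patient had both labeled classes")
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  boxplot_data <- do.call(rbind, box)
  rownames(boxplot_data) <- NULL

  group_tests <- NULL
  if (!is.null(stratification)) {
    ks_cols <- paste0("ks_", chans)
    f <- per_patient$group == "failed"
    if (sum(f) >= 2 && sum(!f) >= 2) {
      ksf <- as.numeric(as.matrix(per_patient[f, ks_cols]))
      kss <- as.numeric(as.matrix(per_patient[!f, ks_cols]))
      grp_ks <- ks_two_sample(ksf, kss)
      # dispersion of movement features: per-trajectory mean speed
      sp_mean <- rowMeans(feats$x[, 1, , drop = FALSE][, 1, ])
      lab <- !is.na(feats$y) & feats$patient %in% per_patient$patient
      gl <- ifelse(feats$patient %in% per_patient$patient[f], "failed",
                   "succeeded")
      lev <- levene_test(split(sp_mean[lab], gl[lab]))
      group_tests <- list(ks = grp_ks, levene = lev)
    }
  }
  structure(list(per_patient = per_patient, group_tests = group_tests,
                 boxplot_data = boxplot_data),
            class = "wm_heterogeneity")
}

#' @export
print.wm_heterogeneity <- function(x, ...) {
  cat(sprintf("<wm_heterogeneity: %d patients>\n", nrow(x$per_patient)))
  ks_cols <- grep("^ks_", names(x$per_patient), value = TRUE)
  cat(sprintf("  mean KS statistic across channels: %.3f\n",
              mean(as.matrix(x$per_patient[, ks_cols]))))
  if (!is.null(x$group_tests))
    cat(sprintf("  failed-vs-succeeded KS: D = %.3f (p = %.3g); Levene W = %.3f (p = %.3g)\n",
                x$group_tests$ks$statistic, x$group_tests$ks$p,
                x$group_tests$levene$statistic, x$group_tests$levene$p))
  invisible(x)
}
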