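test_that("score thresholding is strict at 0.5 and order preserving", {
  expect_identical(predict_labels(c(0.49, 0.51)), c(0L, 1L))
  expect_identical(predict_labels(0.5), 0L)
  sc <- c(0.9, 0.1, 0.6, 0.4)
  expect_identical(predict_labels(sc), c(1L, 0L, 1L, 0L))
})

test_that("a constant predictor on balanced labels gives the degenerate row", {
  y <- rep(c(0, 1), each = 50)
  m <- classification_metrics(y, rep(0, 100))
  expect_equal(unname(m["accuracy"]), 50)
  expect_equal(unname(m["precision"]), 25)
  expect_equal(unname(m["recall"]), 50)
  expect_equal(round(unname(m["f1"]), 2), 33.33)
})

test_that("metrics are exact on perfect predictions and match the oracle", {
  y <- c(0, 1, 1, 0, 1)
  expect_equal(unname(classification_metrics(y, y)), rep(100, 4))
  set.seed(20)
  for (r in 1:20) {
    yt <- sample(0:1, 200, TRUE)
    yp <- sample(0:1, 200, TRUE)
    expect_equal(classification_metrics(yt, yp), metrics_oracle(yt, yp),
                 tolerance = 1e-12)
  }
  expect_error(classification_metrics(integer(0), integer(0)), "empty")
})

test_that("accuracy equals support-weighted recall and metrics stay in range", {
  set.seed(21)
  for (r in 1:25) {
    yt <- sample(0:1, 60, TRUE, prob = c(runif(1, 0.2, 0.8), 0.5))
    yp <- sample(0:1, 60, TRUE)
    m <- classification_metrics(yt, yp)
    expect_equal(unname(m["accuracy"]), unname(m["recall"]),
                 tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 100))
  }
})

test_that("taylor statistics obey the law of cosines and edge cases", {
  y <- c(0, 1, 0, 1)
  ts <- taylor_statistics(y, y)
  expect_equal(ts$pearson_r, 1)
  expect_equal(ts$centered_rmse, 0)
  expect_equal(ts$sd_model, ts$sd_reference)

  anti <- taylor_statistics(1 - y, y)
  expect_equal(anti$pearson_r, -1)

  set.seed(22)
  for (r in 1:20) {
    sc <- runif(30); la <- sample(0:1, 30, TRUE)
    if (sd(la) == 0) la[1] <- 1 - la[1]
    ts <- taylor_statistics(sc, la)
    lhs <- ts$centered_rmse^2
    rhs <- ts$sd_model^2 + ts$sd_reference^2 -
      2 * ts$sd_model * ts$sd_reference * ts$pearson_r
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
  expect_error(taylor_statistics(runif(5), rep(1, 5)), "constant")
})

make_lopo_fixture <- function() {
  cohort <- small_cohort(n_patients = 3, tw = 15, hr = 15, unlabeled = 6,
                         seed = 31)
  build_feature_batch(cohort$trajectories)
}

test_that("LOPO builds one fold per patient with strict isolation", {
  feats <- make_lopo_fixture()
  lp <- lopo_cross_validate(feats, variant = "only-mae",
                            config = small_config(), epochs = 2,
                            batch_size = 16, validation_split = 0,
                            seed = 1)
  expect_length(lp$folds, 3)
  for (f in lp$folds) {
    expect_false(f$patient %in% f$train_patients)
    expect_setequal(c(f$patient, f$train_patients),
                    unique(feats$patient))
    # every labeled point of the held-out patient appears exactly once
    expect_equal(length(f$truth),
                 sum(feats$patient == f$patient & !is.na(feats$y)))
    # metrics recomputable from stored predictions
    expect_equal(f$metrics, classification_metrics(f$truth, f$pred))
  }
  expect_equal(lp$metrics,
               colMeans(do.call(rbind, lapply(lp$folds, `[[`, "metrics"))),
               tolerance = 1e-12)
})

test_that("a patient without labeled points is skipped with a warning", {
  feats <- make_lopo_fixture()
  feats$y[feats$patient == "pat02"] <- NA_integer_
  expect_warning(
    lp <- lopo_cross_validate(feats, variant = "only-mae",
                              config = small_config(), epochs = 1,
                              batch_size = 16, validation_split = 0,
                              seed = 1),
    "no labeled points")
  expect_length(lp$folds, 2)
})

test_that("ablation runs share fold partitions and reject unknown variants", {
  feats <- make_lopo_fixture()
  ab <- run_ablation(feats, variants = c("only-mae", "baseline"),
                     config = small_config(), epochs = 2, batch_size = 16,
                     validation_split = 0, seed = 5)
  expect_equal(nrow(ab$table), 2)
  expect_identical(
    lapply(ab$runs[["only-mae"]]$folds, `[[`, "point_id"),
    lapply(ab$runs[["baseline"]]$folds, `[[`, "point_id"))
  expect_error(run_ablation(feats, variants = "fancy"), "unknown variant")
})

test_that("the baseline variant instantiates LSTM plus two dense layers only", {
  feats <- make_lopo_fixture()
  fit <- wallnet(feats, variant = "baseline", config = small_config(),
                 epochs = 0, seed = 1)
  expect_identical(fit$config$arch, "lstm")
  expect_setequal(names(fit$params),
                  c("lstm_Wx", "lstm_Wh", "lstm_b", "d1_W", "d1_b",
                    "out_W", "out_b"))
  fit2 <- wallnet(feats, variant = "proposed", config = small_config(),
                  epochs = 0, seed = 1)
  expect_true(all(c("conv1_W", "att1_W", "att3_v") %in% names(fit2$params)))
})

test_that("patient stratification splits at the cutoff and recomputes means", {
  feats <- make_lopo_fixture()
  runs <- list(
    "only-mae" = lopo_cross_validate(feats, "only-mae", small_config(),
                                     epochs = 2, batch_size = 16,
                                     validation_split = 0, seed = 2),
    "proposed" = lopo_cross_validate(feats, "proposed", small_config(),
                                     epochs = 2, batch_size = 16,
                                     validation_split = 0, seed = 2))
  # force a known stratification boundary
  runs[["only-mae"]]$folds[[1]]$metrics["accuracy"] <- 79.9
  runs[["only-mae"]]$folds[[2]]$metrics["accuracy"] <- 80.1
  runs[["only-mae"]]$folds[[3]]$metrics["accuracy"] <- 95
  st <- stratify_patients(runs, reference = "only-mae", cutoff = 80)
  expect_length(st$failed, 1)
  expect_length(st$succeeded, 2)
  # stratified means recompute from the stored per-patient metrics
  succ <- st$succeeded
  mm <- do.call(rbind,
                lapply(runs[["proposed"]]$folds[succ], `[[`, "metrics"))
  got <- st$table[st$table$variant == "proposed" &
                    st$table$stratum == "succeeded", 3:6]
  expect_equal(unname(unlist(got)), unname(colMeans(mm)), tolerance = 1e-12)

  # all patients above the cutoff: empty failed set, no error
  runs[["only-mae"]]$folds[[1]]$metrics["accuracy"] <- 99
  st2 <- stratify_patients(runs, reference = "only-mae")
  expect_length(st2$failed, 0)
})
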