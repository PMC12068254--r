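test_that("KS statistic matches the brute-force ECDF oracle", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(runif(20, 0, 1), runif(20, 2, 3))$statistic, 1)
  set.seed(40)
  for (r in 1:25) {
    a <- rnorm(50); b <- rnorm(70, mean = runif(1, 0, 1))
    expect_equal(ks_two_sample(a, b)$statistic, ks_stat_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(ks_two_sample(numeric(0), 1:5), "at least 2")
})

test_that("KS statistic is invariant under strictly monotone transforms", {
  set.seed(41)
  a <- rexp(40); b <- rexp(60, rate = 2)
  d0 <- ks_two_sample(a, b)$statistic
  expect_equal(ks_two_sample(log(a), log(b))$statistic, d0)
  expect_equal(ks_two_sample(a^3, b^3)$statistic, d0)
})

test_that("Levene test detects unequal variances and is null-calibrated", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  out <- levene_test(g)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)

  set.seed(42)
  out2 <- levene_test(list(rnorm(200, sd = 1), rnorm(200, sd = 10)))
  expect_lt(out2$p, 0.001)

  expect_error(levene_test(list(1:3)), ">= 2 groups")
  expect_error(levene_test(list(1:3, 2)), "at least 2 values")
})

test_that("Levene W agrees with the reference implementation", {
  skip_if_not_installed("car")
  set.seed(43)
  for (r in 1:10) {
    groups <- lapply(1:3, function(i) rnorm(30, sd = runif(1, 0.5, 3)))
    mine <- levene_test(groups)
    df <- data.frame(y = unlist(groups),
                     g = factor(rep(1:3, each = 30)))
    ref <- car::leveneTest(y ~ g, data = df, center = mean)
    expect_equal(mine$statistic, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("DTW distance matches exhaustive path enumeration", {
  expect_equal(dtw_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dtw_distance(c(0, 0, 0), c(1, 1, 1)), 3)
  set.seed(44)
  for (r in 1:40) {
    a <- round(runif(sample(2:8, 1), 0, 5), 2)
    b <- round(runif(sample(2:8, 1), 0, 5), 2)
    expect_equal(dtw_distance(a, b), dtw_enum_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_gte(dtw_distance(a, b), 0)
  }
  expect_error(dtw_distance(numeric(0), 1:3), "non-empty")
})

test_that("1-D Wasserstein matches the exact ECDF-integral oracle", {
  set.seed(45)
  a <- rnorm(30)
  expect_equal(wasserstein_1d(a, a), 0)
  expect_equal(wasserstein_1d(a, a + 0.7), 0.7, tolerance = 1e-12)
  for (r in 1:25) {
    a <- rnorm(sample(10:60, 1)); b <- rnorm(sample(10:60, 1), mean = 1)
    expect_equal(wasserstein_1d(a, b), wasserstein_ecdf_oracle(a, b),
                 tolerance = 1e-6)
  }
  # scale equivariance
  a <- rnorm(20); b <- rnorm(25)
  expect_equal(wasserstein_1d(3 * a, 3 * b), 3 * wasserstein_1d(a, b),
               tolerance = 1e-12)
  expect_error(wasserstein_1d(numeric(0), 1), "non-empty")
})

test_that("the heterogeneity report separates hard from easy patients", {
  cohort <- small_cohort(n_patients = 8, tw = 25, hr = 25, unlabeled = 0,
                         separability = 1, hard_fraction = 0.25, seed = 51)
  feats <- build_feature_batch(cohort$trajectories)
  rep <- patient_heterogeneity_report(feats)
  expect_equal(nrow(rep$per_patient), 8)
  ks_cols <- grep("^ks_", names(rep$per_patient), value = TRUE)
  expect_true(all(as.matrix(rep$per_patient[, ks_cols]) >= 0 &
                    as.matrix(rep$per_patient[, ks_cols]) <= 1))
  expect_true(all(rep$per_patient$dtw_speed >= 0))
  expect_true(all(rep$per_patient$wasserstein_speed >= 0))

  hard <- vapply(cohort$manifest$patients, function(p) p$hard, logical(1))
  hard_ids <- vapply(cohort$manifest$patients, function(p) p$id,
                     character(1))[hard]
  mean_ks <- rowMeans(as.matrix(rep$per_patient[, ks_cols]))
  expect_lt(mean(mean_ks[rep$per_patient$patient %in% hard_ids]),
            mean(mean_ks[!rep$per_patient$patient %in% hard_ids]))
})

test_that("stratified group tests and boxplot export are produced", {
  cohort <- small_cohort(n_patients = 6, tw = 20, hr = 20, unlabeled = 0,
                         separability = 1, hard_fraction = 1 / 3, seed = 52)
  feats <- build_feature_batch(cohort$trajectories)
  rep <- patient_heterogeneity_report(feats,
                                      stratification = c("pat01", "pat02"))
  expect_false(is.null(rep$group_tests))
  expect_true(rep$group_tests$ks$statistic >= 0 &&
                rep$group_tests$ks$statistic <= 1)
  expect_true(rep$group_tests$levene$p >= 0 && rep$group_tests$levene$p <= 1)
  expect_identical(sort(unique(rep$boxplot_data$channel)),
                   sort(feature_channels()))
  expect_equal(nrow(rep$boxplot_data), 6 * 5)

  # determinism: recomputation is identical
  rep2 <- patient_heterogeneity_report(feats,
                                       stratification = c("pat01", "pat02"))
  expect_identical(rep$per_patient, rep2$per_patient)
})

test_that("patients missing a labeled class are excluded with a warning", {
  cohort <- small_cohort(n_patients = 2, tw = 10, hr = 10, unlabeled = 0,
                         seed = 53)
  feats <- build_feature_batch(cohort$trajectories)
  feats$y[feats$patient == "pat02" & feats$y == 1] <- 0L
  expect_warning(rep <- patient_heterogeneity_report(feats),
                 "lacks a labeled class")
  expect_equal(nrow(rep$per_patient), 1)
})
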