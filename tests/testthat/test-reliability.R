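# small handmade feature matrix: `values` is participants x tasks for one
# feature; replicated with noise for extra features when k > 1
toy_matrix <- function(values, feature = "word_count", group = NULL) {
  n <- nrow(values)
  pid <- sprintf("p%02d", seq_len(n))
  grp <- group %||% rep("intact", n)
  purrr::map_dfr(seq_along(speech_tasks()), function(t) {
    tibble::tibble(
      participant_id = pid,
      task_id = speech_tasks()[t],
      feature_name = feature,
      value = values[, t],
      group = grp
    )
  })
}

test_that("z-scoring hits the closed form and is idempotent", {
  vals <- matrix(rep(c(2, 4, 6), 5), nrow = 3)
  z <- zscore_features(toy_matrix(vals))
  expect_equal(sort(z$value[z$task_id == "ET1"]), c(-1, 0, 1))

  z2 <- zscore_features(z)
  expect_equal(z2$value, z$value, tolerance = 1e-12)
})

test_that("every stratum of a z-scored random matrix has mean 0 and sample SD 1", {
  fm <- generate_feature_matrix(cohort_spec(n_mci = 5, n_intact = 8, seed = 21))
  z <- zscore_features(fm)
  strata <- z |>
    dplyr::group_by(feature_name, task_id, group) |>
    dplyr::summarise(m = mean(value), s = sd(value), .groups = "drop")
  expect_true(all(abs(strata$m) < 1e-10))
  expect_true(all(abs(strata$s - 1) < 1e-10))
})

test_that("constant strata are rejected with a named error", {
  vals <- matrix(rep(c(2, 4, 6), 5), nrow = 3)
  fm <- toy_matrix(vals)
  fm$value[fm$task_id == "PDT2"] <- 7
  expect_error(
    zscore_features(fm),
    "constant or singleton stratum.*word_count.*PDT2"
  )
})

test_that("Fisher machinery round-trips and averages identical r exactly", {
  r <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(fisher_z_inverse(fisher_z(r)), r, tolerance = 1e-12)
  for (v in c(-0.7, 0, 0.3, 0.95)) {
    expect_equal(fisher_average(rep(v, 3)), v, tolerance = 1e-15)
  }
  # worked pair: atanh(0.2) = 0.2027, atanh(0.6) = 0.6931
  expect_equal(fisher_average(c(0.2, 0.6)), tanh((atanh(0.2) + atanh(0.6)) / 2))
  expect_equal(fisher_average(c(0.2, 0.6)), 0.4202, tolerance = 1e-4)
})

test_that("identical values across tasks give perfect reliability", {
  vals <- matrix(c(1, 3, 7, 2), nrow = 4, ncol = 5)
  est <- within_feature_reliability(toy_matrix(vals), "picture")
  expect_equal(est$r_mean, 1)
  expect_equal(est$n_pairs, 3)
  est_e <- within_feature_reliability(toy_matrix(vals), "expository")
  expect_equal(est_e$r_mean, 1)
  expect_equal(est_e$n_pairs, 1)
})

test_that("picture reliability is the Fisher average of the three pairwise r", {
  set.seed(99)
  vals <- matrix(rnorm(8 * 5), nrow = 8)
  fm <- toy_matrix(vals)
  est <- within_feature_reliability(fm, "picture")
  manual <- fisher_average(c(
    cor(vals[, 3], vals[, 4]),
    cor(vals[, 3], vals[, 5]),
    cor(vals[, 4], vals[, 5])
  ))
  expect_equal(est$r_mean, manual, tolerance = 1e-12)
})

test_that("correlations computed on z-scores equal those on raw values", {
  # z-scoring is affine within each stratum, so correlations are unchanged
  # whenever the correlation is computed over exactly one stratum's
  # participants: group-stratified z for the group analyses, unstratified z
  # for the full sample
  fm <- generate_feature_matrix(cohort_spec(n_mci = 6, n_intact = 10, seed = 8))
  z_grp <- zscore_features(fm, stratify_by_group = TRUE)
  z_all <- zscore_features(fm, stratify_by_group = FALSE)
  for (tt in c("expository", "picture")) {
    for (g in c("MCI", "intact")) {
      raw_r <- within_feature_reliability(fm, tt, g)$r_mean
      z_r <- within_feature_reliability(z_grp, tt, g)$r_mean
      expect_equal(z_r, raw_r, tolerance = 1e-10)
    }
    expect_equal(
      within_feature_reliability(z_all, tt, "full")$r_mean,
      within_feature_reliability(fm, tt, "full")$r_mean,
      tolerance = 1e-10
    )
  }
})

test_that("zero-variance features make the correlation an error", {
  vals <- matrix(rnorm(20), nrow = 4)
  fm <- toy_matrix(vals)
  fm$value[fm$task_id == "ET1"] <- 5
  expect_error(
    within_feature_reliability(fm, "expository"),
    class = "speechlex_stat_error"
  )
})

test_that("random derangements never map a participant to themself", {
  set.seed(5)
  for (n in c(4, 7, 29)) {
    for (i in 1:50) {
      p <- speechlex:::random_derangement(n)
      expect_true(all(p != seq_len(n)))
      expect_equal(sort(p), seq_len(n))
    }
  }
})

test_that("resampling nulls are reproducible and centred near zero", {
  fm <- generate_feature_matrix(cohort_spec(n_mci = 8, n_intact = 21, seed = 4))
  nul1 <- resample_null(fm, "picture", "full", reps = 2000, seed = 10)
  nul2 <- resample_null(fm, "picture", "full", reps = 2000, seed = 10)
  expect_identical(nul1$null, nul2$null)
  expect_lt(abs(nul1$null_mean), 0.03)
  expect_gt(nul1$p_value, 0)
  expect_lte(nul1$p_value, 1)

  nul3 <- resample_null(fm, "picture", "full", reps = 2000, seed = 11)
  expect_false(identical(nul1$null, nul3$null))

  expect_error(resample_null(fm, "picture", "full", reps = 500), "seed")
  expect_warning(
    resample_null(fm, "picture", "full", reps = 50, seed = 1),
    "Fewer than 100"
  )
})

test_that("group comparison reproduces the pooled t-test design", {
  r <- seq(0.1, 0.85, length.out = 16)
  cmp0 <- compare_groups(r, r)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)
  expect_equal(cmp0$df, 30)

  set.seed(12)
  z1 <- rnorm(16, 0.8, 0.1)
  z2 <- rnorm(16, 0.3, 0.1)
  cmp <- compare_groups(tanh(z1), tanh(z2))
  expect_equal(cmp$df, 30)
  expect_lt(cmp$p_value, 0.001)
  # agrees with stats::t.test on the Fisher-z scale
  tt <- t.test(z1, z2, var.equal = TRUE)
  expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(cmp$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(cmp$ci_low, tanh(tt$conf.int[1]), tolerance = 1e-10)
  expect_equal(cmp$ci_high, tanh(tt$conf.int[2]), tolerance = 1e-10)

  expect_error(compare_groups(r, r[-1]), "one mean correlation per feature")

  td <- tidy(cmp)
  expect_equal(td$statistic, cmp$t)
  expect_equal(td$df, 30)
})

test_that("intraindividual variability matches hand-computed SDs", {
  # constant z-scores across tasks -> itv 0
  vals0 <- matrix(c(1, -1, 0.5, -0.5), nrow = 4, ncol = 5)
  itv0 <- intraindividual_variability(toy_matrix(vals0))
  expect_equal(itv0$itv, 0)

  # participant z = (1,-1,1,-1,1): sample SD = sqrt(1.2)
  vals1 <- rbind(
    c(1, -1, 1, -1, 1),
    c(0, 0, 0, 0, 0)
  )
  itv1 <- intraindividual_variability(toy_matrix(vals1))
  expect_equal(itv1$itv, (sqrt(1.2) + 0) / 2, tolerance = 1e-12)
  expect_equal(round(sqrt(1.2), 4), 1.0954)

  # group of two with per-person SDs 0.5 and 1.5 -> mean 1.0
  x1 <- c(-0.5, 0, 0.5) * 0.5 / sd(c(-0.5, 0, 0.5))
  vals2 <- rbind(
    c(x1, 0, 0) + 10,
    3 * c(x1, 0, 0)
  )
  sds <- apply(vals2, 1, sd)
  vals2[1, ] <- (vals2[1, ] - mean(vals2[1, ])) / sds[1] * 0.5 + 1
  vals2[2, ] <- (vals2[2, ] - mean(vals2[2, ])) / sds[2] * 1.5
  itv2 <- intraindividual_variability(toy_matrix(vals2))
  expect_equal(itv2$itv, 1, tolerance = 1e-12)
})

test_that("the pooled-variance ITV mode implements the squared-SD/N form", {
  set.seed(42)
  vals <- matrix(rnorm(6 * 5), nrow = 6)
  fm <- toy_matrix(vals)
  itv <- intraindividual_variability(fm, mode = "variance_pooled")
  manual <- sum(apply(vals, 2, sd)^2) / 6
  expect_equal(itv$itv, manual, tolerance = 1e-12)
})

test_that("missing task values are an error for ITV", {
  vals <- matrix(rnorm(4 * 5), nrow = 4)
  fm <- toy_matrix(vals)
  expect_error(
    intraindividual_variability(fm[-1, ]),
    "missing task values"
  )
})

test_that("higher generative reliability lowers intraindividual variability", {
  itv_at <- function(rho) {
    fm <- generate_feature_matrix(cohort_spec(
      n_mci = 40, n_intact = 60, n_features = 8, rho = rho, seed = 100
    ))
    z <- zscore_features(fm, stratify_by_group = FALSE)
    mean(intraindividual_variability(z, by_group = FALSE)$itv)
  }
  v <- vapply(c(0.2, 0.5, 0.8), itv_at, numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("reliability_analysis assembles estimates, nulls, and comparisons", {
  fm <- generate_feature_matrix(cohort_spec(n_mci = 6, n_intact = 10, seed = 13))
  rel <- reliability_analysis(fm, reps = 300, seed = 2)
  expect_s3_class(rel, "speech_reliability")
  expect_equal(nrow(rel$estimates), 16 * 2 * 3) # features x task types x groups
  expect_equal(nrow(rel$grand), 6)
  expect_equal(nrow(rel$comparisons), 2)
  expect_true(all(rel$comparisons$df == 30))
  expect_equal(nrow(tidy(rel)), 96)
  expect_equal(nrow(glance(rel)), 6)
  # deterministic under the same seed
  rel2 <- reliability_analysis(fm, reps = 300, seed = 2)
  expect_identical(rel$estimates, rel2$estimates)
})
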