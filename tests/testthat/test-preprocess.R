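raw_mat <- function(v, nr, nc) {
  intensity_matrix(matrix(v, nr, nc,
                          dimnames = list(paste0("P", seq_len(nr)),
                                          paste0("s", seq_len(nc)))),
                   "raw")
}

test_that("quantile normalization maps samples onto the per-rank mean distribution", {
  m <- raw_mat(c(1, 2, 3, 4, 5, 6), 3, 2)
  qn <- quantile_normalize(m, log2_transform = FALSE)
  expect_equal(unname(as.matrix(qn)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(qn)[, 2]), c(2.5, 3.5, 4.5))

  # identical columns: output equals log2 of the input
  m2 <- raw_mat(c(5, 1, 9, 5, 1, 9), 3, 2)
  qn2 <- quantile_normalize(m2, offset = 0)
  expect_equal(as.matrix(qn2), log2(as.matrix(m2)))

  expect_error(quantile_normalize(raw_mat(1:3, 3, 1)), ">= 2 samples")
})

test_that("quantile normalization matches the brute-force rank-mean oracle, including ties", {
  set.seed(5)
  for (rep in 1:10) {
    v <- matrix(round(rlnorm(60, 5, 1), 2), 12, 5)
    dimnames(v) <- list(paste0("P", 1:12), paste0("s", 1:5))
    qn <- quantile_normalize(intensity_matrix(v, "raw"),
                             log2_transform = FALSE)
    expect_equal(unname(as.matrix(qn)), unname(brute_quantile_normalize(v)),
                 tolerance = 1e-10)
  }
  # all-equal column: every cell gets the mean reference value at its ranks
  v <- cbind(s1 = c(7, 7, 7), s2 = c(1, 2, 3))
  rownames(v) <- paste0("P", 1:3)
  qn <- quantile_normalize(intensity_matrix(v, "raw"), log2_transform = FALSE)
  expect_equal(unname(as.matrix(qn)), unname(brute_quantile_normalize(v)))
  expect_equal(unname(as.matrix(qn)[, 1]), rep(mean(c(4, 4.5, 5)), 3))
})

test_that("after quantile normalization every sample has the same sorted vector and keeps its rank order", {
  set.seed(6)
  v <- matrix(rlnorm(200, 8, 1.5), 40, 5,
              dimnames = list(paste0("P", 1:40), paste0("s", 1:5)))
  qn <- quantile_normalize(intensity_matrix(v, "raw"))
  s <- apply(unclass(qn), 2, sort)
  for (j in 2:5) expect_equal(s[, j], s[, 1])
  for (j in 1:5) expect_equal(order(unclass(qn)[, j]), order(v[, j]))
})

test_that("scaling-factor normalization equalizes totals and preserves within-sample ratios", {
  m <- raw_mat(c(40, 60, 100, 200, 10, 10), 2, 3)  # totals 100, 300, 20
  sf <- scaling_factor_normalize(m, log2_transform = FALSE)
  f <- attr(sf, "scaling_factors")
  expect_equal(unname(f), c(1, 1 / 3, 5))
  totals <- colSums(unclass(sf))
  expect_equal(totals, setNames(rep(100, 3), colnames(m)))
  expect_equal(unclass(sf)[1, ] / unclass(sf)[2, ],
               unclass(m)[1, ] / unclass(m)[2, ])

  m2 <- raw_mat(rep(5, 6), 2, 3)
  expect_equal(unname(attr(scaling_factor_normalize(m2), "scaling_factors")),
               rep(1, 3))
  m3 <- raw_mat(c(1, 1, 0, 0), 2, 2)
  expect_error(scaling_factor_normalize(m3), "zero total")
})

test_that("sequential imputation leaves observed cells alone and matches a regression oracle", {
  # complete matrix: identity, empty mask
  set.seed(8)
  v <- matrix(rnorm(40, 20, 1), 10, 4,
              dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  nm <- impute_sequential(v)
  expect_equal(as.matrix(nm), v)
  expect_false(any(attr(nm, "imputed_mask")))

  # strongly correlated samples: conditional mean equals the OLS prediction
  # from complete rows (independent route: lm on the observed columns)
  t <- rnorm(30, 20, 2)
  v2 <- cbind(s1 = t + rnorm(30, 0, 0.05),
              s2 = t + rnorm(30, 0, 0.05),
              s3 = t + rnorm(30, 0, 0.05))
  rownames(v2) <- paste0("P", 1:30)
  truth <- v2[30, "s3"]
  v2[30, "s3"] <- NA
  imp <- impute_sequential(v2)
  fit <- lm(s3 ~ s1 + s2, data = as.data.frame(v2[1:29, ]))
  pred <- predict(fit, as.data.frame(t(v2[30, 1:2])))
  expect_equal(unclass(imp)[30, "s3"], unname(pred), tolerance = 1e-4)
  expect_equal(unclass(imp)[30, "s3"], truth, tolerance = 0.2)
  expect_equal(unclass(imp)[-30, ], v2[-30, ])
  expect_equal(sum(attr(imp, "imputed_mask")), 1L)

  # a protein constant across the other samples imputes to that constant
  v3 <- rbind(v2[1:29, ], P30 = c(24, 24, NA))
  imp3 <- impute_sequential(v3)
  expect_equal(unclass(imp3)["P30", "s3"], 24, tolerance = 0.15)

  expect_error(impute_sequential(matrix(c(NA, 1, 1, NA), 2, 2,
                                        dimnames = list(c("a", "b"), c("x", "y")))),
               "complete rows")
})

test_that("imputation error under planted MCAR missingness stays below the residual SD", {
  exp <- generate_secretome_experiment(n_proteins = 300, n_pairs = 6,
                                       missing_rate = 0.01, noise_sd = 0.4,
                                       seed = 31)
  truth <- log2(exp$truth$secretome_true)
  imp <- impute_sequential(log2(unclass(exp$secretome)))
  mask <- is.na(unclass(exp$secretome))
  expect_equal(sum(attr(imp, "imputed_mask")), sum(mask))
  err <- abs(unclass(imp)[mask] - truth[mask])
  expect_lt(median(err), 0.4)
})

test_that("BH q-values from the pipeline match the brute-force step-up procedure", {
  set.seed(9)
  for (rep in 1:20) {
    p <- runif(sample(5:100, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("differential expression is calibrated under the null and powered for large planted effects", {
  set.seed(10)
  n <- 400
  v <- matrix(rnorm(n * 6, 20, 0.5), n, 6,
              dimnames = list(paste0("P", 1:n), paste0("s", 1:6)))
  meta <- sample_metadata(paste0("s", 1:6),
                          condition = rep(c("a", "b"), each = 3),
                          compartment = "lysate")
  de <- differential_expression(
    structure(v, scale = "log2_normalized"), meta, c("a", "b"))
  expect_lte(sum(de$q_value < 0.05, na.rm = TRUE), 2)

  v2 <- matrix(rnorm(100 * 6, 20, 0.3), 100, 6,
               dimnames = list(paste0("P", 1:100), paste0("s", 1:6)))
  v2[, 1:3] <- v2[, 1:3] + 3          # planted log2 FC of 3, SD 0.3
  de2 <- differential_expression(
    structure(v2, scale = "log2_normalized"), meta, c("a", "b"))
  expect_gte(sum(de2$q_value < 0.05, na.rm = TRUE), 95)
  expect_gt(median(de2$log2fc), 2.5)

  expect_error(differential_expression(
    structure(v, scale = "log2_normalized"), meta, c("a", "zzz")),
    "absent from metadata")
})

test_that("the plex block term absorbs batch offsets", {
  set.seed(12)
  n <- 150
  plex <- rep(c("x", "y"), 3)
  batch <- ifelse(plex == "x", 0, 4)
  v <- matrix(rnorm(n * 6, 20, 0.3), n, 6, byrow = FALSE,
              dimnames = list(paste0("P", 1:n), paste0("s", 1:6)))
  v <- sweep(v, 2, batch, `+`)
  meta <- sample_metadata(paste0("s", 1:6),
                          condition = rep(c("a", "b"), each = 3),
                          compartment = "lysate", plex = plex)
  de <- differential_expression(
    structure(v, scale = "log2_normalized"), meta, c("a", "b"))
  # batches are balanced across conditions; with the block term no protein
  # should look differential
  expect_lte(sum(de$q_value < 0.05, na.rm = TRUE), 1)
})

test_that("family-corrected alpha follows the Bonferroni division", {
  expect_equal(corrected_alpha(0.05, 9000), 0.05 / 9000)
  expect_equal(round(corrected_alpha(0.05, 9000), 7), 5.6e-6)
  expect_equal(corrected_alpha(0.05, 1), 0.05)
  expect_equal(corrected_alpha(0.05, 5), 0.01)
  expect_error(corrected_alpha(0.05, 0), ">= 1")
})

test_that("two-sample t sample sizes match the closed-form power oracle", {
  # standard benchmark point
  expect_equal(sample_size_two_sample_t(0.5, 0.05, 0.8), 64)
  oracle <- ceiling(power.t.test(delta = 0.5, sd = 1, sig.level = 0.05,
                                 power = 0.8)$n)
  expect_equal(sample_size_two_sample_t(0.5, 0.05, 0.8), oracle)

  expect_equal(sample_size_two_sample_t(50, 0.05, 0.8), 2)  # floor

  n_design <- sample_size_two_sample_t(2.93, 5.6e-6, 0.8)
  oracle2 <- ceiling(power.t.test(delta = 2.93, sd = 1, sig.level = 5.6e-6,
                                  power = 0.8)$n)
  expect_lte(abs(n_design - oracle2), 1)  # oracle uses a continuous n
  expect_lte(n_design, 12)                # the study size includes margin

  expect_error(sample_size_two_sample_t(0, 0.05, 0.8), "non-zero")
})
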