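test_that("ICC(A,1) matches the aov mean-squares oracle to 1e-10", {
  fixtures <- list(
    list(a = c(9, 6, 8, 7, 10, 6), b = c(2, 1, 4, 1, 5, 2)),
    list(a = c(1.1, 2.3, 3.1, 4.2, 5.3), b = c(1.0, 2.5, 3.0, 4.4, 5.0)),
    list(a = rnorm(30), b = rnorm(30)))
  set.seed(55)
  fixtures[[3]] <- within(list(), {
    subj <- rnorm(30, 0, 2); a <- subj + rnorm(30); b <- subj + 0.5 + rnorm(30)
  })
  for (f in fixtures) {
    got <- icc_absolute(f$a, f$b)
    expect_equal(got$icc, icc_a1_aov(f$a, f$b), tolerance = 1e-10)
  }
})

test_that("duplicated data give ICC = 1; independent noise gives ICC near 0", {
  x <- c(3, 7, 1, 9, 4, 6)
  got <- icc_absolute(x, x)
  expect_equal(got$icc, 1)
  set.seed(56)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(icc_absolute(a, b)$icc), 0.1)
})

test_that("adding noise decreases the expected ICC (Monte-Carlo trend)", {
  set.seed(57)
  iccs <- vapply(c(0.2, 1, 3), function(noise_sd) {
    mean(vapply(1:20, function(i) {
      subj <- rnorm(25, 0, 1)
      icc_absolute(subj + rnorm(25, 0, noise_sd),
                   subj + rnorm(25, 0, noise_sd))$icc
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("zero-variance input flags ICC undefined", {
  expect_warning(out <- icc_absolute(rep(2, 5), rep(2, 5)), "zero total")
  expect_true(is.na(out$icc))
})

test_that("ICC categories reproduce the published thresholds", {
  expect_equal(icc_category(0.39), "poor")
  expect_equal(icc_category(0.40), "fair")
  expect_equal(icc_category(0.59), "fair")
  expect_equal(icc_category(0.60), "good")
  expect_equal(icc_category(0.74), "good")
  expect_equal(icc_category(0.75), "excellent")
  expect_equal(icc_category(0.95), "excellent")
})

test_that("Bland-Altman bias, limits and sign convention are exact", {
  # identical measurements
  x <- c(1, 2, 3)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  expect_true(all(ba0$points$diff == 0))
  # d = {+1, -1}: bias 0, LoA = +/- 1.96 sqrt(2)
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96 * sqrt(2), 1.96 * sqrt(2)), tolerance = 1e-12)
  # sign: a larger than b gives positive bias
  expect_equal(bland_altman(c(2, 3), c(1, 2))$bias, 1)
  # LoA interval contains the bias; width = 2 * 1.96 * sd(d)
  set.seed(58)
  a <- rnorm(20); b <- rnorm(20)
  bb <- bland_altman(a, b)
  expect_gte(bb$bias, bb$loa[1]); expect_lte(bb$bias, bb$loa[2])
  expect_equal(diff(bb$loa), 2 * 1.96 * sd(a - b), tolerance = 1e-12)
})

test_that("Pearson r and r2 match the covariance formula", {
  expect_equal(pearson_agreement(1:5, 1:5)$r, 1)
  expect_equal(pearson_agreement(1:5, -(1:5))$r, -1)
  set.seed(59)
  a <- rnorm(40); b <- 0.3 * a + rnorm(40)
  got <- pearson_agreement(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, oracle, tolerance = 1e-12)
  expect_equal(got$r2, oracle^2, tolerance = 1e-12)
  expect_error(pearson_agreement(rep(1, 5), 1:5), "zero variance")
})

test_that("CV%RMS combines per-subject two-point CVs quadratically", {
  expect_equal(cv_rms(c(1, 2), c(1, 2)), 0)
  # construct subjects with CVs of exactly 3% and 4%
  # two-point CV = |a-b|/sqrt(2)/mean*100
  a <- c(100 + 3 * sqrt(2) / 2, 100 + 4 * sqrt(2) / 2)
  b <- c(100 - 3 * sqrt(2) / 2, 100 - 4 * sqrt(2) / 2)
  expect_equal(cv_rms(a, b), sqrt((9 + 16) / 2), tolerance = 1e-6)
  # scale invariance
  expect_equal(cv_rms(10 * a, 10 * b), cv_rms(a, b), tolerance = 1e-12)
  expect_warning(cv_rms(c(1, 1), c(-1, 1)), "zero pair mean")
})

test_that("statistics are invariant to subject ordering", {
  set.seed(60)
  a <- rnorm(15, 10); b <- a + rnorm(15, 0, 0.5)
  perm <- sample(15)
  expect_equal(icc_absolute(a, b)$icc, icc_absolute(a[perm], b[perm])$icc,
               tolerance = 1e-12)
  expect_equal(bland_altman(a, b)$bias, bland_altman(a[perm], b[perm])$bias,
               tolerance = 1e-12)
  expect_equal(cv_rms(a, b), cv_rms(a[perm], b[perm]), tolerance = 1e-12)
})

test_that("per-scale correlations mirror pearson per column and handle NAs", {
  set.seed(61)
  ref <- rnorm(12, 20, 5)
  ent <- cbind(ref, ref + rnorm(12, 0, 3), rnorm(12))
  out <- scale_correlations(ent, ref)
  expect_equal(nrow(out), 3)
  expect_equal(out$r[1], 1, tolerance = 1e-12)
  expect_equal(out$r[2], pearson_agreement(ent[, 2], ref)$r,
               tolerance = 1e-12)
  # missing values excluded pairwise
  ent[1:3, 3] <- NA
  out2 <- scale_correlations(ent, ref)
  expect_equal(out2$r[3], cor(ent[4:12, 3], ref[4:12]), tolerance = 1e-12)
})
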