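test_that("epoch splitting discards the remainder and warns on short input", {
  x <- scalar_series(rnorm(180 * 400), 400, "resultant_acc_g")
  ep <- split_epochs(x)
  expect_length(ep$epochs, 3)
  expect_true(all(lengths(ep$epochs) == 24000))
  # 150 s -> 2 epochs, 30 s discarded
  ep2 <- split_epochs(scalar_series(rnorm(150 * 400), 400, "resultant_acc_g"))
  expect_length(ep2$epochs, 2)
  expect_warning(
    ep0 <- split_epochs(scalar_series(rnorm(59 * 400), 400, "resultant_acc_g")),
    "shorter")
  expect_length(ep0$epochs, 0)
})

test_that("coarse-graining computes offset block means", {
  x <- 1:6
  expect_equal(coarse_grain(x, 1), 1:6)
  expect_equal(coarse_grain(x, 2, 1), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(x, 2, 2), c(2.5, 4.5))
  expect_error(coarse_grain(x, 2, 3), "offset")
})

test_that("constant epochs give zero sample entropy at every scale", {
  v <- rcme(rep(1, 500), taus = c(1, 2, 5, 10), r = 0.1)$values
  expect_equal(v, rep(0, 4))
})

test_that("RCME at tau = 1 equals the brute-force sample entropy to 1e-10", {
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(500)
    r <- 0.3 * sd(x)
    expect_equal(rcme(x, taus = 1)$values,
                 brute_sampen(x, 4, r), tolerance = 1e-10)
    expect_equal(sample_entropy(x, 4, r), brute_sampen(x, 4, r),
                 tolerance = 1e-10)
  }
})

test_that("RCME at tau = 3 equals a brute-force composite implementation", {
  set.seed(41)
  x <- as.numeric(arima.sim(list(ar = 0.7), 400))
  r <- 0.3 * sd(x)
  expect_equal(rcme(x, taus = 3)$values,
               brute_composite_sampen(x, 4, r, 3), tolerance = 1e-10)
})

test_that("RCME is invariant to affine transforms of the epoch", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.5), 2000))
  v1 <- rcme(x, taus = c(1, 4, 9))$values
  v2 <- rcme(5.5 * x - 3.2, taus = c(1, 4, 9))$values
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("RMPE matches the ordinal-pattern oracle and is monotone invariant", {
  set.seed(43)
  x <- rnorm(1500)
  # tau = 1: single offset, directly comparable to the string-pattern oracle
  expect_equal(rmpe(x, taus = 1)$values, brute_perm_entropy(x, 4),
               tolerance = 1e-12)
  # strictly monotone amplitude transform leaves tau = 1 unchanged exactly
  # (at tau > 1 block means do not commute with nonlinear transforms)
  expect_equal(rmpe(x, taus = 1)$values, rmpe(exp(x), taus = 1)$values,
               tolerance = 1e-12)
  # linear monotone transforms are exact at every scale
  expect_equal(rmpe(x, taus = c(1, 3, 7))$values,
               rmpe(3 * x + 1, taus = c(1, 3, 7))$values, tolerance = 1e-12)
  # degenerate cases
  expect_equal(rmpe(1:100, taus = 1)$values, 0)        # one pattern only
  expect_equal(rmpe(c(4, 1, 3, 2), taus = 1)$values, 0)
})

test_that("iid noise approaches the analytic limits at moderate length", {
  set.seed(44)
  x <- rnorm(4000)
  expect_equal(rcme(x, taus = 1)$values,
               -log(2 * pnorm(0.3 / sqrt(2)) - 1), tolerance = 0.12)
  expect_equal(rmpe(x, taus = 1)$values, log(24), tolerance = 0.05)
})

test_that("entropy profiles of white noise decrease with scale", {
  # RCME: coarse-graining shrinks variance against the fixed tolerance, so
  # the decrease holds per seed; RMPE of iid data stays near ln(4!) with a
  # small finite-sample downward drift, so the trend is tested on the mean
  vs <- matrix(0, 5, 3); ws <- matrix(0, 5, 3)
  for (s in 1:5) {
    set.seed(s)
    x <- rnorm(4000)
    vs[s, ] <- rcme(x, taus = c(1, 5, 20))$values
    ws[s, ] <- rmpe(x, taus = c(1, 5, 20))$values
  }
  expect_true(all(t(apply(vs, 1, diff)) < 0))
  expect_true(all(diff(colMeans(ws)) < 0))
})

test_that("session entropy averages per-scale across epochs with NA propagation", {
  ep <- structure(list(epochs = list(rnorm(800), rnorm(800)),
                       sample_rate = 400), class = "epoch_set")
  taus <- c(1, 2, 4)
  pr <- session_entropy(ep, "RMPE", taus = taus)
  v1 <- rmpe(ep$epochs[[1]], taus = taus)$values
  v2 <- rmpe(ep$epochs[[2]], taus = taus)$values
  expect_equal(pr$values, (v1 + v2) / 2, tolerance = 1e-12)
  expect_equal(pr$n_epochs_averaged, 2L)
  # single epoch -> identical to its own profile
  ep1 <- structure(list(epochs = ep$epochs[1], sample_rate = 400),
                   class = "epoch_set")
  expect_equal(session_entropy(ep1, "RMPE", taus = taus)$values, v1)
  # no epochs -> empty profile
  ep0 <- structure(list(epochs = list(), sample_rate = 400),
                   class = "epoch_set")
  expect_length(session_entropy(ep0, "RCME")$values, 0)
})

test_that("undefined scales are NA, not infinities", {
  # 60 samples cannot support tau = 20 with m = 4 templates
  v <- rcme(rnorm(60), taus = c(1, 20), r = 1e-12)$values
  expect_true(is.na(v[2]))
  expect_false(any(is.infinite(v), na.rm = TRUE))
})
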