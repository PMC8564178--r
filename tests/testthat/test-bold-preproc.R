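test_that("initial-frame discard truncates data and motion in lockstep", {
  b <- random_bold(c(3, 3, 3), nt = 130)
  out <- discard_initial(b, 10)
  expect_identical(dim(out$data)[4], 120L)
  expect_identical(nrow(out$motion_params), 120L)
  expect_equal(out$data[, , , 1], b$data[, , , 11])
  expect_equal(out$motion_params[1, ], b$motion_params[11, ])
  expect_identical(discard_initial(b, 0), b)
  expect_error(discard_initial(random_bold(nt = 25), 10),
               class = "nc_validation_error")
})

test_that("nuisance regression equals the textbook hat-matrix residual", {
  set.seed(3)
  nt <- 60
  mp <- matrix(rnorm(nt * 6, sd = 0.1), nt)
  wm <- rnorm(nt); csf <- rnorm(nt)
  nuis <- nuisance_set(TRUE, wm, csf, mp)
  b <- random_bold(c(4, 4, 2), nt = nt, seed = 8)
  out <- regress_nuisance(b, nuis)
  # explicit (I - H) y oracle
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2, wm, csf, mp)
  H <- X %*% solve(crossprod(X), t(X))
  Y <- t(matrix(b$data, ncol = nt))
  expect_equal(t((diag(nt) - H) %*% Y), matrix(out$data, ncol = nt),
               tolerance = 1e-10)
  # residuals orthogonal to every regressor
  R <- t(matrix(out$data, ncol = nt))
  expect_lt(max(abs(cor(R, X[, -1]))), 1e-10)
  # a series equal to the trend is annihilated
  tr_series <- array(rep(seq_len(nt), each = 2), c(1, 1, 2, nt))
  bt <- bold_series(tr_series, 2)
  expect_lt(max(abs(regress_nuisance(bt, nuisance_set(TRUE))$data)), 1e-9)
  # intercept-only regression just demeans
  b1 <- random_bold(c(2, 2, 2), nt = nt, seed = 9)
  out1 <- regress_nuisance(b1, nuisance_set(FALSE))
  demeaned <- b1$data - array(rep(apply(b1$data, 1:3, mean), nt), dim(b1$data))
  expect_equal(out1$data, demeaned, tolerance = 1e-10)
  # collinear columns are named
  err <- tryCatch(regress_nuisance(b, nuisance_set(TRUE, wm, wm, mp)),
                  error = function(e) e)
  expect_s3_class(err, "nc_rank_error")
  expect_match(conditionMessage(err), "csf")
})

test_that("band-pass keeps the 0.01-0.08 Hz band and removes the rest", {
  nt <- 120; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  mk <- function(x) bold_series(array(x, c(1, 1, 1, nt)), tr)
  inband <- sin(2 * pi * 0.04 * tt)
  out <- bandpass(mk(inband))
  expect_lt(abs(sd(out$data) / sd(inband) - 1), 0.05)
  stop_band <- sin(2 * pi * 0.2 * tt)
  outs <- bandpass(mk(stop_band))
  expect_lt(sd(outs$data) / sd(stop_band), 0.10)
  # constant series (DC) is removed
  outc <- bandpass(mk(rep(7, nt)))
  expect_lt(max(abs(outc$data)), 1e-8)
  expect_error(bandpass(mk(inband), low = 0.05, high = 0.3),
               class = "nc_validation_error")
})

test_that("framewise displacement matches the per-frame formula", {
  mp0 <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(mp0), rep(0, 10))
  # a single 0.1 mm x-translation step
  mp1 <- mp0; mp1[5:10, 1] <- 0.1
  fd <- framewise_displacement(mp1)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, 9))
  # random walk against a brute-force loop
  set.seed(2)
  mp <- apply(matrix(rnorm(40 * 6, sd = 0.2), 40), 2, cumsum)
  fd2 <- framewise_displacement(mp)
  oracle <- numeric(40)
  for (t in 2:40) {
    d <- mp[t, ] - mp[t - 1, ]
    oracle[t] <- sum(abs(d[1:3])) + 50 * sum(abs(d[4:6] * pi / 180))
  }
  expect_equal(fd2, oracle, tolerance = 1e-12)
  expect_equal(fd2[1], 0)
})

test_that("motion exclusion uses 'no more than' boundaries", {
  mp <- matrix(0, 10, 6)
  mp[3, 1] <- 3.0             # exactly 3 mm: passes
  expect_true(motion_exclusion(mp)$pass)
  mp[3, 5] <- 3.1             # 3.1 degrees: fails
  expect_false(motion_exclusion(mp)$pass)
  # fail count over a random cohort equals a brute-force scan
  set.seed(5)
  fails <- 0; oracle <- 0
  for (s in 1:50) {
    m <- matrix(rnorm(30 * 6, sd = 1.4), 30)
    if (!motion_exclusion(m)$pass) fails <- fails + 1
    if (max(abs(m[, 1:3])) > 3 || max(abs(m[, 4:6])) > 3) oracle <- oracle + 1
  }
  expect_identical(fails, oracle)
})

test_that("the pipeline applies discard, regression, band-pass in that order", {
  # a strong linear trend plus an in-band oscillation: regression first
  # removes the trend exactly; band-pass first would leave a trend residual
  nt <- 130; tr <- 2
  tt <- (seq_len(nt) - 1) * tr
  sig <- 5 * tt + sin(2 * pi * 0.05 * tt)
  b <- bold_series(array(sig, c(1, 1, 1, nt)), tr,
                   motion_params = matrix(0, nt, 6))
  nuis <- nuisance_set(TRUE)
  out <- preprocess_bold(b, nuis, n_discard = 10)
  kept <- as.vector(out$data)
  # correct order: output is (almost) the pure oscillation, so its
  # correlation with the trend is tiny and amplitude is preserved
  trend <- seq_along(kept)
  expect_lt(abs(cor(kept, trend)), 0.05)
  expect_lt(abs(sd(kept) / sd(sin(2 * pi * 0.05 * tt[11:nt])) - 1), 0.1)
  # permuting the stages changes the result: band-pass before regression
  # mangles the trend instead of removing it
  alt <- regress_nuisance(bandpass(discard_initial(b, 10)),
                          neurocouple:::trim_nuisance(nuis, 11:nt))
  expect_gt(max(abs(alt$data - out$data)) / sd(kept), 0.01)
})
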