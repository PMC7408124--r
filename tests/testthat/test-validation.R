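explicit_loo <- function(x, y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    fit <- mlr_fit(x[-i, , drop = FALSE], y[-i])
    predict(fit, as.data.frame(x)[i, , drop = FALSE])
  }, numeric(1))
}

test_that("closed-form LOO equals explicit refitting", {
  set.seed(50)
  for (rep in 1:50) {
    n <- sample(10:25, 1); p <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    press_explicit <- sum((y - explicit_loo(x, y))^2)
    q2_explicit <- 1 - press_explicit / sum((y - mean(y))^2)
    expect_equal(q2_loo(x, y), q2_explicit, tolerance = 1e-10)
  }
})

test_that("Q2 limiting behaviour", {
  x <- matrix(seq(1, 5, length.out = 20), dimnames = list(NULL, "x"))
  expect_equal(q2_loo(x, 3 * x[, 1] - 1), 1, tolerance = 1e-9)
  set.seed(8)
  xr <- matrix(rnorm(40), 20, 2)
  yr <- rnorm(20)
  fit <- mlr_fit(xr, yr)
  expect_lt(q2_loo(xr, yr), fit$r_squared)   # CV penalty
})

test_that("external metrics follow their definitions", {
  set.seed(21)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(x %*% c(1, -1, 2)) + rnorm(20, sd = 0.2)
  fit <- mlr_fit(x, y)
  xe <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  # perfect external predictions
  ye <- predict(fit, xe)
  em <- external_metrics(fit, xe, ye, y)
  expect_equal(em$Q2_F1, 1); expect_equal(em$Q2_F2, 1); expect_equal(em$Q2_F3, 1)
  expect_equal(em$CCC_ext, 1); expect_equal(em$RMSE_ext, 0); expect_equal(em$MAE_ext, 0)
  # predictions identically the training mean: Q2F1 = 0 by definition
  fit_const <- fit
  fit_const$coefficients[] <- c(mean(y), 0, 0, 0)
  em0 <- external_metrics(fit_const, xe, rnorm(8, mean(y)), y)
  expect_equal(em0$Q2_F1, 0, tolerance = 1e-12)
})

test_that("Q2F1 >= Q2F2 on arbitrary inputs", {
  set.seed(99)
  for (rep in 1:25) {
    x <- matrix(rnorm(45), 15, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(15)
    fit <- mlr_fit(x, y)
    xe <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
    ye <- rnorm(5)
    em <- external_metrics(fit, xe, ye, y)
    expect_gte(em$Q2_F1, em$Q2_F2)
  }
})

test_that("rm2 metrics behave at the identity and under shifts", {
  set.seed(4)
  y <- rnorm(10, 1.5, 0.3)
  r <- r2m_metrics(y, y)
  expect_equal(r$average, 1)
  expect_equal(r$difference, 0)
  shifted <- r2m_metrics(y, y + 0.5)
  expect_gt(shifted$difference, 0)
  expect_lt(shifted$average, 1)
  expect_error(r2m_metrics(rep(1, 5), rnorm(5)), "variance")
})

test_that("rm2 on a length-6 example equals a hand computation", {
  y_obs <- c(1.0, 1.2, 1.5, 1.7, 1.9, 2.1)
  y_pred <- c(1.1, 1.15, 1.6, 1.65, 2.0, 2.0)
  r2 <- cor(y_obs, y_pred)^2
  r02_a <- {
    k <- sum(y_pred * y_obs) / sum(y_pred^2)
    1 - sum((y_obs - k * y_pred)^2) / sum((y_obs - mean(y_obs))^2)
  }
  r02_b <- {
    k <- sum(y_obs * y_pred) / sum(y_obs^2)
    1 - sum((y_pred - k * y_obs)^2) / sum((y_pred - mean(y_pred))^2)
  }
  a <- r2 * (1 - sqrt(r2 - r02_a))
  b <- r2 * (1 - sqrt(r2 - r02_b))
  r <- r2m_metrics(y_obs, y_pred)
  expect_equal(r$average, (a + b) / 2, tolerance = 1e-12)
  expect_equal(r$difference, abs(a - b), tolerance = 1e-12)
})

test_that("K correlation index spans its limiting cases", {
  # mutually orthogonal columns: all eigenvalues 1, K = 0
  x <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  expect_equal(k_correlation(x), 0, tolerance = 1e-12)
  # perfectly collinear pair: K = 1
  z <- rnorm(10)
  expect_equal(k_correlation(cbind(z, 2 * z)), 1, tolerance = 1e-12)
  # three columns: equals the direct eigenvalue computation
  set.seed(13)
  m <- matrix(rnorm(60), 20, 3)
  lambda <- eigen(cor(m))$values
  k_direct <- sum(abs(lambda / 3 - 1 / 3)) / (2 * 2 / 3)
  expect_equal(k_correlation(m), k_direct, tolerance = 1e-12)
  expect_error(k_correlation(cbind(rep(1, 5), rnorm(5))), "constant")
})

test_that("Y-scrambling matches the null expectation and reproduces", {
  set.seed(77)
  x <- matrix(rnorm(28 * 3), 28, 3)
  y <- rnorm(28)
  s1 <- y_scramble(x, y, n_iter = 500, seed = 11)
  expect_equal(s1$R2_scr, 3 / 27, tolerance = 0.3)  # p/(n-1) null mean
  expect_lt(s1$Q2_scr, s1$R2_scr)
  s2 <- y_scramble(x, y, n_iter = 500, seed = 11)
  expect_identical(s1, s2)
  expect_error(y_scramble(x, y, n_iter = 10), "100")
})

test_that("applicability domain reproduces leverage closed forms", {
  set.seed(6)
  x <- matrix(rnorm(28 * 3), 28, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(x %*% c(1, 1, 1)) + rnorm(28)
  fit <- mlr_fit(x, y)
  ad <- applicability_domain(fit, x, y)
  expect_equal(attr(ad, "h_star"), 3 * 4 / 28)
  expect_equal(round(attr(ad, "h_star"), 3), 0.429)
  # training leverages: equal the hat diagonal, sum to p'
  expect_equal(ad$leverage, unname(fit$hat), tolerance = 1e-10)
  expect_equal(sum(ad$leverage), 4, tolerance = 1e-10)
  # a point at the descriptor centroid has leverage exactly 1/n
  centroid <- as.data.frame(t(colMeans(x)))
  ad_c <- applicability_domain(fit, centroid)
  expect_equal(ad_c$leverage, 1 / 28, tolerance = 1e-12)
  # a far outside point exceeds the warning leverage
  far <- as.data.frame(t(colMeans(x) + 50 * apply(x, 2, sd)))
  ad_f <- applicability_domain(fit, far)
  expect_true(ad_f$out_of_domain)
  # standardized residuals are e/s on training points
  expect_equal(ad$std_residual, unname(fit$residuals / fit$sigma), tolerance = 1e-12)
  expect_equal(ad$outlier, abs(fit$residuals / fit$sigma) > 2)
})

test_that("the full validation report is internally consistent", {
  set.seed(14)
  x <- matrix(rnorm(28 * 3), 28, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(x %*% c(1, -0.5, 0.3)) + rnorm(28, sd = 0.5)
  xe <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  ye <- drop(xe %*% c(1, -0.5, 0.3)) + rnorm(8, sd = 0.5)
  fit <- mlr_fit(x, y)
  val <- validate_model(fit, xe, ye, n_scramble = 100, seed = 5)
  expect_equal(val$N_tr, 28); expect_equal(val$N_ext, 8)
  expect_gte(val$RMSE_tr, val$MAE_tr)
  expect_gte(val$RMSE_ext, val$MAE_ext)
  expect_gte(val$Q2_F1, val$Q2_F2)
  expect_true(val$CCC_tr >= -1 && val$CCC_tr <= 1)
  expect_equal(val$h_star, 3 * 4 / 28)
  expect_equal(val$Q2_LOO, q2_loo(x, y))
  expect_equal(val$R2, fit$r_squared)
  expect_equal(nrow(val$williams), 36)
  expect_equal(sum(val$williams$set == "test"), 8)
  # report flattens and serializes
  df <- as.data.frame(val)
  expect_true("Q2_F3" %in% df$statistic)
  paths <- tempfile(c("v", "v", "w"), fileext = c(".json", ".csv", ".csv"))
  write_validation_report(val, paths[1], paths[2], paths[3])
  expect_equal(jsonlite::read_json(paths[1])$N_tr, 28)
  expect_equal(nrow(read.csv(paths[3])), 36)
  unlink(paths)
})
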