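decay_f <- function(x, Y0, plateau, k) plateau + (Y0 - plateau) * exp(-k * x)
logi_f <- function(x, top, bottom, m, h) {
  bottom + (top - bottom) / (1 + 10^((x - m) * h))
}

test_that("noiseless decay data are recovered to high precision", {
  x <- seq(0, 0.1, length.out = 8)
  y <- decay_f(x, 1, 0.05, 40)
  fit <- fit_decay(data.frame(distance = x, ratio = y))
  expect_s3_class(fit, "decay_fit")
  expect_s3_class(fit, "conservation_fit")
  expect_equal(unname(coef(fit)), c(1, 0.05, 40), tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
})

test_that("noiseless logistic data are recovered exactly", {
  x <- seq(0, 0.1, length.out = 10)
  y <- logi_f(x, 1, 0.05, 0.04, 30)
  fit <- fit_sigmoid(data.frame(x = x, y = y))
  expect_equal(unname(coef(fit)), c(1, 0.05, 0.04, 30), tolerance = 1e-5)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("constant response is flagged degenerate; rising data fit with h < 0", {
  x <- seq(0, 0.1, length.out = 8)
  fit <- fit_decay(data.frame(x = x, y = rep(0.4, 8)))
  expect_true(fit$degenerate)
  expect_equal(unname(coef(fit)[["plateau"]]), 0.4)
  expect_error(prediction_interval(fit, 0.05), "degenerate")
  # monotone-increasing response: handled, slope factor negative
  yup <- logi_f(x, 0.9, 0.1, 0.05, -25)
  up <- fit_sigmoid(data.frame(x = x, y = yup))
  expect_lt(coef(up)[["h"]], 0)
})

test_that("a noisy decay still recovers the rate roughly and r2 is honest", {
  set.seed(14)
  x <- seq(0, 0.1, length.out = 12)
  y <- decay_f(x, 1, 0.05, 40) + rnorm(12, 0, 0.02)
  fit <- fit_decay(data.frame(x = x, y = y))
  expect_lt(abs(coef(fit)[["k"]] - 40) / 40, 0.4)
  # r2 equals an independent recomputation from residuals
  yhat <- decay_f(x, coef(fit)[["Y0"]], coef(fit)[["plateau"]],
                  coef(fit)[["k"]])
  expect_equal(fit$r2, 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
               tolerance = 1e-10)
  expect_equal(residuals(fit), y - yhat, tolerance = 1e-12)
  expect_equal(fitted(fit), yhat, tolerance = 1e-12)
  expect_identical(df.residual(fit), 9L)
  # summary carries standard errors
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
})

test_that("fit results do not depend on point order", {
  set.seed(9)
  x <- seq(0, 0.1, length.out = 12)
  y <- decay_f(x, 1, 0.05, 40) + rnorm(12, 0, 0.02)
  perm <- sample(12)
  f1 <- fit_decay(data.frame(x = x, y = y))
  f2 <- fit_decay(data.frame(x = x[perm], y = y[perm]))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
})

test_that("sigmoid fit on decay-generated data does not dramatically beat decay", {
  set.seed(27)
  x <- seq(0, 0.1, length.out = 12)
  y <- decay_f(x, 1, 0.05, 40) + rnorm(12, 0, 0.02)
  fd <- fit_decay(data.frame(x = x, y = y))
  fs <- fit_sigmoid(data.frame(x = x, y = y))
  expect_lte(fs$r2, fd$r2 + 0.05)
})

test_that("fits require enough distinct distances", {
  expect_error(fit_decay(data.frame(x = c(0, 0.1, 0.1), y = c(1, 0.5, 0.4))),
               "distinct")
  expect_error(fit_sigmoid(data.frame(x = seq(0, 0.3, 0.1),
                                      y = c(1, 0.8, 0.5, 0.2))),
               "distinct")
})

test_that("select_model prefers the simpler model unless F-test says otherwise", {
  x <- seq(0, 0.1, length.out = 12)
  y <- decay_f(x, 1, 0.05, 40)
  fd <- fit_decay(data.frame(x = x, y = y))
  fs <- fit_sigmoid(data.frame(x = x, y = y))
  # single candidate comes back unchanged
  single <- select_model(list(fd))
  expect_identical(single$best, fd)
  # on noiseless decay data the extra parameter cannot be justified
  set.seed(41)
  yn <- y + rnorm(12, 0, 0.02)
  fdn <- fit_decay(data.frame(x = x, y = yn))
  fsn <- fit_sigmoid(data.frame(x = x, y = yn))
  sel <- select_model(list(fsn, fdn))
  expect_true(!is.null(sel$report))
  expect_identical(sel$report$simpler, "decay")
  # identical fits (equal parameter count, equal SS) keep the first: the
  # tie breaks toward no change
  tie <- select_model(list(fdn, fdn))
  expect_identical(tie$best$model, "decay")
  # refuses fits on different data
  other <- fit_decay(data.frame(x = x, y = yn + 0.1))
  expect_error(select_model(list(fdn, other)), "identical points")
})

test_that("on sigmoid-generated data the F-test adopts the sigmoid", {
  set.seed(88)
  x <- seq(0, 0.1, length.out = 14)
  y <- logi_f(x, 1, 0.1, 0.05, 35) + rnorm(14, 0, 0.01)
  fd <- fit_decay(data.frame(x = x, y = y))
  fs <- fit_sigmoid(data.frame(x = x, y = y))
  sel <- select_model(list(fd, fs))
  expect_identical(sel$best$model, "sigmoid")
  expect_lt(sel$report$p_value[1], 0.05)
})

test_that("prediction intervals widen confidence intervals and nest by level", {
  set.seed(3)
  x <- seq(0, 0.1, length.out = 12)
  y <- decay_f(x, 1, 0.05, 40) + rnorm(12, 0, 0.02)
  fit <- fit_decay(data.frame(x = x, y = y))
  grid <- seq(0, 0.1, length.out = 11)
  conf <- predict(fit, grid, interval = "confidence")
  pred <- predict(fit, grid, interval = "prediction")
  expect_true(all(pred[, "lwr"] < conf[, "lwr"]))
  expect_true(all(pred[, "upr"] > conf[, "upr"]))
  expect_true(all(pred[, "lwr"] <= pred[, "fit"] &
                    pred[, "fit"] <= pred[, "upr"]))
  p99 <- predict(fit, grid, interval = "prediction", level = 0.99)
  expect_true(all(p99[, "lwr"] <= pred[, "lwr"] &
                    p99[, "upr"] >= pred[, "upr"]))
  band <- prediction_band(fit, level = 0.95)
  expect_true(all(band$lower <= band$center & band$center <= band$upper))
  expect_identical(attr(band, "level"), 0.95)
  # noiseless fit: the band collapses
  f0 <- fit_decay(data.frame(x = x, y = decay_f(x, 1, 0.05, 40)))
  w <- prediction_interval(f0, 0.05)
  expect_lt(w[, "upr"] - w[, "lwr"], 1e-5)
})

test_that("plot method draws points, curve and band without error", {
  x <- seq(0, 0.1, length.out = 8)
  fit <- fit_decay(data.frame(x = x, y = decay_f(x, 1, 0.05, 40) +
                                rnorm(8, 0, 0.01)))
  png_file <- tempfile(fileext = ".png")
  grDevices::png(png_file)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(png_file))
})

test_that("fit JSON report round-trips the key quantities", {
  x <- seq(0, 0.1, length.out = 8)
  fit <- fit_decay(data.frame(x = x, y = decay_f(x, 1, 0.05, 40)))
  path <- tempfile(fileext = ".json")
  write_fit_json(fit, path)
  got <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(got$model, "decay")
  expect_equal(got$coefficients$k, unname(coef(fit)[["k"]]), tolerance = 1e-9)
  expect_equal(got$r2, fit$r2)
})
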