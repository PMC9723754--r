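test_that("two-SD rescaling has the defining moments and slope algebra", {
  # two-point case under the sample-SD (n-1) convention:
  # (x - 1/2) / (2 * sd(c(0,1))) = +/- 1/(2 sqrt(2))
  expect_equal(as.numeric(rescale_two_sd(c(0, 1))),
               c(-0.5, 0.5) / (2 * sd(c(0, 1))))
  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    z <- rescale_two_sd(x)
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 0.5, tolerance = 1e-12)
  }
  # slope on rescaled x equals 2 sd(x) times the raw slope
  x <- rnorm(100); y <- 1 + 0.7 * x + rnorm(100, sd = 0.3)
  raw <- coef(lm(y ~ x))[2]
  scl <- coef(lm(y ~ z, data = data.frame(y, z = as.numeric(rescale_two_sd(x)))))[2]
  expect_equal(unname(scl), unname(2 * sd(x) * raw), tolerance = 1e-10)
  expect_error(rescale_two_sd(rep(3, 5), name = "tp"), "tp")
})

test_that("standardized univariate estimates equal the Pearson correlation", {
  set.seed(21)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  fit <- fit_effect_model(y, data.frame(x = x))
  est <- fit$coefficients$estimate[fit$coefficients$term == "x"]
  expect_equal(est, cor(x, y), tolerance = 1e-10)
  expect_true(abs(est) <= 1 + 1e-12)

  # perfect fit (summary.lm warns about it; the warning is expected)
  fp <- suppressWarnings(fit_effect_model(x, data.frame(x = x)))
  expect_equal(fp$coefficients$estimate[2], 1.0, tolerance = 1e-10)
  expect_equal(fp$r_squared, 1.0, tolerance = 1e-12)

  # rank deficiency names the collinear column
  expect_error(fit_effect_model(y, data.frame(a = x, b = 2 * x)), "b")
})

test_that("functional-form comparison applies the linear-preference AIC rule", {
  set.seed(31)
  x <- runif(200, 1, 10)
  # noiseless linear data: linear chosen with delta 0
  fc0 <- compare_functional_forms(2 + 3 * x, x)
  expect_identical(attr(fc0, "chosen"), "linear")
  expect_equal(fc0$delta_aic[fc0$form == "linear"], 0, tolerance = 1e-6)

  # strong quadratic signal: quadratic beats linear by >= 4 AIC units
  yq <- 1 + 0.5 * x - 0.35 * x^2 + rnorm(200, sd = 1)
  fcq <- compare_functional_forms(yq, x)
  expect_identical(attr(fcq, "chosen"), "quadratic")
  expect_gte(fcq$aic[fcq$form == "linear"] - fcq$aic[fcq$form == "quadratic"], 4)

  # linear data with noise: linear retained even when another form has a
  # marginally lower AIC (margin < 4)
  found <- FALSE
  for (s in 1:50) {
    set.seed(s)
    yl <- 0.5 * x + rnorm(200)
    fc <- compare_functional_forms(yl, x)
    delta_lin <- fc$delta_aic[fc$form == "linear"]
    if (delta_lin > 0 && delta_lin < 4) {
      expect_identical(attr(fc, "chosen"), "linear")
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # non-positive x: log form skipped with a warning
  expect_warning(fcn <- compare_functional_forms(rnorm(50), c(-1, runif(49))),
                 "logarithmic")
  expect_false("logarithmic" %in% fcn$form)
})

test_that("stepwise AIC selection finds strong predictors and terminates properly", {
  set.seed(41)
  n <- 500
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(X) <- c("signal", paste0("noise", 1:5))
  y <- 1.5 * X$signal + rnorm(n)
  sel <- suppressMessages(stepwise_select(y, X))
  expect_true("signal" %in% sel$selected)

  # termination: final AIC <= initial, and no single move improves it
  expect_lte(sel$trace$aic[nrow(sel$trace)], sel$trace$aic[1])
  ys <- as.numeric(rescale_two_sd(y))
  Xs <- as.data.frame(lapply(X, function(c) as.numeric(rescale_two_sd(c))))
  aic_of <- function(terms) {
    f <- if (length(terms)) reformulate(terms, response = ".y") else .y ~ 1
    AIC(lm(f, data = cbind(.y = ys, Xs)))
  }
  final <- aic_of(sel$selected)
  for (t in setdiff(names(X), sel$selected))
    expect_gte(aic_of(c(sel$selected, t)), final)
  for (t in sel$selected)
    expect_gte(aic_of(setdiff(sel$selected, t)), final)

  # empty candidate set: intercept-only fit
  s0 <- suppressMessages(stepwise_select(y, X[, 0]))
  expect_identical(s0$selected, character(0))

  # deterministic given input ordering
  sel2 <- suppressMessages(stepwise_select(y, X))
  expect_identical(sel$trace, sel2$trace)
})
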