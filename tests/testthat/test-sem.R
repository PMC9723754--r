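test_that("path specs validate acyclicity, grouping and the text format", {
  expect_error(path_spec(data.frame(source = c("a", "b"), target = c("b", "a"))),
               "cycle")
  expect_error(path_spec(data.frame(source = "a", target = "b"),
                         groups = list(g1 = "a")), "not assigned")
  expect_error(path_spec(data.frame(source = "a", target = "b"),
                         groups = list(g1 = c("a", "b"), g2 = "b")),
               "more than one group")

  spec <- read_path_spec(text = c(
    "# facet-level model",
    "respiration ~ active_biomass + sir_efficiency",
    "sir_efficiency ~ total_biomass",
    "total_biomass ~~ active_biomass",
    "group: biomass = total_biomass, active_biomass",
    "group: physiological = sir_efficiency",
    "group: respiration = respiration"))
  expect_s3_class(spec, "path_spec")
  expect_setequal(spec$exogenous, c("active_biomass", "total_biomass"))
  expect_identical(nrow(spec$edges), 3L)
  expect_identical(spec$correlations$a, "total_biomass")
})

test_that("ML path estimates equal per-equation least squares on recursive toys", {
  set.seed(61)
  n <- 1000
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
  y1 <- 0.4 * x1 + 0.3 * x2 + rnorm(n)
  y2 <- 0.6 * y1 + 0.2 * x2 + rnorm(n)
  dat <- data.frame(x1, x2, y1, y2)
  spec <- path_spec(data.frame(source = c("x1", "x1", "x2", "y1", "x2"),
                               target = c("x2", "y1", "y1", "y2", "y2")))
  fit <- fit_path_model(spec, dat)
  ols <- c(coef(lm(x2 ~ x1))[2], coef(lm(y1 ~ x1 + x2))[2:3],
           coef(lm(y2 ~ y1 + x2))[2:3])
  expect_equal(fit$paths$estimate, unname(ols), tolerance = 1e-6)
  # SEs close to the OLS standard errors
  se_ols <- summary(lm(y2 ~ y1 + x2))$coefficients["y1", 2]
  expect_equal(fit$paths$se[fit$paths$source == "y1"], se_ols,
               tolerance = 0.05)
})

test_that("noiseless data are reproduced exactly and saturated fits are perfect", {
  set.seed(62)
  n <- 400
  a <- rnorm(n); b <- rnorm(n)
  # vanishing disturbances: with exactly zero disturbance the sample
  # covariance is singular and the ML discrepancy is undefined, so the
  # noiseless limit is probed at a negligible disturbance scale
  m <- 0.7 * a - 0.2 * b + rnorm(n, sd = 1e-5)
  y <- 0.5 * m + 0.3 * a + rnorm(n, sd = 1e-5)
  dat <- data.frame(a, b, m, y)
  spec <- path_spec(data.frame(source = c("a", "b", "m", "a"),
                               target = c("m", "m", "y", "y")))
  fit <- fit_path_model(spec, dat)
  expect_lt(max(abs(fit$paths$estimate - c(0.7, -0.2, 0.5, 0.3))), 1e-4)
  expect_lt(fit$fml, 1e-6)

  # saturated model: implied covariance reproduces S, chisq ~ 0, df = 0
  y2 <- 0.5 * m + 0.3 * a + rnorm(n)
  dat2 <- data.frame(a, m2 = m + rnorm(n), y2)
  sat <- path_spec(data.frame(source = c("a", "a", "m2"),
                              target = c("m2", "y2", "y2")))
  fs <- fit_path_model(sat, dat2)
  expect_identical(fs$df, 0)
  expect_equal(max(abs(fs$implied - fs$S)), 0, tolerance = 1e-6)
  idx <- sem_fit_indices(fs)
  expect_equal(idx$cfi, 1)
  expect_lt(idx$srmr, 1e-4)
  expect_identical(idx$rmsea, 0)
})

test_that("fit indices follow their closed forms and threshold flags", {
  # RMSEA arithmetic: chisq 50, df 20, n 151 -> sqrt(30/(20*150)) = 0.1
  fake <- list(chisq = 50, df = 20, n = 151,
               baseline = c(chisq = 500, df = 36))
  idx <- sem_fit_indices(fake)
  expect_equal(idx$rmsea, sqrt(30 / (20 * 150)), tolerance = 1e-12)
  expect_equal(idx$rmsea, 0.1, tolerance = 1e-12)
  expect_false(idx$pass[["rmsea"]])  # threshold is strictly < 0.10
  expect_equal(idx$cfi, 1 - 30 / (500 - 36), tolerance = 1e-12)

  # the independence model evaluated against itself has CFI = 0
  self <- list(chisq = 500, df = 36, n = 151,
               baseline = c(chisq = 500, df = 36))
  expect_equal(sem_fit_indices(self)$cfi, 0)
})

test_that("standardization uses model-implied SDs", {
  set.seed(63)
  n <- 5000
  x <- rnorm(n, sd = 2)
  y <- 1 * x + rnorm(n, sd = sqrt(16 - 4))  # sd(y) ~ 4, raw coef 1
  dat <- data.frame(x, y)
  spec <- path_spec(data.frame(source = "x", target = "y"))
  fit <- fit_path_model(spec, dat)
  expect_equal(fit$paths$std_estimate, 1 * 2 / 4, tolerance = 0.03)
  # standardized univariate path equals the Pearson correlation
  expect_equal(fit$paths$std_estimate, cor(x, y), tolerance = 1e-6)

  # pre-standardized data: standardized equals unstandardized
  dat2 <- as.data.frame(scale(dat))
  fit2 <- fit_path_model(spec, dat2)
  expect_equal(fit2$paths$std_estimate, fit2$paths$estimate, tolerance = 1e-6)
})

test_that("effect decomposition: chains, conservation, and the dual algorithm agree", {
  # single chain: A -> B (0.5) -> C (0.4)
  pt <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   estimate = c(0.5, 0.4))
  de <- decompose_effects(pt)
  ac <- de[de$source == "A" & de$target == "C", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2, tolerance = 1e-12)
  expect_equal(ac$total, 0.2, tolerance = 1e-12)

  # total = direct + indirect exactly, and enumeration = matrix series,
  # on 100 random DAGs of up to 8 nodes
  set.seed(64)
  for (i in 1:100) {
    k <- sample(3:8, 1)
    ptr <- random_dag_paths(k)
    if (is.null(ptr)) next
    d <- decompose_effects(ptr)
    expect_equal(d$total, d$direct + d$indirect, tolerance = 0)
    ser <- effect_matrix_series(ptr)
    for (r in seq_len(nrow(d))) {
      expect_equal(d$indirect[r], ser$indirect[d$target[r], d$source[r]],
                   tolerance = 1e-10)
    }
  }
  expect_error(decompose_effects(data.frame(source = c("a", "b"),
                                            target = c("b", "a"),
                                            estimate = c(1, 1))), "cycle")
})

test_that("group summaries sum absolute effects over significant paths only", {
  pt <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
                   estimate = c(0.5, 0.4, -0.3), p = c(0.01, 0.20, 0.01))
  de <- decompose_effects(pt, alpha = 0.05)
  groups <- list(g1 = "A", g2 = c("B", "C"), g3 = "D")
  gs <- group_effect_summary(de, groups, target = "D")
  # A -> D path goes through the non-significant B -> C edge: excluded
  expect_equal(gs$total[gs$group == "g1"], 0)
  # C -> D is direct and significant
  expect_equal(gs$direct[gs$group == "g2"], 0.3)
  # unfiltered mode counts everything
  gt <- group_effect_summary(de, groups, target = "D", mode = "total")
  expect_equal(gt$total[gt$group == "g1"], abs(0.5 * 0.4 * -0.3),
               tolerance = 1e-12)
  expect_error(group_effect_summary(de, groups, target = "nope"), "unknown")
})
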