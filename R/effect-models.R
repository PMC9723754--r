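#' Centre a variable and divide by two standard deviations
#'
#' Rescales `x` to `(x - mean(x)) / (2 sd(x))` (sample SD, n-1 denominator),
#' so the rescaled variable has mean 0 and SD 0.5. On this scale, a linear
#' coefficient of a rescaled predictor corresponds to the change in the
#' response across a two-SD span of the predictor, which puts continuous
#' predictors on a footing comparable to a binary contrast and makes effect
#' sizes comparable across predictors.
#'
#' @param x numeric vector with positive SD.
#' @param name variable name used in error messages.
#' @return numeric vector with attributes `center`, `scale`
#'   (`2 * sd(x)`) and `transform = "2SD"` retained for back-transformation.
#' @examples
#' rescale_two_sd(c(0, 1))  # -0.5, +0.5
#' @export
rescale_two_sd <- function(x, name = deparse(substitute(x))) {
  stopifnot(is.numeric(x))
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort_constant(name)
  m <- mean(x, na.rm = TRUE)
  out <- (x - m) / (2 * s)
  attributes(out) <- list(center = m, scale = 2 * s, transform = "2SD")
  out
}

#' Fit a standardized linear effect model
#'
#' Ordinary least squares of `y` on the columns of `X`, with every
#' predictor (and, by default, the response) centred and divided by two
#' standard deviations, so the coefficients are standardized effect sizes.
#' With both sides rescaled, the univariate estimate equals the Pearson
#' correlation. Rows with missing values are dropped listwise (reported in
#' the result).
#'
#' @param y numeric response vector.
#' @param X data.frame or matrix of predictors (may have zero columns for
#'   an intercept-only fit).
#' @param standardize_response rescale the response too (default `TRUE`).
#' @param data optional data.frame in which `y`/`X` column names are
#'   resolved when given as character.
#' @return object of class `effect_fit`: list with `coefficients`
#'   (data.frame: term, estimate, se, p), `r_squared`, `adj_r_squared`,
#'   `aic`, `n`, `n_dropped`, `diagnostics` (Shapiro-Wilk p and
#'   Breusch-Pagan-type p on the residuals; reported, never used to gate
#'   results), and the underlying `lm` fit.
#' @export
fit_effect_model <- function(y, X, standardize_response = TRUE, data = NULL) {
  if (is.character(y)) { stopifnot(!is.null(data)); yname <- y; y <- data[[y]] }
  else yname <- "y"
  if (is.character(X)) { stopifnot(!is.null(data)); X <- data[, X, drop = FALSE] }
  X <- as.data.frame(X)
  n0 <- length(y)
  stopifnot(nrow(X) == n0 || ncol(X) == 0)
  if (ncol(X) == 0) X <- data.frame(row.names = seq_len(n0))

  keep <- stats::complete.cases(cbind(y, X))
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with missing values dropped (listwise)")
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1)
    stop("need n > p + 1 observations after listwise deletion", call. = FALSE)

  Xs <- if (ncol(X) > 0) {
    out <- as.data.frame(lapply(seq_along(X), function(j)
      as.numeric(rescale_two_sd(X[[j]], names(X)[j]))))
    names(out) <- names(X)
    out
  } else data.frame(row.names = seq_len(n))
  ys <- if (standardize_response) as.numeric(rescale_two_sd(y, yname)) else y

  if (ncol(Xs) > 0) {
    qrX <- qr(cbind(1, as.matrix(Xs)))
    if (qrX$rank < ncol(Xs) + 1) {
      bad <- names(Xs)[qrX$pivot[seq(qrX$rank + 1, ncol(Xs) + 1)] - 1]
      stop("rank-deficient design; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  df <- cbind(data.frame(.y = ys), Xs)
  fit <- if (ncol(Xs) > 0) stats::lm(.y ~ ., data = df)
         else stats::lm(.y ~ 1, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  res <- stats::residuals(fit)

  # residual diagnostics: normality (Shapiro-Wilk) and heteroscedasticity
  # (regression of squared residuals on fitted values, F-test)
  sw <- tryCatch(stats::shapiro.test(res)$p.value, error = function(e) NA_real_)
  bp <- if (ncol(Xs) > 0) {
    aux <- stats::lm(res^2 ~ stats::fitted(fit))
    f <- summary(aux)$fstatistic
    if (is.null(f)) NA_real_ else stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_

  structure(list(
    response = yname,
    predictors = names(Xs),
    coefficients = data.frame(term = rownames(co), estimate = co[, 1],
                              se = co[, 2], p = co[, 4], row.names = NULL),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    aic = stats::AIC(fit),
    n = n, n_dropped = n_dropped,
    diagnostics = c(normality_p = unname(sw), heteroscedasticity_p = unname(bp)),
    lm = fit
  ), class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat("Standardized linear effect model:", x$response, "~",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "1", "\n")
  print(x$coefficients, digits = 3)
  cat(sprintf("n = %d, R2 = %.3f, adj. R2 = %.3f, AIC = %.2f\n",
              x$n, x$r_squared, x$adj_r_squared, x$aic))
  invisible(x)
}

#' Compare linear against non-linear functional forms by AIC
#'
#' Fits linear, quadratic, polynomial (cubic by default) and logarithmic
#' models of `y` on a single predictor `x`, computes AIC on identical
#' observations, and applies a linear-preference rule: the linear form is
#' retained unless some other form beats it by at least `delta` AIC units
#' (default 4); otherwise the lowest-AIC form is chosen.
#'
#' @param y,x numeric vectors; `x` must be positive for the logarithmic
#'   form (otherwise that form is skipped with a warning).
#' @param poly_degree degree of the "polynomial" form (default 3).
#' @param delta AIC margin a non-linear form must exceed (default 4).
#' @return object of class `form_comparison`: data.frame of `form`, `aic`,
#'   `delta_aic` (vs the best form), with attributes `chosen` and `fits`.
#' @export
compare_functional_forms <- function(y, x, poly_degree = 3, delta = 4) {
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  fits <- list(
    linear = stats::lm(y ~ x),
    quadratic = stats::lm(y ~ x + I(x^2)),
    polynomial = stats::lm(y ~ stats::poly(x, poly_degree, raw = TRUE))
  )
  if (all(x > 0)) {
    fits$logarithmic <- stats::lm(y ~ log(x))
  } else {
    warning("non-positive x: logarithmic form skipped", call. = FALSE)
  }
  aics <- vapply(fits, stats::AIC, numeric(1))
  best <- min(aics)
  chosen <- if (aics[["linear"]] - best < delta) "linear"
            else names(aics)[which.min(aics)]
  out <- data.frame(form = names(aics), aic = unname(aics),
                    delta_aic = unname(aics - best), row.names = NULL)
  structure(out, chosen = chosen, fits = fits, class = c("form_comparison",
                                                         "data.frame"))
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starting from the full model (or from the intercept-only model when
#' n <= p, with a message), repeatedly applies the single addition or
#' deletion that most lowers the AIC, until no move improves it. Ties are
#' broken by candidate column order. Selection operates on the listwise-
#' complete rows of the full candidate set so all AICs are comparable.
#'
#' @param y response vector (or column name when `data` is given).
#' @param X_candidates data.frame of candidate predictors.
#' @param standardize standardize response and predictors by two SDs before
#'   selection (default `TRUE`).
#' @param direction `"both"` (default), `"forward"` or `"backward"`.
#' @param data optional data.frame for character `y`/`X_candidates`.
#' @return list with `fit` (an [fit_effect_model()] result on the selected
#'   predictors), `selected` (character vector), and `trace` (data.frame of
#'   step, move, term, AIC).
#' @export
stepwise_select <- function(y, X_candidates, standardize = TRUE,
                            direction = c("both", "forward", "backward"),
                            data = NULL) {
  direction <- match.arg(direction)
  if (is.character(y)) { stopifnot(!is.null(data)); yname <- y; y <- data[[y]] }
  else yname <- "y"
  if (is.character(X_candidates)) {
    stopifnot(!is.null(data))
    X_candidates <- data[, X_candidates, drop = FALSE]
  }
  X <- as.data.frame(X_candidates)
  if (ncol(X) == 0) {
    fit <- fit_effect_model(y, X, standardize_response = standardize)
    return(list(fit = fit, selected = character(0),
                trace = data.frame(step = 0L, move = "init",
                                   term = "(intercept-only)", aic = fit$aic)))
  }
  keep <- stats::complete.cases(cbind(y, X))
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (standardize) {
    X <- as.data.frame(lapply(seq_along(X), function(j)
      as.numeric(rescale_two_sd(X[[j]], names(X)[j]))))
    names(X) <- names(X_candidates)
    y <- as.numeric(rescale_two_sd(y, yname))
  }

  start_full <- n > ncol(X) + 1
  if (!start_full)
    message("n <= p for the full model: starting forward from intercept-only")
  current <- if (start_full && direction != "forward") names(X) else character(0)

  aic_of <- function(terms) {
    f <- if (length(terms))
      stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
    else .y ~ 1
    stats::AIC(stats::lm(f, data = cbind(.y = y, X)))
  }
  cur_aic <- aic_of(current)
  trace <- data.frame(step = 0L, move = "init",
                      term = if (length(current)) paste(current, collapse = "+")
                             else "(intercept-only)",
                      aic = cur_aic, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    moves <- list()
    if (direction %in% c("both", "forward"))
      for (t in setdiff(names(X), current))
        moves[[length(moves) + 1L]] <- list(move = "add", term = t,
                                            terms = c(current, t))
    if (direction %in% c("both", "backward"))
      for (t in current)
        moves[[length(moves) + 1L]] <- list(move = "drop", term = t,
                                            terms = setdiff(current, t))
    if (!length(moves)) break
    aics <- vapply(moves, function(m) aic_of(m$terms), numeric(1))
    best <- which.min(aics)  # ties: first candidate in column order
    if (aics[best] >= cur_aic) break
    current <- moves[[best]]$terms
    cur_aic <- aics[best]
    step_i <- step_i + 1L
    trace <- rbind(trace, data.frame(step = step_i, move = moves[[best]]$move,
                                     term = moves[[best]]$term, aic = cur_aic))
  }
  fit <- fit_effect_model(y, X[, current, drop = FALSE],
                          standardize_response = FALSE)
  fit$response <- yname
  list(fit = fit, selected = current, trace = trace)
}
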