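#' @title Conservation-versus-distance regression models
#'
#' @description
#' The relationship between the normalized observation ratio and 16S
#' evolutionary distance is summarized by one of two nonlinear models:
#'
#' * one-phase exponential decay (3 parameters):
#'   `y(x) = plateau + (Y0 - plateau) * exp(-k * x)`
#' * sigmoidal dose-response, the four-parameter logistic evaluated in
#'   distance space: `y(x) = bottom + (top - bottom) / (1 + 10^((x - m) * h))`
#'
#' Both are fit by unweighted least squares (every observation carries the
#' same weight) via Levenberg-Marquardt with quantile-based initial values
#' and seeded random restarts. The fitted object carries the residual
#' variance and parameter covariance needed for 95 percent prediction
#' bands, which forecast the single next observation at a given distance —
#' the quantity of interest when placing an unsequenced isolate.
#'
#' @name conservation_models
NULL

model_spec <- function(model) {
  switch(model,
    decay = list(
      name = "decay", p = 3L, par_names = c("Y0", "plateau", "k"),
      f = function(x, th) th[2] + (th[1] - th[2]) * exp(-th[3] * x),
      # gradient wrt (Y0, plateau, k), one row per x
      g = function(x, th) {
        e <- exp(-th[3] * x)
        cbind(Y0 = e, plateau = 1 - e, k = -(th[1] - th[2]) * x * e)
      },
      bounds = function(x, y) list(lower = c(-Inf, -Inf, 0),
                                   upper = c(Inf, Inf, Inf)),
      init = function(x, y) {
        y0 <- y[which.min(x)]
        pl <- min(y)
        mid <- (y0 + pl) / 2
        xh <- x[which.min(abs(y - mid))]
        k <- if (xh > min(x)) log(2) / (xh - min(x)) else 1 / max(diff(range(x)), 1e-6)
        c(y0, pl, max(k, 1e-3))
      }),
    sigmoid = list(
      name = "sigmoid", p = 4L, par_names = c("top", "bottom", "m", "h"),
      f = function(x, th) th[2] + (th[1] - th[2]) / (1 + 10^((x - th[3]) * th[4])),
      g = function(x, th) {
        u <- 10^((x - th[3]) * th[4])
        den <- (1 + u)^2
        cbind(top = 1 / (1 + u), bottom = u / (1 + u),
              m = (th[1] - th[2]) * u * log(10) * th[4] / den,
              h = -(th[1] - th[2]) * u * log(10) * (x - th[3]) / den)
      },
      # plateaus are constrained to a window around the observed response
      # range: without data on a limb the 4PL top/bottom are otherwise
      # unidentifiable (an infinite ridge approximating pure exponential)
      bounds = function(x, y) {
        span <- max(diff(range(y)), 1e-6)
        rx <- max(diff(range(x)), 1e-6)
        list(lower = c(max(y) - 0.5 * span, min(y) - 2 * span,
                       min(x) - 2 * rx, -Inf),
             upper = c(max(y) + 2 * span, min(y) + 0.5 * span,
                       max(x) + 2 * rx, Inf))
      },
      init = function(x, y) {
        top <- max(y); bottom <- min(y)
        mid <- (top + bottom) / 2
        m <- x[which.min(abs(y - mid))]
        # h > 0 gives a falling curve; pick sign from the trend
        slope <- stats::coef(stats::lm(y ~ x))[2]
        h <- if (is.na(slope) || slope <= 0) 1 else -1
        h <- h * max(2 / max(diff(range(x)), 1e-6), 1)
        c(top, bottom, m, h)
      })
  )
}

extract_xy <- function(points, x = NULL, y = NULL) {
  if (is.data.frame(points)) {
    xx <- points[["distance"]] %||% points[["x"]]
    yy <- points[["ratio"]] %||% points[["y"]]
    if (is.null(xx) || is.null(yy)) {
      stop_input("points must have columns distance/ratio (or x/y)")
    }
    list(x = as.numeric(xx), y = as.numeric(yy))
  } else {
    list(x = as.numeric(points), y = as.numeric(x))
  }
}

fit_nonlinear <- function(x, y, model, restarts = 5L, seed = 1L,
                          ftol = 1e-10) {
  spec <- model_spec(model)
  n <- length(x)
  if (n != length(y)) stop_input("x and y lengths differ")
  if (length(unique(x)) < spec$p + 1L) {
    stop_input(model, " fit needs at least ", spec$p + 1L,
               " distinct x values")
  }
  cl <- match.call()
  # degenerate: constant response
  if (stats::var(y) == 0) {
    th <- switch(model, decay = c(y[1], y[1], 0), sigmoid = c(y[1], y[1], stats::median(x), 1))
    names(th) <- spec$par_names
    return(new_fit(model, spec, th, x, y, converged = TRUE,
                   degenerate = TRUE, call = cl))
  }
  bnd <- spec$bounds(x, y)
  th0 <- spec$init(x, y)
  starts <- list(th0)
  with_seed(seed, {
    for (i in seq_len(restarts)) {
      starts[[i + 1L]] <- th0 * stats::rlnorm(spec$p, 0, 0.3) +
        stats::rnorm(spec$p, 0, 0.05)
    }
  })
  best <- NULL
  best_any <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, bnd$lower + 1e-9), bnd$upper - 1e-9)
    res <- tryCatch(
      minpack.lm::nls.lm(par = st,
                         fn = function(th) y - spec$f(x, th),
                         lower = bnd$lower, upper = bnd$upper,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = 1e-12, maxiter = 1000,
                           maxfev = 5000)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4
    if (!ok) {
      # iteration cap hit: accept if a continuation run no longer reduces
      # the SS by more than the relative tolerance (flat valley / ridge)
      cont <- tryCatch(
        minpack.lm::nls.lm(par = res$par,
                           fn = function(th) y - spec$f(x, th),
                           lower = bnd$lower, upper = bnd$upper,
                           control = minpack.lm::nls.lm.control(
                             ftol = ftol, maxiter = 100)),
        error = function(e) NULL)
      if (!is.null(cont) &&
          res$deviance - cont$deviance <= ftol * max(res$deviance, 1e-300)) {
        res <- cont
        ok <- TRUE
      }
    }
    if (is.null(best_any) || res$deviance < best_any$deviance) best_any <- res
    if (ok && (is.null(best) || res$deviance < best$deviance)) best <- res
  }
  if (is.null(best)) {
    stop(errorCondition(
      paste0(model, " fit failed to converge",
             if (!is.null(best_any)) paste0(": ", best_any$message) else ""),
      class = c("transprot_fit_failure", "error"),
      best = if (!is.null(best_any))
        stats::setNames(best_any$par, spec$par_names) else NULL))
  }
  th <- stats::setNames(best$par, spec$par_names)
  new_fit(model, spec, th, x, y, converged = TRUE,
          degenerate = model == "decay" && th["k"] * max(x) < 1e-6,
          call = cl)
}

new_fit <- function(model, spec, th, x, y, converged, degenerate, call) {
  fitted <- spec$f(x, th)
  resid <- y - fitted
  n <- length(x); p <- spec$p
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  s2 <- if (n > p) ss_res / (n - p) else NA_real_
  J <- spec$g(x, th)
  jtj <- crossprod(J)
  covar <- tryCatch(s2 * solve(jtj), error = function(e) {
    sv <- svd(jtj)
    pos <- sv$d > max(sv$d) * 1e-12
    s2 * sv$v[, pos, drop = FALSE] %*%
      diag(1 / sv$d[pos], sum(pos)) %*% t(sv$u[, pos, drop = FALSE])
  })
  dimnames(covar) <- list(spec$par_names, spec$par_names)
  structure(list(model = model, coefficients = th,
                 data = data.frame(x = x, y = y),
                 fitted.values = fitted, residuals = resid,
                 ss_res = ss_res, r2 = r2, s2 = s2, n = n, p = p,
                 covariance = covar, converged = converged,
                 degenerate = degenerate, call = call),
            class = c(paste0(model, "_fit"), "conservation_fit"))
}

#' Fit a one-phase exponential decay to conservation points
#'
#' Fits `y(x) = plateau + (Y0 - plateau) * exp(-k * x)` by unweighted
#' nonlinear least squares, where `x` is 16S evolutionary distance and `y`
#' the normalized observation ratio. `Y0` is the ratio at distance zero,
#' `plateau` the asymptote retained at large distance, and `k >= 0` the
#' decay rate per distance unit.
#'
#' @param points A `conservation_profile` data frame (columns
#'   `distance`/`ratio`, or `x`/`y`), or a numeric vector of distances with
#'   ratios in `x`.
#' @param x Ratios when `points` is a numeric vector of distances.
#' @param restarts Number of seeded random restarts around the
#'   quantile-based initial values (default 5).
#' @param seed Seed for the restart perturbations.
#' @return An object of class `c("decay_fit", "conservation_fit")` with
#'   coefficients, `r2`, residual variance `s2`, parameter covariance and
#'   the usual methods ([predict.conservation_fit()], `summary`, `plot`,
#'   `coef`, `residuals`, `fitted`).
#' @seealso [fit_sigmoid()], [select_model()], [prediction_interval()]
#' @examples
#' x <- seq(0, 0.1, length.out = 8)
#' y <- 0.05 + 0.95 * exp(-40 * x)
#' fit <- fit_decay(data.frame(distance = x, ratio = y))
#' coef(fit)
#' @export
fit_decay <- function(points, x = NULL, restarts = 5L, seed = 1L) {
  xy <- extract_xy(points, x)
  if (length(unique(xy$x)) < 4L) {
    stop_input("decay fit needs at least 4 distinct distances")
  }
  fit_nonlinear(xy$x, xy$y, "decay", restarts = restarts, seed = seed)
}

#' Fit a sigmoidal dose-response model to conservation points
#'
#' Fits the four-parameter logistic in distance space,
#' `y(x) = bottom + (top - bottom) / (1 + 10^((x - m) * h))`: `top` and
#' `bottom` are the upper and lower plateaus, `m` the midpoint distance and
#' `h` the slope factor (`h > 0` falls with distance; a rising trend is
#' accommodated by `h < 0`).
#'
#' @inheritParams fit_decay
#' @return An object of class `c("sigmoid_fit", "conservation_fit")`.
#' @seealso [fit_decay()], [select_model()]
#' @export
fit_sigmoid <- function(points, x = NULL, restarts = 5L, seed = 1L) {
  xy <- extract_xy(points, x)
  if (length(unique(xy$x)) < 5L) {
    stop_input("sigmoid fit needs at least 5 distinct distances")
  }
  fit_nonlinear(xy$x, xy$y, "sigmoid", restarts = restarts, seed = seed)
}

#' @method coef conservation_fit
#' @export
coef.conservation_fit <- function(object, ...) object$coefficients

#' @export
fitted.conservation_fit <- function(object, ...) object$fitted.values

#' @method residuals conservation_fit
#' @export
residuals.conservation_fit <- function(object, ...) object$residuals

#' @export
df.residual.conservation_fit <- function(object, ...) object$n - object$p

#' @export
print.conservation_fit <- function(x, ...) {
  label <- switch(x$model, decay = "One-phase exponential decay",
                  sigmoid = "Sigmoidal dose-response (4-parameter logistic)")
  cat(label, "fit\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("n = %d, R2 = %.4f, residual SD = %.4g%s\n", x$n, x$r2,
              sqrt(x$s2), if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @method summary conservation_fit
#' @export
summary.conservation_fit <- function(object, ...) {
  se <- sqrt(diag(object$covariance))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = object$coefficients / se,
               `Pr(>|t|)` = 2 * stats::pt(abs(object$coefficients / se),
                                          object$n - object$p,
                                          lower.tail = FALSE))
  out <- list(model = object$model, coefficients = tab, r2 = object$r2,
              s2 = object$s2, n = object$n, p = object$p,
              degenerate = object$degenerate)
  class(out) <- "summary.conservation_fit"
  out
}

#' @export
print.summary.conservation_fit <- function(x, ...) {
  cat(sprintf("%s model, n = %d, %d parameters\n", x$model, x$n, x$p))
  stats::printCoefmat(x$coefficients)
  cat(sprintf("R2 = %.4f, residual variance = %.4g\n", x$r2, x$s2))
  if (x$degenerate) cat("Note: fit flagged degenerate\n")
  invisible(x)
}

#' Predict from a conservation fit, with optional intervals
#'
#' Evaluates the fitted curve at new distances. `interval = "confidence"`
#' gives the band for the mean curve; `interval = "prediction"` gives the
#' wider band expected to contain a single future observation — the 95
#' percent prediction index used to judge whether an isolate's point is
#' consistent with the panel relationship. Bands use the first-order delta
#' method: `se_conf^2 = g' C g` and `se_pred^2 = s2 + g' C g` with `g` the
#' parameter gradient at `x`, `C` the parameter covariance, and Student-t
#' quantiles on `n - p` degrees of freedom.
#'
#' @param object A `conservation_fit`.
#' @param newdata Numeric vector of distances, or a data frame with column
#'   `x` or `distance`. Defaults to the fitted distances.
#' @param interval `"none"`, `"confidence"` or `"prediction"`.
#' @param level Band level in (0, 1), default 0.95.
#' @param ... Unused.
#' @return A numeric vector (`interval = "none"`) or a matrix with columns
#'   `fit`, `lwr`, `upr`.
#' @export
predict.conservation_fit <- function(object, newdata = NULL,
                                     interval = c("none", "confidence",
                                                  "prediction"),
                                     level = 0.95, ...) {
  interval <- match.arg(interval)
  xnew <- if (is.null(newdata)) object$data$x
          else if (is.data.frame(newdata)) {
            as.numeric(newdata[["x"]] %||% newdata[["distance"]])
          } else as.numeric(newdata)
  spec <- model_spec(object$model)
  yhat <- as.numeric(spec$f(xnew, object$coefficients))
  if (interval == "none") return(yhat)
  if (level <= 0 || level >= 1) stop_input("level must be in (0, 1)")
  if (object$degenerate || !object$converged || !is.finite(object$s2)) {
    stop_input("interval undefined for a degenerate or unconverged fit")
  }
  g <- spec$g(xnew, object$coefficients)
  var_mean <- rowSums((g %*% object$covariance) * g)
  var_mean <- pmax(var_mean, 0)
  se <- as.numeric(if (interval == "confidence") sqrt(var_mean)
                   else sqrt(object$s2 + var_mean))
  tq <- stats::qt(1 - (1 - level) / 2, object$n - object$p)
  cbind(fit = yhat, lwr = yhat - tq * se, upr = yhat + tq * se)
}

#' Prediction interval at one or more distances
#'
#' Convenience wrapper around [predict.conservation_fit()] with
#' `interval = "prediction"`.
#'
#' @param fit A converged `conservation_fit`.
#' @param x Distances.
#' @param level Interval level (default 0.95).
#' @return Matrix with columns `lwr`, `upr` (one row per `x`).
#' @export
prediction_interval <- function(fit, x, level = 0.95) {
  m <- predict(fit, newdata = x, interval = "prediction", level = level)
  m[, c("lwr", "upr"), drop = FALSE]
}

#' Prediction band over a distance grid
#'
#' @param fit A converged `conservation_fit`.
#' @param x Grid of distances; defaults to 101 points spanning the fitted
#'   range.
#' @param level Band level (default 0.95).
#' @return Data frame of class `prediction_band` with columns `x`, `center`,
#'   `lower`, `upper` and attribute `level`.
#' @export
prediction_band <- function(fit, x = NULL, level = 0.95) {
  if (is.null(x)) {
    r <- range(fit$data$x)
    x <- seq(r[1], r[2], length.out = 101L)
  }
  m <- predict(fit, newdata = x, interval = "prediction", level = level)
  structure(data.frame(x = x, center = m[, "fit"], lower = m[, "lwr"],
                       upper = m[, "upr"]),
            class = c("prediction_band", "data.frame"), level = level)
}

#' Plot a conservation fit
#'
#' Points, fitted curve and (optionally) the hashed prediction band, in the
#' style of a conservation-versus-distance figure.
#'
#' @param x A `conservation_fit`.
#' @param band Draw the prediction band (default `TRUE`; skipped for
#'   degenerate fits).
#' @param level Band level.
#' @param ... Passed to [graphics::plot()].
#' @return The fit, invisibly.
#' @method plot conservation_fit
#' @export
plot.conservation_fit <- function(x, band = TRUE, level = 0.95, ...) {
  d <- x$data
  grid <- seq(min(d$x), max(d$x), length.out = 200L)
  spec <- model_spec(x$model)
  curve_y <- spec$f(grid, x$coefficients)
  ylim <- range(d$y, curve_y)
  if (band && !x$degenerate) {
    b <- prediction_band(x, grid, level)
    ylim <- range(ylim, b$lower, b$upper)
  }
  graphics::plot(d$x, d$y, xlab = "16S evolutionary distance",
                 ylab = "Normalized observation ratio", ylim = ylim,
                 pch = 19, ...)
  if (band && !x$degenerate) {
    graphics::polygon(c(b$x, rev(b$x)), c(b$lower, rev(b$upper)),
                      density = 20, angle = 45, border = NA,
                      col = grDevices::grey(0.4))
  }
  graphics::lines(grid, curve_y, lwd = 2)
  invisible(x)
}

#' Select the best regression model
#'
#' Adjudicates between candidate fits of the same points: pairs differing
#' in parameter count are compared by the extra-sum-of-squares F-test at
#' `alpha` (the more complex model is adopted only when it significantly
#' reduces the residual sum of squares); pairs with equal counts by
#' adjusted R2; ties go to the model with fewer parameters.
#'
#' @param fits List of `conservation_fit` objects on identical points.
#' @param alpha Significance level for the F-test (default 0.05).
#' @return An object of class `model_selection`: list with `best` (the
#'   chosen fit) and `report` (data frame of pairwise comparisons with F
#'   statistics and p-values).
#' @export
select_model <- function(fits, alpha = 0.05) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "conservation_fit")))
  d0 <- fits[[1]]$data
  for (f in fits) {
    if (!isTRUE(all.equal(f$data[order(f$data$x, f$data$y), ],
                          d0[order(d0$x, d0$y), ], check.attributes = FALSE))) {
      stop_input("fits were not computed on identical points")
    }
  }
  fits <- fits[order(vapply(fits, `[[`, integer(1), "p"))]
  best <- fits[[1]]
  report <- NULL
  adj_r2 <- function(f) 1 - (1 - f$r2) * (f$n - 1) / (f$n - f$p)
  for (f in fits[-1]) {
    if (f$p != best$p) {
      simple <- if (f$p > best$p) best else f
      complex <- if (f$p > best$p) f else best
      dfn <- complex$p - simple$p
      dfd <- complex$n - complex$p
      Fstat <- ((simple$ss_res - complex$ss_res) / dfn) /
        (complex$ss_res / dfd)
      pval <- if (Fstat <= 0) 1 else stats::pf(Fstat, dfn, dfd,
                                               lower.tail = FALSE)
      chosen <- if (is.finite(pval) && pval < alpha) complex else simple
      report <- rbind(report, data.frame(
        simpler = simple$model, complex = complex$model,
        F = max(Fstat, 0), df1 = dfn, df2 = dfd, p_value = pval,
        chosen = chosen$model, stringsAsFactors = FALSE))
      best <- chosen
    } else {
      a1 <- adj_r2(best); a2 <- adj_r2(f)
      chosen <- if (!is.na(a2) && !is.na(a1) && a2 > a1) f else best
      report <- rbind(report, data.frame(
        simpler = best$model, complex = f$model, F = NA_real_,
        df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
        chosen = chosen$model, stringsAsFactors = FALSE))
      best <- chosen
    }
  }
  structure(list(best = best, report = report), class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Selected model:", x$best$model, "\n")
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Write a fit report as JSON
#'
#' Parameters, covariance, fit statistics and (when supplied) the model
#' selection table.
#'
#' @param fit A `conservation_fit`.
#' @param path Output path.
#' @param selection Optional [select_model()] result.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, selection = NULL) {
  out <- list(model = fit$model, coefficients = as.list(fit$coefficients),
              r2 = fit$r2, s2 = fit$s2, n = fit$n, p = fit$p,
              covariance = fit$covariance, converged = fit$converged,
              degenerate = fit$degenerate)
  if (!is.null(selection)) out$model_selection <- selection$report
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
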