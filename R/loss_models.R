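#' Fit a livestock mortality loss model
#'
#' Fits one of five regression models mapping a standardized forage index
#' (z-score) to seasonal livestock mortality:
#'
#' * `"lm"`  — ordinary least squares on all observations,
#'   `M = b0 + b1 z`.
#' * `"lm0"` — OLS restricted to observations with `z < 0` (mortality
#'   responds to forage scarcity only below the climatological mean).
#' * `"lm5"` — OLS restricted to `z < -0.5`.
#' * `"sm"`  — segmented (continuous piecewise-linear) regression
#'   `M = b0 + b1 z + b2 (z - psi) 1[z > psi]` with the breakpoint `psi`
#'   estimated by profiling the residual sum of squares over candidate
#'   breakpoints (all admissible observed z values) followed by a local
#'   continuous refinement; ties broken toward the smallest `psi`.
#' * `"qr"`  — linear conditional quantile regression at quantile `tau`
#'   (default 0.77), minimizing the pinball (check) loss.  Fitted by
#'   iteratively reweighted least squares with a shrinking smoothing
#'   parameter, then polished onto the exact vertex optimum by enumerating
#'   lines through pairs of near-active observations.
#'
#' @param formula A two-sided formula `mortality ~ z`.
#' @param data A data frame containing the variables of `formula`.
#' @param kind Model kind; one of `"lm"`, `"lm0"`, `"lm5"`, `"sm"`, `"qr"`.
#' @param cutoff Restriction cutoff for truncated fits.  Preset to 0 for
#'   `"lm0"` and -0.5 for `"lm5"`; may be supplied with `kind = "lm"` to
#'   fit on an arbitrary subset `z < cutoff` (use `Inf` for no
#'   restriction).
#' @param tau Quantile level for `kind = "qr"`, in (0, 1).
#' @param min_seg Minimum observations on each side of a candidate
#'   breakpoint (`"sm"` only); identifiability of two slopes needs at
#'   least 3.
#' @return An object of class `"loss_model"` with components
#'   `coefficients` (named: `intercept`, `slope`, and for `"sm"`
#'   `slope_change`), `psi` (breakpoint, `"sm"` only), `cutoff`, `tau`,
#'   `residuals`, `fitted`, `sse`, `n_fit`, and for `"qr"` the achieved
#'   pinball `objective`.  Methods: [predict.loss_model()], `coef`,
#'   `residuals`, `fitted`, `print`, `summary`.
#' @examples
#' d <- simulate_seasons(scenario_config(seed = 1))
#' d$z <- attr(d, "latent_z")
#' fit <- loss_model(mortality ~ z, d, kind = "sm")
#' coef(fit)
#' @export
loss_model <- function(formula, data,
                       kind = c("lm", "lm0", "lm5", "sm", "qr"),
                       cutoff = NULL, tau = 0.77, min_seg = 3L) {
  kind <- match.arg(kind)
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  if (ncol(mf) != 2L) stop("loss_model expects exactly one predictor")
  M <- as.numeric(stats::model.response(mf))
  z <- as.numeric(mf[[2L]])
  if (any(M < 0 | M > 1)) stop("mortality must lie in [0, 1]")
  if (length(M) < 3L) stop("need at least 3 observations")

  cutoff <- switch(kind, lm0 = 0, lm5 = -0.5,
                   if (is.null(cutoff)) Inf else cutoff)
  if (kind == "qr" && (tau <= 0 || tau >= 1)) stop("tau must be in (0, 1)")

  fit <- switch(kind,
    lm  = if (is.finite(cutoff)) .fit_trunc(z, M, cutoff) else .fit_ols(z, M),
    lm0 = .fit_trunc(z, M, cutoff),
    lm5 = .fit_trunc(z, M, cutoff),
    sm  = .fit_segmented(z, M, min_seg = as.integer(min_seg)),
    qr  = .fit_quantile(z, M, tau))

  structure(c(fit, list(
    kind = kind, cutoff = cutoff, tau = if (kind == "qr") tau,
    min_seg = if (kind == "sm") as.integer(min_seg),
    formula = formula, z_range = range(z), call = match.call()
  )), class = "loss_model")
}

.ols_core <- function(X, y) {
  f <- stats::lm.fit(X, y)
  if (f$rank < ncol(X)) stop("degenerate design (collinear regressors)")
  f
}

.fit_ols <- function(z, M) {
  if (length(z) < 3L) stop("need at least 3 observations")
  if (stats::sd(z) == 0) stop("degenerate design: predictor is constant")
  f <- .ols_core(cbind(1, z), M)
  list(coefficients = c(intercept = unname(f$coefficients[1L]),
                        slope = unname(f$coefficients[2L])),
       residuals = unname(f$residuals), fitted = unname(f$fitted.values),
       sse = sum(f$residuals^2), n_fit = length(M))
}

.fit_trunc <- function(z, M, cutoff) {
  sel <- z < cutoff
  if (sum(sel) < 3L) {
    stop("only ", sum(sel), " observation(s) with z < ", cutoff,
         "; need at least 3")
  }
  .fit_ols(z[sel], M[sel])
}

# Profile SSE of the continuous two-slope model over a breakpoint psi.
.seg_sse <- function(psi, z, M) {
  X <- cbind(1, z, pmax(z - psi, 0))
  f <- stats::lm.fit(X, M)
  if (f$rank < 3L) return(Inf)
  sum(f$residuals^2)
}

.fit_segmented <- function(z, M, min_seg = 3L) {
  n <- length(z)
  if (n < 2L * min_seg) stop("need at least ", 2L * min_seg,
                             " observations for a segmented fit")
  zs <- sort(unique(z))
  # admissible psi: >= min_seg points at or below and strictly above
  nb <- vapply(zs, function(p) sum(z <= p), integer(1))
  na_ <- n - nb
  cand <- zs[nb >= min_seg & na_ >= min_seg]
  if (length(cand) == 0L) stop("no admissible breakpoint candidate")
  prof <- vapply(cand, .seg_sse, numeric(1), z = z, M = M)
  if (all(!is.finite(prof))) stop("no admissible breakpoint candidate")
  i <- which.min(prof)  # first minimum -> smallest psi on ties
  psi <- cand[i]; best <- prof[i]
  # local continuous refinement between the neighbouring candidates
  lo <- if (i > 1L) cand[i - 1L] else cand[i]
  hi <- if (i < length(cand)) cand[i + 1L] else cand[i]
  if (hi > lo) {
    opt <- stats::optimize(.seg_sse, c(lo, hi), z = z, M = M, tol = 1e-10)
    if (is.finite(opt$objective) &&
        (opt$objective < best - 1e-12 ||
         (opt$objective <= best + 1e-12 && opt$minimum < psi))) {
      psi <- opt$minimum; best <- opt$objective
    }
  }
  f <- .ols_core(cbind(1, z, pmax(z - psi, 0)), M)
  list(coefficients = c(intercept = unname(f$coefficients[1L]),
                        slope = unname(f$coefficients[2L]),
                        slope_change = unname(f$coefficients[3L])),
       psi = psi,
       residuals = unname(f$residuals), fitted = unname(f$fitted.values),
       sse = sum(f$residuals^2), n_fit = n)
}

#' Pinball (check) loss
#'
#' `sum(u * (tau - (u < 0)))` over residuals `u`; the objective minimized
#' by conditional quantile regression.
#'
#' @param u Residuals (observed minus fitted).
#' @param tau Quantile level in (0, 1).
#' @return The summed check loss.
#' @export
pinball_loss <- function(u, tau) sum(u * (tau - (u < 0)))

.fit_quantile <- function(z, M, tau, maxit = 200L) {
  n <- length(z)
  if (n < 10L) stop("quantile fit needs at least 10 observations")
  if (stats::sd(z) == 0) stop("degenerate design: predictor is constant")
  X <- cbind(1, z)
  b <- stats::lm.fit(X, M)$coefficients
  delta <- 1e-2
  converged <- FALSE
  for (it in seq_len(maxit)) {
    u <- M - drop(X %*% b)
    w <- ifelse(u >= 0, tau, 1 - tau) / pmax(abs(u), delta)
    bn <- stats::lm.wfit(X, M, w)$coefficients
    step <- max(abs(bn - b)); b <- bn
    if (step < 1e-11) {
      if (delta <= 1e-6) { converged <- TRUE; break }
      delta <- max(delta / 10, 1e-6)
    }
  }
  u <- M - drop(X %*% b)
  obj <- pinball_loss(u, tau)
  # Vertex polish: the optimum interpolates two observations; search lines
  # through pairs of the observations closest to the smoothed solution.
  m <- min(n, 40L)
  idx <- order(abs(u))[seq_len(m)]
  best <- list(b = b, obj = obj)
  for (a in seq_len(m - 1L)) {
    for (bb in seq((a + 1L), m)) {
      i <- idx[a]; j <- idx[bb]
      if (z[i] == z[j]) next
      s <- (M[i] - M[j]) / (z[i] - z[j])
      b0 <- M[i] - s * z[i]
      o <- pinball_loss(M - b0 - s * z, tau)
      if (o < best$obj - 1e-14) best <- list(b = c(b0, s), obj = o)
    }
  }
  if (!converged && best$obj >= obj - 1e-14 && it >= maxit) {
    stop("quantile regression failed to converge in ", maxit,
         " iterations (last step ", format(step), ")")
  }
  b <- best$b
  u <- M - drop(X %*% b)
  list(coefficients = c(intercept = unname(b[1L]), slope = unname(b[2L])),
       residuals = u, fitted = M - u,
       sse = sum(u^2), objective = best$obj, n_fit = n)
}

#' Predict mortality from a fitted loss model
#'
#' Evaluates the fitted linear or piecewise-linear mortality response at
#' new index z-scores and (by default) clips the result to the admissible
#' mortality range `[0, 1]`.  Cutoff-restricted models (`lm0`, `lm5`)
#' extrapolate their fitted line over the full z range; their predictions
#' above the cutoff sit below any realistic payout trigger, so payouts are
#' insensitive to this choice.
#'
#' @param object A `"loss_model"`.
#' @param newdata Data frame containing the predictor variable, or a
#'   numeric vector of z values.
#' @param clip Logical; clip predictions into `[0, 1]` (the default; raw
#'   linear predictions with `clip = FALSE` are the regression-diagnostic
#'   convention).
#' @param ... Unused.
#' @return Numeric vector of predicted mortality fractions.
#' @export
predict.loss_model <- function(object, newdata, clip = TRUE, ...) {
  z <- if (is.numeric(newdata)) {
    newdata
  } else {
    v <- all.vars(object$formula[[3L]])
    if (!v %in% names(newdata)) stop("no column '", v, "' in newdata")
    as.numeric(newdata[[v]])
  }
  b <- object$coefficients
  p <- b[["intercept"]] + b[["slope"]] * z
  if (object$kind == "sm") {
    p <- p + b[["slope_change"]] * pmax(z - object$psi, 0)
  }
  if (clip) p <- pmin(pmax(p, 0), 1)
  unname(p)
}

#' Goodness of fit of a loss model on an evaluation set
#'
#' Computes the coefficient of determination and root-mean-square error of
#' the model's predictions on a supplied evaluation set:
#' `R^2 = 1 - SSE / SST` with SST about the mean observed mortality, and
#' `RMSE = sqrt(SSE / n)`.  By default the full evaluation set is used
#' even for cutoff-restricted models, so that all model kinds are compared
#' on a common footing; `subset_only = TRUE` restricts to `z < cutoff`.
#' Predictions are clipped to the admissible mortality range `[0, 1]`
#' (the model's operational output; the cutoff-restricted models
#' extrapolate below zero in good seasons otherwise); `clip = FALSE`
#' evaluates the raw linear predictions instead.
#'
#' @param model A `"loss_model"`.
#' @param data Evaluation data frame containing the model variables.
#' @param subset_only Logical; evaluate only below the model's cutoff.
#' @param clip Logical; evaluate clipped predictions (default `TRUE`).
#' @return A list with `r_squared`, `rmse`, and `n`.
#' @export
goodness_of_fit <- function(model, data, subset_only = FALSE,
                            clip = TRUE) {
  v <- all.vars(model$formula)
  M <- as.numeric(data[[v[1L]]])
  z <- as.numeric(data[[v[2L]]])
  keep <- !is.na(M) & !is.na(z)
  M <- M[keep]; z <- z[keep]
  if (subset_only && is.finite(model$cutoff)) {
    sel <- z < model$cutoff
    M <- M[sel]; z <- z[sel]
  }
  if (length(M) < 2L) stop("evaluation set too small")
  pred <- predict(model, z, clip = clip)
  sse <- sum((M - pred)^2)
  sst <- sum((M - mean(M))^2)
  if (sst == 0) stop("zero variance in observed mortality (SST = 0)")
  list(r_squared = 1 - sse / sst, rmse = sqrt(sse / length(M)),
       n = length(M))
}

#' @export
coef.loss_model <- function(object, ...) object$coefficients

#' @export
residuals.loss_model <- function(object, ...) object$residuals

#' @export
fitted.loss_model <- function(object, ...) object$fitted

#' @export
print.loss_model <- function(x, digits = 4, ...) {
  lab <- switch(x$kind,
    lm = "linear", lm0 = "linear, z < 0", lm5 = "linear, z < -0.5",
    sm = "segmented", qr = sprintf("quantile (tau = %g)", x$tau))
  cat("Mortality loss model [", x$kind, ": ", lab, "]\n", sep = "")
  print(round(x$coefficients, digits))
  if (x$kind == "sm") cat("breakpoint psi:", round(x$psi, digits), "\n")
  cat("n =", x$n_fit, " SSE =", format(x$sse, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.loss_model <- function(object, ...) {
  out <- list(kind = object$kind, coefficients = object$coefficients,
              psi = object$psi, tau = object$tau, n_fit = object$n_fit,
              sse = object$sse,
              residual_sd = stats::sd(object$residuals))
  class(out) <- "summary.loss_model"
  out
}

#' @export
print.summary.loss_model <- function(x, ...) {
  cat("Loss model (", x$kind, "), n = ", x$n_fit, "\n", sep = "")
  print(x$coefficients)
  if (!is.null(x$psi)) cat("psi =", x$psi, "\n")
  cat("SSE =", x$sse, "; residual sd =", x$residual_sd, "\n")
  invisible(x)
}
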