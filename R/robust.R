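#' Tukey bisquare rho function (normalised to max 1)
#'
#' The bisquare (biweight) rho function used throughout the robust trend
#' fits, scaled so that `rho(u) = 1` for `|u| >= c`. With this
#' normalisation the M-scale consistency constant for a 50% breakdown
#' point is 0.5.
#'
#' @param u numeric vector of scaled residuals.
#' @param c tuning constant (> 0).
#' @return numeric vector of the same length as `u`, in `[0, 1]`.
#' @keywords internal
bisquare_rho <- function(u, c) {
  v2 <- (u * u) / (c * c)
  v2[v2 > 1] <- 1
  1 - (1 - v2)^3
}

#' @rdname bisquare_rho
#' @keywords internal
bisquare_psi <- function(u, c) {
  out <- u * (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

#' @rdname bisquare_rho
#' @keywords internal
bisquare_psi_prime <- function(u, c) {
  v2 <- (u / c)^2
  out <- (1 - v2) * (1 - 5 * v2)
  out[abs(u) > c] <- 0
  out
}

#' @rdname bisquare_rho
#' @keywords internal
bisquare_wgt <- function(u, c) {
  out <- (1 - (u / c)^2)^2
  out[abs(u) > c] <- 0
  out
}

# E[rho_c(Z)] for Z ~ N(0,1), the M-scale consistency constant.
# Memoised per tuning constant; c = 1.548 gives ~0.5 (50% breakdown).
.mscale_delta_cache <- new.env(parent = emptyenv())

mscale_delta <- function(c) {
  key <- format(c, digits = 15)
  if (!is.null(.mscale_delta_cache[[key]])) {
    return(.mscale_delta_cache[[key]])
  }
  val <- stats::integrate(function(z) bisquare_rho(z, c) * stats::dnorm(z),
    -Inf, Inf,
    rel.tol = 1e-12
  )$value
  .mscale_delta_cache[[key]] <- val
  val
}

#' Weighted M-scale of residuals
#'
#' Solves `sum(w * rho(r / s)) / sum(w) = delta` for `s` by the standard
#' fixed-point iteration. Case weights multiply each point's rho
#' contribution, so doubling all weights leaves the scale unchanged.
#'
#' @param r numeric residuals.
#' @param w nonnegative case weights (recycled if length 1).
#' @param c bisquare tuning constant.
#' @param delta consistency constant; defaults to `E[rho_c(Z)]` under a
#'   standard normal, making the scale Fisher-consistent at the Gaussian.
#' @param tol relative convergence tolerance.
#' @return the scale estimate (0 for an exact fit).
#' @keywords internal
m_scale <- function(r, w = 1, c = 1.548, delta = mscale_delta(c), tol = 1e-12) {
  w <- rep_len(w, length(r))
  sw <- sum(w)
  s <- weighted_median(abs(r), w) / 0.6745
  if (s <= 0) {
    # more than half the weight sits on zero residuals: exact fit
    if (sum(w * (r != 0)) / sw <= delta) {
      return(0)
    }
    s <- mean(abs(r)[r != 0])
  }
  for (i in 1:200) {
    s_new <- s * sqrt(sum(w * bisquare_rho(r / s, c)) / (delta * sw))
    if (!is.finite(s_new) || s_new <= 0) {
      return(0)
    }
    done <- abs(s_new - s) <= tol * s
    s <- s_new
    if (done) break
  }
  s
}

# weighted median (lower weighted median; deterministic tie-break)
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Settings for the robust trend fit
#'
#' @param s_tuning_c bisquare tuning constant for the S-step. The default
#'   1.548 gives a 50% breakdown point.
#' @param m_tuning_c bisquare tuning constant for the efficiency M-step.
#'   The default 4.685 gives 95% efficiency at the Gaussian model.
#' @param n_subsamples number of random 2-point bases for the S-step when
#'   the sample is too large to enumerate all pairs (n > 60).
#' @param max_iter maximum iterations for the M-step.
#' @param tol relative convergence tolerance on the coefficients.
#' @param ci_level confidence level for slope intervals.
#' @param seed integer seed used only when random subsampling is needed;
#'   fits on n <= 60 points are fully deterministic regardless.
#' @return a list of class `robust_settings`.
#' @export
#' @examples
#' robust_settings(ci_level = 0.9)
robust_settings <- function(s_tuning_c = 1.548, m_tuning_c = 4.685,
                            n_subsamples = 3000, max_iter = 200,
                            tol = 1e-10, ci_level = 0.95, seed = 1L) {
  stopifnot(
    s_tuning_c > 0, m_tuning_c > 0, n_subsamples >= 1,
    max_iter >= 1, tol > 0, ci_level > 0, ci_level < 1
  )
  structure(
    list(
      s_tuning_c = s_tuning_c, m_tuning_c = m_tuning_c,
      n_subsamples = as.integer(n_subsamples),
      max_iter = as.integer(max_iter), tol = tol,
      ci_level = ci_level, seed = as.integer(seed)
    ),
    class = "robust_settings"
  )
}

#' Map a confidence rank to a regression case weight
#'
#' Abundance estimates carry a 1-6 confidence rank (1 = lowest
#' confidence, 6 = highest) that combines reported quantitative error
#' with qualitative source reliability. Ranks enter the trend regressions
#' as case weights through the linear map `rank / 6`, so the most
#' trusted estimates get weight 1.
#'
#' @param acid_rank integer vector with values in 1..6.
#' @return numeric weights in (0, 1].
#' @export
#' @examples
#' acid_to_weight(c(1, 3, 6))
acid_to_weight <- function(acid_rank) {
  if (any(!is.finite(acid_rank)) ||
    any(acid_rank < 1 | acid_rank > 6 | acid_rank != round(acid_rank))) {
    stop("acid_rank must be an integer in 1..6", call. = FALSE)
  }
  acid_rank / 6
}

#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' Abundances (or log abundances) are standardized before the trend fit
#' so that slope estimates are comparable across populations of very
#' different absolute size.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return vector with attributes `center` (mean) and `scale` (sample SD).
#' @export
#' @examples
#' standardize(c(1, 2, 3))
standardize <- function(values) {
  if (length(values) < 2 || !any(is.finite(values))) {
    stop("standardize() needs at least two finite values", call. = FALSE)
  }
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) {
    stop("degenerate input: values are constant, cannot standardize",
      call. = FALSE
    )
  }
  m <- mean(values)
  structure((values - m) / s, center = m, scale = s)
}

# S-step: weighted high-breakdown (intercept, slope, scale) minimising the
# weighted M-scale of residuals, initialised from 2-point bases.
s_step <- function(x, y, w, settings) {
  n <- length(x)
  c_s <- settings$s_tuning_c
  # degrees-of-freedom correction: the candidate line already
  # interpolates p = 2 points, so consistency uses (n - 2)/n
  delta <- mscale_delta(c_s) * (n - 2) / n

  if (n <= 60) {
    pairs <- utils::combn(n, 2L)
  } else {
    pairs <- with_local_seed(settings$seed, {
      matrix(
        replicate(settings$n_subsamples, sample.int(n, 2L)),
        nrow = 2L
      )
    })
  }
  dx <- x[pairs[2L, ]] - x[pairs[1L, ]]
  keep <- abs(dx) > 0
  if (!any(keep)) {
    stop("degenerate predictor: all candidate point pairs share one year",
      call. = FALSE
    )
  }
  pairs <- pairs[, keep, drop = FALSE]
  dx <- dx[keep]
  slope <- (y[pairs[2L, ]] - y[pairs[1L, ]]) / dx
  intercept <- y[pairs[1L, ]] - slope * x[pairs[1L, ]]

  # residual matrix: candidates x points, M-scale iterated for all
  # candidates at once
  res <- outer(intercept, rep(1, n)) + outer(slope, x) # fitted
  res <- -sweep(res, 2L, y) # y - fitted
  sw <- sum(w)
  # rough initial scale per candidate; the winner is re-solved exactly
  s <- as.vector(abs(res) %*% w) / (sw * 0.7979)
  zero <- s <= 0
  if (any(zero)) {
    # candidate interpolates every point exactly
    k <- which(zero)[1L]
    return(list(
      intercept = intercept[k], slope = slope[k], scale = 0, exact = TRUE
    ))
  }
  for (i in 1:25) {
    rho_sum <- as.vector(bisquare_rho(res / s, c_s) %*% w)
    s_new <- s * sqrt(rho_sum / (delta * sw))
    done <- max(abs(s_new - s) / s) < 1e-8
    s <- s_new
    if (done) break
  }
  k <- which.min(s)
  s[k] <- m_scale(res[k, ], w, c_s, delta)
  best <- list(intercept = intercept[k], slope = slope[k], scale = s[k])

  # local refinement of the best candidate: IRWLS steps at the S tuning
  # constant, recomputing the M-scale each step, which can only lower it
  beta <- c(best$intercept, best$slope)
  s_cur <- best$scale
  X <- cbind(1, x)
  for (i in 1:50) {
    r <- y - X %*% beta
    if (s_cur <= 0) break
    ww <- w * bisquare_wgt(as.vector(r) / s_cur, c_s)
    if (sum(ww > 0) < 2) break
    fit <- stats::lm.wfit(X, y, ww)
    beta_new <- fit$coefficients
    if (any(!is.finite(beta_new))) break
    r_new <- y - X %*% beta_new
    s_new <- m_scale(as.vector(r_new), w, c_s, delta)
    if (s_new > s_cur) break
    conv <- max(abs(beta_new - beta)) <= 1e-10 * max(1, abs(beta[2]))
    beta <- beta_new
    s_cur <- s_new
    if (conv) break
  }
  list(intercept = beta[1], slope = beta[2], scale = s_cur, exact = s_cur <= 0)
}

#' Weighted high-breakdown robust line fit (MM-type)
#'
#' Two-stage estimator of an abundance trend line. Stage one (S-step)
#' finds a high-breakdown estimate of intercept, slope and residual scale
#' by minimising the weighted bisquare M-scale of residuals over 2-point
#' candidate bases (exhaustive for n <= 60, seeded random subsampling
#' otherwise) followed by local reweighted refinement. Stage two (M-step)
#' refines the coefficients by iteratively reweighted least squares at a
#' high-efficiency tuning constant with the S-scale held fixed. Case
#' weights (from the confidence ranks) multiply each point's rho
#' contribution in both stages.
#'
#' Standard errors come from the asymptotic sandwich covariance of the
#' M-step with a small-sample `n / (n - 2)` correction; confidence
#' intervals and p-values use a Student-t reference with `n - 2` degrees
#' of freedom, which keeps the empirical type-I rate near nominal at the
#' short series lengths typical of abundance surveys. The
#' robust coefficient of determination is
#' `1 - mscale(residuals)^2 / mscale(centered response)^2`, where the
#' response is centered at a robust (intercept-only) location fit.
#'
#' @param x numeric predictor (survey years).
#' @param y numeric response (standardized abundance or log abundance).
#' @param w positive case weights, one per point (see [acid_to_weight()]).
#' @param settings a [robust_settings()] object.
#' @return an object of class `trend_fit`: list with `slope`, `intercept`,
#'   `se`, `ci` (length-2), `t_value`, `p_value`, `r_squared`, `scale`,
#'   `n_points`, `converged`, `exact_fit`, `model_form` (filled by
#'   [fit_trend()]), `window`.
#' @export
#' @examples
#' x <- 2000:2010
#' y <- 2 * (x - 2005) + rnorm(11, sd = 0.1)
#' fit_robust(x, y, rep(1, 11))
fit_robust <- function(x, y, w = rep(1, length(x)),
                       settings = robust_settings()) {
  n <- length(x)
  if (length(y) != n || length(w) != n) {
    stop("x, y and w must have equal length", call. = FALSE)
  }
  if (n < 3) stop("robust fit needs at least 3 points", call. = FALSE)
  if (any(w <= 0)) stop("case weights must be positive", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("degenerate predictor: all observations share a single year",
      call. = FALSE
    )
  }

  s_est <- s_step(x, y, w, settings)
  c_m <- settings$m_tuning_c
  s <- s_est$scale
  X <- cbind(1, x)
  beta <- c(s_est$intercept, s_est$slope)
  converged <- TRUE

  if (s > 0) {
    # M-step: IRWLS at the efficiency tuning constant, scale fixed
    converged <- FALSE
    for (i in seq_len(settings$max_iter)) {
      r <- as.vector(y - X %*% beta)
      ww <- w * bisquare_wgt(r / s, c_m)
      if (sum(ww > 0) < 2) break
      fit <- stats::lm.wfit(X, y, ww)
      beta_new <- fit$coefficients
      if (any(!is.finite(beta_new))) break
      if (max(abs(beta_new - beta)) <=
        settings$tol * max(1, max(abs(beta)))) {
        beta <- beta_new
        converged <- TRUE
        break
      }
      beta <- beta_new
    }
  }

  r <- as.vector(y - X %*% beta)
  if (s > 0) {
    u <- r / s
    psi <- bisquare_psi(u, c_m)
    psi_p <- bisquare_psi_prime(u, c_m)
    A <- crossprod(X, X * (w * psi_p))
    B <- crossprod(X, X * (w * psi)^2)
    cov_ok <- all(is.finite(A)) && abs(det(A)) > 1e-300
    if (cov_ok) {
      Ai <- solve(A)
      V <- s^2 * (n / (n - 2)) * (Ai %*% B %*% t(Ai))
      se <- sqrt(pmax(diag(V), 0))[2]
    } else {
      se <- NA_real_
      converged <- FALSE
    }
  } else {
    se <- 0
  }

  slope <- unname(beta[2])
  df <- n - 2L
  z <- stats::qt(1 - (1 - settings$ci_level) / 2, df = df)
  if (is.na(se)) {
    ci <- c(NA_real_, NA_real_)
    t_value <- NA_real_
    p_value <- NA_real_
  } else if (se == 0) {
    ci <- c(slope, slope)
    t_value <- sign(slope) * Inf
    p_value <- 0
  } else {
    ci <- slope + c(-1, 1) * z * se
    t_value <- slope / se
    p_value <- 2 * stats::pt(-abs(t_value), df = df)
  }

  # robust R^2 against an intercept-only robust location fit, both
  # scales with matching degrees-of-freedom corrections
  c_s <- settings$s_tuning_c
  s_y <- m_scale(y - m_location(y, w, c_s), w,
    c = c_s, delta = mscale_delta(c_s) * (n - 1) / n
  )
  s_r <- if (s > 0) {
    m_scale(r, w, c = c_s, delta = mscale_delta(c_s) * (n - 2) / n)
  } else {
    0
  }
  r_squared <- if (s_y > 0) {
    min(max(1 - (s_r / s_y)^2, 0), 1)
  } else {
    NA_real_
  }

  structure(
    list(
      model_form = NA_character_,
      slope = slope, intercept = unname(beta[1]),
      se = unname(se), ci = unname(ci),
      t_value = unname(t_value), p_value = unname(p_value),
      r_squared = r_squared, scale = s,
      n_points = n, window = c(min(x), max(x)),
      converged = converged, exact_fit = s <= 0,
      response_center = NA_real_, response_scale = NA_real_,
      log_offset = 0, ci_level = settings$ci_level
    ),
    class = "trend_fit"
  )
}

# robust weighted location (intercept-only analogue of the line fit)
m_location <- function(y, w, c_s) {
  mu <- weighted_median(y, w)
  s <- m_scale(y - mu, w, c_s)
  if (s <= 0) {
    return(mu)
  }
  for (i in 1:100) {
    ww <- w * bisquare_wgt((y - mu) / s, c_s)
    if (sum(ww) <= 0) break
    mu_new <- sum(ww * y) / sum(ww)
    if (abs(mu_new - mu) <= 1e-12 * max(1, abs(mu))) {
      mu <- mu_new
      break
    }
    mu <- mu_new
  }
  mu
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Robust trend fit (", if (is.na(x$model_form)) "raw" else x$model_form,
    ")\n",
    sep = ""
  )
  cat(sprintf(
    "  slope %.6g  se %.3g  %g%% CI [%.6g, %.6g]\n",
    x$slope, x$se, 100 * x$ci_level, x$ci[1], x$ci[2]
  ))
  cat(sprintf(
    "  t %.3g  p %.3g  robust R^2 %.3f  n %d  window %.1f-%.1f\n",
    x$t_value, x$p_value, x$r_squared, x$n_points,
    x$window[1], x$window[2]
  ))
  if (!x$converged) cat("  (did not converge)\n")
  invisible(x)
}

#' Fit a population trend on a windowed series
#'
#' Fits the robust weighted regression of standardized (log) abundance on
#' survey year over the assessment window. For `model_form = "linear"`
#' the response is the standardized abundance; for `"loglinear"` it is
#' the standardized natural log of abundance. Zero abundances under the
#' log-linear form are handled by adding an offset of one individual to
#' the whole series (recorded in `log_offset`) so that extirpation years
#' are retained rather than dropped. Case weights come from each point's
#' confidence rank via [acid_to_weight()].
#'
#' An ineligible window (see [select_window()]) or a constant response
#' returns an `unknown_fit` sentinel carrying the reason, which
#' [classify_trend()] maps to the Unknown category.
#'
#' @param windowed a `windowed_series` from [select_window()].
#' @param model_form `"linear"` or `"loglinear"`.
#' @param settings a [robust_settings()] object.
#' @return a `trend_fit`, or an `unknown_fit` sentinel.
#' @export
fit_trend <- function(windowed, model_form = c("loglinear", "linear"),
                      settings = robust_settings()) {
  model_form <- match.arg(model_form)
  stopifnot(inherits(windowed, "windowed_series"))
  if (!windowed$eligible) {
    return(unknown_fit("ineligible", model_form, windowed))
  }
  pts <- windowed$points
  y_raw <- pts$abundance
  offset <- 0
  if (model_form == "loglinear") {
    if (any(y_raw < 0)) {
      return(unknown_fit("negative abundance", model_form, windowed))
    }
    if (any(y_raw == 0)) offset <- 1
    y_raw <- log(y_raw + offset)
  }
  if (length(unique(y_raw)) < 2 || stats::sd(y_raw) == 0) {
    return(unknown_fit("constant response", model_form, windowed))
  }
  y <- standardize(y_raw)
  fit <- fit_robust(pts$year, as.numeric(y),
    w = acid_to_weight(pts$acid_rank), settings = settings
  )
  fit$model_form <- model_form
  fit$window <- windowed$window
  fit$response_center <- attr(y, "center")
  fit$response_scale <- attr(y, "scale")
  fit$log_offset <- offset
  fit
}

unknown_fit <- function(reason, model_form, windowed = NULL) {
  structure(
    list(
      model_form = model_form, reason = reason,
      window = if (is.null(windowed)) c(NA_real_, NA_real_) else windowed$window,
      n_points = if (is.null(windowed)) 0L else nrow(windowed$points),
      converged = FALSE
    ),
    class = "unknown_fit"
  )
}

#' Back-transform a log-linear trend slope to a growth rate
#'
#' The log-linear fit regresses standardized log abundance on year; the
#' instantaneous per-year growth rate is the slope multiplied by the
#' sample SD of the log abundances (the standardization scale).
#'
#' @param fit a converged `trend_fit` with `model_form = "loglinear"`.
#' @return growth rate in 1/year.
#' @export
growth_rate <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"), identical(fit$model_form, "loglinear"))
  fit$slope * fit$response_scale
}

#' Compare the linear and log-linear robust fits by robust R-squared
#'
#' The model with the larger robust coefficient of determination wins;
#' when the two R-squared values differ by at most 0.01 the comparison is
#' reported as `"similar"` (with the log-linear model used downstream).
#' A non-converged or unknown fit loses to a converged one.
#'
#' @param fit_lin `trend_fit` (or `unknown_fit`) for the linear form.
#' @param fit_log `trend_fit` (or `unknown_fit`) for the log-linear form.
#' @return one of `"loglinear_better"`, `"linear_better"`, `"similar"`,
#'   `"unknown"`.
#' @export
compare_models <- function(fit_lin, fit_log) {
  ok_lin <- inherits(fit_lin, "trend_fit") && fit_lin$converged
  ok_log <- inherits(fit_log, "trend_fit") && fit_log$converged
  if (!ok_lin && !ok_log) {
    return("unknown")
  }
  if (!ok_lin) {
    return("loglinear_better")
  }
  if (!ok_log) {
    return("linear_better")
  }
  d <- fit_log$r_squared - fit_lin$r_squared
  if (is.na(d)) {
    return("unknown")
  }
  if (abs(d) <= 0.01) {
    return("similar")
  }
  if (d > 0) "loglinear_better" else "linear_better"
}

# evaluate an expression under a temporary RNG state, restoring the
# caller's .Random.seed afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
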