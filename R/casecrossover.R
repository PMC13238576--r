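#' Build a case-crossover design from stratum-days
#'
#' Expands the model formula into a design matrix (no intercept; the stratum
#' effect is conditioned out), groups rows by stratum, and drops the strata
#' that carry no information under conditioning: strata whose total count is
#' zero and strata whose covariate rows are all identical. Rows with missing
#' covariate values are excluded first (missing PM2.5 is not imputed).
#'
#' @param formula model formula, e.g.
#'   \code{count ~ exposure_level + holiday + pm25}.
#' @param data a \code{stratum_day} data frame (or any data frame with the
#'   formula's variables and a stratum identifier).
#' @param strata stratum identifier: a column name (character), a one-sided
#'   formula of stratum variables, or a vector of length \code{nrow(data)}.
#' @return list of class \code{ccx_design}: \code{y} counts, \code{X} design
#'   matrix, \code{stratum} factor, and \code{dropped} counts (rows with
#'   missing covariates, zero-total strata, covariate-invariant strata).
#' @export
build_strata <- function(formula, data, strata = "stratum") {
  if (nrow(data) == 0L) stop("empty input")
  sid <- if (inherits(strata, "formula")) {
    interaction(stats::model.frame(strata, data, na.action = NULL),
                drop = TRUE, sep = ":")
  } else if (is.character(strata) && length(strata) == 1L) {
    factor(data[[strata]])
  } else factor(strata)
  if (length(sid) != nrow(data)) stop("strata length must match data rows")
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ok <- stats::complete.cases(X) & !is.na(y)
  n_missing <- sum(!ok)
  y <- y[ok]; X <- X[ok, , drop = FALSE]; sid <- droplevels(sid[ok])
  if (any(y < 0) || any(y != round(y))) stop("counts must be non-negative integers")
  tot <- tapply(y, sid, sum)
  zero <- names(tot)[tot == 0]
  # a stratum is uninformative when every covariate column is constant in it
  rng0 <- rep(TRUE, nlevels(sid))
  for (j in seq_len(ncol(X))) {
    mx <- tapply(X[, j], sid, max)
    mn <- tapply(X[, j], sid, min)
    rng0 <- rng0 & (mx == mn)
  }
  inv <- levels(sid)[rng0]
  drop_strata <- union(zero, inv)
  keep <- !(as.character(sid) %in% drop_strata)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; sid <- droplevels(sid[keep])
  if (nlevels(sid) == 0L)
    stop("no informative strata remain after filtering")
  structure(list(y = y, X = X, stratum = sid,
                 dropped = c(rows_missing_covariate = n_missing,
                             strata_zero_total = length(zero),
                             strata_covariate_invariant =
                               length(setdiff(inv, zero)))),
            class = "ccx_design")
}

# Newton-Raphson on the conditional Poisson (product-multinomial) likelihood.
# l(beta) = sum_i y_i x_i'beta - sum_s N_s log sum_{i in s} exp(x_i'beta)
ccx_newton <- function(y, X, stratum, tol_score = 1e-8, tol_step = 1e-10,
                       maxit = 50L) {
  p <- ncol(X)
  beta <- numeric(p)
  Ns <- drop(rowsum(y, stratum))           # stratum totals, by level order
  si <- as.integer(stratum)
  sp <- split(seq_along(y), si)            # computed once; reused per iter
  grp_max <- function(v) vapply(sp, function(ix) max(v[ix]), numeric(1))
  cond_ll <- function(b) {
    eta <- drop(X %*% b)
    # log-sum-exp per stratum for stability
    mx <- grp_max(eta)
    lse <- log(drop(rowsum(exp(eta - mx[si]), si))) + mx
    sum(y * eta) - sum(Ns * lse)
  }
  mu_of <- function(b) {
    eta <- drop(X %*% b)
    mx <- grp_max(eta)
    w <- exp(eta - mx[si])
    Ws <- drop(rowsum(w, si))
    Ns[si] * w / Ws[si]
  }
  ll <- cond_ll(beta)
  trace <- numeric(0)
  # |log rate ratio| beyond this has no finite-MLE interpretation: the
  # likelihood is monotone in that direction (separation), and the score can
  # pass the convergence tolerance while beta drifts to +/- infinity
  check_separation <- function(beta) {
    if (any(abs(beta) > 15)) {
      j <- which.max(abs(beta))
      stop("apparent separation: column '", colnames(X)[j],
           "' perfectly predicts counts within strata", call. = FALSE)
    }
  }
  for (it in seq_len(maxit)) {
    mu <- mu_of(beta)
    score <- drop(crossprod(X, y - mu))
    Sx <- rowsum(X * mu, si)                 # per-stratum sum mu_i x_i
    info <- crossprod(X * sqrt(mu)) - crossprod(Sx / sqrt(Ns))
    if (max(abs(score)) < tol_score) {
      check_separation(beta)
      return(list(beta = beta, mu = mu, info = info, loglik = ll,
                  iterations = it - 1L, converged = TRUE))
    }
    step <- tryCatch(solve(info, score), error = function(e)
      stop("design is singular: collinear columns ",
           paste(colnames(X), collapse = ", "), call. = FALSE))
    # step-halving to guarantee likelihood ascent
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- cond_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (max(abs(lambda * step)) < tol_step) {
      beta <- cand; ll <- ll_new
      check_separation(beta)
      mu <- mu_of(beta)
      Sx <- rowsum(X * mu, si)
      info <- crossprod(X * sqrt(mu)) - crossprod(Sx / sqrt(Ns))
      return(list(beta = beta, mu = mu, info = info, loglik = ll,
                  iterations = it, converged = TRUE))
    }
    beta <- cand; ll <- ll_new
    trace <- c(trace, ll)
    check_separation(beta)
  }
  stop("conditional Poisson fit did not converge in ", maxit,
       " iterations; log-likelihood trace: ",
       paste(signif(trace, 8), collapse = ", "), call. = FALSE)
}

#' Space-time-stratified case-crossover fit
#'
#' Fits a conditional quasi-Poisson regression of daily event counts on the
#' model covariates, with the stratum (region : year : month : day-of-week)
#' effect eliminated by conditioning on stratum totals. The conditional
#' likelihood is the product-multinomial likelihood; it is maximised by
#' Newton-Raphson from beta = 0 with step-halving, so the fit is
#' deterministic. The covariance is the inverse observed information scaled
#' by a Pearson dispersion factor whose degrees of freedom subtract both the
#' regression parameters and the conditioned-out strata.
#'
#' @inheritParams build_strata
#' @param maxit maximum Newton iterations.
#' @return an object of class \code{ccfit} with components
#'   \code{coefficients}, \code{vcov}, \code{dispersion}, \code{fitted},
#'   \code{y}, \code{stratum}, \code{n_strata}, \code{dropped},
#'   \code{loglik}, \code{iterations}, \code{converged}, \code{call}.
#' @seealso \code{\link{rate_ratios}} for the rate-ratio report,
#'   \code{\link{fit_heatwave_model}} for the standard heatwave analysis
#'   formula.
#' @examples
#' d <- data.frame(count = c(4, 5, 3, 6, 6),
#'                 exposed = c(0, 0, 0, 1, 1), stratum = 1)
#' f <- ccfit(count ~ exposed, d)
#' exp(coef(f))  # closed form: mean(6,6)/mean(4,5,3) = 1.5
#' @export
ccfit <- function(formula, data, strata = "stratum", maxit = 50L) {
  design <- if (inherits(data, "ccx_design")) data
            else build_strata(formula, data, strata)
  nr <- ccx_newton(design$y, design$X, design$stratum, maxit = maxit)
  n <- length(design$y)
  p <- ncol(design$X)
  k <- nlevels(design$stratum)
  df <- n - p - k
  if (df <= 0) stop("non-positive residual degrees of freedom (n - p - strata)")
  phi <- sum((design$y - nr$mu)^2 / nr$mu) / df
  vc <- solve(nr$info) * phi
  dimnames(vc) <- list(colnames(design$X), colnames(design$X))
  beta <- stats::setNames(nr$beta, colnames(design$X))
  structure(list(coefficients = beta, vcov = vc, dispersion = phi,
                 fitted = nr$mu, y = design$y, stratum = design$stratum,
                 n = n, n_strata = k, dropped = design$dropped,
                 df_residual = df, loglik = nr$loglik,
                 iterations = nr$iterations, converged = nr$converged,
                 formula = formula, call = match.call()),
            class = "ccfit")
}

#' Pearson dispersion of a conditional Poisson fit
#'
#' phi = sum (y - mu)^2 / mu over the rows used, divided by
#' (n - p - n_strata). Reported as computed; no floor at 1 is applied.
#'
#' @param fit a \code{ccfit}.
#' @return scalar dispersion estimate.
#' @export
estimate_dispersion <- function(fit) fit$dispersion

#' @export
coef.ccfit <- function(object, ...) object$coefficients

#' @export
vcov.ccfit <- function(object, ...) object$vcov

#' @export
fitted.ccfit <- function(object, ...) object$fitted

#' @export
nobs.ccfit <- function(object, ...) object$n

#' @export
residuals.ccfit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") r / sqrt(object$fitted) else r
}

#' @export
confint.ccfit <- function(object, parm, level = 0.95, ...) {
  b <- coef(object)
  if (missing(parm)) parm <- names(b)
  se <- sqrt(diag(object$vcov))[parm]
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = b[parm] - z * se, upper = b[parm] + z * se)
}

#' Rate ratios with Wald confidence intervals
#'
#' Per model term: the rate ratio exp(beta), its Wald CI on the log scale,
#' and the percent change (RR - 1) x 100. With \code{format = TRUE} the RR
#' columns are rounded to 3 decimals and the percent change to 1 decimal
#' (half-up), the convention of published heatwave risk tables.
#'
#' @param fit a \code{ccfit}.
#' @param level confidence level, default 0.95.
#' @param format round for reporting (default FALSE returns full precision).
#' @return data.frame term, rr, ci_lower, ci_upper, pct_change.
#' @export
rate_ratios <- function(fit, level = 0.95, format = FALSE) {
  ci <- exp(confint(fit, level = level))
  out <- data.frame(term = names(coef(fit)), rr = exp(coef(fit)),
                    ci_lower = ci[, 1], ci_upper = ci[, 2],
                    pct_change = (exp(coef(fit)) - 1) * 100,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (format) {
    out$rr <- round_half_up(out$rr, 3)
    out$ci_lower <- round_half_up(out$ci_lower, 3)
    out$ci_upper <- round_half_up(out$ci_upper, 3)
    out$pct_change <- round_half_up(out$pct_change, 1)
  }
  out
}

#' @export
print.ccfit <- function(x, ...) {
  cat("Space-time-stratified case-crossover fit (conditional quasi-Poisson)\n")
  cat(sprintf("  %d rows in %d strata (dropped: %d zero-total, %d invariant, %d missing-covariate rows)\n",
              x$n, x$n_strata, x$dropped["strata_zero_total"],
              x$dropped["strata_covariate_invariant"],
              x$dropped["rows_missing_covariate"]))
  cat(sprintf("  dispersion phi = %.4f, conditional logLik = %.3f (%d Newton iterations)\n",
              x$dispersion, x$loglik, x$iterations))
  print(rate_ratios(x, format = TRUE))
  invisible(x)
}

#' @export
summary.ccfit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- coef(object) / se
  tab <- cbind(estimate = coef(object), se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, rate_ratios = rate_ratios(object, level),
                 dispersion = object$dispersion, n = object$n,
                 n_strata = object$n_strata, dropped = object$dropped,
                 call = object$call),
            class = "summary.ccfit")
}

#' @export
print.summary.ccfit <- function(x, ...) {
  cat("Conditional quasi-Poisson case-crossover model\n\nCoefficients (log rate-ratio scale):\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nDispersion: %.4f  (%d rows, %d strata)\n",
              x$dispersion, x$n, x$n_strata))
  cat("\nRate ratios:\n")
  print(x$rate_ratios)
  invisible(x)
}

#' Standard heatwave case-crossover analysis
#'
#' Convenience wrapper fitting the canonical model
#' \code{count ~ exposure_level + holiday + pm25} (PM2.5 omitted for the
#' sensitivity analysis) on a zero-filled \code{stratum_day} table, with the
#' region:year:month:day-of-week stratum conditioned out.
#'
#' @param stratum_days output of \code{\link{aggregate_counts}}.
#' @param use_pm25 include the PM2.5 covariate (default TRUE); FALSE
#'   reproduces the air-quality sensitivity analysis.
#' @return a \code{ccfit}.
#' @export
fit_heatwave_model <- function(stratum_days, use_pm25 = TRUE) {
  f <- if (use_pm25) count ~ exposure_level + holiday + pm25
       else count ~ exposure_level + holiday
  ccfit(f, stratum_days, strata = "stratum")
}
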