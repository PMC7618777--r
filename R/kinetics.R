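# Single-exponential fitting of cleavage time courses, initial rates and
# their ratios, and first-order decay half-life estimation.

#' Fit a bounded single exponential to a time course
#'
#' Nonlinear least squares for `y = A * (1 - exp(-k t))`. Initialization is
#' `A0 = 1.02 * max(y)` and `k0` from a log-linear fit of `A0 - y` against
#' time. Replicates (a `replicate` column) are pooled into one joint fit with
#' shared `A` and `k` by default; set `per_replicate = TRUE` for separate
#' fits. The initial rate is the analytic derivative at `t = 0`, `A * k`.
#'
#' @param tc Tibble with columns `time` (minutes), `y` (fraction cleaved) and
#'   optionally `replicate`.
#' @param per_replicate Fit each replicate separately (returns a list of
#'   fits).
#' @return Object of class `exp_fit`: list with `A`, `k`, `se_A`, `se_k`,
#'   `r_squared`, `initial_rate`, `se_initial_rate`, `n`, `fit` (the `nls`
#'   object).
#' @examples
#' tc <- simulate_timecourse(0.8, 0.05, seq(0, 120, 5))
#' fit_exponential(tc)
#' @export
fit_exponential <- function(tc, per_replicate = FALSE) {
  stopifnot(all(c("time", "y") %in% names(tc)))
  if (per_replicate && "replicate" %in% names(tc)) {
    return(lapply(split(tc, tc$replicate), fit_exponential))
  }
  if (nrow(tc) < 4) stop("need at least 4 points to fit")
  if (any(tc$time < 0)) stop("times must be non-negative")
  ord <- order(tc$time)
  t <- tc$time[ord]
  y <- tc$y[ord]
  if (all(diff(stats::aggregate(y, list(t), mean)$x) <= 0) && sd(y) > 0) {
    warning("y decreases with time; a bounded rising exponential may not fit")
  }
  A0 <- max(y) * 1.02
  pos <- A0 - y > 1e-9
  k0 <- if (sum(pos) >= 2) {
    max(-coef(lm(log(A0 - y[pos]) ~ t[pos]))[2], 1e-6)
  } else {
    1 / max(t[t > 0], 1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * t)),
      start = list(A = A0, k = unname(k0)),
      lower = c(1e-9, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop(
        "exponential fit failed to converge (", conditionMessage(e),
        "); starts were A0=", signif(A0, 4), ", k0=", signif(k0, 4)
      )
    }
  )
  s <- summary(fit)
  A <- coef(fit)[["A"]]
  k <- coef(fit)[["k"]]
  se <- s$coefficients[, "Std. Error"]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else 1
  rate_se <- sqrt((A * se[["k"]])^2 + (k * se[["A"]])^2)
  structure(
    list(
      A = A, k = k, se_A = se[["A"]], se_k = se[["k"]],
      r_squared = r2, initial_rate = A * k, se_initial_rate = rate_se,
      n = length(y), fit = fit
    ),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_fit: A = %.4f +/- %.4f, k = %.5f +/- %.5f /min, initial rate %.5f /min, R^2 = %.5f, n = %d>\n",
    x$A, x$se_A, x$k, x$se_k, x$initial_rate, x$r_squared, x$n
  ))
  invisible(x)
}

#' Initial-rate ratio of two fits, as a percentage
#'
#' `100 * initial_rate_test / initial_rate_ref`, with the standard error
#' propagated from both fits when available. Inputs may be `exp_fit` objects
#' or bare numeric rates (per minute), optionally with standard errors.
#'
#' @param fit_test,fit_ref `exp_fit` objects or numeric rates.
#' @param se_test,se_ref Standard errors for numeric inputs (optional).
#' @return One-row tibble: `ratio_percent`, `se_percent`.
#' @examples
#' rate_ratio(0.00570, 0.0301) # ~18.9 percent
#' @export
rate_ratio <- function(fit_test, fit_ref, se_test = NA_real_, se_ref = NA_real_) {
  get_rate <- function(f, se) {
    if (inherits(f, "exp_fit")) c(f$initial_rate, f$se_initial_rate) else c(f, se)
  }
  rt <- get_rate(fit_test, se_test)
  rr <- get_rate(fit_ref, se_ref)
  if (rr[1] == 0) stop("reference rate is zero; ratio undefined")
  ratio <- 100 * rt[1] / rr[1]
  se <- if (anyNA(c(rt[2], rr[2]))) {
    NA_real_
  } else {
    ratio * sqrt((rt[2] / rt[1])^2 + (rr[2] / rr[1])^2)
  }
  tibble::tibble(ratio_percent = ratio, se_percent = se)
}

#' First-order decay fit and half-life
#'
#' Fits `y = exp(-lambda t)` to intact-fraction measurements and reports the
#' half-life `t_half = ln(2) / lambda` with its standard error.
#'
#' @param points Tibble with columns `time` (days) and `y` (intact fraction
#'   in (0, 1]).
#' @return One-row tibble: `lambda`, `se_lambda`, `half_life`,
#'   `se_half_life`.
#' @examples
#' fit_decay(tibble::tibble(time = c(0, 117), y = c(1, 0.5))) # t1/2 = 117 d
#' @export
fit_decay <- function(points) {
  stopifnot(all(c("time", "y") %in% names(points)))
  if (nrow(points) < 2) stop("need at least 2 points")
  if (any(points$y <= 0 | points$y > 1)) stop("intact fractions must lie in (0, 1]")
  ord <- order(points$time)
  t <- points$time[ord]
  y <- points$y[ord]
  if (length(y) > 1 && all(diff(y) >= 0) && any(diff(y) > 0)) {
    warning("y increases with time; first-order decay may not fit")
  }
  nontriv <- t > 0
  lam0 <- if (any(nontriv)) {
    max(mean(-log(y[nontriv]) / t[nontriv]), 1e-9)
  } else {
    1e-3
  }
  fit <- minpack.lm::nlsLM(
    y ~ exp(-lambda * t),
    start = list(lambda = lam0),
    lower = 1e-12,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  lambda <- coef(fit)[["lambda"]]
  se_l <- summary(fit)$coefficients[, "Std. Error"][[1]]
  tibble::tibble(
    lambda = lambda,
    se_lambda = se_l,
    half_life = log(2) / lambda,
    se_half_life = log(2) * se_l / lambda^2
  )
}
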