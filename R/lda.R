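## single-hit Poisson log-likelihood of a dose table at frequency f
.ldaLoglik <- function(f, d, n, k) {
  if (f < 0) return(-Inf)
  pr <- -expm1(-f * d)            # P(positive) = 1 - exp(-f * dose)
  ll <- 0
  for (i in seq_along(d)) {
    if (k[i] > 0) {
      if (pr[i] <= 0) return(-Inf)
      ll <- ll + k[i] * log(pr[i])
    }
    ll <- ll - (n[i] - k[i]) * f * d[i]
  }
  ll
}

.checkLdaTable <- function(table) {
  need <- c("dose", "n_tested", "n_positive")
  if (!all(need %in% names(table)))
    .stopf("dose table needs columns: %s", paste(need, collapse = ", "))
  if (!nrow(table)) .stopf("dose table is empty")
  if (any(table$dose <= 0)) .stopf("doses must be > 0")
  if (any(table$n_tested <= 0)) .stopf("n_tested must be > 0")
  if (any(table$n_positive < 0 | table$n_positive > table$n_tested))
    .stopf("n_positive must lie in [0, n_tested]")
  table
}

## MLE of f by complementary log-log GLM with log-dose offset; falls back to
## direct likelihood maximization if the GLM fails to converge
.ldaMLE <- function(d, n, k) {
  fit <- tryCatch(
    suppressWarnings(glm(cbind(k, n - k) ~ 1 + offset(log(d)),
                         family = binomial(link = "cloglog"))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    return(list(f = exp(coef(fit)[[1L]]),
                se = sqrt(suppressWarnings(stats::vcov(fit))[1L, 1L])))
  }
  opt <- optimize(function(u) .ldaLoglik(exp(u), d, n, k),
                  interval = log(c(1e-3, 1e3) * (1 / max(d))), maximum = TRUE)
  list(f = exp(opt$maximum), se = NA_real_)
}

## profile-likelihood CI around fhat at the given level
.ldaProfileCI <- function(fhat, d, n, k, confLevel) {
  llmax <- .ldaLoglik(fhat, d, n, k)
  crit <- qchisq(confLevel, df = 1) / 2
  g <- function(f) .ldaLoglik(f, d, n, k) - (llmax - crit)
  lo <- fhat
  while (g(lo) > 0 && lo > fhat * 1e-12) lo <- lo / 4
  ciLow <- if (g(lo) <= 0)
    uniroot(g, c(lo, fhat), tol = fhat * 1e-9)$root else 0
  hi <- fhat
  while (g(hi) > 0 && hi < fhat * 1e12) hi <- hi * 4
  ciHigh <- if (g(hi) <= 0)
    uniroot(g, c(fhat, hi), tol = fhat * 1e-9)$root else Inf
  c(ciLow, ciHigh)
}

#' Single-hit Poisson limiting-dilution frequency
#'
#' Maximum-likelihood estimate of the frequency `f` of responding cells
#' from an all-or-none dose-response table, under
#' `P(response at dose d) = 1 - exp(-f * d)` (each animal an independent
#' binomial trial). Fitting uses the complementary log-log GLM
#' parameterization (intercept = `log f`, log-dose offset). The confidence
#' interval is Wald on `log f`; when any dose group is saturated (all
#' positive or all negative) a profile-likelihood interval is used instead.
#' A table with no responders at all returns `f = 0` with a one-sided upper
#' bound; a table with all animals responding returns `f = Inf` (flagged)
#' with a one-sided lower bound.
#'
#' @param table data.frame with columns `dose` (cells per animal, > 0),
#'   `n_tested` (> 0), `n_positive`.
#' @param confLevel Confidence level (default 0.95).
#' @return An [LdaResult-class]; see [oneIn()] for the "1 in N" rendering.
#' @export
ldaFrequency <- function(table, confLevel = 0.95) {
  table <- .checkLdaTable(table)
  d <- as.numeric(table$dose)
  n <- as.numeric(table$n_tested)
  k <- as.numeric(table$n_positive)
  alpha <- 1 - confLevel
  if (sum(k) == 0) {
    ## P(no responder anywhere | f) = exp(-f * sum(n * d)) = alpha
    upper <- -log(alpha) / sum(n * d)
    return(new("LdaResult", frequency = 0, ciLow = 0, ciHigh = upper,
               confLevel = confLevel, flags = "all_negative", table = table))
  }
  if (sum(k) == sum(n)) {
    ## P(every animal responds | f) = alpha at the lower bound
    g <- function(f) sum(n * log(-expm1(-f * d))) - log(alpha)
    fhi <- 1 / min(d)
    while (g(fhi) < 0) fhi <- fhi * 4
    lower <- uniroot(g, c(1e-12 / max(d), fhi), tol = 1e-12)$root
    return(new("LdaResult", frequency = Inf, ciLow = lower, ciHigh = Inf,
               confLevel = confLevel, flags = "all_positive", table = table))
  }
  mle <- .ldaMLE(d, n, k)
  fhat <- mle$f
  saturated <- any(k == 0) || any(k == n)
  flags <- character(0)
  if (saturated || !is.finite(mle$se) || mle$se <= 0) {
    ci <- .ldaProfileCI(fhat, d, n, k, confLevel)
    flags <- c(flags, "profile_ci")
  } else {
    z <- qnorm(1 - alpha / 2)
    ci <- exp(log(fhat) + c(-1, 1) * z * mle$se)
  }
  new("LdaResult", frequency = fhat, ciLow = ci[1L], ciHigh = ci[2L],
      confLevel = confLevel, flags = flags, table = table)
}

#' Compare two limiting-dilution frequencies
#'
#' Frequency ratio `f_a / f_b` with a likelihood-ratio test of the shared-
#' frequency null (both tables generated by one common `f`), 1 df. Results
#' at a boundary (no responders, or all responders) cannot be compared and
#' are flagged with the p-value omitted.
#'
#' @param a,b [LdaResult-class] objects.
#' @return List with `ratio`, `p`, `flags`.
#' @export
compareFrequencies <- function(a, b) {
  stopifnot(is(a, "LdaResult"), is(b, "LdaResult"))
  fa <- ldaEstimate(a); fb <- ldaEstimate(b)
  if (fa == 0 || fb == 0 || is.infinite(fa) || is.infinite(fb))
    return(list(ratio = fa / fb, p = NA_real_, flags = "boundary"))
  ta <- a@table; tb <- b@table
  llSep <- .ldaLoglik(fa, ta$dose, ta$n_tested, ta$n_positive) +
    .ldaLoglik(fb, tb$dose, tb$n_tested, tb$n_positive)
  pooled <- rbind(ta, tb)
  f0 <- .ldaMLE(pooled$dose, pooled$n_tested, pooled$n_positive)$f
  llShared <- .ldaLoglik(f0, pooled$dose, pooled$n_tested, pooled$n_positive)
  stat <- max(0, 2 * (llSep - llShared))
  list(ratio = fa / fb, p = pchisq(stat, df = 1, lower.tail = FALSE),
       flags = character(0))
}
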