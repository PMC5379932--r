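#' Observation likelihood specification
#'
#' The noise model for `betahat_j` given the true effect: normal,
#' `betahat_j ~ N(beta_j, se_j^2)`, or scaled t,
#' `betahat_j = beta_j + se_j * T_df`. The t likelihood is supported only with
#' uniform-family prior components (the posterior stays a truncated t); a
#' normal-component/t-noise convolution has no closed form and is rejected.
#'
#' @param kind `"normal"` or `"t"`.
#' @param df degrees of freedom, required (and > 0) for `kind = "t"`; either a
#'   scalar or one value per observation.
#' @return object of class `"ebs_lik"`.
#' @export
likelihood <- function(kind = c("normal", "t"), df = NULL) {
  kind <- match.arg(kind)
  if (kind == "t") {
    if (is.null(df) || any(!is.finite(df)) || any(df <= 0))
      stop("t likelihood requires finite df > 0")
  } else df <- NULL
  structure(list(kind = kind, df = df), class = "ebs_lik")
}

# log(F(x) - F(y)) for x >= y, where F is pnorm or pt, without catastrophic
# cancellation in either tail: work in whichever tail keeps the log-cdf values
# well separated, then log-diff-exp.
logcdf_diff <- function(x, y, df = NULL) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  if (!is.null(df)) df <- rep_len(df, n)
  logF <- function(q, i, lower) {
    if (is.null(df)) stats::pnorm(q, lower.tail = lower, log.p = TRUE)
    else stats::pt(q, df[i], lower.tail = lower, log.p = TRUE)
  }
  upper <- (x + y) > 0          # bulk of mass in the right tail
  lo <- !upper
  lx <- ly <- numeric(n)
  lx[lo] <- logF(x[lo], lo, TRUE)
  ly[lo] <- logF(y[lo], lo, TRUE)
  # F(x)-F(y) = S(y)-S(x) with survival S; swap roles in the right tail
  lx[upper] <- logF(y[upper], upper, FALSE)
  ly[upper] <- logF(x[upper], upper, FALSE)
  d <- ly - lx                  # <= 0
  out <- lx + ifelse(d > -log(2), log(-expm1(d)), log1p(-exp(d)))
  out[x == y] <- -Inf
  out
}

#' Marginal log-likelihood of one observation under one prior component
#'
#' The log marginal density of `betahat` after integrating the true effect
#' over a single prior component: a convolution of the component with the
#' noise model. Closed forms: normal x normal is normal with summed variances;
#' uniform x normal (or t) is a scaled cdf difference; a point mass leaves the
#' noise density itself.
#'
#' @param betahat,sebetahat numeric vectors (recycled to common length).
#' @param type component type: `"point"`, `"normal"` or `"uniform"`.
#' @param sd component sd (normal), `a`,`b` interval offsets (uniform),
#'   relative to `mode`.
#' @param a,b uniform offsets.
#' @param lik an [likelihood()] object.
#' @param mode prior mode location.
#' @return numeric vector of log densities, finite or `-Inf`, never `NaN`.
#' @export
component_loglik <- function(betahat, sebetahat, type, sd = 0, a = 0, b = 0,
                             lik = likelihood("normal"), mode = 0) {
  stopifnot(all(sebetahat > 0))
  if (type == "uniform" && (b - a) < 1e-12) {  # degenerate: point mass at midpoint
    mode <- mode + (a + b) / 2
    type <- "point"
  }
  switch(type,
    point = {
      z <- (betahat - mode) / sebetahat
      if (lik$kind == "normal") stats::dnorm(z, log = TRUE) - log(sebetahat)
      else stats::dt(z, lik$df, log = TRUE) - log(sebetahat)
    },
    normal = {
      if (lik$kind == "t")
        stop("normal components are not supported with the t likelihood")
      stats::dnorm(betahat, mode, sqrt(sd^2 + sebetahat^2), log = TRUE)
    },
    uniform = {
      x <- (betahat - mode - a) / sebetahat
      y <- (betahat - mode - b) / sebetahat
      df <- if (lik$kind == "t") lik$df else NULL
      logcdf_diff(x, y, df = df) - log(b - a)
    },
    stop("unknown component type: ", type))
}

#' Matrix of per-observation, per-component marginal log-likelihoods
#'
#' @param betahat,sebetahat numeric vectors of length J; all `sebetahat > 0`.
#' @param comps component list as returned by [build_grid()], or the
#'   `type`/`sd`/`a`/`b` fields of a `"mixprior"`.
#' @param lik an [likelihood()] object.
#' @param mode prior mode location.
#' @return J x K numeric matrix of log densities. An error is raised if any
#'   row is entirely `-Inf` (no component explains the observation).
#' @export
loglik_matrix <- function(betahat, sebetahat, comps,
                          lik = likelihood("normal"), mode = 0) {
  if (any(!is.finite(sebetahat)) || any(sebetahat <= 0))
    stop("all standard errors must be finite and positive")
  J <- length(betahat)
  K <- length(comps$type)
  L <- matrix(0, J, K)
  for (k in seq_len(K)) {
    L[, k] <- component_loglik(betahat, sebetahat, comps$type[k],
                               sd = comps$sd[k], a = comps$a[k],
                               b = comps$b[k], lik = lik, mode = mode)
  }
  if (any(bad <- !apply(is.finite(L), 1L, any)))
    stop("observation(s) ", paste(which(bad), collapse = ", "),
         " have zero likelihood under every component")
  L
}
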