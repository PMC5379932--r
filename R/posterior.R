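#' Posterior component weights
#'
#' By Bayes theorem the probability that observation j arose from component k
#' is proportional to `pi_k * exp(L[j,k])`; the computation is stabilized in
#' log space.
#'
#' @param pi prior mixture weights (simplex, length K).
#' @param L J x K log-likelihood matrix (a single row may be passed as a
#'   vector).
#' @return J x K matrix of posterior weights; each row sums to 1.
#' @export
posterior_weights <- function(pi, L) {
  if (is.null(dim(L))) L <- matrix(L, nrow = 1L)
  stopifnot(length(pi) == ncol(L))
  logpi <- ifelse(pi > 0, log(pi), -Inf)
  A <- sweep(L, 2L, logpi, `+`)
  m <- row_max(A)
  if (any(!is.finite(m)))
    stop("observation with zero posterior mass under every component")
  W <- exp(A - m)
  W / rowSums(W)
}

# Truncated-normal moments for N(mu, s^2) restricted to [l, u], vectorized.
# For intervals so deep in the tail that the normalizer underflows the moments
# collapse to the nearest endpoint; such components carry negligible posterior
# weight.
truncnorm_moments <- function(mu, s, l, u) {
  alpha <- (l - mu) / s
  beta <- (u - mu) / s
  logZ <- logcdf_diff(beta, alpha)
  Z <- exp(logZ)
  phia <- stats::dnorm(alpha)
  phib <- stats::dnorm(beta)
  r1 <- (phia - phib) / Z
  # guard 0*Inf at infinite endpoints
  ap <- ifelse(is.finite(alpha), alpha * phia, 0)
  bp <- ifelse(is.finite(beta), beta * phib, 0)
  r2 <- (ap - bp) / Z
  mean <- mu + s * r1
  var <- s^2 * (1 + r2 - r1^2)
  bad <- !is.finite(mean) | !is.finite(var) | var < 0 | Z < 1e-300
  if (any(bad)) {
    nearest <- ifelse(abs(l - mu) < abs(u - mu), l, u)
    nearest[is.infinite(nearest)] <- mu[is.infinite(nearest)]
    mean[bad] <- nearest[bad]
    var[bad] <- 0
  }
  list(mean = mean, var = pmax(var, 0))
}

# Truncated scaled-t moments (location bh, scale s, df nu, interval [l, u])
# by fixed-order Gauss-Legendre quadrature of the renormalized density.
trunct_moments <- function(bh, s, nu, l, u, nq = 64L) {
  gl <- gauss_legendre(nq)
  n <- length(bh)
  mean <- var <- numeric(n)
  for (j in seq_len(n)) {
    x <- (l[j] + u[j]) / 2 + (u[j] - l[j]) / 2 * gl$nodes
    w <- (u[j] - l[j]) / 2 * gl$weights
    d <- stats::dt((x - bh[j]) / s[j], nu[j]) / s[j]
    Z <- sum(w * d)
    if (Z <= 0) { mean[j] <- (l[j] + u[j]) / 2; var[j] <- 0; next }
    m1 <- sum(w * x * d) / Z
    m2 <- sum(w * x^2 * d) / Z
    mean[j] <- m1
    var[j] <- max(m2 - m1^2, 0)
  }
  list(mean = mean, var = var)
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n) {
  i <- seq_len(n - 1L)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- b
  J[cbind(i + 1L, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(nodes = e$values[idx], weights = 2 * e$vectors[1L, idx]^2)
}

# Per-component posterior of beta_j given component k, all observations at
# once. Returns lists of J x K matrices describing each conditional:
# kind (point/normal/truncnorm/trunct), location/scale parameters, and
# truncation limits.
component_posteriors <- function(g, betahat, sebetahat, lik) {
  J <- length(betahat)
  K <- ncomp(g)
  mu <- tau <- lo <- hi <- matrix(0, J, K)
  kind <- character(K)
  nu <- if (lik$kind == "t") rep_len(lik$df, J) else NULL
  for (k in seq_len(K)) {
    switch(g$type[k],
      point = {
        kind[k] <- "point"
        mu[, k] <- g$mode
      },
      normal = {
        kind[k] <- "normal"
        s2 <- g$sd[k]^2
        w <- s2 / (s2 + sebetahat^2)
        mu[, k] <- g$mode + (betahat - g$mode) * w
        tau[, k] <- sqrt(w) * sebetahat
      },
      uniform = {
        kind[k] <- if (lik$kind == "t") "trunct" else "truncnorm"
        mu[, k] <- betahat
        tau[, k] <- sebetahat
        lo[, k] <- g$mode + g$a[k]
        hi[, k] <- g$mode + g$b[k]
      })
  }
  list(kind = kind, mu = mu, tau = tau, lo = lo, hi = hi, nu = nu)
}

# survival function at x of each component posterior: J x K. Computed
# directly (not as 1 - cdf) so tail probabilities are exact.
component_post_sf <- function(cp, x) {
  J <- nrow(cp$mu)
  K <- length(cp$kind)
  S <- matrix(0, J, K)
  for (k in seq_len(K)) {
    S[, k] <- switch(cp$kind[k],
      point = as.numeric(x < cp$mu[, k]),
      normal = stats::pnorm(x, cp$mu[, k], cp$tau[, k], lower.tail = FALSE),
      truncnorm = ,
      trunct = {
        l <- cp$lo[, k]; u <- cp$hi[, k]
        z <- (pmin(pmax(x, l), u) - cp$mu[, k]) / cp$tau[, k]
        zl <- (l - cp$mu[, k]) / cp$tau[, k]
        zu <- (u - cp$mu[, k]) / cp$tau[, k]
        df <- if (cp$kind[k] == "trunct") cp$nu else NULL
        num <- exp(logcdf_diff(zu, z, df = df))
        den <- exp(logcdf_diff(zu, zl, df = df))
        s <- ifelse(den > 0, pmin(num / den, 1),
                    as.numeric(x < (l + u) / 2))
        ifelse(x >= u, 0, ifelse(x < l, 1, s))
      })
  }
  S
}

# cdf at x (vector over observations) of each component posterior: J x K.
component_post_cdf <- function(cp, x) {
  J <- nrow(cp$mu)
  K <- length(cp$kind)
  P <- matrix(0, J, K)
  for (k in seq_len(K)) {
    P[, k] <- switch(cp$kind[k],
      point = as.numeric(x >= cp$mu[, k]),
      normal = stats::pnorm(x, cp$mu[, k], cp$tau[, k]),
      truncnorm = ,
      trunct = {
        l <- cp$lo[, k]; u <- cp$hi[, k]
        z <- (pmin(pmax(x, l), u) - cp$mu[, k]) / cp$tau[, k]
        zl <- (l - cp$mu[, k]) / cp$tau[, k]
        zu <- (u - cp$mu[, k]) / cp$tau[, k]
        df <- if (cp$kind[k] == "trunct") cp$nu else NULL
        num <- exp(logcdf_diff(z, zl, df = df))
        den <- exp(logcdf_diff(zu, zl, df = df))
        # den underflows only when the interval is deep in the noise tail;
        # treat the conditional as an atom at the midpoint then
        p <- ifelse(den > 0, pmin(num / den, 1),
                    as.numeric(x >= (l + u) / 2))
        ifelse(x >= u, 1, ifelse(x < l, 0, p))
      })
  }
  P
}

#' Posterior sign probabilities and local error rates
#'
#' Mixes component-conditional probabilities into `Pr(beta < 0 | data)`,
#' `Pr(beta = 0 | data)` and `Pr(beta > 0 | data)`, and derives
#' `lfdr = Pr(beta = 0)` and
#' `lfsr = min(Pr(beta <= 0), Pr(beta >= 0))` — the probability of declaring
#' the wrong sign if forced to call one. Sign is always taken about zero (the
#' scientific sign of the effect), so with a shifted mode the point mass
#' contributes to the negative or positive probability, not to `lfdr`.
#'
#' @param W J x K posterior weight matrix ([posterior_weights()]).
#' @param cp component posterior description (internal) or `NULL` to build it.
#' @param g,betahat,sebetahat,lik model pieces, used when `cp` is `NULL`.
#' @return data frame with columns NegativeProb, ZeroProb, PositiveProb,
#'   lfdr, lfsr.
#' @export
posterior_probs <- function(W, g, betahat, sebetahat,
                            lik = likelihood("normal"), cp = NULL) {
  if (is.null(cp)) cp <- component_posteriors(g, betahat, sebetahat, lik)
  J <- nrow(W)
  K <- ncol(W)
  # Pr(beta < 0) and Pr(beta > 0) per component, each computed directly so
  # neither inherits rounding error from the other
  P0 <- component_post_cdf(cp, rep(0, J))
  S0 <- component_post_sf(cp, rep(0, J))
  atom0 <- matrix(0, J, K)
  for (k in seq_len(K)) {
    if (cp$kind[k] == "point" && g$mode == 0) {
      atom0[, k] <- 1
      P0[, k] <- 0       # cdf at 0 is all atom; strictly-below part is 0
    } else if (cp$kind[k] == "point") {
      P0[, k] <- as.numeric(g$mode < 0)
    }
  }
  neg <- rowSums(W * P0)
  zero <- rowSums(W * atom0)
  pos <- rowSums(W * S0)
  lfsr <- pmin(neg, pos) + zero
  data.frame(NegativeProb = neg, ZeroProb = zero, PositiveProb = pos,
             lfdr = zero, lfsr = pmin(lfsr, 1))
}

#' Posterior mean and standard deviation
#'
#' Standard mixture moments: `mean = sum_k w_k mu_k` and
#' `var = sum_k w_k (tau_k^2 + mu_k^2) - mean^2`.
#'
#' @inheritParams posterior_probs
#' @return data frame with columns PosteriorMean, PosteriorSD.
#' @export
posterior_moments <- function(W, g, betahat, sebetahat,
                              lik = likelihood("normal"), cp = NULL) {
  if (is.null(cp)) cp <- component_posteriors(g, betahat, sebetahat, lik)
  J <- nrow(W)
  K <- ncol(W)
  M <- V <- matrix(0, J, K)
  for (k in seq_len(K)) {
    switch(cp$kind[k],
      point = { M[, k] <- cp$mu[, k] },
      normal = { M[, k] <- cp$mu[, k]; V[, k] <- cp$tau[, k]^2 },
      truncnorm = {
        mo <- truncnorm_moments(cp$mu[, k], cp$tau[, k], cp$lo[, k], cp$hi[, k])
        M[, k] <- mo$mean; V[, k] <- mo$var
      },
      trunct = {
        mo <- trunct_moments(cp$mu[, k], cp$tau[, k], cp$nu,
                             cp$lo[, k], cp$hi[, k])
        M[, k] <- mo$mean; V[, k] <- mo$var
      })
  }
  mean <- rowSums(W * M)
  second <- rowSums(W * (V + M^2))
  data.frame(PosteriorMean = mean,
             PosteriorSD = sqrt(pmax(second - mean^2, 0)))
}

# full posterior cdf F_j(x_j) for per-observation evaluation points x
posterior_cdf <- function(W, cp, x) {
  rowSums(W * component_post_cdf(cp, x))
}

#' Credible bounds from the posterior mixture
#'
#' Quantiles of each observation's posterior via the generalized inverse
#' `q(p) = inf{x : F(x) >= p}` of the atom-bearing mixture cdf, solved by
#' bisection to 1e-8. When a requested quantile falls inside the atom the
#' bound is the atom's location, so intervals remain well defined despite the
#' discrete mass.
#'
#' @param W posterior weight matrix.
#' @param g fitted `"mixprior"`.
#' @param betahat,sebetahat,lik data and noise model.
#' @param probs vector of probability levels; quantiles are computed per
#'   observation for each level.
#' @param cp internal component-posterior description (optional).
#' @return matrix of dim J x length(probs).
#' @export
posterior_quantiles <- function(W, g, betahat, sebetahat,
                                lik = likelihood("normal"),
                                probs = c(0.025, 0.975), cp = NULL) {
  if (is.null(cp)) cp <- component_posteriors(g, betahat, sebetahat, lik)
  J <- nrow(W)
  # bracket: support of all components with non-negligible weight
  width <- 10 * (max(g$sd) + max(sebetahat)) +
    max(abs(c(g$a, g$b))) + abs(g$mode)
  lo0 <- pmin(betahat, g$mode) - width
  hi0 <- pmax(betahat, g$mode) + width
  has_atom <- any(cp$kind == "point")
  out <- matrix(NA_real_, J, length(probs))
  for (i in seq_along(probs)) {
    p <- probs[i]
    lo <- lo0; hi <- hi0
    while (max(hi - lo) > 1e-8) {
      mid <- (lo + hi) / 2
      ge <- posterior_cdf(W, cp, mid) >= p
      hi[ge] <- mid[ge]
      lo[!ge] <- mid[!ge]
    }
    # a quantile falling in the atom is the atom location exactly, not the
    # bisection endpoint a rounding error above it
    if (has_atom) {
      near <- abs(hi - g$mode) <= 2e-8
      if (any(near)) {
        ok <- near & posterior_cdf(W, cp, rep(g$mode, J)) >= p
        hi[ok] <- g$mode
      }
    }
    out[, i] <- hi
  }
  out
}

#' Full posterior summary table
#'
#' Combines weights, sign probabilities, moments and credible bounds for all
#' observations under a fitted (or specified) mixture prior.
#'
#' @param g a `"mixprior"` object.
#' @param betahat,sebetahat data.
#' @param lik noise model ([likelihood()]).
#' @param ci_level two-sided credible level (default 0.95); the one-sided
#'   lower bound `q(1 - ci_level)` is returned as column `LowerBound`.
#' @param L optional precomputed log-likelihood matrix.
#' @return data frame with one row per observation: NegativeProb, ZeroProb,
#'   PositiveProb, lfdr, lfsr, PosteriorMean, PosteriorSD, CredibleLower,
#'   CredibleUpper, LowerBound.
#' @export
posterior_summary <- function(g, betahat, sebetahat,
                              lik = likelihood("normal"), ci_level = 0.95,
                              L = NULL) {
  comps <- list(type = g$type, sd = g$sd, a = g$a, b = g$b)
  if (is.null(L))
    L <- loglik_matrix(betahat, sebetahat, comps, lik = lik, mode = g$mode)
  W <- posterior_weights(g$pi, L)
  cp <- component_posteriors(g, betahat, sebetahat, lik)
  probs <- posterior_probs(W, g, betahat, sebetahat, lik, cp = cp)
  mom <- posterior_moments(W, g, betahat, sebetahat, lik, cp = cp)
  qs <- posterior_quantiles(W, g, betahat, sebetahat, lik,
                            probs = c((1 - ci_level) / 2,
                                      1 - (1 - ci_level) / 2,
                                      1 - ci_level), cp = cp)
  cbind(probs, mom,
        data.frame(CredibleLower = qs[, 1], CredibleUpper = qs[, 2],
                   LowerBound = qs[, 3]))
}
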