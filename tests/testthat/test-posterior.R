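test_that("posterior weights follow Bayes theorem", {
  # two components, equal prior, densities 0.1 and 0.3
  W <- posterior_weights(c(0.5, 0.5), log(c(0.1, 0.3)))
  expect_equal(as.vector(W), c(0.25, 0.75))

  # degenerate prior passes through; flat likelihood returns the prior
  expect_equal(as.vector(posterior_weights(c(1, 0), log(c(0.2, 0.9)))),
               c(1, 0))
  pi <- c(0.2, 0.3, 0.5)
  expect_equal(as.vector(posterior_weights(pi, rep(log(0.4), 3))), pi)

  expect_error(posterior_weights(c(1, 0), c(-Inf, 0)), "zero posterior mass")
})

test_that("component posteriors have the conjugate closed forms", {
  g <- mixture_prior(pi = c(0.5, 0.5), type = c("point", "normal"),
                     sd = c(0, 1))
  cp <- ebshrink:::component_posteriors(g, 3, 1, likelihood("normal"))
  # sigma_k = se: posterior mean betahat/2, var se^2/2
  expect_equal(cp$mu[1, 2], 1.5)
  expect_equal(cp$tau[1, 2], sqrt(0.5))

  # flat-prior limit: huge sigma_k returns the observation
  g2 <- mixture_prior(pi = 1, type = "normal", sd = 1e6)
  cp2 <- ebshrink:::component_posteriors(g2, 3, 1, likelihood("normal"))
  expect_equal(cp2$mu[1, 1], 3, tolerance = 1e-3)
  expect_equal(cp2$tau[1, 1], 1, tolerance = 1e-3)
})

test_that("truncated posterior moments match quadrature", {
  # uniform (-1,1) prior component, betahat 0.3, se 1
  g <- mixture_prior(pi = 1, type = "uniform", a = -1, b = 1)
  W <- matrix(1, 1, 1)
  mom <- posterior_moments(W, g, 0.3, 1)
  oracle <- quad_posterior(g, 0.3, 1)
  expect_equal(mom$PosteriorMean, oracle$mean, tolerance = 1e-6)
  expect_equal(mom$PosteriorSD, oracle$sd, tolerance = 1e-6)
})

test_that("sign probabilities reproduce the canonical worked example", {
  # posterior with Pr(<0) 0.95, Pr(=0) 0.03, Pr(>0) 0.02 gives lfsr 0.05
  # exactly and lfdr equal to the zero probability; realized here through an
  # actual mixture posterior, not by shortcutting the arithmetic
  g <- mixture_prior(pi = c(0.03, 0.95, 0.02), type = c("point", "uniform",
                                                        "uniform"),
                     a = c(0, -1, 0), b = c(0, 0, 1))
  W <- matrix(g$pi, 1)  # flat likelihood: posterior weights = prior weights
  pr <- posterior_probs(W, g, 0, 1)
  expect_equal(pr$NegativeProb, 0.95)
  expect_equal(pr$ZeroProb, 0.03)
  expect_equal(pr$PositiveProb, 0.02)
  expect_equal(pr$lfsr, 0.05)
  expect_equal(pr$lfdr, 0.03)
})

test_that("degenerate and symmetric cases behave as required", {
  # all mass at zero: lfdr = lfsr = 1
  g <- mixture_prior(pi = c(1, 0), type = c("point", "normal"), sd = c(0, 1))
  L <- loglik_matrix(0.5, 1, g[c("type", "sd", "a", "b")])
  pr <- posterior_probs(posterior_weights(g$pi, L), g, 0.5, 1)
  expect_equal(pr$lfdr, 1)
  expect_equal(pr$lfsr, 1)

  # z = 0 with a symmetric zero-mode prior: lfsr >= 0.5 whatever pi0
  for (p0 in seq(0, 1, by = 0.25)) {
    gs <- mixture_prior(pi = c(p0, (1 - p0) / 2, (1 - p0) / 2),
                        type = c("point", "normal", "normal"),
                        sd = c(0, 0.5, 2))
    Ls <- loglik_matrix(0, 1, gs[c("type", "sd", "a", "b")])
    prs <- posterior_probs(posterior_weights(gs$pi, Ls), gs, 0, 1)
    expect_gte(prs$lfsr, 0.5)
    expect_equal(prs$NegativeProb, prs$PositiveProb, tolerance = 1e-12)
  }
})

test_that("posterior mean shrinks toward the mode for symmetric priors", {
  set.seed(51)
  g <- random_prior(K = 4, mode = 0, family = "normal")
  bh <- seq(-4, 4, by = 0.5)
  L <- loglik_matrix(bh, rep(1, length(bh)), g[c("type", "sd", "a", "b")])
  W <- posterior_weights(g$pi, L)
  mom <- posterior_moments(W, g, bh, rep(1, length(bh)))
  ratio <- mom$PosteriorMean / bh
  ratio <- ratio[bh != 0]
  expect_true(all(ratio >= 0 & ratio <= 1))
  # betahat = 0 with symmetric prior: posterior mean 0
  expect_equal(mom$PosteriorMean[bh == 0], 0, tolerance = 1e-12)
})

test_that("closed-form posterior summaries match full quadrature", {
  set.seed(52)
  n_checked <- 0L
  for (rep in 1:25) {
    fam <- if (rep %% 2) "normal" else "uniform"
    g <- random_prior(K = 3, mode = 0, family = fam)
    bh <- rnorm(2, 0, 2)
    se <- runif(2, 0.5, 1.5)
    L <- loglik_matrix(bh, se, g[c("type", "sd", "a", "b")])
    W <- posterior_weights(g$pi, L)
    pr <- posterior_probs(W, g, bh, se)
    mom <- posterior_moments(W, g, bh, se)
    for (j in 1:2) {
      oracle <- quad_posterior(g, bh[j], se[j])
      expect_equal(pr$NegativeProb[j], oracle$NegativeProb, tolerance = 1e-5)
      expect_equal(pr$lfdr[j], oracle$lfdr, tolerance = 1e-5)
      expect_equal(pr$lfsr[j], oracle$lfsr, tolerance = 1e-5)
      expect_equal(mom$PosteriorMean[j], oracle$mean, tolerance = 1e-5)
      expect_equal(mom$PosteriorSD[j], oracle$sd, tolerance = 1e-5)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 50L)
})

test_that("posterior cdf at zero equals NegativeProb + ZeroProb", {
  set.seed(53)
  for (rep in 1:5) {
    g <- random_prior(K = 3, family = "normal")
    bh <- rnorm(4)
    se <- runif(4, 0.5, 2)
    L <- loglik_matrix(bh, se, g[c("type", "sd", "a", "b")])
    W <- posterior_weights(g$pi, L)
    cp <- ebshrink:::component_posteriors(g, bh, se, likelihood("normal"))
    pr <- posterior_probs(W, g, bh, se, cp = cp)
    F0 <- ebshrink:::posterior_cdf(W, cp, rep(0, 4))
    expect_equal(F0, pr$NegativeProb + pr$ZeroProb, tolerance = 1e-10)
  }
})

test_that("credible bounds invert the atom-bearing mixture cdf", {
  # degenerate posterior: every quantile is the atom
  g <- mixture_prior(pi = c(1, 0), type = c("point", "normal"), sd = c(0, 1))
  W <- matrix(c(1, 0), 1)
  q <- posterior_quantiles(W, g, 0, 1, probs = c(0.05, 0.5, 0.95))
  expect_equal(as.vector(q), c(0, 0, 0), tolerance = 1e-7)

  # pure normal posterior N(1,1): analytic quantile
  g2 <- mixture_prior(pi = 1, type = "normal", sd = 1e8)
  W2 <- matrix(1, 1, 1)
  q2 <- posterior_quantiles(W2, g2, 1, 1, probs = 0.05)
  expect_equal(q2[1, 1], 1 + qnorm(0.05), tolerance = 1e-4)

  # generalized-inverse property on randomized atom-bearing posteriors
  set.seed(54)
  for (rep in 1:5) {
    g3 <- random_prior(K = 3, family = "uniform")
    bh <- rnorm(3); se <- runif(3, 0.5, 1.5)
    L <- loglik_matrix(bh, se, g3[c("type", "sd", "a", "b")])
    W3 <- posterior_weights(g3$pi, L)
    cp <- ebshrink:::component_posteriors(g3, bh, se, likelihood("normal"))
    for (p in c(0.05, 0.4, 0.95)) {
      qs <- posterior_quantiles(W3, g3, bh, se, probs = p, cp = cp)[, 1]
      expect_true(all(ebshrink:::posterior_cdf(W3, cp, qs) >= p - 1e-7))
      expect_true(all(ebshrink:::posterior_cdf(W3, cp, qs - 1e-5) < p + 1e-7))
    }
  }
})

test_that("t-likelihood posteriors match quadrature", {
  g <- mixture_prior(pi = c(0.4, 0.6), type = c("point", "uniform"),
                     a = c(0, -2), b = c(0, 2))
  lik <- likelihood("t", df = 4)
  L <- loglik_matrix(0.8, 1, g[c("type", "sd", "a", "b")], lik = lik)
  W <- posterior_weights(g$pi, L)
  pr <- posterior_probs(W, g, 0.8, 1, lik)
  mom <- posterior_moments(W, g, 0.8, 1, lik)
  oracle <- quad_posterior(g, 0.8, 1, df = 4)
  expect_equal(pr$lfsr, oracle$lfsr, tolerance = 1e-5)
  expect_equal(mom$PosteriorMean, oracle$mean, tolerance = 1e-5)
  expect_equal(mom$PosteriorSD, oracle$sd, tolerance = 1e-4)
})
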