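test_that("penalized log-likelihood matches hand-computed values", {
  # J = 2, K = 2 toy: direct arithmetic
  L <- log(matrix(c(0.2, 0.5, 0.4, 0.1), 2, 2))
  pi <- c(0.5, 0.5)
  lambda <- c(10, 1)
  expected <- log(0.5 * 0.2 + 0.5 * 0.4) + log(0.5 * 0.5 + 0.5 * 0.1) +
    9 * log(0.5)
  expect_equal(penalized_loglik(pi, L, lambda), expected, tolerance = 1e-12)

  # lambda all 1: unpenalized likelihood, even at boundary weights
  expect_equal(penalized_loglik(c(1, 0), L, c(1, 1)),
               sum(L[, 1]))
  # zero weight with an active penalty signals the boundary with -Inf
  expect_identical(penalized_loglik(c(0, 1), L, lambda), -Inf)
  # single component
  expect_equal(penalized_loglik(1, L[, 1, drop = FALSE], 1), sum(L[, 1]))
})

test_that("EM solves degenerate problems immediately", {
  L <- matrix(rnorm(10), 10, 1)
  fit <- fit_pi(L, lambda = 1)
  expect_equal(fit$pi, 1)
  expect_true(fit$converged)

  # identical columns: the likelihood is flat, the penalty decides
  L2 <- matrix(rep(rnorm(20), 3), 20, 3)
  fit2 <- fit_pi(L2, lambda = c(10, 1, 1))
  expect_gt(fit2$pi[1], 0.99)
})

test_that("EM optimum matches a brute-force simplex scan", {
  set.seed(31)
  for (rep in 1:4) {
    J <- 50
    K <- sample(2:3, 1)
    L <- matrix(rnorm(J * K, sd = 1.5), J, K)
    lambda <- c(10, rep(1, K - 1))
    fit <- fit_pi(L, lambda, tol = 1e-12, maxiter = 5e4)
    scan <- simplex_scan(L, lambda)
    expect_gte(fit$penloglik, scan$value - 1e-5)
    expect_lt(abs(fit$penloglik - scan$value), 1e-3)
  }
})

test_that("the penalized objective never decreases along the EM trajectory", {
  set.seed(32)
  for (rep in 1:20) {
    J <- sample(10:80, 1)
    K <- sample(2:6, 1)
    L <- matrix(rnorm(J * K, sd = 2), J, K)
    lambda <- c(sample(c(1, 5, 10), 1), rep(1, K - 1))
    for (acc in c(TRUE, FALSE)) {
      fit <- fit_pi(L, lambda, accelerate = acc)
      expect_true(all(diff(fit$trace) >= -1e-10))
      expect_equal(sum(fit$pi), 1, tolerance = 1e-10)
      expect_true(all(fit$pi >= 0))
    }
  }
})

test_that("fitted weights satisfy first-order optimality on the simplex", {
  set.seed(33)
  L <- matrix(rnorm(200 * 5, sd = 2), 200, 5)
  lambda <- c(10, rep(1, 4))
  fit <- fit_pi(L, lambda, tol = 1e-12, maxiter = 2e4)
  # projected-gradient check: at an interior optimum all active-component
  # gradients are equal; inactive components must not do better
  grad <- function(pi) {
    P <- exp(sweep(L, 2, log(pmax(pi, 1e-300)), `+`))
    den <- rowSums(P)
    colSums(exp(L) / den) + (lambda - 1) / pmax(pi, 1e-300)
  }
  gr <- grad(fit$pi)
  active <- fit$pi > 1e-6
  expect_lt(diff(range(gr[active])), 1e-4 * max(abs(gr[active])) + 1e-4)
  if (any(!active)) expect_true(all(gr[!active] <= max(gr[active]) + 1e-4))
})

test_that("mode estimation recovers a shifted symmetric effect distribution", {
  set.seed(34)
  J <- 2000
  beta <- rnorm(J, 5, 1)
  betahat <- beta + rnorm(J)
  fit <- ash(betahat, rep(1, J), mode = "estimate")
  expect_lt(abs(fit$mode - 5), 0.1)

  # profile value at the estimate beats a coarse scan
  profile_at <- function(m) {
    comps <- ebshrink:::grid_with_pointmass(betahat - m, rep(1, J), sqrt(2),
                                            "normal", TRUE)
    L <- loglik_matrix(betahat, rep(1, J), comps, mode = m)
    fit_pi(L, c(10, rep(1, length(comps$type) - 1)))$penloglik
  }
  scan <- vapply(seq(min(betahat), max(betahat), length.out = 21),
                 profile_at, numeric(1))
  expect_gte(profile_at(fit$mode) + 1e-6, max(scan))
})

test_that("mode estimation is translation-equivariant", {
  set.seed(35)
  betahat <- rnorm(500, 2, 2)
  se <- rep(1, 500)
  m1 <- ash(betahat, se, mode = "estimate")$mode
  m2 <- ash(betahat + 10, se, mode = "estimate")$mode
  expect_equal(m2, m1 + 10, tolerance = 1e-6)
  expect_error(ash(1, 1, mode = "estimate"), "two observations")
})

test_that("alpha selection is invariant and tie-broken for constant se", {
  set.seed(36)
  betahat <- rnorm(300)
  se <- rep(2, 300)
  # all alphas give the same original-scale likelihood; tie goes to smallest
  expect_equal(fit_alpha(betahat, se, alpha_grid = c(0, 0.5, 1)), 0)
  s0 <- ebshrink:::alpha_score(0, betahat, se, likelihood("normal"),
                               "normal", sqrt(2), 10, TRUE, 0)
  s1 <- ebshrink:::alpha_score(1, betahat, se, likelihood("normal"),
                               "normal", sqrt(2), 10, TRUE, 0)
  expect_equal(s0, s1, tolerance = 1e-9)
})

test_that("alpha selection recovers precision-dependent effects", {
  # beta_j = se_j * b_j with b ~ 0.5 delta0 + 0.5 N(0,1): true alpha = 1
  hits <- 0L
  nrep <- 20L
  for (r in seq_len(nrep)) {
    set.seed(100 + r)
    J <- 5000
    se <- runif(J, 0.5, 5)
    b <- ifelse(runif(J) < 0.5, 0, rnorm(J))
    betahat <- se * b + rnorm(J, 0, se)
    if (fit_alpha(betahat, se, alpha_grid = c(0, 0.5, 1)) == 1) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * nrep)
})

test_that("with alpha = 1 inference depends only on z-scores", {
  set.seed(37)
  J <- 500
  betahat <- rnorm(J, 0, 2)
  se <- rep(1, J)
  f1 <- ash(betahat, se, alpha = 1)
  f2 <- ash(2 * betahat, 2 * se, alpha = 1)
  expect_equal(f2$result$lfsr, f1$result$lfsr, tolerance = 1e-8)
  expect_equal(f2$result$lfdr, f1$result$lfdr, tolerance = 1e-8)
})

test_that("ash on pure-null data keeps the null proportion high", {
  set.seed(38)
  betahat <- rnorm(1000)
  fit <- ash(betahat, rep(1, 1000))
  expect_gte(pi0(fit$fitted_g), 0.9)
})

test_that("removing the point mass removes the lfdr atom", {
  set.seed(39)
  betahat <- rnorm(200, 0, 2)
  fit <- ash(betahat, rep(1, 200), pointmass = FALSE)
  expect_true(all(fit$result$lfdr == 0))
  expect_equal(pi0(fit$fitted_g), 0)
  expect_true(all(fit$result$lfsr >= 0))
})

test_that("identical calls give identical fits and lfsr dominates lfdr", {
  set.seed(40)
  betahat <- rnorm(300, 0, 1.5)
  se <- runif(300, 0.5, 2)
  f1 <- ash(betahat, se)
  f2 <- ash(betahat, se)
  expect_identical(f1$result, f2$result)
  expect_true(all(f1$result$lfsr >= f1$result$lfdr - 1e-12))
  expect_error(ash(numeric(0), numeric(0)), "empty")
})
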