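# Independent numeric oracles: everything here integrates densities directly
# with stats::integrate, never through the package's closed forms.

# marginal density of betahat under one prior component convolved with the
# noise model (normal, or scaled t with df)
quad_marginal <- function(betahat, se, type, sd = 0, a = 0, b = 0, mode = 0,
                          df = NULL) {
  noise <- function(beta) {
    if (is.null(df)) dnorm(betahat, beta, se)
    else dt((betahat - beta) / se, df) / se
  }
  switch(type,
    point = noise(mode),
    normal = integrate(function(beta) dnorm(beta, mode, sd) * noise(beta),
                       mode - 10 * sd - 10 * se, mode + 10 * sd + 10 * se,
                       rel.tol = 1e-10)$value,
    uniform = integrate(function(beta) dunif(beta, mode + a, mode + b) *
                          noise(beta),
                        mode + a, mode + b, rel.tol = 1e-10)$value)
}

# posterior summaries for one observation under a full mixture prior, by
# numeric integration of prior x likelihood (atom handled analytically)
quad_posterior <- function(g, betahat, se, df = NULL) {
  noise <- function(beta) {
    if (is.null(df)) dnorm(betahat, beta, se)
    else dt((betahat - beta) / se, df) / se
  }
  f <- function(beta) dmixprior(g, beta)$density * noise(beta)
  atom_mass <- sum(g$pi[g$type == "point"]) * noise(g$mode)
  lim <- abs(g$mode) + max(g$sd) * 12 + max(abs(c(g$a, g$b))) +
    abs(betahat) + 12 * se
  # integrate piecewise between density kinks (uniform edges) for accuracy
  edges <- sort(unique(c(-lim, 0, lim,
                         (g$mode + g$a)[g$type == "uniform"],
                         (g$mode + g$b)[g$type == "uniform"])))
  edges <- edges[edges >= -lim & edges <= lim]
  int_pieces <- function(fun, lo, hi) {
    cuts <- edges[edges > lo & edges < hi]
    pts <- c(lo, cuts, hi)
    sum(vapply(seq_len(length(pts) - 1L), function(i) {
      if (pts[i + 1] <= pts[i]) 0
      else integrate(fun, pts[i], pts[i + 1], rel.tol = 1e-11,
                     abs.tol = 1e-15, subdivisions = 400L)$value
    }, numeric(1)))
  }
  z_neg <- int_pieces(f, -lim, 0)
  z_pos <- int_pieces(f, 0, lim)
  Z <- z_neg + z_pos + atom_mass
  m1 <- (int_pieces(function(b) b * f(b), -lim, lim) + g$mode * atom_mass) / Z
  m2 <- (int_pieces(function(b) b^2 * f(b), -lim, lim) +
           g$mode^2 * atom_mass) / Z
  neg <- (z_neg + atom_mass * (g$mode < 0)) / Z
  zero <- atom_mass * (g$mode == 0) / Z
  pos <- 1 - neg - zero
  list(mean = m1, sd = sqrt(max(m2 - m1^2, 0)),
       NegativeProb = neg, ZeroProb = zero, PositiveProb = pos,
       lfdr = zero, lfsr = min(neg, pos) + zero)
}

# random valid mixture prior on a symmetric-ish grid (seeded by caller)
random_prior <- function(K = 4, mode = 0, family = c("normal", "uniform")) {
  family <- match.arg(family)
  w <- rgamma(K + 1, 1)
  w <- w / sum(w)
  sd <- sort(rexp(K, 1)) + 0.05
  if (family == "normal")
    mixture_prior(pi = w, type = c("point", rep("normal", K)),
                  sd = c(0, sd), mode = mode)
  else
    mixture_prior(pi = w, type = c("point", rep("uniform", K)),
                  a = c(0, -sd), b = c(0, sd), mode = mode)
}

# brute-force penalized-likelihood maximization over a simplex grid
# (vectorized batch evaluation, coarse scan + local refinement)
simplex_scan <- function(L, lambda, step = 0.01, refine_step = 2e-4) {
  K <- ncol(L)
  stopifnot(K <= 3)
  D <- exp(L)
  batch_obj <- function(P) {    # P: n x K matrix of weight vectors
    M <- D %*% t(P)             # J x n mixture densities
    ll <- colSums(log(M))
    pen <- as.vector(ifelse(P > 0, log(P), -Inf) %*% (lambda - 1))
    pen[!is.finite(pen)] <- -Inf
    ll + pen
  }
  make_grid <- function(lo, hi, s) {
    g1 <- seq(max(lo[1], 0), min(hi[1], 1), by = s)
    if (K == 2) {
      P <- cbind(g1, 1 - g1)
    } else {
      g2 <- seq(max(lo[2], 0), min(hi[2], 1), by = s)
      P <- as.matrix(expand.grid(g1, g2))
      P <- cbind(P, 1 - rowSums(P))
      P <- P[P[, K] >= 0, , drop = FALSE]
    }
    P
  }
  if (K == 1) return(list(pi = 1, value = penalized_loglik(1, L, lambda)))
  P <- make_grid(rep(0, K), rep(1, K), step)
  v <- batch_obj(P)
  best <- P[which.max(v), ]
  P2 <- make_grid(best - step, best + step, refine_step)
  v2 <- batch_obj(P2)
  i <- which.max(v2)
  list(pi = P2[i, ], value = v2[i])
}
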