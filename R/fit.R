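# Row-wise max via max.col (C-level; much faster than apply for tall matrices)
row_max <- function(A) A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]

# Row-wise log-sum-exp of L + log(pi) for a weight vector pi.
logsumexp_rows <- function(L, logpi) {
  A <- sweep(L, 2L, logpi, `+`)
  m <- row_max(A)
  m + log(rowSums(exp(A - m)))
}

#' Penalized mixture log-likelihood
#'
#' The observed-data log-likelihood of the mixture weights, `sum_j log sum_k
#' pi_k exp(L[j,k])`, plus a Dirichlet-type penalty `sum_k (lambda_k - 1) *
#' log(pi_k)`. The penalty (default weight 10 on the point mass, 1 elsewhere)
#' pushes the estimated null proportion as high as the data allow, keeping
#' downstream FDR estimates conservative. A term with `lambda_k = 1`
#' contributes exactly 0 whatever `pi_k`; `pi_k = 0` with `lambda_k > 1`
#' yields `-Inf` (a boundary value, not an error).
#'
#' @param pi numeric simplex weights (length K).
#' @param L J x K matrix of component log-likelihoods ([loglik_matrix()]).
#' @param lambda penalty weights, all >= 1.
#' @return numeric scalar (possibly `-Inf`).
#' @export
penalized_loglik <- function(pi, L, lambda = rep(1, length(pi))) {
  stopifnot(length(pi) == ncol(L), length(lambda) == length(pi),
            all(lambda >= 1))
  logpi <- ifelse(pi > 0, log(pi), -Inf)
  ll <- sum(logsumexp_rows(L, logpi))
  pen <- sum(ifelse(lambda == 1, 0, (lambda - 1) * logpi))
  ll + pen
}

# one EM step: responsibilities then penalized weight update
em_step <- function(pi, L, lambda) {
  logpi <- ifelse(pi > 0, log(pi), -Inf)
  A <- sweep(L, 2L, logpi, `+`)
  W <- exp(A - row_max(A))
  W <- W / rowSums(W)
  counts <- colSums(W) + lambda - 1
  counts <- pmax(counts, 0)
  counts / sum(counts)
}

#' Estimate mixture weights by penalized EM
#'
#' Maximizes [penalized_loglik()] over the simplex by EM, with an optional
#' squared-extrapolation (SQUAREM-style) acceleration that is guarded to keep
#' the objective non-decreasing: any extrapolated step that would lower the
#' penalized log-likelihood is replaced by the plain EM step. The objective is
#' concave in `pi`, so the EM fixed point is the global optimum.
#'
#' @param L J x K log-likelihood matrix; every row must contain a finite entry.
#' @param lambda penalty weights (>= 1), length K.
#' @param pi_init optional starting weights; default gives the first component
#'   (the point mass, by convention) half the mass and spreads the rest.
#' @param tol relative tolerance on the penalized log-likelihood (default 1e-7).
#' @param maxiter iteration cap (default 5000).
#' @param accelerate use the extrapolated update (default TRUE).
#' @return list with `pi`, `penloglik` (value at optimum), `loglik`
#'   (unpenalized), `niter`, `converged`, and `trace` of objective values.
#' @export
fit_pi <- function(L, lambda = c(10, rep(1, ncol(L) - 1L)), pi_init = NULL,
                   tol = 1e-7, maxiter = 5000L, accelerate = TRUE) {
  K <- ncol(L)
  stopifnot(length(lambda) == K, all(lambda >= 1))
  if (any(!apply(is.finite(L), 1L, any)))
    stop("every observation needs at least one finite component log-likelihood")
  if (is.null(pi_init)) {
    pi_init <- rep(1 / K, K)
    if (K > 1L) {                       # boost the leading (null) component
      pi_init[1L] <- pi_init[1L] + 0.5
      pi_init <- pi_init / sum(pi_init)
    }
  }
  pi <- pi_init
  obj <- penalized_loglik(pi, L, lambda)
  trace <- obj
  converged <- FALSE
  it <- 0L
  while (it < maxiter) {
    it <- it + 1L
    p1 <- em_step(pi, L, lambda)
    if (accelerate) {
      p2 <- em_step(p1, L, lambda)
      r <- p1 - pi
      v <- p2 - p1 - r
      sv <- sqrt(sum(v^2))
      cand <- if (sv > 0) {
        alpha <- -sqrt(sum(r^2)) / sv
        alpha <- min(alpha, -1)
        pe <- pi - 2 * alpha * r + alpha^2 * v
        pe <- pmax(pe, 0); pe <- pe / sum(pe)
        em_step(pe, L, lambda)          # stabilizing EM step after extrapolation
      } else p2
      new_obj <- penalized_loglik(cand, L, lambda)
      obj2 <- penalized_loglik(p2, L, lambda)
      if (!is.finite(new_obj) || new_obj < obj2) { cand <- p2; new_obj <- obj2 }
    } else {
      cand <- p1
      new_obj <- penalized_loglik(cand, L, lambda)
    }
    if (new_obj < obj - 1e-10) {        # guard: EM never decreases the objective
      cand <- p1
      new_obj <- penalized_loglik(cand, L, lambda)
    }
    pi <- cand
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(new_obj - obj) <= tol * (abs(obj) + 1e-8)) {
      obj <- new_obj
      converged <- TRUE
      break
    }
    obj <- new_obj
  }
  if (!converged)
    warning("EM did not converge in ", maxiter, " iterations")
  logpi <- ifelse(pi > 0, log(pi), -Inf)
  list(pi = pi, penloglik = obj, loglik = sum(logsumexp_rows(L, logpi)),
       niter = it, converged = converged, trace = trace)
}

# profile penalized log-likelihood over the mode by 1-d bounded search;
# grid and likelihood matrix are rebuilt at each candidate so the whole
# problem is translation-equivariant.
fit_mode <- function(betahat, sebetahat, lik, family, gridmult, lambda0,
                     pointmass, tol_scale = 1e-3) {
  if (length(betahat) < 2L)
    stop("mode estimation needs at least two observations")
  profile <- function(m) {
    comps <- grid_with_pointmass(betahat - m, sebetahat, gridmult, family,
                                 pointmass)
    L <- loglik_matrix(betahat, sebetahat, comps, lik = lik, mode = m)
    lambda <- penalty_vector(comps, lambda0, pointmass)
    fit_pi(L, lambda, tol = 1e-6)$penloglik
  }
  opt <- stats::optimize(profile, range(betahat), maximum = TRUE,
                         tol = tol_scale * stats::median(sebetahat))
  opt$maximum
}

# original-scale log-likelihood for a candidate alpha: fit on the rescaled
# problem, add the change-of-variables term -alpha * sum(log se)
alpha_score <- function(alpha, betahat, sebetahat, lik, family, gridmult,
                        lambda0, pointmass, mode) {
  bt <- betahat / sebetahat^alpha
  st <- sebetahat^(1 - alpha)
  comps <- grid_with_pointmass(bt - mode, st, gridmult, family, pointmass)
  L <- loglik_matrix(bt, st, comps, lik = lik, mode = mode)
  lambda <- penalty_vector(comps, lambda0, pointmass)
  fit_pi(L, lambda)$loglik - alpha * sum(log(sebetahat))
}

#' Select the effect-scale exponent alpha by maximum likelihood
#'
#' Under the scaled model the standardized effects `beta_j / se_j^alpha` are
#' i.i.d. from the unimodal prior: `alpha = 0` makes effects independent of
#' their precision, `alpha = 1` ties effect size to standard error (and makes
#' the fit depend on the data only through z-scores). Each candidate alpha is
#' scored by the original-scale marginal log-likelihood (fitted log-likelihood
#' of the rescaled data plus the Jacobian term `-alpha * sum(log se)`); ties
#' go to the smallest alpha (the least aggressive rescaling).
#'
#' @param betahat,sebetahat effect estimates and standard errors.
#' @param alpha_grid candidate values in \[0, 1\].
#' @param family,gridmult,lambda0,pointmass,mode,lik as in [ash()].
#' @return the selected alpha (scalar).
#' @export
fit_alpha <- function(betahat, sebetahat, alpha_grid = c(0, 0.5, 1),
                      family = "normal", gridmult = sqrt(2), lambda0 = 10,
                      pointmass = TRUE, mode = 0,
                      lik = likelihood("normal")) {
  stopifnot(length(alpha_grid) >= 1, all(alpha_grid >= 0 & alpha_grid <= 1))
  alpha_grid <- sort(alpha_grid)
  scores <- vapply(alpha_grid, alpha_score, numeric(1), betahat = betahat,
                   sebetahat = sebetahat, lik = lik, family = family,
                   gridmult = gridmult, lambda0 = lambda0,
                   pointmass = pointmass, mode = mode)
  alpha_grid[which.max(scores)]   # which.max takes the first (smallest) on ties
}

# assemble grid components with the point mass prepended (index 1)
grid_with_pointmass <- function(betahat, sebetahat, gridmult, family,
                                pointmass) {
  comps <- build_grid(betahat, sebetahat, mult = gridmult, family = family)
  if (pointmass) {
    comps$type <- c("point", comps$type)
    comps$sd <- c(0, comps$sd)
    comps$a <- c(0, comps$a)
    comps$b <- c(0, comps$b)
  }
  comps
}

penalty_vector <- function(comps, lambda0, pointmass) {
  K <- length(comps$type)
  lambda <- rep(1, K)
  if (pointmass) lambda[1L] <- lambda0
  lambda
}

#' Adaptive shrinkage: fit the empirical Bayes model
#'
#' Fits a unimodal mixture prior to effect estimates and standard errors by
#' penalized maximum likelihood, then computes per-effect posterior summaries:
#' local false discovery rate (`lfdr`), local false sign rate (`lfsr`),
#' shrinkage posterior mean and sd, credible bounds, and s-/q-values.
#'
#' The prior is a point mass at the mode plus components on a fixed grid of
#' scales ([build_grid()]): zero-centred normals (`mixcompdist = "normal"`,
#' symmetric priors), symmetric uniforms (`"uniform"`), or mode-anchored
#' half-uniform pairs (`"halfuniform"`, allowing asymmetry). Only the weights
#' are estimated ([fit_pi()]); the penalty `lambda0` on the point mass keeps
#' the estimated null proportion — and hence FDR-type quantities —
#' conservative.
#'
#' @param betahat numeric vector of effect estimates.
#' @param sebetahat numeric vector of positive standard errors.
#' @param mixcompdist prior component family: `"normal"`, `"uniform"` or
#'   `"halfuniform"`.
#' @param df degrees of freedom for a t noise model; `NULL` (default) for
#'   normal noise. The t model requires a uniform-family prior.
#' @param pointmass include a point mass at the mode (default TRUE). Turning
#'   it off asserts that no effect is exactly null; `lfdr` is then 0.
#' @param lambda0 penalty weight on the point mass (default 10; 1 disables).
#' @param gridmult grid spacing multiplier (> 1, default `sqrt(2)`).
#' @param alpha effect-scale exponent in \[0,1\], or `"estimate"` to pick it by
#'   maximum likelihood over `alpha_grid`. Default 0 (effects independent of
#'   precision).
#' @param alpha_grid candidates used when `alpha = "estimate"`.
#' @param mode prior mode, or `"estimate"` to fit it by profile likelihood.
#'   Default 0.
#' @param ci_level credible level for the two-sided interval and the one-sided
#'   lower bound (default 0.95).
#' @param tol,maxiter EM stopping rule (relative penalized log-likelihood
#'   change, default 1e-7; cap 5000).
#' @param optimizer `"accelerated_em"` (default) or `"em"`.
#'
#' @return An object of class `"ash"`: list with `fitted_g` (a
#'   [mixture_prior()]), `result` (data frame with columns betahat, sebetahat,
#'   lfdr, lfsr, svalue, qvalue, PosteriorMean, PosteriorSD, CredibleLower,
#'   CredibleUpper, NegativeProb, PositiveProb), `loglik`, `penloglik`,
#'   `alpha`, `mode`, `niter`, `converged`, and the call.
#' @examples
#' set.seed(1)
#' betahat <- c(rnorm(500), rnorm(500, 0, 3))
#' fit <- ash(betahat, rep(1, 1000))
#' head(fit$result)
#' pi0(fit$fitted_g)
#' @export
ash <- function(betahat, sebetahat,
                mixcompdist = c("normal", "uniform", "halfuniform"),
                df = NULL, pointmass = TRUE, lambda0 = 10,
                gridmult = sqrt(2), alpha = 0, alpha_grid = c(0, 0.5, 1),
                mode = 0, ci_level = 0.95, tol = 1e-7, maxiter = 5000L,
                optimizer = c("accelerated_em", "em")) {
  cl <- match.call()
  mixcompdist <- match.arg(mixcompdist)
  optimizer <- match.arg(optimizer)
  if (length(betahat) == 0L) stop("empty input")
  if (length(sebetahat) == 1L) sebetahat <- rep(sebetahat, length(betahat))
  stopifnot(length(sebetahat) == length(betahat),
            ci_level > 0, ci_level < 1, lambda0 >= 1)
  if (any(!is.finite(betahat)) || any(!is.finite(sebetahat)) ||
      any(sebetahat <= 0))
    stop("betahat must be finite and sebetahat finite and positive")
  lik <- if (is.null(df)) likelihood("normal") else likelihood("t", df = df)
  if (lik$kind == "t" && mixcompdist == "normal")
    stop("the t likelihood requires mixcompdist 'uniform' or 'halfuniform'")

  if (identical(alpha, "estimate")) {
    alpha <- fit_alpha(betahat, sebetahat, alpha_grid, family = mixcompdist,
                       gridmult = gridmult, lambda0 = lambda0,
                       pointmass = pointmass,
                       mode = if (identical(mode, "estimate")) 0 else mode,
                       lik = lik)
  }
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  # rescaled problem: beta/se^alpha has standard error se^(1-alpha)
  bt <- betahat / sebetahat^alpha
  st <- sebetahat^(1 - alpha)

  if (identical(mode, "estimate")) {
    if (mixcompdist == "halfuniform")
      message("estimating the mode with half-uniform components; ",
              "the point-mass penalty is retained")
    mode <- fit_mode(bt, st, lik, mixcompdist, gridmult, lambda0, pointmass)
  }
  stopifnot(is.numeric(mode), length(mode) == 1L)

  comps <- grid_with_pointmass(bt - mode, st, gridmult, mixcompdist, pointmass)
  L <- loglik_matrix(bt, st, comps, lik = lik, mode = mode)
  lambda <- penalty_vector(comps, lambda0, pointmass)
  fit <- fit_pi(L, lambda, tol = tol, maxiter = maxiter,
                accelerate = optimizer == "accelerated_em")
  g <- mixture_prior(pi = fit$pi, type = comps$type, sd = comps$sd,
                     a = comps$a, b = comps$b, mode = mode)

  post <- posterior_summary(g, bt, st, lik = lik, ci_level = ci_level, L = L)
  # map back to the original effect scale: beta = se^alpha * (beta/se^alpha)
  sc <- sebetahat^alpha
  res <- data.frame(
    betahat = betahat,
    sebetahat = sebetahat,
    lfdr = post$lfdr,
    lfsr = post$lfsr,
    svalue = svalue(post$lfsr),
    qvalue = qvalue_from_lfdr(post$lfdr),
    PosteriorMean = sc * post$PosteriorMean,
    PosteriorSD = sc * post$PosteriorSD,
    CredibleLower = sc * post$CredibleLower,
    CredibleUpper = sc * post$CredibleUpper,
    NegativeProb = post$NegativeProb,
    PositiveProb = post$PositiveProb)
  structure(list(fitted_g = g, result = res, loglik = fit$loglik,
                 penloglik = fit$penloglik, alpha = alpha, mode = mode,
                 lik = lik, ci_level = ci_level,
                 lower_bound = sc * post$LowerBound, niter = fit$niter,
                 converged = fit$converged, call = cl),
            class = "ash")
}
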