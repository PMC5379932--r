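#' Simulation scenario
#'
#' Describes one generative setting for the simulation harness: a law for the
#' null proportion pi0, a mixture-of-normals distribution g1 for the non-zero
#' effects, a standard-error specification, and the dataset size.
#'
#' @param name scenario label.
#' @param g1_weights,g1_means,g1_sds the non-null effect distribution: a
#'   mixture of normals with these weights (summing to 1), means and sds.
#' @param pi0 either a fixed value in \[0, 1\] or `"uniform"` to draw
#'   `pi0 ~ U[0, 1]` per dataset.
#' @param se_spec `"constant"` (all standard errors `se_value`) or `"mixed"`
#'   (half the observations at `se_value`, half at `10 * se_value`).
#' @param se_value baseline standard error (default 1).
#' @param J observations per dataset (default 1000).
#' @return object of class `"ebs_scenario"`.
#' @export
scenario <- function(name, g1_weights, g1_means, g1_sds, pi0 = "uniform",
                     se_spec = c("constant", "mixed"), se_value = 1,
                     J = 1000L) {
  se_spec <- match.arg(se_spec)
  stopifnot(abs(sum(g1_weights) - 1) < 1e-8,
            length(g1_means) == length(g1_weights),
            length(g1_sds) == length(g1_weights),
            J >= 1)
  if (!identical(pi0, "uniform"))
    stopifnot(is.numeric(pi0), pi0 >= 0, pi0 <= 1)
  structure(list(name = name, g1_weights = g1_weights / sum(g1_weights),
                 g1_means = g1_means, g1_sds = g1_sds, pi0 = pi0,
                 se_spec = se_spec, se_value = se_value, J = as.integer(J)),
            class = "ebs_scenario")
}

#' Standard simulation scenarios
#'
#' The named non-null effect distributions used throughout the simulation
#' study, from a "spiky" scale mixture concentrated near zero (where the null
#' proportion is nearly unidentifiable) to a wide single normal
#' ("big-normal"), plus one asymmetric ("skew") and one deliberately bimodal
#' shape that violates the unimodal assumption.
#'
#' @param names optional subset of scenario names.
#' @return named list of [scenario()] objects.
#' @export
default_scenarios <- function(names = NULL) {
  sc <- list(
    spiky = scenario("spiky", c(0.4, 0.2, 0.2, 0.2), rep(0, 4),
                     c(0.25, 0.5, 1, 2)),
    `near-normal` = scenario("near-normal", c(2/3, 1/3), c(0, 0), c(1, 2)),
    `flat-top` = scenario("flat-top", rep(1/7, 7),
                          seq(-1.5, 1.5, by = 0.5), rep(0.5, 7)),
    skew = scenario("skew", c(1/4, 1/4, 1/3, 1/6), c(-2, -1, 0, 1),
                    c(2, 1.5, 1, 1)),
    `big-normal` = scenario("big-normal", 1, 0, 4),
    bimodal = scenario("bimodal", c(0.5, 0.5), c(-2, 2), c(1, 1)))
  if (!is.null(names)) {
    missing <- setdiff(names, names(sc))
    if (length(missing)) stop("unknown scenario(s): ",
                              paste(missing, collapse = ", "))
    sc <- sc[names]
  }
  sc
}

# the unimodal-assumption scenarios (bimodal excluded)
ua_scenario_names <- function()
  c("spiky", "near-normal", "flat-top", "skew", "big-normal")

#' Simulate one dataset from a scenario
#'
#' Draws `pi0` (if random), true effects from `pi0 * delta_0 + (1 - pi0) *
#' g1`, standard errors per the scenario, and observed estimates
#' `betahat_j ~ N(beta_j, se_j^2)`.
#'
#' @param sc a [scenario()].
#' @param seed integer seed for reproducibility.
#' @return list with `beta`, `betahat`, `se`, `pi0`, `scenario`.
#' @export
simulate_dataset <- function(sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- sc$J
  p0 <- if (identical(sc$pi0, "uniform")) stats::runif(1) else sc$pi0
  null <- stats::runif(J) < p0
  beta <- numeric(J)
  n1 <- sum(!null)
  if (n1 > 0) {
    k <- sample.int(length(sc$g1_weights), n1, replace = TRUE,
                    prob = sc$g1_weights)
    beta[!null] <- stats::rnorm(n1, sc$g1_means[k], sc$g1_sds[k])
  }
  se <- switch(sc$se_spec,
    constant = rep(sc$se_value, J),
    mixed = rep(c(sc$se_value, 10 * sc$se_value), length.out = J))
  betahat <- stats::rnorm(J, beta, se)
  list(beta = beta, betahat = betahat, se = se, pi0 = p0, scenario = sc$name)
}

#' Oracle posterior quantities under the true generative prior
#'
#' Bayes-rule lfdr, lfsr and posterior mean computed from the *true*
#' `pi0` and mixture-of-normals `g1` (closed form: every posterior is again a
#' mixture of a point mass and normals). Used as the ground-truth axis in
#' calibration comparisons.
#'
#' @param p0 true null proportion.
#' @param sc the generating [scenario()] (supplies g1).
#' @param betahat,se observed data.
#' @return data frame with columns lfdr, lfsr, PosteriorMean.
#' @export
true_posterior_quantities <- function(p0, sc, betahat, se) {
  J <- length(betahat)
  w <- sc$g1_weights; mu <- sc$g1_means; sdg <- sc$g1_sds
  K <- length(w)
  # marginal log densities: null column then g1 components
  L <- matrix(0, J, K + 1L)
  L[, 1L] <- stats::dnorm(betahat, 0, se, log = TRUE)
  for (k in seq_len(K))
    L[, k + 1L] <- stats::dnorm(betahat, mu[k], sqrt(sdg[k]^2 + se^2),
                                log = TRUE)
  prior <- c(p0, (1 - p0) * w)
  W <- posterior_weights(prior, L)
  # conditional posteriors: component k is normal
  neg <- W[, 1L] * 0
  post_mean <- numeric(J)
  for (k in seq_len(K)) {
    shr <- sdg[k]^2 / (sdg[k]^2 + se^2)
    m_post <- mu[k] + (betahat - mu[k]) * shr
    tau <- sqrt(shr) * se
    neg <- neg + W[, k + 1L] * stats::pnorm(0, m_post, tau)
    post_mean <- post_mean + W[, k + 1L] * m_post
  }
  zero <- W[, 1L]
  pos <- pmax(1 - neg - zero, 0)
  data.frame(lfdr = zero, lfsr = pmin(neg, pos) + zero,
             PosteriorMean = post_mean)
}

# map the short method labels to ash() arguments
method_family <- function(method = c("ash.n", "ash.u", "ash.hu")) {
  switch(match.arg(method), ash.n = "normal", ash.u = "uniform",
         ash.hu = "halfuniform")
}

#' Null-proportion calibration experiment
#'
#' For each scenario, simulates `nreps` datasets (pi0 drawn uniformly per
#' dataset), fits the model, and records the true and estimated null
#' proportion. The headline summary is the fraction of datasets in which
#' `pi0` is overestimated (conservative behaviour).
#'
#' @param scenarios list of [scenario()] objects (default the five unimodal
#'   ones).
#' @param nreps datasets per scenario (default 100).
#' @param method `"ash.n"`, `"ash.u"` or `"ash.hu"`.
#' @param seed base seed; dataset r of scenario i uses a derived child seed.
#' @return data frame with columns scenario, rep, pi0_true, pi0_hat,
#'   conservative.
#' @export
pi0_calibration_experiment <- function(scenarios =
                                         default_scenarios(ua_scenario_names()),
                                       nreps = 100L, method = "ash.n",
                                       seed = 1L) {
  family <- method_family(method)
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    rows <- vector("list", nreps)
    for (r in seq_len(nreps)) {
      d <- simulate_dataset(sc, seed = child_seed(seed, i, r))
      fit <- ash(d$betahat, d$se, mixcompdist = family)
      rows[[r]] <- data.frame(scenario = sc$name, rep = r, pi0_true = d$pi0,
                              pi0_hat = pi0(fit$fitted_g))
    }
    out[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, out)
  out$conservative <- out$pi0_hat >= out$pi0_true
  rownames(out) <- NULL
  out
}

#' Credible-bound coverage experiment
#'
#' Empirical coverage of nominal one-sided lower credible bounds: the pooled
#' fraction of observations whose true effect lies at or above the fitted
#' `q(1 - level)` posterior quantile. Also reported for the significant
#' discoveries (`lfsr <= 0.05`), split by the sign of the posterior mean,
#' where the lower bound plays a different scientific role (limiting effect
#' magnitude for negative discoveries; guaranteeing a minimum effect for
#' positive ones).
#'
#' @param scenarios list of [scenario()] objects.
#' @param nreps datasets per scenario (default 100).
#' @param level nominal bound level (default 0.95).
#' @param method `"ash.n"`, `"ash.u"` or `"ash.hu"`.
#' @param seed base seed.
#' @param signif_threshold lfsr cutoff defining a discovery (default 0.05).
#' @return data frame with one row per scenario: coverage_all, coverage_neg,
#'   coverage_pos and the pooled counts behind each.
#' @export
coverage_experiment <- function(scenarios = default_scenarios(),
                                nreps = 100L, level = 0.95,
                                method = "ash.n", seed = 1L,
                                signif_threshold = 0.05) {
  family <- method_family(method)
  out <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    cov_all <- n_all <- cov_neg <- n_neg <- cov_pos <- n_pos <- 0
    for (r in seq_len(nreps)) {
      d <- simulate_dataset(sc, seed = child_seed(seed, i, r))
      fit <- ash(d$betahat, d$se, mixcompdist = family, ci_level = level)
      covered <- d$beta >= fit$lower_bound
      cov_all <- cov_all + sum(covered); n_all <- n_all + length(covered)
      sig <- fit$result$lfsr <= signif_threshold
      sneg <- sig & fit$result$PosteriorMean < 0
      spos <- sig & fit$result$PosteriorMean > 0
      cov_neg <- cov_neg + sum(covered[sneg]); n_neg <- n_neg + sum(sneg)
      cov_pos <- cov_pos + sum(covered[spos]); n_pos <- n_pos + sum(spos)
    }
    out[[i]] <- data.frame(
      scenario = sc$name, method = method, level = level,
      coverage_all = cov_all / n_all,
      coverage_neg = if (n_neg > 0) cov_neg / n_neg else NA_real_,
      coverage_pos = if (n_pos > 0) cov_pos / n_pos else NA_real_,
      n_all = n_all, n_neg = n_neg, n_pos = n_pos)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Precision-contamination experiment
#'
#' Half the effects are null and half are N(0, 1), observed either with good
#' precision (se = 1) or poor precision (se = 10). Fits the model to the
#' good-precision observations alone and to the combined data, and compares
#' (i) each good observation's lfsr across the two analyses (poor-precision
#' observations have nearly flat likelihoods, so they should barely move it)
#' and (ii) true-positive yield at matched false-positive counts when ranking
#' by lfsr versus by p-value.
#'
#' @param J_good,J_poor observations at se = 1 and se = 10.
#' @param seed RNG seed.
#' @param fp_counts false-positive counts at which to compare rankings.
#' @return list with `good_lfsr` (data frame: alone, combined, per good
#'   observation), `mean_abs_change`, and `ranking` (data frame: fp, tp_lfsr,
#'   tp_pvalue).
#' @export
contamination_experiment <- function(J_good = 5000L, J_poor = 5000L,
                                     seed = 1L, fp_counts = c(10, 50, 100)) {
  set.seed(seed)
  simulate_half <- function(J, se) {
    null <- stats::runif(J) < 0.5
    beta <- ifelse(null, 0, stats::rnorm(J))
    list(beta = beta, betahat = stats::rnorm(J, beta, se),
         se = rep(se, J), null = null)
  }
  good <- simulate_half(J_good, 1)
  poor <- simulate_half(J_poor, 10)
  fit_alone <- ash(good$betahat, good$se)
  fit_comb <- ash(c(good$betahat, poor$betahat), c(good$se, poor$se))
  lfsr_alone <- fit_alone$result$lfsr
  lfsr_comb_good <- fit_comb$result$lfsr[seq_len(J_good)]

  # ranking comparison on the combined data
  null_all <- c(good$null, poor$null)
  pval <- 2 * stats::pnorm(-abs(c(good$betahat, poor$betahat) /
                                  c(good$se, poor$se)))
  tp_at_fp <- function(score, fp_target) {
    ord <- order(score)
    fp <- cumsum(null_all[ord])
    tp <- cumsum(!null_all[ord])
    vapply(fp_target, function(f) {
      idx <- which(fp <= f)
      if (length(idx) == 0L) 0L else max(tp[idx])
    }, integer(1))
  }
  ranking <- data.frame(fp = fp_counts,
                        tp_lfsr = tp_at_fp(fit_comb$result$lfsr, fp_counts),
                        tp_pvalue = tp_at_fp(pval, fp_counts))
  list(good_lfsr = data.frame(alone = lfsr_alone, combined = lfsr_comb_good),
       mean_abs_change = mean(abs(lfsr_comb_good - lfsr_alone)),
       ranking = ranking)
}

# deterministic child seed below 2^31 from a base seed and indices
child_seed <- function(seed, ...) {
  idx <- c(...)
  val <- as.double(seed)
  for (i in idx) val <- (val * 69069 + i * 12345) %% 2147483647
  as.integer(val)
}
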