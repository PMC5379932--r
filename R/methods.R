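#' @export
print.ash <- function(x, ...) {
  cat("Adaptive shrinkage fit (", length(x$result$betahat),
      " observations)\n", sep = "")
  cat("  family:", unique(x$fitted_g$type[x$fitted_g$type != "point"]),
      " components:", ncomp(x$fitted_g), "\n")
  cat("  mode:", format(x$mode), " alpha:", format(x$alpha), "\n")
  cat("  pi0 (null proportion):", format(pi0(x$fitted_g), digits = 4), "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      " (penalized:", format(x$penloglik, digits = 8), ")\n")
  if (!x$converged) cat("  WARNING: EM did not converge\n")
  invisible(x)
}

#' @export
summary.ash <- function(object, ...) {
  r <- object$result
  out <- list(
    n = nrow(r),
    pi0 = pi0(object$fitted_g),
    mode = object$mode,
    alpha = object$alpha,
    loglik = object$loglik,
    n_signif_lfsr05 = sum(r$lfsr <= 0.05),
    n_signif_qval05 = sum(r$qvalue <= 0.05),
    lfsr_quartiles = stats::quantile(r$lfsr, c(0.25, 0.5, 0.75)))
  class(out) <- "summary.ash"
  out
}

#' @export
print.summary.ash <- function(x, ...) {
  cat("Adaptive shrinkage fit summary\n")
  cat("  observations:       ", x$n, "\n")
  cat("  estimated pi0:      ", format(x$pi0, digits = 4), "\n")
  cat("  mode / alpha:       ", format(x$mode), "/", format(x$alpha), "\n")
  cat("  log-likelihood:     ", format(x$loglik, digits = 8), "\n")
  cat("  lfsr <= 0.05:       ", x$n_signif_lfsr05, "\n")
  cat("  qvalue <= 0.05:     ", x$n_signif_qval05, "\n")
  cat("  lfsr quartiles:     ",
      paste(format(x$lfsr_quartiles, digits = 3), collapse = "  "), "\n")
  invisible(x)
}

#' Shrinkage point estimates
#' @param object an `"ash"` fit.
#' @param ... unused.
#' @return posterior mean effect for each observation.
#' @export
coef.ash <- function(object, ...) object$result$PosteriorMean

#' @export
fitted.ash <- function(object, ...) object$result$PosteriorMean

#' @export
residuals.ash <- function(object, ...)
  object$result$betahat - object$result$PosteriorMean

#' Posterior draws of the effects
#'
#' Simulates from each observation's posterior: draw a component per the
#' posterior weights, then draw from the conditional (degenerate, normal, or
#' truncated noise distribution).
#'
#' @param object an `"ash"` fit.
#' @param nsim number of posterior draws per observation.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a J x nsim matrix of draws on the original effect scale.
#' @export
simulate.ash <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  g <- object$fitted_g
  bt <- object$result$betahat / object$result$sebetahat^object$alpha
  st <- object$result$sebetahat^(1 - object$alpha)
  L <- loglik_matrix(bt, st, g[c("type", "sd", "a", "b")],
                     lik = object$lik, mode = g$mode)
  W <- posterior_weights(g$pi, L)
  cp <- component_posteriors(g, bt, st, object$lik)
  J <- nrow(W)
  out <- matrix(0, J, nsim)
  for (j in seq_len(J)) {
    k <- sample.int(ncol(W), nsim, replace = TRUE, prob = W[j, ])
    for (kk in unique(k)) {
      idx <- which(k == kk)
      out[j, idx] <- switch(cp$kind[kk],
        point = cp$mu[j, kk],
        normal = stats::rnorm(length(idx), cp$mu[j, kk], cp$tau[j, kk]),
        truncnorm = ,
        trunct = {   # inverse-cdf draws within the truncation interval
          u <- stats::runif(length(idx))
          zl <- (cp$lo[j, kk] - cp$mu[j, kk]) / cp$tau[j, kk]
          zu <- (cp$hi[j, kk] - cp$mu[j, kk]) / cp$tau[j, kk]
          if (cp$kind[kk] == "truncnorm") {
            pl <- stats::pnorm(zl); pu <- stats::pnorm(zu)
            cp$mu[j, kk] + cp$tau[j, kk] *
              stats::qnorm(pl + u * (pu - pl))
          } else {
            pl <- stats::pt(zl, cp$nu[j]); pu <- stats::pt(zu, cp$nu[j])
            cp$mu[j, kk] + cp$tau[j, kk] *
              stats::qt(pl + u * (pu - pl), cp$nu[j])
          }
        })
    }
  }
  out * object$result$sebetahat^object$alpha
}

#' Plot a fitted adaptive shrinkage model
#'
#' Shows the fitted prior cdf (with its point-mass jump) and, optionally, the
#' shrinkage of the estimates (posterior mean against betahat).
#'
#' @param x an `"ash"` fit.
#' @param what `"cdf"` (fitted prior cdf) or `"shrinkage"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.ash <- function(x, what = c("cdf", "shrinkage"), ...) {
  what <- match.arg(what)
  g <- x$fitted_g
  if (what == "cdf") {
    lim <- max(abs(x$result$betahat)) + abs(g$mode)
    xs <- seq(-lim, lim, length.out = 400)
    graphics::plot(xs, pmixprior(g, xs), type = "l",
                   xlab = expression(beta), ylab = "cdf",
                   main = "Fitted effect distribution", ...)
  } else {
    graphics::plot(x$result$betahat, x$result$PosteriorMean,
                   xlab = "betahat", ylab = "posterior mean",
                   main = "Shrinkage", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Posterior summaries for new observations under a fitted prior
#'
#' Applies the fitted prior `g` to new (betahat, sebetahat) pairs, i.e. an
#' out-of-sample posterior computation without refitting the weights.
#'
#' @param object an `"ash"` fit.
#' @param newdata data frame with columns `betahat` and `sebetahat`; default
#'   the training data.
#' @param ... unused.
#' @return data frame of posterior summaries (see [posterior_summary()]).
#' @export
predict.ash <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$result)
  stopifnot(all(c("betahat", "sebetahat") %in% names(newdata)))
  bt <- newdata$betahat / newdata$sebetahat^object$alpha
  st <- newdata$sebetahat^(1 - object$alpha)
  post <- posterior_summary(object$fitted_g, bt, st, lik = object$lik,
                            ci_level = object$ci_level)
  sc <- newdata$sebetahat^object$alpha
  for (col in c("PosteriorMean", "PosteriorSD", "CredibleLower",
                "CredibleUpper", "LowerBound"))
    post[[col]] <- post[[col]] * sc
  post
}
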