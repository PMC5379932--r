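#' Construct a unimodal mixture prior
#'
#' A mixture prior `g` is a weighted combination of a point mass at the mode
#' and a set of components located at (or anchored to) the mode: zero-mean
#' normals with scales `sd`, or uniforms on offset intervals `(a, b)` relative
#' to the mode. This is the canonical family for adaptive shrinkage: a fixed,
#' dense grid of component scales with only the weights estimated.
#'
#' @param pi numeric vector of mixture weights; must be non-negative and sum
#'   to 1 (renormalized if within 1e-10, otherwise an error).
#' @param type character vector, one of `"point"`, `"normal"`, `"uniform"` per
#'   component.
#' @param sd numeric vector of component standard deviations (normal
#'   components; 0 otherwise).
#' @param a,b numeric vectors of interval offsets relative to the mode
#'   (uniform components; 0 otherwise). Requires `a <= b`.
#' @param mode location of the prior mode (effect units), default 0.
#'
#' @return An object of class `"mixprior"`: a list with elements `mode`, `pi`,
#'   `type`, `sd`, `a`, `b`.
#' @examples
#' g <- mixture_prior(pi = c(0.5, 0.5), type = c("point", "normal"),
#'                    sd = c(0, 1))
#' dmixprior(g, 0)
#' @export
mixture_prior <- function(pi, type, sd = NULL, a = NULL, b = NULL, mode = 0) {
  K <- length(pi)
  type <- match.arg(type, c("point", "normal", "uniform"), several.ok = TRUE)
  type <- rep_len(type, K)
  if (is.null(sd)) sd <- numeric(K)
  if (is.null(a)) a <- numeric(K)
  if (is.null(b)) b <- numeric(K)
  stopifnot(length(type) == K, length(sd) == K, length(a) == K,
            length(b) == K, is.numeric(mode), length(mode) == 1L)
  if (any(pi < 0)) stop("mixture weights must be non-negative")
  s <- sum(pi)
  if (abs(s - 1) > 1e-8) stop("mixture weights must sum to 1")
  pi <- pi / s
  if (any(sd < 0)) stop("component sd must be >= 0")
  if (any(a > b)) stop("uniform components require a <= b")
  # a degenerate uniform is a point mass at mode + midpoint
  degen <- type == "uniform" & (b - a) < 1e-12
  if (any(degen & (abs(a) > 0 | abs(b) > 0)))
    stop("degenerate uniform away from the mode is not representable; shift the mode")
  type[degen] <- "point"
  a[degen] <- b[degen] <- 0
  sd[type != "normal"] <- 0
  a[type != "uniform"] <- 0
  b[type != "uniform"] <- 0
  structure(list(mode = mode, pi = pi, type = type, sd = sd, a = a, b = b),
            class = "mixprior")
}

#' @export
print.mixprior <- function(x, ...) {
  cat("Unimodal mixture prior, mode =", format(x$mode), "\n")
  tab <- data.frame(type = x$type, pi = x$pi, sd = x$sd, a = x$a, b = x$b)
  print(tab, digits = 4)
  invisible(x)
}

#' Number of mixture components
#' @param g a `"mixprior"` object.
#' @return integer count of components (point mass included).
#' @export
ncomp <- function(g) length(g$pi)

#' Null-proportion of a fitted prior
#'
#' Weight on the point mass located exactly at zero; 0 if the prior carries no
#' such atom (no point mass, or mode shifted away from zero).
#' @param g a `"mixprior"` object.
#' @return numeric scalar in \[0, 1\].
#' @export
pi0 <- function(g) {
  if (g$mode != 0) return(0)
  sum(g$pi[g$type == "point"])
}

#' Build the default grid of component scales
#'
#' Component scales form a geometric sequence `sigma_min * mult^i`, truncated
#' at the first value at or above `sigma_max`, with endpoints
#' `sigma_min = min(se)/10` and `sigma_max = 2 * sqrt(max(betahat^2 - se^2))`
#' (floored at `sigma_min^2` so degenerate data still yield one scale). The
#' grid is dense enough that, with only the weights free, the mixture
#' approximates an arbitrary scale mixture (normal family) or any unimodal
#' distribution (uniform/half-uniform families).
#'
#' @param betahat numeric vector of effect estimates.
#' @param sebetahat numeric vector of standard errors (positive).
#' @param mult grid spacing multiplier, > 1 (default `sqrt(2)`).
#' @param family `"normal"`, `"uniform"` or `"halfuniform"`. Half-uniform
#'   yields mirror-symmetric pairs `(-sigma, 0)` and `(0, sigma)` per scale,
#'   allowing asymmetric unimodal priors.
#'
#' @return list with `type`, `sd`, `a`, `b` vectors describing the grid
#'   components (point mass not included; prepend it via [mixture_prior()]).
#' @examples
#' build_grid(c(-8, 8), c(1, 1), family = "normal")
#' @export
build_grid <- function(betahat, sebetahat, mult = sqrt(2),
                       family = c("normal", "uniform", "halfuniform")) {
  family <- match.arg(family)
  keep <- is.finite(sebetahat) & sebetahat > 0 & is.finite(betahat)
  if (!any(keep)) stop("no observation has a finite positive standard error")
  if (!(is.numeric(mult) && length(mult) == 1L && mult > 1))
    stop("grid multiplier must be a single number > 1")
  betahat <- betahat[keep]
  se <- sebetahat[keep]
  sigma_min <- min(se) / 10
  sigma_max <- 2 * sqrt(max(max(betahat^2 - se^2), sigma_min^2))
  # first scale at or past sigma_max ends the grid; the epsilon keeps exact
  # powers of mult from spilling into an extra scale through rounding
  n_scale <- max(1L, ceiling(log(sigma_max / sigma_min, base = mult) - 1e-10) + 1L)
  sigma <- sigma_min * mult^(seq_len(n_scale) - 1L)
  switch(family,
    normal = list(type = rep("normal", n_scale), sd = sigma,
                  a = numeric(n_scale), b = numeric(n_scale)),
    uniform = list(type = rep("uniform", n_scale), sd = numeric(n_scale),
                   a = -sigma, b = sigma),
    halfuniform = {
      K <- 2L * n_scale
      a <- b <- numeric(K)
      a[seq(1L, K, by = 2L)] <- -sigma   # left-anchored (-sigma, 0)
      b[seq(2L, K, by = 2L)] <- sigma    # right-anchored (0, sigma)
      list(type = rep("uniform", K), sd = numeric(K), a = a, b = b)
    })
}

#' Prior density with its atom
#'
#' Evaluates the continuous part of the prior density and the discrete atom
#' mass separately, because a point mass has no density.
#'
#' @param g a `"mixprior"` object.
#' @param x numeric vector of evaluation points.
#' @return list with numeric vectors `density` (continuous part) and `atom`
#'   (mass of any point component located exactly at `x`).
#' @export
dmixprior <- function(g, x) {
  dens <- numeric(length(x))
  atom <- numeric(length(x))
  for (k in seq_along(g$pi)) {
    w <- g$pi[k]
    if (w == 0) next
    switch(g$type[k],
      point = { atom[x == g$mode] <- atom[x == g$mode] + w },
      normal = { dens <- dens + w * stats::dnorm(x, g$mode, g$sd[k]) },
      uniform = {
        lo <- g$mode + g$a[k]; hi <- g$mode + g$b[k]
        dens <- dens + w * stats::dunif(x, lo, hi)
      })
  }
  list(density = dens, atom = atom)
}

#' Prior cumulative distribution function
#'
#' Right-continuous cdf of the mixture prior; jumps by the point-mass weight
#' at the mode.
#'
#' @inheritParams dmixprior
#' @return numeric vector of probabilities.
#' @export
pmixprior <- function(g, x) {
  p <- numeric(length(x))
  for (k in seq_along(g$pi)) {
    w <- g$pi[k]
    if (w == 0) next
    p <- p + w * switch(g$type[k],
      point = as.numeric(x >= g$mode),
      normal = stats::pnorm(x, g$mode, g$sd[k]),
      uniform = stats::punif(x, g$mode + g$a[k], g$mode + g$b[k]))
  }
  pmin(pmax(p, 0), 1)
}

#' Sample effects from a mixture prior
#'
#' @inheritParams dmixprior
#' @param n number of draws.
#' @param seed optional integer; if given, the RNG state is set (and restored
#'   on exit) so draws are reproducible.
#' @return numeric vector of `n` draws.
#' @export
rmixprior <- function(g, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- sample.int(length(g$pi), n, replace = TRUE, prob = g$pi)
  x <- numeric(n)
  for (kk in unique(k)) {
    idx <- which(k == kk)
    x[idx] <- switch(g$type[kk],
      point = g$mode,
      normal = stats::rnorm(length(idx), g$mode, g$sd[kk]),
      uniform = stats::runif(length(idx), g$mode + g$a[kk], g$mode + g$b[kk]))
  }
  x
}

#' Write a fitted prior to a plain-text file
#'
#' Serializes mode, family information and the per-component table as a
#' key/value header followed by a tab-separated block, so a fitted prior can
#' be reloaded with [read_prior()].
#'
#' @param g a `"mixprior"` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_prior <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("mode\t%.17g", g$mode),
               "component\ttype\tpi\tsd\ta\tb"), con)
  for (k in seq_along(g$pi)) {
    writeLines(sprintf("%d\t%s\t%.17g\t%.17g\t%.17g\t%.17g",
                       k, g$type[k], g$pi[k], g$sd[k], g$a[k], g$b[k]), con)
  }
  invisible(path)
}

#' Read a prior written by [write_prior()]
#' @param path file path.
#' @return a `"mixprior"` object.
#' @export
read_prior <- function(path) {
  lines <- readLines(path)
  mode <- as.numeric(strsplit(lines[1], "\t")[[1]][2])
  tab <- utils::read.delim(text = lines[-1], stringsAsFactors = FALSE)
  mixture_prior(pi = tab$pi, type = tab$type, sd = tab$sd,
                a = tab$a, b = tab$b, mode = mode)
}
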