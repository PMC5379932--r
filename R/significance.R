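#' Tail false sign rate over a set of observations
#'
#' The estimated proportion of sign errors made if the signs of all effects in
#' `gamma` were declared: the mean of their local false sign rates. Replacing
#' lfsr by lfdr gives the usual tail FDR of the set.
#'
#' @param lfsr numeric vector of local false sign rates.
#' @param gamma non-empty integer vector of indices into `lfsr`.
#' @return numeric scalar.
#' @export
tail_fsr <- function(lfsr, gamma) {
  if (length(gamma) == 0L) stop("gamma must be non-empty")
  if (any(gamma < 1L | gamma > length(lfsr))) stop("invalid index in gamma")
  mean(lfsr[gamma])
}

# cumulative mean after ascending sort, mapped back with ties pooled: each
# observation gets the mean of all values <= its own.
cummean_le <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  n <- length(x)
  cm <- cumsum(sort(x)) / seq_len(n)
  cm[rank(x, ties.method = "max")]
}

#' s-values: tail-averaged local false sign rates
#'
#' The s-value of observation j is the average lfsr over all observations at
#' least as significant (lfsr no larger), i.e. the sign-error analogue of the
#' q-value: rejecting every test with an s-value at or below `t` incurs an
#' estimated false sign rate of at most `t`. Tied lfsr values all receive the
#' same s-value.
#'
#' @param lfsr numeric vector in \[0, 1\].
#' @return numeric vector of s-values, `svalue[j] <= lfsr[j]`.
#' @export
svalue <- function(lfsr) cummean_le(lfsr)

#' q-values from local false discovery rates
#'
#' Same tail-averaging as [svalue()] applied to lfdr: the q-value estimates
#' the FDR incurred by declaring all observations with no larger lfdr to be
#' discoveries.
#'
#' @param lfdr numeric vector in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
qvalue_from_lfdr <- function(lfdr) cummean_le(lfdr)
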