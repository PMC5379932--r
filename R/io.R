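#' Read effect estimates from a delimited text file
#'
#' Expects a header with columns `betahat` and `sebetahat` (any order;
#' additional columns such as `df` and `id` are picked up when present). Rows
#' with missing values or non-positive standard errors are excluded with a
#' warning reporting their row numbers.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma from
#'   the header line.
#' @return data frame with columns `betahat`, `sebetahat`, and optionally
#'   `df`, `id`, in input row order.
#' @export
read_effects <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  for (col in c("betahat", "sebetahat"))
    if (!col %in% names(tab)) stop("required column missing: ", col)
  if (nrow(tab) == 0L) stop("empty table: ", path)
  keep <- is.finite(tab$betahat) & is.finite(tab$sebetahat) &
    tab$sebetahat > 0
  if (any(!keep)) {
    warning(sum(!keep), " row(s) excluded (missing values or se <= 0): rows ",
            paste(utils::head(which(!keep), 10L), collapse = ", "),
            if (sum(!keep) > 10L) ", ..." else "")
    tab <- tab[keep, , drop = FALSE]
  }
  if (nrow(tab) == 0L) stop("no usable rows in ", path)
  rownames(tab) <- NULL
  cols <- intersect(c("id", "betahat", "sebetahat", "df"), names(tab))
  tab[cols]
}

#' Write a fit's result table and sidecar model description
#'
#' Writes the fixed 12-column per-observation table (betahat, sebetahat,
#' lfdr, lfsr, svalue, qvalue, PosteriorMean, PosteriorSD, CredibleLower,
#' CredibleUpper, NegativeProb, PositiveProb) as tab-separated text with
#' floats at 6 significant digits, plus a `<path>.g` sidecar holding the
#' fitted prior ([write_prior()]) and headline fit facts.
#'
#' @param fit an `"ash"` object.
#' @param path output file path.
#' @param sidecar write the model sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, sidecar = TRUE) {
  stopifnot(inherits(fit, "ash"))
  cols <- c("betahat", "sebetahat", "lfdr", "lfsr", "svalue", "qvalue",
            "PosteriorMean", "PosteriorSD", "CredibleLower", "CredibleUpper",
            "NegativeProb", "PositiveProb")
  tab <- fit$result[cols]
  tab[] <- lapply(tab, signif, digits = 6)
  con <- file(path, "w")
  tryCatch(utils::write.table(tab, con, sep = "\t", quote = FALSE,
                              row.names = FALSE),
           finally = close(con))
  if (sidecar) {
    gpath <- paste0(path, ".g")
    con <- file(gpath, "w")
    writeLines(c(sprintf("pi0\t%.6g", pi0(fit$fitted_g)),
                 sprintf("alpha\t%.6g", fit$alpha),
                 sprintf("mode\t%.6g", fit$mode),
                 sprintf("loglik\t%.10g", fit$loglik),
                 sprintf("penloglik\t%.10g", fit$penloglik)), con)
    close(con)
    write_prior_append(fit$fitted_g, gpath)
  }
  invisible(path)
}

# append the prior block to an existing sidecar
write_prior_append <- function(g, path) {
  tmp <- tempfile()
  write_prior(g, tmp)
  cat(readLines(tmp), file = path, sep = "\n", append = TRUE)
  unlink(tmp)
  invisible(path)
}
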