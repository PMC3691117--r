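#' Quantile-normalize an intensity matrix
#'
#' Replaces each column's sorted values by the across-column mean of order
#' statistics, so that all columns share one distribution (identical as
#' multisets). Tied input values receive the mean of their candidate quantile
#' values (average-ranks dialect), removing order dependence.
#'
#' @param x numeric matrix, samples in columns; all values finite.
#' @return matrix of the same shape, column order preserved.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in input", call. = FALSE)
  if (ncol(x) < 2L) {
    warning("fewer than 2 columns; returning input unchanged")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

# One median-polish fit (overall + probe effect + sample effect) on a log2
# probe-set block; summary per sample = overall + sample effect.
polish_block <- function(log2block) {
  if (nrow(log2block) == 1L) {
    return(as.numeric(log2block))
  }
  # reaching the iteration cap is a valid stop condition, not a failure
  fit <- withCallingHandlers(
    stats::medpolish(log2block, eps = 1e-8, maxiter = 20, trace.iter = FALSE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fit$overall + fit$col
}

#' Summarize probe-level intensities by Tukey median polish
#'
#' Per probe set, fits \code{log2(intensity) = overall + probe + sample +
#' residual} by alternating median sweeps (rows then columns, relative
#' tolerance 1e-8 on the total absolute residual, at most 20 iterations); the
#' probe-set summary for a sample is \code{overall + sample effect}. Combined
#' with \code{\link{quantile_normalize}} this is the normalization and
#' summarization backbone of RMA-style preprocessing.
#'
#' @param probes linear-scale intensity matrix (probes x samples), all > 0.
#' @param probeset_ids character vector parallel to rows mapping each probe to
#'   its probe set.
#' @return log2 expression matrix, probe sets x samples, probe sets in first-
#'   appearance order.
#' @export
median_polish_summarize <- function(probes, probeset_ids) {
  if (!is.matrix(probes)) probes <- as.matrix(probes)
  if (length(probeset_ids) != nrow(probes)) {
    stop("probeset_ids must map every probe row", call. = FALSE)
  }
  if (any(probes <= 0)) stop("probe intensities must be > 0", call. = FALSE)
  sets <- unique(probeset_ids)
  lp <- log2(probes)
  out <- matrix(NA_real_, length(sets), ncol(probes),
                dimnames = list(sets, colnames(probes)))
  for (s in sets) {
    rows <- which(probeset_ids == s)
    if (length(rows) == 0L) stop("probe set with zero probes: ", s, call. = FALSE)
    out[s, ] <- polish_block(lp[rows, , drop = FALSE])
  }
  out
}
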