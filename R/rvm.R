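#' Fit the random-variance (inverse-gamma) prior to gene-wise variances
#'
#' Under the random-variance model the gene-wise precision is
#' \eqn{1/\sigma_g^2 \sim \mathrm{Gamma}(a, \mathrm{scale}=b)}, which implies
#' the marginal \eqn{s_g^2 \, a b \sim F(d, 2a)} for the pooled residual
#' variance \eqn{s_g^2} on \eqn{d} degrees of freedom. \code{fit_rvm_prior}
#' maximizes the corresponding marginal likelihood over \eqn{(\log a, \log
#' b)}. The fitted prior is shared by every gene and converts the per-gene
#' t-test into a moderated test with \eqn{d + 2a} degrees of freedom (see
#' \code{\link{rvm_t_test}}).
#'
#' @param variances per-gene pooled variances \eqn{s_g^2}; genes with zero
#'   variance are excluded from the fit (their count is recorded).
#' @param d residual degrees of freedom (\eqn{n_1 + n_2 - 2}), >= 1.
#' @param a_max upper cap on \eqn{a}; when the variances are (near-)constant
#'   the likelihood pushes \eqn{a} to infinity, the fit is capped here and
#'   flagged near-degenerate.
#' @return object of class \code{rvm_fit} with elements \code{a}, \code{b},
#'   \code{d}, \code{logLik}, \code{n_used}, \code{n_zero},
#'   \code{near_degenerate}.
#' @export
fit_rvm_prior <- function(variances, d, a_max = 1e6) {
  stopifnot(d >= 1)
  v <- variances[variances > 0]
  n_zero <- sum(variances <= 0)
  if (length(v) < 10L) stop("need at least 10 positive variances", call. = FALSE)

  negll <- function(theta) {
    a <- exp(theta[1]); b <- exp(theta[2])
    # density of s2: ab * f_F(ab * s2; d, 2a)
    ll <- sum(stats::df(v * a * b, d, 2 * a, log = TRUE) + log(a * b))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # moment-based start: for a > 1, E[s2] = 2a / (ab (2a - 2)) = a/(ab(a-1))
  a0 <- 2
  b0 <- a0 / (mean(v) * a0 * (a0 - 1))
  opt <- stats::optim(c(log(a0), log(b0)), negll, method = "L-BFGS-B",
                      lower = c(log(1e-8), log(1e-12)),
                      upper = c(log(a_max), log(1e12)),
                      control = list(maxit = 500))
  if (!opt$convergence %in% c(0L, 52L)) {
    stop("RVM prior fit did not converge (code ", opt$convergence, ") at (a=",
         signif(exp(opt$par[1]), 4), ", b=", signif(exp(opt$par[2]), 4), ")",
         call. = FALSE)
  }
  a_hat <- exp(opt$par[1]); b_hat <- exp(opt$par[2])
  near_deg <- a_hat >= a_max * 0.999
  if (near_deg) warning("near-degenerate prior: a capped at ", a_max)
  structure(list(a = a_hat, b = b_hat, d = d, logLik = -opt$value,
                 n_used = length(v), n_zero = n_zero,
                 near_degenerate = near_deg),
            class = "rvm_fit")
}

#' Log marginal likelihood of variances under a given prior
#'
#' Evaluates the F-marginal log-likelihood used by \code{\link{fit_rvm_prior}}
#' at an arbitrary \eqn{(a, b)}; useful for comparing the fitted prior with
#' the generating one.
#'
#' @param variances positive variances.
#' @param d residual df.
#' @param a,b prior shape and scale.
#' @return log-likelihood (scalar).
#' @export
rvm_logLik <- function(variances, d, a, b) {
  v <- variances[variances > 0]
  sum(stats::df(v * a * b, d, 2 * a, log = TRUE) + log(a * b))
}

#' @export
print.rvm_fit <- function(x, ...) {
  cat("Random-variance prior fit: 1/sigma^2 ~ Gamma(a, scale = b)\n")
  cat(sprintf("  a = %.4g, b = %.4g (d = %d, effective df = d + 2a = %.2f)\n",
              x$a, x$b, x$d, x$d + 2 * x$a))
  cat(sprintf("  logLik = %.2f on %d genes (%d zero-variance excluded)\n",
              x$logLik, x$n_used, x$n_zero))
  if (x$near_degenerate) cat("  NOTE: near-degenerate prior (a at cap)\n")
  invisible(x)
}

#' @export
coef.rvm_fit <- function(object, ...) c(a = object$a, b = object$b)

#' @export
logLik.rvm_fit <- function(object, ...) {
  structure(object$logLik, df = 2, class = "logLik")
}

#' Moderated two-sample t-test with random-variance shrinkage
#'
#' Per gene, the pooled variance \eqn{s_g^2} is shrunk toward the prior as
#' \eqn{\tilde\sigma_g^2 = (d s_g^2 + 2/b) / (d + 2a)} and the statistic
#' \deqn{\tilde t_g = (\bar x_{case} - \bar x_{control}) /
#'   \sqrt{\tilde\sigma_g^2 (1/n_1 + 1/n_2)}}
#' is referred to a Student t distribution with \eqn{d + 2a} degrees of
#' freedom (two-sided). In the degenerate limit \eqn{a \to 0, 1/b \to 0} this
#' reduces exactly to the ordinary pooled-variance t-test. Genes with zero
#' pooled variance receive the pure prior variance \eqn{(2/b)/(d + 2a)}.
#'
#' @param matrix genes x samples log2 matrix.
#' @param labels class per sample ("case"/"control"), both classes >= 2.
#' @param fit an \code{rvm_fit}; if \code{NULL}, fitted on these data.
#' @return data frame of class \code{feature_stats}: per gene the class means,
#'   pooled variance \code{s2}, shrunken \code{sigma2_tilde}, statistic
#'   \code{t}, effective \code{df}, and two-sided \code{p}.
#' @export
rvm_t_test <- function(matrix, labels, fit = NULL) {
  labels <- check_class_labels(labels)
  if (length(labels) != ncol(matrix)) stop("one label per sample", call. = FALSE)
  i1 <- labels == "case"; i2 <- labels == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("both classes need >= 2 samples", call. = FALSE)
  d <- n1 + n2 - 2
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  v1 <- apply(matrix[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(matrix[, i2, drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (is.null(fit)) fit <- fit_rvm_prior(s2, d)
  if (fit$d != d) stop("fit was made for d = ", fit$d, ", data have d = ", d,
                       call. = FALSE)
  sigma2_tilde <- (d * s2 + 2 / fit$b) / (d + 2 * fit$a)
  tstat <- (m1 - m2) / sqrt(sigma2_tilde * (1 / n1 + 1 / n2))
  df_eff <- d + 2 * fit$a
  p <- 2 * stats::pt(-abs(tstat), df_eff)
  out <- data.frame(gene_id = rownames(matrix), mean_case = m1,
                    mean_control = m2, s2 = s2, sigma2_tilde = sigma2_tilde,
                    t = tstat, df = df_eff, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("feature_stats", "data.frame"), fit = fit)
}

#' Select features at an unadjusted significance threshold
#'
#' Retains transcripts with unadjusted p below \code{alpha} (deliberately no
#' multiplicity correction: the step is a non-conservative enrichment filter,
#' not an inference), ordered by ascending p with ties broken by gene id.
#'
#' @param stats a \code{feature_stats} data frame from \code{\link{rvm_t_test}}.
#' @param alpha significance threshold in (0, 1]; default 0.05.
#' @return character vector of selected gene ids.
#' @export
select_features <- function(stats, alpha = 0.05) {
  stopifnot(alpha > 0, alpha <= 1)
  keep <- stats[stats$p < alpha, , drop = FALSE]
  keep$gene_id[order(keep$p, keep$gene_id)]
}
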