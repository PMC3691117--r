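#' Nested leave-one-out cross-validation of the panel-building pipeline
#'
#' For every held-out sample the entire model-building procedure is repeated
#' from scratch on the remaining n-1 samples: SVM-RFE re-selects the panel
#' from the candidate set, the classifier is retrained, and only then is the
#' held-out sample predicted. This nesting is what keeps the error estimate
#' honest; selecting genes on all n samples first and cross-validating only
#' the classifier underestimates the error badly.
#'
#' By default the candidate set (from a univariate filter run on a disjoint
#' enrichment cohort) is held fixed across folds. With
#' \code{refit_filter = TRUE} the random-variance filter is additionally
#' refitted inside every fold (for single-cohort use, where the filter saw
#' the same samples).
#'
#' @param matrix genes x samples log2 matrix.
#' @param labels "case"/"control" per sample; n >= 4, both classes >= 2.
#' @param candidate_gene_ids candidate pool for RFE (ignored when
#'   \code{refit_filter = TRUE}, which filters from all rows).
#' @param target_n panel size; default 10.
#' @param method classifier type; default \code{"dlda"}.
#' @param cost SVM cost for RFE (and the \code{"svm"} classifier).
#' @param refit_filter refit the univariate filter within each fold.
#' @param alpha filter threshold used when \code{refit_filter = TRUE}.
#' @return object of class \code{cv_result}: per-sample predictions, the
#'   error rate \code{error_rate}, and the per-fold panels.
#' @export
loocv <- function(matrix, labels, candidate_gene_ids, target_n = 10,
                  method = "dlda", cost = 1, refit_filter = FALSE,
                  alpha = 0.05) {
  labels <- check_class_labels(labels)
  n <- ncol(matrix)
  if (n < 4) stop("need n >= 4 samples", call. = FALSE)
  preds <- character(n); scores <- numeric(n)
  panels <- vector("list", n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2 || min(table(tr_lab)) < 2) {
      stop("fold ", i, " leaves fewer than 2 samples in a class", call. = FALSE)
    }
    tr <- matrix[, -i, drop = FALSE]
    cand <- if (refit_filter) {
      st <- rvm_t_test(tr, tr_lab)
      sel <- select_features(st, alpha)
      if (length(sel) < target_n) {
        stop("fold ", i, ": filter retained fewer than target_n genes",
             call. = FALSE)
      }
      sel
    } else candidate_gene_ids
    panel <- svm_rfe(tr, tr_lab, cand, target_n = min(target_n, length(cand)),
                     cost = cost)
    fit <- panel_train(tr, tr_lab, panel, method = method, cost = cost)
    pr <- predict(fit, matrix[, i])
    preds[i] <- pr$class; scores[i] <- pr$score
    panels[[i]] <- panel
  }
  res <- list(predictions = data.frame(sample_id = colnames(matrix),
                                       true = labels, predicted = preds,
                                       score = scores, row.names = NULL,
                                       stringsAsFactors = FALSE),
              error_rate = mean(preds != labels), panels = panels,
              target_n = target_n, method = method)
  class(res) <- "cv_result"
  res
}

#' @export
print.cv_result <- function(x, ...) {
  n <- nrow(x$predictions)
  cat("Nested LOOCV (", toupper(x$method), ", ", x$target_n, "-gene panels): ",
      sum(x$predictions$predicted != x$predictions$true), "/", n,
      " misclassified, error rate ", signif(x$error_rate, 3), "\n", sep = "")
  invisible(x)
}

#' Permutation significance of the cross-validated error rate
#'
#' Repeats the full nested LOOCV (including in-fold RFE) for \code{B}
#' uniformly random permutations of the class labels; the p-value is the
#' plain proportion of permutations whose cross-validated error is no
#' greater than the observed one (ties count toward p, so p can be 0).
#' \code{plus_one = TRUE} switches to the (k+1)/(B+1) convention.
#'
#' @inheritParams loocv
#' @param B number of permutations (>= 1).
#' @param seed integer seed; fully determines the permutations.
#' @param plus_one use (k+1)/(B+1) instead of the plain proportion.
#' @return object of class \code{perm_result}: \code{e_obs},
#'   \code{e_perm} (length B), \code{p}, \code{B}, \code{seed}.
#' @export
permutation_test <- function(matrix, labels, candidate_gene_ids,
                             target_n = 10, method = "dlda", cost = 1,
                             refit_filter = FALSE, alpha = 0.05,
                             B = 1000, seed = 1L, plus_one = FALSE) {
  stopifnot(B >= 1)
  labels <- check_class_labels(labels)
  obs <- loocv(matrix, labels, candidate_gene_ids, target_n, method, cost,
               refit_filter, alpha)
  perms <- with_seed(seed, {
    lapply(seq_len(B), function(b) sample(labels))
  })
  e_perm <- vapply(perms, function(pl) {
    loocv(matrix, pl, candidate_gene_ids, target_n, method, cost,
          refit_filter, alpha)$error_rate
  }, numeric(1))
  k <- sum(e_perm <= obs$error_rate)
  p <- if (plus_one) (k + 1) / (B + 1) else k / B
  structure(list(e_obs = obs$error_rate, e_perm = e_perm, p = p, B = B,
                 seed = seed, scheme = "full_loocv", observed = obs),
            class = "perm_result")
}

#' Permutation significance of a frozen model's cohort error
#'
#' For a cohort scored by a frozen \code{gene_model} the predictions are
#' fixed; the class labels are permuted \code{B} times and the error of the
#' fixed predictions recomputed against each permutation. Because the error
#' under a label permutation depends only on how many truly-case samples land
#' among the predicted-case calls, \code{exact = TRUE} enumerates that
#' hypergeometric overlap distribution instead of sampling — exact p for
#' small cohorts.
#'
#' @param predictions predicted classes ("case"/"control") per sample.
#' @param labels true classes per sample.
#' @param B permutations when sampling.
#' @param seed integer seed (sampling mode).
#' @param exact enumerate the exact permutation distribution.
#' @param plus_one use (k+1)/(B+1) in sampling mode.
#' @return object of class \code{perm_result}.
#' @export
frozen_model_permutation <- function(predictions, labels, B = 1000, seed = 1L,
                                     exact = FALSE, plus_one = FALSE) {
  predictions <- check_class_labels(predictions)
  labels <- check_class_labels(labels)
  stopifnot(length(predictions) == length(labels))
  n <- length(labels)
  e_obs <- mean(predictions != labels)
  if (exact) {
    n1 <- sum(labels == "case")
    m <- sum(predictions == "case")
    correct_obs <- sum(predictions == labels)
    # under a uniform label permutation, X = #true-case among predicted-case
    # ~ Hypergeometric; #correct = (n - n1 - m) + 2X
    xs <- max(0, m - (n - n1)):min(m, n1)
    probs <- stats::dhyper(xs, n1, n - n1, m)
    correct_x <- (n - n1 - m) + 2 * xs
    p <- sum(probs[correct_x >= correct_obs])
    return(structure(list(e_obs = e_obs, e_perm = NULL, p = p, B = NA_integer_,
                          seed = NA_integer_, scheme = "frozen_exact"),
                     class = "perm_result"))
  }
  e_perm <- with_seed(seed, {
    vapply(seq_len(B), function(b) mean(predictions != sample(labels)),
           numeric(1))
  })
  k <- sum(e_perm <= e_obs)
  p <- if (plus_one) (k + 1) / (B + 1) else k / B
  structure(list(e_obs = e_obs, e_perm = e_perm, p = p, B = B, seed = seed,
                 scheme = "frozen_sampled"),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test (", x$scheme, "): observed error ",
      signif(x$e_obs, 3), sep = "")
  if (!is.na(x$B)) cat(", B = ", x$B, sep = "")
  cat(", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}
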