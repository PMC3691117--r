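#' Two-class confusion metrics with per-class correct counts
#'
#' Sensitivity is the fraction of case (patient) samples correctly called,
#' specificity the fraction of controls, overall the pooled fraction. Each is
#' also reported as a percent rounded half-up to integer (87.5\% prints as
#' 88\%); the raw ratios are always retained. An empty class leaves the
#' corresponding ratio missing (\code{NA}), never 0.
#'
#' @param predictions predicted classes ("case"/"control").
#' @param truth true classes, same length.
#' @return object of class \code{confusion_summary}.
#' @export
confusion_metrics <- function(predictions, truth) {
  predictions <- check_class_labels(predictions)
  truth <- check_class_labels(truth)
  stopifnot(length(predictions) == length(truth))
  n_case <- sum(truth == "case"); n_control <- sum(truth == "control")
  case_correct <- sum(truth == "case" & predictions == "case")
  control_correct <- sum(truth == "control" & predictions == "control")
  sens <- if (n_case > 0) case_correct / n_case else NA_real_
  spec <- if (n_control > 0) control_correct / n_control else NA_real_
  overall <- if (n_case + n_control > 0) {
    (case_correct + control_correct) / (n_case + n_control)
  } else NA_real_
  structure(list(n_case = n_case, case_correct = case_correct,
                 n_control = n_control, control_correct = control_correct,
                 sensitivity = sens, specificity = spec, overall = overall,
                 sensitivity_pct = percent_half_up(sens),
                 specificity_pct = percent_half_up(spec),
                 overall_pct = percent_half_up(overall)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  fmt <- function(pct) if (is.na(pct)) "NA" else paste0(pct, "%")
  cat("Confusion summary: ", x$case_correct, "/", x$n_case, " case, ",
      x$control_correct, "/", x$n_control, " control correct\n", sep = "")
  cat("  overall ", fmt(x$overall_pct), ", sensitivity ",
      fmt(x$sensitivity_pct), ", specificity ", fmt(x$specificity_pct),
      "\n", sep = "")
  invisible(x)
}

#' Apply a frozen model to one cohort
#'
#' Scores every sample of the named cohort with the frozen model (no
#' refitting) and summarizes the confusion against the annotated classes.
#'
#' @param model a \code{gene_model}.
#' @param matrix genes x samples log2 matrix.
#' @param annot sample annotation (\code{sample_id}, \code{class},
#'   \code{cohort}).
#' @param cohort cohort name to score.
#' @return list with \code{predictions} (data frame) and \code{summary}
#'   (\code{confusion_summary}; \code{NULL} for an empty cohort).
#' @export
predict_cohort <- function(model, matrix, annot, cohort) {
  sel <- annot[annot$cohort == cohort, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(list(predictions = data.frame(sample_id = character(0),
                                         class = character(0),
                                         score = numeric(0),
                                         tie = logical(0)),
                summary = NULL))
  }
  miss <- setdiff(model$gene_ids, rownames(matrix))
  if (length(miss)) stop("model genes missing from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pr <- predict(model, matrix[, sel$sample_id, drop = FALSE])
  list(predictions = pr,
       summary = confusion_metrics(pr$class, sel$class))
}

#' Concordance of class predictions between A and B replicates
#'
#' @param preds_a,preds_b named character vectors (subject -> predicted
#'   class); the subject sets must coincide.
#' @return fraction of subjects with identical A and B predictions.
#' @export
replicate_prediction_concordance <- function(preds_a, preds_b) {
  if (!setequal(names(preds_a), names(preds_b)) ||
      length(preds_a) != length(preds_b)) {
    stop("A and B predictions must cover the same subjects", call. = FALSE)
  }
  subjects <- names(preds_a)
  mean(preds_a[subjects] == preds_b[subjects])
}

#' Two-proportion chi-square (and Fisher) comparison
#'
#' Pearson chi-square on the 2x2 table \code{(k1, n1-k1; k2, n2-k2)},
#' optionally Yates-corrected, plus the two-sided Fisher exact p for the same
#' table. Degenerate margins give statistic 0 and p 1.
#'
#' @param k1,n1 successes and total in group 1.
#' @param k2,n2 successes and total in group 2.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list with \code{statistic}, \code{p}, \code{fisher_p},
#'   \code{table}.
#' @export
two_proportion_chi2 <- function(k1, n1, k2, n2, correct = FALSE) {
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2, n1 >= 1, n2 >= 1)
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p = 1, fisher_p = 1, table = tab))
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  fi <- stats::fisher.test(tab)
  list(statistic = unname(ch$statistic), p = ch$p.value,
       fisher_p = fi$p.value, table = tab)
}
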