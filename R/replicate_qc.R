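#' Thresholds for replicate-concordance quality control
#'
#' @param rho_min minimum Spearman correlation between an A/B pair (default
#'   0.985; a pair with rho below this fails the global-comparison check).
#' @param z_max maximum absolute standardized deviation of the control-gene
#'   log2 A-B difference (default 2.3 SD).
#' @param fail_count_to_drop number of failed checks (of 3) that triggers
#'   removal of the B sample (default 2).
#' @return object of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(rho_min = 0.985, z_max = 2.3, fail_count_to_drop = 2) {
  stopifnot(rho_min > 0, rho_min <= 1, z_max > 0,
            fail_count_to_drop >= 1, fail_count_to_drop <= 3)
  structure(list(rho_min = rho_min, z_max = z_max,
                 fail_count_to_drop = as.integer(fail_count_to_drop)),
            class = "qc_thresholds")
}

#' Spearman rank concordance of two expression profiles
#'
#' Spearman correlation with average ranks for ties. A constant vector makes
#' the correlation undefined; \code{NA} is returned and treated as a failed
#' check downstream.
#'
#' @param x_a,x_b numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or \code{NA} if undefined.
#' @export
spearman_concordance <- function(x_a, x_b) {
  if (length(x_a) != length(x_b) || length(x_a) < 3L) {
    stop("vectors must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x_a) == 0 || stats::sd(x_b) == 0) return(NA_real_)
  stats::cor(x_a, x_b, method = "spearman")
}

#' Do replicate pairs cluster together in the whole transcriptome?
#'
#' Under average-linkage hierarchical clustering, a pair A/B "clusters
#' together" exactly when the two samples are merged with each other before
#' either joins any other sample, i.e. when they are mutual nearest
#' neighbours under the inter-sample distance. That equivalent test is
#' applied directly. Distance is 1 - Pearson correlation of log2 profiles
#' (scale-free, standard for transcriptome clustering) or Euclidean.
#'
#' @param matrix genes x samples log2 matrix.
#' @param pairs data frame with columns \code{subject_id}, \code{A}, \code{B}
#'   (sample ids).
#' @param distance \code{"correlation"} (default) or \code{"euclidean"}.
#' @return named logical vector, one entry per subject.
#' @export
cluster_adjacency_check <- function(matrix, pairs,
                                    distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  ids <- colnames(matrix)
  miss <- setdiff(c(pairs$A, pairs$B), ids)
  if (length(miss)) stop("samples missing from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (ncol(matrix) < 3L) {
    warning("fewer than 3 samples; all pairs pass trivially")
    return(stats::setNames(rep(TRUE, nrow(pairs)), pairs$subject_id))
  }
  d <- if (distance == "correlation") {
    1 - stats::cor(matrix)
  } else {
    as.matrix(stats::dist(t(matrix)))
  }
  pass <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$A[k]; b <- pairs$B[k]
    dab <- d[a, b]
    others_a <- d[a, setdiff(ids, c(a, b))]
    others_b <- d[b, setdiff(ids, c(a, b))]
    pass[k] <- all(dab <= others_a) && all(dab <= others_b)
  }
  stats::setNames(pass, pairs$subject_id)
}

#' Control-gene replicate difference check
#'
#' Standardizes each pair's control-gene difference \eqn{d_i = \log_2 A -
#' \log_2 B} against the mean and sample SD (n-1 denominator) over all pairs;
#' a pair passes iff \eqn{|z_i| \le z_{max}}. With zero SD (or a single pair)
#' the check is degenerate and every pair passes.
#'
#' @param d numeric vector of per-pair control-gene log2 differences.
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @return data frame with columns \code{d}, \code{z}, \code{pass}.
#' @export
control_gene_check <- function(d, thresholds = qc_thresholds()) {
  if (length(d) < 2L) {
    warning("fewer than 2 pairs; control-gene check passes trivially")
    return(data.frame(d = d, z = rep(NA_real_, length(d)),
                      pass = rep(TRUE, length(d))))
  }
  s <- stats::sd(d)
  if (s == 0) {
    return(data.frame(d = d, z = rep(0, length(d)),
                      pass = rep(TRUE, length(d))))
  }
  z <- (d - mean(d)) / s
  data.frame(d = d, z = z, pass = abs(z) <= thresholds$z_max)
}

#' Assess technical-replicate quality and apply the 2-of-3 drop rule
#'
#' Runs the three replicate-concordance checks — transcriptome clustering
#' adjacency, global Spearman correlation (rho >= \code{rho_min}), and the
#' control-gene difference within \code{z_max} SD of the mean — for every A/B
#' pair in the annotation. A pair's B sample is dropped iff it fails at least
#' \code{fail_count_to_drop} of the three checks.
#'
#' @param matrix genes x samples log2 matrix.
#' @param annot sample annotation with \code{subject_id},
#'   \code{replicate_role}.
#' @param control_gene_id row name of the designated control gene; if absent
#'   from the matrix the check is marked not-run and counted as a pass (with a
#'   warning).
#' @param thresholds a \code{\link{qc_thresholds}} object.
#' @return object of class \code{qc_report}: a data frame of per-pair check
#'   outcomes and decisions, with the filtered annotation (dropped B samples
#'   removed) in attribute \code{"filtered_annot"}.
#' @export
assess_replicates <- function(matrix, annot, control_gene_id,
                              thresholds = qc_thresholds()) {
  a_rows <- annot[annot$replicate_role == "A", , drop = FALSE]
  b_rows <- annot[annot$replicate_role == "B", , drop = FALSE]
  subjects <- intersect(a_rows$subject_id, b_rows$subject_id)
  if (length(subjects) == 0L) stop("no A/B replicate pairs found", call. = FALSE)
  pairs <- data.frame(
    subject_id = subjects,
    A = a_rows$sample_id[match(subjects, a_rows$subject_id)],
    B = b_rows$sample_id[match(subjects, b_rows$subject_id)],
    stringsAsFactors = FALSE)

  cluster_pass <- cluster_adjacency_check(matrix, pairs)
  rho <- vapply(seq_len(nrow(pairs)), function(k) {
    spearman_concordance(matrix[, pairs$A[k]], matrix[, pairs$B[k]])
  }, numeric(1))
  rho_pass <- !is.na(rho) & rho >= thresholds$rho_min

  if (!control_gene_id %in% rownames(matrix)) {
    warning("control gene '", control_gene_id,
            "' not in matrix; check not run, counted as pass")
    ctrl <- data.frame(d = NA_real_, z = NA_real_,
                       pass = rep(TRUE, nrow(pairs)))
  } else {
    d <- matrix[control_gene_id, pairs$A] - matrix[control_gene_id, pairs$B]
    ctrl <- control_gene_check(as.numeric(d), thresholds)
  }

  n_fail <- (!cluster_pass) + (!rho_pass) + (!ctrl$pass)
  report <- data.frame(
    subject_id = pairs$subject_id,
    cluster_pass = as.logical(cluster_pass),
    rho = rho, rho_pass = rho_pass,
    control_d = ctrl$d, control_z = ctrl$z, control_pass = ctrl$pass,
    n_fail = as.integer(n_fail),
    decision = ifelse(n_fail >= thresholds$fail_count_to_drop,
                      "drop_B", "keep_B"),
    stringsAsFactors = FALSE)
  dropped <- pairs$B[report$decision == "drop_B"]
  filtered <- annot[!annot$sample_id %in% dropped, , drop = FALSE]
  structure(report, class = c("qc_report", "data.frame"),
            filtered_annot = filtered, thresholds = thresholds)
}

#' @export
print.qc_report <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("Replicate QC report: ", nrow(x), " A/B pairs\n", sep = "")
  cat(sprintf("  thresholds: rho >= %.3f, |z| <= %.1f, drop on >= %d fails\n",
              th$rho_min, th$z_max, th$fail_count_to_drop))
  cat("  dropped B samples: ", sum(x$decision == "drop_B"), "\n", sep = "")
  NextMethod()
  invisible(x)
}
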