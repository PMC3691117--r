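CLASSIFIERS <- c("dlda", "ccp", "nc", "knn1", "knn3", "svm")

# Extract the primal weight vector and bias of a linear e1071::svm fit,
# oriented so that positive decision values point toward "case".
svm_weights <- function(model, case_level = "case") {
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  # libsvm's +1 class is the first level it saw; flip if that is not "case"
  if (model$levels[1] != case_level) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

# Standardize columns (samples x genes) with given centers/scales; zero-sd
# genes are centred and left unscaled.
standardize_cols <- function(x, center, scale) {
  scale[scale == 0] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Train a fixed-panel expression classifier
#'
#' Fits one of six classical two-class expression classifiers on a fixed gene
#' panel: diagonal linear discriminant analysis (\code{"dlda"}: per-gene
#' pooled-variance-scaled distance to class centroids), compound covariate
#' predictor (\code{"ccp"}: pooled-t-weighted linear score thresholded at the
#' midpoint of the class mean scores), nearest centroid (\code{"nc"}),
#' k-nearest neighbours (\code{"knn1"}, \code{"knn3"}; Euclidean), or a linear
#' soft-margin SVM (\code{"svm"}, fitted on per-gene standardized data).
#'
#' Deterministic conventions: panels and training samples are used in the
#' order given; prediction ties go to \code{"control"}; a zero pooled variance
#' in DLDA is replaced by the smallest positive pooled variance in the panel.
#'
#' @param matrix genes x samples log2 training matrix.
#' @param labels "case"/"control" per sample; both classes non-empty.
#' @param gene_ids the panel (rows of \code{matrix}); order preserved.
#' @param method one of \code{"dlda"}, \code{"ccp"}, \code{"nc"},
#'   \code{"knn1"}, \code{"knn3"}, \code{"svm"}.
#' @param cost soft-margin cost for the SVM (default 1).
#' @return object of class \code{gene_model}.
#' @export
panel_train <- function(matrix, labels, gene_ids, method = "dlda", cost = 1) {
  method <- match.arg(method, CLASSIFIERS)
  labels <- check_class_labels(labels)
  miss <- setdiff(gene_ids, rownames(matrix))
  if (length(miss)) stop("genes missing from matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(gene_ids)) stop("panel ids must be unique", call. = FALSE)
  if (!all(c("case", "control") %in% labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  x <- matrix[gene_ids, , drop = FALSE]
  i1 <- labels == "case"; i2 <- labels == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  cent_case <- rowMeans(x[, i1, drop = FALSE])
  cent_control <- rowMeans(x[, i2, drop = FALSE])
  model <- list(gene_ids = gene_ids, method = method,
                centroid_case = cent_case, centroid_control = cent_control,
                n_case = n1, n_control = n2)

  if (method %in% c("dlda", "ccp")) {
    if (n1 < 2 || n2 < 2) stop("dlda/ccp need >= 2 samples per class", call. = FALSE)
    v1 <- apply(x[, i1, drop = FALSE], 1, stats::var)
    v2 <- apply(x[, i2, drop = FALSE], 1, stats::var)
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (any(s2 == 0)) {
      pos <- s2[s2 > 0]
      if (!length(pos)) stop("all panel genes have zero pooled variance", call. = FALSE)
      warning("zero pooled variance for ", sum(s2 == 0),
              " gene(s); substituted smallest positive panel variance")
      s2[s2 == 0] <- min(pos)
    }
    model$pooled_var <- s2
    if (method == "ccp") {
      tw <- (cent_case - cent_control) / sqrt(s2 * (1 / n1 + 1 / n2))
      model$t_weights <- tw
      score_case <- sum(tw * cent_case)
      score_control <- sum(tw * cent_control)
      model$threshold <- (score_case + score_control) / 2
    }
  } else if (method %in% c("knn1", "knn3")) {
    model$k <- if (method == "knn1") 1L else 3L
    model$train_x <- x
    model$train_labels <- labels
  } else if (method == "svm") {
    center <- rowMeans(x)
    scale <- apply(x, 1, stats::sd)
    xs <- standardize_cols(t(x), center, scale)
    fit <- e1071::svm(xs, factor(labels, levels = c("case", "control")),
                      kernel = "linear", cost = cost, scale = FALSE)
    wb <- svm_weights(fit)
    model$center <- center
    model$scale <- scale
    model$w <- stats::setNames(wb$w, gene_ids)
    model$bias <- wb$b
    model$cost <- cost
  }
  class(model) <- "gene_model"
  model
}

# Per-type decision scores; positive score => "case". One sample (named
# numeric vector over at least the panel genes) at a time.
score_one <- function(model, xv) {
  miss <- setdiff(model$gene_ids, names(xv))
  if (length(miss)) stop("sample is missing panel gene(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  xv <- xv[model$gene_ids]
  switch(model$method,
    dlda = {
      d_case <- sum((xv - model$centroid_case)^2 / model$pooled_var)
      d_control <- sum((xv - model$centroid_control)^2 / model$pooled_var)
      d_control - d_case
    },
    nc = {
      d_case <- sum((xv - model$centroid_case)^2)
      d_control <- sum((xv - model$centroid_control)^2)
      d_control - d_case
    },
    ccp = sum(model$t_weights * xv) - model$threshold,
    svm = sum(model$w * ((xv - model$center) / ifelse(model$scale == 0, 1, model$scale))) +
      model$bias,
    knn1 = knn_score(model, xv),
    knn3 = knn_score(model, xv)
  )
}

# KNN "score": (votes for case - votes for control) / k; distance ties broken
# by training-sample index (stable order of which neighbours are counted).
knn_score <- function(model, xv) {
  d2 <- colSums((model$train_x - xv)^2)
  ord <- order(d2, seq_along(d2))
  nb <- model$train_labels[ord[seq_len(model$k)]]
  (sum(nb == "case") - sum(nb == "control")) / model$k
}

#' Predict classes with a trained gene model
#'
#' Applies the frozen model to new samples; no parameter is refitted. The
#' decision score is signed with \code{"case"} positive; an exactly zero score
#' is a tie and is resolved to \code{"control"} (the negative call), with the
#' tie flag set.
#'
#' @param object a \code{gene_model}.
#' @param newdata genes x samples matrix (or a named vector for one sample).
#' @param ... unused.
#' @return data frame with \code{sample_id}, \code{class}, \code{score},
#'   \code{tie}.
#' @export
predict.gene_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample_1"))
  }
  ids <- colnames(newdata)
  if (is.null(ids)) ids <- paste0("sample_", seq_len(ncol(newdata)))
  scores <- vapply(seq_len(ncol(newdata)), function(j) {
    score_one(object, stats::setNames(newdata[, j], rownames(newdata)))
  }, numeric(1))
  data.frame(sample_id = ids,
             class = ifelse(scores > 0, "case", "control"),
             score = scores, tie = scores == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene-panel classifier (", toupper(x$method), "), ",
      length(x$gene_ids), " genes\n", sep = "")
  cat("  trained on ", x$n_case, " case / ", x$n_control, " control samples\n",
      sep = "")
  cat("  panel: ", paste(utils::head(x$gene_ids, 10), collapse = ", "),
      if (length(x$gene_ids) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
coef.gene_model <- function(object, ...) {
  switch(object$method,
    ccp = object$t_weights,
    svm = object$w,
    object$centroid_case - object$centroid_control)
}

#' @export
summary.gene_model <- function(object, ...) {
  print(object)
  tab <- data.frame(gene_id = object$gene_ids,
                    centroid_case = object$centroid_case,
                    centroid_control = object$centroid_control,
                    weight = coef(object), row.names = NULL)
  print(utils::head(tab, 20))
  invisible(tab)
}

#' Serialize / restore a gene model as JSON
#'
#' @param model a \code{gene_model}.
#' @param path file path.
#' @return \code{read_gene_model} returns the restored \code{gene_model}.
#' @export
write_gene_model <- function(model, path) {
  obj <- unclass(model)
  obj$train_x <- if (!is.null(obj$train_x)) {
    list(values = unname(obj$train_x), gene_ids = rownames(obj$train_x),
         sample_ids = colnames(obj$train_x))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("centroid_case", "centroid_control", "pooled_var", "t_weights",
              "center", "scale", "w")) {
    if (!is.null(obj[[f]])) obj[[f]] <- stats::setNames(as.numeric(obj[[f]]),
                                                        obj$gene_ids)
  }
  if (!is.null(obj$train_x) && is.list(obj$train_x)) {
    tx <- obj$train_x
    m <- matrix(unlist(tx$values), nrow = length(tx$gene_ids),
                dimnames = list(tx$gene_ids, tx$sample_ids))
    obj$train_x <- m
  }
  class(obj) <- "gene_model"
  obj
}

#' SVM recursive feature elimination to a fixed panel size
#'
#' Iteratively fits a linear soft-margin SVM on per-gene standardized training
#' data over the surviving genes, ranks genes by squared weight \eqn{w_g^2},
#' and eliminates the lowest-ranked block until exactly \code{target_n}
#' survive. While more than \code{2 target_n} genes survive, 10\% (rounded up)
#' are removed per iteration; thereafter one per iteration
#' (\code{strict = TRUE} forces one-at-a-time throughout). Weight ties are
#' broken by candidate index (the lower-indexed gene survives). Survivors are
#' returned ranked by final \eqn{|w|}, descending.
#'
#' @param matrix genes x samples log2 matrix.
#' @param labels "case"/"control" per sample, both classes >= 2.
#' @param candidate_gene_ids candidate pool (rows of \code{matrix}).
#' @param target_n panel size to retain; default 10.
#' @param cost SVM cost; default 1.
#' @param strict eliminate strictly one gene per iteration.
#' @return character vector of \code{target_n} gene ids.
#' @export
svm_rfe <- function(matrix, labels, candidate_gene_ids, target_n = 10,
                    cost = 1, strict = FALSE) {
  labels <- check_class_labels(labels)
  if (target_n > length(candidate_gene_ids)) {
    stop("target_n exceeds number of candidates", call. = FALSE)
  }
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2) {
    stop("both classes need >= 2 samples", call. = FALSE)
  }
  surv <- candidate_gene_ids
  y <- factor(labels, levels = c("case", "control"))
  xt <- t(matrix[candidate_gene_ids, , drop = FALSE])  # samples x genes
  center <- colMeans(xt)
  scale <- apply(xt, 2, stats::sd)
  xt <- standardize_cols(xt, center, scale)
  idx_of <- stats::setNames(seq_along(candidate_gene_ids), candidate_gene_ids)
  while (length(surv) > target_n) {
    fit <- e1071::svm(xt[, surv, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- svm_weights(fit)$w
    n_drop <- if (!strict && length(surv) > 2 * target_n) {
      min(ceiling(0.1 * length(surv)), length(surv) - target_n)
    } else 1L
    # ascending w^2; among ties the higher original index is dropped first
    ord <- order(w^2, -idx_of[surv])
    drop <- surv[ord[seq_len(n_drop)]]
    surv <- setdiff(surv, drop)
  }
  # final ranking by |w| from a fit on the survivors
  fit <- e1071::svm(xt[, surv, drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- svm_weights(fit)$w
  surv[order(-abs(w), idx_of[surv])]
}
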