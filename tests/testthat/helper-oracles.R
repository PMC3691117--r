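# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from the definitions, not by calling the
# package's own code paths.

# Iterative median-sweep polish: rows then columns, until the total absolute
# residual stabilizes. Returns per-column summaries overall + col effect.
oracle_median_polish <- function(m, max_iter = 200, tol = 1e-12) {
  overall <- 0
  row_eff <- rep(0, nrow(m))
  col_eff <- rep(0, ncol(m))
  r <- m
  last <- Inf
  for (it in seq_len(max_iter)) {
    rm_ <- apply(r, 1, median)
    row_eff <- row_eff + rm_
    r <- sweep(r, 1, rm_)
    cm <- median(row_eff)
    overall <- overall + cm
    row_eff <- row_eff - cm
    cm_ <- apply(r, 2, median)
    col_eff <- col_eff + cm_
    r <- sweep(r, 2, cm_)
    rm2 <- median(col_eff)
    overall <- overall + rm2
    col_eff <- col_eff - rm2
    s <- sum(abs(r))
    if (abs(last - s) <= tol * max(s, 1)) break
    last <- s
  }
  list(overall = overall, col = col_eff, row = row_eff, residuals = r,
       summary = overall + col_eff)
}

oracle_dlda <- function(cent_case, cent_control, s2, x) {
  d1 <- sum((x - cent_case)^2 / s2)
  d2 <- sum((x - cent_control)^2 / s2)
  if (d1 < d2) "case" else "control"
}

oracle_nc <- function(cent_case, cent_control, x) {
  d1 <- sqrt(sum((x - cent_case)^2))
  d2 <- sqrt(sum((x - cent_control)^2))
  if (d1 < d2) "case" else "control"
}

# CCP from scratch: pooled-t weights, score, midpoint threshold.
oracle_ccp <- function(train, labels, x) {
  i1 <- labels == "case"; i2 <- labels == "control"
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- rowMeans(train[, i1, drop = FALSE])
  m2 <- rowMeans(train[, i2, drop = FALSE])
  v1 <- apply(train[, i1, drop = FALSE], 1, var)
  v2 <- apply(train[, i2, drop = FALSE], 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tw <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  ct <- (sum(tw * m1) + sum(tw * m2)) / 2
  sc <- sum(tw * x)
  if (sc > ct) "case" else "control"
}

oracle_knn <- function(train, labels, x, k) {
  d <- sqrt(colSums((train - x)^2))
  ord <- order(d, seq_along(d))
  nb <- labels[ord[seq_len(k)]]
  if (sum(nb == "case") > k / 2) "case" else "control"
}

# Deliberately NON-nested LOOCV: panel selected once on ALL samples, only
# the classifier is refit per fold. Exists only to demonstrate selection bias.
nonnested_loocv_error <- function(matrix, labels, alpha = 0.05, target_n = 10) {
  st <- rvm_t_test(matrix, labels)
  cand <- select_features(st, alpha)
  panel <- svm_rfe(matrix, labels, cand, target_n = target_n)
  preds <- vapply(seq_len(ncol(matrix)), function(i) {
    fit <- panel_train(matrix[, -i, drop = FALSE], labels[-i], panel)
    predict(fit, matrix[, i])$class
  }, "")
  mean(preds != labels)
}

# Small two-class matrix with planted standardized effects, unit variance.
make_planted_matrix <- function(n_genes, n_case, n_control, planted_idx,
                                effect, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_case + n_control)), n_genes)
  m[planted_idx, seq_len(n_case)] <- m[planted_idx, seq_len(n_case)] + effect
  rownames(m) <- sprintf("g%04d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  list(matrix = m, labels = rep(c("case", "control"), c(n_case, n_control)))
}
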