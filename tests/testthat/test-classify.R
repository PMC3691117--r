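test_that("all classifier types separate an easy two-gene problem", {
  set.seed(5)
  m <- rbind(g1 = c(rnorm(6, 5, 0.1), rnorm(6, 9, 0.1)),
             g2 = c(rnorm(6, 9, 0.1), rnorm(6, 5, 0.1)))
  colnames(m) <- paste0("s", 1:12)
  labels <- rep(c("case", "control"), each = 6)
  for (meth in c("dlda", "ccp", "nc", "knn1", "knn3", "svm")) {
    fit <- panel_train(m, labels, c("g1", "g2"), method = meth)
    pr <- predict(fit, m)
    expect_identical(pr$class, labels)
  }
})

test_that("training parameters match a naive two-pass oracle", {
  set.seed(6)
  m <- matrix(rnorm(8 * 9), 8, dimnames = list(paste0("g", 1:8),
                                               paste0("s", 1:9)))
  labels <- c(rep("case", 4), rep("control", 5))
  fit <- panel_train(m, labels, rownames(m), method = "dlda")
  for (g in rownames(m)) {
    x1 <- m[g, labels == "case"]; x2 <- m[g, labels == "control"]
    expect_equal(fit$centroid_case[[g]], mean(x1), tolerance = 1e-12)
    expect_equal(fit$centroid_control[[g]], mean(x2), tolerance = 1e-12)
    expect_equal(fit$pooled_var[[g]],
                 (3 * var(x1) + 4 * var(x2)) / 7, tolerance = 1e-12)
  }
})

test_that("predictions match brute-force oracles on 100 random instances", {
  set.seed(7)
  for (i in 1:100) {
    ng <- sample(2:6, 1)
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    m <- matrix(rnorm(ng * (n1 + n2), sd = 2), ng)
    rownames(m) <- paste0("g", seq_len(ng))
    colnames(m) <- paste0("s", seq_len(n1 + n2))
    labels <- rep(c("case", "control"), c(n1, n2))
    x <- rnorm(ng, sd = 2); names(x) <- rownames(m)

    dl <- panel_train(m, labels, rownames(m), "dlda")
    expect_identical(predict(dl, x)$class,
                     oracle_dlda(dl$centroid_case, dl$centroid_control,
                                 dl$pooled_var, x))
    nc <- panel_train(m, labels, rownames(m), "nc")
    expect_identical(predict(nc, x)$class,
                     oracle_nc(nc$centroid_case, nc$centroid_control, x))
    cc <- panel_train(m, labels, rownames(m), "ccp")
    expect_identical(predict(cc, x)$class, oracle_ccp(m, labels, x))
    for (k in c(1, 3)) {
      kn <- panel_train(m, labels, rownames(m), paste0("knn", k))
      expect_identical(predict(kn, x)$class, oracle_knn(m, labels, x, k))
    }
  }
})

test_that("deterministic tie-breaks resolve to control and are flagged", {
  m <- rbind(g1 = c(0, 0, 2, 2), g2 = c(0, 0, 2, 2)) + 0
  m[1, ] <- m[1, ] + c(-0.1, 0.1, -0.1, 0.1)
  m[2, ] <- m[2, ] + c(0.1, -0.1, 0.1, -0.1) # nonzero pooled variances
  colnames(m) <- paste0("s", 1:4)
  labels <- c("case", "case", "control", "control")
  fit <- panel_train(m, labels, c("g1", "g2"), "dlda")
  # midpoint of symmetric centroids: exactly equidistant
  x <- (fit$centroid_case + fit$centroid_control) / 2
  pr <- predict(fit, x)
  expect_identical(pr$class, "control")
  expect_true(pr$tie)
  nc <- panel_train(m, labels, c("g1", "g2"), "nc")
  prn <- predict(nc, (nc$centroid_case + nc$centroid_control) / 2)
  expect_identical(prn$class, "control")
  expect_true(prn$tie)
})

test_that("CCP on one gene reduces to a sign-weighted midpoint threshold", {
  set.seed(9)
  m <- matrix(c(rnorm(5, 8), rnorm(5, 6)), 1,
              dimnames = list("g1", paste0("s", 1:10)))
  labels <- rep(c("case", "control"), each = 5)
  fit <- panel_train(m, labels, "g1", "ccp")
  mid <- (mean(m[1, 1:5]) + mean(m[1, 6:10])) / 2
  for (v in seq(5, 9, by = 0.25)) {
    x <- c(g1 = v)
    expected <- if (sign(fit$t_weights) * (v - mid) > 0) "case" else "control"
    expect_identical(predict(fit, x)$class, expected)
  }
})

test_that("KNN1 recalls a training point's own label", {
  set.seed(10)
  m <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  labels <- rep(c("case", "control"), 5)
  fit <- panel_train(m, labels, rownames(m), "knn1")
  for (j in 1:10) expect_identical(predict(fit, m[, j])$class, labels[j])
})

test_that("DLDA and NC coincide when pooled variances are equal", {
  m <- rbind(g1 = c(0, 1, 4, 5), g2 = c(1, 0, 5, 4)) # equal pooled variances
  colnames(m) <- paste0("s", 1:4)
  labels <- c("case", "case", "control", "control")
  dl <- panel_train(m, labels, c("g1", "g2"), "dlda")
  nc <- panel_train(m, labels, c("g1", "g2"), "nc")
  set.seed(11)
  for (i in 1:20) {
    x <- c(g1 = rnorm(1, 2.5, 2), g2 = rnorm(1, 2.5, 2))
    expect_identical(predict(dl, x)$class, predict(nc, x)$class)
  }
})

test_that("models are invariant to training sample order", {
  set.seed(12)
  m <- matrix(rnorm(60), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
  labels <- rep(c("case", "control"), each = 6)
  perm <- sample(12)
  for (meth in c("dlda", "ccp", "nc")) {
    f1 <- panel_train(m, labels, rownames(m), meth)
    f2 <- panel_train(m[, perm], labels[perm], rownames(m), meth)
    expect_equal(f1$centroid_case, f2$centroid_case, tolerance = 1e-12)
    if (meth == "ccp") expect_equal(f1$t_weights, f2$t_weights,
                                    tolerance = 1e-12)
  }
})

test_that("zero-variance panel genes are substituted, not fatal", {
  m <- rbind(g1 = c(1, 1, 1, 1, 2, 2, 2, 2), g2 = c(1, 2, 3, 4, 5, 6, 7, 8))
  colnames(m) <- paste0("s", 1:8)
  labels <- rep(c("case", "control"), each = 4)
  expect_warning(fit <- panel_train(m, labels, c("g1", "g2"), "dlda"),
                 "zero pooled variance")
  expect_equal(unname(fit$pooled_var["g1"]), unname(fit$pooled_var["g2"]))
})

test_that("prediction on a sample missing a panel gene names the gene", {
  m <- rbind(g1 = c(1, 2, 5, 6), g2 = c(2, 1, 6, 5))
  colnames(m) <- paste0("s", 1:4)
  fit <- panel_train(m, c("case", "case", "control", "control"),
                     c("g1", "g2"), "nc")
  expect_error(predict(fit, c(g1 = 1)), "g2")
})

test_that("RFE keeps planted strong genes, is deterministic, and handles edges", {
  # target equals candidate count: unchanged
  set.seed(13)
  m <- matrix(rnorm(6 * 10), 6, dimnames = list(paste0("g", 1:6),
                                                paste0("s", 1:10)))
  labels <- rep(c("case", "control"), each = 5)
  expect_setequal(svm_rfe(m, labels, rownames(m), target_n = 6), rownames(m))
  # rerun equality
  r1 <- svm_rfe(m, labels, rownames(m), target_n = 3)
  r2 <- svm_rfe(m, labels, rownames(m), target_n = 3)
  expect_identical(r1, r2)
  # duplicated gene rows: deterministic elimination
  md <- rbind(m, gdup = m[1, ])
  d1 <- svm_rfe(md, labels, rownames(md), target_n = 3)
  d2 <- svm_rfe(md, labels, rownames(md), target_n = 3)
  expect_identical(d1, d2)
  # planted recovery: 2 strong genes among 98 nulls
  wins <- 0L
  for (s in 1:20) {
    dat <- make_planted_matrix(100, 20, 20, planted_idx = c(5, 50),
                               effect = 3, seed = 1300 + s)
    panel <- svm_rfe(dat$matrix, dat$labels, rownames(dat$matrix),
                     target_n = 10)
    if (all(c("g0005", "g0050") %in% panel)) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})

test_that("the model-size sweep over published panel sizes runs cleanly", {
  dat <- make_planted_matrix(60, 10, 10, planted_idx = 1:5, effect = 2,
                             seed = 99)
  for (n in c(5, 15, 20, 25, 30, 35, 40)) {
    panel <- svm_rfe(dat$matrix, dat$labels, rownames(dat$matrix),
                     target_n = n)
    expect_length(panel, n)
  }
})

test_that("a gene model survives a JSON round trip", {
  set.seed(14)
  m <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  labels <- rep(c("case", "control"), each = 5)
  x <- rnorm(5); names(x) <- rownames(m)
  for (meth in c("dlda", "ccp", "knn3", "svm")) {
    fit <- panel_train(m, labels, rownames(m), meth)
    path <- tempfile(fileext = ".json")
    write_gene_model(fit, path)
    back <- read_gene_model(path)
    expect_identical(predict(fit, x)$class, predict(back, x)$class)
    expect_equal(predict(fit, x)$score, predict(back, x)$score,
                 tolerance = 1e-10)
  }
})
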